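test_that("an isolated residue is fully exposed and a caged residue fully buried", {
  iso <- structure_model(tibble::tibble(
    chain = "A", resno = 1L, insert = NA_character_, resname = "ALA",
    atom = c("CA", "CB"), element = "C", x = c(0, 1.5), y = 0, z = 0))
  expect_gte(relative_sasa(iso)$rel_sasa, 0.9)

  # cage of 60 pseudo-carbon atoms on a 4-Angstrom shell
  pts <- 4 * fvhumanize:::sphere_points(60)
  caged <- structure_model(dplyr::bind_rows(
    tibble::tibble(chain = "A", resno = 1L, insert = NA_character_,
                   resname = "GLY", atom = "CA", element = "C",
                   x = 0, y = 0, z = 0),
    tibble::tibble(chain = "A", resno = 3L, insert = NA_character_,
                   resname = "LEU", atom = paste0("CD", seq_len(60)),
                   element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3])))
  rs <- relative_sasa(caged)
  expect_lte(rs$rel_sasa[rs$resno == 1], 0.05)
})

test_that("two-sphere SASA matches the closed-form spherical-cap area within 2%", {
  r1 <- 1.70 + 1.4; r2 <- 1.52 + 1.4   # C and O expanded radii
  for (d in c(3.0, 4.0, 5.0)) {
    m <- structure_model(tibble::tibble(
      chain = "A", resno = c(1L, 3L), insert = NA_character_,
      resname = c("GLY", "GLY"), atom = c("CA", "O"), element = c("C", "O"),
      x = c(0, d), y = 0, z = 0))
    got <- atom_sasa(m, n_points = 960)$sasa
    # analytic buried cap: h = r1 - (d^2 + r1^2 - r2^2) / (2 d)
    cap <- function(r_self, r_other) {
      h <- r_self - (d^2 + r_self^2 - r_other^2) / (2 * d)
      h <- min(max(h, 0), 2 * r_self)
      4 * pi * r_self^2 - 2 * pi * r_self * h
    }
    expect_equal(got[1], cap(r1, r2), tolerance = 0.02)
    expect_equal(got[2], cap(r2, r1), tolerance = 0.02)
  }
})

test_that("unknown residue names are skipped with a warning in relative SASA", {
  m <- structure_model(tibble::tibble(
    chain = "A", resno = c(1L, 3L), insert = NA_character_,
    resname = c("ALA", "XYZ"), atom = "CA", element = "C",
    x = c(0, 30), y = 0, z = 0))
  expect_warning(rs <- relative_sasa(m), "XYZ")
  expect_identical(rs$resname, "ALA")
})

mock_world <- function(seed, separation = 0) {
  pool <- gen_germline_pool(2, 0.85, seed = seed)
  parent <- gen_parent_fv(pool, fr_mutation_rate = 0.05, seed = seed)
  rmH <- segment_regions(number_chain(parent$heavy, "heavy"))
  rmL <- segment_regions(number_chain(parent$light, "kappa"))
  mock <- gen_fv_mock_structure(rmH, rmL, seed = seed,
                                chain_separation = separation)
  c(mock, list(parent = parent, rmH = rmH, rmL = rmL, pool = pool))
}

test_that("classification recovers the mock structure's planted truth exactly", {
  w <- mock_world(71)
  asg <- classify_residues(w$model, w$regions)
  m <- dplyr::inner_join(asg, w$truth, by = c("chain", "resno"),
                         suffix = c("", ".truth"))
  expect_identical(nrow(m), nrow(w$truth))
  expect_identical(m$type1, m$type1.truth)
  expect_identical(m$type2, m$type2.truth)
  expect_identical(m$type3, m$type3.truth)
  # evidence consistency: every Type 3 flag cites an interaction record
  expect_true(all(vapply(m$evidence[m$type3], nrow, 1L) > 0))
  # the planted Type 3 evidence is the constructed hydrogen bond
  ev <- m$evidence[m$type3][[1]]
  expect_true("hbond" %in% ev$class)
  expect_equal(min(ev$distance[ev$class == "hbond"]), 3.2, tolerance = 1e-6)
})

test_that("chains separated by 50 Angstrom yield zero Type 1 flags", {
  w <- mock_world(72, separation = 50)
  asg <- classify_residues(w$model, w$regions)
  expect_identical(sum(asg$type1), 0L)
})

test_that("classification is invariant to chain supply order and monotone in thresholds", {
  w <- mock_world(73)
  asg <- classify_residues(w$model, w$regions)
  flipped <- w$model[order(match(w$model$chain, c("L", "H"))), ]
  asg2 <- classify_residues(structure_model(flipped, label = "flipped"),
                            w$regions)
  for (col in c("chain", "resno", "type1", "type2", "type3")) {
    expect_identical(asg[[col]], asg2[[col]])
  }
  # widening every threshold never shrinks the flagged sets
  wide <- classify_residues(w$model, w$regions, d_interface = 6.5,
                            d_near = 9.0, r_buried = 0.6)
  for (ty in c("type1", "type2", "type3")) {
    expect_true(all(!asg[[ty]] | wide[[ty]]))
  }
})

test_that("orphan residues and wrong chain counts raise mapping errors", {
  w <- mock_world(74)
  expect_error(classify_residues(w$model, w$regions[-5, ]),
               class = "fvh_mapping_error")
  single <- structure_model(w$model[w$model$chain == "H", ], label = "single")
  expect_error(classify_residues(single, w$regions),
               class = "fvh_mapping_error")
})

test_that("proposed back mutations are exactly the flagged framework differences", {
  w <- mock_world(75)
  ncH <- number_chain(w$parent$heavy, "heavy")
  sel <- select_germline_per_fr(list(w$rmH, w$rmL), w$pool)
  g <- graft(w$rmH, sel)
  asg <- classify_residues(w$model, w$regions)

  cand <- propose_back_mutations(ncH, g, asg, "H")
  gt <- tidy(g)
  diffs <- which(startsWith(gt$region, "FR") & gt$aa != ncH$aa)
  flagged <- asg$resno[asg$chain == "H" & (asg$type1 | asg$type2 | asg$type3)]
  expect_setequal(cand$position, gt$position[intersect(diffs, flagged)])
  expect_true(all(cand$installed == ncH$aa[match(cand$position, ncH$position)]))
  # candidates are a subset of parent/graft differences
  expect_true(all(cand$position %in% gt$position[diffs]))

  # graft identical to parent -> empty list
  parent0 <- gen_parent_fv(w$pool, fr_mutation_rate = 0, seed = 75)
  rmH0 <- segment_regions(number_chain(parent0$heavy, "heavy"))
  rmL0 <- segment_regions(number_chain(parent0$light, "kappa"))
  sel0 <- select_germline_per_fr(list(rmH0, rmL0), w$pool)
  g0 <- graft(rmH0, sel0)
  mock0 <- gen_fv_mock_structure(rmH0, rmL0, seed = 75)
  asg0 <- classify_residues(mock0$model, mock0$regions)
  cand0 <- propose_back_mutations(number_chain(parent0$heavy, "heavy"), g0,
                                  asg0, "H")
  expect_identical(nrow(cand0), 0L)
})

test_that("a planted difference at a flagged position is proposed; an unflagged one is not", {
  w <- mock_world(76)
  ncH <- number_chain(w$parent$heavy, "heavy")
  asg <- classify_residues(w$model, w$regions)
  t3 <- w$truth[w$truth$type3 & w$truth$chain == "H", ]
  never <- w$truth[!(w$truth$type1 | w$truth$type2 | w$truth$type3) &
                     w$truth$chain == "H" & w$truth$region == "FR4", ][1, ]

  # a graft equal to the parent except at the Type-3 site and one unflagged site
  gt0 <- tibble::tibble(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    sequence = w$rmH$sequence, origin = "synthetic")
  chars <- strsplit(w$parent$heavy, "")[[1]]
  for (idx in c(t3$resno, never$resno)) {
    chars[idx] <- if (chars[idx] == "A") "C" else "A"
  }
  lens <- w$rmH$length
  starts <- cumsum(c(1, lens[-7]))
  gt0$sequence <- vapply(seq_len(7), function(k)
    paste(chars[starts[k]:(starts[k] + lens[k] - 1)], collapse = ""), "")
  g <- fv_design(gt0, "heavy", "imgt")

  cand <- propose_back_mutations(ncH, g, asg, "H")
  expect_identical(cand$position, g$position[t3$resno])
  expect_true(cand$type3[1])
  expect_false(never$resno %in% match(cand$position, g$position))
})
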