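two_atoms <- function(resname_a, atom_a, resname_b, atom_b, d, resno_b = 5L) {
  structure_model(tibble::tibble(
    chain = "A", resno = c(1L, resno_b), insert = NA_character_,
    resname = c(resname_a, resname_b), atom = c(atom_a, atom_b),
    element = toupper(substr(gsub("^[0-9]+", "", c(atom_a, atom_b)), 1, 1)),
    x = c(0, d), y = 0, z = 0
  ))
}

test_that("hydrogen bonds follow the 3.5-Angstrom N/O rule with adjacency exclusion", {
  expect_identical(nrow(hydrogen_bonds(two_atoms("GLY", "N", "SER", "O", 3.40))), 1L)
  expect_identical(nrow(hydrogen_bonds(two_atoms("GLY", "N", "SER", "O", 3.60))), 0L)
  # peptide-bond neighbors: backbone N-O of adjacent residues is suppressed
  adj <- two_atoms("GLY", "O", "GLY", "N", 2.3, resno_b = 2L)
  expect_identical(nrow(hydrogen_bonds(adj)), 0L)
  expect_identical(nrow(hydrogen_bonds(adj, exclude_adjacent = FALSE)), 1L)
  # side-chain N/O of adjacent residues still counts
  side <- two_atoms("SER", "OG", "LYS", "NZ", 3.0, resno_b = 2L)
  expect_identical(nrow(hydrogen_bonds(side)), 1L)
})

test_that("hydrophobic contacts exclude alpha carbons and non-hydrophobic residues", {
  expect_identical(nrow(hydrophobic_contacts(two_atoms("LEU", "CD1", "VAL", "CG1", 4.8))), 1L)
  expect_identical(nrow(hydrophobic_contacts(two_atoms("LEU", "CA", "VAL", "CA", 4.0))), 0L)
  expect_identical(nrow(hydrophobic_contacts(two_atoms("SER", "CB", "LEU", "CD1", 4.0))), 0L)
  expect_identical(nrow(hydrophobic_contacts(two_atoms("LEU", "CD1", "VAL", "CG1", 5.2))), 0L)
})

test_that("salt bridges pair opposite charges only, within 4.0 Angstrom", {
  expect_identical(nrow(salt_bridges(two_atoms("LYS", "NZ", "ASP", "OD1", 3.8))), 1L)
  expect_identical(nrow(salt_bridges(two_atoms("ARG", "NH1", "GLU", "OE1", 4.2))), 0L)
  expect_identical(nrow(salt_bridges(two_atoms("LYS", "NZ", "ARG", "NH1", 3.0))), 0L)
  # histidine counts as basic
  expect_identical(nrow(salt_bridges(two_atoms("HIS", "NE2", "GLU", "OE2", 3.9))), 1L)
})

phe_ring <- function(resno, center) {
  th <- seq(0, 300, by = 60) * pi / 180
  tibble::tibble(chain = "A", resno = resno, insert = NA_character_,
                 resname = "PHE",
                 atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                 element = "C",
                 x = center[1] + 1.39 * cos(th), y = center[2],
                 z = center[3] + 1.39 * sin(th))
}

test_that("pi stacking uses ring centroids at 6.5 Angstrom and warns on broken rings", {
  m <- structure_model(dplyr::bind_rows(phe_ring(1L, c(0, 0, 0)),
                                        phe_ring(5L, c(0, 5.9, 0))))
  rec <- pi_stacking(m)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$distance, 5.9, tolerance = 1e-9)
  far <- structure_model(dplyr::bind_rows(phe_ring(1L, c(0, 0, 0)),
                                          phe_ring(5L, c(0, 6.8, 0))))
  expect_identical(nrow(pi_stacking(far)), 0L)
  broken <- structure_model(dplyr::bind_rows(phe_ring(1L, c(0, 0, 0)),
                                             phe_ring(5L, c(0, 5, 0))[1:4, ]))
  expect_warning(out <- pi_stacking(broken), "missing ring atoms")
  expect_identical(nrow(out), 0L)
})

test_that("ring centroids agree with an independent mean-of-coordinates computation", {
  for (seed in 1:20) {
    R <- random_rotation(seed)
    shift <- withr::with_seed(seed, stats::rnorm(3, sd = 10))
    ring1 <- phe_ring(1L, c(0, 0, 0))
    ring2 <- phe_ring(5L, c(0, 5.5, 0))
    m <- transform_model(structure_model(dplyr::bind_rows(ring1, ring2)),
                         rotation = R, translation = shift)
    rec <- pi_stacking(m)
    df <- as.data.frame(m)
    cen <- t(sapply(split(df, df$resno), function(g)
      colMeans(g[, c("x", "y", "z")])))
    expect_equal(rec$distance, sqrt(sum((cen[1, ] - cen[2, ])^2)),
                 tolerance = 1e-9)
  }
})

test_that("each detector equals the all-pairs brute-force oracle on random structures", {
  cutoffs <- c(hbond = 3.5, hydrophobic = 5.0, salt_bridge = 4.0, pi_pi = 6.5)
  for (seed in 1:12) {
    m <- random_structure(seed)
    expect_lte(nrow(m), 500)
    recs <- list(
      hbond = hydrogen_bonds(m), hydrophobic = hydrophobic_contacts(m),
      salt_bridge = salt_bridges(m), pi_pi = suppressWarnings(pi_stacking(m))
    )
    for (cls in names(cutoffs)) {
      expect_identical(impl_keys(recs[[cls]]),
                       suppressWarnings(oracle_keys(m, cls, cutoffs[[cls]])),
                       info = paste(cls, "seed", seed))
    }
  }
})

test_that("interaction records are canonical, rigid-motion invariant and threshold-monotone", {
  for (seed in 13:18) {
    m <- random_structure(seed)
    rec <- suppressWarnings(detect_interactions(m))
    # canonical orientation: A <= B, no mirrored duplicates
    key <- paste(rec$class, rec$chain_a, rec$resno_a, rec$chain_b, rec$resno_b)
    expect_identical(anyDuplicated(key), 0L)
    expect_true(all(rec$chain_a < rec$chain_b |
                      (rec$chain_a == rec$chain_b & rec$resno_a < rec$resno_b)))
    # rigid motion
    m2 <- transform_model(m, random_rotation(seed),
                          withr::with_seed(seed, stats::rnorm(3, sd = 30)))
    rec2 <- suppressWarnings(detect_interactions(m2))
    expect_identical(sort(key), sort(paste(rec2$class, rec2$chain_a, rec2$resno_a,
                                           rec2$chain_b, rec2$resno_b)))
    # monotonicity in the cutoff
    for (cls in c("hbond", "hydrophobic", "salt_bridge", "pi_pi")) {
      lo <- suppressWarnings(detect_interactions(m, classes = cls))
      hi <- suppressWarnings(detect_interactions(
        m, classes = cls,
        cutoffs = stats::setNames(DEFAULTS <- c(hbond = 3.5, hydrophobic = 5,
                                                salt_bridge = 4, pi_pi = 6.5)[cls] + 1.0, cls)))
      expect_true(all(impl_keys(lo) %in% impl_keys(hi)))
    }
  }
})

test_that("model comparison reports shared, unique and Jaccard correctly", {
  m <- random_structure(21)
  same <- compare_models(list(m, m))
  expect_equal(same$jaccard$jaccard, 1)
  expect_identical(length(same$unique[[1]]), 0L)

  # displacing one residue past all thresholds makes its interactions unique to A
  rec <- suppressWarnings(detect_interactions(m))
  counts <- sort(table(c(paste(rec$chain_a, rec$resno_a),
                         paste(rec$chain_b, rec$resno_b))), decreasing = TRUE)
  target <- strsplit(names(counts)[1], " ")[[1]]
  m2 <- m
  sel <- m2$chain == target[1] & m2$resno == as.integer(target[2])
  m2$x[sel] <- m2$x[sel] + 500
  attr(m2, "label") <- "displaced"
  cmp <- suppressWarnings(compare_models(list(m, m2)))
  uniq_a <- cmp$unique[[1]]
  involving <- grepl(paste0(target[1], ":", target[2], ":"), uniq_a, fixed = TRUE)
  expect_true(all(involving))
  expect_identical(length(uniq_a), as.integer(counts[1]))

  # disjoint interaction sets give Jaccard 0 (both non-empty)
  hb <- two_atoms("GLY", "N", "SER", "O", 3.0)
  hb2 <- hb; hb2$x <- hb2$x + c(0, 1.0); attr(hb2, "label") <- "shifted"
  sb <- two_atoms("LYS", "NZ", "ASP", "OD1", 3.8)
  attr(sb, "label") <- "bridge"
  cmp2 <- compare_models(list(hb, sb))
  expect_equal(cmp2$jaccard$jaccard, 0)

  expect_error(compare_models(list(m)), class = "fvh_comparison_error")
  far <- m; far$resno <- far$resno + 1000L; attr(far, "label") <- "renumbered"
  expect_error(suppressWarnings(compare_models(list(m, far))),
               class = "fvh_comparison_error")
})

test_that("structure I/O: fixtures round-trip, models index, malformed files error", {
  dir <- withr::local_tempdir()
  m <- random_structure(30)
  f <- file.path(dir, "m.pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_identical(nrow(m2), nrow(m))
  expect_equal(as.data.frame(m2[c("x", "y", "z")]),
               as.data.frame(m[c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)

  # two MODELs: index 2 returns the second model's coordinates
  lines1 <- readLines(f)
  atoms1 <- grep("^ATOM", lines1, value = TRUE)
  shift <- function(l) {
    x <- as.numeric(substr(l, 31, 38)) + 10
    paste0(substr(l, 1, 30), formatC(x, width = 8, format = "f", digits = 3),
           substr(l, 39, nchar(l)))
  }
  multi <- c("MODEL     1", atoms1, "ENDMDL",
             "MODEL     2", vapply(atoms1, shift, ""), "ENDMDL", "END")
  f2 <- file.path(dir, "multi.pdb")
  writeLines(multi, f2)
  ma <- read_structure(f2, model_index = 1)
  mb <- read_structure(f2, model_index = 2)
  expect_equal(mb$x, ma$x + 10, tolerance = 1e-6)
  expect_error(read_structure(f2, model_index = 3), class = "fvh_format_error")

  # truncated ATOM line
  f3 <- file.path(dir, "trunc.pdb")
  writeLines(c(atoms1[1], substr(atoms1[2], 1, 40)), f3)
  expect_error(read_structure(f3), class = "fvh_format_error")
})
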