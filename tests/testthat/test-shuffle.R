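shuffle_world <- function(seed, n_per_slot = 2, identity = 0.8) {
  pool <- gen_germline_pool(n_per_slot, identity, seed = seed)
  parent <- gen_parent_fv(pool, fr_mutation_rate = 0, seed = seed + 1)
  list(pool = pool, cdrs = parent$cdrs)
}

random_choice <- function(pool, seed) {
  withr::with_seed(seed, {
    pick <- function(ct) vapply(c("FR1", "FR2", "FR3", "FR4"), function(sl) {
      cands <- pool$name[pool$chain_type == ct & pool$slot == sl]
      sample(cands, 1)
    }, "")
    fr_choice(pick("heavy"), pick("kappa"))
  })
}

test_that("assembled variants are the positional concatenation of FRs and CDRs", {
  for (seed in 41:45) {
    w <- shuffle_world(seed)
    ch <- random_choice(w$pool, seed)
    v <- assemble_variant(w$cdrs, ch, w$pool)
    for (ct in c("heavy", "kappa")) {
      design <- if (ct == "heavy") v$heavy else v$light
      expected <- paste(vapply(
        c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
        function(r) {
          if (startsWith(r, "FR")) {
            w$pool$sequence[w$pool$chain_type == ct & w$pool$slot == r &
                              w$pool$name == ch$germline[ch$chain_type == ct & ch$slot == r]]
          } else {
            w$cdrs$sequence[w$cdrs$chain_type == ct & w$cdrs$region == r]
          }
        }, ""), collapse = "")
      expect_identical(design_sequence(design), expected)
    }
  }
  w <- shuffle_world(46)
  bad <- fr_choice(c("IGHV9-99", "SGHV2-1", "SGHV3-1", "SJH1"),
                   c("SGKV1-1", "SGKV2-1", "SGKV3-1", "SJK1"))
  expect_error(assemble_variant(w$cdrs, bad, w$pool), class = "fvh_lookup_error")
})

test_that("decompose(assemble(x)) recovers the framework choice on distinct-segment pools", {
  for (seed in 51:58) {
    w <- shuffle_world(seed)
    ch <- random_choice(w$pool, seed)
    v <- assemble_variant(w$cdrs, ch, w$pool)
    d <- decompose_origin(v, w$pool)
    got <- d[order(d$chain_type, d$slot), ]
    want <- ch[order(ch$chain_type, ch$slot), ]
    expect_identical(got$origin, want$germline)
    expect_true(all(got$mismatches == 0))
  }
})

test_that("identical segments under two names are reported as tied origins", {
  w <- shuffle_world(61)
  donor <- w$pool[w$pool$chain_type == "heavy" & w$pool$slot == "FR2", ][1, ]
  twin <- dplyr::mutate(donor, name = "ZZZ-TWIN")
  pool2 <- germline_pool(dplyr::bind_rows(w$pool, twin))
  ch <- fr_choice(c("SGHV1-1", donor$name, "SGHV3-1", "SJH1"),
                  c("SGKV1-1", "SGKV2-1", "SGKV3-1", "SJK1"))
  d <- decompose_origin(assemble_variant(w$cdrs, ch, pool2), pool2)
  tied <- d$tied[d$chain_type == "heavy" & d$slot == "FR2"][[1]]
  expect_setequal(tied, c(donor$name, "ZZZ-TWIN"))
})

test_that("a planted FR2 mutation is found with mismatch count 1 by a brute-force minimum", {
  w <- shuffle_world(62)
  ch <- random_choice(w$pool, 62)
  v <- assemble_variant(w$cdrs, ch, w$pool)
  seqs <- list(heavy = design_sequence(v$heavy), light = design_sequence(v$light))
  rm <- segment_regions(number_chain(seqs$heavy, "heavy"))
  fr2 <- rm$sequence[rm$region == "FR2"]
  chars <- strsplit(seqs$heavy, "")[[1]]
  offset <- sum(rm$length[1:2])          # FR1 + CDR1 lengths
  pos <- offset + 5
  chars[pos] <- setdiff(c("A", "C"), chars[pos])[1]
  mutated <- list(heavy = paste(chars, collapse = ""), light = seqs$light)
  d <- decompose_origin(mutated, w$pool)
  row <- d[d$chain_type == "heavy" & d$slot == "FR2", ]
  # brute-force minimum over the slot
  cands <- w$pool[w$pool$chain_type == "heavy" & w$pool$slot == "FR2", ]
  mm <- vapply(cands$sequence, function(s) {
    a <- strsplit(row$sequence, "")[[1]]; b <- strsplit(s, "")[[1]]
    sum(a != b)
  }, numeric(1))
  expect_identical(row$mismatches, 1L)
  expect_identical(as.integer(min(mm)), 1L)
  expect_identical(row$origin, cands$name[which.min(mm)])
})

test_that("slots mutated past the ceiling report a not-applicable origin", {
  w <- shuffle_world(63)
  cands <- w$pool[w$pool$chain_type == "heavy" & w$pool$slot == "FR2", ]
  c1 <- strsplit(cands$sequence[1], "")[[1]]
  c2 <- strsplit(cands$sequence[2], "")[[1]]
  ch <- fr_choice(c("SGHV1-1", cands$name[1], "SGHV3-1", "SJH1"),
                  c("SGKV1-1", "SGKV2-1", "SGKV3-1", "SJK1"))
  v <- assemble_variant(w$cdrs, ch, w$pool)
  seqs <- list(heavy = design_sequence(v$heavy), light = design_sequence(v$light))
  rm <- segment_regions(number_chain(seqs$heavy, "heavy"))
  chars <- strsplit(seqs$heavy, "")[[1]]
  offset <- sum(rm$length[1:2])
  # flip 5 positions where both pool members agree: the minimum mismatch over
  # the slot becomes exactly 5, deterministically above the ceiling of 3
  agree <- which(c1 == c2)[1:5]
  for (k in agree) {
    chars[offset + k] <- if (chars[offset + k] == "A") "C" else "A"
  }
  mutated <- list(heavy = paste(chars, collapse = ""), light = seqs$light)
  d <- decompose_origin(mutated, w$pool, max_mismatch = 3)
  row <- d[d$chain_type == "heavy" & d$slot == "FR2", ]
  expect_gte(row$mismatches, 4L)
  expect_true(is.na(row$origin))
  expect_length(row$tied[[1]], 0)
})

test_that("library sampling is seed-deterministic and uniform per slot", {
  w <- shuffle_world(64)
  a <- sample_library(w$cdrs, w$pool, 25, seed = 123)
  b <- sample_library(w$cdrs, w$pool, 25, seed = 123)
  expect_identical(a$heavy_sequence, b$heavy_sequence)
  expect_identical(a$light_sequence, b$light_sequence)

  big <- sample_library(w$cdrs, w$pool, 1e5, seed = 7, assemble = FALSE)
  for (col in c("heavy_FR1", "heavy_FR3", "kappa_FR2", "kappa_FR4")) {
    tab <- table(big[[col]])
    expect_identical(length(tab), 2L)
    expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  }
})

test_that("exhaustive sampling without replacement enumerates the whole library", {
  pool <- gen_germline_pool(2, 0.8, seed = 65)
  pool <- germline_pool(pool[!(pool$slot %in% c("FR2", "FR3")) |
                               !grepl("2$", pool$name), ])
  w <- list(pool = pool, cdrs = shuffle_world(65)$cdrs)
  div <- pool_diversity(pool)
  lib <- sample_library(w$cdrs, pool, div, seed = 9, replacement = FALSE,
                        assemble = FALSE)
  combos <- do.call(paste, lib[paste(rep(c("heavy", "kappa"), each = 4),
                                     c("FR1", "FR2", "FR3", "FR4"), sep = "_")])
  expect_identical(length(unique(combos)), as.integer(div))
  # brute-force enumeration as a set
  slots <- split(pool$name, paste(pool$chain_type, pool$slot))
  grid <- do.call(tidyr::expand_grid, slots)
  all_combos <- do.call(paste, grid[paste(rep(c("heavy", "kappa"), each = 4),
                                          c("FR1", "FR2", "FR3", "FR4"))])
  expect_setequal(combos, all_combos)

  expect_error(sample_library(w$cdrs, pool, div + 1, seed = 1,
                              replacement = FALSE),
               class = "fvh_sampling_error")
})

test_that("every sampled variant decomposes with zero mismatches and a tiny pool is fully covered", {
  w <- shuffle_world(66)
  lib <- sample_library(w$cdrs, w$pool, 8, seed = 31)
  for (pr in lib$pair) {
    d <- decompose_origin(pr, w$pool)
    expect_true(all(d$mismatches == 0))
  }
  # coupon-collector coverage of a 1-slot-varying pool
  tiny <- germline_pool(w$pool[w$pool$slot != "FR1" | grepl("1$", w$pool$name) |
                                 w$pool$chain_type == "heavy", ])
  div <- pool_diversity(tiny)
  big <- sample_library(w$cdrs, tiny, 60 * div, seed = 8, assemble = FALSE)
  combos <- unique(do.call(paste, big[paste(rep(c("heavy", "kappa"), each = 4),
                                            c("FR1", "FR2", "FR3", "FR4"),
                                            sep = "_")]))
  expect_identical(length(combos), as.integer(div))
})
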