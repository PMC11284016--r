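# FR-shuffling humanization: assemble variants from fixed CDRs plus germline
# framework choices, sample/enumerate the combinatorial library, and decompose
# a variant back to its per-slot germline origins.

SHUFFLE_SLOTS <- tidyr::expand_grid(chain_type = c("heavy", "kappa"),
                                    slot = c("FR1", "FR2", "FR3", "FR4"))

#' Fixed CDR set for framework shuffling
#'
#' @param h1,h2,h3 Heavy-chain CDR sequences.
#' @param l1,l2,l3 Kappa-chain CDR sequences.
#' @param scheme Numbering scheme the CDR delineation refers to.
#' @return A `cdr_set` tibble: `chain_type`, `region`, `sequence`.
#' @export
cdr_set <- function(h1, h2, h3, l1, l2, l3, scheme = "imgt") {
  scheme <- check_scheme(scheme)
  df <- tibble::tibble(
    chain_type = rep(c("heavy", "kappa"), each = 3),
    region = rep(CDR_SLOTS, 2),
    sequence = c(h1, h2, h3, l1, l2, l3)
  )
  for (i in seq_len(nrow(df))) {
    df$sequence[i] <- check_sequence(df$sequence[i],
                                     paste(df$chain_type[i], df$region[i]))
    tmpl_len <- nchar(template_region(scheme, df$chain_type[i], df$region[i]))
    if (nchar(df$sequence[i]) < 2 || nchar(df$sequence[i]) > tmpl_len + 15) {
      fvh_abort("fvh_input_error", sprintf(
        "%s %s length %d outside the scheme-legal range [2, %d]",
        df$chain_type[i], df$region[i], nchar(df$sequence[i]), tmpl_len + 15))
    }
  }
  new_fvh_tbl(df, "cdr_set", scheme = scheme)
}

#' Extract the six CDRs of an Fv from its region maps
#'
#' @param heavy_rm,light_rm `region_map`s of the heavy and kappa chains.
#' @return A `cdr_set`.
#' @export
cdrs_from_regions <- function(heavy_rm, light_rm) {
  cdr_set(
    region_sequence(heavy_rm, "CDR1"), region_sequence(heavy_rm, "CDR2"),
    region_sequence(heavy_rm, "CDR3"),
    region_sequence(light_rm, "CDR1"), region_sequence(light_rm, "CDR2"),
    region_sequence(light_rm, "CDR3"),
    scheme = attr(heavy_rm, "scheme")
  )
}

#' Framework choice for one library variant
#'
#' @param heavy,kappa Character vectors of four germline names each
#'   (FR1-FR4 in order).
#' @return An `fr_choice` tibble: `chain_type`, `slot`, `germline`.
#' @export
fr_choice <- function(heavy, kappa) {
  stopifnot(length(heavy) == 4, length(kappa) == 4)
  new_fvh_tbl(
    tibble::tibble(chain_type = rep(c("heavy", "kappa"), each = 4),
                   slot = rep(FR_SLOTS, 2), germline = unname(c(heavy, kappa))),
    "fr_choice")
}

lookup_segment <- function(pool, chain_type, slot, name) {
  hit <- dplyr::filter(pool, .data$chain_type == !!chain_type,
                       .data$slot == !!slot, .data$name == !!name)
  if (nrow(hit) != 1) {
    fvh_abort("fvh_lookup_error", sprintf(
      "germline '%s' not found in pool slot %s/%s", name, chain_type, slot))
  }
  hit$sequence
}

#' Assemble a library variant from CDRs and a framework choice
#'
#' Each chain is the concatenation FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4 with
#' frameworks taken from the chosen germlines and CDRs from the fixed set.
#'
#' @param cdrs A `cdr_set`.
#' @param choice An `fr_choice`.
#' @param pool A `germline_pool`.
#' @param label Optional variant label.
#' @return An `fv_pair`: list with `heavy` and `light` `fv_design`s.
#' @export
assemble_variant <- function(cdrs, choice, pool, label = NULL) {
  scheme <- attr(cdrs, "scheme")
  chains <- purrr::map(c(heavy = "heavy", kappa = "kappa"), function(ct) {
    ch <- dplyr::filter(choice, .data$chain_type == ct)
    regions <- tibble::tibble(
      region = REGION_ORDER,
      sequence = purrr::map_chr(REGION_ORDER, function(r) {
        if (r %in% FR_SLOTS) {
          lookup_segment(pool, ct, r, ch$germline[ch$slot == r])
        } else {
          cdrs$sequence[cdrs$chain_type == ct & cdrs$region == r]
        }
      }),
      origin = purrr::map_chr(REGION_ORDER, function(r) {
        if (r %in% FR_SLOTS) ch$germline[ch$slot == r] else "fixed CDR"
      })
    )
    fv_design(regions, ct, scheme, label = label)
  })
  structure(list(heavy = chains$heavy, light = chains$kappa,
                 choice = choice, label = label),
            class = "fv_pair")
}

#' @export
tidy.fv_pair <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$heavy), chain_type = "heavy", .before = 1),
    dplyr::mutate(tidy(x$light), chain_type = "kappa", .before = 1)
  )
}

decode_choice <- function(idx, slot_tables) {
  fr_choice(
    heavy = purrr::map_chr(1:4, function(j) slot_tables[[j]]$name[idx[j]]),
    kappa = purrr::map_chr(5:8, function(j) slot_tables[[j]]$name[idx[j]])
  )
}

#' Sample the combinatorial framework-shuffled library
#'
#' Draws variants uniformly over the space of framework choices (heavy and
#' kappa choices independent, as in a fully shuffled library). Identical
#' seeds give identical output.
#'
#' @param cdrs A `cdr_set`.
#' @param pool A `germline_pool`.
#' @param n Number of variants to draw.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param replacement Sample with replacement (default)? Without replacement
#'   requires `n <= pool_diversity(pool)`.
#' @param assemble Attach assembled `fv_pair`s and sequences (default). Set
#'   `FALSE` to get framework choices only (cheap at large `n`).
#' @return A `shuffle_library` tibble: `variant_id`, one column per
#'   chain-slot (e.g. `heavy_FR1`), and when `assemble = TRUE` also
#'   `heavy_sequence`, `light_sequence` and a `pair` list-column.
#' @export
sample_library <- function(cdrs, pool, n, seed = NULL, replacement = TRUE,
                           assemble = TRUE) {
  if (!rlang::is_scalar_integerish(n) || n < 1) {
    fvh_abort("fvh_sampling_error", "`n` must be a positive integer")
  }
  div <- pool_diversity(pool)
  if (!replacement && n > div) {
    fvh_abort("fvh_sampling_error", sprintf(
      "cannot draw %d distinct variants from a library of diversity %s",
      n, format(div, big.mark = ",")))
  }
  slot_tables <- purrr::pmap(SHUFFLE_SLOTS, function(chain_type, slot) {
    pool_slot(pool, chain_type, slot)
  })
  sizes <- purrr::map_int(slot_tables, nrow)

  draw <- function() {
    if (replacement) {
      vapply(sizes, function(s) sample.int(s, n, replace = TRUE), integer(n)) |>
        matrix(nrow = n)
    } else if (div <= 1e6) {
      combos <- sample.int(div, n)
      t(vapply(combos, function(code) {
        code <- code - 1
        idx <- integer(8)
        for (j in 8:1) { idx[j] <- as.integer(code %% sizes[j]) + 1L; code <- code %/% sizes[j] }
        idx
      }, integer(8)))
    } else {
      seen <- character(0); rows <- list()
      while (length(rows) < n) {
        cand <- vapply(sizes, function(s) sample.int(s, 1), integer(1))
        key <- paste(cand, collapse = "-")
        if (!key %in% seen) { seen <- c(seen, key); rows[[length(rows) + 1]] <- cand }
      }
      do.call(rbind, rows)
    }
  }
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (n == 1) idx <- matrix(idx, nrow = 1)

  cols <- purrr::map(seq_len(8), function(j) slot_tables[[j]]$name[idx[, j]])
  names(cols) <- paste(SHUFFLE_SLOTS$chain_type, SHUFFLE_SLOTS$slot, sep = "_")
  out <- dplyr::bind_cols(tibble::tibble(variant_id = sprintf("V%04d", seq_len(n))),
                          tibble::as_tibble(cols))
  if (assemble) {
    pairs <- purrr::map(seq_len(n), function(i) {
      assemble_variant(cdrs, decode_choice(idx[i, ], slot_tables), pool,
                       label = out$variant_id[i])
    })
    out$heavy_sequence <- purrr::map_chr(pairs, ~ design_sequence(.x$heavy))
    out$light_sequence <- purrr::map_chr(pairs, ~ design_sequence(.x$light))
    out$pair <- pairs
  }
  new_fvh_tbl(out, "shuffle_library", seed = seed, diversity = div,
              cdrs = cdrs, replacement = replacement)
}

#' Decompose a variant into per-framework germline origins
#'
#' For each chain and framework slot, reports the pool segment with the
#' minimum mismatch count to the variant's framework (exact matches report 0
#' mismatches). A slot whose best match still exceeds `max_mismatch`
#' mismatches reports origin `NA` (not applicable), mirroring how heavily
#' mutated frameworks are reported in shuffled-library sequence analyses.
#' Ties are all reported in the `tied` list-column; `origin` carries the
#' lexicographically first name.
#'
#' @param variant An `fv_pair`, or a list/named vector with `heavy` and
#'   `light` sequences.
#' @param pool A `germline_pool`.
#' @param max_mismatch Mismatch ceiling per slot before declaring
#'   not-applicable (default 3).
#' @param scheme Numbering scheme used to segment the variant.
#' @return A tibble: `chain_type`, `slot`, `origin`, `mismatches`, `tied`
#'   (list of all minimal-mismatch names), `sequence` (the variant's
#'   framework segment).
#' @export
decompose_origin <- function(variant, pool, max_mismatch = 3, scheme = "imgt") {
  seqs <- if (inherits(variant, "fv_pair")) {
    list(heavy = design_sequence(variant$heavy),
         light = design_sequence(variant$light))
  } else {
    list(heavy = variant$heavy, light = variant$light)
  }
  rms <- list(
    heavy = segment_regions(number_chain(seqs$heavy, "heavy", scheme)),
    kappa = segment_regions(number_chain(seqs$light, "kappa", scheme))
  )
  purrr::pmap(SHUFFLE_SLOTS, function(chain_type, slot) {
    seg <- region_sequence(rms[[chain_type]], slot)
    cands <- pool_slot(pool, chain_type, slot)
    mm <- purrr::map_int(cands$sequence, ~ as.integer(mismatch_count(seg, .x)))
    best <- min(mm)
    tied <- sort(cands$name[mm == best])
    tibble::tibble(
      chain_type = chain_type, slot = slot,
      origin = if (best > max_mismatch) NA_character_ else tied[1],
      mismatches = best,
      tied = list(if (best > max_mismatch) character(0) else tied),
      sequence = seg
    )
  }) |> dplyr::bind_rows()
}
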