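# CDR-grafting humanization: per-framework germline selection, grafting,
# back mutation, full-antibody enumeration.

#' Build an Fv design from region sequences
#'
#' Low-level constructor shared by [graft()] and [assemble_variant()]. Scheme
#' positions are assigned from the boundary table: each region's residues are
#' numbered from the region's start position; residues overflowing the
#' region's scheme interval receive insertion codes at the interval's end.
#'
#' @param regions A data frame with columns `region` (FR1..FR4, CDR1..CDR3 in
#'   order), `sequence` and `origin` (provenance label per region).
#' @param chain_type,scheme Chain type and numbering scheme.
#' @param label Optional design label.
#' @return An `fv_design`: per-residue tibble with columns `position`,
#'   `insertion`, `aa`, `region`, `origin`.
#' @export
fv_design <- function(regions, chain_type, scheme = "imgt", label = NULL) {
  chain_type <- check_chain_type(chain_type)
  scheme <- check_scheme(scheme)
  regions <- tibble::as_tibble(regions)
  if (!identical(regions$region, REGION_ORDER)) {
    fvh_abort("fvh_input_error",
              "`regions` must contain exactly FR1,CDR1,FR2,CDR2,FR3,CDR3,FR4 in order")
  }
  bounds <- cdr_boundaries(scheme, chain_type)
  bounds <- bounds[match(REGION_ORDER, bounds$region), ]

  rows <- purrr::pmap(
    list(regions$region, regions$sequence, regions$origin, bounds$start, bounds$end),
    function(region, sequence, origin, start, end) {
      aa <- strsplit(check_sequence(sequence, paste0(region, " sequence")), "")[[1]]
      span <- end - start + 1L
      n <- length(aa)
      pos <- pmin(start + seq_len(n) - 1L, end)
      ins <- rep(NA_character_, n)
      if (n > span) ins[(span + 1L):n] <- LETTERS[seq_len(n - span)]
      tibble::tibble(position = as.integer(pos), insertion = ins, aa = aa,
                     region = region, origin = origin)
    }
  )
  new_fvh_tbl(dplyr::bind_rows(rows), "fv_design",
              chain_type = chain_type, scheme = scheme, label = label,
              back_mutations = tibble::tibble())
}

#' Full amino-acid sequence of a design
#' @param design An `fv_design`.
#' @return A string.
#' @export
design_sequence <- function(design) paste(design$aa, collapse = "")

#' @export
tidy.fv_design <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("position", "insertion", "aa", "region", "origin")])
}

#' @export
glance.fv_design <- function(x, ...) {
  tibble::tibble(
    chain_type = attr(x, "chain_type"), scheme = attr(x, "scheme"),
    label = attr(x, "label") %||% NA_character_,
    length = nrow(x),
    n_back_mutations = nrow(attr(x, "back_mutations"))
  )
}

#' Select the most homologous germline per framework
#'
#' For each chain and framework slot, scans the pool and keeps the segment
#' with the highest percent identity to the parent framework (matches over
#' the parent-FR length, global alignment with affine gaps and BLOSUM62
#' scoring). Ties are broken by lexicographically smallest germline name so
#' the selection is deterministic.
#'
#' @param parent_regions A `region_map` or a list of region maps (one per
#'   chain) from [segment_regions()].
#' @param pool A `germline_pool`.
#' @return An `fr_selection` tibble: `chain_type`, `slot`, `germline`,
#'   `identity`, `alignment_length`, `sequence`.
#' @export
select_germline_per_fr <- function(parent_regions, pool) {
  if (inherits(parent_regions, "region_map")) parent_regions <- list(parent_regions)
  rows <- purrr::map(parent_regions, function(rm) {
    ct <- attr(rm, "chain_type")
    purrr::map(FR_SLOTS, function(slot) {
      parent_fr <- region_sequence(rm, slot)
      cands <- pool_slot(pool, ct, slot)
      stats_list <- purrr::map(cands$sequence, function(s) {
        st <- alignment_stats(parent_fr, s)
        tibble::tibble(identity = 100 * st$matches / nchar(parent_fr),
                       alignment_length = st$length)
      })
      scored <- dplyr::bind_cols(cands, dplyr::bind_rows(stats_list)) |>
        dplyr::arrange(dplyr::desc(.data$identity), .data$name)
      tibble::tibble(chain_type = ct, slot = slot,
                     germline = scored$name[1],
                     identity = scored$identity[1],
                     alignment_length = scored$alignment_length[1],
                     sequence = scored$sequence[1])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  new_fvh_tbl(rows, "fr_selection")
}

#' Graft parent CDRs onto selected germline frameworks
#'
#' Produces a design whose CDRs are byte-identical to the parent's and whose
#' frameworks are byte-identical to the selected germline segments.
#'
#' @param parent_regions A `region_map` for one chain.
#' @param selection An `fr_selection` covering that chain.
#' @param label Optional design label.
#' @return An `fv_design`.
#' @export
graft <- function(parent_regions, selection, label = NULL) {
  ct <- attr(parent_regions, "chain_type")
  scheme <- attr(parent_regions, "scheme")
  sel <- dplyr::filter(selection, .data$chain_type == ct)
  if (!setequal(sel$slot, FR_SLOTS)) {
    fvh_abort("fvh_config_error", sprintf(
      "selection does not resolve all four FR slots for the %s chain", ct))
  }
  bounds <- cdr_boundaries(scheme, ct)
  for (slot in FR_SLOTS) {
    span <- with(bounds[bounds$region == slot, ], end - start + 1L)
    len <- nchar(sel$sequence[sel$slot == slot])
    tol <- max(4L, round(0.3 * span))
    if (abs(len - span) > tol) {
      fvh_abort("fvh_grafting_error", sprintf(
        "germline segment for %s/%s has length %d, outside the scheme's allowed range (%d +/- %d)",
        ct, slot, len, span, tol))
    }
  }
  regions <- tibble::tibble(
    region = REGION_ORDER,
    sequence = purrr::map_chr(REGION_ORDER, function(r) {
      if (r %in% FR_SLOTS) sel$sequence[sel$slot == r]
      else region_sequence(parent_regions, r)
    }),
    origin = purrr::map_chr(REGION_ORDER, function(r) {
      if (r %in% FR_SLOTS) sel$germline[sel$slot == r] else "parent CDR"
    })
  )
  fv_design(regions, ct, scheme, label = label %||% paste0(ct, "-germline-grafted"))
}

#' Build a back-mutation specification
#'
#' Site labels follow the convention `installed` = the parent (murine) residue
#' restored at the scheme position, `replaced` = the germline residue removed.
#' The numbering scheme tag is mandatory because site labels are meaningless
#' without it.
#'
#' @param scheme Numbering scheme the positions refer to.
#' @param position Integer scheme positions.
#' @param installed,replaced One-letter residues installed/replaced.
#' @param insertion Optional insertion codes (default none).
#' @return A `back_mutation_spec` tibble.
#' @export
back_mutation_spec <- function(scheme, position, installed, replaced,
                               insertion = NA_character_) {
  scheme <- check_scheme(scheme)
  df <- tibble::tibble(scheme = scheme, position = as.integer(position),
                       insertion = insertion, installed = installed,
                       replaced = replaced)
  if (any(df$installed == df$replaced)) {
    fvh_abort("fvh_input_error", "installed residue must differ from replaced residue")
  }
  new_fvh_tbl(df, "back_mutation_spec")
}

#' Apply back mutations to a grafted design
#'
#' Reverts the listed framework positions to the parent residue. The spec's
#' `replaced` residue must match the design's current residue (unless the
#' mutation was already applied, making the call idempotent), `installed` must
#' equal the parent residue at that position, and CDR positions are rejected:
#' back mutations are framework edits.
#'
#' @param design An `fv_design`.
#' @param spec A `back_mutation_spec` (possibly empty).
#' @param parent The parent `numbered_chain` for the same chain.
#' @return The edited `fv_design`; applied mutations are recorded in the
#'   design's `back_mutations` attribute.
#' @export
apply_back_mutations <- function(design, spec, parent) {
  if (nrow(spec) == 0) return(design)
  if (!identical(unique(spec$scheme), attr(design, "scheme"))) {
    fvh_abort("fvh_consistency_error", sprintf(
      "spec is tagged with scheme '%s' but the design uses '%s'",
      unique(spec$scheme), attr(design, "scheme")))
  }
  out <- design
  applied <- list()
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    j <- which(out$position == row$position &
                 (is.na(row$insertion) & is.na(out$insertion) |
                    !is.na(row$insertion) & !is.na(out$insertion) &
                    out$insertion == row$insertion))
    if (length(j) != 1) {
      fvh_abort("fvh_consistency_error", sprintf(
        "position %s%s does not exist in the design",
        row$position, ifelse(is.na(row$insertion), "", row$insertion)))
    }
    if (startsWith(out$region[j], "CDR")) {
      fvh_abort("fvh_consistency_error", sprintf(
        "position %d lies inside %s; back mutations are framework edits only",
        row$position, out$region[j]))
    }
    k <- which(parent$position == row$position &
                 (is.na(row$insertion) & is.na(parent$insertion) |
                    !is.na(row$insertion) & !is.na(parent$insertion) &
                    parent$insertion == row$insertion))
    if (length(k) != 1 || parent$aa[k] != row$installed) {
      fvh_abort("fvh_consistency_error", sprintf(
        "installed residue %s at position %d does not match the parent residue (%s)",
        row$installed, row$position,
        if (length(k) == 1) parent$aa[k] else "absent"))
    }
    if (out$aa[j] == row$installed) next  # already applied: no-op
    if (out$aa[j] != row$replaced) {
      fvh_abort("fvh_consistency_error", sprintf(
        "spec expects residue %s at position %d but the design holds %s",
        row$replaced, row$position, out$aa[j]))
    }
    out$aa[j] <- row$installed
    out$origin[j] <- "back-mutated"
    applied[[length(applied) + 1]] <- row
  }
  prev <- attr(design, "back_mutations")
  attr(out, "back_mutations") <- dplyr::distinct(
    dplyr::bind_rows(prev, dplyr::bind_rows(applied)))
  out
}

#' Enumerate paired antibody designs
#'
#' Full Cartesian pairing of heavy-chain and light-chain variants; the
#' pairing of eight heavy with four light variants is how a 32-antibody
#' design panel arises.
#'
#' @param heavy_variants,light_variants Lists of `fv_design` objects.
#' @return A tibble with one row per paired design: `design_id`,
#'   `heavy_label`, `light_label`, `heavy_sequence`, `light_sequence`, and
#'   list-columns `heavy`, `light` holding the designs.
#' @export
enumerate_designs <- function(heavy_variants, light_variants) {
  if (length(heavy_variants) == 0 || length(light_variants) == 0) {
    fvh_abort("fvh_enumeration_error",
              "both heavy and light variant lists must be non-empty")
  }
  lab <- function(v, prefix) purrr::imap_chr(
    v, function(d, i) attr(d, "label") %||% paste0(prefix, i))
  hl <- lab(heavy_variants, "H"); ll <- lab(light_variants, "L")
  grid <- tidyr::expand_grid(h = seq_along(heavy_variants),
                             l = seq_along(light_variants))
  tibble::tibble(
    design_id = paste0(hl[grid$h], "x", ll[grid$l]),
    heavy_label = hl[grid$h], light_label = ll[grid$l],
    heavy_sequence = purrr::map_chr(heavy_variants[grid$h], design_sequence),
    light_sequence = purrr::map_chr(light_variants[grid$l], design_sequence),
    heavy = heavy_variants[grid$h], light = light_variants[grid$l]
  )
}

`%||%` <- rlang::`%||%`
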