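# Canonical structure-determining residue classification and back-mutation
# candidate proposal. Three multi-label framework residue types:
#   Type 1 -- VH/VL interface packing: any inter-chain heavy-atom pair within
#             d_interface.
#   Type 2 -- buried CDR-proximal: minimum heavy-atom distance to any CDR
#             atom within d_near AND relative SASA at or below r_buried
#             (conjunctive reading).
#   Type 3 -- direct CDR interaction: participates in at least one detected
#             interaction (any of the four classes) whose partner residue is
#             in a CDR.

#' Map sequence regions onto structure residue numbers
#'
#' Assumes the structure numbers residues sequentially within each chain
#' (resno 1..n matching residue order in the sequence), the convention used
#' by the bundled mock-structure generator.
#'
#' @param heavy_rm,light_rm `region_map`s for the two chains.
#' @param chains Chain identifiers in the structure (heavy, light).
#' @return A tibble `chain`, `resno`, `region`.
#' @export
structure_regions <- function(heavy_rm, light_rm, chains = c("H", "L")) {
  one <- function(rm, ch) {
    lens <- rm$length
    tibble::tibble(chain = ch,
                   resno = seq_len(sum(lens)),
                   region = rep(rm$region, lens))
  }
  dplyr::bind_rows(one(heavy_rm, chains[1]), one(light_rm, chains[2]))
}

#' Classify framework residues into canonical structure-determining types
#'
#' @param model A `structure_model` containing exactly the two Fv chains.
#' @param regions Residue-to-region map as from [structure_regions()]:
#'   a tibble `chain`, `resno`, `region` covering every residue.
#' @param d_interface Inter-chain heavy-atom cutoff for Type 1 (default 4.5).
#' @param d_near CDR-proximity cutoff for Type 2 (default 6.0).
#' @param r_buried Relative-SASA burial ceiling for Type 2 (default 0.20).
#' @param cutoffs Interaction cutoffs for Type 3, see [detect_interactions()].
#' @param n_points Shrake-Rupley sample points for the burial term.
#' @return A `canonical_assignment`: one row per framework residue with
#'   columns `chain`, `resno`, `resname`, `region`, logical `type1`, `type2`,
#'   `type3`, the supporting evidence (`min_interchain`, `min_cdr_dist`,
#'   `rel_sasa`) and an `evidence` list-column of the Type-3 interaction
#'   records. Parameters are carried as attributes.
#' @export
classify_residues <- function(model, regions, d_interface = 4.5, d_near = 6.0,
                              r_buried = 0.20, cutoffs = DEFAULT_CUTOFFS,
                              n_points = 960) {
  chains <- sort(unique(model$chain))
  if (length(chains) != 2) {
    fvh_abort("fvh_mapping_error", sprintf(
      "model must contain exactly two chains; found: %s",
      paste(chains, collapse = ", ")))
  }
  regions <- tibble::as_tibble(regions)
  res <- dplyr::distinct(model, .data$chain, .data$resno, .data$resname) |>
    dplyr::left_join(regions, by = c("chain", "resno"))
  if (any(is.na(res$region))) {
    orphans <- res[is.na(res$region), ]
    fvh_abort("fvh_mapping_error", sprintf(
      "region map does not cover structure residue(s): %s",
      paste(paste0(orphans$chain, orphans$resno), collapse = ", ")))
  }

  at <- dplyr::left_join(tibble::as_tibble(model), regions,
                         by = c("chain", "resno"))
  coords <- as.matrix(at[c("x", "y", "z")])
  rkey <- residue_key(at$chain, at$resno, at$insert)

  min_dist_to <- function(mask_from, mask_to) {
    # per-residue (over mask_from atoms) minimum distance to mask_to atoms
    if (!any(mask_from) || !any(mask_to)) {
      return(stats::setNames(numeric(0), character(0)))
    }
    a <- coords[mask_from, , drop = FALSE]
    b <- coords[mask_to, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    d <- sqrt(pmax(d2, 0))
    tapply(apply(d, 1, min), rkey[mask_from], min)
  }

  is_fr <- startsWith(at$region, "FR")
  is_cdr <- startsWith(at$region, "CDR")

  # Type 1: inter-chain proximity of FR residues
  m1a <- min_dist_to(is_fr & at$chain == chains[1], at$chain == chains[2])
  m1b <- min_dist_to(is_fr & at$chain == chains[2], at$chain == chains[1])
  min_interchain <- c(m1a, m1b)

  # Type 2: proximity to any CDR atom (excluding the residue itself handled
  # by FR/CDR disjointness) plus burial
  mcdr <- min_dist_to(is_fr, is_cdr)
  rs <- relative_sasa(model, n_points = n_points)
  rs_key <- residue_key(rs$chain, rs$resno, rs$insert)

  # Type 3: interaction with a CDR partner
  recs <- detect_interactions(model, cutoffs = cutoffs)
  region_of <- stats::setNames(res$region, residue_key(res$chain, res$resno, NA))
  rec_reg_a <- region_of[residue_key(recs$chain_a, recs$resno_a, NA)]
  rec_reg_b <- region_of[residue_key(recs$chain_b, recs$resno_b, NA)]
  fr_cdr <- (startsWith(rec_reg_a, "FR") & startsWith(rec_reg_b, "CDR")) |
    (startsWith(rec_reg_a, "CDR") & startsWith(rec_reg_b, "FR"))
  t3recs <- recs[fr_cdr, ]

  fr_res <- res[startsWith(res$region, "FR"), ]
  fr_key <- residue_key(fr_res$chain, fr_res$resno, NA)
  out <- fr_res |>
    dplyr::mutate(
      min_interchain = as.vector(min_interchain[fr_key]),
      min_cdr_dist = as.vector(mcdr[fr_key]),
      rel_sasa = as.vector(stats::setNames(rs$rel_sasa, rs_key)[fr_key]),
      type1 = !is.na(.data$min_interchain) & .data$min_interchain <= d_interface,
      type2 = !is.na(.data$min_cdr_dist) & .data$min_cdr_dist <= d_near &
        !is.na(.data$rel_sasa) & .data$rel_sasa <= r_buried,
      evidence = purrr::map2(.data$chain, .data$resno, function(ch, rn) {
        t3recs[(t3recs$chain_a == ch & t3recs$resno_a == rn) |
                 (t3recs$chain_b == ch & t3recs$resno_b == rn), ]
      }),
      type3 = purrr::map_lgl(.data$evidence, ~ nrow(.x) > 0)
    ) |>
    dplyr::select("chain", "resno", "resname", "region", "type1", "type2",
                  "type3", "min_interchain", "min_cdr_dist", "rel_sasa",
                  "evidence") |>
    dplyr::arrange(.data$chain, .data$resno)
  new_fvh_tbl(out, "canonical_assignment",
              params = list(d_interface = d_interface, d_near = d_near,
                            r_buried = r_buried))
}

#' Propose back-mutation candidates for a grafted design
#'
#' Candidates are framework positions where the grafted residue differs from
#' the parent residue and the residue carries at least one canonical flag;
#' the installed residue is the parent (murine) one. Sequence positions are
#' mapped to structure residues by sequential index within the chain.
#'
#' @param parent A `numbered_chain` of the parent (murine) chain.
#' @param design The grafted `fv_design` for the same chain (same numbering).
#' @param assignment A `canonical_assignment` from [classify_residues()].
#' @param chain_id The structure chain id corresponding to this chain
#'   (default `"H"` for heavy, `"L"` for kappa).
#' @return A `back_mutation_spec` with additional evidence columns
#'   (`type1`, `type2`, `type3`), sorted by position.
#' @export
propose_back_mutations <- function(parent, design, assignment,
                                   chain_id = NULL) {
  if (is.null(chain_id)) {
    chain_id <- if (attr(design, "chain_type") == "heavy") "H" else "L"
  }
  pkey <- paste(parent$position, dplyr::coalesce(parent$insertion, ""))
  dkey <- paste(design$position, dplyr::coalesce(design$insertion, ""))
  if (!identical(sort(pkey), sort(dkey))) {
    fvh_abort("fvh_mapping_error",
              "parent and design do not share a common numbering")
  }
  flagged <- assignment |>
    dplyr::filter(.data$chain == chain_id,
                  .data$type1 | .data$type2 | .data$type3)

  parent_aa <- stats::setNames(parent$aa, pkey)
  cand <- design |>
    dplyr::mutate(seq_index = dplyr::row_number(),
                  parent_aa = unname(parent_aa[dkey])) |>
    dplyr::filter(startsWith(.data$region, "FR"),
                  .data$aa != .data$parent_aa,
                  .data$seq_index %in% flagged$resno)
  flags <- flagged[match(cand$seq_index, flagged$resno), c("type1", "type2", "type3")]
  out <- tibble::tibble(
    scheme = attr(design, "scheme"),
    position = cand$position, insertion = cand$insertion,
    installed = cand$parent_aa, replaced = cand$aa,
    type1 = flags$type1, type2 = flags$type2, type3 = flags$type3
  ) |> dplyr::arrange(.data$position)
  new_fvh_tbl(out, "back_mutation_spec")
}
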