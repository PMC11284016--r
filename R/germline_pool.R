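# Germline framework segment pools.

#' Construct a germline framework pool
#'
#' A pool organizes human germline framework segments by chain type
#' (heavy/kappa) and framework slot (FR1-FR4). FR4 entries are the
#' framework-encoding part of a J segment; the caller supplies the FR4-only
#' sequence (the pool never trims J genes itself). Names are kept verbatim
#' (allele suffixes such as `*01` included) and matched as exact strings.
#'
#' @param segments A data frame with columns `name`, `chain_type`, `slot`,
#'   `sequence`.
#' @return A `germline_pool` tibble.
#' @export
germline_pool <- function(segments) {
  df <- tibble::as_tibble(segments)
  req <- c("name", "chain_type", "slot", "sequence")
  if (!all(req %in% names(df))) {
    fvh_abort("fvh_schema_error", sprintf(
      "pool table must have columns %s", paste(req, collapse = ", ")))
  }
  if (any(!df$chain_type %in% CHAIN_TYPES)) {
    fvh_abort("fvh_schema_error", "chain_type must be 'heavy' or 'kappa'")
  }
  if (any(!df$slot %in% FR_SLOTS)) {
    fvh_abort("fvh_schema_error", "slot must be one of FR1-FR4")
  }
  df$sequence <- unname(vapply(df$sequence, check_sequence, "",
                               what = "germline segment",
                               error_class = "fvh_schema_error"))

  dup <- df |>
    dplyr::count(.data$chain_type, .data$slot, .data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    fvh_abort("fvh_schema_error", sprintf(
      "duplicate germline name(s) within a slot: %s",
      paste(unique(dup$name), collapse = ", ")))
  }

  # Gene-class consistency where the name is parseable as a real gene symbol.
  heavy_like <- grepl("^IGH|^JH", df$name)
  kappa_like <- grepl("^IGK|^JK", df$name)
  bad <- (heavy_like & df$chain_type != "heavy") | (kappa_like & df$chain_type != "kappa")
  j_like <- grepl("^JH|^JK|^IGHJ|^IGKJ", df$name)
  bad <- bad | (j_like & df$slot != "FR4")
  if (any(bad)) {
    fvh_abort("fvh_schema_error", sprintf(
      "segment name(s) inconsistent with declared chain/slot: %s",
      paste(df$name[bad], collapse = ", ")))
  }

  empty <- tidyr::expand_grid(chain_type = CHAIN_TYPES, slot = FR_SLOTS) |>
    dplyr::anti_join(df, by = c("chain_type", "slot"))
  if (nrow(empty) > 0) {
    rlang::warn(sprintf(
      "pool has empty slot(s): %s",
      paste(paste(empty$chain_type, empty$slot), collapse = ", ")))
  }
  df <- dplyr::arrange(df, .data$chain_type, match(.data$slot, FR_SLOTS), .data$name)
  new_fvh_tbl(df, "germline_pool")
}

#' Load a germline pool from FASTA plus a segment table
#'
#' @param segments_fasta Path to a FASTA of germline segment sequences.
#' @param segment_table Path to a TSV mapping record `name` to `chain_type`
#'   and `slot` (FR1-FR4).
#' @return A `germline_pool` tibble.
#' @export
load_pool <- function(segments_fasta, segment_table) {
  seqs <- Biostrings::readAAStringSet(segments_fasta)
  tab <- readr::read_tsv(segment_table, col_types = readr::cols(
    name = readr::col_character(), chain_type = readr::col_character(),
    slot = readr::col_character()
  ))
  nm <- sub("\\s.*$", "", names(seqs))
  unmapped <- setdiff(nm, tab$name)
  if (length(unmapped) > 0) {
    fvh_abort("fvh_schema_error", sprintf(
      "FASTA record(s) absent from the segment table: %s",
      paste(unmapped, collapse = ", ")))
  }
  missing <- setdiff(tab$name, nm)
  if (length(missing) > 0) {
    fvh_abort("fvh_schema_error", sprintf(
      "segment table row(s) without a FASTA record: %s",
      paste(missing, collapse = ", ")))
  }
  df <- tibble::tibble(name = nm, sequence = as.character(seqs)) |>
    dplyr::left_join(tab, by = "name") |>
    dplyr::select("name", "chain_type", "slot", "sequence")
  germline_pool(df)
}

#' Write a germline pool to FASTA + segment table
#'
#' @param pool A `germline_pool`.
#' @param segments_fasta,segment_table Output paths.
#' @return Invisibly, the pool.
#' @export
write_pool <- function(pool, segments_fasta, segment_table) {
  write_fasta(stats::setNames(pool$sequence, pool$name), segments_fasta)
  readr::write_tsv(pool[c("name", "chain_type", "slot")], segment_table)
  invisible(pool)
}

pool_slot <- function(pool, chain_type, slot) {
  out <- dplyr::filter(pool, .data$chain_type == !!chain_type, .data$slot == !!slot)
  if (nrow(out) == 0) {
    fvh_abort("fvh_config_error", sprintf(
      "pool slot %s/%s is empty", chain_type, slot))
  }
  out
}

#' Combinatorial diversity of a framework pool
#'
#' The number of distinct FR1-FR4 combinations (heavy x kappa) available at
#' fixed CDRs: the product of the eight slot sizes.
#'
#' @param pool A `germline_pool` with all eight slots non-empty.
#' @return A single number (double, since real pools exceed integer range).
#' @export
pool_diversity <- function(pool) {
  sizes <- tidyr::expand_grid(chain_type = CHAIN_TYPES, slot = FR_SLOTS) |>
    dplyr::left_join(dplyr::count(pool, .data$chain_type, .data$slot),
                     by = c("chain_type", "slot"))
  if (any(is.na(sizes$n) | sizes$n == 0)) {
    empty <- sizes[is.na(sizes$n) | sizes$n == 0, ]
    fvh_abort("fvh_config_error", sprintf(
      "pool_diversity requires all 8 slots non-empty; empty: %s",
      paste(paste(empty$chain_type, empty$slot), collapse = ", ")))
  }
  prod(as.numeric(sizes$n))
}

#' @export
glance.germline_pool <- function(x, ...) {
  counts <- dplyr::count(x, .data$chain_type, .data$slot) |>
    tidyr::unite("key", "chain_type", "slot") |>
    tidyr::pivot_wider(names_from = "key", values_from = "n")
  div <- tryCatch(pool_diversity(x), error = function(e) NA_real_)
  dplyr::bind_cols(tibble::tibble(n_segments = nrow(x), diversity = div), counts)
}
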