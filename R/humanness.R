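# Repertoire-based humanness metrics and MHC class II strong-binder counting.
# These implement the scoring logic (9-mer repertoire content; mean identity
# to the top-k most similar references) against a user-supplied or synthetic
# repertoire. They deliberately do not reproduce any external database-backed
# score: reports carry the repertoire's source label so numbers are never
# compared across repertoires.

#' Build a repertoire index
#'
#' Indexes a reference sequence set for humanness scoring: every overlapping
#' 9-mer with its prevalence (fraction of reference sequences containing it),
#' plus the full-length references for top-k identity.
#'
#' @param sequences Named character vector of reference sequences (or a path
#'   handled by [read_fasta()] first).
#' @param label Source label propagated into reports.
#' @param prevalence Optional precomputed prevalence tibble
#'   (`ninemer`, `prevalence` in `[0, 1]`), overriding the computed one.
#' @return A `repertoire_index`: list with `label`, `ninemers`, `references`.
#' @export
repertoire_index <- function(sequences, label = "user-repertoire",
                             prevalence = NULL) {
  sequences <- vapply(sequences, check_sequence, "", what = "reference sequence")
  if (is.null(prevalence)) {
    per_seq <- purrr::map(sequences, function(s) {
      if (nchar(s) < 9) return(character(0))
      unique(substring(s, 1:(nchar(s) - 8), 9:nchar(s)))
    })
    counts <- table(unlist(per_seq))
    prevalence <- tibble::tibble(ninemer = names(counts),
                                 prevalence = as.numeric(counts) / length(sequences))
  } else {
    prevalence <- tibble::as_tibble(prevalence)
    if (any(prevalence$prevalence < 0 | prevalence$prevalence > 1) ||
        any(nchar(prevalence$ninemer) != 9)) {
      fvh_abort("fvh_input_error",
                "prevalence table must hold 9-mers with prevalences in [0, 1]")
    }
    prevalence$ninemer <- toupper(prevalence$ninemer)
  }
  structure(list(label = label, ninemers = prevalence,
                 references = sequences),
            class = "repertoire_index")
}

#' 9-mer repertoire content
#'
#' Fraction of the sequence's overlapping 9-mers whose prevalence in the
#' repertoire index is at least `min_prevalence`. A peptide-level humanness
#' measure: 1 means every 9-mer window is common in the reference repertoire.
#'
#' @param sequence Query amino-acid sequence (length >= 9).
#' @param index A [repertoire_index()].
#' @param min_prevalence Prevalence threshold in `[0, 1]` (default 0.01).
#' @return A score in `[0, 1]`.
#' @export
ninemer_content <- function(sequence, index, min_prevalence = 0.01) {
  sequence <- check_sequence(sequence)
  if (nchar(sequence) < 9) {
    fvh_abort("fvh_input_error", "sequence must be at least 9 residues long")
  }
  windows <- substring(sequence, 1:(nchar(sequence) - 8), 9:nchar(sequence))
  prev <- stats::setNames(index$ninemers$prevalence, index$ninemers$ninemer)
  p <- unname(prev[windows])
  p[is.na(p)] <- 0
  mean(p >= min_prevalence)
}

#' Mean identity to the top-k most similar references
#'
#' Global-alignment percent identity (matches over alignment length, gaps
#' counting against identity) to every reference; the mean of the `k` largest
#' is returned, with `k` capped at the number of references.
#'
#' @param sequence Query amino-acid sequence.
#' @param references Character vector of reference sequences, or a
#'   `repertoire_index`.
#' @param k Number of top references to average (default 20).
#' @return Mean percent identity in `[0, 100]`.
#' @export
topk_identity <- function(sequence, references, k = 20) {
  if (inherits(references, "repertoire_index")) references <- references$references
  if (length(references) == 0) {
    fvh_abort("fvh_input_error", "reference set must be non-empty")
  }
  sequence <- check_sequence(sequence)
  ids <- vapply(references, function(r) percent_identity(sequence, r, "alignment"),
                numeric(1))
  k <- min(k, length(ids))
  mean(sort(ids, decreasing = TRUE)[seq_len(k)])
}

#' Per-chain humanness report
#'
#' @param heavy,light Chain sequences.
#' @param index A [repertoire_index()].
#' @param min_prevalence Passed to [ninemer_content()].
#' @param k Passed to [topk_identity()].
#' @return A `humanness_report` tibble: one row per chain with
#'   `ninemer_content`, `topk_identity`, `k`, `min_prevalence`, `repertoire`.
#' @export
humanness_report <- function(heavy, light, index, min_prevalence = 0.01, k = 20) {
  rows <- purrr::map2(
    c(heavy = heavy, light = light), c("heavy", "light"),
    function(s, ct) {
      tibble::tibble(
        chain = ct,
        ninemer_content = ninemer_content(s, index, min_prevalence),
        topk_identity = topk_identity(s, index, k),
        k = min(k, length(index$references)),
        min_prevalence = min_prevalence,
        repertoire = index$label
      )
    })
  new_fvh_tbl(dplyr::bind_rows(rows), "humanness_report")
}

#' @export
tidy.humanness_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' Read an MHC class II prediction table
#'
#' @param path TSV with columns `peptide`, `allele`, `rank` (percentile rank
#'   as emitted by an MHC-II binding predictor).
#' @return An epitope table tibble.
#' @export
read_epitope_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    peptide = readr::col_character(), allele = readr::col_character(),
    rank = readr::col_double()
  ))
}

#' Count predicted MHC class II strong binders
#'
#' A peptide row is a strong binder for its allele when its percentile rank
#' is at or below `rank_threshold` (default 1% rank). Returns per-allele
#' counts plus a `total` row summing over alleles.
#'
#' @param table Epitope table with columns `peptide`, `allele`, `rank`.
#' @param rank_threshold Strong-binder percentile-rank threshold (default 1).
#' @return An `epitope_counts` tibble: `allele`, `strong_binders`, ending in
#'   a `total` row.
#' @export
count_strong_binders <- function(table, rank_threshold = 1.0) {
  table <- tibble::as_tibble(table)
  if (!all(c("peptide", "allele", "rank") %in% names(table))) {
    fvh_abort("fvh_validation_error",
              "epitope table must have columns peptide, allele, rank")
  }
  if (any(is.na(table$rank) | table$rank < 0)) {
    fvh_abort("fvh_validation_error", "percentile ranks must be non-negative")
  }
  if (any(is.na(table$allele) | !nzchar(table$allele))) {
    fvh_abort("fvh_validation_error", "allele names must be non-empty")
  }
  per <- table |>
    dplyr::group_by(allele = .data$allele) |>
    dplyr::summarise(strong_binders = sum(.data$rank <= rank_threshold),
                     .groups = "drop") |>
    dplyr::arrange(.data$allele)
  out <- dplyr::bind_rows(
    per, tibble::tibble(allele = "total",
                        strong_binders = sum(per$strong_binders)))
  new_fvh_tbl(out, "epitope_counts", rank_threshold = rank_threshold)
}
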