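# Chain numbering and region segmentation.

#' Number an antibody variable-domain chain
#'
#' Assigns scheme positions to every residue of a heavy or kappa variable
#' domain by global alignment to the bundled consensus template of the chosen
#' scheme. Template-matched residues inherit the template position; residues
#' falling in a template gap (insertions relative to the template) are labeled
#' with the last matched position plus an insertion code (`"A"`, `"B"`, ...).
#'
#' @param sequence Amino-acid string (one-letter codes), 90-140 residues.
#' @param chain_type `"heavy"` or `"kappa"`. Lambda chains are rejected.
#' @param scheme `"imgt"` (default) or `"kabat"`.
#' @param min_score Alignment-score floor; a query whose BLOSUM62 global
#'   alignment to the template scores below this is considered unalignable.
#' @return A `numbered_chain`: a tibble with columns `position` (integer
#'   scheme position), `insertion` (letter or `NA`), `aa`, carrying
#'   `chain_type`, `scheme` and `sequence` attributes.
#' @examples
#' nc <- number_chain(scheme_template("imgt", "heavy")$sequence, "heavy")
#' head(nc)
#' @export
number_chain <- function(sequence, chain_type, scheme = "imgt", min_score = 0) {
  chain_type <- check_chain_type(chain_type)
  scheme <- check_scheme(scheme)
  sequence <- check_sequence(sequence)
  if (nchar(sequence) < 90 || nchar(sequence) > 140) {
    fvh_abort("fvh_input_error", sprintf(
      "sequence length %d outside plausible Fv-domain bounds (90-140)", nchar(sequence)))
  }
  tmpl <- scheme_template(scheme, chain_type)

  if (identical(sequence, tmpl$sequence)) {
    pos <- seq_len(nchar(sequence))
    ins <- rep(NA_character_, length(pos))
  } else {
    # stiff gap penalties: numbering wants positional transfer, so gaps are
    # admitted only where an indel is genuinely required
    al <- align_global(sequence, tmpl$sequence, gap_open = 25, gap_extend = 2)
    if (al$score < min_score) {
      fvh_abort("fvh_annotation_error", sprintf(
        "%s chain could not be aligned to the %s template (score %.1f < floor %.1f)",
        chain_type, scheme, al$score, min_score))
    }
    pos <- integer(0); ins <- character(0)
    tpos <- 0L; ins_run <- 0L
    for (i in seq_along(al$pattern)) {
      q <- al$pattern[i]; t <- al$subject[i]
      if (t != "-") { tpos <- tpos + 1L; ins_run <- 0L }
      if (q != "-") {
        if (t != "-") {
          pos <- c(pos, tpos); ins <- c(ins, NA_character_)
        } else {
          ins_run <- ins_run + 1L
          pos <- c(pos, tpos); ins <- c(ins, LETTERS[ins_run])
        }
      }
    }
  }
  new_fvh_tbl(
    tibble::tibble(position = as.integer(pos), insertion = ins,
                   aa = strsplit(sequence, "")[[1]]),
    "numbered_chain",
    chain_type = chain_type, scheme = scheme, sequence = sequence
  )
}

#' Segment a numbered chain into framework and CDR regions
#'
#' Cuts a [number_chain()] result into FR1-FR4 and CDR1-CDR3 using the
#' scheme's CDR boundary table. Residues numbered before the FR1 interval
#' (leading insertions) fall into FR1 so that the seven regions always
#' concatenate back to the input sequence.
#'
#' @param nc A `numbered_chain`.
#' @param boundaries Optional boundary table (see [cdr_boundaries()]).
#' @return A `region_map`: tibble with columns `region`, `start`, `end`
#'   (scheme interval), `length`, `sequence`, carrying the chain's attributes.
#' @export
segment_regions <- function(nc, boundaries = NULL) {
  if (!inherits(nc, "numbered_chain")) {
    fvh_abort("fvh_input_error", "`nc` must be a numbered_chain")
  }
  chain_type <- attr(nc, "chain_type"); scheme <- attr(nc, "scheme")
  bounds <- if (is.null(boundaries)) cdr_boundaries(scheme, chain_type) else
    dplyr::filter(boundaries, .data$scheme == !!scheme, .data$chain_type == !!chain_type)
  bounds <- bounds[match(REGION_ORDER, bounds$region), ]

  # Assign each residue to the region whose interval contains its position;
  # positions below FR1's start are swept into FR1.
  idx <- findInterval(nc$position, bounds$start)
  idx[idx == 0L] <- 1L
  region <- bounds$region[idx]

  present <- REGION_ORDER %in% region
  if (!all(present)) {
    fvh_abort("fvh_partial_chain_error", sprintf(
      "chain is incomplete: missing region(s) %s",
      paste(REGION_ORDER[!present], collapse = ", ")))
  }

  seqs <- vapply(REGION_ORDER, function(r) paste(nc$aa[region == r], collapse = ""), "")
  new_fvh_tbl(
    tibble::tibble(region = REGION_ORDER, start = bounds$start, end = bounds$end,
                   length = unname(nchar(seqs)), sequence = unname(seqs)),
    "region_map",
    chain_type = chain_type, scheme = scheme,
    sequence = paste(nc$aa, collapse = "")
  )
}

region_sequence <- function(rm, region) {
  rm$sequence[match(region, rm$region)]
}
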