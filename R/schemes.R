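# Numbering-scheme machinery: bundled consensus templates and CDR boundary
# tables. Numbering is alignment-to-template: a query is globally aligned to
# the scheme's consensus template and inherits the template's positions.
# Both templates here are gapless (every scheme position occupied), so the
# template's own numbering is simply 1..N; queries with indels pick up skipped
# positions or insertion codes. The CDR boundary table ships as an editable
# TSV (inst/extdata/cdr_boundaries.tsv) so users can swap CDR definitions
# without touching code.

TEMPLATE_REGIONS <- list(
  imgt = list(
    heavy = c(
      FR1  = "EVQLVESGGGLVQPGGSLRLSCAASG",
      CDR1 = "GFTFSSYGMSVK",
      FR2  = "WVRQAPGKGLEWVSAIG",
      CDR2 = "ISGSGGSTYY",
      FR3  = "ADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAKG",
      CDR3 = "ARDGSSYGYFDYV",
      FR4  = "WGQGTLVTVSS"
    ),
    kappa = c(
      FR1  = "EIVLTQSPGTLSLSPGERATLSCRAS",
      CDR1 = "QSVSSSYLASNK",
      FR2  = "WYQQKPGQAPRLLIYGA",
      CDR2 = "GASSRATSLE",
      FR3  = "GIPDRFSGSGSGTDFTLTISRLEPEDFAVYYCSQESGVP",
      CDR3 = "QQYNSYSPLYTWS",
      FR4  = "FGQGTKVEIK"
    )
  ),
  kabat = list(
    heavy = c(
      FR1  = "EVQLVESGGGLVQPGGSLRLSCAASGFTFS",
      CDR1 = "SYAMS",
      FR2  = "WVRQAPGKGLEWVS",
      CDR2 = "AISGSGGSTYYADSVK",
      FR3  = "GRFTISRDNSKNTLYLQMNSLRAEDTAVY",
      CDR3 = "DRGGYFDY",
      FR4  = "WGQGTLVTVSS"
    ),
    kappa = c(
      FR1  = "EIVLTQSPGTLSLSPGERATLSC",
      CDR1 = "RASQSVSSYLA",
      FR2  = "WYQQKPGQAPRLLIY",
      CDR2 = "GASSRAT",
      FR3  = "GIPDRFSGSGSGTDFTLTISRLEPEDFAVYYC",
      CDR3 = "QQYGSSPYT",
      FR4  = "FGQGTKVEIK"
    )
  )
)

.fvh_cache <- new.env(parent = emptyenv())

#' CDR/FR boundary definitions
#'
#' Reads the bundled (or a user-supplied) boundary table giving, for each
#' numbering scheme and chain type, the scheme-position interval of each of
#' the seven variable-domain regions (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4).
#'
#' @param scheme Optional filter: `"imgt"` or `"kabat"`.
#' @param chain_type Optional filter: `"heavy"` or `"kappa"`.
#' @param path Path to a boundary TSV with columns
#'   `scheme`, `chain_type`, `region`, `start`, `end`. Defaults to the table
#'   bundled with the package.
#' @return A tibble with columns `scheme`, `chain_type`, `region`, `start`,
#'   `end`.
#' @export
cdr_boundaries <- function(scheme = NULL, chain_type = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cdr_boundaries.tsv", package = "fvhumanize")
  }
  key <- paste0("boundaries::", path)
  if (is.null(.fvh_cache[[key]])) {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      scheme = readr::col_character(), chain_type = readr::col_character(),
      region = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer()
    ))
    .fvh_cache[[key]] <- tibble::as_tibble(tab)
  }
  out <- .fvh_cache[[key]]
  if (!is.null(scheme)) out <- dplyr::filter(out, .data$scheme == !!scheme)
  if (!is.null(chain_type)) out <- dplyr::filter(out, .data$chain_type == !!chain_type)
  out
}

#' Scheme consensus template
#'
#' Returns the bundled consensus template used for alignment-based numbering:
#' the full template sequence plus its per-region decomposition with scheme
#' position intervals.
#'
#' @param scheme `"imgt"` or `"kabat"`.
#' @param chain_type `"heavy"` or `"kappa"`.
#' @return A list with elements `sequence` (string) and `regions` (tibble of
#'   `region`, `start`, `end`, `sequence`).
#' @export
scheme_template <- function(scheme = "imgt", chain_type = "heavy") {
  scheme <- check_scheme(scheme)
  chain_type <- check_chain_type(chain_type)
  regs <- TEMPLATE_REGIONS[[scheme]][[chain_type]]
  bounds <- cdr_boundaries(scheme, chain_type)
  bounds <- bounds[match(REGION_ORDER, bounds$region), ]
  widths <- bounds$end - bounds$start + 1L
  if (!identical(unname(nchar(regs[REGION_ORDER])), as.integer(widths))) {
    fvh_abort("fvh_config_error", sprintf(
      "boundary table widths do not tile the %s/%s template", scheme, chain_type))
  }
  list(
    sequence = paste(regs[REGION_ORDER], collapse = ""),
    regions = tibble::tibble(
      region = REGION_ORDER,
      start = bounds$start, end = bounds$end,
      sequence = unname(regs[REGION_ORDER])
    )
  )
}

template_region <- function(scheme, chain_type, region) {
  TEMPLATE_REGIONS[[scheme]][[chain_type]][[region]]
}
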