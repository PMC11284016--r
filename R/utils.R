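# Shared validation helpers and error conditions. All package errors carry a
# subclass of the form "fvh_*_error" so callers can condition on failure mode.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

fvh_abort <- function(class, msg, ...) {
  rlang::abort(msg, class = c(class, "fvh_error"), ...)
}

check_sequence <- function(sequence, what = "sequence",
                           error_class = "fvh_input_error") {
  if (!rlang::is_string(sequence) || !nzchar(sequence)) {
    fvh_abort(error_class, sprintf("%s must be a non-empty string", what))
  }
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad) > 0) {
    fvh_abort(error_class, sprintf(
      "%s contains characters outside the 20-letter amino-acid alphabet: %s",
      what, paste(unique(bad), collapse = ", ")
    ))
  }
  sequence
}

check_chain_type <- function(chain_type) {
  if (identical(chain_type, "lambda")) {
    fvh_abort("fvh_input_error",
              "lambda light chains are not supported; only heavy and kappa chains are modeled")
  }
  rlang::arg_match0(chain_type, c("heavy", "kappa"))
}

check_scheme <- function(scheme) {
  rlang::arg_match0(scheme, c("imgt", "kabat"))
}

FR_SLOTS <- c("FR1", "FR2", "FR3", "FR4")
CDR_SLOTS <- c("CDR1", "CDR2", "CDR3")
REGION_ORDER <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
CHAIN_TYPES <- c("heavy", "kappa")

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

new_fvh_tbl <- function(df, class, ...) {
  out <- tibble::as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}

# Random amino-acid string helper shared by the generators.
random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

mutate_sequence <- function(sequence, rate) {
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  list(sequence = paste(chars, collapse = ""), positions = hit)
}
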