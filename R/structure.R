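# Atomic structure container and PDB I/O (via bio3d).

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `insert`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param label Model label used in comparisons.
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms, label = "model") {
  df <- tibble::as_tibble(atoms)
  req <- c("chain", "resno", "insert", "resname", "atom", "element", "x", "y", "z")
  if (!all(req %in% names(df))) {
    fvh_abort("fvh_format_error", sprintf(
      "atom table must have columns %s", paste(req, collapse = ", ")))
  }
  if (nrow(df) == 0) fvh_abort("fvh_format_error", "structure model is empty")
  coords <- as.matrix(df[c("x", "y", "z")])
  if (any(!is.finite(coords))) {
    fvh_abort("fvh_format_error", "non-finite atomic coordinates")
  }
  key <- paste(df$chain, df$resno, df$insert, df$atom)
  if (anyDuplicated(key)) {
    fvh_abort("fvh_format_error", "duplicate (chain, resno, insertion, atom) records")
  }
  new_fvh_tbl(df, "structure_model", label = label)
}

element_from_name <- function(atom, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- nzchar(e)
  } else {
    e <- character(length(atom)); ok <- rep(FALSE, length(atom))
  }
  guess <- toupper(substr(gsub("^[0-9]+", "", atom), 1, 1))
  ifelse(ok, e, guess)
}

#' Read a structure model from a PDB file
#'
#' Parses with `bio3d::read.pdb()`. By default hydrogens and HETATM records
#' are dropped and alternate locations are resolved to the highest-occupancy
#' conformer. Multi-model files are indexed with `model_index`.
#'
#' @param pdb_path Path to a PDB file.
#' @param model_index 1-based MODEL index (default 1).
#' @param keep_hydrogens,keep_het Keep hydrogen / HETATM records?
#' @param label Model label (defaults to the file name).
#' @return A `structure_model` tibble.
#' @export
read_structure <- function(pdb_path, model_index = 1, keep_hydrogens = FALSE,
                           keep_het = FALSE, label = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_path, multi = TRUE, verbose = FALSE)),
    error = function(e) fvh_abort("fvh_format_error", sprintf(
      "could not parse PDB file '%s': %s", pdb_path, conditionMessage(e)))
  )
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    fvh_abort("fvh_format_error", sprintf(
      "model_index %d out of range (file has %d model(s))", model_index, n_models))
  }
  xyz <- pdb$xyz[model_index, ]
  at$x <- xyz[seq(1, length(xyz), 3)]
  at$y <- xyz[seq(2, length(xyz), 3)]
  at$z <- xyz[seq(3, length(xyz), 3)]

  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z) | is.na(at$resno))) {
    fvh_abort("fvh_format_error", sprintf(
      "malformed ATOM record(s) in '%s' (missing coordinates or residue numbers)",
      pdb_path))
  }
  if (!keep_het) at <- at[at$type == "ATOM", ]
  at$element <- element_from_name(at$elety, at$elesy)
  if (!keep_hydrogens) at <- at[!at$element %in% c("H", "D"), ]
  if (nrow(at) == 0) fvh_abort("fvh_format_error", "model contains no atoms after filtering")

  df <- tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", NA_character_, at$insert),
    resname = at$resid, atom = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z,
    alt = ifelse(is.na(at$alt), "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
  df <- df |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-"alt", -"occupancy", -".ord")
  structure_model(df, label = label %||% basename(pdb_path))
}

#' Write a structure model to a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(model[c("x", "y", "z")]))),
    resno = model$resno, chain = model$chain, resid = model$resname,
    elety = model$atom, insert = ifelse(is.na(model$insert), "", model$insert),
    elesy = model$element, eleno = seq_len(nrow(model))
  )
  invisible(path)
}

#' Apply a rigid motion to a structure model
#'
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 translation vector in Angstrom.
#' @return The transformed `structure_model`.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  coords <- as.matrix(model[c("x", "y", "z")]) %*% t(rotation)
  model$x <- coords[, 1] + translation[1]
  model$y <- coords[, 2] + translation[2]
  model$z <- coords[, 3] + translation[3]
  model
}
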