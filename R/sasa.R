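# Shrake-Rupley solvent-accessible surface area.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
DEFAULT_VDW <- 1.70

# Theoretical per-residue maxima in an extended Gly-X-Gly context
# (Tien et al. 2013), square Angstrom.
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA: each atom's solvent-expanded sphere
#' (van der Waals radius plus probe) is sampled at `n_points` deterministic
#' sphere points; points falling inside any neighboring expanded sphere are
#' buried, and the accessible fraction scales the sphere's area.
#'
#' @param model A `structure_model` (heavy atoms).
#' @param n_points Sample points per atom (default 960).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @return The model's atom table with `radius` and `sasa` columns.
#' @export
atom_sasa <- function(model, n_points = 960, probe = 1.4) {
  n <- nrow(model)
  coords <- as.matrix(model[c("x", "y", "z")])
  radii <- unname(VDW_RADII[model$element])
  radii[is.na(radii)] <- DEFAULT_VDW
  expanded <- radii + probe
  pts <- sphere_points(n_points)

  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") - 2 * coords %*% t(coords)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (expanded[i] + expanded)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      sasa[i] <- 4 * pi * expanded[i]^2
      next
    }
    sp <- sweep(pts * expanded[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
        (sp[, 3] - coords[j, 3])^2
      free <- free & dj2 > expanded[j]^2
      if (!any(free)) break
    }
    sasa[i] <- mean(free) * 4 * pi * expanded[i]^2
  }
  dplyr::mutate(tibble::as_tibble(model), radius = radii, sasa = sasa)
}

#' Per-residue relative solvent accessibility
#'
#' Sums atom SASA per residue and divides by the bundled per-residue maximum
#' (Gly-X-Gly reference); values are clipped to `[0, 1]`. Residues with names
#' outside the 20 standard amino acids are skipped with a warning.
#'
#' @inheritParams atom_sasa
#' @return A tibble: `chain`, `resno`, `insert`, `resname`, `sasa`,
#'   `max_sasa`, `rel_sasa`.
#' @export
relative_sasa <- function(model, n_points = 960, probe = 1.4) {
  at <- atom_sasa(model, n_points = n_points, probe = probe)
  res <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resname) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
  unknown <- !res$resname %in% names(MAX_ASA)
  if (any(unknown)) {
    rlang::warn(sprintf(
      "skipping residue(s) with unknown name(s) for relative SASA: %s",
      paste(unique(res$resname[unknown]), collapse = ", ")))
    res <- res[!unknown, ]
  }
  res$max_sasa <- unname(MAX_ASA[res$resname])
  res$rel_sasa <- pmin(1, pmax(0, res$sasa / res$max_sasa))
  res
}
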