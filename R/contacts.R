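# Four-class residue interaction analysis at fixed distance thresholds:
# hydrogen bonds (N/O atoms, 3.5 A), hydrophobic contacts (non-alpha side
# chain carbons of LEU/ILE/VAL/PHE/TRP/MET, 5.0 A), salt bridges (basic
# side-chain N vs acidic side-chain O, 4.0 A) and pi-pi stacking (aromatic
# ring centroids, 6.5 A). Definitions are purely distance-based; no
# donor/acceptor chemistry, protonation or ring-angle terms.

HYDROPHOBIC_SET <- c("LEU", "ILE", "VAL", "PHE", "TRP", "MET")
BASIC_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
RING_ATOMS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(pyrrole = c("CG", "CD1", "NE1", "CE2", "CD2"),
             benzene = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)
DEFAULT_CUTOFFS <- c(hbond = 3.5, hydrophobic = 5.0, salt_bridge = 4.0, pi_pi = 6.5)

residue_key <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert), "", insert), sep = ":")
}

# Cross-set atom pairs within cutoff, reduced to one record per residue pair
# (minimal realizing distance), canonicalized so A < B by (chain, resno,
# insertion).
pair_records <- function(a, b, cutoff, class, same_set = FALSE,
                         exclude = NULL) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_records())
  ax <- as.matrix(a[c("x", "y", "z")]); bx <- as.matrix(b[c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_records())
  ia <- hit[, 1]; ib <- hit[, 2]
  rec <- tibble::tibble(
    class = class,
    chain_a = a$chain[ia], resno_a = a$resno[ia], insert_a = a$insert[ia],
    resname_a = a$resname[ia], atom_a = a$atom[ia],
    chain_b = b$chain[ib], resno_b = b$resno[ib], insert_b = b$insert[ib],
    resname_b = b$resname[ib], atom_b = b$atom[ib],
    distance = sqrt(d2[hit])
  )
  key_a <- residue_key(rec$chain_a, rec$resno_a, rec$insert_a)
  key_b <- residue_key(rec$chain_b, rec$resno_b, rec$insert_b)
  rec <- rec[key_a != key_b, ]
  if (nrow(rec) == 0) return(empty_records())
  if (!is.null(exclude)) {
    rec <- rec[!exclude(rec), ]
    if (nrow(rec) == 0) return(empty_records())
  }
  canonicalize_records(rec, dedupe_mirror = same_set)
}

canonicalize_records <- function(rec, dedupe_mirror = FALSE) {
  swap <- with(rec, chain_b < chain_a |
                 (chain_b == chain_a & (resno_b < resno_a |
                    (resno_b == resno_a &
                       dplyr::coalesce(insert_b, "") < dplyr::coalesce(insert_a, "")))))
  if (any(swap)) {
    acols <- c("chain_a", "resno_a", "insert_a", "resname_a", "atom_a")
    bcols <- c("chain_b", "resno_b", "insert_b", "resname_b", "atom_b")
    tmp <- rec[swap, acols]
    rec[swap, acols] <- rec[swap, bcols]
    rec[swap, bcols] <- tmp
  }
  rec |>
    dplyr::group_by(.data$class, .data$chain_a, .data$resno_a, .data$insert_a,
                    .data$chain_b, .data$resno_b, .data$insert_b) |>
    dplyr::arrange(.data$distance, .data$atom_a, .data$atom_b, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b)
}

empty_records <- function() {
  tibble::tibble(
    class = character(), chain_a = character(), resno_a = integer(),
    insert_a = character(), resname_a = character(), atom_a = character(),
    chain_b = character(), resno_b = integer(), insert_b = character(),
    resname_b = character(), atom_b = character(), distance = numeric()
  )
}

#' Hydrogen bonds (distance-only definition)
#'
#' All nitrogen-oxygen atom pairs within `cutoff`, one record per residue
#' pair keeping the minimal realizing distance. Pairs within one residue are
#' never counted, and by default the backbone N-O pair of sequence-adjacent
#' residues is excluded to suppress the covalent peptide-bond artifact.
#'
#' @param model A `structure_model`.
#' @param cutoff Distance threshold in Angstrom (default 3.5).
#' @param exclude_adjacent Drop backbone N-O pairs of residues adjacent in
#'   sequence (default `TRUE`).
#' @return A tibble of interaction records.
#' @export
hydrogen_bonds <- function(model, cutoff = 3.5, exclude_adjacent = TRUE) {
  no <- model[model$element %in% c("N", "O"), ]
  excl <- NULL
  if (exclude_adjacent) {
    excl <- function(rec) {
      rec$chain_a == rec$chain_b & abs(rec$resno_a - rec$resno_b) == 1 &
        ((rec$atom_a == "N" & rec$atom_b == "O") |
           (rec$atom_a == "O" & rec$atom_b == "N"))
    }
  }
  pair_records(no, no, cutoff, "hbond", same_set = TRUE, exclude = excl)
}

#' Hydrophobic contacts
#'
#' Side-chain carbon pairs (alpha carbons excluded) between residues in the
#' hydrophobic set LEU/ILE/VAL/PHE/TRP/MET within `cutoff`.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Distance threshold in Angstrom (default 5.0).
#' @return A tibble of interaction records.
#' @export
hydrophobic_contacts <- function(model, cutoff = 5.0) {
  cc <- model[model$element == "C" & model$atom != "CA" &
                model$resname %in% HYDROPHOBIC_SET, ]
  pair_records(cc, cc, cutoff, "hydrophobic", same_set = TRUE)
}

#' Salt bridges
#'
#' A basic side-chain nitrogen (ARG NE/NH1/NH2, LYS NZ, HIS ND1/NE2 --
#' histidine is treated as positively charged) within `cutoff` of an acidic
#' side-chain oxygen (ASP OD1/OD2, GLU OE1/OE2).
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Distance threshold in Angstrom (default 4.0).
#' @return A tibble of interaction records.
#' @export
salt_bridges <- function(model, cutoff = 4.0) {
  pick <- function(def) {
    keep <- rep(FALSE, nrow(model))
    for (rn in names(def)) {
      keep <- keep | (model$resname == rn & model$atom %in% def[[rn]])
    }
    model[keep, ]
  }
  pair_records(pick(BASIC_ATOMS), pick(ACIDIC_ATOMS), cutoff, "salt_bridge")
}

ring_centroids <- function(model) {
  arom <- model[model$resname %in% names(RING_ATOMS), ]
  if (nrow(arom) == 0) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          insert = character(), resname = character(),
                          ring = character(), x = numeric(), y = numeric(),
                          z = numeric()))
  }
  arom |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resname) |>
    dplyr::group_modify(function(df, key) {
      rings <- RING_ATOMS[[key$resname]]
      purrr::imap(rings, function(atoms, ring_name) {
        sub <- df[df$atom %in% atoms, ]
        if (nrow(sub) < length(atoms)) {
          rlang::warn(sprintf(
            "residue %s %s%s is missing ring atoms; skipped for pi-pi analysis",
            key$resname, key$resno, ifelse(is.na(key$insert), "", key$insert)))
          return(NULL)
        }
        tibble::tibble(ring = ring_name, x = mean(sub$x), y = mean(sub$y),
                       z = mean(sub$z))
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::ungroup()
}

#' Pi-pi stacking
#'
#' Aromatic ring centroid pairs (PHE, TYR, TRP, HIS) within `cutoff`;
#' tryptophan contributes both its pyrrole and benzene rings, and the
#' minimal centroid-centroid distance per residue pair is kept. Distance
#' only -- no ring-plane angle term.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Distance threshold in Angstrom (default 6.5).
#' @return A tibble of interaction records.
#' @export
pi_stacking <- function(model, cutoff = 6.5) {
  cen <- ring_centroids(model)
  if (nrow(cen) == 0) return(empty_records())
  cen$atom <- paste0("ring:", cen$ring)
  cen$element <- "X"
  pair_records(cen, cen, cutoff, "pi_pi", same_set = TRUE)
}

#' Detect all interaction classes at once
#'
#' @inheritParams hydrogen_bonds
#' @param classes Which classes to compute.
#' @param cutoffs Named numeric vector of per-class distance thresholds.
#' @param exclude_adjacent Passed to [hydrogen_bonds()].
#' @return A tibble of interaction records across the requested classes.
#' @export
detect_interactions <- function(model,
                                classes = c("hbond", "hydrophobic",
                                            "salt_bridge", "pi_pi"),
                                cutoffs = DEFAULT_CUTOFFS,
                                exclude_adjacent = TRUE) {
  classes <- match.arg(classes, several.ok = TRUE)
  cutoffs <- utils::modifyList(as.list(DEFAULT_CUTOFFS), as.list(cutoffs))
  out <- list()
  if ("hbond" %in% classes) {
    out$hbond <- hydrogen_bonds(model, cutoffs$hbond, exclude_adjacent)
  }
  if ("hydrophobic" %in% classes) {
    out$hydrophobic <- hydrophobic_contacts(model, cutoffs$hydrophobic)
  }
  if ("salt_bridge" %in% classes) {
    out$salt_bridge <- salt_bridges(model, cutoffs$salt_bridge)
  }
  if ("pi_pi" %in% classes) out$pi_pi <- pi_stacking(model, cutoffs$pi_pi)
  dplyr::bind_rows(out)
}

interaction_keys <- function(records) {
  if (nrow(records) == 0) return(character(0))
  with(records, paste(class,
                      residue_key(chain_a, resno_a, insert_a),
                      residue_key(chain_b, resno_b, insert_b)))
}

#' Compare interaction sets across predicted structures
#'
#' Interactions are keyed by (class, residue-pair identity, chain ids); the
#' report lists interactions shared by all models, interactions unique to
#' each model, and the pairwise Jaccard similarity of the interaction sets.
#' High similarity across independently predicted models of the same Fv
#' indicates that the detected contacts are robust to the modeling method.
#'
#' @param models A list of two or more `structure_model`s with compatible
#'   residue identifiers.
#' @param ... Passed to [detect_interactions()].
#' @return A `model_comparison`: list with `interactions` (long tibble with a
#'   `model` column), `shared` (keys present in every model), `unique`
#'   (named list of per-model unique keys) and `jaccard` (pairwise tibble).
#' @export
compare_models <- function(models, ...) {
  if (length(models) < 2) {
    fvh_abort("fvh_comparison_error", "need at least two models to compare")
  }
  labels <- purrr::imap_chr(models, function(m, i) {
    attr(m, "label") %||% paste0("model", i)
  })
  if (anyDuplicated(labels)) labels <- make.unique(labels)

  res_sets <- purrr::map(models, ~ unique(residue_key(.x$chain, .x$resno, .x$insert)))
  common <- Reduce(intersect, res_sets)
  if (length(common) == 0) {
    fvh_abort("fvh_comparison_error", paste(
      "models share no residue identifiers; renumber the structures or supply",
      "a residue mapping before comparing"))
  }

  recs <- purrr::map(models, detect_interactions, ...)
  keys <- purrr::map(recs, interaction_keys)
  names(recs) <- names(keys) <- labels

  shared <- Reduce(intersect, keys)
  uniq <- purrr::imap(keys, function(k, lab) {
    setdiff(k, unique(unlist(keys[setdiff(labels, lab)])))
  })
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  jac <- purrr::map(pairs, function(p) {
    u <- union(keys[[p[1]]], keys[[p[2]]])
    j <- if (length(u) == 0) 1 else
      length(intersect(keys[[p[1]]], keys[[p[2]]])) / length(u)
    tibble::tibble(model_a = p[1], model_b = p[2], jaccard = j)
  }) |> dplyr::bind_rows()

  long <- purrr::imap(recs, function(r, lab) {
    dplyr::mutate(r, model = lab, key = interaction_keys(r), .before = 1)
  }) |> dplyr::bind_rows()

  structure(list(interactions = long, shared = shared, unique = uniq,
                 jaccard = jac, labels = labels),
            class = "model_comparison")
}

#' @export
tidy.model_comparison <- function(x, ...) {
  if (nrow(x$interactions) == 0) {
    return(tibble::tibble(key = character(), class = character()))
  }
  x$interactions |>
    dplyr::distinct(.data$key, .data$class) |>
    dplyr::left_join(
      x$interactions |>
        dplyr::distinct(.data$key, .data$model) |>
        dplyr::mutate(present = TRUE) |>
        tidyr::pivot_wider(names_from = "model", values_from = "present",
                           values_fill = FALSE),
      by = "key")
}

#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$labels),
    n_interactions = length(unique(x$interactions$key)),
    n_shared = length(x$shared),
    mean_jaccard = mean(x$jaccard$jaccard)
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Interaction comparison across %d models (%s)\n",
              length(x$labels), paste(x$labels, collapse = ", ")))
  cat(sprintf("  shared by all: %d; mean pairwise Jaccard: %.3f\n",
              length(x$shared), mean(x$jaccard$jaccard)))
  invisible(x)
}
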