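# Independent oracles and random fixture builders shared across tests.
# The contact oracle works from the full all-atom-pairs distance matrix
# (stats::dist) with plain logical masks -- a different computation path from
# the package's subset-then-cross-distance implementation.

HYDRO6 <- c("LEU", "ILE", "VAL", "PHE", "TRP", "MET")

ORACLE_BASIC <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
ORACLE_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
ORACLE_RINGS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(pyrrole = c("CG", "CD1", "NE1", "CE2", "CD2"),
             benzene = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

res_key <- function(chain, resno) paste(chain, resno, sep = ":")

pair_keys_from_mask <- function(df, D, mask_a, mask_b, cutoff,
                                extra_drop = NULL) {
  # all-pairs scan: returns sorted unique canonical residue-pair keys
  ia <- which(mask_a); ib <- which(mask_b)
  keys <- character(0)
  for (i in ia) for (j in ib) {
    if (i == j) next
    ka <- res_key(df$chain[i], df$resno[i]); kb <- res_key(df$chain[j], df$resno[j])
    if (ka == kb) next
    if (!is.null(extra_drop) && extra_drop(i, j)) next
    if (D[i, j] <= cutoff) {
      keys <- c(keys, paste(sort(c(ka, kb)), collapse = "|"))
    }
  }
  sort(unique(keys))
}

oracle_keys <- function(model, class, cutoff, exclude_adjacent = TRUE) {
  df <- as.data.frame(model)
  D <- as.matrix(stats::dist(df[, c("x", "y", "z")]))
  if (class == "hbond") {
    m <- df$element %in% c("N", "O")
    drop <- NULL
    if (exclude_adjacent) {
      drop <- function(i, j) {
        df$chain[i] == df$chain[j] && abs(df$resno[i] - df$resno[j]) == 1 &&
          ((df$atom[i] == "N" && df$atom[j] == "O") ||
             (df$atom[i] == "O" && df$atom[j] == "N"))
      }
    }
    return(pair_keys_from_mask(df, D, m, m, cutoff, drop))
  }
  if (class == "hydrophobic") {
    m <- df$element == "C" & df$atom != "CA" & df$resname %in% HYDRO6
    return(pair_keys_from_mask(df, D, m, m, cutoff))
  }
  if (class == "salt_bridge") {
    pick <- function(def) {
      keep <- rep(FALSE, nrow(df))
      for (rn in names(def)) keep <- keep | (df$resname == rn & df$atom %in% def[[rn]])
      keep
    }
    return(pair_keys_from_mask(df, D, pick(ORACLE_BASIC), pick(ORACLE_ACIDIC),
                               cutoff))
  }
  if (class == "pi_pi") {
    # independent centroid computation: colMeans over ring atoms per residue
    cen <- list()
    for (grp in split(seq_len(nrow(df)),
                      paste(df$chain, df$resno, sep = ":"))) {
      rn <- df$resname[grp[1]]
      if (!rn %in% names(ORACLE_RINGS)) next
      for (ring in ORACLE_RINGS[[rn]]) {
        sel <- grp[df$atom[grp] %in% ring]
        if (length(sel) < length(ring)) next
        cen[[length(cen) + 1]] <- data.frame(
          chain = df$chain[grp[1]], resno = df$resno[grp[1]],
          t(colMeans(df[sel, c("x", "y", "z")])))
      }
    }
    if (length(cen) == 0) return(character(0))
    cdf <- do.call(rbind, cen)
    keys <- character(0)
    for (i in seq_len(nrow(cdf))) for (j in seq_len(nrow(cdf))) {
      if (i == j) next
      ka <- res_key(cdf$chain[i], cdf$resno[i])
      kb <- res_key(cdf$chain[j], cdf$resno[j])
      if (ka == kb) next
      d <- sqrt(sum((cdf[i, 3:5] - cdf[j, 3:5])^2))
      if (d <= cutoff) keys <- c(keys, paste(sort(c(ka, kb)), collapse = "|"))
    }
    return(sort(unique(keys)))
  }
  stop("unknown class")
}

impl_keys <- function(records) {
  if (nrow(records) == 0) return(character(0))
  ka <- res_key(records$chain_a, records$resno_a)
  kb <- res_key(records$chain_b, records$resno_b)
  sort(unique(mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"), ka, kb,
                     USE.NAMES = FALSE)))
}

# Random toy structure with realistic residue/atom naming for oracle checks.
RANDOM_ATOM_SETS <- list(
  GLY = c("N", "CA", "C", "O"),
  ALA = c("N", "CA", "C", "O", "CB"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
          "CZ2", "CZ3", "CH2"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2")
)

random_structure <- function(seed, n_res = 28, box = 22, n_chains = 2) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_res)) {
      rn <- sample(names(RANDOM_ATOM_SETS), 1)
      atoms <- RANDOM_ATOM_SETS[[rn]]
      center <- stats::runif(3, 0, box)
      rows[[i]] <- tibble::tibble(
        chain = if (i <= n_res / n_chains) "A" else "B",
        resno = as.integer(if (i <= n_res / n_chains) i else i - floor(n_res / n_chains)),
        insert = NA_character_, resname = rn, atom = atoms,
        element = toupper(substr(gsub("^[0-9]+", "", atoms), 1, 1)),
        x = center[1] + stats::runif(length(atoms), -1.6, 1.6),
        y = center[2] + stats::runif(length(atoms), -1.6, 1.6),
        z = center[3] + stats::runif(length(atoms), -1.6, 1.6)
      )
    }
    structure_model(dplyr::bind_rows(rows), label = paste0("rand", seed))
  })
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_out <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_out)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

# Random plausible Fv chain: template with substitutions and a CDR3 indel.
random_fv_sequence <- function(chain_type, seed, scheme = "imgt") {
  withr::with_seed(seed, {
    tmpl <- scheme_template(scheme, chain_type)$regions
    parts <- tmpl$sequence
    names(parts) <- tmpl$region
    for (r in names(parts)) {
      chars <- strsplit(parts[[r]], "")[[1]]
      hit <- which(stats::runif(length(chars)) < 0.08)
      for (k in hit) chars[k] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], chars[k]), 1)
      parts[[r]] <- paste(chars, collapse = "")
    }
    # length variation in CDR3
    delta <- sample(-2:3, 1)
    cdr3 <- strsplit(parts[["CDR3"]], "")[[1]]
    if (delta > 0) {
      cdr3 <- append(cdr3, sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], delta, replace = TRUE),
                     after = 5)
    } else if (delta < 0) {
      cdr3 <- cdr3[-(6:(5 - delta))]
    }
    parts[["CDR3"]] <- paste(cdr3, collapse = "")
    paste(parts, collapse = "")
  })
}
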