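# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed): the same call reproduces byte-identical output. Toy
# structures use legal residue/atom naming but make no claim of
# stereochemical realism -- the geometry exists to exercise the
# distance-threshold logic, and each requested interaction is realized on an
# isolated "island" of two residues spaced far from all other islands.

DEFAULT_SEED <- 20240715

#' Generate a synthetic germline framework pool
#'
#' Derives `n_per_slot` segments per chain/slot from the scheme template's
#' framework segments by independent seeded substitutions, calibrated so the
#' expected pairwise identity within a slot is about `base_identity`
#' (substitution probability `1 - sqrt(base_identity)` per position per
#' segment). Segments within a slot are guaranteed pairwise distinct. Names
#' are synthetic but format-compatible (e.g. `SGHV1-1`, `SJH2`).
#'
#' @param n_per_slot Segments per chain/slot (>= 1).
#' @param base_identity Target expected pairwise identity, in (0.5, 1).
#' @param seed Integer seed.
#' @param scheme Numbering scheme whose template seeds the segments.
#' @return A `germline_pool`.
#' @export
gen_germline_pool <- function(n_per_slot = 4, base_identity = 0.85,
                              seed = DEFAULT_SEED, scheme = "imgt") {
  if (n_per_slot < 1) fvh_abort("fvh_input_error", "n_per_slot must be >= 1")
  if (base_identity <= 0.5 || base_identity >= 1) {
    fvh_abort("fvh_input_error", "base_identity must lie in (0.5, 1)")
  }
  p <- 1 - sqrt(base_identity)
  withr::with_seed(seed, {
    rows <- purrr::pmap(SHUFFLE_SLOTS, function(chain_type, slot) {
      base <- template_region(scheme, chain_type, slot)
      slot_num <- match(slot, FR_SLOTS)
      seqs <- character(0)
      for (i in seq_len(n_per_slot)) {
        s <- mutate_sequence(base, p)$sequence
        guard <- 0
        while (s %in% seqs && guard < 100) {
          s <- mutate_sequence(base, p)$sequence
          guard <- guard + 1
        }
        seqs <- c(seqs, s)
      }
      prefix <- if (slot == "FR4") {
        if (chain_type == "heavy") "SJH" else "SJK"
      } else {
        sprintf("S%sV%d-", if (chain_type == "heavy") "GH" else "GK", slot_num)
      }
      tibble::tibble(
        name = paste0(prefix, seq_len(n_per_slot)),
        chain_type = chain_type, slot = slot, sequence = seqs
      )
    })
    germline_pool(dplyr::bind_rows(rows))
  })
}

#' Generate a murine-like parent Fv with planted truth
#'
#' Builds a parent heavy/kappa pair from one germline per slot (drawn from
#' the pool) plus seeded framework substitutions at `fr_mutation_rate`, and
#' random CDRs. The returned truth table records the true slot origins and
#' mutated positions -- the recovery target for [select_germline_per_fr()]
#' and [propose_back_mutations()].
#'
#' @param pool A `germline_pool`.
#' @param cdr_lengths Named list with `heavy` and `kappa` integer vectors of
#'   three CDR lengths; defaults to the scheme template's CDR lengths.
#' @param fr_mutation_rate Per-position substitution probability in `[0, 0.3]`.
#' @param seed Integer seed.
#' @param scheme Numbering scheme.
#' @return A `parent_fv`: list with `heavy`/`light` sequences, `truth`
#'   (tibble: `chain_type`, `slot`, `germline`, `n_mutations`, `positions`),
#'   `cdrs` (a `cdr_set`) and `regions` (list of per-chain region tibbles).
#' @export
gen_parent_fv <- function(pool, cdr_lengths = NULL, fr_mutation_rate = 0.05,
                          seed = DEFAULT_SEED, scheme = "imgt") {
  if (fr_mutation_rate < 0 || fr_mutation_rate > 0.3) {
    fvh_abort("fvh_input_error", "fr_mutation_rate must lie in [0, 0.3]")
  }
  if (is.null(cdr_lengths)) {
    cdr_lengths <- purrr::map(
      stats::setNames(CHAIN_TYPES, CHAIN_TYPES),
      function(ct) vapply(CDR_SLOTS, function(r)
        nchar(template_region(scheme, ct, r)), integer(1)))
  }
  withr::with_seed(seed, {
    truth <- list(); chains <- list(); cdr_seqs <- list()
    for (ct in CHAIN_TYPES) {
      parts <- character(0)
      for (k in seq_along(REGION_ORDER)) {
        r <- REGION_ORDER[k]
        if (r %in% FR_SLOTS) {
          cands <- pool_slot(pool, ct, r)
          pick <- cands[sample.int(nrow(cands), 1), ]
          mut <- mutate_sequence(pick$sequence, fr_mutation_rate)
          truth[[length(truth) + 1]] <- tibble::tibble(
            chain_type = ct, slot = r, germline = pick$name,
            n_mutations = length(mut$positions),
            positions = list(mut$positions))
          parts <- c(parts, mut$sequence)
        } else {
          len <- cdr_lengths[[ct]][match(r, CDR_SLOTS)]
          s <- random_aa(len)
          cdr_seqs[[paste(ct, r)]] <- s
          parts <- c(parts, s)
        }
      }
      chains[[ct]] <- paste(parts, collapse = "")
    }
    cdrs <- cdr_set(cdr_seqs[["heavy CDR1"]], cdr_seqs[["heavy CDR2"]],
                    cdr_seqs[["heavy CDR3"]], cdr_seqs[["kappa CDR1"]],
                    cdr_seqs[["kappa CDR2"]], cdr_seqs[["kappa CDR3"]],
                    scheme = scheme)
    structure(list(heavy = chains$heavy, light = chains$kappa,
                   truth = dplyr::bind_rows(truth), cdrs = cdrs,
                   seed = seed, fr_mutation_rate = fr_mutation_rate,
                   scheme = scheme),
              class = "parent_fv")
  })
}

#' Random satisfiable interaction specification
#'
#' Draws `n` interaction requests (class, distance, interact flag) within
#' ranges that [gen_toy_structure()] can realize without cross-class
#' leakage: requested salt bridges stay above the 3.5-Angstrom N-O
#' hydrogen-bond threshold, and requested non-interactions violate their
#' class threshold by at least 0.2 Angstrom.
#'
#' @param n Number of requests.
#' @param seed Integer seed.
#' @return A spec tibble: `class`, `distance`, `interact`.
#' @export
gen_interaction_spec <- function(n = 8, seed = DEFAULT_SEED) {
  lo <- c(hbond = 2.6, hydrophobic = 3.5, salt_bridge = 3.55, pi_pi = 4.5)
  withr::with_seed(seed, {
    cls <- sample(names(DEFAULT_CUTOFFS), n, replace = TRUE)
    interact <- stats::runif(n) < 0.6
    dist <- ifelse(
      interact,
      lo[cls] + stats::runif(n) * (DEFAULT_CUTOFFS[cls] - lo[cls]),
      DEFAULT_CUTOFFS[cls] + 0.2 + stats::runif(n) * 1.3
    )
    tibble::tibble(class = cls, distance = round(unname(dist), 3),
                   interact = interact)
  })
}

# Atom placement recipes for one interaction island. x0 is the island's
# x-offset; d the requested realizing distance. Geometry keeps every
# unintended same-class atom pair strictly farther than the requested
# distance and every cross-class pair outside its threshold.
island_atoms <- function(class, d, x0, resno_a, resno_b) {
  at <- function(resno, resname, atom, x, y, z) {
    tibble::tibble(chain = "A", resno = resno, insert = NA_character_,
                   resname = resname, atom = atom,
                   element = element_from_name(atom), x = x, y = y, z = z)
  }
  switch(class,
    hbond = dplyr::bind_rows(
      at(resno_a, "GLY", "N", x0 - 2.4, 1.4, 0),
      at(resno_a, "GLY", "CA", x0 - 1.2, 2.0, 0),
      at(resno_a, "GLY", "C", x0, 1.23, 0),
      at(resno_a, "GLY", "O", x0, 0, 0),
      at(resno_b, "GLY", "N", x0, -d, 0),
      at(resno_b, "GLY", "CA", x0 + 1.2, -d - 0.8, 0),
      at(resno_b, "GLY", "C", x0 + 1.0, -d - 2.2, 0),
      at(resno_b, "GLY", "O", x0 + 0.2, -d - 3.0, 0)
    ),
    hydrophobic = dplyr::bind_rows(
      at(resno_a, "LEU", "CA", x0, 2.5, 0),
      at(resno_a, "LEU", "CB", x0, 1.0, 0),
      at(resno_a, "LEU", "CG", x0 + 0.6, 0.4, 0),
      at(resno_a, "LEU", "CD1", x0, 0, 0),
      at(resno_a, "LEU", "CD2", x0 - 0.8, 0.5, 0),
      at(resno_b, "VAL", "CG1", x0, -d, 0),
      at(resno_b, "VAL", "CB", x0 + 0.7, -d - 1.2, 0),
      at(resno_b, "VAL", "CG2", x0 - 0.5, -d - 1.8, 0),
      at(resno_b, "VAL", "CA", x0, -d - 2.4, 0)
    ),
    salt_bridge = dplyr::bind_rows(
      at(resno_a, "LYS", "NZ", x0, 0, 0),
      at(resno_a, "LYS", "CE", x0, 1.5, 0),
      at(resno_a, "LYS", "CD", x0 + 0.8, 2.7, 0),
      at(resno_a, "LYS", "CA", x0, 4.0, 0),
      at(resno_b, "ASP", "OD1", x0, -d, 0),
      at(resno_b, "ASP", "CG", x0 + 0.9, -d - 1.0, 0),
      at(resno_b, "ASP", "OD2", x0 + 2.05, -d - 1.25, 0),
      at(resno_b, "ASP", "CB", x0 + 0.6, -d - 2.4, 0),
      at(resno_b, "ASP", "CA", x0, -d - 3.6, 0)
    ),
    pi_pi = {
      ring <- function(resno, yc) {
        th <- seq(0, 300, by = 60) * pi / 180
        tibble::tibble(chain = "A", resno = resno, insert = NA_character_,
                       resname = "TYR",
                       atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       element = "C",
                       x = x0 + 1.39 * cos(th), y = yc, z = 1.39 * sin(th))
      }
      dplyr::bind_rows(ring(resno_a, 0), ring(resno_b, -d))
    }
  )
}

#' Generate a toy structure realizing requested interactions
#'
#' Places minimal legal residue pairs so that every requested interaction is
#' realized at its requested distance and every requested non-interaction
#' violates its class threshold by at least 0.2 Angstrom. Each request lives
#' on its own island, 30 Angstrom from the next, so islands never interact.
#' A requested salt bridge at or below the 3.5-Angstrom hydrogen-bond
#' threshold is rejected as unsatisfiable: its N-O pair would unavoidably
#' also register as a hydrogen bond.
#'
#' @param spec Tibble with columns `class` (`hbond`, `hydrophobic`,
#'   `salt_bridge`, `pi_pi`), `distance` (Angstrom) and `interact` (logical).
#' @param seed Integer seed (recorded; the layout itself is deterministic).
#' @return A list: `model` (a `structure_model`) and `truth` (the spec with
#'   residue numbers `resno_a`, `resno_b` attached).
#' @export
gen_toy_structure <- function(spec, seed = DEFAULT_SEED) {
  spec <- tibble::as_tibble(spec)
  bad_class <- setdiff(spec$class, names(DEFAULT_CUTOFFS))
  if (length(bad_class) > 0) {
    fvh_abort("fvh_input_error", sprintf(
      "unknown interaction class(es): %s", paste(bad_class, collapse = ", ")))
  }
  thr <- DEFAULT_CUTOFFS[spec$class]
  viol <- (spec$interact & spec$distance > thr) |
    (!spec$interact & spec$distance < thr + 0.2) |
    (spec$class == "salt_bridge" & spec$interact & spec$distance <= 3.5) |
    spec$distance <= 0
  if (any(viol)) {
    fvh_abort("fvh_constraint_error", sprintf(
      "request(s) not geometrically satisfiable without cross-class leakage: row(s) %s",
      paste(which(viol), collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(spec)), function(k) {
    island_atoms(spec$class[k], spec$distance[k], 30 * (k - 1),
                 resno_a = 10L * (k - 1L) + 1L, resno_b = 10L * (k - 1L) + 4L)
  })
  truth <- dplyr::mutate(spec,
                         chain_a = "A", resno_a = 10L * (dplyr::row_number() - 1L) + 1L,
                         chain_b = "A", resno_b = 10L * (dplyr::row_number() - 1L) + 4L)
  list(model = structure_model(dplyr::bind_rows(rows),
                               label = sprintf("toy-%d", seed)),
       truth = truth, seed = seed)
}

#' Generate a coarse two-chain Fv mock structure with planted truth
#'
#' Builds a pseudo-atomic two-chain arrangement from the chains' region maps
#' (sequential residue numbering per chain) containing one planted positive
#' control for each canonical residue type and negative controls everywhere
#' else: a VH/VL interface pair (Type 1), a framework residue buried inside
#' a cage of CDR2 atoms (Type 2), and a framework residue hydrogen-bonded to
#' a CDR residue (Type 3). All remaining residues sit on well-separated
#' lines and carry no flags.
#'
#' @param heavy_rm,light_rm `region_map`s of the two chains.
#' @param seed Integer seed (recorded; the layout is deterministic).
#' @param chain_separation Extra z-offset applied to the light chain
#'   (Angstrom); 50 abolishes all interface contacts.
#' @return A list: `model`, `truth` (per FR residue: `chain`, `resno`,
#'   `type1`, `type2`, `type3`), `regions` (residue-to-region map).
#' @export
gen_fv_mock_structure <- function(heavy_rm, light_rm, seed = DEFAULT_SEED,
                                  chain_separation = 0) {
  regions <- structure_regions(heavy_rm, light_rm)
  regH <- regions[regions$chain == "H", ]
  regL <- regions[regions$chain == "L", ]

  mid <- function(reg, r) {
    idx <- reg$resno[reg$region == r]
    idx[ceiling(length(idx) / 2)]
  }
  t1H <- mid(regH, "FR2"); t1L <- mid(regL, "FR2")
  t2H <- mid(regH, "FR3"); t3H <- mid(regH, "FR1")
  partner <- regH$resno[regH$region == "CDR1"][1]
  cage <- regH$resno[regH$region == "CDR2"]

  at <- function(chain, resno, resname, atom, x, y, z) {
    tibble::tibble(chain = chain, resno = as.integer(resno),
                   insert = NA_character_, resname = resname, atom = atom,
                   element = element_from_name(atom), x = x, y = y, z = z)
  }
  ala <- function(chain, resno, x, y, z) {
    dplyr::bind_rows(at(chain, resno, "ALA", "CA", x, y, z),
                     at(chain, resno, "ALA", "CB", x, y + 1.5, z))
  }

  atoms <- list()
  for (i in regH$resno) {
    if (i %in% c(t1H, t2H, t3H, partner, cage)) next
    y <- if (startsWith(regH$region[regH$resno == i], "FR")) 0 else -40
    atoms[[length(atoms) + 1]] <- ala("H", i, 6 * i, y, 0)
  }
  for (j in regL$resno) {
    if (j == t1L) next
    y <- if (startsWith(regL$region[regL$resno == j], "FR")) 40 else -80
    atoms[[length(atoms) + 1]] <- ala("L", j, 6 * j, y, 0)
  }

  # Type 1 pair: interface contact at 2.5 A between heavy CB and light CA
  atoms[[length(atoms) + 1]] <- ala("H", t1H, -30, 0, 0)
  atoms[[length(atoms) + 1]] <- ala("L", t1L, -30, 4.0, 0)

  # Type 2: ALA buried inside a cage of CDR2 LEU atoms at radius 4.2 A
  atoms[[length(atoms) + 1]] <- dplyr::bind_rows(
    at("H", t2H, "ALA", "CA", -60, 0, 0),
    at("H", t2H, "ALA", "CB", -60, 0, 1.5))
  leu_atoms <- c("CA", "CB", "CG", "CD1", "CD2")
  n_cage_atoms <- length(cage) * length(leu_atoms)
  pts <- sphere_points(n_cage_atoms) * 4.2
  k <- 1
  for (ci in seq_along(cage)) {
    for (an in leu_atoms) {
      atoms[[length(atoms) + 1]] <- at("H", cage[ci], "LEU", an,
                                       -60 + pts[k, 1], pts[k, 2],
                                       0.75 + pts[k, 3])
      k <- k + 1
    }
  }

  # Type 3: FR1 GLY hydrogen-bonded (O...N at 3.2 A) to the first CDR1 residue
  atoms[[length(atoms) + 1]] <- dplyr::bind_rows(
    at("H", t3H, "GLY", "N", -92.4, 1.4, 0),
    at("H", t3H, "GLY", "CA", -91.2, 2.0, 0),
    at("H", t3H, "GLY", "C", -90, 1.23, 0),
    at("H", t3H, "GLY", "O", -90, 0, 0),
    at("H", partner, "GLY", "N", -90, -3.2, 0),
    at("H", partner, "GLY", "CA", -88.8, -4.0, 0),
    at("H", partner, "GLY", "C", -89.0, -5.4, 0),
    at("H", partner, "GLY", "O", -89.8, -6.2, 0))

  df <- dplyr::bind_rows(atoms)
  df[df$chain == "L", "z"] <- df$z[df$chain == "L"] + chain_separation

  fr <- regions[startsWith(regions$region, "FR"), ]
  truth <- dplyr::mutate(
    fr,
    type1 = (.data$chain == "H" & .data$resno == t1H) |
      (.data$chain == "L" & .data$resno == t1L),
    type2 = .data$chain == "H" & .data$resno == t2H,
    type3 = .data$chain == "H" & .data$resno == t3H
  )
  list(model = structure_model(df, label = sprintf("fv-mock-%d", seed)),
       truth = truth, regions = regions, seed = seed)
}

#' Generate a synthetic reference repertoire
#'
#' Human-like Fv sequences derived from the scheme templates by seeded
#' substitutions, alternating heavy and kappa chains.
#'
#' @param n_seqs Number of sequences.
#' @param seed Integer seed.
#' @param mutation_rate Per-position substitution probability.
#' @param scheme Numbering scheme.
#' @return Named character vector of sequences.
#' @export
gen_repertoire <- function(n_seqs = 50, seed = DEFAULT_SEED,
                           mutation_rate = 0.06, scheme = "imgt") {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_seqs), function(i) {
      ct <- CHAIN_TYPES[(i %% 2) + 1]
      mutate_sequence(scheme_template(scheme, ct)$sequence, mutation_rate)$sequence
    }, "")
    stats::setNames(seqs, sprintf("REF%04d", seq_len(n_seqs)))
  })
}

#' Generate a synthetic MHC class II prediction table with planted truth
#'
#' @param n_rows Number of peptide-allele rows.
#' @param strong_fraction Probability a row is a strong binder (rank drawn
#'   at or below 1); other rows draw ranks in (1.5, 40).
#' @param seed Integer seed.
#' @param alleles Allele names to sample from.
#' @return A list: `table` (peptide, allele, rank) and `truth` (per-allele
#'   strong-binder counts with a `total` row).
#' @export
gen_epitope_table <- function(n_rows = 60, strong_fraction = 0.2,
                              seed = DEFAULT_SEED,
                              alleles = c("DRB1*01:01", "DRB1*03:01",
                                          "DRB1*04:01", "DRB1*07:01",
                                          "DRB1*11:01", "DRB1*15:01")) {
  if (strong_fraction < 0 || strong_fraction > 1) {
    fvh_abort("fvh_input_error", "strong_fraction must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    strong <- stats::runif(n_rows) < strong_fraction
    tab <- tibble::tibble(
      peptide = vapply(seq_len(n_rows), function(i) random_aa(15), ""),
      allele = sample(alleles, n_rows, replace = TRUE),
      rank = round(ifelse(strong, stats::runif(n_rows, 0.05, 1.0),
                          stats::runif(n_rows, 1.5, 40)), 3)
    )
    truth <- tibble::tibble(allele = tab$allele, strong = strong) |>
      dplyr::group_by(.data$allele) |>
      dplyr::summarise(strong_binders = sum(.data$strong), .groups = "drop") |>
      dplyr::arrange(.data$allele)
    truth <- dplyr::bind_rows(
      truth, tibble::tibble(allele = "total",
                            strong_binders = sum(truth$strong_binders)))
    list(table = tab, truth = truth, seed = seed)
  })
}

#' Write a complete fixture bundle to disk
#'
#' Generates every input the pipeline needs (germline pool, murine-like
#' parent, toy interaction structure, Fv mock structure, repertoire, epitope
#' table) and writes them with a manifest recording the seed and parameters;
#' regenerating with the manifest's seed reproduces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_per_slot,base_identity,fr_mutation_rate,n_seqs,n_rows,strong_fraction
#'   Generator parameters, see the individual `gen_*` functions.
#' @param scheme Numbering scheme.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_bundle <- function(dir, seed = DEFAULT_SEED, n_per_slot = 4,
                                base_identity = 0.85, fr_mutation_rate = 0.05,
                                n_seqs = 50, n_rows = 60, strong_fraction = 0.2,
                                scheme = "imgt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  pool <- gen_germline_pool(n_per_slot, base_identity, seed, scheme)
  write_pool(pool, p("germline_pool.fasta"), p("germline_pool.tsv"))

  parent <- gen_parent_fv(pool, fr_mutation_rate = fr_mutation_rate,
                          seed = seed, scheme = scheme)
  write_fasta(c(parent_heavy = parent$heavy, parent_light = parent$light),
              p("parent_fv.fasta"))
  truth <- dplyr::mutate(parent$truth,
                         positions = purrr::map_chr(.data$positions,
                                                    paste, collapse = ","))
  readr::write_tsv(truth, p("parent_truth.tsv"))

  toy <- gen_toy_structure(gen_interaction_spec(8, seed), seed)
  write_structure(toy$model, p("toy_interactions.pdb"))
  readr::write_tsv(toy$truth, p("toy_truth.tsv"))

  hrm <- segment_regions(number_chain(parent$heavy, "heavy", scheme))
  lrm <- segment_regions(number_chain(parent$light, "kappa", scheme))
  mock <- gen_fv_mock_structure(hrm, lrm, seed)
  write_structure(mock$model, p("fv_mock.pdb"))
  readr::write_tsv(mock$truth, p("fv_mock_truth.tsv"))
  readr::write_tsv(mock$regions, p("fv_mock_regions.tsv"))

  reps <- gen_repertoire(n_seqs, seed, scheme = scheme)
  write_fasta(reps, p("repertoire.fasta"))
  idx <- repertoire_index(reps, label = sprintf("synthetic-%d", seed))
  readr::write_tsv(idx$ninemers, p("repertoire_ninemers.tsv"))

  epi <- gen_epitope_table(n_rows, strong_fraction, seed)
  readr::write_tsv(epi$table, p("epitope_table.tsv"))
  readr::write_tsv(epi$truth, p("epitope_truth.tsv"))

  manifest <- list(
    seed = seed, scheme = scheme,
    params = list(n_per_slot = n_per_slot, base_identity = base_identity,
                  fr_mutation_rate = fr_mutation_rate, n_seqs = n_seqs,
                  n_rows = n_rows, strong_fraction = strong_fraction),
    files = list.files(dir)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
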