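# Workflow orchestration: configuration plus the two humanization workflows
# (CDR grafting with optional structure-guided back-mutation candidates, and
# combinatorial framework shuffling with per-variant decomposition).

#' Workflow configuration
#'
#' Collects every tunable threshold in one validated object. All distances
#' are in Angstrom; `rank_threshold` is an MHC-II percentile rank;
#' `min_prevalence` a repertoire prevalence fraction.
#'
#' @param scheme Numbering scheme.
#' @param d_interface,d_near,r_buried Canonical-classification thresholds.
#' @param hbond_cutoff,hydrophobic_cutoff,salt_bridge_cutoff,pi_pi_cutoff
#'   Interaction-class distance thresholds.
#' @param rank_threshold Strong-binder percentile rank.
#' @param min_prevalence 9-mer prevalence threshold.
#' @param k Top-k for repertoire identity.
#' @param max_mismatch Decomposition mismatch ceiling per slot.
#' @param seed Default seed for seeded stages.
#' @return A `humanizer_config` list.
#' @export
humanizer_config <- function(scheme = "imgt", d_interface = 4.5, d_near = 6.0,
                             r_buried = 0.20, hbond_cutoff = 3.5,
                             hydrophobic_cutoff = 5.0, salt_bridge_cutoff = 4.0,
                             pi_pi_cutoff = 6.5, rank_threshold = 1.0,
                             min_prevalence = 0.01, k = 20, max_mismatch = 3,
                             seed = DEFAULT_SEED) {
  cfg <- list(scheme = check_scheme(scheme), d_interface = d_interface,
              d_near = d_near, r_buried = r_buried,
              hbond_cutoff = hbond_cutoff,
              hydrophobic_cutoff = hydrophobic_cutoff,
              salt_bridge_cutoff = salt_bridge_cutoff,
              pi_pi_cutoff = pi_pi_cutoff, rank_threshold = rank_threshold,
              min_prevalence = min_prevalence, k = k,
              max_mismatch = max_mismatch, seed = seed)
  num <- cfg[setdiff(names(cfg), c("scheme", "seed", "min_prevalence"))]
  if (any(!vapply(num, is.numeric, TRUE)) || any(unlist(num) <= 0)) {
    fvh_abort("fvh_config_error", "all thresholds must be positive numbers")
  }
  if (cfg$min_prevalence < 0 || cfg$min_prevalence > 1) {
    fvh_abort("fvh_config_error", "min_prevalence must lie in [0, 1]")
  }
  structure(cfg, class = "humanizer_config")
}

config_cutoffs <- function(config) {
  c(hbond = config$hbond_cutoff, hydrophobic = config$hydrophobic_cutoff,
    salt_bridge = config$salt_bridge_cutoff, pi_pi = config$pi_pi_cutoff)
}

#' Write / read a configuration as JSON
#'
#' The round trip is lossless: `read_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A `humanizer_config`.
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `humanizer_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in setdiff(names(raw), "scheme")) raw[[nm]] <- as.numeric(raw[[nm]])
  do.call(humanizer_config, raw)
}

#' Run the CDR-grafting humanization workflow
#'
#' Annotate the parent chains, select the most homologous germline per
#' framework, graft, optionally classify canonical residues on a structure
#' and propose back-mutation candidates, apply user-selected back-mutation
#' variants, and enumerate all heavy x light pairings.
#'
#' @param parent_heavy,parent_light Parent (murine) chain sequences.
#' @param pool A `germline_pool`.
#' @param structure Optional `structure_model` of the parent Fv (sequential
#'   residue numbering, chains H/L) enabling candidate proposal.
#' @param heavy_mutations,light_mutations Optional lists of
#'   `back_mutation_spec`s; each spec yields one additional chain variant
#'   beyond the plain graft.
#' @param config A [humanizer_config()].
#' @return A `graft_workflow` list: `selection` (per-slot germline and
#'   identity report), `heavy_variants`, `light_variants`, `designs`
#'   (the enumerated pairings), `candidates` (proposed back mutations per
#'   chain, when a structure was given), `config`.
#' @export
run_graft_workflow <- function(parent_heavy, parent_light, pool,
                               structure = NULL, heavy_mutations = list(),
                               light_mutations = list(),
                               config = humanizer_config()) {
  ncH <- number_chain(parent_heavy, "heavy", config$scheme)
  ncL <- number_chain(parent_light, "kappa", config$scheme)
  rmH <- segment_regions(ncH)
  rmL <- segment_regions(ncL)
  selection <- select_germline_per_fr(list(rmH, rmL), pool)
  graftH <- graft(rmH, selection, label = "H-grafted")
  graftL <- graft(rmL, selection, label = "L-grafted")

  candidates <- NULL
  if (!is.null(structure)) {
    assignment <- classify_residues(
      structure, structure_regions(rmH, rmL),
      d_interface = config$d_interface, d_near = config$d_near,
      r_buried = config$r_buried, cutoffs = config_cutoffs(config))
    candidates <- list(
      heavy = propose_back_mutations(ncH, graftH, assignment, "H"),
      light = propose_back_mutations(ncL, graftL, assignment, "L"))
  }

  variants <- function(base, specs, parent, prefix) {
    out <- list(base)
    for (i in seq_along(specs)) {
      v <- apply_back_mutations(base, specs[[i]], parent)
      attr(v, "label") <- paste0(prefix, i)
      out[[length(out) + 1]] <- v
    }
    out
  }
  heavy_variants <- variants(graftH, heavy_mutations, ncH, "H-bm")
  light_variants <- variants(graftL, light_mutations, ncL, "L-bm")
  designs <- enumerate_designs(heavy_variants, light_variants)

  structure(list(selection = selection, heavy_variants = heavy_variants,
                 light_variants = light_variants, designs = designs,
                 candidates = candidates, config = config),
            class = "graft_workflow")
}

#' Run the framework-shuffling workflow
#'
#' Samples the combinatorial library over the framework pool at fixed CDRs
#' and decomposes every sampled variant back to per-slot germline origins.
#'
#' @param cdrs A `cdr_set`.
#' @param pool A `germline_pool`.
#' @param n Number of variants to sample.
#' @param seed Seed (defaults to the config's).
#' @param config A [humanizer_config()].
#' @return A `shuffle_workflow` list: `library` (sampled variants),
#'   `decomposition` (one row per variant: per-slot origins and mismatch
#'   totals), `diversity`, `config`.
#' @export
run_shuffle_workflow <- function(cdrs, pool, n, seed = NULL,
                                 config = humanizer_config()) {
  seed <- seed %||% config$seed
  lib <- sample_library(cdrs, pool, n, seed = seed)
  dec <- purrr::map2(lib$pair, lib$variant_id, function(pr, id) {
    d <- decompose_origin(pr, pool, max_mismatch = config$max_mismatch,
                          scheme = config$scheme)
    nm <- paste(ifelse(d$chain_type == "heavy", "VH", "VL"), d$slot, sep = "_")
    wide <- tibble::as_tibble(as.list(stats::setNames(d$origin, nm)))
    dplyr::bind_cols(tibble::tibble(variant = id), wide,
                     tibble::tibble(total_mismatches = sum(d$mismatches)))
  }) |> dplyr::bind_rows()
  structure(list(library = lib, decomposition = dec,
                 diversity = pool_diversity(pool), config = config),
            class = "shuffle_workflow")
}
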