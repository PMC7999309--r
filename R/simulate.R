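#' Simulation settings for a synthetic label-free proteomics experiment
#'
#' Bundles and validates the parameters of the abundance-matrix generator.
#' Defaults emulate a small urinary-exosome case/control study: about two
#' thousand proteins quantified over 5 case ("V-AKI") and 7 control samples,
#' log2-normal intensities, a small fraction of truly differential proteins
#' with a two-fold-per-unit log2 effect, and 10% missing measurements.
#'
#' @param n_proteins number of proteins (rows).
#' @param n_case,n_control samples per group; each must be at least 2.
#' @param frac_diff fraction of proteins carrying a planted group effect.
#' @param effect_log2fc absolute planted effect, in log2 units (>= 0).
#' @param base_log2_mean grand mean of log2 abundance. The default 20
#'   (~1e6 on the raw scale) is a typical summed MS1 peak-area magnitude.
#' @param protein_sd between-protein spread of log2 baseline abundance.
#' @param noise_sd within-protein measurement noise on the log2 scale.
#' @param missing_rate marginal fraction of missing cells, in [0, 1).
#' @param missing_mode "random" (missing completely at random) or
#'   "intensity_dependent" (missingness probability falls with log2
#'   abundance through a logistic curve calibrated to `missing_rate`).
#' @param seed integer seed; identical configurations reproduce the
#'   simulated study exactly.
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [simulate_abundance()], [simulate_network()]
#' @export
simulation_config <- function(n_proteins = 2000L, n_case = 5L, n_control = 7L,
                              frac_diff = 0.05, effect_log2fc = 2,
                              base_log2_mean = 20, protein_sd = 2,
                              noise_sd = 0.5, missing_rate = 0.1,
                              missing_mode = c("random", "intensity_dependent"),
                              seed = 1L) {
  cfg <- list(
    n_proteins = assert_count(n_proteins, "n_proteins", min = 1L),
    n_case = assert_count(n_case, "n_case", min = 2L),
    n_control = assert_count(n_control, "n_control", min = 2L),
    frac_diff = assert_fraction(frac_diff, "frac_diff"),
    effect_log2fc = effect_log2fc,
    base_log2_mean = base_log2_mean,
    protein_sd = protein_sd,
    noise_sd = noise_sd,
    missing_rate = assert_fraction(missing_rate, "missing_rate", upper_open = TRUE),
    missing_mode = match.arg(missing_mode),
    seed = assert_count(seed, "seed")
  )
  if (cfg$effect_log2fc < 0) stop("'effect_log2fc' must be >= 0", call. = FALSE)
  if (cfg$protein_sd <= 0 || cfg$noise_sd <= 0) {
    stop("'protein_sd' and 'noise_sd' must be > 0", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate an abundance matrix with planted differential proteins
#'
#' Draws log2 abundances as
#' `log2(a_ij) = base + b_i + e_i * g_j + eps_ij`, where `b_i ~ N(0,
#' protein_sd^2)` is a per-protein baseline, `g_j` indicates case samples,
#' `e_i` is the signed planted effect (zero for non-differential proteins)
#' and `eps_ij ~ N(0, noise_sd^2)`. Exactly `round(frac_diff * n_proteins)`
#' proteins carry an effect; half are up-shifted in cases and half down,
#' with the odd one (if any) going up. Missing cells are encoded as `NA`,
#' never as zero.
#'
#' @param config a [simulation_config()].
#' @return a list with elements
#'   \describe{
#'     \item{abundance}{numeric matrix, proteins x samples, `NA` = missing.}
#'     \item{metadata}{data.frame with `sample_id` and `group`
#'       ("V-AKI" / "control").}
#'     \item{truth}{ground truth: data.frame `differential` with
#'       `protein_id` and signed `effect_log2fc`, plus the config used.}
#'   }
#' @export
simulate_abundance <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    np <- config$n_proteins
    ns <- config$n_case + config$n_control
    protein_ids <- sprintf("P%04d", seq_len(np))
    sample_ids <- c(sprintf("AKI_%02d", seq_len(config$n_case)),
                    sprintf("CTRL_%02d", seq_len(config$n_control)))
    group <- c(rep("V-AKI", config$n_case), rep("control", config$n_control))

    n_diff <- as.integer(round(config$frac_diff * np))
    effect <- numeric(np)
    diff_idx <- if (n_diff > 0) sort(sample.int(np, n_diff)) else integer(0)
    if (n_diff > 0) {
      n_up <- ceiling(n_diff / 2)   # tie goes to up-shifted
      effect[diff_idx[seq_len(n_up)]] <- config$effect_log2fc
      if (n_diff > n_up) {
        effect[diff_idx[(n_up + 1L):n_diff]] <- -config$effect_log2fc
      }
    }

    b <- stats::rnorm(np, 0, config$protein_sd)
    g <- as.numeric(group == "V-AKI")
    log2a <- config$base_log2_mean + b + outer(effect, g) +
      matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
    abundance <- 2^log2a
    dimnames(abundance) <- list(protein_ids, sample_ids)

    if (config$missing_rate > 0) {
      p_miss <- missing_probabilities(log2a, config)
      abundance[stats::runif(np * ns) < p_miss] <- NA_real_
    }

    truth <- list(
      differential = data.frame(
        protein_id = protein_ids[diff_idx],
        effect_log2fc = effect[diff_idx],
        stringsAsFactors = FALSE
      ),
      config = unclass(config)
    )
    list(
      abundance = abundance,
      metadata = data.frame(sample_id = sample_ids, group = group,
                            stringsAsFactors = FALSE),
      truth = truth
    )
  })
}

# Per-cell missingness probabilities. "random" is a flat missing_rate;
# "intensity_dependent" uses a logistic in log2 abundance with unit scale,
# with its midpoint calibrated so the marginal rate equals missing_rate.
missing_probabilities <- function(log2a, config) {
  if (config$missing_mode == "random") {
    return(matrix(config$missing_rate, nrow(log2a), ncol(log2a)))
  }
  target <- config$missing_rate
  f <- function(mu0) mean(stats::plogis(mu0 - log2a)) - target
  lo <- min(log2a) - 50; hi <- max(log2a) + 50
  mu0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  stats::plogis(mu0 - log2a)
}

#' Simulate a STRING-style cytokine/protein interaction network
#'
#' Draws undirected cytokine-protein edges independently: a (cytokine,
#' protein) pair gets an edge with probability `p_planted` when the
#' cytokine is planted and the protein is a case protein, and `p_base`
#' otherwise. Each realized edge receives a combined confidence score
#' drawn uniformly from `score_range`. Optionally a sparse protein-protein
#' background can be added with probability `p_protein_protein` per pair.
#'
#' @param proteins character vector of protein identifiers.
#' @param case_proteins subset of `proteins` treated as case-associated.
#' @param cytokine_panel character vector of cytokine identifiers
#'   (see [expand_cytokine_panel()]).
#' @param planted_cytokines subset of `cytokine_panel` with planted
#'   enrichment toward `case_proteins`.
#' @param p_base,p_planted edge probabilities in [0, 1].
#' @param score_range interval inside [0, 1] for the combined score.
#' @param p_protein_protein probability of a background protein-protein
#'   edge (default 0: cytokine-protein edges only).
#' @param seed integer seed.
#' @return a data.frame edge list with columns `node1`, `node2`,
#'   `combined_score`.
#' @export
simulate_network <- function(proteins, case_proteins, cytokine_panel,
                             planted_cytokines, p_base = 0.05,
                             p_planted = 0.8, score_range = c(0, 1),
                             p_protein_protein = 0, seed = 1L) {
  if (!all(case_proteins %in% proteins)) {
    stop("unknown identifiers in 'case_proteins': ",
         paste(setdiff(case_proteins, proteins), collapse = ", "), call. = FALSE)
  }
  if (!all(planted_cytokines %in% cytokine_panel)) {
    stop("unknown identifiers in 'planted_cytokines': ",
         paste(setdiff(planted_cytokines, cytokine_panel), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(p_base >= 0, p_base <= 1, p_planted >= 0, p_planted <= 1,
            length(score_range) == 2, score_range[1] <= score_range[2],
            score_range[1] >= 0, score_range[2] <= 1)

  with_local_seed(seed, {
    nc <- length(cytokine_panel); np <- length(proteins)
    pmat <- matrix(p_base, nc, np,
                   dimnames = list(cytokine_panel, proteins))
    pmat[cytokine_panel %in% planted_cytokines,
         proteins %in% case_proteins] <- p_planted
    hit <- matrix(stats::runif(nc * np), nc, np) < pmat
    idx <- which(hit, arr.ind = TRUE)
    edges <- data.frame(
      node1 = cytokine_panel[idx[, 1]],
      node2 = proteins[idx[, 2]],
      stringsAsFactors = FALSE
    )
    if (p_protein_protein > 0 && np >= 2) {
      pairs <- utils::combn(np, 2)
      keep <- stats::runif(ncol(pairs)) < p_protein_protein
      if (any(keep)) {
        edges <- rbind(edges, data.frame(
          node1 = proteins[pairs[1, keep]],
          node2 = proteins[pairs[2, keep]],
          stringsAsFactors = FALSE
        ))
      }
    }
    edges$combined_score <- stats::runif(nrow(edges), score_range[1], score_range[2])
    rownames(edges) <- NULL
    edges
  })
}

#' Write a simulated study to disk as plain text
#'
#' Writes the abundance matrix, sample metadata, and the ground-truth JSON
#' sidecar into `dir` (created if needed), using the tab-delimited formats
#' read back by [read_abundance()] and [read_metadata()].
#'
#' @param sim output of [simulate_abundance()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_simulation_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_abundance(sim$abundance, paths[["abundance"]])
  write_metadata(sim$metadata, paths[["metadata"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
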