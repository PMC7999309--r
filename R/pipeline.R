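#' Configuration for an end-to-end pipeline run
#'
#' Collects input locations (paths to the tab-delimited formats, or the
#' in-memory objects themselves), the analysis thresholds, and the seed.
#' Defaults mirror the study conventions: significance at |pi| > 1,
#' interactions above a 0.4 combined score, cytokine eligibility at five
#' connections, and 999 permutations for PERMANOVA.
#'
#' @param abundance path to an abundance TSV, or a matrix.
#' @param metadata path to a metadata TSV, or a data.frame.
#' @param network path to an edge-list TSV, or a data.frame; `NULL` skips
#'   the cytokine stage.
#' @param out_dir output directory for all result tables; `NULL` keeps
#'   results in memory only.
#' @param pi_threshold strict |pi| significance cutoff.
#' @param min_interaction_score strict combined-score cutoff.
#' @param min_connections cytokine eligibility cutoff (inclusive).
#' @param n_permutations PERMANOVA budget.
#' @param class_weighting enrichment class-total definition
#'   (see [enrichment_scores()]).
#' @param pseudocount fold-change stabilizer.
#' @param case_label metadata `group` value marking case samples.
#' @param cytokine_panel cytokine identifiers
#'   (default [expand_cytokine_panel()]).
#' @param cytokine_classes pro-/anti-inflammatory table
#'   (default [default_cytokine_classes()]).
#' @param top_k volcano top hits per class.
#' @param seed integer master seed; stages draw from named substreams so
#'   rerunning a single stage reproduces its part of a full run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, metadata, network = NULL,
                            out_dir = NULL, pi_threshold = 1,
                            min_interaction_score = 0.4,
                            min_connections = 5, n_permutations = 999,
                            class_weighting = "protein_count",
                            pseudocount = 0, case_label = "V-AKI",
                            cytokine_panel = expand_cytokine_panel(),
                            cytokine_classes = default_cytokine_classes(),
                            top_k = 10, seed = 1L) {
  stopifnot(pi_threshold >= 0, min_interaction_score >= 0,
            min_interaction_score <= 1, pseudocount >= 0)
  cfg <- list(abundance = abundance, metadata = metadata, network = network,
              out_dir = out_dir, pi_threshold = pi_threshold,
              min_interaction_score = min_interaction_score,
              min_connections = assert_count(min_connections, "min_connections"),
              n_permutations = assert_count(n_permutations, "n_permutations", 1L),
              class_weighting = class_weighting, pseudocount = pseudocount,
              case_label = case_label, cytokine_panel = cytokine_panel,
              cytokine_classes = cytokine_classes,
              top_k = assert_count(top_k, "top_k"),
              seed = assert_count(seed, "seed"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes normalization, differential testing with pi-score
#' classification, Bray-Curtis/PCoA/PERMANOVA ordination, and (when a
#' network is supplied) cytokine enrichment inference, writing every
#' intermediate table plus a machine-readable run report. Outputs are
#' plain text and deterministic: the same config and seed reproduce every
#' file byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return the run report (invisibly if `out_dir` is set): a list with
#'   normalization, differential, ordination and cytokine summaries plus
#'   every result object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  abundance <- if (is.character(config$abundance)) {
    read_abundance(config$abundance)
  } else config$abundance
  metadata <- if (is.character(config$metadata)) {
    read_metadata(config$metadata)
  } else config$metadata
  network <- if (is.character(config$network)) {
    read_network(config$network)
  } else config$network
  validate_abundance(abundance)

  if (!setequal(colnames(abundance), metadata$sample_id)) {
    stop("sample identifiers in abundance and metadata do not match",
         call. = FALSE)
  }
  grp <- metadata$group[match(colnames(abundance), metadata$sample_id)]
  if (length(unique(grp)) != 2) {
    stop("metadata group must be binary", call. = FALSE)
  }
  if (min(table(grp)) < 2) stop("need at least 2 samples per group", call. = FALSE)

  norm <- normalize_two_step(abundance)
  diff_tab <- differential_test(norm$abundance, metadata,
                                case_label = config$case_label,
                                pseudocount = config$pseudocount,
                                pi_threshold = config$pi_threshold)
  volcano <- volcano_table(diff_tab, top_k = config$top_k)

  d <- bray_curtis(norm$abundance)
  ord <- pcoa(d)
  perm <- permanova(d, grp, n_permutations = config$n_permutations,
                    seed = stage_seed(config$seed, "permanova"))
  dist_summary <- between_group_distance_summary(d, grp)

  cytokine <- NULL
  if (!is.null(network)) {
    filtered <- filter_edges(network, min_score = config$min_interaction_score)
    sig <- diff_tab[diff_tab$class_label != "not_significant",
                    c("protein_id", "class_label")]
    enr <- enrichment_scores(filtered, sig, cytokines = config$cytokine_panel,
                             min_connections = config$min_connections,
                             class_weighting = config$class_weighting)
    decorated <- decorate_network(filtered, diff_tab, enr,
                                  classes = config$cytokine_classes)
    cytokine <- list(filtered = filtered, enrichment = enr,
                     decorated = decorated)
  }

  class_counts <- table(factor(diff_tab$class_label,
                               levels = c("case_associated",
                                          "control_associated",
                                          "not_significant")))
  report <- list(
    config = config_echo(config),
    n_samples = ncol(abundance),
    n_proteins = nrow(abundance),
    n_proteins_tested = nrow(diff_tab),
    n_proteins_skipped = length(attr(diff_tab, "skipped")),
    class_counts = as.list(class_counts),
    permanova = list(pseudo_F = perm$pseudo_F, p_value = perm$p_value,
                     n_permutations = perm$n_permutations,
                     exhaustive = perm$exhaustive),
    eligible_cytokines = if (is.null(cytokine)) character(0) else
      cytokine$enrichment$cytokine,
    fold_connections = if (is.null(cytokine)) NULL else
      stats::setNames(as.list(cytokine$enrichment$fold_connection),
                      cytokine$enrichment$cytokine)
  )

  results <- list(report = report, normalized = norm, differential = diff_tab,
                  volcano = volcano, distance = d, pcoa = ord,
                  permanova = perm, distance_summary = dist_summary,
                  cytokine = cytokine)

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(results, config)
    return(invisible(results))
  }
  results
}

config_echo <- function(config) {
  keep <- setdiff(names(config), c("abundance", "metadata", "network",
                                   "cytokine_classes", "cytokine_panel",
                                   "out_dir"))
  out <- unclass(config)[keep]
  out$cytokine_panel_size <- length(config$cytokine_panel)
  out
}

write_pipeline_outputs <- function(results, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)

  write_abundance(results$normalized$abundance, p("normalized_abundance.tsv"))
  write_normalization_factors(results$normalized$factors,
                              p("normalization_factors_protein.tsv"),
                              p("normalization_factors_sample.tsv"))

  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(results$volcano, "differential_table.tsv")
  skipped <- attr(results$differential, "skipped")
  wt(data.frame(protein_id = skipped), "skipped_proteins.tsv")

  dd <- data.frame(sample_id = rownames(results$distance), results$distance,
                   check.names = FALSE)
  wt(dd, "bray_curtis_distance.tsv")
  if (ncol(results$pcoa$coordinates)) {
    cc <- data.frame(sample_id = rownames(results$pcoa$coordinates),
                     results$pcoa$coordinates, check.names = FALSE)
    wt(cc, "pcoa_coordinates.tsv")
  }
  wt(data.frame(axis = seq_along(results$pcoa$eigenvalues),
                eigenvalue = results$pcoa$eigenvalues),
     "pcoa_eigenvalues.tsv")
  wt(results$distance_summary, "distance_summary.tsv")

  if (!is.null(results$cytokine)) {
    wt(results$cytokine$enrichment, "cytokine_enrichment.tsv")
    write_decorated_network(results$cytokine$decorated,
                            graphml_path = p("network_decorated.graphml"),
                            sif_path = p("network.sif"),
                            node_attr_path = p("network_node_attributes.tsv"))
  }

  jsonlite::write_json(results$report, p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # config echo doubles as the run log; no timestamps so reruns are
  # byte-identical
  writeLines(c("cytopi pipeline run",
               paste0(names(results$report$config), " = ",
                      vapply(results$report$config, function(v)
                        paste(format(v), collapse = ","), character(1)))),
             p("run_log.txt"))
  invisible(NULL)
}
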