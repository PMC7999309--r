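#' Expand a cytokine panel specification
#'
#' Panel entries are either plain names ("TNF") or numbered ranges written
#' `PREFIXa-b` ("CXCL1-16" expands to CXCL1 ... CXCL16). The default panel
#' covers TGFb, TNF, IFN and the IL, CXCL and CCL families (86 names).
#' The expansion is de-duplicated and order-preserving.
#'
#' @param panel_spec character vector of names and range strings.
#' @return character vector of cytokine identifiers.
#' @examples
#' expand_cytokine_panel("CXCL1-16")
#' length(expand_cytokine_panel())  # 86
#' @export
expand_cytokine_panel <- function(panel_spec = c("TGFb", "TNF", "IFN",
                                                 "IL1-40", "CXCL1-16",
                                                 "CCL1-27")) {
  out <- character(0)
  for (s in panel_spec) {
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9_]*?)([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) == 4) {
      a <- as.integer(m[3]); b <- as.integer(m[4])
      if (a > b) stop("malformed range (a > b): ", s, call. = FALSE)
      out <- c(out, paste0(m[2], a:b))
    } else if (grepl("^[A-Za-z][A-Za-z0-9_]*$", s)) {
      out <- c(out, s)
    } else {
      stop("malformed panel entry: ", s, call. = FALSE)
    }
  }
  out[!duplicated(out)]
}

#' Filter interaction edges by combined score
#'
#' Retains edges whose combined confidence score is strictly greater than
#' `min_score`; a score exactly at the threshold is removed, matching the
#' "minimum interaction score > 0.4" convention.
#'
#' @param network edge-list data.frame (`node1`, `node2`,
#'   `combined_score`).
#' @param min_score score threshold (default 0.4).
#' @return the filtered edge list.
#' @export
filter_edges <- function(network, min_score = 0.4) {
  validate_network(network)
  out <- network[network$combined_score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Edges between a given cytokine and a set of proteins, case-insensitive
# matching with optional alias resolution (alias -> canonical name).
canonical <- function(x, aliases = NULL) {
  x <- as.character(x)
  if (!is.null(aliases)) {
    hit <- match(toupper(x), toupper(names(aliases)))
    x[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  toupper(x)
}

#' Cytokines eligible for enrichment scoring
#'
#' A cytokine is eligible when it has at least `min_connections` filtered
#' edges to significantly altered proteins (either class). Matching of
#' cytokine and protein identifiers is exact-string and case-insensitive,
#' with an optional alias table.
#'
#' @param network a (score-filtered) edge list.
#' @param significant_proteins data.frame with `protein_id` and
#'   `class_label` in `{case_associated, control_associated}` — e.g. the
#'   significant rows of [differential_test()] output.
#' @param cytokines panel of cytokine identifiers
#'   (default [expand_cytokine_panel()]).
#' @param min_connections eligibility cutoff (default 5, inclusive).
#' @param aliases optional named character vector, alias -> canonical.
#' @return character vector of eligible cytokine identifiers (as given in
#'   `cytokines`).
#' @export
eligible_cytokines <- function(network, significant_proteins,
                               cytokines = expand_cytokine_panel(),
                               min_connections = 5, aliases = NULL) {
  counts <- cytokine_edge_counts(network, significant_proteins, cytokines,
                                 aliases)
  cytokines[counts$k_total >= min_connections]
}

cytokine_edge_counts <- function(network, significant_proteins, cytokines,
                                 aliases = NULL) {
  stopifnot(is.data.frame(significant_proteins),
            all(c("protein_id", "class_label") %in% names(significant_proteins)))
  cyt <- canonical(cytokines, aliases)
  n1 <- canonical(network$node1, aliases)
  n2 <- canonical(network$node2, aliases)
  sig <- canonical(significant_proteins$protein_id, aliases)
  cls <- significant_proteins$class_label
  case_set <- sig[cls == "case_associated"]
  ctrl_set <- sig[cls == "control_associated"]

  count_to <- function(target_set) {
    vapply(cyt, function(c0) {
      partner <- c(n2[n1 == c0], n1[n2 == c0])
      sum(partner %in% target_set & !partner %in% cyt)
    }, integer(1), USE.NAMES = FALSE)
  }
  k_case <- count_to(case_set)
  k_control <- count_to(ctrl_set)
  data.frame(cytokine = cytokines, k_case = k_case, k_control = k_control,
             k_total = k_case + k_control, stringsAsFactors = FALSE)
}

#' Cytokine connection-enrichment scores
#'
#' For each eligible cytokine `c`, the proportion of its connections going
#' to class-`d` proteins is compared with the class's share of the
#' network: `e_d(c) = (k_d(c) / T_d) / (k_total(c) / T_total)` with
#' `T_total = T_case + T_control`. The class totals `T_d` are either the
#' number of significant proteins in class `d` (`protein_count`, default)
#' or the number of filtered protein-protein edges incident to class-`d`
#' proteins, cytokine edges excluded (`edge_count`). The fold-connection
#' ratio is `e_case / e_control` and may be infinite when a cytokine has
#' no control-class connections; it is reported as such, never capped.
#'
#' @inheritParams eligible_cytokines
#' @param class_weighting `"protein_count"` or `"edge_count"` (the two
#'   readings of the class total).
#' @return data.frame with one row per eligible cytokine: `cytokine`,
#'   `k_case`, `k_control`, `k_total`, `e_case`, `e_control`,
#'   `fold_connection`, sorted by decreasing `fold_connection`.
#' @export
enrichment_scores <- function(network, significant_proteins,
                              cytokines = expand_cytokine_panel(),
                              min_connections = 5,
                              class_weighting = c("protein_count", "edge_count"),
                              aliases = NULL) {
  class_weighting <- match.arg(class_weighting)
  counts <- cytokine_edge_counts(network, significant_proteins, cytokines,
                                 aliases)
  counts <- counts[counts$k_total >= min_connections, , drop = FALSE]

  sig <- canonical(significant_proteins$protein_id, aliases)
  cls <- significant_proteins$class_label
  cyt <- canonical(cytokines, aliases)
  if (class_weighting == "protein_count") {
    t_case <- sum(cls == "case_associated")
    t_control <- sum(cls == "control_associated")
  } else {
    n1 <- canonical(network$node1, aliases)
    n2 <- canonical(network$node2, aliases)
    pp <- !(n1 %in% cyt) & !(n2 %in% cyt)
    incident <- function(set) sum(pp & (n1 %in% set | n2 %in% set))
    t_case <- incident(sig[cls == "case_associated"])
    t_control <- incident(sig[cls == "control_associated"])
  }
  t_total <- t_case + t_control

  score <- function(k_d, t_d) {
    if (t_d == 0) return(rep(NA_real_, nrow(counts)))
    (k_d / t_d) / (counts$k_total / t_total)
  }
  counts$e_case <- score(counts$k_case, t_case)
  counts$e_control <- score(counts$k_control, t_control)
  counts$fold_connection <- counts$e_case / counts$e_control
  counts <- counts[order(-counts$fold_connection), , drop = FALSE]
  rownames(counts) <- NULL
  attr(counts, "class_totals") <- c(case = t_case, control = t_control)
  attr(counts, "class_weighting") <- class_weighting
  counts
}

#' Default pro-/anti-inflammatory cytokine classification
#'
#' A deliberately small, user-editable starting table: IL6 and TNF as
#' pro-inflammatory and IL10 as anti-inflammatory; every other panel
#' member is unclassified. Supply your own table to override.
#'
#' @param cytokines panel to classify.
#' @return data.frame with `cytokine` and `class`
#'   (`pro_inflammatory` / `anti_inflammatory` / `unclassified`).
#' @export
default_cytokine_classes <- function(cytokines = expand_cytokine_panel()) {
  cls <- rep("unclassified", length(cytokines))
  cls[toupper(cytokines) %in% c("IL6", "TNF")] <- "pro_inflammatory"
  cls[toupper(cytokines) == "IL10"] <- "anti_inflammatory"
  data.frame(cytokine = cytokines, class = cls, stringsAsFactors = FALSE)
}

#' Decorate a network with differential and inflammation attributes
#'
#' Produces Cytoscape-style node and edge attribute tables: significant
#' proteins are sized by |pi-score|; each protein is colored by its
#' connections to enriched cytokines (`pro` if connected to any
#' pro-inflammatory enriched cytokine — pro takes precedence — `anti` if
#' connected only to anti-inflammatory ones, `none` otherwise). Cytokine
#' nodes carry their enrichment fold. Proteins present in the network but
#' absent from the differential table get `NA` attributes with a warning.
#'
#' @param network a (filtered) edge list.
#' @param differential a classified differential table.
#' @param enrichment output of [enrichment_scores()] (its rows define the
#'   enriched cytokines).
#' @param classes a cytokine classification table
#'   (default [default_cytokine_classes()]).
#' @param aliases optional alias table as in [eligible_cytokines()].
#' @return list with `nodes` (node, type, size, inflammation_color,
#'   fold_connection) and `edges` (node1, node2, combined_score).
#' @export
decorate_network <- function(network, differential, enrichment,
                             classes = default_cytokine_classes(),
                             aliases = NULL) {
  validate_network(network)
  nodes <- unique(c(network$node1, network$node2))
  cyt_can <- canonical(enrichment$cytokine, aliases)
  cls_can <- canonical(classes$cytokine, aliases)
  node_can <- canonical(nodes, aliases)
  all_cyt_can <- unique(c(cls_can, cyt_can))
  type <- ifelse(node_can %in% all_cyt_can, "cytokine", "protein")

  diff_can <- canonical(differential$protein_id, aliases)
  hit <- match(node_can, diff_can)
  size <- rep(NA_real_, length(nodes))
  is_prot <- type == "protein"
  known <- is_prot & !is.na(hit)
  sig <- known & differential$class_label[hit] != "not_significant"
  size[sig] <- abs(differential$pi_score[hit[sig]])
  if (any(is_prot & is.na(hit))) {
    warning("proteins absent from the differential table: ",
            paste(nodes[is_prot & is.na(hit)], collapse = ", "))
  }

  pro_cyt <- cls_can[classes$class == "pro_inflammatory"]
  anti_cyt <- cls_can[classes$class == "anti_inflammatory"]
  pro_enriched <- intersect(cyt_can, pro_cyt)
  anti_enriched <- intersect(cyt_can, anti_cyt)
  n1 <- canonical(network$node1, aliases)
  n2 <- canonical(network$node2, aliases)
  color <- vapply(seq_along(nodes), function(i) {
    if (!is_prot[i]) return(NA_character_)
    partners <- c(n2[n1 == node_can[i]], n1[n2 == node_can[i]])
    if (any(partners %in% pro_enriched)) "pro"
    else if (any(partners %in% anti_enriched)) "anti"
    else "none"
  }, character(1))

  fold <- rep(NA_real_, length(nodes))
  ehit <- match(node_can, cyt_can)
  fold[!is.na(ehit)] <- enrichment$fold_connection[ehit[!is.na(ehit)]]

  list(
    nodes = data.frame(node = nodes, type = type, size = size,
                       inflammation_color = color, fold_connection = fold,
                       stringsAsFactors = FALSE),
    edges = network[, c("node1", "node2", "combined_score")]
  )
}

#' Write a decorated network as GraphML and SIF
#'
#' GraphML via igraph carries all node and edge attributes; the SIF pair
#' (`.sif` plus a node-attribute TSV) is the classic Cytoscape import
#' format.
#'
#' @param decorated output of [decorate_network()].
#' @param graphml_path,sif_path,node_attr_path output paths; any may be
#'   `NULL` to skip that format.
#' @return invisibly, the paths written.
#' @export
write_decorated_network <- function(decorated, graphml_path = NULL,
                                    sif_path = NULL, node_attr_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      decorated$edges, directed = FALSE,
      vertices = decorated$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(sif_path)) {
    sif <- data.frame(node1 = decorated$edges$node1,
                      interaction = "interacts",
                      node2 = decorated$edges$node2)
    utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, sif_path)
  }
  if (!is.null(node_attr_path)) {
    utils::write.table(decorated$nodes, node_attr_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, node_attr_path)
  }
  invisible(written)
}
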