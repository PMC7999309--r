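#' Welch's unequal-variance t-test for one protein
#'
#' Two-sided independent t-test with Welch-Satterthwaite degrees of
#' freedom, on the present (non-missing) values of each group. Degenerate
#' inputs are resolved explicitly: if both groups are constant with equal
#' values the protein shows no evidence of change (`t = 0`, `p = 1`); if
#' both are constant but unequal the difference is infinitely significant
#' relative to zero variance, and `p` is clamped to the smallest positive
#' double with a warning.
#'
#' @param case_values,control_values numeric vectors; at least two present
#'   values each.
#' @return list with `statistic` (t), `p_value`, and `df`.
#' @export
welch_t <- function(case_values, control_values) {
  x <- case_values[!is.na(case_values)]
  y <- control_values[!is.na(control_values)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs at least 2 present values per group", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    }
    warning("both groups constant but unequal; p clamped to smallest double")
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                p_value = .Machine$double.xmin, df = NA_real_))
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(res$statistic),
       p_value = res$p.value,
       df = unname(res$parameter))
}

#' Log2 fold-change of group means
#'
#' `log2((mean_case + pseudocount) / (mean_control + pseudocount))`, with
#' means taken over present values. The ratio of arithmetic group means is
#' the common label-free convention; the pseudocount (default 0) guards
#' against zero means when needed.
#'
#' @inheritParams welch_t
#' @param pseudocount non-negative stabilizer added to both means.
#' @return signed log2 fold-change (case over control).
#' @export
log2_fold_change <- function(case_values, control_values, pseudocount = 0) {
  mc <- mean(case_values, na.rm = TRUE) + pseudocount
  mk <- mean(control_values, na.rm = TRUE) + pseudocount
  if (mc <= 0 || mk <= 0) {
    stop("fold-change undefined: group mean + pseudocount must be > 0",
         call. = FALSE)
  }
  log2(mc / mk)
}

#' Pi-score: signed fold-change times significance
#'
#' `pi = log2fc * (-log10 p)`. The sign follows the fold-change; the
#' magnitude grows as the p-value shrinks or the fold-change grows, so the
#' score ranks proteins by combined effect size and significance. `p = 0`
#' is clamped to the smallest positive double with a warning.
#'
#' @param p_value p-value in (0, 1].
#' @param log2fc signed log2 fold-change.
#' @return the signed pi-score.
#' @export
pi_score <- function(p_value, log2fc) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) {
    stop("p_value must lie in (0, 1]", call. = FALSE)
  }
  if (any(p_value == 0, na.rm = TRUE)) {
    warning("p-value of 0 clamped to smallest positive double")
    p_value[p_value == 0] <- .Machine$double.xmin
  }
  log2fc * (-log10(p_value))
}

#' Per-protein differential abundance table
#'
#' Runs [welch_t()] and [log2_fold_change()] on every protein of a
#' (normalized) abundance matrix, computes pi-scores, and classifies
#' proteins at the pi threshold. Proteins with fewer than two present
#' values in either group cannot be tested and are reported in the
#' `skipped` attribute. A Benjamini-Hochberg `bh_q` column is provided for
#' reference but plays no role in classification, which uses the raw
#' p-value through the pi-score.
#'
#' @param abundance abundance matrix (proteins x samples).
#' @param metadata data.frame with `sample_id` and `group` covering the
#'   matrix columns.
#' @param case_label value of `group` identifying case samples.
#' @param pseudocount passed to [log2_fold_change()].
#' @param pi_threshold classification threshold on |pi| (strict).
#' @return a `data.frame` with columns `protein_id`, `mean_case`,
#'   `mean_control`, `log2fc`, `p_value`, `bh_q`, `pi_score`,
#'   `class_label`; untestable proteins in `attr(, "skipped")`.
#' @export
differential_test <- function(abundance, metadata, case_label = "V-AKI",
                              pseudocount = 0, pi_threshold = 1) {
  validate_abundance(abundance)
  if (!all(colnames(abundance) %in% metadata$sample_id)) {
    stop("metadata does not cover all samples", call. = FALSE)
  }
  grp <- metadata$group[match(colnames(abundance), metadata$sample_id)]
  if (!case_label %in% grp) stop("no samples with case label '", case_label, "'",
                                 call. = FALSE)
  is_case <- grp == case_label
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }

  n_case_present <- rowSums(!is.na(abundance[, is_case, drop = FALSE]))
  n_ctrl_present <- rowSums(!is.na(abundance[, !is_case, drop = FALSE]))
  testable <- n_case_present >= 2 & n_ctrl_present >= 2
  skipped <- rownames(abundance)[!testable]

  ids <- rownames(abundance)[testable]
  res <- lapply(ids, function(id) {
    x <- abundance[id, is_case]
    y <- abundance[id, !is_case]
    w <- welch_t(x, y)
    lfc <- log2_fold_change(x, y, pseudocount)
    data.frame(protein_id = id,
               mean_case = mean(x, na.rm = TRUE),
               mean_control = mean(y, na.rm = TRUE),
               log2fc = lfc,
               p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (is.null(tab)) {
    tab <- data.frame(protein_id = character(0), mean_case = numeric(0),
                      mean_control = numeric(0), log2fc = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  }
  tab$bh_q <- stats::p.adjust(tab$p_value, method = "BH")
  tab$pi_score <- pi_score(tab$p_value, tab$log2fc)
  tab <- classify_proteins(tab, threshold = pi_threshold)
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  tab
}

#' Classify proteins by pi-score
#'
#' Strict threshold per the significance rule |pi| > threshold:
#' `case_associated` when `pi > threshold`, `control_associated` when
#' `pi < -threshold`, otherwise `not_significant`. A pi-score exactly at
#' the threshold is not significant.
#'
#' @param table differential table with a `pi_score` column.
#' @param threshold positive pi cutoff (default 1).
#' @return the table with a `class_label` column (re)assigned.
#' @export
classify_proteins <- function(table, threshold = 1) {
  stopifnot(is.data.frame(table), "pi_score" %in% names(table), threshold >= 0)
  cls <- rep("not_significant", nrow(table))
  cls[table$pi_score > threshold] <- "case_associated"
  cls[table$pi_score < -threshold] <- "control_associated"
  table$class_label <- cls
  table
}

#' Volcano export with top-k flags
#'
#' Adds `neg_log10_p` and a `top_hit` flag marking, within each
#' significant class, the `top_k` proteins by |pi| (ties broken by smaller
#' p-value, then by table order). This mirrors the usual volcano-plot
#' labeling of the ten strongest case- and control-associated proteins.
#'
#' @param table a classified differential table.
#' @param top_k number of proteins to flag per class.
#' @return the table with `neg_log10_p` and logical `top_hit` columns,
#'   ordered as input.
#' @export
volcano_table <- function(table, top_k = 10) {
  stopifnot(is.data.frame(table),
            all(c("pi_score", "p_value", "class_label") %in% names(table)))
  table$neg_log10_p <- -log10(table$p_value)
  table$top_hit <- FALSE
  for (cls in c("case_associated", "control_associated")) {
    idx <- which(table$class_label == cls)
    if (!length(idx)) next
    ord <- idx[order(-abs(table$pi_score[idx]), table$p_value[idx], idx)]
    table$top_hit[utils::head(ord, top_k)] <- TRUE
  }
  table
}
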