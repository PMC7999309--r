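#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` over proteins, bounded in
#' [0, 1] for non-negative data. Missing abundances are treated as zeros
#' for the distance computation only (the single `as_zero` policy),
#' matching how community-ecology tooling handles absences.
#'
#' @param mat abundance matrix (proteins x samples, `NA` = missing).
#' @param missing_policy how to treat missing values; only `"as_zero"`.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(mat, missing_policy = c("as_zero")) {
  validate_abundance(mat)
  match.arg(missing_policy)
  x <- mat
  x[is.na(x)] <- 0
  n <- ncol(x)
  ids <- colnames(x)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(x[, i] + x[, j])
      if (denom == 0) {
        stop("Bray-Curtis undefined for all-zero sample pair: ",
             ids[i], ", ", ids[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(abs(x[, i] - x[, j])) / denom
    }
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-d^2 / 2` followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues — which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis — are
#' reported but receive no axes and no correction. Proportions explained
#' are taken over the positive-eigenvalue total.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return list of class `cytopi_pcoa` with `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, descending), and
#'   `proportion_explained` (per positive axis).
#' @export
pcoa <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12)) {
    stop("'d' must be symmetric with zero diagonal", call. = FALSE)
  }
  n <- nrow(d)
  a <- -0.5 * d^2
  center <- diag(n) - matrix(1 / n, n, n)
  b <- center %*% a %*% center
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-8
  pos <- which(e$values > tol)
  if (!length(pos)) {
    warning("no positive eigenvalues: all samples coincide")
    coords <- matrix(numeric(0), nrow = n, ncol = 0,
                     dimnames = list(rownames(d), NULL))
    prop <- numeric(0)
  } else {
    coords <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), length(pos))
    dimnames(coords) <- list(rownames(d), paste0("Axis.", seq_along(pos)))
    prop <- e$values[pos] / sum(e$values[pos])
  }
  structure(list(coordinates = coords, eigenvalues = e$values,
                 proportion_explained = prop),
            class = "cytopi_pcoa")
}

#' @export
print.cytopi_pcoa <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("PCoA:", nrow(x$coordinates), "samples,", k, "positive axes\n")
  if (k) {
    cat("proportion explained (first axes):",
        paste(sprintf("%.3f", utils::head(x$proportion_explained, 5)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F in Anderson's sums-of-squares form computed directly from
#' pairwise distances: `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` from
#' within-group pairs (each group divided by its size), `SS_between =
#' SS_total - SS_within`, and
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))` for `a` groups.
#' The null distribution comes from permuting group labels. When the
#' number of distinct relabelings is within the permutation budget the
#' test enumerates all of them exhaustively (p = fraction of relabelings,
#' observed included, with `F >= F_obs`); otherwise it samples
#' `n_permutations` labelings uniformly with replacement and uses the
#' `(1 + more extreme) / (1 + n_permutations)` convention, so p is never 0.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   members).
#' @param n_permutations permutation budget (default 999).
#' @param seed integer seed for the sampled mode; the caller's RNG state
#'   is left untouched.
#' @return list of class `cytopi_permanova`: `pseudo_F`, `p_value`,
#'   `n_permutations` (actually used), `exhaustive`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), length(groups) == nrow(d))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  off <- d[upper.tri(d)]
  if (max(off) - min(off) < .Machine$double.eps * 100) {
    stop("constant distance matrix: pseudo-F undefined", call. = FALSE)
  }
  d2 <- d^2
  f_obs <- pseudo_f(d2, groups)

  n_distinct <- exp(lfactorial(length(groups)) - sum(lfactorial(sizes)))
  if (n_distinct <= n_permutations + 0.5) {
    perms <- enumerate_labelings(groups)
    f_perm <- vapply(perms, function(g) pseudo_f(d2, g), numeric(1))
    p <- sum(f_perm >= f_obs - 1e-12) / length(f_perm)
    res <- list(pseudo_F = f_obs, p_value = p,
                n_permutations = length(f_perm), exhaustive = TRUE,
                seed = seed)
  } else {
    f_perm <- with_local_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) pseudo_f(d2, sample(groups)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    res <- list(pseudo_F = f_obs, p_value = p,
                n_permutations = n_permutations, exhaustive = FALSE,
                seed = seed)
  }
  class(res) <- "cytopi_permanova"
  res
}

#' @export
print.cytopi_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

pseudo_f <- function(d2, groups) {
  n <- length(groups)
  lv <- unique(groups)
  a <- length(lv)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# All distinct assignments of the multiset of labels to positions.
enumerate_labelings <- function(groups) {
  lv <- sort(unique(groups))
  sizes <- vapply(lv, function(g) sum(groups == g), integer(1))
  recurse <- function(positions, k) {
    if (k == length(lv)) {
      lab <- character(length(groups))
      lab[positions] <- lv[k]
      return(list(stats::setNames(lab, NULL)))
    }
    out <- list()
    for (sel in utils::combn(length(positions), sizes[k], simplify = FALSE)) {
      chosen <- positions[sel]
      rest <- positions[-sel]
      for (tail in recurse(rest, k + 1)) {
        tail[chosen] <- lv[k]
        out[[length(out) + 1L]] <- tail
      }
    }
    out
  }
  base <- recurse(seq_along(groups), 1)
  base
}

#' Summarize pairwise distances within and between groups
#'
#' For every unordered pair of group labels (including each group with
#' itself) reports the five-number summary of the pairwise distances, the
#' usual companion to an ordination plot. A within-group comparison for a
#' singleton group has no pairs and is reported with `n_pairs = 0` and
#' `NA` statistics, not zeros.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample.
#' @return data.frame with `comparison`, `n_pairs`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
between_group_distance_summary <- function(d, groups) {
  stopifnot(is.matrix(d), length(groups) == nrow(d))
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  combos <- list()
  for (i in seq_along(lv)) {
    for (j in i:length(lv)) {
      combos[[length(combos) + 1L]] <- c(lv[i], lv[j])
    }
  }
  rows <- lapply(combos, function(cmb) {
    ij <- which(upper.tri(d), arr.ind = TRUE)
    gi <- groups[ij[, 1]]; gj <- groups[ij[, 2]]
    keep <- (gi == cmb[1] & gj == cmb[2]) | (gi == cmb[2] & gj == cmb[1])
    vals <- d[ij[keep, , drop = FALSE]]
    if (!length(vals)) {
      data.frame(comparison = paste(cmb[1], cmb[2], sep = " vs "),
                 n_pairs = 0L, min = NA_real_, q1 = NA_real_,
                 median = NA_real_, q3 = NA_real_, max = NA_real_)
    } else {
      q <- stats::quantile(vals, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(comparison = paste(cmb[1], cmb[2], sep = " vs "),
                 n_pairs = length(vals), min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
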