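# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct transcription of the defining formula, kept
# separate from the package implementation it checks.

# Welch's t from first principles
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}

# Bray-Curtis for one pair, straight from the definition
oracle_bray <- function(u, v) sum(abs(u - v)) / sum(u + v)

# One-way pseudo-F via vegan (independent of the package's sums)
oracle_pseudo_f <- function(d, groups) {
  fit <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 0)
  fit$F[1]
}

# Exhaustive two-group permutation p using the vegan-based F
oracle_exhaustive_p <- function(d, groups) {
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  n <- length(groups)
  k <- sum(groups == lv[1])
  f_obs <- oracle_pseudo_f(d, groups)
  sets <- utils::combn(n, k, simplify = FALSE)
  f_all <- vapply(sets, function(idx) {
    g <- rep(lv[2], n); g[idx] <- lv[1]
    oracle_pseudo_f(d, g)
  }, numeric(1))
  mean(f_all >= f_obs - 1e-12)
}

# Random abundance matrix with optional missing cells
random_abundance <- function(n_prot, n_samp, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(2^rnorm(n_prot * n_samp, 10, 2), n_prot, n_samp,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              sprintf("S%02d", seq_len(n_samp))))
  if (missing_rate > 0) {
    m[runif(length(m)) < missing_rate] <- NA
    # keep every row and column testable for normalization
    for (i in which(rowSums(!is.na(m)) == 0)) m[i, 1] <- 2^rnorm(1, 10, 2)
    for (j in which(colSums(!is.na(m)) == 0)) m[1, j] <- 2^rnorm(1, 10, 2)
  }
  m
}

worked_2x2 <- function() {
  matrix(c(2, 4, 8, 16), nrow = 2, byrow = TRUE,
         dimnames = list(c("P1", "P2"), c("s1", "s2")))
}

# A tiny hand-built significant-protein table + network for enrichment
hand_network <- function() {
  sig <- data.frame(
    protein_id = c("A1", "A2", "A3", "C1", "C2"),
    class_label = c(rep("case_associated", 3), rep("control_associated", 2)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    node1 = c("IL6", "IL6", "IL6"),
    node2 = c("A1", "A2", "C1"),
    combined_score = c(0.9, 0.8, 0.7),
    stringsAsFactors = FALSE
  )
  list(sig = sig, edges = edges)
}
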