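#' Two-step abundance normalization
#'
#' Label-free protein abundances are normalized in two median-anchored
#' steps. Step 1 removes between-protein scale: each protein's abundances
#' are divided by `f_i = mean_i / median(mean_i over proteins)`, where
#' `mean_i` is the protein's average abundance across the experiment.
#' Afterwards every protein's mean equals the original median of protein
#' means. Step 2 removes between-sample (run-to-run) scale: each sample's
#' values are divided by `g_j = median_j / median(all values)`, where
#' `median_j` is the sample's median abundance. Afterwards every sample's
#' median equals the pre-step overall median.
#'
#' All means and medians are taken over present (non-missing) values only;
#' `NA` cells stay `NA` — no imputation. Zeros are legitimate values and
#' enter the statistics, but a protein whose values are all missing or all
#' zero (step 1), or a sample with median zero (step 2), makes the factor
#' undefined and is reported as an error rather than dropped silently.
#' Medians of even-length sets are the midpoint of the two central values.
#'
#' @param mat abundance matrix (proteins x samples, `NA` = missing).
#' @return a list with
#'   \describe{
#'     \item{abundance}{the normalized matrix (same shape and missingness).}
#'     \item{factors}{the scaling factors: `protein_factor` (step 1),
#'       `sample_factor` (step 2), `grand_median_of_protein_means`, and
#'       `overall_median_after_step1`. `normalize_two_step()` returns all
#'       four; the single steps return their own.}
#'   }
#' @examples
#' m <- matrix(c(2, 4, 8, 16), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' normalize_two_step(m)$abundance   # every entry 7.5
#' @export
normalize_two_step <- function(mat) {
  s1 <- step1_protein_scaling(mat)
  s2 <- step2_sample_scaling(s1$abundance)
  list(abundance = s2$abundance,
       factors = c(s1$factors, s2$factors))
}

#' @rdname normalize_two_step
#' @export
step1_protein_scaling <- function(mat) {
  validate_abundance(mat)
  means <- rowMeans(mat, na.rm = TRUE)
  bad <- rownames(mat)[!is.finite(means) | means <= 0]
  if (length(bad)) {
    stop("step 1 factor undefined (all-missing or all-zero protein): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grand <- stats::median(means)
  f <- means / grand
  list(abundance = mat / f,
       factors = list(protein_factor = f,
                      grand_median_of_protein_means = grand))
}

#' @rdname normalize_two_step
#' @export
step2_sample_scaling <- function(mat) {
  validate_abundance(mat)
  med_j <- apply(mat, 2, stats::median, na.rm = TRUE)
  overall <- stats::median(mat, na.rm = TRUE)
  bad <- colnames(mat)[!is.finite(med_j) | med_j <= 0]
  if (length(bad)) {
    stop("step 2 factor undefined (sample median zero or all-missing): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- med_j / overall
  list(abundance = sweep(mat, 2, g, "/"),
       factors = list(sample_factor = g,
                      overall_median_after_step1 = overall))
}

#' Write normalization factors as a two-table report
#'
#' @param factors the `factors` element returned by [normalize_two_step()].
#' @param protein_path,sample_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_normalization_factors <- function(factors, protein_path, sample_path) {
  utils::write.table(
    data.frame(protein_id = names(factors$protein_factor),
               protein_factor = unname(factors$protein_factor)),
    protein_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(factors$sample_factor),
               sample_factor = unname(factors$sample_factor)),
    sample_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(protein_path, sample_path))
}
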