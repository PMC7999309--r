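#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG state: set the seed if given, and
# restore the caller's .Random.seed afterwards so package functions never
# perturb the global stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a per-stage seed from the pipeline seed, kept inside 32-bit range.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, network = 211L, permanova = 307L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

assert_fraction <- function(x, name, upper_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 &&
    (if (upper_open) x < 1 else x <= 1)
  if (!ok) {
    stop("'", name, "' must be a single number in [0, ",
         if (upper_open) "1)" else "1]", call. = FALSE)
  }
  as.numeric(x)
}

# Validate an abundance matrix: numeric, non-negative where present, unique
# dimnames. NA encodes a missing measurement, never zero.
validate_abundance <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("abundance must be a numeric matrix (proteins x samples)", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("abundance matrix needs protein rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate protein identifiers", call. = FALSE)
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers", call. = FALSE)
  if (any(mat < 0, na.rm = TRUE)) stop("abundances must be non-negative", call. = FALSE)
  invisible(mat)
}
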