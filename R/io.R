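#' Read and write the plain-text interchange formats
#'
#' The pipeline exchanges all data as tab-delimited text. An abundance
#' table has a `protein_id` first column and one column per sample;
#' empty cells and `NA` are missing measurements. Metadata has columns
#' `sample_id` and `group`. A network is a STRING-style three-column edge
#' list `node1`, `node2`, `combined_score` with scores in [0, 1].
#'
#' @param path file path.
#' @return `read_abundance()` a numeric matrix (proteins x samples, `NA` =
#'   missing); `read_metadata()` and `read_network()` data.frames.
#' @name cytopi_io
NULL

#' @rdname cytopi_io
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "protein_id") {
    stop("abundance table must have a 'protein_id' first column", call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$protein_id
  validate_abundance(mat)
  mat
}

#' @rdname cytopi_io
#' @param mat abundance matrix with protein rownames and sample colnames.
#' @export
write_abundance <- function(mat, path) {
  validate_abundance(mat)
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cytopi_io
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("metadata must have 'sample_id' and 'group' columns", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  df
}

#' @rdname cytopi_io
#' @param metadata data.frame with `sample_id` and `group`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cytopi_io
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node1", "node2", "combined_score") %in% names(df))) {
    stop("network must have columns node1, node2, combined_score", call. = FALSE)
  }
  validate_network(df)
  df
}

#' @rdname cytopi_io
#' @param network edge-list data.frame.
#' @export
write_network <- function(network, path) {
  validate_network(network)
  utils::write.table(network[, c("node1", "node2", "combined_score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_network <- function(network) {
  stopifnot(is.data.frame(network),
            all(c("node1", "node2", "combined_score") %in% names(network)))
  if (any(network$node1 == network$node2)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  s <- network$combined_score
  if (any(is.na(s)) || any(s < 0) || any(s > 1)) {
    stop("combined_score must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pmin(network$node1, network$node2),
               pmax(network$node1, network$node2))
  if (anyDuplicated(key)) stop("duplicate edges in network", call. = FALSE)
  invisible(network)
}
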