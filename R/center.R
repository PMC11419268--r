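#' Center each sample (column) to zero mean over features
#'
#' Subtracts from every column its mean over the features, so each sample's
#' profile sums to zero. This is the centering the PACA pipeline applies to
#' both the case and the control matrix before the sample-space CCA: it is a
#' per-sample operation, which makes centering of new samples independent of
#' the training data and lets fitted loadings transfer to other cohorts as a
#' pure matrix product.
#'
#' @param x numeric feature-by-sample matrix (features in rows).
#' @return A matrix of the same shape and dimnames with zero-mean columns.
#' @seealso [paca()] for the `center_features` pre-centering option.
#' @examples
#' m <- matrix(1:6, 3, 2)
#' colSums(center_columns(m))
#' @export
center_columns <- function(x) {
  x <- as_data_matrix(x, "x")
  sweep(x, 2L, colMeans(x), "-")
}

# Per-feature (row) centering used by the optional `center_features` flag.
center_rows <- function(x, means = rowMeans(x)) {
  list(values = x - means, means = means)
}
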