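## Functional connectivity networks: full Pearson correlation of regional
## time series. No thresholding, no Fisher transform -- the downstream
## coupling statistic is rank-based, so any monotone transform of the
## entries would leave it unchanged.

#' Build a functional connectivity network for one subject
#'
#' Computes the region-by-region Pearson correlation matrix of a
#' volumes-by-regions time-series matrix.
#'
#' @param series Numeric T x R matrix (T >= 3, no missing values). Column
#'   names are the region labels and must match the subject's morphological
#'   network ordering; unnamed columns receive consecutive labels.
#' @return Symmetric correlation matrix with unit diagonal and entries in
#'   `[-1, 1]`.
#' @examples
#' ts <- matrix(rnorm(60), 20, 3)
#' build_fcn(ts)
#' @export
build_fcn <- function(series) {
  if (is.list(series) && !is.null(series$values)) series <- series$values
  if (!is.matrix(series) || !is.numeric(series)) stop_mfc("series must be a numeric matrix")
  if (anyNA(series)) stop_mfc("series contains missing values")
  if (nrow(series) < 3L) stop_mfc("need at least 3 time points")
  if (ncol(series) < 2L) stop_mfc("need at least 2 regions")
  if (is.null(colnames(series))) colnames(series) <- region_labels(ncol(series))
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0))
    stop_mfc("zero-variance regions: ",
             paste(colnames(series)[sds == 0], collapse = ", "),
             class = "mfc_degenerate_error")
  m <- stats::cor(series)
  diag(m) <- 1
  m[m > 1] <- 1
  m[m < -1] <- -1
  m
}
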