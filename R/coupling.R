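## Morphology-function coupling: column-wise Spearman correlation between a
## subject's morphological similarity matrix and functional connectivity
## matrix, excluding self-connections. Ties receive average ranks (midranks).

check_coupling_inputs <- function(msn, fcn) {
  check_symmetric(msn, tol = 1e-9, what = "morphological network")
  check_symmetric(fcn, tol = 1e-9, what = "functional network")
  check_aligned(msn, fcn, "morphological network", "functional network")
  invisible(TRUE)
}

#' Regional morphology-function coupling
#'
#' For each region r, the Spearman rank correlation between the off-diagonal
#' entries of column r of the morphological similarity network and the same
#' entries of column r of the functional connectivity network. The diagonal
#' (self-connection) element is excluded from both columns.
#'
#' @param msn,fcn Aligned symmetric region-by-region matrices (see
#'   [build_msn()], [build_fcn()]).
#' @return Named numeric vector of per-region coupling values in `[-1, 1]`.
#' @export
regional_coupling <- function(msn, fcn) {
  check_coupling_inputs(msn, fcn)
  R <- nrow(msn)
  labs <- rownames(msn)
  if (is.null(labs)) labs <- region_labels(R)
  out <- vapply(seq_len(R), function(r) {
    x <- msn[-r, r]; y <- fcn[-r, r]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, 0)
  if (anyNA(out))
    stop_mfc("coupling undefined (constant column) for regions: ",
             paste(labs[is.na(out)], collapse = ", "),
             class = "mfc_degenerate_error")
  names(out) <- labs
  out
}

#' Global morphology-function coupling
#'
#' Spearman rank correlation between the unique off-diagonal (upper-triangle)
#' entries of the morphological and functional networks, giving one
#' whole-brain coherence value per subject. The mean of the regional coupling
#' map, an alternative global summary, is attached as attribute
#' `"mean_regional"`.
#'
#' @inheritParams regional_coupling
#' @return Single value in `[-1, 1]` with attribute `mean_regional`.
#' @export
global_coupling <- function(msn, fcn) {
  check_coupling_inputs(msn, fcn)
  ut <- upper.tri(msn)
  x <- msn[ut]; y <- fcn[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_mfc("global coupling undefined: constant off-diagonal entries",
             class = "mfc_degenerate_error")
  g <- stats::cor(x, y, method = "spearman")
  attr(g, "mean_regional") <- mean(regional_coupling(msn, fcn))
  g
}

as_partition <- function(partition, labs) {
  if (is.data.frame(partition)) {
    need <- c("region_index", "network")
    if (!all(need %in% names(partition)))
      stop_mfc("partition needs columns region_index and network")
    p <- partition$network[order(partition$region_index)]
    idx <- sort(partition$region_index)
    if (!identical(idx, seq_along(labs)))
      stop_mfc("partition must assign every region exactly once",
               class = "mfc_partition_error")
    stats::setNames(as.character(p), labs)
  } else {
    p <- stats::setNames(as.character(partition), names(partition) %||% labs)
    if (!all(labs %in% names(p)))
      stop_mfc("partition is missing regions: ",
               paste(setdiff(labs, names(p)), collapse = ", "),
               class = "mfc_partition_error")
    p[labs]
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Network-level coupling summaries
#'
#' Arithmetic mean of regional coupling values within each network of a
#' region-to-network partition (such as the seven canonical cortical
#' systems).
#'
#' @param map Named per-region coupling vector (see [regional_coupling()]).
#' @param partition Either a data frame with columns `region_index` and
#'   `network`, or a named character vector mapping region label to network.
#' @return Named numeric vector of per-network means.
#' @export
network_coupling <- function(map, partition) {
  labs <- names(map) %||% region_labels(length(map))
  p <- as_partition(partition, labs)
  if (anyNA(p)) stop_mfc("partition contains unassigned regions",
                         class = "mfc_partition_error")
  means <- tapply(as.numeric(map), p, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out[unique(p)]
}

#' Cohort-mean regional coupling map
#'
#' Elementwise mean of per-subject regional coupling maps.
#'
#' @param maps List of named coupling vectors, or a subjects-by-regions
#'   matrix.
#' @return Named numeric vector (mean map).
#' @export
cohort_mean_map <- function(maps) {
  if (is.matrix(maps)) return(colMeans(maps))
  if (!is.list(maps) || !length(maps)) stop_mfc("need a non-empty collection of maps")
  labs <- names(maps[[1]])
  for (m in maps) {
    if (length(m) != length(maps[[1]]) ||
        (!is.null(labs) && !identical(names(m), labs)))
      stop_mfc("all coupling maps must share the same regions")
  }
  colMeans(do.call(rbind, maps))
}
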