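#' @keywords internal
#' @useDynLib mfcoupling, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Shared validation helpers and seed handling.

stop_mfc <- function(..., class = "mfc_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before. All stochastic operations in the
#' package route their randomness through this helper so that a single seed
#' determines every draw.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is_count(seed, min = 0L)) stop_mfc("seed must be a single non-negative integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Region labels are fixed-width so that lexicographic and numeric order agree.
region_labels <- function(n) sprintf("R%03d", seq_len(n))

check_square_labeled <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop_mfc(what, " must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop_mfc(what, " must be square")
  if (anyNA(m)) stop_mfc(what, " contains missing values")
  invisible(m)
}

check_symmetric <- function(m, tol = 1e-9, what = "matrix") {
  check_square_labeled(m, what)
  if (max(abs(m - t(m))) > tol)
    stop_mfc(what, " is not symmetric (tolerance ", format(tol), ")")
  invisible(m)
}

check_aligned <- function(a, b, what_a = "first matrix", what_b = "second matrix") {
  if (nrow(a) != nrow(b)) stop_mfc(what_a, " and ", what_b, " have different sizes")
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop_mfc("region labels of ", what_a, " and ", what_b, " do not match")
  invisible(TRUE)
}
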