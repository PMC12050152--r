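## The inferential battery: rank tests, FDR control, covariate adjustment,
## partial correlation, distribution comparison, and the summary-statistic
## tests used for cohort demographics tables.

#' Residualize values on a covariate design
#'
#' Least-squares residuals of `y` on an intercept plus the given covariates.
#' The returned residuals are orthogonal to every covariate column.
#'
#' @param y Numeric response vector.
#' @param covariates Numeric matrix or data frame of covariates (may be
#'   `NULL` or zero-column, in which case `y - mean(y)` is returned). Factor
#'   and character columns are expanded to dummy variables.
#' @return Residual vector of the same length as `y`.
#' @export
residualize <- function(y, covariates = NULL) {
  if (!is.numeric(y)) stop_mfc("y must be numeric")
  if (is.null(covariates) || NCOL(covariates) == 0L) return(y - mean(y))
  X <- design_matrix(covariates)
  if (nrow(X) != length(y)) stop_mfc("covariates and y differ in length")
  X1 <- cbind(`(intercept)` = 1, X)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    drop_cols <- colnames(X1)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X1))]]
    stop_mfc("rank-deficient covariate design; collinear columns: ",
             paste(drop_cols, collapse = ", "), class = "mfc_design_error")
  }
  as.numeric(qr.resid(qr_x, y))
}

## Expand a covariate table to a numeric matrix (factors -> dummies).
design_matrix <- function(covariates) {
  if (is.matrix(covariates) && is.numeric(covariates)) {
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    return(covariates)
  }
  df <- as.data.frame(covariates, stringsAsFactors = TRUE)
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Mann-Whitney U test (normal approximation)
#'
#' Rank-sum test for a difference in location between two samples. Uses
#' midranks for ties, the tie-corrected variance, and a continuity
#' correction; the two-sided p-value comes from the normal approximation.
#' `U` counts, over all cross-pairs, how often an `x` value exceeds a `y`
#' value (ties counting one half).
#'
#' @param x,y Numeric samples.
#' @return List with elements `U`, `z` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_mfc("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) return(list(U = U, z = 0, p = 1))
  dev <- U - mu
  z <- if (dev == 0) 0 else (dev - sign(dev) * 0.5) / sqrt(v)
  list(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_{j >= i} p_(j) * m / j`
#' over the sorted p-values, capped at 1, returned in the original order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop_mfc("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after projecting
#' out an intercept and the columns of `Z`; the p-value uses the t
#' distribution with `n - ncol(Z) - 2` degrees of freedom. With empty `Z`
#' this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param Z Optional covariate matrix / data frame.
#' @return List with `r`, `df` and `p`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  if (length(x) != length(y)) stop_mfc("x and y must have equal length")
  k <- if (is.null(Z)) 0L else ncol(design_matrix(Z))
  n <- length(x)
  if (n <= k + 2L) stop_mfc("need more observations than covariates + 2")
  rx <- residualize(x, Z)
  ry <- residualize(y, Z)
  if (stats::sd(rx) <= 1e-8 * (stats::sd(x) + .Machine$double.eps) ||
      stats::sd(ry) <= 1e-8 * (stats::sd(y) + .Machine$double.eps))
    stop_mfc("degenerate residuals: correlation undefined",
             class = "mfc_degenerate_error")
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between the two empirical cumulative distribution
#' functions with the asymptotic two-sided p-value.
#'
#' @param a,b Numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop_mfc("both samples must be non-empty")
  w <- sort(unique(c(a, b)))
  Fa <- vapply(w, function(t) mean(a <= t), 0)
  Fb <- vapply(w, function(t) mean(b <= t), 0)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- sqrt(n_eff) * D
  if (lambda == 0) return(list(D = 0, p = 1))
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(1, max(0, p)))
}

#' Two-sample t statistic from summary statistics
#'
#' Computes the two-tailed two-sample t-test from group means, standard
#' deviations and sizes, as used for demographic comparisons reported in
#' summary tables. The unequal-variance (Welch) form is the default; the
#' pooled-variance form is available via `var_equal = TRUE`.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param var_equal Use the pooled-variance form.
#' @return List with `t`, `df` and `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop_mfc("standard deviations must be positive")
  if (!is_count(n1, 2L) || !is_count(n2, 2L)) stop_mfc("group sizes must be integers >= 2")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Chi-square statistic without continuity correction for the table
#' `rbind(c(a, b), c(c, d))`, as used for sex-by-group comparisons.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return List with `chi2`, `df` (= 1) and `p`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) stop_mfc("counts must be non-negative")
  n <- sum(cells)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop_mfc("zero margin in 2x2 table")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Total score range of a 17-item symptom scale
#'
#' Range of the total score implied by per-item maxima of the 17-item
#' depression rating scale (nine items scored 0-4 and eight scored 0-2,
#' giving 0-52).
#'
#' @param item_maxima Vector of 17 non-negative per-item maximum scores.
#' @return `c(min_total, max_total)`.
#' @examples
#' hamd_total_range()  # c(0, 52)
#' @export
hamd_total_range <- function(item_maxima = c(rep(4, 9), rep(2, 8))) {
  if (length(item_maxima) != 17L)
    stop_mfc("expected 17 item maxima, got ", length(item_maxima))
  if (any(item_maxima < 0) || anyNA(item_maxima))
    stop_mfc("item maxima must be non-negative")
  c(0, sum(item_maxima))
}
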