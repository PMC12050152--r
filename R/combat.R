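## Empirical-Bayes location/scale harmonization of multi-site features
## ("ComBat"): per-feature standardization that preserves protected covariate
## effects, normal / inverse-gamma shrinkage of per-site location and scale
## parameters toward site-level priors, removal of the shrunken site effects,
## and restoration of the covariate structure.
##
## Per-site scale estimates use the 1/n (maximum-likelihood) convention, the
## same convention as the pooled variance; this makes a single-site call an
## exact no-op up to floating point.

## Iterative solution of the EB posterior for one batch.
eb_site_solve <- function(z_batch, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                          conv = 1e-6, max_iter = 200L) {
  n_b <- ncol(z_batch)
  g_old <- g_hat
  d_old <- d_hat
  for (i in seq_len(max_iter)) {
    g_new <- (n_b * t2 * g_hat + d_old * g_bar) / (n_b * t2 + d_old)
    sum2 <- rowSums((z_batch - g_new)^2)
    d_new <- (b_prior + 0.5 * sum2) / (n_b / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Empirical-Bayes site harmonization of feature matrices
#'
#' Removes additive and multiplicative site (batch) effects from a
#' subjects-by-features matrix while preserving the effects of protected
#' covariates, by the parametric empirical-Bayes location/scale model. Site
#' location and scale parameters are estimated per feature, shrunk toward
#' site-level normal / inverse-gamma priors, and removed; covariate effects
#' are fit jointly and restored unchanged.
#'
#' When the scale estimates within a site are (numerically) constant across
#' features the scale prior is degenerate and no shrinkage is applied to
#' them; in particular a single-site input is returned unchanged.
#'
#' @param features Numeric subjects x features matrix.
#' @param site Site label per subject (>= 2 subjects per site).
#' @param covariates Optional protected covariate matrix / data frame
#'   (for example group plus nuisance covariates).
#' @return Harmonized matrix with the dimensions and dimnames of `features`.
#' @export
combat_harmonize <- function(features, site, covariates = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features)) stop_mfc("features must be numeric without NA")
  n <- nrow(features)
  site <- factor(site)
  if (length(site) != n) stop_mfc("site labels must match the number of subjects")
  n_i <- table(site)
  if (any(n_i < 2L))
    stop_mfc("every site needs at least 2 subjects; offending: ",
             paste(names(n_i)[n_i < 2], collapse = ", "))
  if (any(n_i < 10L))
    warning("sites with fewer than 10 subjects: ",
            paste(names(n_i)[n_i < 10], collapse = ", "))
  B <- nlevels(site)

  X <- t(features)  # p x n
  p <- nrow(X)
  batch_design <- vapply(levels(site), function(l) as.numeric(site == l),
                         numeric(n))
  mod <- if (is.null(covariates) || NCOL(covariates) == 0L) NULL else design_matrix(covariates)
  design <- cbind(batch_design, mod)
  if (qr(design)$rank < ncol(design))
    stop_mfc("rank-deficient design (confounded site and covariates?)",
             class = "mfc_design_error")

  beta <- solve(crossprod(design), crossprod(design, t(X)))  # q x p
  grand_mean <- as.numeric(crossprod(as.numeric(n_i) / n, beta[seq_len(B), , drop = FALSE]))
  resid <- t(X) - design %*% beta
  var_pooled <- colSums(resid^2) / n  # ML convention, per feature
  var_pooled <- pmax(var_pooled, .Machine$double.eps)

  stand_mean <- matrix(grand_mean, p, n)
  if (!is.null(mod))
    stand_mean <- stand_mean + t(mod %*% beta[-seq_len(B), , drop = FALSE])
  Z <- (X - stand_mean) / sqrt(var_pooled)

  Z_adj <- Z
  for (b in levels(site)) {
    idx <- which(site == b)
    zb <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- rowSums((zb - g_hat)^2) / length(idx)  # ML variance within site
    d_hat <- pmax(d_hat, 1e-12)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m_d <- mean(d_hat)
    s2_d <- stats::var(d_hat)
    if (p < 2L || !is.finite(t2)) t2 <- 0
    if (p < 2L || !is.finite(s2_d)) s2_d <- 0
    if (t2 < 1e-12 && s2_d < 1e-12) {
      ## degenerate priors (e.g. a single feature or single site): no shrinkage
      g_star <- g_hat
      d_star <- d_hat
    } else if (s2_d < 1e-12) {
      sol <- eb_site_solve(zb, g_hat, d_hat, g_bar, max(t2, 1e-12),
                           a_prior = 2, b_prior = m_d)  # weak scale prior
      g_star <- sol$gamma_star
      d_star <- d_hat
    } else {
      a_prior <- (2 * s2_d + m_d^2) / s2_d
      b_prior <- (m_d * s2_d + m_d^3) / s2_d
      sol <- eb_site_solve(zb, g_hat, d_hat, g_bar, max(t2, 1e-12), a_prior, b_prior)
      g_star <- sol$gamma_star
      d_star <- sol$delta_star
    }
    Z_adj[, idx] <- (zb - g_star) / sqrt(pmax(d_star, 1e-12))
  }

  out <- sqrt(var_pooled) * Z_adj + stand_mean
  out <- t(out)
  dimnames(out) <- dimnames(features)
  out
}
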