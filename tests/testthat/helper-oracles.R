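# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration, explicit rank arithmetic, and
# closed-form Gaussian divergences.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- apply(idx, 2L, u_of)
  mu <- length(x) * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Spearman by explicit midranks + Pearson on ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-pass covariance -> correlation oracle.
brute_cor <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# Gaussian symmetric-KLD similarity, written out independently of the
# package's vectorized version.
oracle_gaussian_kls <- function(m1, s1, m2, s2) {
  d <- (s1^2 + (m1 - m2)^2) / (2 * s2^2) + (s2^2 + (m1 - m2)^2) / (2 * s1^2) - 1
  exp(-d)
}

# Construct n x k data whose sample correlation matrix is exactly R:
# orthonormalize random centered columns, then multiply by chol(R).
exact_cor_data <- function(n, R_target, seed = 1) {
  set.seed(seed)
  k <- nrow(R_target)
  repeat {
    X <- matrix(rnorm(n * k), n, k)
    X <- scale(X, center = TRUE, scale = FALSE)
    q <- qr.Q(qr(X))
    if (abs(max(crossprod(q) - diag(k))) < 1e-10) break
  }
  q %*% chol(R_target)
}

# Small deterministic voxel-sample fixture: Gaussian regions.
make_regions <- function(mu, sigma, n, seed = 1) {
  set.seed(seed)
  samp <- lapply(seq_along(mu), function(i) rnorm(n, mu[i], sigma[i]))
  names(samp) <- sprintf("R%03d", seq_along(mu))
  samp
}

# Random centroids on the unit sphere, split into hemispheres.
make_centroids <- function(R, seed = 1) {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * R), R, 3)
  xyz <- xyz / sqrt(rowSums(xyz^2))
  hemi <- rep(c("L", "R"), length.out = R)
  xyz[, 1] <- abs(xyz[, 1]) * ifelse(hemi == "L", -1, 1)
  data.frame(region_index = seq_len(R), hemisphere = hemi,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
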