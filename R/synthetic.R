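## Synthetic cohorts with analytically known ground truth. Regional
## gray-matter values are Gaussian (so pairwise similarities have a closed
## form), functional covariance tracks the morphological similarity with a
## planted per-region fidelity, and site, group, and symptom effects are
## injected where configured.

YEO7 <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")

#' Closed-form similarity between two Gaussian distributions
#'
#' The similarity `exp(-D)` where `D` is the symmetric (summed) Gaussian
#' Kullback-Leibler divergence
#' `D = (s1^2 + d^2) / (2 s2^2) + (s2^2 + d^2) / (2 s1^2) - 1`
#' with `d = mu1 - mu2`. For equal scales this reduces to `exp(-d^2 / s^2)`.
#' Serves as the analytic oracle for the KDE-based pipeline similarity on
#' Gaussian-generated regions.
#'
#' @param mu1,mu2 Locations.
#' @param sigma1,sigma2 Strictly positive scales.
#' @return Similarity in `(0, 1]`; vectorized over its arguments.
#' @examples
#' gaussian_kls(0, 1, 1, 1)  # exp(-1)
#' gaussian_kls(0, 1, 0, 2)  # exp(-1.125)
#' @export
gaussian_kls <- function(mu1, sigma1, mu2, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) stop_mfc("scales must be strictly positive")
  d2 <- (mu1 - mu2)^2
  D <- (sigma1^2 + d2) / (2 * sigma2^2) + (sigma2^2 + d2) / (2 * sigma1^2) - 1
  exp(-D)
}

#' Configuration of a synthetic cohort
#'
#' Collects and validates the generative parameters of [simulate_cohort()].
#' Defaults describe a plausible resting-state cohort: regional gray-matter
#' value distributions with means spread over a morphological gradient (in
#' modulated gray-matter volume units), a planted coupling-fidelity gradient
#' across regions, a handful of acquisition sites with small additive batch
#' shifts, a case-control contrast confined to designated networks, and
#' symptom scores on the 17-item depression scale (range 0-52) linked to the
#' planted coupling of one network.
#'
#' @param n_regions Number of cortical regions (default 96).
#' @param n_subjects_per_group Subjects per group (cases = controls).
#' @param n_voxels_per_region Gray-matter values per region (>= 2).
#' @param timeseries_length Number of volumes per functional run.
#' @param region_mu,region_sigma Per-region location and scale of the
#'   Gaussian gray-matter value distribution (recycled if scalar).
#' @param coupling_fidelity Per-region fidelity `gamma` in `[0, 1]` with
#'   which functional covariance tracks morphological similarity.
#' @param group_effect Additive increment to `gamma` for affected regions in
#'   the case group; `gamma + group_effect` must stay in `[0, 1]`.
#' @param affected_networks Network labels receiving the group effect.
#' @param n_sites Number of acquisition sites.
#' @param site_shift,site_scale Per-site additive / multiplicative batch
#'   effects applied to the coupling-fidelity parameters.
#' @param symptom_link Slope tying case symptom scores to subject-level
#'   planted coupling in the first affected network.
#' @param mu_jitter Between-subject standard deviation of regional locations.
#' @param gamma_jitter Between-subject standard deviation of the fidelities.
#' @param fc_strength Scale of off-diagonal functional correlations.
#' @return A validated list of class `mfc_cohort_config`.
#' @export
cohort_config <- function(n_regions = 96L,
                          n_subjects_per_group = 20L,
                          n_voxels_per_region = 5000L,
                          timeseries_length = 200L,
                          region_mu = NULL,
                          region_sigma = 0.15,
                          coupling_fidelity = NULL,
                          group_effect = 0.1,
                          affected_networks = c("VIS", "SMN", "DAN"),
                          n_sites = 4L,
                          site_shift = NULL,
                          site_scale = NULL,
                          symptom_link = 40,
                          mu_jitter = 0.005,
                          gamma_jitter = 0.02,
                          fc_strength = 0.35) {
  if (!is_count(n_regions, 2L)) stop_mfc("n_regions must be an integer >= 2")
  if (!is_count(n_subjects_per_group, 1L)) stop_mfc("n_subjects_per_group must be a positive integer")
  if (!is_count(n_voxels_per_region, 2L)) stop_mfc("n_voxels_per_region must be an integer >= 2")
  if (!is_count(timeseries_length, 3L)) stop_mfc("timeseries_length must be an integer >= 3")
  if (!is_count(n_sites, 1L)) stop_mfc("n_sites must be a positive integer")
  if (is.null(region_mu)) region_mu <- seq(0.30, 0.80, length.out = n_regions)
  region_mu <- rep_len(region_mu, n_regions)
  region_sigma <- rep_len(region_sigma, n_regions)
  if (any(region_sigma <= 0)) stop_mfc("region_sigma must be strictly positive")
  if (is.null(coupling_fidelity)) coupling_fidelity <- seq(0.15, 0.85, length.out = n_regions)
  gamma <- rep_len(coupling_fidelity, n_regions)
  if (any(gamma < 0 | gamma > 1)) stop_mfc("coupling_fidelity must lie in [0, 1]")
  if (length(group_effect) != 1L || !is.finite(group_effect))
    stop_mfc("group_effect must be a single number")
  if (any(gamma + group_effect < 0 | gamma + group_effect > 1))
    stop_mfc("coupling_fidelity + group_effect leaves [0, 1]: infeasible configuration",
             class = "mfc_config_error")
  if (!all(affected_networks %in% YEO7))
    stop_mfc("affected_networks must be a subset of: ", paste(YEO7, collapse = ", "))
  if (is.null(site_shift)) {
    site_shift <- if (n_sites == 1L) 0 else seq(-0.04, 0.04, length.out = n_sites)
  }
  site_shift <- rep_len(site_shift, n_sites)
  if (is.null(site_scale)) site_scale <- rep(1, n_sites)
  site_scale <- rep_len(site_scale, n_sites)
  if (any(site_scale <= 0)) stop_mfc("site_scale must be strictly positive")
  if (mu_jitter < 0 || gamma_jitter < 0) stop_mfc("jitter values must be non-negative")
  if (fc_strength <= 0 || fc_strength > 0.9) stop_mfc("fc_strength must be in (0, 0.9]")
  structure(list(
    n_regions = as.integer(n_regions),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_voxels_per_region = as.integer(n_voxels_per_region),
    timeseries_length = as.integer(timeseries_length),
    region_mu = region_mu, region_sigma = region_sigma,
    coupling_fidelity = gamma, group_effect = group_effect,
    affected_networks = affected_networks,
    n_sites = as.integer(n_sites), site_shift = site_shift, site_scale = site_scale,
    symptom_link = symptom_link, mu_jitter = mu_jitter,
    gamma_jitter = gamma_jitter, fc_strength = fc_strength
  ), class = "mfc_cohort_config")
}

#' Nearest valid correlation matrix by eigenvalue clipping
#'
#' Repairs a symmetric matrix to a positive semidefinite matrix with unit
#' diagonal by alternately clipping negative eigenvalues and rescaling the
#' diagonal, iterated to tolerance `1e-8` (at most 100 iterations). Inputs
#' that are already valid correlation matrices are returned unchanged.
#'
#' @param m Symmetric numeric matrix.
#' @return A valid correlation matrix of the same dimension.
#' @export
nearest_correlation <- function(m) {
  check_symmetric(m, tol = 1e-8, what = "input")
  x <- (m + t(m)) / 2
  for (k in seq_len(100L)) {
    e <- eigen(x, symmetric = TRUE)
    if (min(e$values) >= -1e-8 && max(abs(diag(x) - 1)) <= 1e-8) break
    v <- pmax(e$values, 1e-8)
    x <- e$vectors %*% (v * t(e$vectors))
    d <- 1 / sqrt(pmax(diag(x), .Machine$double.eps))
    x <- x * tcrossprod(d)
    x <- (x + t(x)) / 2
  }
  diag(x) <- 1
  dimnames(x) <- dimnames(m)
  x
}

#' Simulate regional time series from a target covariance
#'
#' Draws `n_volumes` independent zero-mean multivariate normal rows with the
#' given target correlation structure. A target that is not positive
#' semidefinite is first repaired with [nearest_correlation()].
#'
#' @param cov_target Symmetric matrix with unit diagonal.
#' @param n_volumes Number of rows (time points).
#' @param seed Optional integer seed.
#' @return `n_volumes` x `nrow(cov_target)` numeric matrix.
#' @export
simulate_timeseries <- function(cov_target, n_volumes, seed = NULL) {
  check_symmetric(cov_target, tol = 1e-8, what = "cov_target")
  if (max(abs(diag(cov_target) - 1)) > 1e-6)
    stop_mfc("cov_target must have unit diagonal")
  if (!is_count(n_volumes, 2L)) stop_mfc("n_volumes must be an integer >= 2")
  C <- nearest_correlation(cov_target)
  L <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-8, nrow(C))))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_volumes * nrow(C)), n_volumes, nrow(C))
    ts <- z %*% L
    colnames(ts) <- colnames(cov_target)
    ts
  })
}

## Fixed signal correlation structure: a monotone (normal-scores) transform
## of the ground-truth similarity profiles, symmetrized, scaled to realistic
## functional-connectivity magnitude and repaired once. Computed per cohort.
signal_fc_structure <- function(s_true, fc_strength) {
  R <- nrow(s_true)
  zs <- apply(s_true, 2L, function(col) stats::qnorm(rank(col) / (R + 1)))
  zs <- scale(zs)
  a <- fc_strength * (zs + t(zs)) / 2
  a <- pmin(pmax(a, -0.95), 0.95)
  diag(a) <- 1
  nearest_correlation(a)
}

## Per-subject target correlation: entry (i, j) blends the fixed signal
## structure with a per-subject random (positive-semidefinite, factor-model)
## noise correlation at the pairwise-average fidelity (gamma_i + gamma_j)/2.
## Region r's column therefore tracks the morphological similarity profile
## the more faithfully the larger gamma_r, and the blend of two valid
## correlation matrices needs only a mild final repair. (A literal
## column-by-column mix followed by symmetrization and eigenvalue repair
## distorts the planted gradient, because the repair acts most strongly on
## the noise-dominated columns.)
subject_fc_target <- function(sig, gamma, n_factors = 8L) {
  R <- nrow(sig)
  G <- matrix(stats::rnorm(R * n_factors), R, n_factors)
  noise <- tcrossprod(G) + diag(0.5, R)
  d <- 1 / sqrt(diag(noise))
  noise <- noise * tcrossprod(d)
  w <- outer(gamma, gamma, function(a, b) (a + b) / 2)
  a <- w * sig + (1 - w) * noise
  diag(a) <- 1
  nearest_correlation(a)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a two-group, multi-site cohort: per-subject voxel-level gray-matter
#' values (Gaussian per region, with a small between-subject jitter of the
#' regional means), per-subject regional time series whose covariance tracks
#' the ground-truth similarity matrix at the planted per-region fidelity
#' (plus group and site effects), covariates matched to a typical depression
#' consortium cohort, and symptom scores linked to the planted coupling of
#' the first affected network.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `mfc_cohort`: lists `voxels` (one
#'   [voxel_samples()] per subject) and `timeseries` (T x R matrices), the
#'   covariate data frame `cohort`, the region-to-network `partition`,
#'   spherical region `centroids`, and ground truth (`s_true`, `gamma`,
#'   per-subject realized parameters).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  if (!inherits(config, "mfc_cohort_config")) stop_mfc("config must be a cohort_config()")
  R <- config$n_regions
  npg <- config$n_subjects_per_group
  n <- 2L * npg
  labs <- region_labels(R)

  s_true <- outer(seq_len(R), seq_len(R), function(i, j)
    gaussian_kls(config$region_mu[i], config$region_sigma[i],
                 config$region_mu[j], config$region_sigma[j]))
  dimnames(s_true) <- list(labs, labs)
  sig_fc <- signal_fc_structure(s_true, config$fc_strength)

  partition <- data.frame(
    region_index = seq_len(R),
    network = YEO7[ceiling(seq_len(R) / R * 7)],
    stringsAsFactors = FALSE
  )
  affected_regions <- partition$region_index[partition$network %in% config$affected_networks]
  symptom_regions <- partition$region_index[partition$network == config$affected_networks[1]]
  if (!length(symptom_regions)) symptom_regions <- seq_len(R)

  with_seed(seed, {
    ## region centroids on the unit sphere, split into hemispheres
    hemi <- rep(c("L", "R"), length.out = R)
    cxyz <- matrix(stats::rnorm(3 * R), R, 3)
    cxyz <- cxyz / sqrt(rowSums(cxyz^2))
    cxyz[, 1] <- abs(cxyz[, 1]) * ifelse(hemi == "L", -1, 1)
    centroids <- data.frame(region_index = seq_len(R), hemisphere = hemi,
                            x = cxyz[, 1], y = cxyz[, 2], z = cxyz[, 3],
                            stringsAsFactors = FALSE)

    subject_id <- sprintf("S%04d", seq_len(n))
    group <- rep(c("case", "control"), each = npg)
    site <- rep_len(seq_len(config$n_sites), n)  # deterministic round robin
    age <- pmin(pmax(stats::rnorm(n, 35.8, 12.4), 18), 65)
    sex <- ifelse(stats::runif(n) < 0.62, "female", "male")
    education <- pmin(pmax(stats::rnorm(n, 12.5, 3.4), 3), 22)
    mean_fd <- pmin(pmax(abs(stats::rnorm(n, 0.13, 0.08)), 0.02), 0.2)

    gamma_subj <- matrix(NA_real_, n, R, dimnames = list(subject_id, labs))
    mu_subj <- matrix(NA_real_, n, R, dimnames = list(subject_id, labs))
    voxels <- vector("list", n)
    timeseries <- vector("list", n)
    names(voxels) <- names(timeseries) <- subject_id

    for (s in seq_len(n)) {
      mu_s <- config$region_mu + stats::rnorm(R, 0, config$mu_jitter)
      mu_subj[s, ] <- mu_s
      samp <- lapply(seq_len(R), function(r)
        stats::rnorm(config$n_voxels_per_region, mu_s[r], config$region_sigma[r]))
      names(samp) <- labs
      voxels[[s]] <- voxel_samples(subject_id[s], samp)

      g <- config$coupling_fidelity * config$site_scale[site[s]] +
        config$site_shift[site[s]]
      if (group[s] == "case" && length(affected_regions))
        g[affected_regions] <- g[affected_regions] + config$group_effect
      g <- g + stats::rnorm(R, 0, config$gamma_jitter)
      g <- pmin(pmax(g, 0), 1)
      gamma_subj[s, ] <- g

      C <- subject_fc_target(sig_fc, g)
      L <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-8, R)))
      z <- matrix(stats::rnorm(config$timeseries_length * R),
                  config$timeseries_length, R)
      ts <- z %*% L
      colnames(ts) <- labs
      timeseries[[s]] <- ts
    }

    ## symptom scores: cases only, tied to planted coupling in the first
    ## affected network, clipped to the 17-item scale range [0, 52]
    gbar <- rowMeans(gamma_subj[, symptom_regions, drop = FALSE])
    symptom <- rep(NA_real_, n)
    is_case <- group == "case"
    symptom[is_case] <- 22 + config$symptom_link * (gbar[is_case] - mean(gbar[is_case])) +
      stats::rnorm(sum(is_case), 0, 5)
    symptom[is_case] <- round(pmin(pmax(symptom[is_case], 0), 52), 1)

    cohort <- data.frame(subject_id = subject_id, group = group,
                         site = paste0("site", site), age = age, sex = sex,
                         education = education, mean_fd = mean_fd,
                         symptom_score = symptom, stringsAsFactors = FALSE)

    structure(list(
      config = config, seed = seed,
      voxels = voxels, timeseries = timeseries, cohort = cohort,
      partition = partition, centroids = centroids,
      s_true = s_true, gamma = config$coupling_fidelity,
      mu_subject = mu_subj, gamma_subject = gamma_subj
    ), class = "mfc_cohort")
  })
}

#' @export
print.mfc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "subjects (",
      sum(x$cohort$group == "case"), "cases /",
      sum(x$cohort$group == "control"), "controls ),",
      x$config$n_regions, "regions,", x$config$n_sites, "sites\n")
  cat("  voxels per region:", x$config$n_voxels_per_region,
      "; volumes:", x$config$timeseries_length, "; seed:", x$seed, "\n")
  invisible(x)
}
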