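test_that("gaussian_kls reproduces closed-form values and validates scales", {
  expect_equal(gaussian_kls(0, 1, 0, 1), 1)
  expect_equal(gaussian_kls(0, 1, 1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(gaussian_kls(0, 1, 0, 2), exp(-1.125), tolerance = 1e-12)
  # equal scales reduce to exp(-dmu^2 / sigma^2)
  expect_equal(gaussian_kls(0.3, 0.15, 0.45, 0.15), exp(-(0.15 / 0.15)^2),
               tolerance = 1e-12)
  expect_identical(gaussian_kls(1, 2, 3, 4), gaussian_kls(3, 4, 1, 2))
  expect_error(gaussian_kls(0, 0, 1, 1), "positive")
  expect_error(gaussian_kls(0, 1, 1, -1), "positive")
})

test_that("nearest_correlation fixes non-PSD matrices and leaves valid ones alone", {
  expect_equal(nearest_correlation(diag(3)), diag(3))
  set.seed(1)
  C <- cov2cor(crossprod(matrix(rnorm(64), 8, 8)) + diag(0.5, 8))
  expect_equal(nearest_correlation(C), C, tolerance = 1e-10)
  # classic infeasible pattern: r12 = r13 = 0.9, r23 = -0.9
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  fixed <- nearest_correlation(bad)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-8)
  expect_equal(diag(fixed), rep(1, 3))
  expect_identical(fixed, t(fixed))
  expect_error(nearest_correlation(matrix(1:9, 3, 3)), "symmetric")
})

test_that("simulate_timeseries approaches its target correlation", {
  idv <- diag(6)
  ts <- simulate_timeseries(idv, 10000, seed = 2)
  emp <- cor(ts)
  expect_lt(mean(abs(emp[upper.tri(emp)])), 0.05)
  tgt <- diag(2); tgt[1, 2] <- tgt[2, 1] <- 0.9
  ts2 <- simulate_timeseries(tgt, 10000, seed = 3)
  expect_lt(abs(cor(ts2)[1, 2] - 0.9), 0.05)
  expect_identical(simulate_timeseries(tgt, 50, seed = 9),
                   simulate_timeseries(tgt, 50, seed = 9))
  expect_error(simulate_timeseries(matrix(1:4 / 4, 2, 2), 10), "symmetric")
})

test_that("cohort_config enforces its invariants", {
  expect_error(cohort_config(coupling_fidelity = 0.95, group_effect = 0.1),
               class = "mfc_config_error")
  expect_error(cohort_config(region_sigma = 0), "positive")
  expect_error(cohort_config(n_voxels_per_region = 1), ">= 2")
  expect_error(cohort_config(affected_networks = "XXX"), "subset")
  cfg <- cohort_config(n_regions = 10)
  expect_s3_class(cfg, "mfc_cohort_config")
  expect_length(cfg$region_mu, 10)
})

test_that("cohort regeneration with one seed is bit-identical", {
  cfg <- cohort_config(n_regions = 6, n_subjects_per_group = 3,
                       n_voxels_per_region = 50, timeseries_length = 30)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$voxels, b$voxels)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$cohort, b$cohort)
  c2 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$voxels, c2$voxels))
})

test_that("cohort dimensions, covariates and symptom scores are consistent", {
  cfg <- cohort_config(n_regions = 14, n_subjects_per_group = 8,
                       n_voxels_per_region = 60, timeseries_length = 40)
  ch <- simulate_cohort(cfg, seed = 5)
  expect_length(ch$voxels, 16)
  expect_length(ch$timeseries, 16)
  expect_identical(dim(ch$timeseries[[1]]), c(40L, 14L))
  expect_identical(dim(ch$s_true), c(14L, 14L))
  expect_length(ch$gamma, 14)
  expect_identical(nrow(ch$cohort), 16L)
  cases <- ch$cohort$group == "case"
  expect_true(all(!is.na(ch$cohort$symptom_score[cases])))
  expect_true(all(is.na(ch$cohort$symptom_score[!cases])))
  sc <- ch$cohort$symptom_score[cases]
  expect_true(all(sc >= 0 & sc <= 52))
  expect_true(all(ch$cohort$age >= 18 & ch$cohort$age <= 65))
  expect_true(all(table(ch$cohort$site) >= 2))
  # no group effect planted outside the affected networks
  aff <- ch$partition$network %in% cfg$affected_networks
  unaff <- which(!aff)
  gs <- ch$gamma_subject
  base <- cfg$coupling_fidelity
  # per-subject gamma for unaffected regions deviates only by site + jitter
  dev <- abs(sweep(gs[, unaff, drop = FALSE], 2, base[unaff]))
  expect_lt(max(dev), max(abs(cfg$site_shift)) + 6 * cfg$gamma_jitter)
})

test_that("empirical sample means track region_mu within CLT bounds", {
  cfg <- cohort_config(n_regions = 8, n_subjects_per_group = 2,
                       n_voxels_per_region = 5000, timeseries_length = 10,
                       mu_jitter = 0)
  ch <- simulate_cohort(cfg, seed = 21)
  for (s in seq_along(ch$voxels)) {
    means <- vapply(ch$voxels[[s]]$samples, mean, 0)
    se <- cfg$region_sigma / sqrt(cfg$n_voxels_per_region)
    expect_true(all(abs(means - cfg$region_mu) < 3.9 * se))
  }
})

test_that("zero group effect leaves case and control gamma profiles identical", {
  cfg <- cohort_config(n_regions = 6, n_subjects_per_group = 4,
                       n_voxels_per_region = 40, timeseries_length = 20,
                       group_effect = 0, gamma_jitter = 0, n_sites = 1)
  ch <- simulate_cohort(cfg, seed = 2)
  cases <- ch$cohort$group == "case"
  expect_equal(colMeans(ch$gamma_subject[cases, ]),
               colMeans(ch$gamma_subject[!cases, ]))
  expect_equal(unname(ch$gamma_subject[1, ]), cfg$coupling_fidelity)
})

test_that("KDE pipeline similarities agree with the Gaussian oracle per subject", {
  # oracle evaluated at each subject's realized (jittered) parameters
  cfg <- cohort_config(n_regions = 10, n_subjects_per_group = 1,
                       n_voxels_per_region = 5000, timeseries_length = 10,
                       region_mu = seq(0.3, 0.8, length.out = 10))
  ch <- simulate_cohort(cfg, seed = 31)
  for (s in 1:2) {
    msn <- build_msn(ch$voxels[[s]])
    mu_s <- ch$mu_subject[s, ]
    oracle <- outer(seq_len(10), seq_len(10), function(i, j)
      oracle_gaussian_kls(mu_s[i], cfg$region_sigma[i], mu_s[j], cfg$region_sigma[j]))
    expect_lt(max(abs(msn - oracle)), 0.05)
    expect_gt(cor(msn[upper.tri(msn)], oracle[upper.tri(oracle)],
                  method = "spearman"), 0.95)
  }
})
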