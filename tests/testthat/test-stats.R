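test_that("residualize projects out covariates exactly", {
  set.seed(1)
  age <- rnorm(50, 40, 10)
  # exact linear dependence -> zero residuals
  y <- 2 * age
  expect_lt(max(abs(residualize(y, data.frame(age = age)))), 1e-10)
  # noisy dependence -> orthogonal residuals
  y2 <- 2 * age + rnorm(50)
  r2 <- residualize(y2, data.frame(age = age))
  expect_lt(abs(cor(r2, age)), 1e-10)
  expect_lt(abs(mean(r2)), 1e-12)
  # covariate orthogonal to y: residuals are y - mean(y)
  z <- residualize(y2, NULL)
  expect_equal(z, y2 - mean(y2))
  # collinear design named in the error
  X <- data.frame(a = age, b = 2 * age)
  err <- expect_error(residualize(y2, X), class = "mfc_design_error")
  expect_match(conditionMessage(err), "b")
})

test_that("mann_whitney matches its definition and the exact null at small n", {
  # x = (1,2), y = (3,4): U = 0, exact two-sided p = 1/3
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(exact_mw_p(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  # identical multisets: z = 0, p = 1
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$z, 0)
  expect_equal(mw2$p, 1)
  # agreement with the tie-corrected continuity-corrected reference
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:10, 8, replace = TRUE)
    y <- sample(1:10, 6, replace = TRUE)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    mw3 <- mann_whitney(x, y)
    expect_equal(mw3$U, unname(wt$statistic))
    expect_equal(mw3$p, wt$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation p stays within 0.05 of enumeration at n = 5 vs 5", {
  set.seed(3)
  worst <- 0
  for (i in 1:200) {
    x <- rnorm(5); y <- rnorm(5, runif(1, -2, 2))
    d <- abs(mann_whitney(x, y)$p - exact_mw_p(x, y))
    worst <- max(worst, d)
  }
  expect_lt(worst, 0.05)
})

test_that("bh_fdr reproduces the step-up procedure and is order invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  # q >= p elementwise; permutation invariance
  set.seed(4)
  for (i in 1:10) {
    pp <- runif(20)
    q <- bh_fdr(pp)
    expect_true(all(q >= pp - 1e-15))
    perm <- sample(20)
    expect_equal(bh_fdr(pp[perm])[order(perm)], q, tolerance = 1e-15)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("partial correlation matches the closed-form identity", {
  # all pairwise correlations exactly 0.5 -> partial r = (0.5 - 0.25)/0.75 = 1/3
  Rt <- matrix(0.5, 3, 3); diag(Rt) <- 1
  D <- exact_cor_data(40, Rt, seed = 7)
  pc <- partial_correlation(D[, 1], D[, 2], D[, 3, drop = FALSE])
  expect_equal(pc$r, 1 / 3, tolerance = 1e-10)
  expect_equal(pc$df, 40 - 1 - 2)
  # empty Z -> plain Pearson
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, y)$p, cor.test(x, y)$p.value,
               tolerance = 1e-10)
  # x identical to the covariate -> degenerate residuals
  expect_error(partial_correlation(x, y, data.frame(z = x)),
               class = "mfc_degenerate_error")
  # general agreement with the 3-variable recursion formula
  for (i in 1:10) {
    a <- rnorm(25); b <- rnorm(25); cc <- rnorm(25)
    rxy <- cor(a, b); rxz <- cor(a, cc); ryz <- cor(b, cc)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(partial_correlation(a, b, data.frame(z = cc))$r, closed,
                 tolerance = 1e-10)
  }
})

test_that("ks_two_sample computes the ECDF sup-distance", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:3, c(10, 11))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3,
               tolerance = 1e-12)
  set.seed(6)
  a <- rnorm(40); b <- rnorm(35, 0.8)
  ref <- suppressWarnings(ks.test(a, b, exact = FALSE))
  got <- ks_two_sample(a, b)
  expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("summary-statistic t test matches hand formula and table values", {
  expect_equal(t_from_summary(1, 1, 10, 1, 1, 10)$t, 0)
  # SE = sqrt(2/100) -> t = -7.0711
  expect_equal(t_from_summary(0, 1, 100, 1, 1, 100)$t, -1 / sqrt(0.02),
               tolerance = 1e-10)
  # pooled and Welch agree for equal variances/sizes
  a <- t_from_summary(0, 1, 50, 0.4, 1, 50)
  b <- t_from_summary(0, 1, 50, 0.4, 1, 50, var_equal = TRUE)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_error(t_from_summary(0, 0, 10, 1, 1, 10), "positive")
})

test_that("chi-square for 2x2 tables matches hand computation and chisq.test", {
  expect_equal(chi2_2x2(10, 20, 30, 60)$chi2, 0)
  expect_equal(chi2_2x2(10, 0, 0, 10)$chi2, 20)
  ref <- chisq.test(matrix(c(34, 16, 25, 29), 2, 2, byrow = TRUE), correct = FALSE)
  got <- chi2_2x2(34, 16, 25, 29)
  expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("symptom scale range arithmetic", {
  expect_equal(hamd_total_range(), c(0, 52))
  expect_equal(hamd_total_range(rep(0, 17)), c(0, 0))
  expect_equal(hamd_total_range(rep(1, 17)), c(0, 17))
  expect_error(hamd_total_range(rep(2, 16)), "17")
})
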