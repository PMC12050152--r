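test_that("symmetric KLD and KLS reproduce hand-worked values", {
  # sum_i P log(P/Q) + Q log(Q/P), natural log
  expect_equal(kld_symmetric(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kld_symmetric(c(0.9, 0.1), c(0.1, 0.9)), 1.6 * log(9), tolerance = 1e-12)
  expect_equal(kld_symmetric(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3) + 0.25 * log(0.5) + 0.75 * log(1.5),
               tolerance = 1e-12)
  expect_equal(kls_similarity(c(0.25, 0.75), c(0.25, 0.75)), 1)
  expect_equal(kls_similarity(c(0.5, 0.5), c(0.25, 0.75)), exp(-0.2746531),
               tolerance = 1e-6)
  expect_equal(kls_similarity(c(0.9, 0.1), c(0.1, 0.9)), exp(-1.6 * log(9)),
               tolerance = 1e-12)
  # symmetry is exact
  for (i in 1:20) {
    p <- prop.table(runif(16) + 0.01)
    q <- prop.table(runif(16) + 0.01)
    expect_identical(kls_similarity(p, q), kls_similarity(q, p))
  }
})

test_that("kld_symmetric rejects invalid probability vectors", {
  expect_error(kld_symmetric(c(0.5, 0.5), c(0, 1)), "strictly positive")
  expect_error(kld_symmetric(c(0.5, 0.5), c(0.3, 0.3)), "sum to 1")
  expect_error(kld_symmetric(c(0.5, 0.5), c(0.2, 0.3, 0.5)), "equal length")
})

test_that("kde_density discretizes a normalized pmf with a sane peak and bandwidth", {
  set.seed(42)
  x <- rnorm(10000)
  grid <- seq(min(x) - 0.5, max(x) + 0.5, length.out = 128)
  d <- kde_density(x, grid)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
  expect_true(all(d$pmf > 0))
  # density at the grid point nearest 0 close to the N(0,1) peak
  peak <- d$density[which.min(abs(d$grid))]
  expect_lt(abs(peak - dnorm(0)), 0.02)
  # automatic bandwidth within a factor 1.5 of the AMISE reference rule
  ref <- 1.06 * sd(x) * length(x)^(-1 / 5)
  expect_gt(d$bandwidth, ref / 1.5)
  expect_lt(d$bandwidth, ref * 1.5)
})

test_that("kde_density validates inputs", {
  expect_error(kde_density(numeric(0)), "empty")
  expect_error(kde_density(rep(1, 10)), class = "mfc_degenerate_error")
  expect_error(kde_density(rnorm(100), seq(0, 0.5, length.out = 32)), "cover")
  expect_error(kde_density(rnorm(100), c(-10, -2, 0, 1, 3, 7, 8, 10)), "equally spaced")
})

test_that("compiled ISJ search matches the R-level discrepancy equation", {
  # the R implementation of the fixed-point discrepancy is the reference:
  # the bandwidth returned by the compiled search must be (near) a root
  set.seed(7)
  for (x in list(rnorm(2000), rgamma(2000, 3), c(rnorm(1000), rnorm(1000, 5)))) {
    h <- select_bandwidth(x)
    n_grid <- if (length(x) > 1000) 2^10 else 2^8
    rng <- range(x); span <- rng[2] - rng[1]
    ext <- span * 1.2
    breaks <- seq(rng[1] - span / 10, rng[2] + span / 10, length.out = n_grid + 1)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_grid)
    a <- mfcoupling:::dct1d(counts / length(x))
    a2 <- (a[-1] / 2)^2
    I <- as.numeric(seq_len(n_grid - 1))^2
    Ia2 <- lapply(1:7, function(s) I^s * a2)
    t_star <- (h / ext)^2
    val <- mfcoupling:::isj_discrepancy(t_star, length(unique(x)), I, Ia2)
    expect_lt(abs(val), 1e-5 * t_star + 1e-12)
  }
})

test_that("shared_grid_pmf yields comparable, strictly positive pmfs", {
  set.seed(1)
  x <- rnorm(2000)
  pq <- shared_grid_pmf(x, x)
  expect_equal(pq$p$pmf, pq$q$pmf)
  expect_identical(pq$p$grid, pq$q$grid)
  expect_length(pq$p$grid, 128L)
  # disjoint supports still give strictly positive floored pmfs, finite KLD
  a <- runif(500, 0, 1); b <- runif(500, 10, 11)
  pq2 <- shared_grid_pmf(a, b)
  expect_true(all(pq2$p$pmf > 0) && all(pq2$q$pmf > 0))
  expect_true(is.finite(kld_symmetric(pq2$p, pq2$q)))
  # well-separated Gaussians approach the closed-form similarity
  set.seed(2)
  g1 <- rnorm(5000); g2 <- rnorm(5000, 3)
  pq3 <- shared_grid_pmf(g1, g2)
  expect_lt(abs(kls_similarity(pq3$p, pq3$q) - exp(-9)), 0.05)
})

test_that("build_msn produces a valid similarity matrix with oracle ordering", {
  samp <- make_regions(c(0, 1, 4), c(1, 1, 1), 5000, seed = 3)
  m <- build_msn(samp)
  expect_equal(diag(m), setNames(rep(1, 3), rownames(m)))
  expect_identical(m, t(m))
  expect_true(all(m > 0 & m <= 1))
  # ordering matches the Gaussian oracle: KLS(1,2) > KLS(2,3) > KLS(1,3)
  expect_gt(m[1, 2], m[2, 3])
  expect_gt(m[2, 3], m[1, 3])
  # byte-identical sample vectors give near-unit similarity
  samp2 <- samp
  samp2[[2]] <- samp2[[1]]
  m2 <- build_msn(samp2)
  expect_gte(m2[1, 2], 0.999)
})

test_that("each pair's similarity depends only on that pair's samples", {
  samp <- make_regions(c(0.3, 0.5, 0.7, 0.9), rep(0.12, 4), 800, seed = 9)
  m1 <- build_msn(samp)
  samp_perturbed <- samp
  samp_perturbed[[4]] <- samp_perturbed[[4]] + 5  # unrelated region moved far away
  m2 <- build_msn(samp_perturbed)
  expect_equal(m1[1:3, 1:3], m2[1:3, 1:3], tolerance = 1e-12)
})

test_that("fast interpolated path agrees with exact per-pair evaluation", {
  samp <- make_regions(seq(0.3, 0.8, length.out = 5), rep(0.15, 5), 2000, seed = 5)
  m_fast <- build_msn(samp)
  m_exact <- build_msn(samp, exact = TRUE)
  expect_lt(max(abs(m_fast - m_exact)), 1e-3)
})

test_that("degenerate regions are rejected with their labels", {
  samp <- make_regions(c(0, 1), c(1, 1), 100, seed = 2)
  samp$R002 <- rep(2, 100)
  err <- expect_error(build_msn(samp), class = "mfc_degenerate_error")
  expect_match(conditionMessage(err), "R002")
})
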