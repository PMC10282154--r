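test_that("Wald ratios follow by/bx with first-order SEs", {
  h <- make_h(bx = c(0.1, -0.1), sx = 0.01, by = c(0.05, 0.05), sy = 0.1)
  r <- wald_ratios(h)
  expect_equal(r$theta, c(0.5, -0.5))
  expect_equal(r$se, c(1, 1))
  expect_equal(r$weight, c(1, 1))

  h0 <- make_h(bx = c(0, 0.1), sx = 0.01, by = c(0.05, 0.05), sy = 0.1)
  expect_warning(r0 <- wald_ratios(h0), "zero exposure beta")
  expect_equal(nrow(r0), 1L)
  h00 <- make_h(bx = c(0, 0), sx = 0.01, by = c(0.05, 0.05), sy = 0.1)
  expect_error(wald_ratios(h00), "all exposure betas")
})

test_that("IVW reproduces the hand-computed weighted mean and its SEs", {
  h <- make_h(bx = c(0.1, 0.2), sx = 0.01, by = c(0.02, 0.06),
              sy = c(0.01, 0.02))
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, 0.25)
  expect_equal(fit$Q, 0.5)
  # Q/(J-1) = 0.5 < 1, so the multiplicative factor floors at 1
  expect_equal(fit$se, sqrt(1 / 200))
  expect_equal(fit$I2, 0)

  # independent WLS-through-origin oracle on the same data
  o <- oracle_wls(matrix(h$bx), h$by, 1 / h$sy^2)
  expect_equal(fit$estimate, unname(o$beta), tolerance = 1e-12)

  # homogeneous ratios: estimate c, Q = 0, I2 = 0
  hc <- make_h(bx = c(0.1, 0.2, 0.4), sx = 0.01,
               by = c(0.03, 0.06, 0.12), sy = 0.02)
  fitc <- mr_ivw(hc)
  expect_equal(fitc$estimate, 0.3)
  expect_equal(fitc$Q, 0, tolerance = 1e-20)
  expect_equal(fitc$I2, 0)

  # single variant degrades to its Wald ratio
  h1 <- make_h(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.1)
  fit1 <- mr_ivw(h1)
  expect_equal(fit1$estimate, 0.5)
  expect_equal(fit1$se, 1)
  expect_equal(fit1$n_snps, 1L)
})

test_that("IVW heterogeneity inflates the SE multiplicatively", {
  set.seed(1)
  J <- 30
  bx <- abs(rnorm(J, 0, 0.05)) + 0.02
  by <- 0.2 * bx + rnorm(J, 0, 0.05)   # overdispersed relative to sy
  h <- make_h(bx, 0.005, by, 0.01)
  fit <- mr_ivw(h)
  w <- (h$bx / h$sy)^2
  theta <- h$by / h$bx
  est <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - est)^2)
  expect_equal(fit$se, sqrt(1 / sum(w)) * sqrt(Q / (J - 1)), tolerance = 1e-12)
  expect_gt(fit$I2, 50)
})

test_that("Egger recovers exact lines and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3)
  h <- make_h(bx, 0.01, by = 0.01 + 0.2 * bx, sy = 0.02)
  fit <- mr_egger(h)
  expect_equal(fit$estimate, 0.2, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.01, tolerance = 1e-10)
  expect_equal(fit$Q, 0, tolerance = 1e-16)

  # no-pleiotropy limit: exact proportionality gives zero intercept
  h0 <- make_h(bx, 0.01, by = 0.37 * bx, sy = 0.02)
  expect_equal(mr_egger(h0)$egger_intercept, 0, tolerance = 1e-12)

  # random instances equal the normal-equations oracle to 1e-10
  set.seed(7)
  for (rep in 1:5) {
    J <- 8
    bx <- rnorm(J, 0, 0.1)
    by <- rnorm(J, 0.3 * bx, 0.05)
    sy <- runif(J, 0.01, 0.05)
    h <- make_h(bx, 0.01, by, sy)
    fit <- mr_egger(h)
    sgn <- ifelse(bx < 0, -1, 1)
    o <- oracle_wls(cbind(1, bx * sgn), by * sgn, 1 / sy^2)
    expect_equal(fit$estimate, unname(o$beta[2]), tolerance = 1e-10)
    expect_equal(fit$egger_intercept, unname(o$beta[1]), tolerance = 1e-10)
    scale2 <- max(1, o$rss / (J - 2))
    expect_equal(fit$se, sqrt(o$cov[2, 2] * scale2), tolerance = 1e-10)
  }

  expect_error(mr_egger(make_h(c(0.1, 0.2), 0.01, c(0.1, 0.1), 0.02)),
               "at least 3")
  expect_error(mr_egger(make_h(c(0.1, 0.1, -0.1), 0.01, c(0.1, 0.1, 0.1), 0.02)),
               "collinear")
})

test_that("weighted median interpolates cumulative midpoint weights", {
  # equal weights: ordinary median
  h <- make_h(bx = c(1, 1, 1), sx = 0.01, by = c(0.1, 0.2, 0.9), sy = 1)
  fit <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(fit$estimate, 0.2)
  expect_gt(fit$se, 0)

  # hand-interpolated unequal-weight case: weights (1, 1, 6)
  sy <- 1 / sqrt(c(1, 1, 6))
  h2 <- make_h(bx = c(1, 1, 1), sx = 0.001, by = c(0.1, 0.2, 0.4), sy = sy)
  fit2 <- mr_weighted_median(h2, n_boot = 200, seed = 1)
  expect_equal(fit2$estimate, 0.2 + (0.5 - 0.1875) / (0.625 - 0.1875) * 0.2,
               tolerance = 1e-10)

  # identical ratios: estimate c with positive bootstrap SE
  hc <- make_h(bx = c(0.2, 0.3, 0.4), sx = 0.01,
               by = 0.3 * c(0.2, 0.3, 0.4), sy = 0.02)
  fitc <- mr_weighted_median(hc, n_boot = 200, seed = 2)
  expect_equal(fitc$estimate, 0.3)
  expect_gt(fitc$se, 0)

  # random instances match the fine-grid weighted-quantile oracle
  set.seed(21)
  for (rep in 1:3) {
    J <- 9
    bx <- abs(rnorm(J, 0, 0.1)) + 0.05
    by <- rnorm(J, 0.25 * bx, 0.03)
    sy <- runif(J, 0.01, 0.05)
    h <- make_h(bx, 0.001, by, sy)
    fit <- mr_weighted_median(h, n_boot = 50, seed = 3)
    o <- oracle_weighted_median(by / bx, (bx / sy)^2)
    expect_equal(fit$estimate, o, tolerance = 1e-4)
  }

  # estimate always lies within the range of the ratios
  set.seed(31)
  for (rep in 1:10) {
    J <- 7
    bx <- abs(rnorm(J, 0, 0.1)) + 0.05
    by <- rnorm(J, 0, 0.1)
    sy <- runif(J, 0.01, 0.05)
    h <- make_h(bx, 0.001, by, sy)
    est <- mr_weighted_median(h, n_boot = 10, seed = 4)$estimate
    theta <- by / bx
    expect_gte(est, min(theta))
    expect_lte(est, max(theta))
  }
})

test_that("mode-based estimator finds the dominant cluster of ratios", {
  # point mass: every ratio identical
  hc <- make_h(bx = c(0.2, 0.3, 0.4), sx = 0.01,
               by = 0.3 * c(0.2, 0.3, 0.4), sy = 0.02)
  expect_equal(mr_mode(hc, n_boot = 100, seed = 1)$estimate, 0.3)

  # 7 of 10 ratios near 0.2, 3 near 1.0: the mode sits at the majority cluster
  set.seed(13)
  theta <- c(rnorm(7, 0.2, 0.01), rnorm(3, 1.0, 0.01))
  bx <- rep(1, 10)
  h <- make_h(bx, 0.001, by = theta, sy = 0.05)
  fit <- mr_mode(h, n_boot = 100, seed = 2)
  expect_lt(abs(fit$estimate - 0.2), 0.05)

  # grid argmax equals an independent KDE-maximisation oracle
  set.seed(17)
  for (rep in 1:3) {
    J <- 12
    bx <- abs(rnorm(J, 0, 0.1)) + 0.05
    by <- rnorm(J, 0.3 * bx, 0.04)
    sy <- runif(J, 0.01, 0.05)
    h <- make_h(bx, 0.001, by, sy)
    fit <- mr_mode(h, n_boot = 10, seed = 5)
    o <- oracle_mode(by / bx, (bx / sy)^2)
    theta_rng <- diff(range(by / bx))
    expect_lt(abs(fit$estimate - o), theta_rng / 200)  # grid resolution
  }
})

test_that("MVMR fits exact planes and matches the two-regressor WLS oracle", {
  bx1 <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  bx2 <- c(0.05, 0.01, 0.2, 0.3, 0.1)
  d <- tibble::tibble(bx1 = bx1, bx2 = bx2,
                      by = 0.3 * bx1 + 0.5 * bx2, sy = 0.02)
  fit <- mr_mvmr(d)
  expect_equal(fit$estimate, c(0.3, 0.5), tolerance = 1e-10)

  # rank-deficient designs are rejected
  d0 <- tibble::tibble(bx1 = bx1, bx2 = 0, by = 0.3 * bx1, sy = 0.02)
  expect_error(mr_mvmr(d0), "collinear")

  set.seed(23)
  for (rep in 1:5) {
    J <- 10
    bx1 <- rnorm(J, 0, 0.1); bx2 <- rnorm(J, 0, 0.1)
    sy <- runif(J, 0.01, 0.05)
    by <- rnorm(J, 0.3 * bx1 + 0.5 * bx2, sy)
    d <- tibble::tibble(bx1 = bx1, bx2 = bx2, by = by, sy = sy)
    fit <- mr_mvmr(d)
    o <- oracle_wls(cbind(bx1, bx2), by, 1 / sy^2)
    expect_equal(fit$estimate, unname(o$beta), tolerance = 1e-10)
    scale2 <- max(1, o$rss / (J - 2))
    expect_equal(fit$se, unname(sqrt(diag(o$cov) * scale2)), tolerance = 1e-10)
  }
})

test_that("estimators are sign-equivariant and consistent with each other", {
  set.seed(41)
  J <- 12
  bx <- abs(rnorm(J, 0, 0.1)) + 0.05
  by <- rnorm(J, 0.3 * bx, 0.03)
  sy <- runif(J, 0.01, 0.05)
  h_pos <- make_h(bx, 0.001, by, sy)
  h_neg <- make_h(bx, 0.001, -by, sy)
  # closed-form estimators: exact sign equivariance of estimate and SE
  for (f in list(mr_ivw, mr_egger)) {
    p <- f(h_pos); n <- f(h_neg)
    expect_equal(n$estimate, -p$estimate, tolerance = 1e-10)
    expect_equal(n$se, p$se, tolerance = 1e-10)
  }
  # bootstrap-SE estimators: exact point negation; SEs agree in distribution,
  # so compare at Monte-Carlo accuracy
  for (f in list(function(h, s) mr_weighted_median(h, n_boot = 400, seed = s),
                 function(h, s) mr_mode(h, n_boot = 400, seed = s))) {
    p <- f(h_pos, 9); n <- f(h_neg, 9)
    expect_equal(n$estimate, -p$estimate, tolerance = 1e-10)
    expect_equal(n$se, p$se, tolerance = 0.3)
  }

  # IVW with equal weights equals the unweighted mean of ratios
  heq <- make_h(bx = c(0.1, -0.1, 0.1, 0.1), sx = 0.001,
                by = c(0.01, 0.02, 0.03, 0.05), sy = 0.02)
  expect_equal(mr_ivw(heq)$estimate,
               mean(heq$by / heq$bx), tolerance = 1e-12)

  # when the fitted Egger intercept is exactly zero, slope equals IVW
  bx3 <- c(0.1, 0.2, 0.3)
  h3 <- make_h(bx3, 0.001, by = 0.4 * bx3, sy = 0.02)
  expect_equal(mr_egger(h3)$estimate, mr_ivw(h3)$estimate, tolerance = 1e-10)
})

test_that("odds-ratio views exponentiate estimate and bounds", {
  h <- make_h(bx = c(0.1, 0.2), sx = 0.01, by = c(0.02, 0.06),
              sy = c(0.01, 0.02))
  orv <- as_odds_ratios(mr_ivw(h))
  expect_equal(orv$or, exp(orv$estimate))
  expect_true(orv$or_low <= orv$or & orv$or <= orv$or_high)
})
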