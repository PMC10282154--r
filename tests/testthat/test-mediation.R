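test_that("indirect effect follows the product rule with Delta-method SE", {
  ie <- indirect_effect(a = 0.2, se_a = 0.05, b = 0.4, se_b = 0.05)
  expect_equal(ie$nie, 0.08)
  expect_equal(ie$se_nie, sqrt(0.0005))
  expect_equal(ie$nie_or, exp(0.08))

  # numerical-gradient oracle for the same variance
  v <- oracle_delta_var(function(p) p[1] * p[2], c(0.2, 0.4), c(0.05, 0.05))
  expect_equal(ie$se_nie^2, v, tolerance = 1e-6)

  # null path: a = 0 gives NIE 0, OR-scale NIE 1
  ie0 <- indirect_effect(0, 0.05, 0.4, 0.05)
  expect_equal(ie0$nie, 0)
  expect_equal(ie0$nie_or, 1)

  # symmetric in (a, b)
  ie1 <- indirect_effect(0.2, 0.03, 0.4, 0.07)
  ie2 <- indirect_effect(0.4, 0.07, 0.2, 0.03)
  expect_equal(ie1$nie, ie2$nie)
  expect_equal(ie1$se_nie, ie2$se_nie)
})

test_that("proportion mediated divides indirect by total on the log scale", {
  # worked example: white bread -> insomnia -> migraine
  p <- proportion_from_or(te_or = 1.42896, nie_or = 1.049)
  expect_equal(p, 13.4, tolerance = 0.01)

  pm <- proportion_mediated(te = log(1.42896), se_te = 0.1,
                            nie = log(1.049), se_nie = 0.01)
  expect_equal(pm$proportion, p)
  expect_true(pm$ci_low < pm$proportion & pm$proportion < pm$ci_high)

  # ratio Delta variance against the numerical-gradient oracle
  v <- oracle_delta_var(function(x) x[1] / x[2],
                        c(log(1.049), log(1.42896)), c(0.01, 0.1))
  expect_equal((pm$se_proportion / 100)^2, v, tolerance = 1e-6)

  expect_equal(proportion_mediated(0.3, 0.01, 0.3, 0.01)$proportion, 100)
  expect_equal(proportion_mediated(0.3, 0.01, 0, 0.01)$proportion, 0)
  expect_error(proportion_mediated(0, 0.01, 0.1, 0.01), "undefined")
})

test_that("published worked examples are internally consistent on the log scale", {
  tab <- mediation_worked_examples()
  expect_gt(nrow(tab), 15)
  recomputed <- proportion_from_or(tab$te_or, tab$nie_or)
  # every printed proportion re-derives from the printed TE and NIE within
  # what +-0.0005 rounding of the printed NIE propagates to (plus the 0.005
  # rounding of the printed proportion itself)
  rounding_bound <- 100 * (0.0005 / tab$nie_or) / abs(log(tab$te_or)) + 0.005
  expect_true(all(abs(recomputed - tab$proportion_pct) < rounding_bound))
  # most rows agree much more closely than the bound requires
  expect_gte(mean(abs(recomputed - tab$proportion_pct) < 0.1), 0.75)
})

test_that("proportion CI width is monotone in each SE and scale-invariant", {
  base <- proportion_mediated(0.3, 0.02, 0.1, 0.01)
  wider_te <- proportion_mediated(0.3, 0.05, 0.1, 0.01)
  wider_nie <- proportion_mediated(0.3, 0.02, 0.1, 0.03)
  width <- function(x) x$ci_high - x$ci_low
  expect_gte(width(wider_te), width(base))
  expect_gte(width(wider_nie), width(base))

  # rescaling the exposure rescales a and te together; nie/te is unchanged
  k <- 2.5
  p1 <- indirect_effect(0.2, 0.01, 0.4, 0.01)$nie / 0.3
  p2 <- indirect_effect(0.2 * k, 0.01, 0.4, 0.01)$nie / (0.3 * k)
  expect_equal(p1, p2)
})

test_that("the three-step gate admits only fully significant pathways", {
  fit <- function(est, se) tibble::tibble(estimate = est, se = se,
                                          pval = 2 * pnorm(-abs(est / se)))
  s <- step_effects(fit(0.3, 0.05), fit(0.2, 0.04), fit(0.5, 0.1))
  expect_true(s$gate_passed)
  expect_equal(s$te, 0.3)

  # an insignificant exposure->mediator step closes the gate
  s2 <- step_effects(fit(0.3, 0.05), fit(0.03, 0.04), fit(0.5, 0.1))
  expect_false(s2$gate_passed)

  expect_error(step_effects(NULL, fit(0.2, 0.04), fit(0.5, 0.1)), "missing")
})

test_that("run_mediation recovers a known mediated proportion end to end", {
  cfg <- sim_config(J = 60, a = 0.3, b = 0.5, theta = 0.1, seed = 313)
  trip <- simulate_mediation_triplet(cfg)
  expect_equal(trip$truth$proportion_true, 0.15 / 0.25)

  res <- run_mediation(trip$exposure, trip$mediator, trip$outcome)
  expect_true(res$gate_passed)
  expect_lt(abs(res$a - 0.3), 0.05)
  expect_lt(abs(res$b - 0.5), 0.08)
  expect_lt(abs(res$proportion - 60), 12)

  # a zero mediator path is gated out at step 2
  cfg0 <- sim_config(J = 60, a = 0, b = 0.5, theta = 0.2, seed = 314)
  trip0 <- simulate_mediation_triplet(cfg0)
  res0 <- run_mediation(trip0$exposure, trip0$mediator, trip0$outcome)
  expect_false(res0$gate_passed)
  expect_true(is.na(res0$proportion))

  # mediator and outcome must be different traits
  expect_error(run_mediation(trip$exposure, trip$outcome, trip$outcome),
               "must differ")
})

test_that("mediation tidiers expose effects and the gate decision", {
  cfg <- sim_config(J = 50, a = 0.3, b = 0.5, theta = 0.1, seed = 99)
  trip <- simulate_mediation_triplet(cfg)
  res <- run_mediation(trip$exposure, trip$mediator, trip$outcome)
  td <- tidy(res)
  expect_equal(nrow(td), 4L)
  expect_setequal(td$term, c("total", "exposure_on_mediator",
                             "mediator_on_outcome_adj", "indirect"))
  gl <- glance(res)
  expect_true(gl$gate_passed)
  expect_equal(gl$nie_or, exp(res$nie))
})
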