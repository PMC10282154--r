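#' @importFrom stats pnorm pt qnorm sd mad dnorm rnorm approx runif setNames
NULL

Z95 <- qnorm(0.975)

# Assemble the common one-row mr_result tibble.
new_mr_result <- function(method, estimate, se, pval, n_snps, Q = NA_real_,
                          I2 = NA_real_, egger_intercept = NA_real_,
                          egger_intercept_p = NA_real_, term = NA_character_) {
  out <- tibble::tibble(
    method = method, term = term,
    estimate = estimate, se = se,
    ci_low = estimate - Z95 * se, ci_high = estimate + Z95 * se,
    pval = pval, n_snps = as.integer(n_snps),
    Q = Q, I2 = I2,
    egger_intercept = egger_intercept, egger_intercept_p = egger_intercept_p
  )
  class(out) <- c("mr_result", class(out))
  out
}

i2_from_q <- function(Q, df) {
  if (is.na(Q) || Q <= 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Per-variant Wald ratio estimates
#'
#' The variant-specific causal estimate is the outcome beta divided by the
#' exposure beta, with first-order standard error `sy / |bx|`. Variants with
#' `bx == 0` are dropped with a warning (their ratio is undefined).
#'
#' @param h A `harmonized_set`.
#' @return Tibble with columns `variant_id`, `theta` (ratio), `se`
#'   (first-order SE) and `weight` (`1/se^2`).
#' @export
wald_ratios <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  zero <- h$bx == 0
  if (all(zero)) stop("wald_ratios: all exposure betas are zero", call. = FALSE)
  if (any(zero)) {
    warning("wald_ratios: dropping ", sum(zero),
            " variant(s) with zero exposure beta", call. = FALSE)
    h <- subset_harmonized(h, !zero)
  }
  se <- h$sy / abs(h$bx)
  tibble::tibble(variant_id = h$variant_id,
                 theta = h$by / h$bx,
                 se = se,
                 weight = 1 / se^2)
}

#' Inverse-variance weighted MR (multiplicative random effects)
#'
#' Combines per-variant Wald ratios with first-order inverse-variance weights
#' \eqn{w_j = \beta_{Xj}^2 / \sigma_{Yj}^2}. The point estimate is the weighted
#' mean; heterogeneity is measured by Cochran's Q, and the fixed-effect SE is
#' inflated by \eqn{\sqrt{\max(1, Q/(J-1))}} — the multiplicative
#' random-effects model, which widens the interval when the variant-specific
#' estimates disagree more than chance but never narrows it. A single variant
#' degrades gracefully to its Wald ratio.
#'
#' @param h A `harmonized_set` with at least one usable variant.
#' @return A one-row `mr_result` tibble.
#' @export
mr_ivw <- function(h) {
  r <- wald_ratios(h)
  J <- nrow(r)
  if (J < 1L) stop("mr_ivw: no usable variants", call. = FALSE)
  w <- r$weight
  est <- sum(w * r$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (J == 1L) {
    se <- r$se[1L]
    return(new_mr_result("IVW", r$theta[1L], se,
                         2 * pnorm(-abs(r$theta[1L] / se)), 1L,
                         Q = 0, I2 = 0))
  }
  Q <- sum(w * (r$theta - est)^2)
  se <- se_fixed * sqrt(max(1, Q / (J - 1)))
  pval <- 2 * pnorm(-abs(est / se))
  new_mr_result("IVW", est, se, pval, J, Q = Q, I2 = i2_from_q(Q, J - 1))
}

# Weighted simple linear regression via explicit normal equations; returns
# coefficients, fixed-effect covariance and weighted RSS. Kept internal —
# mr_egger and mr_mvmr share it.
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  if (abs(det(XtWX)) < 1e-300) stop("collinear design", call. = FALSE)
  V <- solve(XtWX)
  dimnames(V) <- NULL
  beta <- unname(drop(V %*% (XtW %*% y)))
  resid <- y - drop(X %*% beta)
  list(beta = beta, cov_fixed = V, rss_w = sum(w * resid^2))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' weights `1/sy^2`, after orienting every variant so its exposure beta is
#' non-negative (variant orientation is arbitrary; the intercept is only
#' meaningful with a common orientation). The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy, and its test (p < 0.05 conventionally) signals
#' horizontal pleiotropy. SEs use multiplicative random effects
#' (inflation by \eqn{\sqrt{\max(1, RSS_w/(J-2))}}) and t tests with J - 2
#' degrees of freedom.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @return A one-row `mr_result` tibble with `egger_intercept` and
#'   `egger_intercept_p` filled in.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 3L) stop("mr_egger: at least 3 variants required", call. = FALSE)
  sgn <- ifelse(h$bx < 0, -1, 1)
  bx <- h$bx * sgn
  by <- h$by * sgn
  if (sd(bx) == 0) stop("mr_egger: zero variance in exposure betas (collinear)",
                        call. = FALSE)
  w <- 1 / h$sy^2
  fit <- wls_fit(cbind(1, bx), by, w)
  scale <- sqrt(max(1, fit$rss_w / (J - 2)))
  ses <- sqrt(diag(fit$cov_fixed)) * scale
  tvals <- fit$beta / ses
  pvals <- 2 * pt(-abs(tvals), df = J - 2)
  Q <- fit$rss_w
  new_mr_result("Egger", fit$beta[2L], ses[2L], pvals[2L], J,
                Q = Q, I2 = i2_from_q(Q, J - 2),
                egger_intercept = fit$beta[1L], egger_intercept_p = pvals[1L])
}

# Weighted median of theta with weights w: order theta, form cumulative
# midpoint weights, interpolate at 0.5.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1L]) return(theta[1L])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  approx(p, theta, xout = 0.5, ties = "ordered")$y
}

# Draw a parametric-bootstrap SE for an estimator of the Wald-ratio cloud.
boot_se <- function(h, n_boot, seed, point_fun) {
  withr::with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(h), h$bx, h$sx)
      by <- rnorm(nrow(h), h$by, h$sy)
      point_fun(bx, by, h$sy)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median MR
#'
#' The weighted median of the per-variant Wald ratios, consistent when at
#' least half the weight comes from valid instruments. Weights are first-order
#' inverse variances. The SE comes from a seeded parametric bootstrap
#' (resampling `bx` and `by` from their estimated sampling distributions).
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @param n_boot Bootstrap replicates for the SE. Default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h) < 3L) stop("mr_weighted_median: at least 3 variants required",
                         call. = FALSE)
  point <- function(bx, by, sy) {
    theta <- by / bx
    w <- (bx / sy)^2
    weighted_median_point(theta, w)
  }
  est <- point(h$bx, h$by, h$sy)
  se <- boot_se(h, n_boot, seed, point)
  pval <- 2 * pnorm(-abs(est / se))
  new_mr_result("WeightedMedian", est, se, pval, nrow(h))
}

# Mode of the inverse-variance-weighted normal-kernel density of theta over a
# dense grid; ties resolved to the smallest grid value.
mode_point <- function(theta, w, phi, grid_n = 2000L) {
  s <- phi * 0.9 * min(sd(theta), mad(theta)) * length(theta)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(theta[1L])  # all ratios identical
  grid <- seq(min(theta) - 3 * s, max(theta) + 3 * s, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, theta, s)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based MR
#'
#' The weighted mode of the Wald-ratio distribution: the causal effect is
#' estimated by the value around which the largest (inverse-variance-weighted)
#' cluster of variant-specific ratios concentrates, so it is consistent when
#' the single largest group of instruments is valid even if they carry less
#' than half the weight. The density uses a normal kernel with bandwidth
#' \eqn{0.9\,\phi\,\min(sd, 1.4826\,mad)\, J^{-1/5}} maximised over a dense
#' grid (2000 points). SE by seeded parametric bootstrap.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @param phi Bandwidth tuning factor. Default 1.
#' @param n_boot Bootstrap replicates for the SE. Default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return A one-row `mr_result` tibble.
#' @export
mr_mode <- function(h, phi = 1, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h) < 3L) stop("mr_mode: at least 3 variants required", call. = FALSE)
  point <- function(bx, by, sy) {
    theta <- by / bx
    w <- (bx / sy)^2
    mode_point(theta, w, phi)
  }
  est <- point(h$bx, h$by, h$sy)
  se <- boot_se(h, n_boot, seed, point)
  pval <- 2 * pnorm(-abs(est / se))
  new_mr_result("ModeBased", est, se, pval, nrow(h))
}

#' Multivariable MR with two exposures
#'
#' Weighted regression (no intercept, weights `1/sy^2`) of outcome betas on
#' the genetic associations with two exposures jointly — typically the primary
#' exposure and a candidate mediator — giving each one's direct effect
#' conditional on the other. SEs are inflated by
#' \eqn{\sqrt{\max(1, RSS_w/(J-2))}} and tested against t with J - 2 df.
#'
#' @param data Data frame with columns `bx1`, `bx2`, `by`, `sy` (one row per
#'   mutually independent variant from the union of both instrument sets),
#'   optionally `variant_id`.
#' @param terms Length-2 character vector labelling the regressors.
#' @return A two-row `mr_result` tibble (one row per regressor, identified by
#'   `term`).
#' @export
mr_mvmr <- function(data, terms = c("exposure", "mediator")) {
  required <- c("bx1", "bx2", "by", "sy")
  if (!all(required %in% names(data))) {
    stop("mr_mvmr: data needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  J <- nrow(data)
  if (J < 3L) stop("mr_mvmr: at least 3 variants required", call. = FALSE)
  X <- cbind(data$bx1, data$bx2)
  if (qr(X)$rank < 2L) stop("mr_mvmr: collinear exposures", call. = FALSE)
  w <- 1 / data$sy^2
  fit <- wls_fit(X, data$by, w)
  scale <- sqrt(max(1, fit$rss_w / (J - 2)))
  ses <- sqrt(diag(fit$cov_fixed)) * scale
  pvals <- 2 * pt(-abs(fit$beta / ses), df = J - 2)
  out <- dplyr::bind_rows(
    tibble::as_tibble(new_mr_result("MVMR", fit$beta[1L], ses[1L], pvals[1L], J,
                                    term = terms[1L])),
    tibble::as_tibble(new_mr_result("MVMR", fit$beta[2L], ses[2L], pvals[2L], J,
                                    term = terms[2L]))
  )
  class(out) <- c("mr_result", class(tibble::tibble()))
  out
}

#' Run the full battery of univariable MR estimators
#'
#' Convenience wrapper returning IVW, MR-Egger, weighted-median and mode-based
#' estimates stacked in one tibble.
#'
#' @inheritParams mr_weighted_median
#' @param phi Mode-based bandwidth tuning factor.
#' @return An `mr_result` tibble with one row per method.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1L, phi = 1) {
  out <- dplyr::bind_rows(
    tibble::as_tibble(mr_ivw(h)),
    tibble::as_tibble(mr_egger(h)),
    tibble::as_tibble(mr_weighted_median(h, n_boot = n_boot, seed = seed)),
    tibble::as_tibble(mr_mode(h, phi = phi, n_boot = n_boot, seed = seed + 1L))
  )
  class(out) <- c("mr_result", class(tibble::tibble()))
  out
}

#' Odds-ratio view of an MR estimate
#'
#' Exponentiates a log-odds-scale estimate and its confidence bounds. Only
#' meaningful for binary outcomes.
#'
#' @param result An `mr_result` tibble.
#' @return The input with `or`, `or_low`, `or_high` columns appended.
#' @export
as_odds_ratios <- function(result) {
  dplyr::mutate(result,
                or = exp(.data$estimate),
                or_low = exp(.data$ci_low),
                or_high = exp(.data$ci_high))
}
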