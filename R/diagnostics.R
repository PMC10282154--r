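#' Cochran's Q heterogeneity test for Wald ratios
#'
#' Measures disagreement among the variant-specific Wald estimates beyond what
#' their sampling variances predict. `I2 = max(0, (Q - df)/Q) * 100` is the
#' percentage of variability attributable to heterogeneity rather than chance.
#'
#' @param h A `harmonized_set` with at least 2 variants.
#' @return A list with `Q`, `df` (`J - 1`) and `I2` (in `[0, 100)`).
#' @export
cochran_q <- function(h) {
  r <- wald_ratios(h)
  J <- nrow(r)
  if (J < 2L) stop("cochran_q: at least 2 variants required", call. = FALSE)
  est <- sum(r$weight * r$theta) / sum(r$weight)
  Q <- sum(r$weight * (r$theta - est)^2)
  list(Q = Q, df = J - 1L, I2 = i2_from_q(Q, J - 1L))
}

# Vectorised leave-one-out IVW point estimates. Returns the J estimates
# theta_hat_(-j) without SEs; avoids dividing by bx.
loo_ivw_points <- function(bx, by, sy) {
  w <- (bx / sy)^2
  swt <- sum(bx * by / sy^2)          # = sum(w * theta)
  sw <- sum(w)
  (swt - bx * by / sy^2) / (sw - w)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimator J times, omitting one variant each time, to assess
#' whether the result relies on any single variant. The `flag` is raised when
#' the full-set IVW is significant (p <= 0.05) but at least one leave-one-out
#' fit is not — the evidence then hinges on one particular variant.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @return A list with `results` (tibble: `excluded_variant`, `estimate`,
#'   `se`, `pval`) and `flag` (logical).
#' @export
leave_one_out <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 3L) stop("leave_one_out: at least 3 variants required", call. = FALSE)
  fits <- purrr::map(seq_len(J), function(j) mr_ivw(subset_harmonized(h, -j)))
  results <- tibble::tibble(
    excluded_variant = h$variant_id,
    estimate = purrr::map_dbl(fits, "estimate"),
    se = purrr::map_dbl(fits, "se"),
    pval = purrr::map_dbl(fits, "pval")
  )
  full_p <- mr_ivw(h)$pval
  flag <- full_p <= 0.05 && any(results$pval > 0.05)
  list(results = results, flag = flag)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Monte-Carlo test for horizontal pleiotropy. The observed residual sum of
#' squares uses leave-one-out IVW predictions,
#' \eqn{RSS = \sum_j (b_{Yj} - \hat\theta_{(-j)} b_{Xj})^2}; its null
#' distribution is simulated by redrawing every `bx` and `by` from their
#' estimated sampling distributions around the leave-one-out fit. Per-variant
#' squared residuals give an outlier test (Bonferroni-corrected across the J
#' variants); a distortion test compares the raw-vs-outlier-corrected IVW
#' difference against removals of random subsets of the same size. Empirical
#' p-values use the (1 + k)/(n + 1) convention, so they are never exactly 0.
#'
#' @param h A `harmonized_set` with at least 4 variants.
#' @param n_sim Simulations for the global/outlier null. Default 1000.
#' @param seed Integer seed; all randomness is derived from it.
#' @param outlier_alpha Significance level for the Bonferroni-corrected
#'   per-variant outlier test. Default 0.05.
#' @param n_distortion Random same-size removals for the distortion test.
#'   Default 1000.
#' @return An object of class `presso_result`: list with `global_rss`,
#'   `global_p`, `outlier_table` (tibble: `variant_id`, `resid2`, `pval`,
#'   `pval_bonf`, `outlier`), `outliers` (ids), `distortion_p` (NA when no
#'   outliers), `estimate_raw` and `estimate_corrected` (`mr_result` rows;
#'   corrected is NULL when nothing was removed).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, outlier_alpha = 0.05,
                      n_distortion = 1000) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 4L) stop("mr_presso: PRESSO requires >= 4 instruments", call. = FALSE)

  bx <- h$bx; by <- h$by; sx <- h$sx; sy <- h$sy
  theta_loo <- loo_ivw_points(bx, by, sy)
  resid_obs <- by - theta_loo * bx
  rss_obs <- sum(resid_obs^2)

  withr::with_seed(seed, {
    # J x n_sim draws under the no-pleiotropy null
    bx_star <- matrix(rnorm(J * n_sim, bx, sx), nrow = J)
    by_star <- matrix(rnorm(J * n_sim, theta_loo * bx, sy), nrow = J)
    w_star <- bx_star^2 / sy^2
    wt_star <- bx_star * by_star / sy^2
    sw <- colSums(w_star)
    swt <- colSums(wt_star)
    theta_loo_star <- sweep(-wt_star, 2, swt, "+") / sweep(-w_star, 2, sw, "+")
    resid_star <- by_star - theta_loo_star * bx_star
    rss_star <- colSums(resid_star^2)

    global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + rowSums(resid_star^2 >= resid_obs^2)) / (n_sim + 1)
    outlier_p_bonf <- pmin(1, outlier_p * J)
    is_out <- outlier_p_bonf < outlier_alpha

    est_raw <- mr_ivw(h)
    est_corr <- NULL
    distortion_p <- NA_real_
    if (any(is_out) && sum(!is_out) >= 2L) {
      est_corr <- mr_ivw(subset_harmonized(h, !is_out))
      d_obs <- est_corr$estimate - est_raw$estimate
      k <- sum(is_out)
      w_all <- bx^2 / sy^2
      wt_all <- bx * by / sy^2
      d_rand <- vapply(seq_len(n_distortion), function(i) {
        drop_idx <- sample.int(J, k)
        # IVW point estimate on the random subset (same weighted mean as mr_ivw)
        sum(wt_all[-drop_idx]) / sum(w_all[-drop_idx]) - est_raw$estimate
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_distortion + 1)
    }
  })

  structure(list(
    global_rss = rss_obs,
    global_p = global_p,
    outlier_table = tibble::tibble(
      variant_id = h$variant_id, resid2 = resid_obs^2,
      pval = outlier_p, pval_bonf = outlier_p_bonf, outlier = is_out
    ),
    outliers = h$variant_id[is_out],
    distortion_p = distortion_p,
    estimate_raw = est_raw,
    estimate_corrected = est_corr
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat("<presso_result> global RSS ", format(x$global_rss, digits = 4),
      ", global p ", format(x$global_p, digits = 3), ", ",
      length(x$outliers), " outlier(s)\n", sep = "")
  invisible(x)
}

#' Egger-gated outlier removal and rerun
#'
#' The study protocol removes likely pleiotropic variants only when the
#' MR-Egger intercept test signals horizontal pleiotropy (p < 0.05); it then
#' reruns the IVW and leave-one-out analyses on the pruned set. When the gate
#' is not triggered the input is returned unchanged.
#'
#' @param h A `harmonized_set`.
#' @param presso A `presso_result` for `h` (supplies the outlier list), or
#'   `NULL` to compute one.
#' @param egger_intercept_p Intercept p-value from [mr_egger()]; computed from
#'   `h` when `NULL`.
#' @param gate_alpha Gate level. Default 0.05.
#' @param ... Passed to [mr_presso()] when it has to be computed.
#' @return A list with `h` (possibly pruned), `ivw` (`mr_result`), `loo`
#'   (leave-one-out list), `removed` (character vector of variant ids) and
#'   `triggered` (logical).
#' @export
remove_outliers_and_rerun <- function(h, presso = NULL, egger_intercept_p = NULL,
                                      gate_alpha = 0.05, ...) {
  stopifnot(inherits(h, "harmonized_set"))
  if (is.null(egger_intercept_p)) egger_intercept_p <- mr_egger(h)$egger_intercept_p
  if (is.na(egger_intercept_p) || egger_intercept_p >= gate_alpha) {
    return(list(h = h, ivw = mr_ivw(h), loo = leave_one_out(h),
                removed = character(0), triggered = FALSE))
  }
  if (is.null(presso)) presso <- mr_presso(h, ...)
  removed <- presso$outliers
  keep <- !h$variant_id %in% removed
  if (sum(keep) < 2L) {
    stop("remove_outliers_and_rerun: pruning would leave fewer than 2 variants",
         call. = FALSE)
  }
  h2 <- subset_harmonized(h, keep)
  list(h = h2, ivw = mr_ivw(h2),
       loo = if (nrow(h2) >= 3L) leave_one_out(h2) else NULL,
       removed = removed, triggered = TRUE)
}
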