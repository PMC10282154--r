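#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MR result
#'
#' Returns the estimate rows in broom's standard column vocabulary.
#'
#' @param x An `mr_result` tibble.
#' @param exponentiate Report odds ratios instead of log-odds. Default FALSE.
#' @param ... Unused.
#' @return A tibble with columns `method`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::tibble(
    method = x$method,
    term = ifelse(is.na(x$term), x$method, x$term),
    estimate = x$estimate,
    std.error = x$se,
    statistic = x$estimate / x$se,
    p.value = x$pval,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Model-level summary of an MR result
#'
#' @param x An `mr_result` tibble.
#' @param ... Unused.
#' @return A tibble with `method`, `n_snps`, `Q`, `I2`, `egger_intercept`,
#'   `egger_intercept_p`.
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snps = x$n_snps, Q = x$Q, I2 = x$I2,
                 egger_intercept = x$egger_intercept,
                 egger_intercept_p = x$egger_intercept_p)
}

#' Tidy a mediation result
#'
#' One row per effect (total, exposure->mediator, adjusted mediator->outcome,
#' indirect) per triplet, in broom vocabulary.
#'
#' @param x A `mediation_result` tibble.
#' @param ... Unused.
#' @return A long tibble with `exposure`, `mediator`, `outcome`, `term`,
#'   `estimate`, `std.error`.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  x <- tibble::as_tibble(x)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    tibble::tibble(
      exposure = r$exposure, mediator = r$mediator, outcome = r$outcome,
      term = c("total", "exposure_on_mediator", "mediator_on_outcome_adj",
               "indirect"),
      estimate = c(r$te, r$a, r$b, r$nie),
      std.error = c(r$se_te, r$se_a, r$se_b, r$se_nie)
    )
  })
}

#' Summary of a mediation analysis
#'
#' @param x A `mediation_result` tibble.
#' @param ... Unused.
#' @return A tibble with the triplet names, gate decision, indirect-effect
#'   odds ratio with CI and the proportion mediated (percent) with CI.
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("exposure", "mediator", "outcome", "gate_passed",
                           "nie_or", "nie_or_low", "nie_or_high",
                           "proportion", "prop_ci_low", "prop_ci_high")]
}
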