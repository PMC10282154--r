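#' Indirect effect by the product method
#'
#' The natural indirect effect through a mediator is the product of the
#' exposure-to-mediator effect `a` and the mediator-to-outcome effect `b`
#' (adjusted for the exposure), both on the log scale. Its standard error uses
#' the first-order Delta method assuming independence of the two estimates
#' (they come from separate regressions):
#' \eqn{SE_{ab} = \sqrt{a^2 SE_b^2 + b^2 SE_a^2}}.
#'
#' @param a,se_a Exposure-to-mediator effect and SE (log scale).
#' @param b,se_b Mediator-to-outcome effect (exposure-adjusted) and SE.
#' @return A list with `nie`, `se_nie`, `ci_low`, `ci_high` (log scale) and
#'   `nie_or`, `nie_or_low`, `nie_or_high` (exponentiated).
#' @export
indirect_effect <- function(a, se_a, b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  nie <- a * b
  se_nie <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  ci_low <- nie - Z95 * se_nie
  ci_high <- nie + Z95 * se_nie
  list(nie = nie, se_nie = se_nie, ci_low = ci_low, ci_high = ci_high,
       nie_or = exp(nie), nie_or_low = exp(ci_low), nie_or_high = exp(ci_high))
}

#' Proportion of the total effect that is mediated
#'
#' Divides the indirect effect by the total effect, both on the log scale, and
#' builds a Delta-method interval for the ratio (independence of the two
#' estimates assumed):
#' \eqn{Var(nie/te) \approx SE_{nie}^2/te^2 + nie^2 SE_{te}^2/te^4}.
#' Reported as a percentage.
#'
#' @param te,se_te Total effect and SE (log scale); `te` must be non-zero.
#' @param nie,se_nie Indirect effect and SE (log scale).
#' @return A list with `proportion`, `ci_low`, `ci_high` (percent) and
#'   `se_proportion` (percent).
#' @export
proportion_mediated <- function(te, se_te, nie, se_nie) {
  if (te == 0) stop("proportion_mediated: undefined proportion (total effect is 0)",
                    call. = FALSE)
  prop <- nie / te
  v <- se_nie^2 / te^2 + nie^2 * se_te^2 / te^4
  se_prop <- sqrt(v)
  list(proportion = 100 * prop,
       ci_low = 100 * (prop - Z95 * se_prop),
       ci_high = 100 * (prop + Z95 * se_prop),
       se_proportion = 100 * se_prop)
}

#' Proportion mediated from odds-ratio-scale effects
#'
#' Converts a total effect and indirect effect reported as odds ratios back to
#' the log scale and returns `100 * ln(NIE) / ln(TE)` — the proportion of the
#' total effect mediated, in percent.
#'
#' @param te_or Total effect as an odds ratio (non-1).
#' @param nie_or Indirect effect as an odds ratio.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' proportion_from_or(1.42896, 1.049)  # ~13.4%
proportion_from_or <- function(te_or, nie_or) {
  stopifnot(all(te_or > 0), all(nie_or > 0), all(te_or != 1))
  100 * log(nie_or) / log(te_or)
}

#' Published mediation worked examples
#'
#' A small table of published diet–mediator–migraine mediation rows (total
#' effect and natural indirect effect as odds ratios, with the reported
#' proportion mediated) bundled with the package. Used as a worked-example
#' surface: `proportion_from_or(te_or, nie_or)` reproduces the
#' `proportion_pct` column to within rounding of the printed odds ratios.
#'
#' @return A tibble with columns `exposure`, `mediator`, `outcome`, `te_or`,
#'   `nie_or`, `nie_or_low`, `nie_or_high`, `proportion_pct`,
#'   `proportion_low_pct`, `proportion_high_pct`.
#' @export
mediation_worked_examples <- function() {
  path <- system.file("extdata", "mediation_examples.tsv", package = "mrpath",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Assemble the three mediation steps and apply the significance gate
#'
#' Mediation proceeds only when associations are observed in all three steps:
#' (1) exposure on outcome (total effect), (2) exposure on mediator, and
#' (3) mediator on outcome adjusted for the exposure (from multivariable MR).
#' "Observed" means nominal p < `gate_alpha` in each fit. All effects must be
#' supplied on the log scale; odds-ratio-scale inputs are rejected.
#'
#' @param total_fit `mr_result` row for exposure -> outcome.
#' @param mediator_fit `mr_result` row for exposure -> mediator.
#' @param mvmr_mediator_fit `mr_result` row for the mediator coefficient from
#'   the exposure-adjusted MVMR.
#' @param gate_alpha Nominal significance level for each step. Default 0.05.
#' @return A list with `te`, `se_te`, `a`, `se_a`, `b`, `se_b`, `gate_passed`
#'   and `gate_detail` (per-step p-values).
#' @export
step_effects <- function(total_fit, mediator_fit, mvmr_mediator_fit,
                         gate_alpha = 0.05) {
  fits <- list(total = total_fit, mediator = mediator_fit,
               mvmr = mvmr_mediator_fit)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (is.null(f) || !all(c("estimate", "se", "pval") %in% names(f))) {
      stop("step_effects: missing or malformed fit for step '", nm, "'",
           call. = FALSE)
    }
    if (any(c("or", "or_low") %in% names(f)) && !"estimate" %in% names(f)) {
      stop("step_effects: supply log-scale estimates, not odds ratios",
           call. = FALSE)
    }
  }
  if (nrow(mvmr_mediator_fit) != 1L) {
    stop("step_effects: mvmr_mediator_fit must be the single mediator row",
         call. = FALSE)
  }
  pvals <- c(total = total_fit$pval, mediator = mediator_fit$pval,
             mvmr = mvmr_mediator_fit$pval)
  list(te = total_fit$estimate, se_te = total_fit$se,
       a = mediator_fit$estimate, se_a = mediator_fit$se,
       b = mvmr_mediator_fit$estimate, se_b = mvmr_mediator_fit$se,
       gate_passed = all(pvals < gate_alpha),
       gate_detail = pvals)
}

# Build the aligned MVMR design table for exposure + mediator on the outcome:
# union of both instrument sets, re-pruned for mutual independence, harmonized
# to the outcome's effect alleles.
build_mvmr_design <- function(exposure, mediator, outcome, panel = NULL,
                              p_threshold = 5e-6, window_bp = 1e6,
                              r2_max = 0.001) {
  inst_x <- ld_clump(select_by_pvalue(exposure, p_threshold), panel,
                     window_bp, r2_max)
  inst_m <- ld_clump(select_by_pvalue(mediator, p_threshold), panel,
                     window_bp, r2_max)
  union_ids <- union(inst_x$variant_id, inst_m$variant_id)
  # re-prune the union so MVMR instruments are mutually independent; rank by
  # the smaller of the two p-values
  pool <- tibble::as_tibble(exposure)[exposure$variant_id %in% union_ids, ]
  pm <- mediator$pval[match(pool$variant_id, mediator$variant_id)]
  pool$pval <- pmin(pool$pval, pm, na.rm = TRUE)
  pool_ss <- structure(pool, trait_name = trait_name(exposure),
                       trait_type = trait_type(exposure),
                       n_dropped = 0L, class = class(exposure))
  pruned <- ld_clump(pool_ss, panel, window_bp, r2_max)

  keep_x <- structure(tibble::as_tibble(exposure)[
    exposure$variant_id %in% pruned$variant_id, ],
    trait_name = trait_name(exposure), trait_type = trait_type(exposure),
    n_dropped = 0L, class = class(exposure))
  hx <- harmonize(keep_x, outcome)
  hm <- harmonize(keep_x, mediator)  # mediator betas on the exposure's alleles
  shared <- intersect(hx$variant_id, hm$variant_id)
  hx <- subset_harmonized(hx, match(shared, hx$variant_id))
  hm <- subset_harmonized(hm, match(shared, hm$variant_id))
  tibble::tibble(
    variant_id = shared,
    bx1 = hx$bx, sx1 = hx$sx,
    bx2 = hm$by, sx2 = hm$sy,
    by = hx$by, sy = hx$sy
  )
}

#' Three-step network-MR mediation analysis
#'
#' Orchestrates the full mediation design for one exposure–mediator–outcome
#' triplet: (1) total effect of the exposure on the outcome by IVW on the
#' exposure's instruments; (2) effect of the exposure on the mediator by IVW
#' on the same instruments; (3) effect of the mediator on the outcome adjusted
#' for the exposure by multivariable MR on the re-pruned union of both
#' instrument sets. If all three are nominally significant, the indirect
#' effect is `a * b` and the proportion mediated `a * b / te`, each with
#' Delta-method intervals.
#'
#' @param exposure,mediator,outcome `summary_stats` tibbles. Mediator and
#'   outcome must be different traits.
#' @param panel Optional [ld_panel()] used for clumping.
#' @param p_threshold Instrument p-value threshold. Default 5e-6.
#' @param window_bp,r2_max Clumping parameters. Defaults 1 Mb and 0.001.
#' @param gate_alpha Per-step significance gate. Default 0.05.
#' @return A one-row tibble of class `mediation_result`: trait names, `te`,
#'   `se_te`, `a`, `se_a`, `b`, `se_b`, `nie`, `se_nie`, `nie_or` with CI,
#'   `proportion` with CI (percent), `gate_passed`, and the per-step p-values.
#'   When the gate fails, the effect columns up to the gate are filled and
#'   `nie`/`proportion` are `NA`.
#' @export
run_mediation <- function(exposure, mediator, outcome, panel = NULL,
                          p_threshold = 5e-6, window_bp = 1e6, r2_max = 0.001,
                          gate_alpha = 0.05) {
  if (identical(trait_name(mediator), trait_name(outcome))) {
    stop("run_mediation: mediator and outcome must differ", call. = FALSE)
  }
  inst <- ld_clump(select_by_pvalue(exposure, p_threshold), panel,
                   window_bp, r2_max)
  if (nrow(inst) < 2L) {
    stop("run_mediation: too few instruments for '", trait_name(exposure), "'",
         call. = FALSE)
  }
  total_fit <- mr_ivw(harmonize(inst, outcome))
  a_fit <- mr_ivw(harmonize(inst, mediator))

  design <- build_mvmr_design(exposure, mediator, outcome, panel,
                              p_threshold, window_bp, r2_max)
  mv <- mr_mvmr(design, terms = c(trait_name(exposure), trait_name(mediator)))
  b_fit <- mv[mv$term == trait_name(mediator), ]

  steps <- step_effects(total_fit, a_fit, b_fit, gate_alpha = gate_alpha)

  out <- tibble::tibble(
    exposure = trait_name(exposure),
    mediator = trait_name(mediator),
    outcome = trait_name(outcome),
    te = steps$te, se_te = steps$se_te,
    a = steps$a, se_a = steps$se_a,
    b = steps$b, se_b = steps$se_b,
    p_total = steps$gate_detail[["total"]],
    p_mediator = steps$gate_detail[["mediator"]],
    p_mvmr = steps$gate_detail[["mvmr"]],
    gate_passed = steps$gate_passed,
    nie = NA_real_, se_nie = NA_real_,
    nie_or = NA_real_, nie_or_low = NA_real_, nie_or_high = NA_real_,
    proportion = NA_real_, prop_ci_low = NA_real_, prop_ci_high = NA_real_
  )
  if (steps$gate_passed) {
    ie <- indirect_effect(steps$a, steps$se_a, steps$b, steps$se_b)
    pm <- proportion_mediated(steps$te, steps$se_te, ie$nie, ie$se_nie)
    out$nie <- ie$nie; out$se_nie <- ie$se_nie
    out$nie_or <- ie$nie_or; out$nie_or_low <- ie$nie_or_low
    out$nie_or_high <- ie$nie_or_high
    out$proportion <- pm$proportion
    out$prop_ci_low <- pm$ci_low; out$prop_ci_high <- pm$ci_high
  }
  class(out) <- c("mediation_result", class(tibble::tibble()))
  out
}
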