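#' Define an analysis plan
#'
#' Describes a full study: a panel of exposures (each labelled with a subtype,
#' from which Bonferroni denominators are derived), one or more outcomes,
#' candidate mediators, instrument-selection thresholds and the root seed.
#' All traits are in-memory `summary_stats` objects (use
#' [read_summary_stats()] to load files first).
#'
#' @param exposures Named list of `summary_stats`.
#' @param outcomes Named list of `summary_stats`.
#' @param mediators Named list of `summary_stats` (may be empty).
#' @param subtypes Character vector, one label per exposure (recycled if
#'   length 1). Bonferroni thresholds use the subtype sizes.
#' @param panel Optional [ld_panel()] shared by all clumping steps.
#' @param p_threshold Instrument p-value threshold. Default 5e-6.
#' @param window_bp,r2_max Clumping parameters. Defaults 1 Mb, 0.001.
#' @param n_boot Bootstrap replicates for median/mode SEs. Default 1000.
#' @param presso_n_sim MR-PRESSO simulations. Default 1000.
#' @param mediation_threshold `"bonferroni"` (default) or `"nominal"`: which
#'   forward-stage significance defines the exposures taken into mediation.
#' @param seed Root seed; each analysis derives its own seed from it.
#' @return A list of class `analysis_plan`.
#' @export
analysis_plan <- function(exposures, outcomes, mediators = list(),
                          subtypes = "all", panel = NULL,
                          p_threshold = 5e-6, window_bp = 1e6, r2_max = 0.001,
                          n_boot = 1000, presso_n_sim = 1000,
                          mediation_threshold = c("bonferroni", "nominal"),
                          seed = 1L) {
  mediation_threshold <- match.arg(mediation_threshold)
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    stop("analysis_plan: exposures and outcomes must be named lists", call. = FALSE)
  }
  if (length(subtypes) == 1L) subtypes <- rep(subtypes, length(exposures))
  if (length(subtypes) != length(exposures)) {
    stop("analysis_plan: one subtype label per exposure required", call. = FALSE)
  }
  structure(list(exposures = exposures, outcomes = outcomes,
                 mediators = mediators,
                 subtypes = stats::setNames(subtypes, names(exposures)),
                 panel = panel, p_threshold = p_threshold,
                 window_bp = window_bp, r2_max = r2_max, n_boot = n_boot,
                 presso_n_sim = presso_n_sim,
                 mediation_threshold = mediation_threshold,
                 seed = as.integer(seed)),
            class = "analysis_plan")
}

#' Full single-pair MR analysis
#'
#' One exposure–outcome analysis following the study protocol: instrument
#' selection (p-value filter + LD clumping), harmonization, instrument-strength
#' F statistics, the estimator battery (IVW, MR-Egger, weighted median, mode),
#' Egger-intercept-gated MR-PRESSO outlier removal with IVW/leave-one-out
#' rerun, and evidence grading against the supplied Bonferroni threshold.
#'
#' @param exposure,outcome `summary_stats`.
#' @param alpha_bonf Bonferroni threshold for criterion 1. Default 0.05.
#' @param panel Optional [ld_panel()].
#' @param p_threshold,window_bp,r2_max Instrument-selection parameters.
#' @param n_boot,presso_n_sim Monte-Carlo sizes.
#' @param seed Integer seed for bootstrap and PRESSO.
#' @return A list of class `mr_analysis`: `instruments`, `harmonized`,
#'   `f_stats`, `fits` (`mr_result` tibble), `rerun` (outlier-removal result),
#'   `loo`, `presso` (NULL unless the gate fired), `grading` and `status`.
#' @export
mr_analysis <- function(exposure, outcome, alpha_bonf = 0.05, panel = NULL,
                        p_threshold = 5e-6, window_bp = 1e6, r2_max = 0.001,
                        n_boot = 1000, presso_n_sim = 1000, seed = 1L) {
  inst <- ld_clump(select_by_pvalue(exposure, p_threshold), panel,
                   window_bp, r2_max)
  if (nrow(inst) < 3L) {
    return(structure(list(instruments = inst, harmonized = NULL, f_stats = NULL,
                          fits = NULL, rerun = NULL, loo = NULL, presso = NULL,
                          grading = NULL, status = "no_instruments"),
                     class = "mr_analysis"))
  }
  h <- harmonize(inst, outcome)
  if (nrow(h) < 3L) {
    return(structure(list(instruments = inst, harmonized = h, f_stats = NULL,
                          fits = NULL, rerun = NULL, loo = NULL, presso = NULL,
                          grading = NULL, status = "too_few_harmonized"),
                     class = "mr_analysis"))
  }
  fstat <- f_statistics(h)
  fits <- mr_all_methods(h, n_boot = n_boot, seed = seed)
  egger_p <- fits$egger_intercept_p[fits$method == "Egger"]

  presso <- NULL
  if (!is.na(egger_p) && egger_p < 0.05 && nrow(h) >= 4L) {
    presso <- mr_presso(h, n_sim = presso_n_sim, seed = seed + 1L)
  }
  rerun <- remove_outliers_and_rerun(h, presso = presso,
                                     egger_intercept_p = egger_p)
  loo <- rerun$loo
  post_ests <- c(IVW = rerun$ivw$estimate)
  if (nrow(rerun$h) >= 3L) {
    post_fits <- mr_all_methods(rerun$h, n_boot = n_boot, seed = seed + 2L)
    post_ests <- stats::setNames(post_fits$estimate, post_fits$method)
  }
  grading <- grade_evidence(
    ivw_p = rerun$ivw$pval,
    alpha_bonf = alpha_bonf,
    estimates = stats::setNames(fits$estimate, fits$method),
    post_estimates = post_ests,
    post_ivw_p = rerun$ivw$pval,
    loo_flag = if (is.null(loo)) FALSE else loo$flag
  )
  structure(list(instruments = inst, harmonized = h, f_stats = fstat,
                 fits = fits, rerun = rerun, loo = loo, presso = presso,
                 grading = grading, status = "ok"),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("<mr_analysis> status: ", x$status, "\n", sep = "")
  if (!is.null(x$fits)) print(x$fits)
  if (!is.null(x$grading)) cat("grade:", x$grading$grade, "\n")
  invisible(x)
}

# One summary row for the results table of run_forward/run_bidirectional.
analysis_row <- function(exposure_name, outcome_name, subtype, alpha_bonf, an) {
  base <- tibble::tibble(
    exposure = exposure_name, outcome = outcome_name, subtype = subtype,
    status = an$status, n_instruments = nrow(an$instruments),
    mean_F = NA_real_, estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, pval = NA_real_, Q = NA_real_, I2 = NA_real_,
    egger_intercept = NA_real_, egger_intercept_p = NA_real_,
    n_removed = NA_integer_, loo_flag = NA, alpha_bonf = alpha_bonf,
    grade = NA_character_
  )
  if (an$status != "ok") return(base)
  ivw <- an$rerun$ivw
  egger <- an$fits[an$fits$method == "Egger", ]
  base$mean_F <- an$f_stats$mean_F
  base$estimate <- ivw$estimate; base$se <- ivw$se
  base$ci_low <- ivw$ci_low; base$ci_high <- ivw$ci_high
  base$pval <- ivw$pval; base$Q <- ivw$Q; base$I2 <- ivw$I2
  base$egger_intercept <- egger$egger_intercept
  base$egger_intercept_p <- egger$egger_intercept_p
  base$n_removed <- length(an$rerun$removed)
  base$loo_flag <- an$grading$loo_flag
  base$grade <- an$grading$grade
  base
}

#' Forward MR over an exposure panel
#'
#' Runs [mr_analysis()] for every exposure–outcome pair in the plan.
#' Failures are per-pair: an error in one analysis is recorded in its `status`
#' column and the pipeline continues. Deterministic under the plan seed.
#'
#' @param plan An [analysis_plan()].
#' @return A tibble with one row per pair: IVW estimate (after any
#'   Egger-gated outlier removal), heterogeneity, Egger intercept, instrument
#'   counts, subtype Bonferroni threshold and grade.
#' @export
run_forward <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  subtype_n <- table(plan$subtypes)
  idx <- 0L
  rows <- purrr::imap(plan$exposures, function(ex, ex_name) {
    purrr::imap(plan$outcomes, function(ou, ou_name) {
      idx <<- idx + 1L
      subtype <- plan$subtypes[[ex_name]]
      alpha_bonf <- bonferroni_threshold(subtype_n[[subtype]])
      an <- tryCatch(
        mr_analysis(ex, ou, alpha_bonf = alpha_bonf, panel = plan$panel,
                    p_threshold = plan$p_threshold,
                    window_bp = plan$window_bp, r2_max = plan$r2_max,
                    n_boot = plan$n_boot, presso_n_sim = plan$presso_n_sim,
                    seed = plan$seed + 13L * idx),
        error = function(e) {
          structure(list(instruments = tibble::tibble(), status = paste0(
            "error: ", conditionMessage(e))), class = "mr_analysis")
        })
      analysis_row(ex_name, ou_name, subtype, alpha_bonf, an)
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Mediation stage over forward hits
#'
#' For every exposure–outcome pair whose forward IVW passes its subtype
#' threshold (Bonferroni by default), runs the three-step mediation analysis
#' against every mediator in the plan.
#'
#' @param plan An [analysis_plan()] with mediators.
#' @param forward Result tibble from [run_forward()].
#' @return A `mediation_result` tibble, one row per (hit, mediator); empty
#'   when there are no forward hits.
#' @export
run_mediation_stage <- function(plan, forward) {
  stopifnot(inherits(plan, "analysis_plan"))
  thr <- if (plan$mediation_threshold == "bonferroni") forward$alpha_bonf else 0.05
  hits <- forward[!is.na(forward$pval) & forward$pval < thr, ]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    for (med_name in names(plan$mediators)) {
      res <- tryCatch(
        run_mediation(plan$exposures[[hits$exposure[i]]],
                      plan$mediators[[med_name]],
                      plan$outcomes[[hits$outcome[i]]],
                      panel = plan$panel, p_threshold = plan$p_threshold,
                      window_bp = plan$window_bp, r2_max = plan$r2_max),
        error = function(e) NULL)
      if (!is.null(res)) out[[length(out) + 1L]] <- tibble::as_tibble(res)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(exposure = character(0), mediator = character(0),
                          outcome = character(0)))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("mediation_result", class(tibble::tibble()))
  res
}

#' Reverse-direction MR
#'
#' Swaps the roles in the plan — each outcome becomes the exposure and each
#' exposure the outcome — and runs the same estimator battery and grading, to
#' probe reverse causation.
#'
#' @param plan An [analysis_plan()].
#' @return A tibble like [run_forward()]'s, with `exposure` and `outcome`
#'   showing the swapped roles.
#' @export
run_bidirectional <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  rev_plan <- plan
  rev_plan$exposures <- plan$outcomes
  rev_plan$outcomes <- plan$exposures
  rev_plan$subtypes <- stats::setNames(rep("reverse", length(plan$outcomes)),
                                       names(plan$outcomes))
  rev_plan$seed <- plan$seed + 7919L
  run_forward(rev_plan)
}
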