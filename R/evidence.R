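#' Bonferroni-corrected significance threshold within a trait subtype
#'
#' Multiple testing is controlled within each subtype of related exposures:
#' the threshold is `0.05 / n`, where `n` is the number of traits in the
#' subtype.
#'
#' @param n_in_subtype Number of traits in the subtype (>= 1).
#' @return The corrected alpha.
#' @export
bonferroni_threshold <- function(n_in_subtype) {
  if (!is.numeric(n_in_subtype) || n_in_subtype < 1) {
    stop("bonferroni_threshold: n must be >= 1", call. = FALSE)
  }
  0.05 / n_in_subtype
}

.grades <- c("reliable", "insufficient", "weak", "none")

#' Map evidence criteria to a grade
#'
#' The three-level rubric grades an MR finding on: (1) strength — the IVW
#' p-value passes the subtype Bonferroni threshold; (2) fitness of the MR
#' assumptions — after removal of likely pleiotropic variants, the estimates
#' remain sign-consistent and the IVW stays nominally significant;
#' (3) direction — all sensitivity estimators agree in sign with the IVW.
#' All three give "reliable"; (2) and (3) with only nominal significance give
#' "insufficient"; nominal significance with consistent direction but failing
#' (2) gives "weak"; anything else "none". A leave-one-out dependence on a
#' single variant demotes the grade by one level.
#'
#' @param criterion1,criterion2,criterion3 Logicals as defined above.
#' @param nominal Logical: IVW p < 0.05. `criterion1` implies `nominal`.
#' @param loo_flag Logical: leave-one-out flag (demotes one level when TRUE).
#' @return One of `"reliable"`, `"insufficient"`, `"weak"`, `"none"`.
#' @export
grade_from_criteria <- function(criterion1, criterion2, criterion3,
                                nominal = criterion1, loo_flag = FALSE) {
  nominal <- nominal || criterion1
  base <-
    if (criterion1 && criterion2 && criterion3) "reliable"
    else if (criterion2 && criterion3 && nominal) "insufficient"
    else if (nominal && criterion3 && !criterion2) "weak"
    else "none"
  if (loo_flag && base != "none") {
    base <- .grades[match(base, .grades) + 1L]
  }
  base
}

#' Grade the evidence for one MR analysis
#'
#' Computes the three criteria from the fitted estimates and applies
#' [grade_from_criteria()].
#'
#' @param ivw_p Final IVW p-value (after any Egger-gated outlier removal).
#' @param alpha_bonf Subtype Bonferroni threshold from
#'   [bonferroni_threshold()].
#' @param estimates Named numeric vector of point estimates from the method
#'   battery; must contain an `"IVW"` entry (sign reference for criterion 3).
#' @param post_estimates Point estimates after outlier removal; defaults to
#'   `estimates` when no removal occurred.
#' @param post_ivw_p IVW p-value after removal; defaults to `ivw_p`.
#' @param loo_flag Leave-one-out flag from [leave_one_out()].
#' @param require_sensitivity_significance When TRUE, criterion 2 additionally
#'   requires every post-removal sensitivity estimate to be nominally
#'   significant (stricter reading; low-precision methods such as MR-Egger and
#'   the mode often fail it). Default FALSE.
#' @param post_pvals Named p-values for the post-removal estimates; only used
#'   with `require_sensitivity_significance`.
#' @return One-row tibble: the criteria, `loo_flag` and `grade`.
#' @export
grade_evidence <- function(ivw_p, alpha_bonf, estimates,
                           post_estimates = estimates, post_ivw_p = ivw_p,
                           loo_flag = FALSE,
                           require_sensitivity_significance = FALSE,
                           post_pvals = NULL) {
  if (length(estimates) == 0L || !"IVW" %in% names(estimates)) {
    stop("grade_evidence: estimates must include an 'IVW' entry", call. = FALSE)
  }
  ref_sign <- sign(estimates[["IVW"]])
  c1 <- ivw_p < alpha_bonf
  c3 <- all(sign(estimates) == ref_sign)
  c2 <- all(sign(post_estimates) == ref_sign) && post_ivw_p < 0.05
  if (require_sensitivity_significance && !is.null(post_pvals)) {
    c2 <- c2 && all(post_pvals < 0.05)
  }
  nominal <- ivw_p < 0.05
  tibble::tibble(
    ivw_p = ivw_p, alpha_bonf = alpha_bonf,
    criterion1 = c1, criterion2 = c2, criterion3 = c3,
    loo_flag = loo_flag,
    grade = grade_from_criteria(c1, c2, c3, nominal, loo_flag)
  )
}
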