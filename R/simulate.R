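#' Configuration for the summary-statistics simulator
#'
#' Defines the causal structure and GWAS dimensions of a synthetic two-sample
#' (or three-sample mediation) dataset. Effects for binary traits are
#' generated directly on the log-odds scale. Per-variant exposure effects are
#' drawn half-normal, i.e. every variant is oriented to its
#' exposure-increasing allele — the convention under which "directional"
#' pleiotropy is directional on the Wald-ratio scale.
#'
#' Default sample sizes emulate the large consortium GWAS this kind of study
#' draws on: ~450k for a biobank dietary exposure, ~260k for a disease outcome
#' cohort, ~1.33M for a meta-analysed mediator such as insomnia.
#'
#' @param J Number of variants. Default 100.
#' @param n_exp,n_out,n_med GWAS sample sizes (effective n for case-control).
#' @param maf_range Minor-allele-frequency range, drawn uniform. Default
#'   (0.05, 0.5).
#' @param theta True direct exposure-to-outcome effect (log-odds scale).
#' @param a True exposure-to-mediator effect. Default 0 (no mediation).
#' @param b True mediator-to-outcome effect. Default 0.
#' @param pleiotropy_frac Fraction of variants with a direct (pleiotropic)
#'   outcome effect. Default 0.
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters of the pleiotropic
#'   effects: mean 0 is balanced, non-zero mean is directional.
#' @param gamma_sd Scale of the half-normal true variant-exposure effects.
#'   Default 0.03 (strong instruments at biobank sample sizes).
#' @param ld_blocks List of `(size, rho)` pairs partitioning the variants into
#'   AR(1) LD blocks; `NULL` means all variants independent.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(J = 100L, n_exp = 450000L, n_out = 260000L,
                       n_med = 1330000L, maf_range = c(0.05, 0.5),
                       theta = 0.25, a = 0, b = 0,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.02, gamma_sd = 0.03,
                       ld_blocks = NULL, seed = 1L) {
  if (J < 1L) stop("sim_config: J must be >= 1", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    stop("sim_config: maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    stop("sim_config: pleiotropy_frac must be in [0, 1]", call. = FALSE)
  }
  if (any(c(n_exp, n_out, n_med) < 1)) {
    stop("sim_config: sample sizes must be positive", call. = FALSE)
  }
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, function(b) b[[1]], numeric(1))
    if (sum(sizes) != J) {
      stop("sim_config: ld_blocks sizes must sum to J", call. = FALSE)
    }
  }
  structure(list(J = as.integer(J), n_exp = n_exp, n_out = n_out, n_med = n_med,
                 maf_range = maf_range, theta = theta, a = a, b = b,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 gamma_sd = gamma_sd, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# GWAS standard error under the standard approximation for a variant with
# minor-allele frequency maf in a sample of size n.
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Positions: variants laid out on chromosome 1, LD blocks contiguous (10 kb
# spacing) and separated by > 1 Mb so distance-based clumping respects blocks.
sim_positions <- function(J, ld_blocks) {
  if (is.null(ld_blocks)) {
    # independent variants: cycle over 22 chromosomes, spaced beyond any
    # clumping window (keeps positions within integer range for large J)
    i <- seq_len(J) - 1L
    return(list(chrom = as.character(i %% 22L + 1L),
                pos = (i %/% 22L + 1L) * 2000000L))
  }
  sizes <- vapply(ld_blocks, function(b) as.integer(b[[1]]), integer(1))
  pos <- integer(0)
  offset <- 0L
  for (s in sizes) {
    pos <- c(pos, offset + seq_len(s) * 10000L)
    offset <- offset + s * 10000L + 2000000L
  }
  list(chrom = rep("1", J), pos = pos)
}

.make_stats <- function(ids, chrom, pos, eaf, beta, se, n, trait, type) {
  summary_stats(tibble::tibble(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = n
  ), trait_name = trait, trait_type = type)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws minor-allele frequencies uniform on `maf_range`, half-normal true
#' variant-exposure effects \eqn{\gamma_j}, pleiotropic direct effects
#' \eqn{\alpha_j} for a random `pleiotropy_frac` subset, and then observed
#' betas around the truth with the standard GWAS standard errors
#' \eqn{1/\sqrt{2 n \cdot maf(1-maf)}}. The total causal effect is
#' `theta_total = a*b + theta` (the direct effect plus any mediated path).
#' Exposure and outcome noise are independent (two-sample design).
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `exposure` and `outcome` (`summary_stats`) and `truth`
#'   (a `sim_truth` list: `gamma`, `alpha`, `maf`, `theta_total`,
#'   `proportion_true`, plus the config).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    J <- cfg$J
    ids <- sprintf("rs%05d", seq_len(J))
    loc <- sim_positions(J, cfg$ld_blocks)
    maf <- runif(J, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- abs(rnorm(J, 0, cfg$gamma_sd))
    alpha <- rep(0, J)
    k <- round(cfg$pleiotropy_frac * J)
    if (k > 0) {
      idx <- sample.int(J, k)
      alpha[idx] <- rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }
    theta_total <- cfg$a * cfg$b + cfg$theta
    se_x <- gwas_se(cfg$n_exp, maf)
    se_y <- gwas_se(cfg$n_out, maf)
    bx <- rnorm(J, gamma, se_x)
    by <- rnorm(J, theta_total * gamma + alpha, se_y)

    exposure <- .make_stats(ids, loc$chrom, loc$pos, maf, bx, se_x,
                            cfg$n_exp, "sim_exposure", "continuous")
    outcome <- .make_stats(ids, loc$chrom, loc$pos, maf, by, se_y,
                           cfg$n_out, "sim_outcome", "binary")
    truth <- structure(list(
      gamma = gamma, alpha = alpha, maf = maf,
      theta_total = theta_total,
      proportion_true = if (theta_total != 0) cfg$a * cfg$b / theta_total else NA_real_,
      cfg = cfg
    ), class = "sim_truth")
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate an exposure–mediator–outcome summary-statistics triplet
#'
#' Extends [simulate_two_sample()] with a mediator on the causal path
#' exposure -> mediator -> outcome. The panel holds `2 * J` variants: `J`
#' exposure instruments (effects \eqn{\gamma_j} on the exposure,
#' \eqn{a\gamma_j} on the mediator, \eqn{(ab+\theta)\gamma_j + \alpha_j} on
#' the outcome) and `J` mediator-specific instruments (half-normal effects
#' \eqn{\delta_j} on the mediator only, \eqn{b\delta_j} on the outcome) so the
#' mediator has its own instruments for the multivariable step. The three
#' studies use independent noise draws (three non-overlapping samples).
#'
#' @param cfg A [sim_config()] with `a` and `b` set.
#' @return A list with `exposure`, `mediator`, `outcome` (`summary_stats` over
#'   the 2J variants) and `truth` (includes `delta` and `proportion_true =
#'   a*b/(a*b + theta)`).
#' @export
simulate_mediation_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    J <- cfg$J
    J2 <- 2L * J
    ids <- sprintf("rs%05d", seq_len(J2))
    i2 <- seq_len(J2) - 1L
    loc <- list(chrom = as.character(i2 %% 22L + 1L),
                pos = (i2 %/% 22L + 1L) * 2000000L)
    maf <- runif(J2, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- c(abs(rnorm(J, 0, cfg$gamma_sd)), rep(0, J))       # exposure effects
    delta <- c(rep(0, J), abs(rnorm(J, 0, cfg$gamma_sd)))       # mediator-specific
    alpha <- rep(0, J2)
    k <- round(cfg$pleiotropy_frac * J)
    if (k > 0) {
      idx <- sample.int(J, k)   # pleiotropy among the exposure instruments
      alpha[idx] <- rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }
    theta_total <- cfg$a * cfg$b + cfg$theta
    mu_x <- gamma
    mu_m <- cfg$a * gamma + delta
    mu_y <- theta_total * gamma + cfg$b * delta + alpha
    se_x <- gwas_se(cfg$n_exp, maf)
    se_m <- gwas_se(cfg$n_med, maf)
    se_y <- gwas_se(cfg$n_out, maf)

    exposure <- .make_stats(ids, loc$chrom, loc$pos, maf,
                            rnorm(J2, mu_x, se_x), se_x, cfg$n_exp,
                            "sim_exposure", "continuous")
    mediator <- .make_stats(ids, loc$chrom, loc$pos, maf,
                            rnorm(J2, mu_m, se_m), se_m, cfg$n_med,
                            "sim_mediator", "binary")
    outcome <- .make_stats(ids, loc$chrom, loc$pos, maf,
                           rnorm(J2, mu_y, se_y), se_y, cfg$n_out,
                           "sim_outcome", "binary")
    truth <- structure(list(
      gamma = gamma, delta = delta, alpha = alpha, maf = maf,
      theta_total = theta_total,
      proportion_true = if (theta_total != 0) cfg$a * cfg$b / theta_total else NA_real_,
      cfg = cfg
    ), class = "sim_truth")
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth)
  })
}

#' Simulate a block-diagonal LD panel
#'
#' Builds an r-squared matrix with AR(1) within-block structure: for variants
#' `i`, `j` in a block with parameter `rho`, \eqn{r^2_{ij} = \rho^{2|i-j|}};
#' zero across blocks; unit diagonal.
#'
#' @param cfg A [sim_config()] whose `ld_blocks` partition its `J` variants.
#' @return An [ld_panel()] over the same variant ids as
#'   [simulate_two_sample()] produces.
#' @export
simulate_ld_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$ld_blocks)) {
    r2 <- diag(cfg$J)
  } else {
    sizes <- vapply(cfg$ld_blocks, function(b) as.integer(b[[1]]), integer(1))
    if (sum(sizes) != cfg$J) stop("simulate_ld_panel: block sizes must sum to J",
                                  call. = FALSE)
    rhos <- vapply(cfg$ld_blocks, function(b) as.numeric(b[[2]]), numeric(1))
    blocks <- purrr::map2(sizes, rhos, function(s, rho) {
      d <- abs(outer(seq_len(s), seq_len(s), "-"))
      (rho^d)^2
    })
    r2 <- matrix(0, cfg$J, cfg$J)
    off <- 0L
    for (b in blocks) {
      s <- nrow(b)
      r2[off + seq_len(s), off + seq_len(s)] <- b
      off <- off + s
    }
  }
  ld_panel(r2, variant_ids = sprintf("rs%05d", seq_len(cfg$J)))
}
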