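# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (normal equations, grids, exhaustive greedy)
# and never call the implementation paths they check.

make_stats <- function(variant_id, beta, se, pval = NULL,
                       chrom = "1", pos = NULL,
                       ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                       trait = "trait", type = "continuous") {
  J <- length(variant_id)
  if (is.null(pos)) pos <- seq_len(J) * 2e6L
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  summary_stats(tibble::tibble(
    variant_id = variant_id,
    chrom = rep_len(chrom, J), pos = pos,
    effect_allele = rep_len(ea, J), other_allele = rep_len(oa, J),
    eaf = rep_len(eaf, J), beta = beta, se = se, pval = pval,
    n = rep_len(n, J)
  ), trait_name = trait, trait_type = type)
}

# Harmonized set directly from beta/SE vectors (already aligned).
make_h <- function(bx, sx, by, sy, ids = sprintf("rs%03d", seq_along(bx))) {
  ex <- make_stats(ids, bx, sx, trait = "exposure")
  ou <- make_stats(ids, by, sy, trait = "outcome", type = "binary")
  harmonize(ex, ou)
}

# --- Oracles ----------------------------------------------------------------

# Weighted least squares through the normal equations, no shortcuts.
oracle_wls <- function(X, y, w) {
  A <- matrix(0, ncol(X), ncol(X))
  b <- numeric(ncol(X))
  for (i in seq_len(nrow(X))) {
    A <- A + w[i] * (X[i, ] %o% X[i, ])
    b <- b + w[i] * X[i, ] * y[i]
  }
  beta <- solve(A, b)
  rss <- sum(w * (y - as.vector(X %*% beta))^2)
  list(beta = beta, cov = solve(A), rss = rss)
}

# Weighted median by fine-grid inversion of the piecewise-linear weighted CDF
# through the cumulative midpoint weights (computed by hand, no approx()).
oracle_weighted_median <- function(theta, w, grid_n = 200001L) {
  ord <- order(theta)
  th <- theta[ord]; ww <- w[ord]
  p <- (cumsum(ww) - ww / 2) / sum(ww)
  if (p[1] >= 0.5) return(th[1])
  if (p[length(p)] <= 0.5) return(th[length(th)])
  grid <- seq(min(th), max(th), length.out = grid_n)
  cdf <- vapply(grid, function(m) {
    j <- max(which(th <= m))
    if (j == length(th)) return(p[j])
    if (th[j + 1] == th[j]) return(p[j + 1])
    p[j] + (m - th[j]) / (th[j + 1] - th[j]) * (p[j + 1] - p[j])
  }, numeric(1))
  grid[which.min(abs(cdf - 0.5))]
}

# Mode oracle: same bandwidth rule, independent dense-grid KDE maximisation.
oracle_mode <- function(theta, w, phi = 1, grid_n = 20000L) {
  s <- phi * 0.9 * min(sd(theta), mad(theta)) * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * s, max(theta) + 3 * s, length.out = grid_n)
  dens <- sapply(grid, function(g) sum(w * exp(-(g - theta)^2 / (2 * s^2))))
  grid[which.max(dens)]
}

# Exhaustive greedy clump: re-derives the index set from scratch each round.
oracle_clump <- function(stats, panel, window_bp = 1e6, r2_max = 0.001) {
  ids <- stats$variant_id
  alive <- rep(TRUE, length(ids))
  picked <- character(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(stats$pval[cand], stats$variant_id[cand])][1]
    picked <- c(picked, stats$variant_id[best])
    for (j in which(alive)) {
      if (j == best) next
      same_chr <- stats$chrom[j] == stats$chrom[best]
      near <- abs(stats$pos[j] - stats$pos[best]) <= window_bp
      r2 <- panel$r2[stats$variant_id[best], stats$variant_id[j]]
      if (same_chr && near && r2 > r2_max) alive[j] <- FALSE
    }
    alive[best] <- FALSE
  }
  picked
}

# Numerical-gradient Delta-method variance for g(a, b) with independent SEs.
oracle_delta_var <- function(g, pars, ses, eps = 1e-6) {
  grad <- vapply(seq_along(pars), function(i) {
    up <- pars; up[i] <- up[i] + eps
    dn <- pars; dn[i] <- dn[i] - eps
    (g(up) - g(dn)) / (2 * eps)
  }, numeric(1))
  sum(grad^2 * ses^2)
}
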