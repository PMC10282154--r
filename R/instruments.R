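#' Construct an LD reference panel
#'
#' Holds squared correlations (r-squared) between variants, as estimated from a
#' reference population. Supplied as an explicit matrix so that clumping is
#' fully deterministic and needs no genotype data.
#'
#' @param r2 Square symmetric numeric matrix of squared correlations with unit
#'   diagonal and values in `[0, 1]`.
#' @param variant_ids Character vector naming rows/columns; taken from
#'   `rownames(r2)` when omitted.
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("ld_panel: variant ids required", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(variant_ids)) {
    stop("ld_panel: r2 must be square with one row per variant id", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("ld_panel: r2 must be symmetric", call. = FALSE)
  if (any(r2 < -1e-12) || any(r2 > 1 + 1e-12)) {
    stop("ld_panel: r2 values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("ld_panel: diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("<ld_panel> ", length(x$variant_ids), " variants\n", sep = "")
  invisible(x)
}

#' Read an LD panel from a square TSV matrix
#'
#' Expects a header row of variant ids and a first column of variant ids.
#' @param path File path.
#' @return An `ld_panel`.
#' @export
read_ld_panel <- function(path) {
  m <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  ld_panel(as.matrix(m), variant_ids = rownames(m))
}

#' Write an LD panel to a square TSV matrix
#' @param panel An `ld_panel`.
#' @param path File path.
#' @export
write_ld_panel <- function(panel, path) {
  df <- data.frame(variant_id = panel$variant_ids, panel$r2, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter summary statistics by p-value
#'
#' Keeps variants with association p-value strictly below `threshold`,
#' preserving input order. The default threshold of 5e-6 is the relaxed
#' genome-wide threshold commonly used to improve instrument power for
#' behavioural traits.
#'
#' @param stats A `summary_stats` tibble.
#' @param threshold P-value cutoff in (0, 1). Default `5e-6`.
#' @return A `summary_stats` tibble (possibly empty, with a warning).
#' @export
select_by_pvalue <- function(stats, threshold = 5e-6) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("select_by_pvalue: threshold must be in (0, 1)", call. = FALSE)
  }
  keep <- which(stats$pval < threshold)
  if (length(keep) == 0L) {
    warning("select_by_pvalue: no variants pass p < ", format(threshold),
            " for '", trait_name(stats), "'", call. = FALSE)
  }
  out <- tibble::as_tibble(stats)[keep, , drop = FALSE]
  structure(out,
            trait_name = trait_name(stats), trait_type = trait_type(stats),
            n_dropped = attr(stats, "n_dropped"),
            class = class(stats))
}

#' Greedy LD clumping
#'
#' Selects an LD-independent set of index variants: repeatedly take the
#' remaining variant with the smallest p-value (ties broken by variant id,
#' lexicographically), then remove every remaining variant on the same
#' chromosome within `window_bp` whose r-squared with it exceeds `r2_max`.
#' Cross-chromosome pairs are never pruned. The defaults (1 Mb, r² 0.001)
#' give near-independent instruments.
#'
#' @param stats A `summary_stats` tibble (typically already p-value filtered).
#' @param panel An [ld_panel()] covering every variant in `stats`, or `NULL`
#'   for variants known to be mutually independent (no pruning occurs).
#' @param window_bp Clumping distance in base pairs. Default 1e6.
#' @param r2_max Maximum allowed squared correlation. Default 0.001.
#' @return A `summary_stats` tibble of index variants, in selection order
#'   (most significant first).
#' @export
ld_clump <- function(stats, panel = NULL, window_bp = 1e6, r2_max = 0.001) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats) == 0L) return(stats)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "ld_panel"))
    missing_v <- setdiff(stats$variant_id, panel$variant_ids)
    if (length(missing_v) > 0L) {
      stop("ld_clump: variant(s) absent from LD panel: ",
           paste(utils::head(missing_v, 5L), collapse = ", "), call. = FALSE)
    }
  }
  # deterministic processing order: ascending p, ties by variant_id
  ord <- order(stats$pval, stats$variant_id)
  remaining <- ord
  picked <- integer(0)
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    picked <- c(picked, i)
    remaining <- remaining[-1L]
    if (length(remaining) > 0L) {
      near <- stats$chrom[remaining] == stats$chrom[i] &
        abs(stats$pos[remaining] - stats$pos[i]) <= window_bp
      if (!is.null(panel) && any(near)) {
        r2 <- panel$r2[stats$variant_id[i], stats$variant_id[remaining]]
        prune <- near & r2 > r2_max
      } else {
        prune <- rep(FALSE, length(remaining))
      }
      remaining <- remaining[!prune]
    }
  }
  out <- tibble::as_tibble(stats)[picked, , drop = FALSE]
  structure(out,
            trait_name = trait_name(stats), trait_type = trait_type(stats),
            n_dropped = attr(stats, "n_dropped"),
            class = class(stats))
}

#' Instrument-strength F statistics
#'
#' Per-SNP F statistic from the summary-data approximation
#' \eqn{F_j = (\beta_{Xj}/SE_{Xj})^2}, their mean, and the conventional
#' weak-instrument flag (mean F strictly below 10).
#'
#' @param h A `harmonized_set` (uses `bx`, `sx`), or a `summary_stats`
#'   (uses `beta`, `se`).
#' @return A list with `per_snp` (tibble of `variant_id`, `F`), `mean_F`,
#'   and `weak` (logical).
#' @export
f_statistics <- function(h) {
  if (inherits(h, "harmonized_set")) {
    b <- h$bx; s <- h$sx
  } else if (inherits(h, "summary_stats")) {
    b <- h$beta; s <- h$se
  } else {
    stop("f_statistics: need a harmonized_set or summary_stats", call. = FALSE)
  }
  if (length(b) == 0L) stop("f_statistics: empty instrument set", call. = FALSE)
  f <- (b / s)^2
  list(per_snp = tibble::tibble(variant_id = h$variant_id, F = f),
       mean_F = mean(f),
       weak = mean(f) < 10)
}
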