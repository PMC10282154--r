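#' Construct a summary-statistics table
#'
#' Wraps a data frame of per-variant GWAS association records into a validated
#' `summary_stats` tibble. One row per variant: identifier, location, alleles,
#' effect-allele frequency, effect estimate with its standard error, p-value
#' and sample size. For binary traits `beta` is on the log-odds scale; for
#' continuous traits it is in trait units or SD.
#'
#' Rows with missing `beta` or non-positive `se` are dropped (the number
#' dropped is kept in the `n_dropped` attribute). Alleles are upper-cased.
#'
#' @param data Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` may be `NA`.
#' @param trait_name Character scalar naming the trait.
#' @param trait_type `"binary"` or `"continuous"`.
#' @return A tibble of class `summary_stats` with attributes `trait_name`,
#'   `trait_type` and `n_dropped`.
#' @export
#' @examples
#' ss <- summary_stats(
#'   tibble::tibble(
#'     variant_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'     effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'     eaf = c(0.3, 0.4), beta = c(0.1, -0.05), se = c(0.02, 0.02),
#'     pval = c(1e-7, 0.01), n = 10000L
#'   ),
#'   trait_name = "coffee intake", trait_type = "continuous"
#' )
summary_stats <- function(data, trait_name, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("summary_stats: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)[required]
  out$variant_id <- as.character(out$variant_id)
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))

  bad <- is.na(out$beta) | is.na(out$se) | out$se <= 0
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  if (anyDuplicated(out$variant_id)) {
    stop("summary_stats: duplicate variant_id in '", trait_name, "'", call. = FALSE)
  }
  if (any(out$effect_allele == out$other_allele)) {
    stop("summary_stats: effect_allele equals other_allele for some variants",
         call. = FALSE)
  }
  structure(out,
            trait_name = trait_name,
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("summary_stats", class(tibble::tibble())))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> trait: ", attr(x, "trait_name"),
      " (", attr(x, "trait_type"), "), ", nrow(x), " variants\n", sep = "")
  NextMethod()
}

#' Name and type of the trait behind a summary-statistics table
#' @param x A `summary_stats` object.
#' @return Character scalar.
#' @export
trait_name <- function(x) attr(x, "trait_name")

#' @rdname trait_name
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' Default column mapping for summary-statistics files
#'
#' Maps the internal field names to the column headers conventionally used in
#' GWAS summary files. Override individual entries when reading files with
#' different headers.
#' @return Named character vector (internal name -> file column).
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header row, renames columns via
#' `column_map`, and validates the result with [summary_stats()]. Rows with
#' missing beta or non-positive SE are dropped and counted.
#'
#' @param path File path.
#' @param trait_name Trait label; defaults to the file name without extension.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param column_map Named character vector mapping internal names
#'   (see [default_column_map()]) to the file's column headers. Entries you
#'   supply override the defaults.
#' @param delim Field delimiter; guessed from the file extension by default
#'   (`.csv` -> comma, otherwise tab).
#' @return A `summary_stats` tibble.
#' @export
read_summary_stats <- function(path, trait_name = NULL,
                               trait_type = c("binary", "continuous"),
                               column_map = NULL, delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("read_summary_stats: file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(trait_name)) trait_name <- sub("\\.[^.]*$", "", basename(path))

  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) stop("read_summary_stats: empty file: ", path, call. = FALSE)
  mandatory <- setdiff(names(map), "eaf")
  absent <- map[mandatory][!map[mandatory] %in% names(raw)]
  if (length(absent) > 0L) {
    stop("read_summary_stats: mandatory column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    variant_id = raw[[map["variant_id"]]],
    chrom = raw[[map["chrom"]]],
    pos = raw[[map["pos"]]],
    effect_allele = raw[[map["effect_allele"]]],
    other_allele = raw[[map["other_allele"]]],
    eaf = if (map["eaf"] %in% names(raw)) as.numeric(raw[[map["eaf"]]]) else NA_real_,
    beta = as.numeric(raw[[map["beta"]]]),
    se = as.numeric(raw[[map["se"]]]),
    pval = as.numeric(raw[[map["pval"]]]),
    n = raw[[map["n"]]]
  )
  summary_stats(out, trait_name = trait_name, trait_type = trait_type)
}

# DNA complement for strand flips
.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two studies to a shared variant list and a common effect allele so
#' that, for every retained variant, the outcome beta is expressed per copy of
#' the exposure's effect allele.
#'
#' Variants are matched by id. If the outcome alleles are swapped relative to
#' the exposure, the outcome beta sign is flipped and its frequency replaced by
#' `1 - eaf`; if the alleles match only after strand complement, the complement
#' is taken first and the same rule applied. Palindromic variants (A/T or C/G),
#' whose strand cannot be resolved from the alleles, are oriented by allele
#' frequency when both studies report a frequency outside the ambiguity window
#' `[0.5 - palindromic_eaf_window, 0.5 + palindromic_eaf_window]`, and dropped
#' (reason `"palindromic_ambiguous"`) otherwise. Variants whose alleles cannot
#' be reconciled are dropped with reason `"allele_mismatch"`.
#'
#' @param exposure,outcome `summary_stats` tibbles.
#' @param palindromic_eaf_window Half-width of the frequency window around 0.5
#'   within which a palindromic variant is considered ambiguous. Default 0.08.
#' @return A tibble of class `harmonized_set` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `bx`, `sx`,
#'   `px`, `by`, `sy`, `py`; attributes `exposure_name`, `outcome_name` and
#'   `dropped` (a tibble of `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L) {
    stop("harmonize: no shared variants between '", trait_name(exposure),
         "' and '", trait_name(outcome), "'", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  ea_yc <- unname(.complement[ea_y]); oa_yc <- unname(.complement[oa_y])

  pal <- .is_palindromic(ea_x, oa_x)
  same    <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  csame    <- !is.na(ea_yc) & ea_yc == ea_x & oa_yc == oa_x
  cswapped <- !is.na(ea_yc) & ea_yc == oa_x & oa_yc == ea_x

  flip <- rep(NA, length(shared))      # NA = unmatchable
  flip[same | csame] <- FALSE
  flip[swapped | cswapped] <- TRUE

  # palindromic: allele labels cannot distinguish strand from swap; orient by
  # allele frequency instead
  pal_ok <- pal & (same | swapped)   # same allele pair (complement is the same set)
  if (any(pal_ok)) {
    fx <- ex$eaf[pal_ok]; fy <- ou$eaf[pal_ok]
    lo <- 0.5 - palindromic_eaf_window; hi <- 0.5 + palindromic_eaf_window
    informative <- !is.na(fx) & !is.na(fy) &
      (fx < lo | fx > hi) & (fy < lo | fy > hi)
    pal_flip <- rep(NA, sum(pal_ok))
    # frequencies on opposite sides of 0.5 mean the outcome's effect allele is
    # the exposure's other allele (after any strand flip)
    pal_flip[informative] <- (fx[informative] < 0.5) != (fy[informative] < 0.5)
    flip[pal_ok] <- pal_flip
  }
  flip[pal & !pal_ok] <- NA

  reason <- rep(NA_character_, length(shared))
  reason[is.na(flip) & pal_ok] <- "palindromic_ambiguous"
  reason[is.na(flip) & !pal_ok] <- "allele_mismatch"
  keep <- !is.na(flip)

  by <- ifelse(flip, -ou$beta, ou$beta)
  h <- tibble::tibble(
    variant_id = shared,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ea_x, other_allele = oa_x,
    eaf = ex$eaf,
    bx = ex$beta, sx = ex$se, px = ex$pval,
    by = by, sy = ou$se, py = ou$pval
  )[keep, ]
  dropped <- tibble::tibble(variant_id = shared[!keep], reason = reason[!keep])

  structure(h,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            dropped = dropped,
            class = c("harmonized_set", class(tibble::tibble())))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set> ", attr(x, "exposure_name"), " -> ",
      attr(x, "outcome_name"), ": ", nrow(x), " variants (",
      nrow(attr(x, "dropped")), " dropped)\n", sep = "")
  NextMethod()
}

# Rebuild a harmonized_set from a row subset, keeping attributes. Used by
# leave-one-out, outlier removal and clump-to-instruments plumbing.
subset_harmonized <- function(h, idx) {
  out <- tibble::as_tibble(h)[idx, , drop = FALSE]
  structure(out,
            exposure_name = attr(h, "exposure_name"),
            outcome_name = attr(h, "outcome_name"),
            dropped = attr(h, "dropped"),
            class = c("harmonized_set", class(tibble::tibble())))
}

#' Variants dropped during harmonization
#' @param h A `harmonized_set`.
#' @return Tibble with columns `variant_id` and `reason`.
#' @export
harmonization_drops <- function(h) attr(h, "dropped")
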