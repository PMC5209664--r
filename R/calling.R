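#' Estimate bisulfite conversion error from the lambda spike-in
#'
#' The unmethylated lambda phage spike-in calibrates the error background
#' for methylation calling: every read base reported methylated at a lambda
#' cytosine is either a bisulfite conversion failure or a T-to-C sequencing
#' error. The non-conversion rate is the pooled methylated-read fraction
#' over all lambda cytosines; the T-C error rate is not estimable from the
#' spike-in and is supplied as configuration. The combined per-read error
#' probability used by the binomial caller is
#' `p_error = 1 - (1 - nonconversion_rate) * (1 - tc_error_rate)`.
#'
#' @param lambda_records Cytosine table of spike-in records, or a full
#'   sample table from which rows with `chrom == lambda_chrom` are taken.
#' @param tc_error_rate Assumed T-to-C sequencing error rate (default
#'   0.001).
#' @param lambda_chrom Spike-in contig name (default `"lambda"`).
#' @param min_total_coverage Minimum pooled lambda coverage required for a
#'   stable estimate (default 100).
#' @return An object of class `conversion_estimate`: a list with
#'   `nonconversion_rate`, `tc_error_rate`, `p_error`, `lambda_coverage`.
#' @export
estimate_conversion <- function(lambda_records, tc_error_rate = 0.001,
                                lambda_chrom = "lambda",
                                min_total_coverage = 100L) {
  tab <- as.data.table(lambda_records)
  if (lambda_chrom %in% tab$chrom) tab <- tab[chrom == lambda_chrom]
  total <- sum(tab$meth + tab$unmeth)
  if (total == 0L)
    stopf("calibration error: zero lambda spike-in coverage")
  if (total < min_total_coverage)
    stopf("calibration error: pooled lambda coverage %d < %d",
          total, min_total_coverage)
  nc <- sum(tab$meth) / total
  est <- list(nonconversion_rate = nc,
              tc_error_rate = tc_error_rate,
              p_error = 1 - (1 - nc) * (1 - tc_error_rate),
              lambda_coverage = total)
  class(est) <- "conversion_estimate"
  est
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf(
    "conversion estimate: non-conversion %.5f, T-C error %.5f, p_error %.5f (lambda coverage %d)\n",
    x$nonconversion_rate, x$tc_error_rate, x$p_error, x$lambda_coverage))
  invisible(x)
}

#' Call per-cytosine methylation status
#'
#' One-sided binomial test per cytosine against the conversion-error
#' background: `p = P(X >= meth | coverage, p_error)`. P-values are
#' corrected across all callable sites with Benjamini-Hochberg, and a site
#' is called methylated when its q-value is at most `fpr`, so the expected
#' proportion of false methylation calls among truly unmethylated sites is
#' controlled below `fpr`. Sites with coverage below `min_coverage` are
#' uncallable (status `NA`). A raw per-site threshold mode is available for
#' sensitivity analysis.
#'
#' @param table Cytosine table (one sample).
#' @param est A `conversion_estimate` from [estimate_conversion()].
#' @param fpr Target false-positive control level (default 0.05).
#' @param min_coverage Minimum coverage to call a site (default 3).
#' @param method `"fdr"` (Benjamini-Hochberg, default) or `"raw"` (per-site
#'   p-value threshold).
#' @return A `data.table` with `chrom, pos, strand, context, coverage,
#'   status` (`"M"`, `"U"` or `NA`), `p`, `q`.
#' @export
call_methylation_status <- function(table, est, fpr = 0.05,
                                    min_coverage = 3L,
                                    method = c("fdr", "raw")) {
  method <- match.arg(method)
  stopifnot(inherits(est, "conversion_estimate"))
  tab <- as.data.table(table)
  out <- tab[, .(chrom, pos, strand,
                 context = if ("context" %in% names(tab)) context else
                   NA_character_,
                 coverage = meth + unmeth, meth)]
  out[, p := NA_real_]
  callable <- out$coverage >= min_coverage
  out$p[callable] <- pbinom(out$meth[callable] - 1L, out$coverage[callable],
                            est$p_error, lower.tail = FALSE)
  out[, q := NA_real_]
  out$q[callable] <- p.adjust(out$p[callable], method = "BH")
  crit <- if (method == "fdr") out$q else out$p
  out[, status := ifelse(callable, ifelse(crit <= fpr, "M", "U"),
                         NA_character_)]
  out[, meth := NULL]
  out[]
}

#' Per-site methylation status matrix across samples
#'
#' Runs [call_methylation_status()] on each sample and joins the calls on
#' `(chrom, pos, strand)`, producing the per-site, per-sample status matrix
#' consumed by [call_smps()].
#'
#' @param tables Named list of cytosine tables (names are sample labels).
#' @param est A shared `conversion_estimate`, or a named list of per-sample
#'   estimates.
#' @param sites Optional site table (e.g. from [build_eligible_set()]) to
#'   restrict to.
#' @inheritParams call_methylation_status
#' @return A `data.table` keyed by `(chrom, pos, strand)` with one
#'   `status.<sample>` column per sample.
#' @export
status_matrix <- function(tables, est, fpr = 0.05, min_coverage = 3L,
                          sites = NULL, method = c("fdr", "raw")) {
  method <- match.arg(method)
  stopifnot(is.list(tables), !is.null(names(tables)))
  keys <- c("chrom", "pos", "strand")
  out <- NULL
  for (nm in names(tables)) {
    e <- if (inherits(est, "conversion_estimate")) est else est[[nm]]
    calls <- call_methylation_status(tables[[nm]], e, fpr = fpr,
                                     min_coverage = min_coverage,
                                     method = method)
    col <- calls[, c(keys, "status"), with = FALSE]
    setnames(col, "status", paste0("status.", nm))
    out <- if (is.null(out)) col else
      merge(out, col, by = keys, all = TRUE, sort = FALSE)
  }
  if (!is.null(sites))
    out <- merge(as.data.table(sites)[, keys, with = FALSE], out,
                 by = keys, all.x = TRUE, sort = FALSE)
  setorderv(out, keys)
  out[]
}

#' Methylation level of a cytosine or a region
#'
#' The methylation level of a single cytosine is the proportion of reads
#' showing methylation among all reads covering it. The level of a region
#' is the unweighted mean of the per-site levels over its covered
#' cytosines — not the read-pooled ratio (sites with levels 0.9 and 0.0
#' give 0.45 regardless of their coverages). A read-pooled mode is
#' available for comparison.
#'
#' @param meth,unmeth Integer vectors of methylated/unmethylated read
#'   counts, one element per cytosine in the region (length-1 input gives
#'   the single-site level).
#' @param pooled If `TRUE`, return `sum(meth)/sum(meth + unmeth)` instead
#'   of the mean of site levels.
#' @return A level in \[0, 1\]. Signals an error when no site has coverage.
#' @export
methylation_level <- function(meth, unmeth, pooled = FALSE) {
  stopifnot(length(meth) == length(unmeth))
  cov <- meth + unmeth
  covered <- cov > 0
  if (!any(covered))
    stopf("methylation level undefined: no covered cytosines")
  if (pooled) return(sum(meth[covered]) / sum(cov[covered]))
  mean(meth[covered] / cov[covered])
}

#' Methylation density of a region
#'
#' The proportion of methylated cytosines among the cytosines of a region.
#' By default the denominator counts callable cytosines only (uncallable
#' sites would otherwise deflate density as a function of sequencing
#' depth); `denominator = "all"` gives the strict all-cytosines reading.
#'
#' @param status Character vector of per-site calls (`"M"`, `"U"`, `NA`)
#'   for the cytosines in the region.
#' @param denominator `"callable"` (default) or `"all"`.
#' @return A density in \[0, 1\]; error when the denominator is empty.
#' @export
methylation_density <- function(status, denominator = c("callable", "all")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "callable") sum(!is.na(status)) else length(status)
  if (den == 0L)
    stopf("methylation density undefined: no cytosines in denominator")
  sum(status == "M", na.rm = TRUE) / den
}

#' Methylation level from MSRE-qPCR Ct values
#'
#' Methylation-sensitive restriction enzyme qPCR validation: the level of
#' the assayed site is `2^(-ddCt) * 100` percent, with
#' `ddCt = Ct(digested) - Ct(undigested)`. Values above 100 percent (from
#' negative `ddCt`) are returned as computed, with a warning.
#'
#' @param ct_digested,ct_undigested Ct values of the digested and
#'   undigested products.
#' @return Methylation level in percent.
#' @export
#' @examples
#' msre_qpcr_level(21, 20)  # ddCt = 1 -> 50
msre_qpcr_level <- function(ct_digested, ct_undigested) {
  stopifnot(is.finite(ct_digested), is.finite(ct_undigested))
  ddct <- ct_digested - ct_undigested
  lvl <- 2^(-ddct) * 100
  if (any(lvl > 100))
    warnf("MSRE-qPCR level above 100%% (negative delta-delta-Ct)")
  lvl
}
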