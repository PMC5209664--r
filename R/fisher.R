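#' Vectorized Fisher's exact test for 2x2 count tables
#'
#' Exact hypergeometric test for many 2x2 tables at once, as used per
#' cytosine (methylated vs unmethylated reads in two samples) and per
#' sliding window (pooled counts in two groups). The two-sided p-value is
#' the sum of hypergeometric point probabilities not exceeding that of the
#' observed table (the same definition as [stats::fisher.test()], which
#' this function matches and which serves as its reference in the test
#' suite); one-sided alternatives are exact tail probabilities.
#'
#' Table layout per element: rows are groups, columns are (methylated,
#' unmethylated): \code{rbind(c(a, b), c(c, d))}.
#'
#' @param a,b,c,d Integer vectors of equal length: methylated and
#'   unmethylated counts in group 1 (`a`, `b`) and group 2 (`c`, `d`).
#' @param alternative `"two.sided"` (default), `"greater"` (group 1 more
#'   methylated) or `"less"`.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
#' @examples
#' fisher_exact_2x2(9, 1, 1, 9)
#' stats::fisher.test(rbind(c(9, 1), c(1, 9)))$p.value
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (!n) return(numeric())
  if (any(c(a, b, c, d) < 0, na.rm = TRUE))
    stopf("negative counts in 2x2 table")
  n1 <- a + b          # group-1 margin
  n2 <- c + d          # group-2 margin
  K  <- a + c          # methylated margin
  if (alternative == "greater")
    return(phyper(a - 1, n1, n2, K, lower.tail = FALSE))
  if (alternative == "less")
    return(phyper(a, n1, n2, K))
  lo <- pmax(0L, K - n2)
  hi <- pmin(K, n1)
  len <- hi - lo + 1L
  idx <- rep.int(seq_len(n), len)
  kk <- sequence(len) - 1L + rep.int(lo, len)
  dk <- dhyper(kk, n1[idx], n2[idx], K[idx])
  dobs <- dhyper(a, n1, n2, K)
  # relative tolerance guards against ties lost to floating point,
  # mirroring fisher.test()
  keep <- dk <= dobs[idx] * (1 + 1e-7)
  # every table contributes at least one term, so rowsum covers 1..n in order
  p <- rowsum(dk * keep, idx, reorder = TRUE)[, 1]
  unname(pmin(p, 1))
}
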