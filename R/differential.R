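#' Call differentially methylated positions (DMPs)
#'
#' Per eligible cytosine, Fisher's exact test compares methylated vs
#' unmethylated read counts between the two groups. In the default
#' `combine = "cross_pair"` mode the four cross-group replicate pairings
#' (g1 rep i vs g2 rep j) are each tested and combined conservatively by
#' Bonferroni: `combined_p = min(4 p-values) * 4`, capped at 1. A site is a
#' candidate when `combined_p < p_thresh` \emph{and} neither within-group
#' replicate-vs-replicate test is significant at `p_thresh` (sites where
#' siblings disagree are filtered out). The genome-wide false discovery
#' rate is controlled by Benjamini-Hochberg across the combined p-values
#' of \emph{all} tested eligible sites; candidates with `q <= fdr` are
#' reported. Direction is `hyper` when the pooled level of group 1 exceeds
#' that of group 2.
#'
#' @param tables Named list of cytosine tables covering both groups.
#' @param g1,g2 [group_spec()]s (group 1 is reported relative to group 2).
#' @param eligible Eligible-site universe from [build_eligible_set()].
#' @param p_thresh Per-site combined p-value threshold (default 0.01),
#'   also used by the replicate filter.
#' @param fdr Benjamini-Hochberg level across candidate sites (default
#'   0.05).
#' @param combine `"cross_pair"` (default) or `"pooled"` (single test on
#'   replicate-pooled counts; the replicate filter still applies).
#' @param alternative Passed to [fisher_exact_2x2()]; default two-sided.
#' @return A `data.table` of class `dmp_set`: `chrom, pos, strand,
#'   context, direction` (`hyper`/`hypo`), `combined_p`, `q`, `level1`,
#'   `level2`.
#' @export
call_dmps <- function(tables, g1, g2, eligible, p_thresh = 0.01,
                      fdr = 0.05, combine = c("cross_pair", "pooled"),
                      alternative = "two.sided") {
  combine <- match.arg(combine)
  stopifnot(inherits(g1, "group_spec"), inherits(g2, "group_spec"))
  samples <- c(g1$samples, g2$samples)
  missing_s <- setdiff(samples, names(tables))
  if (length(missing_s))
    stopf("samples absent from tables: %s", paste(missing_s, collapse = ", "))
  keys <- c("chrom", "pos", "strand")
  wide <- as.data.table(eligible)[, keys, with = FALSE]
  n_univ <- nrow(wide)
  ctx <- NULL
  for (i in seq_along(samples)) {
    tab <- as.data.table(tables[[samples[i]]])
    cols <- tab[, c(keys, "meth", "unmeth",
                    if (is.null(ctx) && "context" %in% names(tab)) "context"),
                with = FALSE]
    setnames(cols, c("meth", "unmeth"),
             paste0(c("m", "u"), i))
    wide <- merge(wide, cols, by = keys, sort = FALSE)
    ctx <- ctx %||% "context"
  }
  skipped <- n_univ - nrow(wide)
  if (skipped > 0)
    message(sprintf("call_dmps: %d eligible sites absent from a sample table, skipped", skipped))
  if (!nrow(wide)) return(empty_dmp_set())
  m1 <- wide$m1; u1 <- wide$u1; m2 <- wide$m2; u2 <- wide$u2
  m3 <- wide$m3; u3 <- wide$u3; m4 <- wide$m4; u4 <- wide$u4
  if (combine == "cross_pair") {
    p11 <- fisher_exact_2x2(m1, u1, m3, u3, alternative)
    p12 <- fisher_exact_2x2(m1, u1, m4, u4, alternative)
    p21 <- fisher_exact_2x2(m2, u2, m3, u3, alternative)
    p22 <- fisher_exact_2x2(m2, u2, m4, u4, alternative)
    combined <- pmin(1, 4 * pmin(p11, p12, p21, p22))
  } else {
    combined <- fisher_exact_2x2(m1 + m2, u1 + u2, m3 + m4, u3 + u4,
                                 alternative)
  }
  # replicate-DMP filter: siblings must agree within each group
  pw1 <- fisher_exact_2x2(m1, u1, m2, u2, alternative)
  pw2 <- fisher_exact_2x2(m3, u3, m4, u4, alternative)
  level1 <- (m1 + m2) / (m1 + u1 + m2 + u2)
  level2 <- (m3 + m4) / (m3 + u3 + m4 + u4)
  # genome-wide FDR: BH over the combined p-values of every tested site,
  # then the per-site threshold and the sibling-concordance filter
  qall <- p.adjust(combined, method = "BH")
  cand <- combined < p_thresh & pw1 >= p_thresh & pw2 >= p_thresh
  out <- wide[cand, keys, with = FALSE]
  if ("context" %in% names(wide)) out[, context := wide$context[cand]]
  else out[, context := NA_character_]
  out[, combined_p := combined[cand]]
  out[, q := qall[cand]]
  out[, level1 := level1[cand]]
  out[, level2 := level2[cand]]
  out <- out[q <= fdr & level1 != level2]
  out[, direction := ifelse(level1 > level2, "hyper", "hypo")]
  setorderv(out, keys)
  data.table::setattr(out, "class", c("dmp_set", class(out)))
  out[]
}

empty_dmp_set <- function() {
  out <- data.table(chrom = character(), pos = integer(),
                    strand = character(), context = character(),
                    combined_p = numeric(), q = numeric(),
                    level1 = numeric(), level2 = numeric(),
                    direction = character())
  data.table::setattr(out, "class", c("dmp_set", class(out)))
  out
}

#' Call single-cytosine methylation polymorphisms (SMPs)
#'
#' Status-level differences between two groups: a site is an SMP when both
#' replicates of group 1 share one binary methylation status, both
#' replicates of group 2 share the other, and the site is not invariant
#' across the whole sample panel (sites with the same status in every
#' panel sample carry no information and are removed from the SMP
#' universe). Direction is `re_methylated` when group 1 is methylated and
#' group 2 unmethylated, `de_methylated` for the reverse.
#'
#' @param statuses A status matrix from [status_matrix()] covering the
#'   whole panel (all 16 samples of the design, or any superset of the
#'   comparison).
#' @param g1,g2 [group_spec()]s.
#' @return A `data.table` of class `smp_set`: `chrom, pos, strand,
#'   direction`.
#' @export
call_smps <- function(statuses, g1, g2) {
  stopifnot(inherits(g1, "group_spec"), inherits(g2, "group_spec"))
  st <- as.data.table(statuses)
  panel_cols <- grep("^status\\.", names(st), value = TRUE)
  need <- paste0("status.", c(g1$samples, g2$samples))
  missing_s <- setdiff(need, panel_cols)
  if (length(missing_s))
    stopf("status matrix lacks columns: %s", paste(missing_s, collapse = ", "))
  s <- as.matrix(st[, need, with = FALSE])
  callable <- rowSums(is.na(s)) == 0L
  # invariant across the whole panel -> excluded from the SMP universe
  panel <- as.matrix(st[, panel_cols, with = FALSE])
  invariant <- apply(panel, 1L, function(x) {
    x <- x[!is.na(x)]
    length(x) == length(panel_cols) && length(unique(x)) == 1L
  })
  conc1 <- s[, 1L] == s[, 2L]
  conc2 <- s[, 3L] == s[, 4L]
  differs <- s[, 1L] != s[, 3L]
  hit <- which(callable & !invariant & conc1 & conc2 & differs)
  out <- st[hit, .(chrom, pos, strand)]
  out[, direction := ifelse(s[hit, 1L] == "M", "re_methylated",
                            "de_methylated")]
  setorderv(out, c("chrom", "pos", "strand"))
  data.table::setattr(out, "class", c("smp_set", class(out)))
  out[]
}

# window tiling per chromosome: 1-based inclusive windows of `window` bp
# every `step` bp starting at position 1
tile_windows <- function(chrom_len, window, step) {
  starts <- seq.int(1L, max(chrom_len - 1L, 1L), by = step)
  starts <- starts[starts <= chrom_len]
  data.table(win_start = starts,
             win_end = pmin(starts + window - 1L, chrom_len))
}

#' Call differentially methylated regions (DMRs)
#'
#' The sliding-window DMR screen: 200-bp windows advanced in 50-bp steps
#' tile each chromosome from position 1. Per window, Fisher's exact test
#' compares the replicate-pooled (methylated, unmethylated) counts of the
#' two groups; p-values are Benjamini-Hochberg adjusted over all tested
#' windows. A window is retained when its adjusted p-value is below
#' `adj_p`, its pooled methylation level changes at least `fold`-fold
#' between groups, and it contains at least `min_dmps` DMPs (matching the
#' window's direction by default). Retained same-direction windows whose
#' gap is at most `merge_gap` bp (overlapping windows included) are merged
#' into DMRs; opposite-direction neighbours are never merged. Windows with
#' a zero level on one side use the pseudo-level `1 / (pooled reads + 1)`
#' for the fold change; windows with both levels zero are never
#' candidates. Terminal partial windows (shorter than `window`) are tested
#' only if they contain at least `min_dmps` eligible cytosines.
#'
#' @inheritParams call_dmps
#' @param dmps The `dmp_set` called for the same comparison.
#' @param window,step Window size and step in bp (defaults 200, 50).
#' @param min_dmps Minimum DMPs inside a retained window (default 7).
#' @param fold Minimum fold change between pooled window levels (default
#'   1.5).
#' @param adj_p Adjusted p-value threshold (default 0.01).
#' @param merge_gap Maximum gap between merged windows in bp (default
#'   100).
#' @param chrom_sizes Optional named vector of chromosome lengths;
#'   defaults to the maximum site position per chromosome.
#' @param direction_match Count only DMPs whose direction matches the
#'   window's (default `TRUE`).
#' @param trim Trim each merged DMR to its outermost supporting DMPs
#'   (default `TRUE`); with `trim = FALSE` boundaries are the union of
#'   qualifying windows.
#' @return A `data.table` of class `dmr_set`: `chrom, start, end`
#'   (1-based inclusive), `direction, n_dmps, level1, level2, fold,
#'   adj_p`.
#' @export
call_dmrs <- function(tables, g1, g2, dmps, eligible = NULL, window = 200L,
                      step = 50L, min_dmps = 7L, fold = 1.5, adj_p = 0.01,
                      merge_gap = 100L, chrom_sizes = NULL,
                      direction_match = TRUE, trim = TRUE,
                      alternative = "two.sided") {
  stopifnot(inherits(g1, "group_spec"), inherits(g2, "group_spec"))
  keys <- c("chrom", "pos", "strand")
  samples <- c(g1$samples, g2$samples)
  missing_s <- setdiff(samples, names(tables))
  if (length(missing_s))
    stopf("samples absent from tables: %s", paste(missing_s, collapse = ", "))
  # pooled per-site counts per group over the analysis universe
  wide <- NULL
  for (i in seq_along(samples)) {
    tab <- as.data.table(tables[[samples[i]]])[, c(keys, "meth", "unmeth"),
                                               with = FALSE]
    setnames(tab, c("meth", "unmeth"), paste0(c("m", "u"), i))
    wide <- if (is.null(wide)) tab else merge(wide, tab, by = keys,
                                              sort = FALSE)
  }
  if (!is.null(eligible))
    wide <- merge(as.data.table(eligible)[, keys, with = FALSE], wide,
                  by = keys, sort = FALSE)
  if (!nrow(wide)) return(empty_dmr_set())
  wide[, `:=`(gm1 = m1 + m2, gu1 = u1 + u2, gm2 = m3 + m4, gu2 = u3 + u4)]
  dmp_dt <- as.data.table(dmps)
  wins_all <- list()
  for (ch in unique(wide$chrom)) {
    sub <- wide[chrom == ch]
    clen <- if (!is.null(chrom_sizes) && ch %in% names(chrom_sizes))
      as.integer(chrom_sizes[[ch]]) else max(sub$pos)
    wins <- tile_windows(clen, window, step)
    wins[, chrom := ch]
    # per-window pooled counts and cytosine tally via cumulative sums over
    # position-sorted sites
    posv <- sub$pos
    ord <- order(posv)
    posv <- posv[ord]
    cm1 <- cumsum(sub$gm1[ord]); cu1 <- cumsum(sub$gu1[ord])
    cm2 <- cumsum(sub$gm2[ord]); cu2 <- cumsum(sub$gu2[ord])
    lo <- findInterval(wins$win_start - 0.5, posv)      # sites < start
    hi <- findInterval(wins$win_end + 0.5, posv)        # sites <= end
    wins[, n_sites := hi - lo]
    csum <- function(cs, a, b)
      ifelse(b > 0L, cs[pmax(b, 1L)], 0) - ifelse(a > 0L, cs[pmax(a, 1L)], 0)
    wins[, `:=`(gm1 = csum(cm1, lo, hi), gu1 = csum(cu1, lo, hi),
                gm2 = csum(cm2, lo, hi), gu2 = csum(cu2, lo, hi))]
    # DMPs per window and direction
    dsub <- dmp_dt[chrom == ch]
    if (nrow(dsub)) {
      dpos_hyper <- sort(dsub$pos[dsub$direction == "hyper"])
      dpos_hypo <- sort(dsub$pos[dsub$direction == "hypo"])
      wins[, n_dmp_hyper := findInterval(win_end + 0.5, dpos_hyper) -
             findInterval(win_start - 0.5, dpos_hyper)]
      wins[, n_dmp_hypo := findInterval(win_end + 0.5, dpos_hypo) -
             findInterval(win_start - 0.5, dpos_hypo)]
    } else {
      wins[, `:=`(n_dmp_hyper = 0L, n_dmp_hypo = 0L)]
    }
    wins_all[[ch]] <- wins
  }
  wins <- rbindlist(wins_all)
  # tested windows: at least one covered cytosine, not an under-populated
  # terminal partial window, and not level-zero on both sides
  cov1 <- wins$gm1 + wins$gu1
  cov2 <- wins$gm2 + wins$gu2
  partial <- (wins$win_end - wins$win_start + 1L) < window
  tested <- wins$n_sites > 0L & cov1 > 0 & cov2 > 0 &
    (!partial | wins$n_sites >= min_dmps) &
    (wins$gm1 + wins$gm2 > 0)
  wins <- wins[tested]
  if (!nrow(wins)) return(empty_dmr_set())
  p <- fisher_exact_2x2(wins$gm1, wins$gu1, wins$gm2, wins$gu2, alternative)
  wins[, adj_p := p.adjust(p, method = "BH")]
  wins[, `:=`(level1 = gm1 / (gm1 + gu1), level2 = gm2 / (gm2 + gu2))]
  eps1 <- 1 / (wins$gm1 + wins$gu1 + 1)
  eps2 <- 1 / (wins$gm2 + wins$gu2 + 1)
  l1 <- ifelse(wins$level1 == 0, eps1, wins$level1)
  l2 <- ifelse(wins$level2 == 0, eps2, wins$level2)
  wins[, fold := pmax(l1, l2) / pmin(l1, l2)]
  wins[, direction := ifelse(level1 > level2, "hyper", "hypo")]
  wins[, n_dmps := ifelse(direction == "hyper", n_dmp_hyper, n_dmp_hypo)]
  if (!direction_match) wins[, n_dmps := n_dmp_hyper + n_dmp_hypo]
  adj_p_thr <- adj_p; fold_thr <- fold; min_dmps_thr <- min_dmps
  keep <- wins[wins$adj_p < adj_p_thr & wins$fold >= fold_thr &
                 wins$n_dmps >= min_dmps_thr & wins$level1 != wins$level2]
  if (!nrow(keep)) return(empty_dmr_set())
  merged <- merge_windows(keep, merge_gap)
  # recount DMPs over each merged span (direction-matched unless disabled)
  # and trim boundaries to the outermost supporting DMPs
  if (nrow(dmp_dt)) {
    for (i in seq_len(nrow(merged))) {
      dsub <- dmp_dt[chrom == merged$chrom[i] & pos >= merged$start[i] &
                       pos <= merged$end[i]]
      if (direction_match)
        dsub <- dsub[direction == merged$direction[i]]
      data.table::set(merged, i, "n_dmps", nrow(dsub))
      if (trim && nrow(dsub)) {
        data.table::set(merged, i, "start", min(dsub$pos))
        data.table::set(merged, i, "end", max(dsub$pos))
      }
    }
  }
  data.table::setattr(merged, "class", c("dmr_set", class(merged)))
  merged[]
}

empty_dmr_set <- function() {
  out <- data.table(chrom = character(), start = integer(),
                    end = integer(), direction = character(),
                    n_dmps = integer(), level1 = numeric(),
                    level2 = numeric(), fold = numeric(),
                    adj_p = numeric())
  data.table::setattr(out, "class", c("dmr_set", class(out)))
  out
}

# merge same-direction qualifying windows/regions whose gap is <= merge_gap
merge_windows <- function(keep, merge_gap) {
  keep <- copy(as.data.table(keep))
  if (!"start" %in% names(keep))
    setnames(keep, c("win_start", "win_end"), c("start", "end"))
  setorderv(keep, c("chrom", "direction", "start", "end"))
  out <- list()
  for (grp in split(keep, by = c("chrom", "direction"))) {
    if (!nrow(grp)) next
    cur <- grp[1]
    merged_rows <- list()
    flush <- function(cur) data.table(
      chrom = cur$chrom, start = cur$start, end = cur$end,
      direction = cur$direction, n_dmps = max(cur$n_dmps),
      level1 = cur$level1, level2 = cur$level2, fold = cur$fold,
      adj_p = cur$adj_p)
    for (i in seq_len(nrow(grp))[-1]) {
      nxt <- grp[i]
      gap <- nxt$start - cur$end - 1L
      if (gap <= merge_gap) {
        cur$end <- max(cur$end, nxt$end)
        cur$n_dmps <- max(cur$n_dmps, nxt$n_dmps)
        cur$adj_p <- min(cur$adj_p, nxt$adj_p)
        # pooled levels of the union approximated by coverage-weighted
        # combination is not available post hoc; keep the extreme window
        cur$level1 <- if (cur$direction == "hyper")
          max(cur$level1, nxt$level1) else min(cur$level1, nxt$level1)
        cur$level2 <- if (cur$direction == "hyper")
          min(cur$level2, nxt$level2) else max(cur$level2, nxt$level2)
        cur$fold <- max(cur$fold, nxt$fold)
      } else {
        merged_rows[[length(merged_rows) + 1L]] <- flush(cur)
        cur <- nxt
      }
    }
    merged_rows[[length(merged_rows) + 1L]] <- flush(cur)
    out[[length(out) + 1L]] <- rbindlist(merged_rows)
  }
  merged <- rbindlist(out)
  setorderv(merged, c("chrom", "start", "end"))
  merged[]
}

#' Re-merge a DMR set
#'
#' Applies the DMR merge rule (same chromosome, same direction, gap at
#' most `merge_gap` bp) to an existing DMR set. Merging the output of
#' [call_dmrs()] again is a no-op, which the test suite asserts.
#'
#' @param dmrs A `dmr_set`.
#' @param merge_gap Maximum merge gap in bp (default 100).
#' @return A `dmr_set`.
#' @export
merge_dmrs <- function(dmrs, merge_gap = 100L) {
  if (!nrow(dmrs)) return(dmrs)
  merged <- merge_windows(as.data.table(dmrs), merge_gap)
  data.table::setattr(merged, "class", c("dmr_set", class(merged)))
  merged[]
}

#' Export DMRs as BED6+
#'
#' Writes DMRs with 0-based half-open coordinates, direction in the name
#' field and `n_dmps`, `fold`, `adj_p` as extra columns.
#'
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  dt <- as.data.table(dmrs)
  zero <- to_zero_based(dt$start, dt$end)
  bed <- data.table(chrom = dt$chrom, start = zero$start, end = zero$end,
                    name = paste0(dt$direction, "_",
                                  seq_len(max(nrow(dt), 0L))),
                    score = 0L, strand = ".", n_dmps = dt$n_dmps,
                    fold = dt$fold, adj_p = dt$adj_p)
  writeLines(tool_comment(), path)
  if (nrow(bed)) data.table::fwrite(bed, path, sep = "\t",
                                    col.names = FALSE, append = TRUE)
  invisible(path)
}
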