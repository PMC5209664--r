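# locus+direction keys for matching events across comparisons
event_keys <- function(events) {
  dt <- as.data.table(events)
  if ("pos" %in% names(dt)) {
    paste(dt$chrom, dt$pos, dt$strand, dt$direction, sep = ":")
  } else {
    paste(dt$chrom, dt$start, dt$end, dt$direction, sep = ":")
  }
}

is_region_set <- function(events) {
  dt <- as.data.table(events)
  !("pos" %in% names(dt)) && all(c("start", "end") %in% names(dt))
}

# match region events between two sets by reciprocal overlap and equal
# direction; returns logical vector over `query` rows
region_matched <- function(query, subject, min_overlap = 0.5) {
  q <- as.data.table(query); s <- as.data.table(subject)
  if (!nrow(q)) return(logical(0))
  if (!nrow(s)) return(rep(FALSE, nrow(q)))
  gq <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$start, q$end))
  gs <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start, s$end))
  hits <- GenomicRanges::findOverlaps(gq, gs, ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gq[qi], gs[si]))
  recip <- ov / GenomicRanges::width(gq[qi]) >= min_overlap &
    ov / GenomicRanges::width(gs[si]) >= min_overlap &
    q$direction[qi] == s$direction[si]
  out <- rep(FALSE, nrow(q))
  out[unique(qi[recip])] <- TRUE
  out
}

#' Recurrence ("hot spot") analysis of epimutation events
#'
#' Given the event sets of K independent comparisons (e.g. drought vs
#' well-watered in each of four generations), counts for every distinct
#' locus+direction the number of comparisons it appears in. A locus
#' recurring in two or more comparisons is a candidate "hot spot"; the
#' observed recurring fraction is compared against the expectation under
#' uniform random placement from [expected_random_recurrence()]. Position
#' events (DMPs/SMPs) match by exact (chrom, pos, strand, direction);
#' region events (DMRs) by reciprocal overlap (default at least 50%) with
#' equal direction.
#'
#' @param event_sets List of K event tables (`dmp_set`, `smp_set` or
#'   `dmr_set`) sharing a direction vocabulary.
#' @param eligible_n Size of the eligible-locus universe the events were
#'   called from.
#' @param min_overlap Reciprocal-overlap threshold for region matching.
#' @return An object of class `recurrence_table`: list with
#'   `by_frequency` (`data.table` of direction, frequency, n_loci) and
#'   `summary` (per direction: distinct loci, recurring loci, observed
#'   and expected random recurring percentages).
#' @export
recurrence_analysis <- function(event_sets, eligible_n,
                                min_overlap = 0.5) {
  stopifnot(is.list(event_sets), length(event_sets) >= 1L)
  K <- length(event_sets)
  region <- is_region_set(event_sets[[1L]])
  if (!region) {
    keys <- lapply(event_sets, function(e) unique(event_keys(e)))
    all_keys <- unlist(keys)
    dirs <- sub("^.*:", "", all_keys)
    tab <- data.table(key_ = all_keys, direction = dirs)
    freq_dt <- tab[, .(freq = .N), by = .(key_, direction)]
  } else {
    # cluster same-direction regions across comparisons by reciprocal
    # overlap (union-find over overlap pairs), then count the number of
    # distinct comparisons per cluster
    pooled <- rbindlist(lapply(seq_len(K), function(i) {
      dt <- as.data.table(event_sets[[i]])[, .(chrom, start, end, direction)]
      dt[, comparison := i]
      dt
    }))
    if (!nrow(pooled)) {
      freq_dt <- data.table(key_ = character(), direction = character(),
                            freq = integer())
    } else {
      gr <- GenomicRanges::GRanges(pooled$chrom,
                                   IRanges::IRanges(pooled$start, pooled$end))
      hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
      qi <- queryHits(hits); si <- subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[qi], gr[si]))
      good <- ov / GenomicRanges::width(gr[qi]) >= min_overlap &
        ov / GenomicRanges::width(gr[si]) >= min_overlap &
        pooled$direction[qi] == pooled$direction[si]
      parent <- seq_len(nrow(pooled))
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (h in which(good)) {
        a <- find(qi[h]); b <- find(si[h])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nrow(pooled)), find, integer(1))
      pooled[, cluster := root]
      freq_dt <- pooled[, .(freq = data.table::uniqueN(comparison),
                            direction = direction[1L]), by = cluster]
      freq_dt[, key_ := paste0("cluster", cluster)]
    }
  }
  n_distinct_total <- nrow(freq_dt)
  if (eligible_n < n_distinct_total)
    stopf("consistency error: eligible_n (%s) < distinct loci (%s)",
          format(eligible_n), format(n_distinct_total))
  by_freq <- freq_dt[, .(n_loci = .N), by = .(direction, frequency = freq)]
  setorderv(by_freq, c("direction", "frequency"))
  summ <- freq_dt[, .(n_distinct = .N, n_recurring = sum(freq >= 2L)),
                  by = direction]
  summ[, observed_pct := pct(n_recurring, n_distinct)]
  expected <- vapply(summ$direction, function(d) {
    counts <- vapply(event_sets, function(e) {
      dt <- as.data.table(e)
      sum(dt$direction == d)
    }, numeric(1))
    100 * expected_random_recurrence(counts, eligible_n,
                                     method = "analytic")
  }, numeric(1))
  summ[, expected_random_pct := expected]
  out <- list(by_frequency = by_freq, summary = summ[], K = K,
              eligible_n = eligible_n)
  class(out) <- "recurrence_table"
  out
}

#' @export
print.recurrence_table <- function(x, ...) {
  cat(sprintf("recurrence over %d comparisons (eligible N = %s)\n", x$K,
              format(x$eligible_n, big.mark = ",")))
  print(x$summary)
  invisible(x)
}

#' Expected recurring fraction under uniform random placement
#'
#' If each of K comparisons placed its events uniformly at random among
#' `eligible_n` loci, what fraction of hit loci would be hit by two or
#' more comparisons? The analytic answer treats each locus as a
#' Poisson-binomial draw over the K per-comparison hit probabilities
#' `p_i = k_i / N`: the expected recurring fraction is
#' `E[# loci hit >= 2] / E[# loci hit >= 1]`. The permutation method
#' averages the realised fraction over `n_rep` seeded random placements
#' (each comparison's events placed without replacement).
#'
#' @param event_counts Integer vector of per-comparison event counts.
#' @param eligible_n Universe size N.
#' @param method `"analytic"` (default) or `"permutation"`.
#' @param n_rep Permutation replicates (default 100).
#' @param seed Optional seed for the permutation method.
#' @return Expected recurring fraction in \[0, 1\].
#' @export
expected_random_recurrence <- function(event_counts, eligible_n,
                                       method = c("analytic", "permutation"),
                                       n_rep = 100L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(event_counts >= 0), all(event_counts <= eligible_n))
  K <- length(event_counts)
  if (K <= 1L || sum(event_counts > 0) <= 1L) return(0)
  if (method == "analytic") {
    p <- event_counts / eligible_n
    none <- prod(1 - p)
    exactly_one <- sum(vapply(seq_len(K), function(i)
      p[i] * prod(1 - p[-i]), numeric(1)))
    p_ge1 <- 1 - none
    if (p_ge1 <= 0) return(0)
    return((p_ge1 - exactly_one) / p_ge1)
  }
  if (!is.null(seed)) set.seed(seed)
  fracs <- vapply(seq_len(n_rep), function(r) {
    hits <- unlist(lapply(event_counts, function(k)
      sample.int(eligible_n, k, replace = FALSE)))
    hits <- sort(hits)
    dup <- hits[duplicated(hits)]
    n_hit <- length(unique(hits))
    if (n_hit == 0L) return(0)
    length(unique(dup)) / n_hit
  }, numeric(1))
  mean(fracs)
}

# shared matcher: which induced events appear (same locus + direction) in
# a list of other event sets; returns matrix [n_events x n_sets]
match_matrix <- function(events, other_sets, min_overlap = 0.5) {
  region <- is_region_set(events)
  if (!region) {
    k0 <- event_keys(events)
    vapply(other_sets, function(s) k0 %in% event_keys(s),
           logical(nrow(as.data.table(events))))
  } else {
    vapply(other_sets, function(s)
      region_matched(events, s, min_overlap),
      logical(nrow(as.data.table(events))))
  }
}

inheritance_report <- function(events, flag, direction, what) {
  dt <- data.table(direction = direction, flag = flag)
  tab <- dt[, .(n_events = .N, n_maintained = sum(flag)), by = direction]
  setorderv(tab, "direction")
  pooled <- data.table(direction = "total", n_events = nrow(dt),
                       n_maintained = sum(dt$flag))
  tab <- rbind(tab, pooled)
  tab[, percentage := pct(n_maintained, n_events)]
  share <- if (sum(dt$flag) > 0)
    dt[flag == TRUE, .(n = .N), by = direction][
      , .(direction, share_pct = pct(n, sum(n)))]
  else data.table(direction = character(), share_pct = numeric())
  out <- list(table = tab[], direction_share = share, what = what,
              events = events, flags = flag)
  class(out) <- "inheritance_report"
  out
}

#' @export
print.inheritance_report <- function(x, ...) {
  cat(sprintf("%s report\n", x$what))
  print(x$table)
  if (nrow(x$direction_share)) {
    cat("direction share among inherited events:\n")
    print(x$direction_share)
  }
  invisible(x)
}

#' Maintenance of induced epimutations in advanced generations
#'
#' An epimutation induced in the original generation (events of the
#' D0-vs-W0 comparison) is \emph{maintained} when the same locus appears
#' with the same direction in the drought-vs-control comparisons of
#' advanced generations (G10, G11, G10R1). `mode = "any"` (default)
#' requires presence in at least one advanced comparison, `mode = "all"`
#' in every one.
#'
#' @param induced Event set of the inducing comparison.
#' @param advanced Named list of event sets of the advanced-generation
#'   comparisons, with the same orientation (treated vs control).
#' @param mode `"any"` (default) or `"all"`.
#' @param min_overlap Reciprocal-overlap threshold for region events.
#' @return An `inheritance_report`: per-direction and pooled counts of
#'   maintained events with percentages (two decimals, half-up).
#' @export
classify_maintenance <- function(induced, advanced, mode = c("any", "all"),
                                 min_overlap = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.list(advanced), length(advanced) >= 1L)
  dt <- as.data.table(induced)
  if (!nrow(dt))
    return(inheritance_report(dt, logical(0), character(0), "maintenance"))
  mm <- match_matrix(induced, advanced, min_overlap)
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = nrow(dt))
  flag <- if (mode == "any") rowSums(mm) > 0L else
    rowSums(mm) == length(advanced)
  inheritance_report(dt, flag, dt$direction, "maintenance")
}

#' Transgenerational inheritance of accumulated epimutations
#'
#' An accumulated epimutation (events of the D10-vs-D0 comparison) is
#' \emph{transgenerational} when its locus and direction are present both
#' in at least one drought-treated offspring comparison (e.g. D11 vs D0)
#' and in at least one well-watered recovery comparison (e.g. D10R1 vs
#' D0): the change survived another treated generation and persisted when
#' the stress was removed.
#'
#' @param accumulated Event set of the accumulation comparison.
#' @param treated_offspring List of event sets from drought-treated
#'   offspring comparisons.
#' @param recovery List of event sets from well-watered recovery
#'   comparisons.
#' @param min_overlap Reciprocal-overlap threshold for region events.
#' @return An `inheritance_report`; its `direction_share` table gives each
#'   direction's share among transgenerational events.
#' @export
classify_transgenerational <- function(accumulated, treated_offspring,
                                       recovery, min_overlap = 0.5) {
  stopifnot(is.list(treated_offspring), is.list(recovery))
  dt <- as.data.table(accumulated)
  if (!nrow(dt))
    return(inheritance_report(dt, logical(0), character(0),
                              "transgenerational"))
  m_t <- match_matrix(accumulated, treated_offspring, min_overlap)
  m_r <- match_matrix(accumulated, recovery, min_overlap)
  if (is.null(dim(m_t))) m_t <- matrix(m_t, nrow = nrow(dt))
  if (is.null(dim(m_r))) m_r <- matrix(m_r, nrow = nrow(dt))
  flag <- rowSums(m_t) > 0L & rowSums(m_r) > 0L
  inheritance_report(dt, flag, dt$direction, "transgenerational")
}

#' Percentage tally table
#'
#' Turns labelled numerator/denominator count pairs into the percentage
#' table layout used throughout the reports, with an aggregate row
#' computed as the ratio of summed counts (not the mean of percentages).
#' Percentages are rounded half-up to two decimals.
#'
#' @param n Numerators (named vector, or unnamed with `labels`).
#' @param total Denominators, recycled against `n`.
#' @param labels Optional row labels.
#' @param aggregate Add a pooled `total` row (default `TRUE`).
#' @return A `data.table` with `label, n, total, percentage`.
#' @export
#' @examples
#' tally_report(c(hypo = 13130, hyper = 55329), c(349056, 858301))
tally_report <- function(n, total, labels = NULL, aggregate = TRUE) {
  if (is.null(labels)) labels <- names(n) %||% as.character(seq_along(n))
  stopifnot(length(n) == length(total) || length(total) == 1L)
  total <- rep_len(total, length(n))
  if (any(total == 0))
    warnf("zero denominator: percentage undefined for %s",
          paste(labels[total == 0], collapse = ", "))
  out <- data.table(label = labels, n = as.numeric(n),
                    total = as.numeric(total),
                    percentage = pct(n, total))
  if (aggregate && length(n) > 1L)
    out <- rbind(out, data.table(label = "total", n = sum(n),
                                 total = sum(total),
                                 percentage = pct(sum(n), sum(total))))
  out[]
}

#' Hierarchical clustering of samples by methylation levels
#'
#' Average-linkage agglomerative clustering of samples over a chosen locus
#' set (typically the loci of called epimutations). Loci with an undefined
#' level in any sample are dropped; samples are ordered lexicographically
#' by label before clustering so ties resolve deterministically.
#'
#' @param levels Numeric matrix of per-locus methylation levels, loci in
#'   rows, samples in columns (column names are sample labels).
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (`1 - Pearson r`).
#' @param linkage Agglomeration method; only `"average"` is offered.
#' @return An object of class `sample_clustering`: list with `hclust`,
#'   `newick` (the dendrogram as a Newick string) and `merge_table`.
#' @export
cluster_samples <- function(levels, metric = c("euclidean", "correlation"),
                            linkage = "average") {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage, "average")
  stopifnot(is.matrix(levels), !is.null(colnames(levels)))
  if (ncol(levels) < 3L)
    stopf("clustering needs at least 3 samples, got %d", ncol(levels))
  levels <- levels[, order(colnames(levels)), drop = FALSE]
  keep <- rowSums(is.na(levels)) == 0L
  levels <- levels[keep, , drop = FALSE]
  if (!nrow(levels))
    stopf("no loci with defined levels in all samples")
  d <- if (metric == "euclidean") dist(t(levels)) else {
    cc <- suppressWarnings(stats::cor(levels))
    cc[is.na(cc)] <- 0
    as.dist(1 - cc)
  }
  hc <- hclust(d, method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  out <- list(hclust = hc, newick = newick,
              merge_table = data.table(merge1 = hc$merge[, 1L],
                                       merge2 = hc$merge[, 2L],
                                       height = hc$height),
              n_loci = nrow(levels), metric = metric)
  class(out) <- "sample_clustering"
  out
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample clustering (%s, average linkage) on %d loci\n",
              x$metric, x$n_loci))
  cat(x$newick, "\n")
  invisible(x)
}

#' Per-sample methylation levels at a locus set
#'
#' Builds the loci x samples level matrix consumed by
#' [cluster_samples()] from raw count tables: level = meth / coverage,
#' `NA` where a site is uncovered in a sample.
#'
#' @param tables Named list of cytosine tables.
#' @param loci Site table with `chrom, pos, strand`.
#' @return Numeric matrix, loci in rows (named `chrom:pos:strand`),
#'   samples in columns.
#' @export
sample_level_matrix <- function(tables, loci) {
  keys <- c("chrom", "pos", "strand")
  loci <- as.data.table(loci)[, keys, with = FALSE]
  out <- matrix(NA_real_, nrow = nrow(loci), ncol = length(tables),
                dimnames = list(site_key(loci$chrom, loci$pos, loci$strand),
                                names(tables)))
  for (nm in names(tables)) {
    tab <- as.data.table(tables[[nm]])
    m <- merge(loci, tab[, c(keys, "meth", "unmeth"), with = FALSE],
               by = keys, all.x = TRUE, sort = FALSE)
    lvl <- m$meth / (m$meth + m$unmeth)
    out[site_key(m$chrom, m$pos, m$strand), nm] <- lvl
  }
  out
}
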