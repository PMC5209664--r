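test_that("recurrence counting matches enumeration on toy comparisons", {
  # K=2 with events {A,B,C} and {B,C,D}: 4 distinct, 2 recurring
  s1 <- make_events(c(10, 20, 30))
  s2 <- make_events(c(20, 30, 40))
  rec <- recurrence_analysis(list(s1, s2), eligible_n = 1000)
  expect_equal(rec$summary$n_distinct, 4L)
  expect_equal(rec$summary$n_recurring, 2L)
  expect_equal(rec$summary$observed_pct, 50)
  expect_equal(sum(rec$by_frequency$n_loci), 4L)
  expect_true(all(rec$by_frequency$frequency <= 2L))

  # K=1: nothing can recur
  rec1 <- recurrence_analysis(list(s1), eligible_n = 1000)
  expect_equal(rec1$summary$n_recurring, 0L)
  expect_equal(rec1$summary$observed_pct, 0)

  # invariant to comparison order
  recr <- recurrence_analysis(list(s2, s1), eligible_n = 1000)
  expect_equal(rec$summary, recr$summary)

  # direction-aware: the same locus in opposite directions never recurs
  s3 <- make_events(20, direction = "hypo")
  rec2 <- recurrence_analysis(list(s1, s3), eligible_n = 1000)
  expect_equal(rec2$summary[direction == "hyper"]$n_recurring, 0L)

  expect_error(recurrence_analysis(list(s1, s2), eligible_n = 2),
               "consistency error")
})

test_that("recurrence matches region events by reciprocal overlap", {
  r1 <- data.table::data.table(chrom = "chr1", start = c(100L, 900L),
                               end = c(300L, 1100L),
                               direction = c("hyper", "hypo"))
  r2 <- data.table::data.table(chrom = "chr1", start = c(120L, 2000L),
                               end = c(320L, 2200L),
                               direction = c("hyper", "hypo"))
  rec <- recurrence_analysis(list(r1, r2), eligible_n = 10000)
  hyper <- rec$summary[direction == "hyper"]
  expect_equal(hyper$n_distinct, 1L)     # the two overlapping regions fuse
  expect_equal(hyper$n_recurring, 1L)
  hypo <- rec$summary[direction == "hypo"]
  expect_equal(hypo$n_distinct, 2L)      # disjoint regions stay distinct
  expect_equal(hypo$n_recurring, 0L)
})

test_that("analytic random recurrence equals full enumeration on a tiny universe", {
  # counts (2,2) over N=4: enumerate all C(4,2)^2 = 36 joint placements
  combos <- utils::combn(4, 2, simplify = FALSE)
  # the analytic value is a ratio of expectations, so enumerate
  # E[# recurring] / E[# hit] over all joint placements
  rec_counts <- c(); hit_counts <- c()
  for (p1 in combos) for (p2 in combos) {
    hits <- c(p1, p2)
    rec_counts <- c(rec_counts, sum(table(hits) >= 2))
    hit_counts <- c(hit_counts, length(unique(hits)))
  }
  oracle <- mean(rec_counts) / mean(hit_counts)
  expect_equal(expected_random_recurrence(c(2, 2), 4), oracle,
               tolerance = 1e-12)
  expect_equal(expected_random_recurrence(5, 100), 0)  # K = 1
})

test_that("permutation and analytic random recurrence agree within Monte-Carlo error", {
  counts <- c(200, 300, 250, 150)
  N <- 10000
  analytic <- expected_random_recurrence(counts, N)
  set.seed(60)
  reps <- vapply(1:200, function(r) {
    hits <- unlist(lapply(counts, function(k) sample.int(N, k)))
    sum(table(hits) >= 2) / length(unique(hits))
  }, numeric(1))
  perm <- expected_random_recurrence(counts, N, method = "permutation",
                                     n_rep = 200, seed = 61)
  mc_se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(perm - analytic), 3 * mc_se + 1e-4)
})

test_that("maintenance classification tallies per direction with exact pooled percentages", {
  induced <- make_events(c(1, 2, 3), direction = c("hyper", "hyper", "hypo"))
  adv1 <- make_events(c(1, 9), direction = c("hyper", "hypo"))
  adv2 <- make_events(3, direction = "hypo")
  rep_any <- classify_maintenance(induced, list(adv1, adv2), mode = "any")
  tab <- rep_any$table
  expect_equal(tab[direction == "total"]$n_events, 3L)
  expect_equal(tab[direction == "total"]$n_maintained, 2L)
  expect_equal(tab[direction == "total"]$percentage, 66.67)
  expect_true(all(tab$n_maintained <= tab$n_events))
  # "all" mode requires presence in every advanced comparison
  rep_all <- classify_maintenance(induced, list(adv1, adv2), mode = "all")
  expect_equal(rep_all$table[direction == "total"]$n_maintained, 0L)
  # direction must match: locus 1 as hypo is not maintained
  rep_dir <- classify_maintenance(
    make_events(1, direction = "hypo"), list(adv1))
  expect_equal(rep_dir$table[direction == "total"]$n_maintained, 0L)
})

test_that("transgenerational events need both a treated-offspring and a recovery hit", {
  acc <- make_events(c(1, 2, 3, 4),
                     direction = c("hyper", "hyper", "hypo", "hyper"))
  treated <- make_events(c(1, 2), direction = c("hyper", "hyper"))
  recov <- make_events(c(2, 3), direction = c("hyper", "hypo"))
  rep <- classify_transgenerational(acc, list(treated), list(recov))
  # locus 1: treated only; locus 3: recovery only; locus 2: both
  expect_equal(rep$table[direction == "total"]$n_maintained, 1L)
  expect_equal(rep$table[direction == "total"]$percentage, 25)
  expect_equal(rep$direction_share$direction, "hyper")
  expect_equal(rep$direction_share$share_pct, 100)
  # empty accumulated set gives an empty report, not an error
  empty <- classify_transgenerational(acc[0], list(treated), list(recov))
  expect_equal(nrow(empty$table), 1L)
  expect_equal(empty$table$n_events, 0L)
})

test_that("tally report rounds half-up to two decimals and aggregates counts", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  tr <- tally_report(c(a = 1, b = 3), c(8, 8))
  expect_equal(tr$percentage, c(12.5, 37.5, 25))
  expect_equal(tr[label == "total"]$n, 4)
  expect_equal(tr[label == "total"]$total, 16)
  expect_warning(tz <- tally_report(c(x = 0), 0, aggregate = FALSE),
                 "zero denominator")
  expect_true(is.na(tz$percentage))
  expect_equal(tally_report(c(z = 0), 10, aggregate = FALSE)$percentage, 0)
})

test_that("sample clustering is deterministic, re-parseable, and merges identical samples at height zero", {
  m <- cbind(A.X.1 = c(0.1, 0.9, 0.4), A.X.2 = c(0.1, 0.9, 0.4),
             B.Y.1 = c(0.8, 0.2, 0.6))
  cl <- cluster_samples(m)
  expect_equal(min(cl$hclust$height), 0)
  first_pair <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first_pair, c("A.X.1", "A.X.2"))
  # newick output reparses to the same cophenetic structure
  phy <- ape::read.tree(text = cl$newick)
  cd1 <- as.matrix(stats::cophenetic(cl$hclust))
  cd2 <- ape::cophenetic.phylo(phy)[rownames(cd1), colnames(cd1)]
  expect_equal(cd1, cd2, tolerance = 1e-6)
  expect_error(cluster_samples(m[, 1:2]), "at least 3")
  # loci with NA in any sample are dropped
  m2 <- m; m2[1, 1] <- NA
  cl2 <- cluster_samples(m2)
  expect_equal(cl2$n_loci, 2L)
})
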