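# four-sample toy builder: one table per sample from per-site (meth, unmeth)
toy_tables <- function(pos, counts, context = "CG") {
  labs <- c("G0.D.1", "G0.D.2", "G0.W.1", "G0.W.2")
  out <- lapply(seq_along(labs), function(i)
    make_cx("chr1", pos, meth = counts[[i]][, 1], unmeth = counts[[i]][, 2],
            context = context))
  names(out) <- labs
  out
}
g1 <- group_spec("G0", "D")
g2 <- group_spec("G0", "W")

test_that("identical counts in all samples yield no DMPs", {
  cnt <- matrix(c(5L, 5L), nrow = 10, ncol = 2, byrow = TRUE)
  tabs <- toy_tables(1:10, list(cnt, cnt, cnt, cnt))
  elig <- build_eligible_set(tabs)
  expect_equal(nrow(call_dmps(tabs, g1, g2, elig)), 0L)
})

test_that("a clean group contrast is a DMP whose combined p is 4x the best cross-pair Fisher p", {
  mk <- function(m, u) matrix(c(m, u), ncol = 2)
  tabs <- toy_tables(100L, list(mk(30L, 0L), mk(28L, 1L),
                                mk(0L, 30L), mk(1L, 29L)))
  elig <- build_eligible_set(tabs)
  dmps <- call_dmps(tabs, g1, g2, elig, p_thresh = 0.01, fdr = 0.05)
  expect_equal(nrow(dmps), 1L)
  expect_equal(dmps$direction, "hyper")
  pairs <- list(c(30, 0, 0, 30), c(30, 0, 1, 29),
                c(28, 1, 0, 30), c(28, 1, 1, 29))
  oracle <- vapply(pairs, function(x) fisher_oracle(x[1], x[2], x[3], x[4]),
                   numeric(1))
  expect_equal(dmps$combined_p, min(1, 4 * min(oracle)), tolerance = 1e-12)
})

test_that("sites with discordant sibling replicates are filtered out", {
  mk <- function(m, u) matrix(c(m, u), ncol = 2)
  # group 1 replicates disagree completely; group 2 is a clean contrast
  tabs <- toy_tables(100L, list(mk(30L, 0L), mk(0L, 30L),
                                mk(0L, 30L), mk(1L, 29L)))
  elig <- build_eligible_set(tabs)
  expect_equal(nrow(call_dmps(tabs, g1, g2, elig)), 0L)
})

test_that("swapping the groups swaps hyper and hypo exactly", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 2500, depth_mean = 20,
                  induction_rate = c(CG = 0.02, CHG = 0.02, CHH = 0.02),
                  drift_rate = 0, n_dmr_events = 0, seed = 51)
  sim <- simulate_methylome(d)
  elig <- build_eligible_set(sim$tables, exclude = "lambda")
  fwd <- call_dmps(sim$tables, g1, g2, elig)
  rev <- call_dmps(sim$tables, g2, g1, elig)
  expect_gt(nrow(fwd), 5)
  expect_equal(nrow(fwd), nrow(rev))
  key_fwd <- paste(dmp_keys(fwd), fwd$direction)
  flip <- c(hyper = "hypo", hypo = "hyper")
  key_rev <- paste(dmp_keys(rev), flip[rev$direction])
  expect_setequal(key_fwd, key_rev)
  # hyper and hypo sets are disjoint by construction
  expect_equal(anyDuplicated(dmp_keys(fwd)), 0L)
})

test_that("SMP calling follows the status truth table", {
  labs <- c("G0.D.1", "G0.D.2", "G0.W.1", "G0.W.2",
            "G10.D.1", "G10.D.2")
  st <- make_status_matrix(
    "chr1", 1:5, "+",
    setNames(list(
      c("M", "M", "M", "M", "M"),     # G0.D.1
      c("M", "M", "U", "M", "M"),     # G0.D.2 (site 3 discordant)
      c("U", "M", "U", "U", NA),      # G0.W.1 (site 5 uncallable)
      c("U", "M", "U", "U", "U"),     # G0.W.2
      c("U", "M", "M", "M", "M"),     # G10.D.1 (breaks invariance)
      c("U", "M", "M", "M", "M")),    # G10.D.2
      labs))
  smps <- call_smps(st, g1, g2)
  # site 1: (M,M) vs (U,U) -> re_methylated
  # site 2: all samples methylated -> invariant, excluded
  # site 3: replicate discordance -> none
  # site 4: (M,M) vs (U,U) -> re_methylated
  # site 5: uncallable in one sample -> skipped
  expect_equal(smps$pos, c(1L, 4L))
  expect_equal(smps$direction, c("re_methylated", "re_methylated"))
  rev <- call_smps(st, g2, g1)
  expect_equal(rev$direction, c("de_methylated", "de_methylated"))
})

test_that("a dense differential run of sites becomes exactly one DMR with trimmed boundaries", {
  # 8 CG sites within 160 bp on a 1-kb chromosome, level 0.9 vs 0.2;
  # 12 background sites with no contrast
  run_pos <- seq(401L, 560L, by = 22L)        # 8 sites, 401..555
  bg_pos <- c(seq(50L, 350L, by = 50L), seq(650L, 950L, by = 60L))
  pos <- sort(c(run_pos, bg_pos))
  in_run <- pos %in% run_pos
  mk <- function(m_run, u_run, m_bg, u_bg)
    matrix(c(ifelse(in_run, m_run, m_bg), ifelse(in_run, u_run, u_bg)),
           ncol = 2)
  tabs <- toy_tables(pos, list(mk(18L, 2L, 10L, 10L), mk(17L, 3L, 10L, 10L),
                               mk(4L, 16L, 10L, 10L), mk(4L, 16L, 10L, 10L)))
  elig <- build_eligible_set(tabs)
  dmps <- call_dmps(tabs, g1, g2, elig)
  expect_true(all(run_pos %in% dmps$pos))
  dmrs <- call_dmrs(tabs, g1, g2, dmps, eligible = elig,
                    chrom_sizes = c(chr1 = 1000L))
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "hyper")
  expect_gte(dmrs$n_dmps, 8L)
  # trimmed to the outermost supporting DMPs
  expect_equal(dmrs$start, min(run_pos))
  expect_equal(dmrs$end, max(run_pos))
  # untrimmed boundaries equal the union of qualifying windows, which
  # contains the run and aligns to the 50-bp tiling
  raw <- call_dmrs(tabs, g1, g2, dmps, eligible = elig, trim = FALSE,
                   chrom_sizes = c(chr1 = 1000L))
  expect_equal(nrow(raw), 1L)
  expect_lte(raw$start, min(run_pos))
  expect_gte(raw$end, max(run_pos))
  expect_equal((raw$start - 1L) %% 50L, 0L)
  # re-merging the caller's output changes nothing
  expect_identical(as.data.frame(merge_dmrs(dmrs)), as.data.frame(dmrs))
})

test_that("DMR merging joins same-direction regions at gaps up to 100 bp and no further", {
  mk_set <- function(starts, ends, dirs) {
    out <- data.table::data.table(
      chrom = "chr1", start = starts, end = ends, direction = dirs,
      n_dmps = 8L, level1 = 0.9, level2 = 0.2, fold = 4.5, adj_p = 1e-5)
    data.table::setattr(out, "class", c("dmr_set", class(out)))
    out
  }
  # gap of exactly 100 bp -> one DMR
  m <- merge_dmrs(mk_set(c(1L, 301L), c(200L, 500L), c("hyper", "hyper")))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 500L))
  # gap of 101 bp -> two DMRs
  m <- merge_dmrs(mk_set(c(1L, 302L), c(200L, 500L), c("hyper", "hyper")))
  expect_equal(nrow(m), 2L)
  # gap of 150 bp -> two DMRs
  m <- merge_dmrs(mk_set(c(1L, 351L), c(200L, 500L), c("hyper", "hyper")))
  expect_equal(nrow(m), 2L)
  # opposite directions never merge, whatever the gap
  m <- merge_dmrs(mk_set(c(1L, 211L), c(200L, 400L), c("hyper", "hypo")))
  expect_equal(nrow(m), 2L)
  # idempotence
  two <- mk_set(c(1L, 351L), c(200L, 500L), c("hyper", "hyper"))
  expect_identical(as.data.frame(merge_dmrs(merge_dmrs(two))),
                   as.data.frame(merge_dmrs(two)))
})

test_that("no DMPs anywhere means no DMRs", {
  cnt <- matrix(c(5L, 5L), nrow = 10, ncol = 2, byrow = TRUE)
  tabs <- toy_tables(seq(10, 500, by = 50), list(cnt, cnt, cnt, cnt))
  elig <- build_eligible_set(tabs)
  dmps <- call_dmps(tabs, g1, g2, elig)
  dmrs <- call_dmrs(tabs, g1, g2, dmps, eligible = elig)
  expect_equal(nrow(dmrs), 0L)
})
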