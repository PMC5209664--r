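test_that("context assignment reads the two downstream bases on the cytosine's strand", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "CGTCATCAGTACGC"))
  #                                        12345678901234
  expect_equal(assign_context(ref, "chr1", 1, "+"), "CG")   # CGT
  expect_equal(assign_context(ref, "chr1", 4, "+"), "CHH")  # CAT
  expect_equal(assign_context(ref, "chr1", 7, "+"), "CHG")  # CAG
  # bottom-strand C pairs the G at position 13; its 3' neighbour is the
  # complement of the C at position 12, i.e. G: context CG
  expect_equal(assign_context(ref, "chr1", 13, "-"), "CG")
  # too close to the end for a full trinucleotide
  expect_true(is.na(assign_context(ref, "chr1", 14, "+")))
  expect_error(assign_context(ref, "chr1", 2, "+"), "not a cytosine")
  refN <- Biostrings::DNAStringSet(c(chr1 = "CNA"))
  expect_true(is.na(assign_context(refN, "chr1", 1, "+")))
})

test_that("region labels follow the precedence policy and the promoter window", {
  feats <- GenomicRanges::GRanges(
    rep("chr1", 4),
    IRanges::IRanges(c(2000, 2100, 2600, 2100), c(3000, 2500, 2900, 2300)),
    strand = "+",
    kind = c("gene", "CDS", "intron", "TE"),
    id = c("g1", "g1", "g1", "te1"))
  site <- function(p) data.frame(chrom = "chr1", pos = p)
  expect_equal(assign_region(site(2400), feats), "CDS")
  expect_equal(assign_region(site(2200), feats), "TE")   # TE beats CDS
  expect_equal(assign_region(site(2700), feats), "intron")
  expect_equal(assign_region(site(1500), feats), "promoter")  # 500 bp up
  expect_equal(assign_region(site(500), feats), "intergenic") # 1500 bp up
  expect_equal(assign_region(site(1500), feats, promoter_length = 200),
               "intergenic")
})

test_that("distribution summaries conserve event counts in their marginals", {
  ev <- data.table::data.table(
    chrom = "chr1", pos = 1:5, strand = "+",
    direction = c(rep("hyper", 3), rep("hypo", 2)),
    context = c("CG", "CG", "CG", "CHH", "CHH"),
    region = c(rep("promoter", 3), rep("TE", 2)))
  dist <- distribution_summary(ev)
  expect_equal(sum(dist$n), 5L)
  expect_equal(dist[context == "CG" & region == "promoter" &
                      direction == "hyper"]$n, 3L)
  expect_equal(dist[context == "CHH" & region == "TE" &
                      direction == "hypo"]$n, 2L)
  expect_equal(sum(dist$n == 0), nrow(dist) - 2L)
})

test_that("DMR-gene association follows the majority-overlap rule with ties to body", {
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 4000),
                                  strand = "+", kind = "gene", id = "g1")
  mk_dmr <- function(s, e) {
    out <- data.table::data.table(chrom = "chr1", start = s, end = e,
                                  direction = "hyper", n_dmps = 7L,
                                  level1 = .9, level2 = .2, fold = 4.5,
                                  adj_p = 1e-4)
    data.table::setattr(out, "class", c("dmr_set", class(out)))
    out
  }
  # fully inside the body
  expect_equal(overlap_dmrs_genes(mk_dmr(2500L, 2700L), feats)$location,
               "body")
  # fully inside the promoter window (1000..1999)
  expect_equal(overlap_dmrs_genes(mk_dmr(1200L, 1400L), feats)$location,
               "promoter")
  # straddling 60% promoter / 40% body
  expect_equal(overlap_dmrs_genes(mk_dmr(1940L, 2039L), feats)$location,
               "promoter")
  # exact tie goes to body
  expect_equal(overlap_dmrs_genes(mk_dmr(1950L, 2049L), feats)$location,
               "body")
  # no overlap, no row
  expect_equal(nrow(overlap_dmrs_genes(mk_dmr(5000L, 5100L), feats)), 0L)
})

test_that("metagene profiles are flat for flat input and dip where the truth dips", {
  feats <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(1200, 3000), c(1799, 3599)),
    strand = c("+", "-"), kind = "gene", id = c("gp", "gm"))
  lv_flat <- data.table::data.table(chrom = "chr1", pos = 1:5000,
                                    level = 0.5)
  mp <- metagene_profile(lv_flat, feats, flank = 200, body_bins = 10,
                         flank_bins = 5)
  expect_true(all(abs(mp$mean_level - 0.5) < 1e-12))
  expect_equal(nrow(mp), 20L)

  # level 0 within 100 bp of each TSS, 0.8 elsewhere
  lv <- data.table::data.table(chrom = "chr1", pos = 1:5000, level = 0.8)
  lv[abs(pos - 1200) <= 100 | abs(pos - 3599) <= 100, level := 0]
  mp <- metagene_profile(lv, feats, flank = 200, body_bins = 10,
                         flank_bins = 5)
  tss_bins <- c(5, 6)   # last upstream and first body bin
  other <- setdiff(seq_len(20), 4:7)
  expect_lt(max(mp$mean_level[mp$bin %in% tss_bins]),
            min(mp$mean_level[mp$bin %in% other]))
})

test_that("metagene profiles mirror minus-strand features and shift with coordinates", {
  lv <- data.table::data.table(chrom = "chr1", pos = 1:4000,
                               level = rep(c(0.2, 0.8), each = 2000))
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 2499),
                                 strand = "+", kind = "gene", id = "gp")
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1502, 2501),
                                  strand = "-", kind = "gene", id = "gm")
  lv_rev <- data.table::data.table(chrom = "chr1", pos = 1:4000,
                                   level = rev(lv$level))
  mp_p <- metagene_profile(lv, plus, flank = 500, body_bins = 10,
                           flank_bins = 5)
  mp_m <- metagene_profile(lv_rev, minus, flank = 500, body_bins = 10,
                           flank_bins = 5)
  expect_equal(mp_p$mean_level, mp_m$mean_level, tolerance = 1e-9)

  shift <- 123L
  lv_s <- data.table::data.table(chrom = "chr1", pos = lv$pos + shift,
                                 level = lv$level)
  plus_s <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(1500 + shift,
                                                    2499 + shift),
                                   strand = "+", kind = "gene", id = "gp")
  mp_s <- metagene_profile(lv_s, plus_s, flank = 500, body_bins = 10,
                           flank_bins = 5)
  expect_equal(mp_p$mean_level, mp_s$mean_level)
})
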