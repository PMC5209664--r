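test_that("context mix controls simulated contexts and CG sites are more methylated than CHH", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 800,
                  context_mix = c(CG = 1, CHG = 0, CHH = 0), seed = 2)
  truth <- build_reference_methylome(d)
  expect_true(all(truth$sites$context == "CG"))

  d <- sim_design(n_chroms = 2, sites_per_chrom = 5000, seed = 2)
  truth <- build_reference_methylome(d)
  mCG <- mean(truth$sites$base_level[truth$sites$context == "CG"])
  mCHH <- mean(truth$sites$base_level[truth$sites$context == "CHH"])
  expect_gt(mCG, mCHH)
  # TE-resident sites are methylated in all contexts
  te <- truth$sites$region == "TE"
  expect_gt(mean(truth$sites$base_level[te]),
            mean(truth$sites$base_level[!te]))

  expect_error(sim_design(context_mix = c(CG = 0.5, CHG = 0.5, CHH = 0.5)),
               "config error")
})

test_that("identical designs reproduce byte-identical output", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 600, seed = 33)
  s1 <- simulate_methylome(d)
  s2 <- simulate_methylome(d)
  expect_identical(s1$levels, s2$levels)
  expect_identical(as.data.frame(s1$ledger), as.data.frame(s2$ledger))
  expect_identical(lapply(s1$tables, as.data.frame),
                   lapply(s2$tables, as.data.frame))
  f1 <- withr::local_tempdir(); f2 <- withr::local_tempdir()
  write_simulated_methylome(s1, f1)
  write_simulated_methylome(s2, f2)
  m1 <- tools::md5sum(list.files(f1, full.names = TRUE))
  m2 <- tools::md5sum(list.files(f2, full.names = TRUE))
  expect_identical(unname(m1), unname(m2))
})

test_that("with no event sources all generations share the baseline and the ledger is empty", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 800,
                  induction_rate = c(CG = 0, CHG = 0, CHH = 0),
                  drift_rate = 0, n_dmr_events = 0, seed = 5)
  planted <- plant_epimutations(build_reference_methylome(d), d)
  expect_equal(nrow(planted$ledger), 0L)
  for (col in colnames(planted$levels))
    expect_identical(planted$levels[, col], planted$levels[, "G0.D"])
})

test_that("full maintenance propagates every G0-induced event to all advanced drought lineages", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 1500,
                  induction_rate = c(CG = 0.02, CHG = 0.02, CHH = 0.02),
                  drift_rate = 0, n_dmr_events = 0, hotspot_fraction = 0,
                  maintenance_prob = 1, seed = 8)
  planted <- plant_epimutations(build_reference_methylome(d), d)
  led <- planted$ledger[planted$ledger$induced_in == "G0"]
  expect_gt(nrow(led), 10)
  expect_true(all(led$maintained_G10 & led$maintained_G11 &
                    led$maintained_G10R1))
  rows <- match(ledger_keys(led),
                with(planted$sites, paste(chrom, pos, strand, sep = ":")))
  for (g in c("G10", "G11", "G10R1")) {
    expect_identical(planted$levels[rows, paste0(g, ".D")],
                     planted$levels[rows, "G0.D"])
    # control lineage keeps the baseline
    expect_identical(planted$levels[rows, paste0(g, ".W")],
                     planted$sites$base_level[rows])
  }
})

test_that("hot spots concentrate recurrent induction across generations", {
  d <- sim_design(n_chroms = 2, sites_per_chrom = 5000,
                  hotspot_fraction = 0.01, hotspot_multiplier = 10,
                  induction_rate = c(CG = 0.02, CHG = 0.02, CHH = 0.02),
                  drift_rate = 0, n_dmr_events = 0, seed = 13)
  planted <- plant_epimutations(build_reference_methylome(d), d)
  led <- planted$ledger
  # events per locus: hotspot loci recur across generations far more often
  tab <- led[, .(n_gen = data.table::uniqueN(induced_in)),
             by = .(chrom, start, strand, hotspot)]
  expect_gt(mean(tab$n_gen[tab$hotspot] >= 2),
            5 * max(mean(tab$n_gen[!tab$hotspot] >= 2), 1e-3))
})

test_that("every ledger event is backed by a true-level contrast of at least half the effect size", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 3000,
                  drift_rate = 0.01, n_dmr_events = 3, seed = 21)
  planted <- plant_epimutations(build_reference_methylome(d), d)
  led <- planted$ledger
  keys <- with(planted$sites, paste(chrom, pos, strand, sep = ":"))
  for (i in seq_len(nrow(led))) {
    ev <- led[i]
    rows <- if (ev$kind == "DMR-like") {
      which(planted$sites$chrom == ev$chrom &
              planted$sites$pos >= ev$start & planted$sites$pos <= ev$end)
    } else match(paste(ev$chrom, ev$start, ev$strand, sep = ":"), keys)
    contrast <- if (ev$drift) {
      abs(planted$levels[rows, "G10.D"] - planted$levels[rows, "G0.D"])
    } else {
      g <- ev$induced_in
      abs(planted$levels[rows, paste0(g, ".D")] -
            planted$levels[rows, paste0(g, ".W")])
    }
    # point events carry the full contrast at their site; region events
    # (recovered from pooled window counts) carry it at region level,
    # where clamping of individual extreme-baseline sites averages out
    contrast <- if (ev$kind == "DMR-like") mean(contrast) else contrast
    expect_true(all(contrast >= d$effect_size / 2),
                label = sprintf("event %d contrast", i))
  }
})

test_that("count sampling respects degenerate depths and probabilities", {
  d0 <- sim_design(n_chroms = 1, sites_per_chrom = 300, depth_mean = 0,
                   seed = 3)
  planted <- plant_epimutations(build_reference_methylome(d0), d0)
  tab <- simulate_sample_counts(planted, "G0", "D", 1, d0)
  expect_true(all(tab$coverage == 0L))

  d1 <- sim_design(n_chroms = 1, sites_per_chrom = 1000, depth_mean = 30,
                   base_level_fixed = 1, nonconversion_rate = 0,
                   induction_rate = c(CG = 0, CHG = 0, CHH = 0),
                   drift_rate = 0, n_dmr_events = 0, seed = 3)
  planted <- plant_epimutations(build_reference_methylome(d1), d1)
  tab <- simulate_sample_counts(planted, "G0", "D", 1, d1)
  expect_true(all(tab[tab$chrom != "lambda", ]$unmeth == 0L))
})

test_that("lambda spike-in counts estimate the non-conversion rate within 3 binomial SE", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 200, depth_mean = 13,
                  nonconversion_rate = 0.01, n_lambda_sites = 5000,
                  seed = 17)
  planted <- plant_epimutations(build_reference_methylome(d), d)
  tab <- simulate_sample_counts(planted, "G0", "W", 1, d)
  lam <- tab[tab$chrom == "lambda", ]
  est <- estimate_conversion(lam, tc_error_rate = 0)
  n <- sum(lam$coverage)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(est$nonconversion_rate - 0.01), 3 * se)
})

test_that("simulated levels converge to the truth at high depth", {
  d <- sim_design(n_chroms = 1, sites_per_chrom = 2000, depth_mean = 500,
                  induction_rate = c(CG = 0, CHG = 0, CHH = 0),
                  drift_rate = 0, n_dmr_events = 0, seed = 29)
  planted <- plant_epimutations(build_reference_methylome(d), d)
  tab <- simulate_sample_counts(planted, "G0", "D", 1, d)
  tab <- tab[tab$chrom != "lambda", ]
  lvl <- tab$meth / tab$coverage
  # compare against the observation probability (truth plus conversion error)
  p_obs <- planted$sites$base_level * (1 - d$mc_fail_rate) +
    (1 - planted$sites$base_level) * d$nonconversion_rate
  expect_lt(mean(abs(lvl - p_obs)), 0.02)
})
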