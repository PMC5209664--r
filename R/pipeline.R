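#' Pipeline run configuration
#'
#' Collects the simulation design, calling thresholds and comparison plan
#' of an end-to-end run. Threshold defaults are the study's published
#' calling parameters: minimum coverage 3, per-site combined p < 0.01,
#' FDR 5%, 200-bp windows at 50-bp steps with at least 7 DMPs and a
#' 1.5-fold level change at adjusted p < 0.01, 100-bp merge gap, and a 5%
#' false-positive control level for the binomial mC caller.
#'
#' @param design A [sim_design()] (simulated input is the packaged mode of
#'   operation; real count tables can be substituted stage by stage).
#' @param comparisons List of comparisons, each a list with `label`,
#'   `g1 = c(generation, treatment)`, `g2 = c(generation, treatment)`.
#'   Default plan: drought vs well-watered within each generation
#'   (D0vsW0 ... D10R1vsW10R1), the accumulation comparison D10vsD0 and
#'   the offspring comparisons D11vsD0 and D10R1vsD0.
#' @param min_coverage,p_thresh,fdr,fpr,window,step,min_dmps,fold,adj_p,merge_gap
#'   Calling thresholds (see above).
#' @param out_dir Output directory.
#' @param seed Overrides `design$seed` when given.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(design = sim_design(),
                       comparisons = NULL,
                       min_coverage = 3L, p_thresh = 0.01, fdr = 0.05,
                       fpr = 0.05, window = 200L, step = 50L,
                       min_dmps = 7L, fold = 1.5, adj_p = 0.01,
                       merge_gap = 100L,
                       out_dir = tempfile("epimutools_run_"),
                       seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) design$seed <- as.integer(seed)
  if (is.null(comparisons)) {
    comparisons <- list(
      list(label = "D0vsW0", g1 = c("G0", "D"), g2 = c("G0", "W")),
      list(label = "D10vsW10", g1 = c("G10", "D"), g2 = c("G10", "W")),
      list(label = "D11vsW11", g1 = c("G11", "D"), g2 = c("G11", "W")),
      list(label = "D10R1vsW10R1", g1 = c("G10R1", "D"),
           g2 = c("G10R1", "W")),
      list(label = "D10vsD0", g1 = c("G10", "D"), g2 = c("G0", "D")),
      list(label = "D11vsD0", g1 = c("G11", "D"), g2 = c("G0", "D")),
      list(label = "D10R1vsD0", g1 = c("G10R1", "D"), g2 = c("G0", "D")))
  }
  labels <- vapply(comparisons, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stopf("config error: duplicate comparison labels")
  valid <- sample_keys()
  for (cmp in comparisons) {
    for (side in c("g1", "g2")) {
      gt <- cmp[[side]]
      if (!gt[1] %in% GENERATIONS || !gt[2] %in% TREATMENTS)
        stopf("config error: comparison '%s' references unknown sample group %s.%s",
              cmp$label, gt[1], gt[2])
    }
  }
  thresholds <- list(min_coverage = as.integer(min_coverage),
                     p_thresh = p_thresh, fdr = fdr, fpr = fpr,
                     window = as.integer(window), step = as.integer(step),
                     min_dmps = as.integer(min_dmps), fold = fold,
                     adj_p = adj_p, merge_gap = as.integer(merge_gap))
  bad <- vapply(thresholds, function(x) !is.numeric(x) || x < 0, logical(1))
  if (any(bad)) stopf("config error: thresholds must be non-negative")
  out <- list(design = design, comparisons = comparisons,
              thresholds = thresholds, out_dir = out_dir,
              seed = design$seed)
  class(out) <- "run_config"
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate, conversion calibration, methylation calling,
#' DMP/SMP/DMR calling per configured comparison, dynamics (recurrence,
#' maintenance, transgenerational inheritance, clustering), annotation and
#' reporting as one seeded, logged run. Identical configurations produce
#' byte-identical outputs. All intermediates are plain files (TSV/BED/
#' JSON/FASTA/GFF3) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return An object of class `run_report`: per-stage record counts,
#'   parameter echo, tally tables and a file manifest with MD5 checksums.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  t_all <- Sys.time()
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = th, seed = config$seed, stages = list())

  sim <- stage("simulate", simulate_methylome(config$design))
  paths <- stage("write", write_simulated_methylome(
    sim, file.path(config$out_dir, "sim")))
  report$stages$simulate <- list(n_sites = nrow(sim$sites),
                                 n_samples = length(sim$tables),
                                 n_planted_events = nrow(sim$ledger))

  est <- stage("conversion", {
    pooled <- rbindlist(lapply(sim$tables, function(t)
      as.data.table(t)[chrom == "lambda"]))
    estimate_conversion(pooled, tc_error_rate = config$design$tc_error_rate)
  })
  report$stages$conversion <- list(
    nonconversion_rate = est$nonconversion_rate, p_error = est$p_error)

  eligible <- stage("eligible", build_eligible_set(
    sim$tables, min_coverage = th$min_coverage, exclude = "lambda"))
  report$stages$eligible <- list(n_sites = nrow(eligible))

  statuses <- stage("callmc", status_matrix(
    sim$tables, est, fpr = th$fpr, min_coverage = th$min_coverage,
    sites = eligible))

  calls <- list()
  for (cmp in config$comparisons) {
    lab <- cmp$label
    g1 <- group_spec(cmp$g1[1], cmp$g1[2])
    g2 <- group_spec(cmp$g2[1], cmp$g2[2])
    missing_s <- setdiff(c(g1$samples, g2$samples), names(sim$tables))
    if (length(missing_s))
      stopf("stage 'differential' failed: sample '%s' absent for comparison %s",
            missing_s[1], lab)
    res <- stage(paste0("compare:", lab), {
      dmps <- call_dmps(sim$tables, g1, g2, eligible,
                        p_thresh = th$p_thresh, fdr = th$fdr)
      smps <- call_smps(statuses, g1, g2)
      dmrs <- call_dmrs(sim$tables, g1, g2, dmps, eligible = eligible,
                        window = th$window, step = th$step,
                        min_dmps = th$min_dmps, fold = th$fold,
                        adj_p = th$adj_p, merge_gap = th$merge_gap)
      list(dmps = dmps, smps = smps, dmrs = dmrs)
    })
    calls[[lab]] <- res
    write_tsv(res$dmps, file.path(config$out_dir,
                                  paste0("dmps_", lab, ".tsv")),
              params = list(comparison = lab))
    write_tsv(res$smps, file.path(config$out_dir,
                                  paste0("smps_", lab, ".tsv")),
              params = list(comparison = lab))
    write_dmrs_bed(res$dmrs, file.path(config$out_dir,
                                       paste0("dmrs_", lab, ".bed")))
    report$stages[[paste0("compare:", lab)]] <- list(
      n_dmps = nrow(res$dmps), n_smps = nrow(res$smps),
      n_dmrs = nrow(res$dmrs))
  }

  # dynamics over the drought-vs-control series
  dvw <- grep("vsW", names(calls), value = TRUE)
  if (length(dvw) >= 2L) {
    rec <- stage("recurrence", recurrence_analysis(
      lapply(calls[dvw], `[[`, "dmps"), eligible_n = nrow(eligible)))
    report$stages$recurrence <- list(summary = rec$summary)
    write_tsv(rec$summary, file.path(config$out_dir,
                                     "recurrence_summary.tsv"))
  }
  if ("D0vsW0" %in% names(calls)) {
    adv <- setdiff(dvw, "D0vsW0")
    if (length(adv)) {
      maint <- stage("maintenance", classify_maintenance(
        calls$D0vsW0$dmps, lapply(calls[adv], `[[`, "dmps")))
      report$stages$maintenance <- list(table = maint$table)
      write_tsv(maint$table, file.path(config$out_dir,
                                       "maintenance_dmps.tsv"))
    }
  }
  if (all(c("D10vsD0", "D11vsD0", "D10R1vsD0") %in% names(calls))) {
    trans <- stage("transgenerational", classify_transgenerational(
      calls$D10vsD0$dmps, list(calls$D11vsD0$dmps),
      list(calls$D10R1vsD0$dmps)))
    report$stages$transgenerational <- list(table = trans$table)
    write_tsv(trans$table, file.path(config$out_dir,
                                     "transgenerational_dmps.tsv"))
  }
  if ("D0vsW0" %in% names(calls) && nrow(calls$D0vsW0$dmps) >= 3L) {
    clus <- stage("cluster", {
      lvls <- sample_level_matrix(sim$tables, calls$D0vsW0$dmps)
      cluster_samples(lvls)
    })
    report$stages$cluster <- list(n_loci = clus$n_loci)
    writeLines(clus$newick, file.path(config$out_dir,
                                      "clustering_induced.nwk"))
  }

  if ("D0vsW0" %in% names(calls) && nrow(calls$D0vsW0$dmps)) {
    annot <- stage("annotate", {
      ann <- annotate_events(calls$D0vsW0$dmps, sim$features,
                             sim$reference)
      distribution_summary(ann)
    })
    report$stages$annotate <- list(n_cells = nrow(annot))
    write_tsv(annot, file.path(config$out_dir,
                               "distribution_D0vsW0_dmps.tsv"))
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.table(file = sub(paste0("^", config$out_dir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)))
  report$manifest <- manifest
  report$runtime_s <- as.numeric(difftime(Sys.time(), t_all,
                                          units = "secs"))
  jsonlite::write_json(
    list(seed = report$seed, parameters = report$parameters,
         stages = report$stages, runtime_s = report$runtime_s),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d), %.1fs\n", x$seed, x$runtime_s))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    scalar <- st[vapply(st, function(v) is.atomic(v) && length(v) == 1L,
                        logical(1))]
    cat(sprintf("  %-22s %s\n", nm,
                paste(names(scalar), unlist(scalar), sep = "=",
                      collapse = " ")))
  }
  cat(sprintf("  %d files in manifest\n", nrow(x$manifest)))
  invisible(x)
}
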