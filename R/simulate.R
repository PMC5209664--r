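#' Simulation design for a multi-generation methylome study
#'
#' Parameters of the synthetic whole-genome bisulfite design the package is
#' validated on: per variety, 16 samples = 4 generations (G0, G10, G11 and
#' the well-watered recovery generation G10R1) x 2 treatments (drought D,
#' well-watered W) x 2 sibling replicates, sequenced at a mean strand-
#' specific depth of about 13x, with an unmethylated lambda spike-in for
#' conversion calibration.
#'
#' @param n_chroms Number of simulated chromosomes.
#' @param sites_per_chrom Cytosines retained per chromosome.
#' @param depth_mean Mean per-site read depth (Poisson, or negative
#'   binomial when `coverage_model = "nbinom"`). Default 13.
#' @param coverage_model `"poisson"` (default) or `"nbinom"`.
#' @param nb_size Negative-binomial size parameter (dispersion) when
#'   `coverage_model = "nbinom"`.
#' @param nonconversion_rate Probability that an unmethylated cytosine
#'   escapes bisulfite conversion and reads as methylated (default 0.005).
#' @param mc_fail_rate Probability that a methylated cytosine is
#'   over-converted and reads as unmethylated (default 0).
#' @param tc_error_rate T-to-C sequencing error rate echoed to the caller
#'   configuration (default 0.001).
#' @param context_mix Named probabilities over contexts CG/CHG/CHH; must
#'   sum to 1.
#' @param te_fraction Approximate fraction of the genome covered by
#'   transposable elements (default 0.35).
#' @param gene_fraction Approximate fraction covered by genes.
#' @param hotspot_fraction Fraction of sites designated epimutation hot
#'   spots (default 0.01).
#' @param hotspot_multiplier Fold elevation of the induction rate at hot
#'   spots (default 10).
#' @param induction_rate Named per-context probability that a site acquires
#'   a drought-induced epimutation in a given generation.
#' @param drift_rate Fraction of sites acquiring a generation-accumulated
#'   epimutation present in both lineages of all advanced generations
#'   (models spontaneous epimutation accumulation between G0 and G10).
#' @param effect_size Absolute shift in true methylation level per planted
#'   event, in (0, 1]; default 0.6.
#' @param maintenance_prob Probability that a planted change is inherited
#'   along the lineage (G0 to G10; and conditional on G10, onward to G11
#'   and to G10R1, each independently). Default 0.8.
#' @param n_dmr_events Number of planted region events (contiguous runs of
#'   at least `dmr_min_sites` shifted cytosines within `dmr_span` bp).
#' @param dmr_span,dmr_min_sites Region-event geometry (defaults 200 bp,
#'   8 sites).
#' @param base_level_fixed If non-`NULL`, every site's baseline methylation
#'   level is set to this value (useful for controlled power studies).
#' @param n_lambda_sites Number of spike-in cytosines per sample.
#' @param seed Integer seed; identical designs give byte-identical output.
#' @return An object of class `sim_design` (a validated list).
#' @export
sim_design <- function(n_chroms = 2L,
                       sites_per_chrom = 5000L,
                       depth_mean = 13,
                       coverage_model = c("poisson", "nbinom"),
                       nb_size = 5,
                       nonconversion_rate = 0.005,
                       mc_fail_rate = 0,
                       tc_error_rate = 0.001,
                       context_mix = c(CG = 0.25, CHG = 0.25, CHH = 0.5),
                       te_fraction = 0.35,
                       gene_fraction = 0.30,
                       hotspot_fraction = 0.01,
                       hotspot_multiplier = 10,
                       induction_rate = c(CG = 0.005, CHG = 0.005,
                                          CHH = 0.005),
                       drift_rate = 0.01,
                       effect_size = 0.6,
                       maintenance_prob = 0.8,
                       n_dmr_events = 4L,
                       dmr_span = 200L,
                       dmr_min_sites = 8L,
                       base_level_fixed = NULL,
                       n_lambda_sites = 1000L,
                       seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  if (abs(sum(context_mix) - 1) > 1e-6)
    stopf("config error: context_mix must sum to 1")
  if (!all(names(context_mix) %in% CONTEXTS) || length(context_mix) != 3L)
    stopf("config error: context_mix must be named over %s",
          paste(CONTEXTS, collapse = "/"))
  rates <- c(nonconversion_rate, mc_fail_rate, tc_error_rate,
             hotspot_fraction, drift_rate, maintenance_prob, induction_rate,
             te_fraction, gene_fraction)
  if (any(rates < 0 | rates > 1))
    stopf("config error: all rates and fractions must lie in [0, 1]")
  if (effect_size <= 0 || effect_size > 1)
    stopf("config error: effect_size must lie in (0, 1]")
  if (te_fraction + gene_fraction > 0.95)
    stopf("config error: te_fraction + gene_fraction too large")
  design <- list(
    n_chroms = as.integer(n_chroms),
    sites_per_chrom = as.integer(sites_per_chrom),
    depth_mean = depth_mean, coverage_model = coverage_model,
    nb_size = nb_size,
    nonconversion_rate = nonconversion_rate, mc_fail_rate = mc_fail_rate,
    tc_error_rate = tc_error_rate,
    context_mix = context_mix[CONTEXTS],
    te_fraction = te_fraction, gene_fraction = gene_fraction,
    hotspot_fraction = hotspot_fraction,
    hotspot_multiplier = hotspot_multiplier,
    induction_rate = induction_rate[CONTEXTS],
    drift_rate = drift_rate, effect_size = effect_size,
    maintenance_prob = maintenance_prob,
    n_dmr_events = as.integer(n_dmr_events),
    dmr_span = as.integer(dmr_span),
    dmr_min_sites = as.integer(dmr_min_sites),
    base_level_fixed = base_level_fixed,
    n_lambda_sites = as.integer(n_lambda_sites),
    seed = as.integer(seed))
  names(design$induction_rate) <- CONTEXTS
  class(design) <- "sim_design"
  design
}

#' The 16-sample design key table
#'
#' @return A `data.table` of the full design per variety: generation
#'   (G0/G10/G11/G10R1) x treatment (D/W) x replicate (1/2), with a
#'   `label` column like `"G10.D.2"`.
#' @export
sample_keys <- function() {
  keys <- data.table::CJ(generation = GENERATIONS, treatment = TREATMENTS,
                         replicate = 1:2, sorted = FALSE)
  keys[, generation := factor(generation, levels = GENERATIONS)]
  setorderv(keys, c("generation", "treatment", "replicate"))
  keys[, label := paste(generation, treatment, replicate, sep = ".")]
  keys[, generation := as.character(generation)]
  keys[]
}

#' A replicate group (generation x treatment)
#'
#' @param generation One of G0, G10, G11, G10R1.
#' @param treatment `"D"` (drought) or `"W"` (well-watered).
#' @return A `group_spec`: the pair of sibling-replicate sample labels of
#'   one generation/treatment cell, with a short label such as `"D10"`.
#' @export
group_spec <- function(generation, treatment) {
  generation <- match.arg(generation, GENERATIONS)
  treatment <- match.arg(treatment, TREATMENTS)
  out <- list(generation = generation, treatment = treatment,
              samples = paste(generation, treatment, 1:2, sep = "."),
              label = paste0(treatment, sub("^G", "", generation)))
  class(out) <- "group_spec"
  out
}

# truth level column for a sample
level_column <- function(generation, treatment) paste(generation, treatment,
                                                      sep = ".")

clamp01 <- function(x) pmin(1, pmax(0, x))

# scan a chromosome sequence for cytosines on both strands, with context
# and trinucleotide (5'->3' on the cytosine's strand)
scan_cytosines <- function(seq_chars, chrom) {
  L <- length(seq_chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # plus strand: C at pos, context from pos+1, pos+2
  ppos <- which(seq_chars == "C")
  ppos <- ppos[ppos <= L - 2L]
  b1 <- seq_chars[ppos + 1L]; b2 <- seq_chars[ppos + 2L]
  pctx <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  pctx[b1 == "N" | (b1 != "G" & b2 == "N")] <- NA
  ptri <- paste0("C", b1, b2)
  # minus strand: G at pos is a C on the bottom strand; its 3' neighbours
  # are the complements of pos-1, pos-2
  mpos <- which(seq_chars == "G")
  mpos <- mpos[mpos >= 3L]
  c1 <- comp[seq_chars[mpos - 1L]]; c2 <- comp[seq_chars[mpos - 2L]]
  mctx <- ifelse(c1 == "G", "CG", ifelse(c2 == "G", "CHG", "CHH"))
  mctx[c1 == "N" | (c1 != "G" & c2 == "N")] <- NA
  mtri <- paste0("C", c1, c2)
  dt <- data.table(
    chrom = chrom,
    pos = c(ppos, mpos),
    strand = rep(c("+", "-"), c(length(ppos), length(mpos))),
    context = c(pctx, mctx),
    trinucleotide = c(ptri, mtri))
  dt <- dt[!is.na(context)]
  setorderv(dt, c("pos", "strand"))
  dt[]
}

# lay out non-overlapping gene/TE features along a chromosome, with
# exon/intron/UTR structure for genes
layout_features <- function(L, chrom, design) {
  avg <- c(gene = 1600, TE = 850, gap = 350)
  w <- c(gene = design$gene_fraction / avg["gene"],
         TE = design$te_fraction / avg["TE"],
         gap = max(1 - design$gene_fraction - design$te_fraction, 0.05) /
           avg["gap"])
  w <- w / sum(w)
  rows <- list()
  pos <- sample.int(300L, 1L)
  gid <- 0L; tid <- 0L
  while (pos < L - 2500L) {
    type <- sample(c("gene", "TE", "gap"), 1L, prob = w)
    if (type == "gap") {
      pos <- pos + sample(100:600, 1L)
    } else if (type == "TE") {
      len <- sample(200:1500, 1L)
      tid <- tid + 1L
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, start = pos, end = min(pos + len - 1L, L),
        strand = "+", kind = "TE", id = sprintf("%s_TE%03d", chrom, tid))
      pos <- pos + len + sample(50:200, 1L)
    } else {
      len <- sample(800:2400, 1L)
      gid <- gid + 1L
      id <- sprintf("%s_g%03d", chrom, gid)
      gstrand <- sample(c("+", "-"), 1L)
      gstart <- pos; gend <- min(pos + len - 1L, L)
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, start = gstart, end = gend, strand = gstrand,
        kind = "gene", id = id)
      # 2-3 exons separated by introns; terminal 100 bp of the gene are
      # UTRs (5' at the strand-aware start)
      n_ex <- sample(2:3, 1L)
      cuts <- sort(sample(seq(gstart + 150L, gend - 150L, by = 10L),
                          2L * (n_ex - 1L)))
      bounds <- matrix(c(gstart, cuts, gend), ncol = 2L, byrow = TRUE)
      for (e in seq_len(nrow(bounds))) {
        rows[[length(rows) + 1L]] <- data.table(
          chrom = chrom, start = bounds[e, 1L], end = bounds[e, 2L],
          strand = gstrand, kind = "CDS", id = id)
        if (e < nrow(bounds))
          rows[[length(rows) + 1L]] <- data.table(
            chrom = chrom, start = bounds[e, 2L] + 1L,
            end = bounds[e + 1L, 1L] - 1L, strand = gstrand,
            kind = "intron", id = id)
      }
      utr5 <- if (gstrand == "+") c(gstart, gstart + 99L) else
        c(gend - 99L, gend)
      utr3 <- if (gstrand == "+") c(gend - 99L, gend) else
        c(gstart, gstart + 99L)
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, start = utr5[1L], end = utr5[2L], strand = gstrand,
        kind = "five_prime_UTR", id = id)
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, start = utr3[1L], end = utr3[2L], strand = gstrand,
        kind = "three_prime_UTR", id = id)
      pos <- pos + len + sample(100:400, 1L)
    }
  }
  if (!length(rows)) return(NULL)
  rbindlist(rows)
}

# baseline methylation level per site given context and TE membership:
# CG bimodal with a dominant high mode, CHH low, TE sites methylated in
# all contexts
draw_base_levels <- function(context, in_te, fixed = NULL) {
  n <- length(context)
  if (!is.null(fixed)) return(rep(fixed, n))
  lvl <- numeric(n)
  for (ctx in CONTEXTS) {
    i <- which(context == ctx & !in_te)
    if (length(i)) {
      p_high <- switch(ctx, CG = 0.55, CHG = 0.35, CHH = 0.08)
      high <- runif(length(i)) < p_high
      lvl[i[high]] <- rbeta(sum(high), 8, 2)
      lvl[i[!high]] <- rbeta(sum(!high), 0.6, 12)
    }
    j <- which(context == ctx & in_te)
    if (length(j))
      lvl[j] <- if (ctx == "CHH") rbeta(length(j), 5, 3) else
        rbeta(length(j), 8, 2)
  }
  lvl
}

#' Build the baseline (pre-event) true methylome
#'
#' Simulates reference sequences, gene/TE annotation and a per-site true
#' baseline methylation level shared by all samples before any epimutation
#' is planted. CG sites draw from a predominantly high-level mode and CHH
#' sites from a low-level mode; TE-resident sites are methylated in all
#' contexts.
#'
#' @param design A [sim_design()].
#' @return An object of class `true_methylome`: list with `sites` (a
#'   `data.table` of chrom, pos, strand, context, trinucleotide, region,
#'   base_level, hotspot), `reference` (a
#'   [Biostrings::DNAStringSet]), `features` (a `GRanges`) and the design.
#' @export
build_reference_methylome <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  chroms <- paste0("chr", seq_len(design$n_chroms))
  # size the chromosome so every context's random-sequence availability
  # (CG:CHG:CHH = 4:3:9 among cytosines, ~0.5 cytosines/bp over both
  # strands) exceeds its target with margin
  avail_frac <- c(CG = 4, CHG = 3, CHH = 9) / 16
  need <- design$context_mix / (0.5 * avail_frac)
  L <- as.integer(ceiling(design$sites_per_chrom * max(2.4,
                                                       1.35 * max(need))))
  seqs <- vector("list", length(chroms))
  site_list <- vector("list", length(chroms))
  feat_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqs[[ci]] <- paste(chars, collapse = "")
    cand <- scan_cytosines(chars, chroms[ci])
    # stratified subsample to the design's context mix
    target <- round(design$context_mix * design$sites_per_chrom)
    pick <- integer()
    for (ctx in CONTEXTS) {
      avail <- which(cand$context == ctx)
      pick <- c(pick, sample(avail, min(target[[ctx]], length(avail))))
    }
    short <- design$sites_per_chrom - length(pick)
    if (short > 0) {
      rest <- setdiff(seq_len(nrow(cand)), pick)
      pick <- c(pick, sample(rest, min(short, length(rest))))
    }
    site_list[[ci]] <- cand[sort(pick)]
    feat_list[[ci]] <- layout_features(L, chroms[ci], design)
  }
  sites <- rbindlist(site_list)
  feats <- rbindlist(feat_list[!vapply(feat_list, is.null, logical(1))])
  features <- if (nrow(feats)) {
    GenomicRanges::GRanges(feats$chrom,
                           IRanges::IRanges(feats$start, feats$end),
                           strand = feats$strand, kind = feats$kind,
                           id = feats$id)
  } else GenomicRanges::GRanges(kind = character(), id = character())
  reference <- Biostrings::DNAStringSet(setNames(unlist(seqs), chroms))
  # region labels: TE beats gene beats intergenic
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos))
  in_te <- overlapsAny(gr_sites, features[mcols(features)$kind == "TE"],
                       ignore.strand = TRUE)
  in_gene <- overlapsAny(gr_sites, features[mcols(features)$kind == "gene"],
                         ignore.strand = TRUE)
  sites[, region := ifelse(in_te, "TE", ifelse(in_gene, "gene",
                                               "intergenic"))]
  sites[, base_level := draw_base_levels(context, in_te,
                                         design$base_level_fixed)]
  n_hot <- round(design$hotspot_fraction * nrow(sites))
  sites[, hotspot := FALSE]
  if (n_hot > 0) sites$hotspot[sample.int(nrow(sites), n_hot)] <- TRUE
  sites[, site_id := seq_len(.N)]
  out <- list(sites = sites, reference = reference, features = features,
              design = design)
  class(out) <- "true_methylome"
  out
}

#' Plant heritable epimutations into a true methylome
#'
#' Expands the baseline methylome to a per-(generation, treatment) truth
#' level matrix and plants three classes of events, recording every one in
#' a truth ledger:
#' \itemize{
#'   \item \emph{Drought-induced point events}: in each generation, sites
#'     (hot spots at an elevated rate) shift their true level by
#'     `effect_size` in the drought sample of that generation relative to
#'     its well-watered sibling group. Direction is hyper when the
#'     baseline is below 0.5, hypo otherwise, so the planted contrast is
#'     always at least `effect_size / 2` after clamping to \[0, 1\].
#'   \item \emph{Inheritance}: a G0-induced change persists into the G10
#'     drought lineage with probability `maintenance_prob`, and (given
#'     G10) onward into G11 and into the well-watered recovery generation
#'     G10R1, each with probability `maintenance_prob`; G10-induced
#'     changes persist into G11 and G10R1 the same way.
#'   \item \emph{Generational drift}: a `drift_rate` fraction of sites
#'     shift in \emph{both} lineages of all advanced generations,
#'     modelling spontaneous epimutation accumulation between G0 and G10.
#'   \item \emph{Region events}: `n_dmr_events` runs of at least
#'     `dmr_min_sites` cytosines within `dmr_span` bp shifted as a unit,
#'     giving the window-based DMR caller recoverable targets.
#' }
#'
#' @param truth A `true_methylome` from [build_reference_methylome()].
#' @param design The same [sim_design()].
#' @return An object of class `planted_methylome`: list with `sites`,
#'   `levels` (sites x 8 matrix, columns `G0.D`, `G0.W`, ...), `ledger`
#'   (a `data.table` of planted events with maintenance flags), plus the
#'   reference, features and design.
#' @export
plant_epimutations <- function(truth, design) {
  stopifnot(inherits(truth, "true_methylome"),
            inherits(design, "sim_design"))
  set.seed(design$seed + 1L)
  sites <- truth$sites
  n <- nrow(sites)
  cols <- as.vector(outer(GENERATIONS, TREATMENTS, level_column))
  levels <- matrix(rep(sites$base_level, length(cols)), nrow = n,
                   dimnames = list(NULL, cols))
  eff <- design$effect_size
  m <- design$maintenance_prob
  ledger <- list()
  shifted_level <- function(base, direction)
    clamp01(base + ifelse(direction == "hyper", eff, -eff))

  # --- drought-induced point events ---------------------------------------
  rate <- design$induction_rate[sites$context] *
    ifelse(sites$hotspot, design$hotspot_multiplier, 1)
  rate <- pmin(rate, 1)
  site_has_event <- rep(FALSE, n)
  for (g in GENERATIONS) {
    idx <- which(runif(n) < rate)
    site_has_event[idx] <- TRUE
    if (!length(idx)) next
    dir <- ifelse(sites$base_level[idx] < 0.5, "hyper", "hypo")
    newlvl <- shifted_level(sites$base_level[idx], dir)
    clamped <- abs(newlvl - sites$base_level[idx]) < eff - 1e-12
    levels[idx, level_column(g, "D")] <- newlvl
    m10 <- m11 <- m10r1 <- rep(NA, length(idx))
    if (g == "G0") {
      m10 <- runif(length(idx)) < m
      m11 <- m10 & runif(length(idx)) < m
      m10r1 <- m10 & runif(length(idx)) < m
    } else if (g == "G10") {
      m11 <- runif(length(idx)) < m
      m10r1 <- runif(length(idx)) < m
    }
    for (adv in c("G10", "G11", "G10R1")) {
      flag <- switch(adv, G10 = m10, G11 = m11, G10R1 = m10r1)
      take <- which(!is.na(flag) & flag)
      if (length(take))
        levels[idx[take], level_column(adv, "D")] <- newlvl[take]
    }
    ledger[[length(ledger) + 1L]] <- data.table(
      chrom = sites$chrom[idx], start = sites$pos[idx],
      end = sites$pos[idx], strand = sites$strand[idx],
      kind = "DMP-like", direction = dir, context = sites$context[idx],
      induced_in = g, hotspot = sites$hotspot[idx], drift = FALSE,
      maintained_G10 = m10, maintained_G11 = m11,
      maintained_G10R1 = m10r1, clamped = clamped)
  }

  # --- generational drift (both lineages of advanced generations) ---------
  if (design$drift_rate > 0) {
    # drift never lands on a drought-induced site, so every ledger event
    # keeps its full planted contrast in its inducing comparison
    idx <- which(runif(n) < design$drift_rate & !site_has_event)
    site_has_event[idx] <- TRUE
    if (length(idx)) {
      dir <- ifelse(sites$base_level[idx] < 0.5, "hyper", "hypo")
      newlvl <- shifted_level(sites$base_level[idx], dir)
      clamped <- abs(newlvl - sites$base_level[idx]) < eff - 1e-12
      m11 <- runif(length(idx)) < m
      m10r1 <- runif(length(idx)) < m
      for (adv in c("G10", "G11", "G10R1")) {
        flag <- switch(adv, G10 = rep(TRUE, length(idx)), G11 = m11,
                       G10R1 = m10r1)
        take <- which(flag)
        if (length(take)) {
          levels[idx[take], level_column(adv, "D")] <- newlvl[take]
          levels[idx[take], level_column(adv, "W")] <- newlvl[take]
        }
      }
      ledger[[length(ledger) + 1L]] <- data.table(
        chrom = sites$chrom[idx], start = sites$pos[idx],
        end = sites$pos[idx], strand = sites$strand[idx],
        kind = "DMP-like", direction = dir, context = sites$context[idx],
        induced_in = "G10", hotspot = sites$hotspot[idx], drift = TRUE,
        maintained_G10 = TRUE, maintained_G11 = m11,
        maintained_G10R1 = m10r1, clamped = clamped)
    }
  }

  # --- region (DMR-like) events -------------------------------------------
  if (design$n_dmr_events > 0) {
    used <- GenomicRanges::GRanges()
    planted <- 0L
    for (try in seq_len(design$n_dmr_events * 20L)) {
      if (planted >= design$n_dmr_events) break
      ch <- sample(unique(sites$chrom), 1L)
      sub_rows <- which(sites$chrom == ch)
      ord <- sub_rows[order(sites$pos[sub_rows])]
      posv <- sites$pos[ord]
      k <- design$dmr_min_sites
      if (length(posv) < k) next
      starts <- which(posv[seq_len(length(posv) - k + 1L) + k - 1L] -
                        posv[seq_len(length(posv) - k + 1L)] <
                        design$dmr_span)
      if (!length(starts)) next
      s <- sample(starts, 1L)
      span_start <- posv[s]
      span_end <- span_start + design$dmr_span - 1L
      reg <- GenomicRanges::GRanges(ch, IRanges::IRanges(span_start,
                                                         span_end))
      if (length(used) && any(suppressWarnings(overlapsAny(reg, used)))) next
      rows <- ord[posv >= span_start & posv <= span_end]
      if (any(site_has_event[rows])) next
      used <- suppressWarnings(c(used, reg))
      site_has_event[rows] <- TRUE
      base <- sites$base_level[rows]
      dir <- if (mean(base) < 0.5) "hyper" else "hypo"
      g <- sample(c("G0", "G10"), 1L)
      newlvl <- shifted_level(base, dir)
      levels[rows, level_column(g, "D")] <- newlvl
      m10 <- m11 <- m10r1 <- NA
      if (g == "G0") {
        m10 <- runif(1) < m
        m11 <- m10 && runif(1) < m
        m10r1 <- m10 && runif(1) < m
      } else {
        m11 <- runif(1) < m
        m10r1 <- runif(1) < m
      }
      for (adv in c("G10", "G11", "G10R1")) {
        flag <- switch(adv, G10 = m10, G11 = m11, G10R1 = m10r1)
        if (!is.na(flag) && flag)
          levels[rows, level_column(adv, "D")] <- newlvl
      }
      ledger[[length(ledger) + 1L]] <- data.table(
        chrom = ch, start = span_start,
        end = max(sites$pos[rows]), strand = "*",
        kind = "DMR-like", direction = dir, context = NA_character_,
        induced_in = g, hotspot = FALSE, drift = FALSE,
        maintained_G10 = m10, maintained_G11 = m11,
        maintained_G10R1 = m10r1,
        clamped = any(abs(newlvl - base) < eff - 1e-12))
      planted <- planted + 1L
    }
  }

  ledger <- if (length(ledger)) rbindlist(ledger) else data.table(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), direction = character(),
    context = character(), induced_in = character(), hotspot = logical(),
    drift = logical(), maintained_G10 = logical(),
    maintained_G11 = logical(), maintained_G10R1 = logical(),
    clamped = logical())
  ledger[, event_id := seq_len(.N)]
  out <- list(sites = sites, levels = levels, ledger = ledger,
              reference = truth$reference, features = truth$features,
              design = design)
  class(out) <- "planted_methylome"
  out
}

#' Simulate per-cytosine bisulfite counts for one sample
#'
#' Coverage is Poisson (or negative binomial) around the design depth;
#' methylated reads are binomial with success probability
#' `p_true * (1 - mc_fail_rate) + (1 - p_true) * nonconversion_rate`.
#' Sibling replicates share the same truth column and differ only by
#' sampling. Appends `n_lambda_sites` unmethylated spike-in records on a
#' contig named `"lambda"`.
#'
#' @param planted A `planted_methylome` from [plant_epimutations()].
#' @param generation,treatment,replicate The sample key.
#' @param design The [sim_design()].
#' @return A cytosine `data.table` in the [read_cytosine_report()] layout.
#' @export
simulate_sample_counts <- function(planted, generation, treatment,
                                   replicate, design) {
  stopifnot(inherits(planted, "planted_methylome"))
  keys <- sample_keys()
  lab <- paste(generation, treatment, replicate, sep = ".")
  k <- match(lab, keys$label)
  if (is.na(k)) stopf("unknown sample key '%s'", lab)
  set.seed(design$seed + 7919L * k)
  sites <- planted$sites
  n <- nrow(sites)
  p_true <- planted$levels[, level_column(generation, treatment)]
  draw_cov <- function(nn) {
    if (design$coverage_model == "poisson") rpois(nn, design$depth_mean)
    else rnbinom(nn, mu = design$depth_mean, size = design$nb_size)
  }
  cov <- draw_cov(n)
  p_obs <- p_true * (1 - design$mc_fail_rate) +
    (1 - p_true) * design$nonconversion_rate
  meth <- rbinom(n, cov, p_obs)
  dt <- data.table(chrom = sites$chrom, pos = sites$pos,
                   strand = sites$strand, meth = meth,
                   unmeth = cov - meth, context = sites$context,
                   trinucleotide = sites$trinucleotide)
  if (design$n_lambda_sites > 0) {
    lcov <- draw_cov(design$n_lambda_sites)
    lmeth <- rbinom(design$n_lambda_sites, lcov, design$nonconversion_rate)
    dt <- rbind(dt, data.table(
      chrom = "lambda", pos = seq_len(design$n_lambda_sites),
      strand = "+", meth = lmeth, unmeth = lcov - lmeth,
      context = rep_len(CONTEXTS, design$n_lambda_sites),
      trinucleotide = "CTA"))
  }
  dt[, coverage := meth + unmeth]
  dt[, low_coverage := coverage < 3L]
  dt[]
}

#' Simulate the full 16-sample methylome study
#'
#' Convenience wrapper: builds the baseline methylome, plants epimutations
#' and simulates counts for all 16 samples of the design.
#'
#' @param design A [sim_design()].
#' @return An object of class `methylome_sim`: list with `tables` (named
#'   list of 16 cytosine tables), `sites`, `levels`, `ledger`,
#'   `reference`, `features`, `keys` and the design.
#' @export
simulate_methylome <- function(design) {
  truth <- build_reference_methylome(design)
  planted <- plant_epimutations(truth, design)
  keys <- sample_keys()
  tables <- vector("list", nrow(keys))
  names(tables) <- keys$label
  for (i in seq_len(nrow(keys)))
    tables[[i]] <- simulate_sample_counts(planted, keys$generation[i],
                                          keys$treatment[i],
                                          keys$replicate[i], design)
  out <- list(design = design, sites = planted$sites,
              levels = planted$levels, ledger = planted$ledger,
              tables = tables, reference = planted$reference,
              features = planted$features, keys = keys)
  class(out) <- "methylome_sim"
  out
}

#' Write a simulated study to disk
#'
#' Emits one cytosine report per sample, the reference FASTA, the feature
#' annotation as GFF3 and the truth ledger as TSV.
#'
#' @param sim A `methylome_sim` from [simulate_methylome()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_simulated_methylome <- function(sim, dir) {
  stopifnot(inherits(sim, "methylome_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(sim$tables)) {
    p <- file.path(dir, paste0(nm, ".cx.tsv"))
    write_cytosine_report(sim$tables[[nm]], p,
                          params = list(sample = nm, seed = sim$design$seed))
    paths[[nm]] <- p
  }
  paths$reference <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(sim$reference, paths$reference)
  paths$features <- file.path(dir, "features.gff3")
  if (length(sim$features)) {
    rtracklayer::export(sim$features, paths$features, format = "gff3")
  } else {
    writeLines("##gff-version 3", paths$features)
  }
  paths$ledger <- file.path(dir, "truth_ledger.tsv")
  write_tsv(sim$ledger, paths$ledger, params = list(seed = sim$design$seed))
  invisible(paths)
}
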