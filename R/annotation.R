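#' Sequence context of a cytosine
#'
#' Reads the two bases 3' of the cytosine on its own strand: CG when the
#' next base is G, CHG when the base after next is G, otherwise CHH
#' (H = A, C or T). Positions too close to the chromosome end, or whose
#' determining bases are N, are undefined (`NA`).
#'
#' @param reference A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param chrom,pos,strand Parallel vectors identifying cytosines
#'   (1-based; strand `+` or `-`).
#' @return Character vector over `CG`, `CHG`, `CHH`, `NA`. Errors when the
#'   referenced base is not a cytosine on the given strand.
#' @export
assign_context <- function(reference, chrom, pos, strand) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand))
  out <- rep(NA_character_, length(pos))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (ch in unique(chrom)) {
    if (!ch %in% names(reference))
      stopf("chromosome '%s' absent from reference", ch)
    s <- strsplit(as.character(reference[[ch]]), "")[[1L]]
    L <- length(s)
    sel <- which(chrom == ch)
    p <- pos[sel]; st <- strand[sel]
    if (any(p < 1L | p > L))
      stopf("position out of range on '%s'", ch)
    base <- ifelse(st == "+", s[p], comp[s[p]])
    if (any(base != "C"))
      stopf("base at %s:%d(%s) is not a cytosine on that strand",
            ch, p[which(base != "C")[1L]], st[which(base != "C")[1L]])
    b1 <- ifelse(st == "+",
                 ifelse(p + 1L <= L, s[pmin(p + 1L, L)], NA),
                 ifelse(p - 1L >= 1L, comp[s[pmax(p - 1L, 1L)]], NA))
    b2 <- ifelse(st == "+",
                 ifelse(p + 2L <= L, s[pmin(p + 2L, L)], NA),
                 ifelse(p - 2L >= 1L, comp[s[pmax(p - 2L, 1L)]], NA))
    ctx <- ifelse(is.na(b1) | b1 == "N", NA_character_,
                  ifelse(b1 == "G", "CG",
                         ifelse(is.na(b2) | b2 == "N", NA_character_,
                                ifelse(b2 == "G", "CHG", "CHH"))))
    out[sel] <- ctx
  }
  out
}

#' Genomic region label of a site
#'
#' Assigns each site the highest-precedence feature containing it. The
#' default precedence is TE > CDS > 5'UTR > 3'UTR > intron > promoter >
#' intergenic: TEs are tallied separately even where they overlap gene
#' bodies. Promoters are `promoter_length` bp upstream of the gene start
#' on the gene's strand; introns are derived from the gene model where not
#' annotated.
#'
#' @param sites Table or `GRanges` with `chrom, pos` (strand ignored:
#'   labels are positional).
#' @param features A `GRanges` from [read_features()] (or the simulator).
#' @param promoter_length Promoter window in bp (default 1000).
#' @param precedence Ordered character vector of labels, highest first.
#' @return Character vector of region labels, `"intergenic"` where no
#'   feature overlaps.
#' @export
assign_region <- function(sites, features, promoter_length = 1000L,
                          precedence = c("TE", "CDS", "five_prime_UTR",
                                         "three_prime_UTR", "intron",
                                         "promoter", "intergenic")) {
  dt <- as.data.table(sites)
  posn <- if ("pos" %in% names(dt)) dt$pos else dt$start
  gr_sites <- GenomicRanges::GRanges(dt$chrom,
                                     IRanges::IRanges(posn, posn))
  feats <- features
  if (!"promoter" %in% mcols(feats)$kind && "promoter" %in% precedence)
    feats <- c(feats, derive_promoters(features, promoter_length))
  if (!"intron" %in% mcols(feats)$kind && "intron" %in% precedence) {
    intr <- derive_introns(features)
    if (length(intr)) feats <- c(feats, intr)
  }
  out <- rep("intergenic", length(gr_sites))
  # walk precedence from lowest to highest so later assignments win
  for (kind in rev(setdiff(precedence, "intergenic"))) {
    sel <- feats[mcols(feats)$kind == kind]
    if (!length(sel)) next
    hit <- suppressWarnings(overlapsAny(gr_sites, sel,
                                        ignore.strand = TRUE))
    out[hit] <- kind
  }
  out
}

#' Annotate events with context and region
#'
#' Adds `context` (from the reference, where missing) and `region` columns
#' to an event table. Region events (DMRs) are labelled by their midpoint.
#'
#' @param events Event table (`dmp_set`, `smp_set` or `dmr_set`).
#' @param features Feature `GRanges`.
#' @param reference Optional `DNAStringSet` to fill missing contexts
#'   (position events only).
#' @inheritParams assign_region
#' @return The event table with `context` and `region` columns.
#' @export
annotate_events <- function(events, features, reference = NULL,
                            promoter_length = 1000L,
                            precedence = c("TE", "CDS", "five_prime_UTR",
                                           "three_prime_UTR", "intron",
                                           "promoter", "intergenic")) {
  dt <- copy(as.data.table(events))
  if (!"pos" %in% names(dt)) {
    mid <- as.integer((dt$start + dt$end) %/% 2L)
    dt[, region := assign_region(data.table(chrom = dt$chrom, pos = mid),
                                 features, promoter_length, precedence)]
    if (!"context" %in% names(dt)) dt[, context := NA_character_]
  } else {
    dt[, region := assign_region(dt, features, promoter_length, precedence)]
    if ((!"context" %in% names(dt) || anyNA(dt$context)) &&
        !is.null(reference)) {
      fill <- assign_context(reference, dt$chrom, dt$pos, dt$strand)
      if (!"context" %in% names(dt)) dt[, context := fill]
      else dt$context[is.na(dt$context)] <- fill[is.na(dt$context)]
    }
  }
  dt[]
}

#' Distribution of events over contexts and regions
#'
#' Cross-tabulates annotated events by sequence context, genomic region
#' and direction. The counts partition the event set: marginals equal the
#' event total, with unannotated values pooled under `"unknown"`.
#'
#' @param events Annotated event table (see [annotate_events()]).
#' @param contexts,regions Factor levels for the table (defaults: the
#'   three contexts; the precedence labels).
#' @return A `data.table` with `context, region, direction, n` covering
#'   the full grid.
#' @export
distribution_summary <- function(events,
                                 contexts = CONTEXTS,
                                 regions = c("TE", "CDS",
                                             "five_prime_UTR",
                                             "three_prime_UTR", "intron",
                                             "promoter", "intergenic")) {
  dt <- as.data.table(events)
  n_unknown_ctx <- 0L
  if (!nrow(dt)) {
    grid <- data.table::CJ(context = contexts, region = regions,
                           direction = character(0))
    return(data.table(context = character(), region = character(),
                      direction = character(), n = integer()))
  }
  ctx <- as.character(dt$context)
  ctx[is.na(ctx) | !ctx %in% contexts] <- "unknown"
  reg <- as.character(dt$region)
  reg[is.na(reg) | !reg %in% regions] <- "unknown"
  if (any(ctx == "unknown") || any(reg == "unknown"))
    message(sprintf("distribution_summary: %d events with unknown context/region",
                    sum(ctx == "unknown" | reg == "unknown")))
  counts <- data.table(context = ctx, region = reg,
                       direction = dt$direction)[, .(n = .N),
                                                 by = .(context, region,
                                                        direction)]
  grid <- data.table::CJ(context = unique(c(contexts,
                                            intersect("unknown", ctx))),
                         region = unique(c(regions,
                                           intersect("unknown", reg))),
                         direction = sort(unique(dt$direction)))
  out <- merge(grid, counts, by = c("context", "region", "direction"),
               all.x = TRUE)
  out[is.na(n), n := 0L]
  out[]
}

#' Overlap DMRs with genes
#'
#' One association per (DMR, gene) pair with any overlap of the gene body
#' or its promoter window. `location` is decided by majority overlap
#' (promoter vs body bp), ties going to `body`.
#'
#' @param dmrs A `dmr_set`.
#' @param features Feature `GRanges` containing `gene` features.
#' @param promoter_length Promoter window in bp (default 1000).
#' @return `data.table` with `gene_id, dmr_id, location`
#'   (`promoter`/`body`).
#' @export
overlap_dmrs_genes <- function(dmrs, features, promoter_length = 1000L) {
  dt <- as.data.table(dmrs)
  if (!nrow(dt))
    return(data.table(gene_id = character(), dmr_id = character(),
                      location = character()))
  dt[, dmr_id := paste0("DMR_", sprintf("%04d", seq_len(.N)))]
  gr_dmr <- GenomicRanges::GRanges(dt$chrom,
                                   IRanges::IRanges(dt$start, dt$end))
  genes <- features[mcols(features)$kind == "gene"]
  proms <- derive_promoters(features, promoter_length)
  rows <- list()
  count_overlap <- function(gr, regions) {
    hits <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
    ov <- integer(length(gr))
    if (length(hits)) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[queryHits(hits)], regions[subjectHits(hits)]))
      agg <- rowsum(w, queryHits(hits))
      ov[as.integer(rownames(agg))] <- agg[, 1L]
    }
    ov
  }
  for (gi in seq_along(genes)) {
    gid <- mcols(genes)$id[gi]
    body_ov <- count_overlap(gr_dmr, genes[gi])
    prom_gi <- proms[mcols(proms)$id == gid]
    prom_ov <- if (length(prom_gi)) count_overlap(gr_dmr, prom_gi) else
      integer(length(gr_dmr))
    touched <- which(body_ov + prom_ov > 0L)
    for (di in touched) {
      rows[[length(rows) + 1L]] <- data.table(
        gene_id = gid, dmr_id = dt$dmr_id[di],
        location = if (prom_ov[di] > body_ov[di]) "promoter" else "body")
    }
  }
  if (!length(rows))
    return(data.table(gene_id = character(), dmr_id = character(),
                      location = character()))
  rbindlist(rows)
}

#' Metagene methylation profile
#'
#' Averages per-site methylation levels over features of one kind in a
#' strand-aware metagene coordinate system: an upstream flank in absolute
#' bp (TSS on the left), the feature body rescaled to \[0, 1\], and a
#' downstream flank. Per feature, site levels are averaged within each
#' bin; bins are then averaged unweighted across features.
#'
#' @param levels Table with `chrom, pos, level` and optionally `context`
#'   (profiles are then computed per context).
#' @param features Feature `GRanges`.
#' @param kind Feature kind to profile (default `"gene"`).
#' @param flank Flank length in bp (default 1000).
#' @param body_bins,flank_bins Bin counts (defaults 60, 20).
#' @return `data.table` with `bin` (1..`2 * flank_bins + body_bins`),
#'   `segment` (`upstream`/`body`/`downstream`), `context`, `mean_level`.
#' @export
metagene_profile <- function(levels, features, kind = "gene",
                             flank = 1000L, body_bins = 60L,
                             flank_bins = 20L) {
  lv <- as.data.table(levels)
  stopifnot(all(c("chrom", "pos", "level") %in% names(lv)))
  if (!"context" %in% names(lv)) lv[, context := "all"]
  feats <- features[mcols(features)$kind == kind]
  if (!length(feats))
    stopf("no features of kind '%s'", kind)
  total_bins <- 2L * flank_bins + body_bins
  acc <- list()
  fstart <- GenomicRanges::start(feats)
  fend <- GenomicRanges::end(feats)
  fstrand <- as.character(GenomicRanges::strand(feats))
  fchrom <- as.character(GenomicRanges::seqnames(feats))
  for (fi in seq_along(feats)) {
    minus <- fstrand[fi] == "-"
    sub <- lv[chrom == fchrom[fi] &
                pos >= fstart[fi] - flank & pos <= fend[fi] + flank]
    if (!nrow(sub)) next
    # metagene coordinate: [-1, 0) upstream, [0, 1] body, (1, 2] downstream
    w <- fend[fi] - fstart[fi] + 1L
    rel <- ifelse(sub$pos < fstart[fi],
                  (sub$pos - fstart[fi]) / flank,
                  ifelse(sub$pos > fend[fi],
                         1 + (sub$pos - fend[fi]) / flank,
                         (sub$pos - fstart[fi]) / max(w - 1L, 1L)))
    if (minus) {
      rel <- ifelse(rel < 0, 1 + (-rel),          # upstream <-> downstream
                    ifelse(rel > 1, -(rel - 1), 1 - rel))
    }
    bin <- ifelse(rel < 0,
                  pmax(1L, flank_bins + 1L + floor(rel * flank_bins)),
                  ifelse(rel > 1,
                         pmin(total_bins,
                              flank_bins + body_bins +
                                ceiling((rel - 1) * flank_bins)),
                         flank_bins + 1L +
                           pmin(body_bins - 1L, floor(rel * body_bins))))
    sub <- data.table(bin = as.integer(bin), context = sub$context,
                      level = sub$level)
    acc[[length(acc) + 1L]] <- sub[, .(feat_mean = mean(level)),
                                   by = .(bin, context)]
  }
  if (!length(acc))
    stopf("no sites overlap the requested features")
  per_feat <- rbindlist(acc)
  out <- per_feat[, .(mean_level = mean(feat_mean)), by = .(bin, context)]
  grid <- data.table::CJ(bin = seq_len(total_bins),
                         context = sort(unique(lv$context)))
  out <- merge(grid, out, by = c("bin", "context"), all.x = TRUE)
  out[, segment := ifelse(bin <= flank_bins, "upstream",
                          ifelse(bin <= flank_bins + body_bins, "body",
                                 "downstream"))]
  setorderv(out, c("context", "bin"))
  out[]
}
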