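#' Read a cytosine report (Bismark CX dialect)
#'
#' Parses a 7-column tab-separated per-cytosine count table:
#' chromosome, 1-based position, strand (+/-), methylated read count,
#' unmethylated read count, context (CG/CHG/CHH), trinucleotide. Lines
#' starting with `#` are ignored. Records below `min_coverage` are kept but
#' flagged (`low_coverage`) so that density denominators over all cytosines
#' remain computable.
#'
#' @param path Path to the report.
#' @param min_coverage Coverage below which a record is flagged (default 3).
#' @return A `data.table` with columns `chrom, pos, strand, meth, unmeth,
#'   context, trinucleotide, coverage, low_coverage`, in file order.
#' @export
read_cytosine_report <- function(path, min_coverage = 3L) {
  cols <- c("chrom", "pos", "strand", "meth", "unmeth", "context",
            "trinucleotide")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  if (!length(line_no)) {
    dt <- data.table(chrom = character(), pos = integer(),
                     strand = character(), meth = integer(),
                     unmeth = integer(), context = character(),
                     trinucleotide = character())
  } else {
    dt <- tryCatch(
      data.table::fread(text = lines[keep], sep = "\t", header = FALSE,
                        colClasses = list(character = c(1, 3, 6, 7),
                                          integer = c(2, 4, 5))),
      error = function(e) stopf("malformed cytosine report '%s': %s",
                                path, conditionMessage(e)))
    if (ncol(dt) != 7L)
      stopf("cytosine report '%s' has %d columns, expected 7", path, ncol(dt))
    setnames(dt, cols)
    bad <- which(!dt$strand %in% c("+", "-"))
    if (length(bad))
      stopf("parse error at line %d of '%s': invalid strand '%s'",
            line_no[bad[1]], path, dt$strand[bad[1]])
    bad <- which(!dt$context %in% CONTEXTS)
    if (length(bad))
      stopf("parse error at line %d of '%s': invalid context '%s'",
            line_no[bad[1]], path, dt$context[bad[1]])
    bad <- which(is.na(dt$meth) | is.na(dt$unmeth) | dt$meth < 0L |
                   dt$unmeth < 0L)
    if (length(bad))
      stopf("parse error at line %d of '%s': negative or missing count",
            line_no[bad[1]], path)
    bad <- which(is.na(dt$pos) | dt$pos < 1L)
    if (length(bad))
      stopf("parse error at line %d of '%s': position must be >= 1",
            line_no[bad[1]], path)
  }
  dt[, coverage := meth + unmeth]
  dt[, low_coverage := coverage < min_coverage]
  dt[]
}

#' Write a cytosine report
#'
#' Emits the 7-column tab-separated dialect read by
#' [read_cytosine_report()], headerless (format-compatible with Bismark CX
#' reports) with a leading `#` comment carrying tool version and parameters.
#'
#' @param table A cytosine `data.table` (extra columns are dropped).
#' @param path Output path.
#' @param params Optional named list echoed into the comment line.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(table, path, params = NULL) {
  cols <- c("chrom", "pos", "strand", "meth", "unmeth", "context",
            "trinucleotide")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stopf("table lacks columns: %s", paste(missing_cols, collapse = ", "))
  writeLines(tool_comment(params), path)
  if (nrow(table))
    data.table::fwrite(as.data.table(table)[, cols, with = FALSE], path,
                       sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Build the eligible-site universe
#'
#' The universe of cytosines with at least `min_coverage` reads in every
#' supplied sample, the shared substrate of all differential analyses.
#'
#' @param tables A list of cytosine tables (as from
#'   [read_cytosine_report()]), typically one per sample in the design.
#' @param min_coverage Minimum coverage required in every table (default 3).
#' @param exclude Chromosome names to drop (e.g. a spike-in contig).
#' @return A `data.table` of `(chrom, pos, strand)` sorted by chromosome,
#'   position, strand, with attribute `min_coverage`.
#' @export
build_eligible_set <- function(tables, min_coverage = 3L, exclude = NULL) {
  if (!is.list(tables) || !length(tables))
    stopf("design error: build_eligible_set needs at least one cytosine table")
  if (length(tables) == 1L)
    warnf("building an eligible set from a single sample; a multi-sample design is expected")
  keys <- c("chrom", "pos", "strand")
  elig <- NULL
  for (tab in tables) {
    tab <- as.data.table(tab)
    ok <- tab[(meth + unmeth) >= min_coverage, keys, with = FALSE]
    elig <- if (is.null(elig)) ok else {
      merge(elig, ok, by = keys, sort = FALSE)
    }
  }
  elig <- unique(elig)
  if (!is.null(exclude)) elig <- elig[!chrom %in% exclude]
  setorderv(elig, keys)
  setattr(elig, "min_coverage", min_coverage)
  elig[]
}

#' Read genomic features (GFF3 or BED6)
#'
#' Imports gene-model and repeat annotation into a [GenomicRanges::GRanges]
#' with metadata columns `kind` (gene, CDS, five_prime_UTR,
#' three_prime_UTR, intron, TE) and `id`. Coordinates are 1-based inclusive
#' internally; BED input (0-based half-open) is shifted on import. Introns
#' missing from a GFF3 are derived per gene as the gene span minus its
#' exonic parts.
#'
#' @param path Path to a GFF3 or BED6 file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param default_kind Feature kind assigned to BED records (BED carries no
#'   type column); default `"gene"`.
#' @param te_types GFF3 `type` values mapped to `TE`.
#' @return A `GRanges` with `kind` and `id` metadata.
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed"),
                          default_kind = "gene",
                          te_types = c("transposable_element",
                                       "transposon_fragment",
                                       "repeat_region", "TE")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (file.size(path) == 0 ||
      !length(grep("^[^#]", readLines(path, warn = FALSE)))) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$kind <- character()
    mcols(gr)$id <- character()
    return(gr)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stopf("format error reading '%s': %s", path,
                              conditionMessage(e)))
  if (format == "bed") {
    mcols(gr)$kind <- default_kind
    mcols(gr)$id <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
      else paste0(default_kind, "_", seq_along(gr))
  } else {
    type <- as.character(mcols(gr)$type)
    kind <- type
    kind[type %in% te_types] <- "TE"
    keep <- kind %in% c("gene", "CDS", "five_prime_UTR", "three_prime_UTR",
                        "intron", "TE", "exon")
    gr <- gr[keep]
    kind <- kind[keep]
    mcols_id <- mcols(gr)$ID
    if (is.null(mcols_id)) mcols_id <- mcols(gr)$Name
    parent <- mcols(gr)$Parent
    parent <- if (is.null(parent)) rep(NA_character_, length(gr))
      else vapply(as.list(parent),
                  function(p) if (length(p)) as.character(p[[1]]) else
                    NA_character_, character(1))
    id <- as.character(mcols_id)
    id[is.na(id) | !nzchar(id)] <- parent[is.na(id) | !nzchar(id)]
    id[is.na(id)] <- paste0(kind[is.na(id)], "_", which(is.na(id)))
    mcols(gr) <- NULL
    mcols(gr)$kind <- kind
    mcols(gr)$id <- id
    gr <- c(gr[kind != "exon"], derive_introns(gr))
    gr <- gr[mcols(gr)$kind != "exon"]
  }
  if (any(GenomicRanges::width(gr) < 1L))
    stopf("format error: feature with end < start in '%s'", path)
  sort(gr, ignore.strand = TRUE)
}

# introns = gene span minus exonic parts (exons if annotated, else
# CDS + UTRs), derived only for genes without annotated introns
derive_introns <- function(gr) {
  kind <- mcols(gr)$kind
  genes <- gr[kind == "gene"]
  if (!length(genes)) return(GenomicRanges::GRanges(kind = character(),
                                                    id = character()))
  exonic_kind <- if ("exon" %in% kind) "exon" else
    c("CDS", "five_prime_UTR", "three_prime_UTR")
  exonic <- gr[kind %in% exonic_kind]
  have_introns <- unique(mcols(gr)$id[kind == "intron"])
  out <- list()
  for (i in seq_along(genes)) {
    gid <- mcols(genes)$id[i]
    if (gid %in% have_introns) next
    parts <- exonic[overlapsAny(exonic, genes[i])]
    if (!length(parts)) next
    gaps <- GenomicRanges::setdiff(genes[i], GenomicRanges::reduce(parts),
                                   ignore.strand = TRUE)
    # trim terminal gaps: introns lie strictly between exonic parts
    gaps <- gaps[GenomicRanges::start(gaps) > min(GenomicRanges::start(parts)) &
                   GenomicRanges::end(gaps) < max(GenomicRanges::end(parts))]
    if (length(gaps)) {
      GenomicRanges::strand(gaps) <- GenomicRanges::strand(genes[i])
      mcols(gaps)$kind <- "intron"
      mcols(gaps)$id <- gid
      out[[length(out) + 1L]] <- gaps
    }
  }
  if (!length(out)) {
    g <- GenomicRanges::GRanges()
    mcols(g)$kind <- character(); mcols(g)$id <- character()
    return(g)
  }
  do.call(c, out)
}

#' Derive promoter windows from gene features
#'
#' The promoter is taken as `promoter_length` bp immediately upstream of the
#' gene start on the gene's strand, trimmed at position 1.
#'
#' @param features A `GRanges` from [read_features()].
#' @param promoter_length Upstream window size in bp (default 1000).
#' @return A `GRanges` of promoter windows (`kind = "promoter"`).
#' @export
derive_promoters <- function(features, promoter_length = 1000L) {
  genes <- features[mcols(features)$kind == "gene"]
  if (!length(genes)) {
    g <- GenomicRanges::GRanges()
    mcols(g)$kind <- character(); mcols(g)$id <- character()
    return(g)
  }
  prom <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoter_length,
                             downstream = 0L))
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  prom <- prom[GenomicRanges::width(prom) > 0L]
  mcols(prom)$kind <- "promoter"
  prom
}
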