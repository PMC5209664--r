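suppressMessages({
  library(data.table)
})

# small deterministic cytosine table
make_cx <- function(chrom, pos, strand = "+", meth = 0L, unmeth = 0L,
                    context = "CG", trinucleotide = "CGA") {
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                   meth = as.integer(meth), unmeth = as.integer(unmeth),
                   context = context, trinucleotide = trinucleotide)
  dt[, coverage := meth + unmeth]
  dt[, low_coverage := coverage < 3L]
  dt[]
}

# independent two-sided Fisher oracle: explicit hypergeometric enumeration
# from log binomial coefficients (one table at a time)
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; K <- a + c; N <- n1 + n2
  lo <- max(0L, K - n2); hi <- min(K, n1)
  kk <- lo:hi
  logp <- lchoose(n1, kk) + lchoose(n2, K - kk) - lchoose(N, K)
  pk <- exp(logp)
  pobs <- pk[match(a, kk)]
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
}

# tiny status matrix builder: `calls` is a named list label -> character
# vector of per-site statuses
make_status_matrix <- function(chrom, pos, strand, calls) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = strand)
  for (nm in names(calls)) dt[, (paste0("status.", nm)) := calls[[nm]]]
  dt
}

# minimal dmp-like event table for dynamics tests
make_events <- function(pos, direction = "hyper", chrom = "chr1",
                        strand = "+") {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             direction = direction)
}

# fraction of samples whose nearest cophenetic neighbour is their sibling
adjacency_score <- function(clustering) {
  cd <- as.matrix(stats::cophenetic(clustering$hclust))
  diag(cd) <- Inf
  labs <- colnames(cd)
  sib_of <- function(l) {
    p <- strsplit(l, ".", fixed = TRUE)[[1]]
    paste(p[1], p[2], ifelse(p[3] == "1", "2", "1"), sep = ".")
  }
  mean(vapply(labs, function(l) cd[l, sib_of(l)] <= min(cd[l, ]) + 1e-12,
              logical(1)))
}

# do the given labels form a monophyletic clade of the dendrogram?
is_clade <- function(clustering, labels) {
  phy <- ape::read.tree(text = clustering$newick)
  ape::is.monophyletic(phy, labels)
}

# site keys of ledger point events
ledger_keys <- function(ledger) {
  paste(ledger$chrom, ledger$start, ledger$strand, sep = ":")
}
dmp_keys <- function(dmps) {
  paste(dmps$chrom, dmps$pos, dmps$strand, sep = ":")
}
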