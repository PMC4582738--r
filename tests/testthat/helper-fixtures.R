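# Small in-code fixture builders shared across test files.

# methylome from explicit positions and counts
mk_meth <- function(pos, n_meth, n_unmeth, chrom = "chr1",
                    label = "test") {
  methylome(data.frame(chrom = chrom, pos = pos, n_meth = n_meth,
                       n_unmeth = n_unmeth), label)
}

# evenly spaced CpGs at a constant methylation percent and coverage
uniform_meth <- function(n, spacing = 100, pct = 100, cov = 10,
                         chrom = "chr1", start = 0) {
  nm <- round(cov * pct / 100)
  mk_meth(seq(start, by = spacing, length.out = n),
          n_meth = nm, n_unmeth = cov - nm, chrom = chrom)
}

# annotation from a list of transcripts; each element:
# list(tx, gene, chrom, strand, exons = list(c(start, end), ...))
mk_ann <- function(txs, fpkm = NULL) {
  rows <- lapply(txs, function(t) {
    ex <- do.call(rbind, lapply(t$exons, function(e)
      data.frame(start = e[1], end = e[2])))
    data.frame(chrom = t$chrom, start = ex$start, end = ex$end,
               strand = t$strand, transcript_id = t$tx,
               gene_id = t$gene, stringsAsFactors = FALSE)
  })
  annotation_set(do.call(rbind, rows), fpkm = fpkm)
}

mk_track <- function(chrom, start, end, strand = NULL, kind = "feature",
                     ...) {
  df <- genomic_intervals(chrom, start, end, strand = strand, ...)
  attr(df, "kind") <- kind
  df
}

# random non-overlapping classed domain set for refinement properties
random_domain_set <- function(n_max = 20, chroms = c("cA", "cB")) {
  rows <- list()
  for (ch in chroms) {
    pos <- 0
    n <- sample(0:n_max, 1)
    for (i in seq_len(n)) {
      pos <- pos + sample(c(0, 100, 500, 1500, 2500, 5000), 1)
      len <- sample(c(300, 800, 1500, 2500, 6000, 20000), 1)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = pos, end = pos + len,
        class = sample(c("hyper", "hypo"), 1), stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character()))
  do.call(rbind, rows)
}

# random methylome on one chromosome with block-structured methylation,
# for oracle-equivalence trials
random_block_methylome <- function(n_cpg = NULL) {
  if (is.null(n_cpg)) n_cpg <- sample(60:300, 1)
  pos <- cumsum(sample(10:400, n_cpg, replace = TRUE))
  n_blocks <- sample(1:6, 1)
  cuts <- sort(sample(seq_len(n_cpg), n_blocks - 1))
  block <- findInterval(seq_len(n_cpg), c(1, cuts + 1))
  targets <- sample(c(0.03, 0.1, 0.5, 0.9, 0.97), n_blocks,
                    replace = TRUE)
  p <- targets[block]
  cov <- rpois(n_cpg, 8)
  nm <- rbinom(n_cpg, cov, p)
  mk_meth(pos, nm, cov - nm)
}
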