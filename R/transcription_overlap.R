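# Quantifying transcription over domains: read contigs, overlap
# fractions, the tiered explanation cascades for HyperDs and HypoDs,
# the FPKM-vs-methylation crossover, escapee genes, and 2x2 feature
# enrichment tests.

#' Build transcription contigs from stranded read intervals
#'
#' A contig is a maximal genomic run covered by at least `min_depth`
#' reads on the same strand in at least one dataset; the final track is
#' the union over datasets (strand kept).
#'
#' @param reads data frame of read intervals: chrom, start, end, strand,
#'   dataset.
#' @param min_depth minimum same-strand read depth (default 3).
#' @return contig feature track (chrom, start, end, strand), sorted and
#'   non-overlapping per strand.
#' @export
build_contigs <- function(reads, min_depth = 3) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    attr(empty, "kind") <- "contig"
    return(empty)
  }
  stopifnot(all(c("chrom", "start", "end", "strand", "dataset") %in%
                  names(reads)))
  pieces <- list()
  for (ds in unique(reads$dataset)) {
    for (st in unique(reads$strand)) {
      r <- reads[reads$dataset == ds & reads$strand == st, , drop = FALSE]
      if (nrow(r) == 0) next
      gr <- as_granges(r[c("chrom", "start", "end")])
      covr <- GenomicRanges::coverage(gr)
      runs <- IRanges::slice(covr, lower = min_depth, rangesOnly = TRUE)
      df <- as.data.frame(runs)
      if (nrow(df) == 0) next
      pieces[[length(pieces) + 1]] <-
        data.frame(chrom = as.character(df$group_name),
                   start = df$start - 1, end = df$end, strand = st,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(pieces) == 0) {
    attr(empty, "kind") <- "contig"
    return(empty)
  }
  out <- reduce_intervals_stranded(do.call(rbind, pieces))
  attr(out, "kind") <- "contig"
  out
}

#' Fraction of a domain covered by intervals
#'
#' @param domains domain set (or any interval data frame).
#' @param intervals evidence intervals; unioned before measuring.
#' @param strand_aware if `TRUE`, both inputs must carry strands and only
#'   same-strand coverage counts (default `FALSE`: DNA methylation is
#'   strand-symmetric, so domain overlap is strand-agnostic).
#' @return numeric vector in `[0, 1]`, one value per domain row.
#' @export
overlap_fraction <- function(domains, intervals, strand_aware = FALSE) {
  if (nrow(domains) == 0) return(numeric(0))
  len <- domains$end - domains$start
  if (any(len <= 0)) stop("zero-length domain")
  if (!strand_aware) return(covered_bp(domains, intervals) / len)
  out <- numeric(nrow(domains))
  for (st in c("+", "-")) {
    idx <- domains$strand == st
    if (!any(idx)) next
    out[idx] <- covered_bp(domains[idx, , drop = FALSE],
                           intervals[intervals$strand == st, ,
                                     drop = FALSE]) / len[idx]
  }
  out
}

#' Explain HyperDs by a cumulative transcription-evidence cascade
#'
#' Evidence tiers, cumulative: (1) expressed reference genes
#' (FPKM > `ref_fpkm_min`); (2) plus the oocyte assembly; (3) plus read
#' contigs; (4) plus regions of partial methylation in the control
#' methylomes.  A domain is assigned the first tier whose cumulative
#' overlap fraction exceeds `explain_cut`; domains never explained are
#' `unexplained`.  A domain whose assembly-plus-contig fraction is below
#' `untranscribed_cut` is additionally flagged untranscribed.
#'
#' @param domains HyperD rows of a domain set.
#' @param reference_genes interval data frame of reference gene spans with
#'   an `fpkm` column.
#' @param assembly interval data frame of assembled gene/transcript spans.
#' @param contigs contig track (strand collapsed here).
#' @param partial_meth_regions intervals of partial control methylation
#'   (may be empty).
#' @param ref_fpkm_min reference expression floor (default 0.001).
#' @param explain_cut overlap fraction needed to explain a domain
#'   (default 0.5, strict).
#' @param untranscribed_cut assembly+contig fraction below which a domain
#'   counts as untranscribed (default 0.05).
#' @return list: `per_domain` data frame (id, tier fractions, tier,
#'   untranscribed) and `summary` (tier fractions over domains,
#'   untranscribed count and mean length, total-length-weighted overlap).
#' @export
explain_hyperds <- function(domains, reference_genes, assembly, contigs,
                            partial_meth_regions = NULL,
                            ref_fpkm_min = 0.001, explain_cut = 0.5,
                            untranscribed_cut = 0.05) {
  tiers <- c("reference_expressed", "assembly", "assembly_plus_contigs",
             "plus_partial_meth", "unexplained")
  ref <- reference_genes
  if (nrow(ref) && "fpkm" %in% names(ref))
    ref <- ref[ref$fpkm > ref_fpkm_min, , drop = FALSE]
  e1 <- ref[c("chrom", "start", "end")]
  e2 <- rbind(e1, assembly[c("chrom", "start", "end")])
  e3 <- rbind(e2, contigs[c("chrom", "start", "end")])
  e4 <- if (!is.null(partial_meth_regions) && nrow(partial_meth_regions))
    rbind(e3, partial_meth_regions[c("chrom", "start", "end")]) else e3
  f1 <- overlap_fraction(domains, e1)
  f2 <- overlap_fraction(domains, e2)
  f3 <- overlap_fraction(domains, e3)
  f4 <- overlap_fraction(domains, e4)
  f_asm_ctg <- overlap_fraction(
    domains, rbind(assembly[c("chrom", "start", "end")],
                   contigs[c("chrom", "start", "end")]))
  tier <- rep("unexplained", nrow(domains))
  tier[f4 > explain_cut] <- "plus_partial_meth"
  tier[f3 > explain_cut] <- "assembly_plus_contigs"
  tier[f2 > explain_cut] <- "assembly"
  tier[f1 > explain_cut] <- "reference_expressed"
  untr <- f_asm_ctg < untranscribed_cut
  per <- data.frame(id = domains$id,
                    frac_reference = f1, frac_assembly = f2,
                    frac_assembly_contigs = f3, frac_partial_meth = f4,
                    tier = factor(tier, levels = tiers),
                    untranscribed = untr, stringsAsFactors = FALSE)
  len <- domains$end - domains$start
  summ <- list(
    tier_fractions = as.numeric(table(per$tier)) / max(1, nrow(per)),
    n_untranscribed = sum(untr),
    untranscribed_fraction = mean(untr),
    mean_untranscribed_length = if (any(untr)) mean(len[untr]) else NA_real_,
    length_weighted_overlap =
      sum(f3 * len) / max(1, sum(len)))
  names(summ$tier_fractions) <- tiers
  list(per_domain = per, summary = summ)
}

#' Explain HypoDs by transcription state
#'
#' A HypoD overlapping the assembly for more than `explain_cut` of its
#' length is transcribed; transcribed domains are subdivided into
#' `low_fpkm_gene` (the majority of their transcribed bp comes from genes
#' below `fpkm_cut`), `alt_downstream_promoter` (overlap above
#' `explain_cut` with 2-kbp windows downstream of alternative/downstream
#' TSSs), else `unexplained_transcribed`.  Domains at or below
#' `explain_cut` are `untranscribed`.
#'
#' @param domains HypoD rows of a domain set.
#' @param assembly gene-span intervals with `gene_id` column.
#' @param gene_fpkm named numeric vector of gene FPKM.
#' @param alt_tss_track intervals of 2-kbp windows downstream of
#'   downstream/alternative TSSs (see [alt_tss_windows()]).
#' @param fpkm_cut low-expression threshold (default 0.5).
#' @param explain_cut overlap fraction for "transcribed" (default 0.5,
#'   strict).
#' @return list: `per_domain` (id, frac_assembly, frac_alt_tss, tier,
#'   transcribed) and `summary` tier fractions.
#' @export
explain_hypods <- function(domains, assembly, gene_fpkm, alt_tss_track,
                           fpkm_cut = 0.5, explain_cut = 0.5) {
  tiers <- c("low_fpkm_gene", "alt_downstream_promoter",
             "unexplained_transcribed", "untranscribed")
  f_asm <- overlap_fraction(domains, assembly)
  f_alt <- if (!is.null(alt_tss_track) && nrow(alt_tss_track))
    overlap_fraction(domains, alt_tss_track) else numeric(nrow(domains))
  if (!length(f_alt)) f_alt <- rep(0, nrow(domains))
  fv <- unname(gene_fpkm[assembly$gene_id])
  fv[is.na(fv)] <- 0
  low <- assembly[fv < fpkm_cut, , drop = FALSE]
  f_low <- overlap_fraction(domains, low)
  transcribed <- f_asm > explain_cut
  tier <- rep("untranscribed", nrow(domains))
  tier[transcribed] <- "unexplained_transcribed"
  tier[transcribed & f_alt > explain_cut] <- "alt_downstream_promoter"
  # low-FPKM attribution wins when the majority of transcribed bp is low
  tier[transcribed & f_low > f_asm / 2] <- "low_fpkm_gene"
  per <- data.frame(id = domains$id, frac_assembly = f_asm,
                    frac_alt_tss = f_alt, frac_low_fpkm = f_low,
                    tier = factor(tier, levels = tiers),
                    transcribed = transcribed, stringsAsFactors = FALSE)
  fr <- as.numeric(table(per$tier)) / max(1, nrow(per))
  names(fr) <- tiers
  list(per_domain = per,
       summary = list(tier_fractions = fr,
                      transcribed_fraction = mean(transcribed)))
}

#' 2-kbp windows downstream of alternative/downstream TSSs
#'
#' For every transcript whose TSS is not its gene's most upstream TSS,
#' emit the 2-kbp window downstream of that TSS in the direction of
#' transcription.
#'
#' @param ann an [annotation_set].
#' @param width window width (default 2000).
#' @return interval data frame (merged).
#' @export
alt_tss_windows <- function(ann, width = 2000) {
  tx <- ann$transcripts
  g <- ann$genes
  if (nrow(tx) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  gene_tss <- setNames(g$tss, g$gene_id)
  alt <- tx[tx$tss != gene_tss[tx$gene_id], , drop = FALSE]
  if (nrow(alt) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  start <- ifelse(alt$strand == "-", pmax(0, alt$tss - width + 1), alt$tss)
  end <- ifelse(alt$strand == "-", alt$tss + 1, alt$tss + width)
  reduce_intervals(data.frame(chrom = alt$chrom, start = start, end = end))
}

# gene-body methylation under the "n CpGs with >= min_reads" scoring rule;
# NA when fewer than min_cpgs qualifying CpGs
region_meth <- function(regions, meth, min_cpgs = 3, min_reads = 3) {
  if (nrow(regions) == 0) return(numeric(0))
  cpgs <- meth$cpgs
  cov <- cpgs$n_meth + cpgs$n_unmeth
  sc <- cpgs[cov >= min_reads, , drop = FALSE]
  out <- rep(NA_real_, nrow(regions))
  if (nrow(sc) == 0) return(out)
  pct <- 100 * sc$n_meth / (sc$n_meth + sc$n_unmeth)
  gr <- as_granges(regions[c("chrom", "start", "end")])
  gc <- as_granges(data.frame(chrom = sc$chrom, start = sc$pos,
                              end = sc$pos + 1))
  hits <- GenomicRanges::findOverlaps(gc, gr)
  ri <- S4Vectors::subjectHits(hits)
  pv <- pct[S4Vectors::queryHits(hits)]
  if (length(ri)) {
    nn <- tapply(pv, ri, length)
    mm <- tapply(pv, ri, mean)
    idx <- as.integer(names(mm))
    ok <- nn >= min_cpgs
    out[idx[ok]] <- mm[ok]
  }
  out
}

#' Gene-body methylation versus expression, binned by FPKM
#'
#' Gene bodies are scored by the 3-CpG / 3-read rule; genes are binned by
#' FPKM (0-0.1, 0.1-0.2, ...) and each bin reports the fraction of genes
#' unmethylated (< 25 %) and methylated (> 75 %).  The crossover
#' threshold is the upper edge of the last bin in which unmethylated
#' genes outnumber methylated ones.
#'
#' @param genes gene-span data frame with `gene_id` and `fpkm` columns.
#' @param meth target [methylome].
#' @param bin_width FPKM bin width (default 0.1).
#' @param fpkm_max upper FPKM limit of the binning grid (default 5;
#'   higher values pool into the last bin).
#' @return list: `bins` data frame (lower, upper, n, frac_unmeth,
#'   frac_meth), `threshold`, `n_unscored`.
#' @export
fpkm_meth_relation <- function(genes, meth, bin_width = 0.1, fpkm_max = 5) {
  if (nrow(genes) == 0) stop("no scorable genes")
  gb <- region_meth(genes, meth, min_cpgs = 3, min_reads = 3)
  scored <- !is.na(gb)
  if (!any(scored)) stop("no scorable genes")
  g <- genes[scored, , drop = FALSE]
  gb <- gb[scored]
  bin <- pmin(floor(g$fpkm / bin_width), fpkm_max / bin_width - 1)
  lower <- sort(unique(bin)) * bin_width
  rows <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(lower = b * bin_width, upper = (b + 1) * bin_width,
               n = sum(i), frac_unmeth = mean(gb[i] < 25),
               frac_meth = mean(gb[i] > 75))
  })
  bins <- do.call(rbind, rows)
  qual <- bins$frac_unmeth > bins$frac_meth
  threshold <- if (any(qual)) max(bins$upper[qual]) else NA_real_
  list(bins = bins, threshold = threshold, n_unscored = sum(!scored))
}

#' Detect genes escaping gene-body methylation
#'
#' Stage 1 screens for genes with FPKM above `min_fpkm`, length at least
#' `min_len` and gene-body methylation below `max_meth` (the profile of a
#' normally methylated gene, but unmethylated).  Stage 2 confirms by
#' tiling the gene body with running windows (`window`, `step`) scored by
#' the 3-CpG / 3-read rule: a gene is confirmed when every scored window
#' is below `max_meth` and at least `min_scored_frac` of windows are
#' scored.
#'
#' @param genes gene-span data frame with `gene_id` and `fpkm`.
#' @param meth target [methylome].
#' @param min_fpkm,min_len,max_meth stage-1 screen (defaults 1, 10 kbp,
#'   25 %).
#' @param window,step running-window geometry (defaults 10 kbp / 5 kbp).
#' @param min_scored_frac minimum fraction of scored windows (default
#'   0.8).
#' @return data frame of screened genes: gene_id, fpkm, length,
#'   gene_body_meth, n_windows, n_scored, confirmed.
#' @export
detect_escapees <- function(genes, meth, min_fpkm = 1, min_len = 10000,
                            max_meth = 25, window = 10000, step = 5000,
                            min_scored_frac = 0.8) {
  len <- genes$end - genes$start
  gb <- region_meth(genes, meth, min_cpgs = 3, min_reads = 3)
  screen <- genes$fpkm > min_fpkm & len >= min_len &
    !is.na(gb) & gb < max_meth
  cand <- genes[screen, , drop = FALSE]
  out <- data.frame(gene_id = cand$gene_id, fpkm = cand$fpkm,
                    length = len[screen], gene_body_meth = gb[screen],
                    n_windows = rep(NA_integer_, nrow(cand)),
                    n_scored = rep(NA_integer_, nrow(cand)),
                    confirmed = logical(nrow(cand)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    starts <- seq(cand$start[i], cand$end[i] - 1, by = step)
    wins <- data.frame(chrom = cand$chrom[i], start = starts,
                       end = pmin(starts + window, cand$end[i]))
    wm <- region_meth(wins, meth, min_cpgs = 3, min_reads = 3)
    out$n_windows[i] <- nrow(wins)
    out$n_scored[i] <- sum(!is.na(wm))
    out$confirmed[i] <- out$n_scored[i] >= min_scored_frac * nrow(wins) &&
      all(wm[!is.na(wm)] < max_meth)
  }
  out
}

#' Feature enrichment between two domain groups
#'
#' Counts domains whose overlap fraction with the feature track exceeds
#' `min_overlap` in each group and tests the 2x2 table with Pearson's
#' chi-squared (no continuity correction, 1 df).
#'
#' @param group_a,group_b domain sets (both non-empty).
#' @param feature_track feature intervals.
#' @param min_overlap overlap fraction cut (default 0.5, strict; use 0
#'   for any-base overlap).
#' @return list: `counts` 2x2 matrix, `chisq`, `p`, `low_expected`
#'   (TRUE when an expected cell is below 5).
#' @export
feature_enrichment <- function(group_a, group_b, feature_track,
                               min_overlap = 0.5) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stop("both domain groups must be non-empty")
  hit_a <- overlap_fraction(group_a, feature_track) > min_overlap
  hit_b <- overlap_fraction(group_b, feature_track) > min_overlap
  counts <- matrix(c(sum(hit_a), sum(!hit_a), sum(hit_b), sum(!hit_b)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("group_a", "group_b"),
                                   c("overlap", "no_overlap")))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low <- any(expected < 5)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    chisq <- 0; p <- 1
  } else {
    tst <- suppressWarnings(chisq.test(counts, correct = FALSE))
    chisq <- unname(tst$statistic); p <- tst$p.value
    if (is.nan(chisq)) { chisq <- 0; p <- 1 }
  }
  list(counts = counts, chisq = chisq, p = p, low_expected = low)
}
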