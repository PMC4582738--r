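# Curation of raw transcriptome assemblies: expression thresholding
# against size-matched intergenic regions (CDF-gap rule), mono-exonic
# filtering, classification against a reference annotation, novel-gene
# and novel-upstream-TSS calling, and TSS classification by CGI/TE.

#' Sample random size-matched intergenic regions
#'
#' For each requested size, places `n_per_size` intervals uniformly on the
#' genome outside annotated genes (with a buffer), by rejection sampling.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param ann an [annotation_set] whose gene spans are avoided.
#' @param sizes numeric vector of interval sizes.
#' @param n_per_size intervals per size.
#' @param seed RNG seed (reproducible).
#' @param buffer bp added around each gene span (default 1000).
#' @param max_tries rejection-sampling budget per interval (default
#'   10000); exhausting it is an error naming the size.
#' @return interval data frame with a `size` column.
#' @export
sample_size_matched_intergenic <- function(chrom_lengths, ann, sizes,
                                           n_per_size, seed = 1,
                                           buffer = 1000,
                                           max_tries = 10000) {
  set.seed(seed)
  g <- ann$genes
  forbidden <- if (nrow(g)) reduce_intervals(
    data.frame(chrom = g$chrom, start = pmax(0, g$start - buffer),
               end = g$end + buffer)) else NULL
  chroms <- names(chrom_lengths)
  pr <- chrom_lengths / sum(chrom_lengths)
  out <- list()
  for (sz in sizes) {
    for (k in seq_len(n_per_size)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(chroms, 1, prob = pr)
        if (chrom_lengths[[ch]] <= sz) next
        st <- floor(runif(1, 0, chrom_lengths[[ch]] - sz))
        cand <- data.frame(chrom = ch, start = st, end = st + sz)
        if (is.null(forbidden) || !any(overlaps_any(cand, forbidden))) {
          cand$size <- sz
          out[[length(out) + 1]] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place intergenic region of size ", sz,
             " after ", max_tries, " tries")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expression threshold from the maximum CDF gap
#'
#' Evaluates the empirical CDFs of annotated-transcript FPKM and random
#' size-matched intergenic FPKM on the pooled value grid; the threshold
#' is the grid point maximising `CDF(intergenic) - CDF(transcripts)`,
#' ties broken toward the smallest value.  Transcripts at or below the
#' threshold are considered non-transcribed.
#'
#' @param transcript_fpkms,intergenic_fpkms non-empty numeric vectors.
#' @return list: `threshold`, `cdf_gap`, `grid`.
#' @export
rabt_threshold <- function(transcript_fpkms, intergenic_fpkms) {
  stopifnot(length(transcript_fpkms) > 0, length(intergenic_fpkms) > 0)
  grid <- sort(unique(c(transcript_fpkms, intergenic_fpkms)))
  ft <- ecdf(transcript_fpkms)
  fi <- ecdf(intergenic_fpkms)
  diff <- fi(grid) - ft(grid)
  gap <- max(diff)
  threshold <- grid[which(diff == gap)[1]]
  if (length(grid) == 1 || gap == 0)
    warning("degenerate CDF gap: samples are not separated")
  list(threshold = threshold, cdf_gap = gap, grid = grid)
}

#' Curate mono-exonic transcripts of a raw assembly
#'
#' Applies, in order: (a) remove mono-exonic transcripts without strand
#' information; (b) remove mono-exonic transcripts lying entirely within
#' an intron of a multi-exonic transcript on the same strand; (c) merge
#' same-strand mono-exonic transcripts starting within `merge_window` bp
#' downstream of a multi-exonic transcript's 3' end (or of a previously
#' merged extension) into that transcript, iterating to a fixpoint;
#' (d) remove mono-exonic genes whose depth-normalised read count (counts
#' per million) does not exceed a threshold derived from normalised
#' random-intergenic counts by the CDF-gap rule.  The rule-(d) threshold
#' is derived from the read-support table itself (all mono-exonic
#' transcripts it lists), so re-running the curation on its own output
#' changes nothing.
#'
#' @param ann raw [annotation_set].
#' @param read_support list with `transcript_counts` (named vector of
#'   read counts per transcript), `total_reads`, `intergenic_counts`
#'   (numeric vector), `intergenic_total`.
#' @param merge_window 3'-merge window in bp (default 2000).
#' @return list: `annotation` (curated [annotation_set]) and `report`
#'   (counts removed/merged per rule, rule-(d) threshold).
#' @export
curate_monoexonic <- function(ann, read_support, merge_window = 2000) {
  ex <- ann$exons
  tx <- ann$transcripts
  mono_ids <- tx$transcript_id[tx$n_exons == 1]
  report <- list(removed_no_strand = 0L, removed_intronic = 0L,
                 merged_3prime = 0L, removed_low_expression = 0L,
                 threshold = NA_real_)
  # (a) drop unstranded mono-exonic transcripts
  drop_a <- intersect(mono_ids, tx$transcript_id[tx$strand == "*"])
  report$removed_no_strand <- length(drop_a)
  ex <- ex[!ex$transcript_id %in% drop_a, , drop = FALSE]
  tx <- tx[!tx$transcript_id %in% drop_a, , drop = FALSE]
  # (b) drop mono-exonic transcripts inside same-strand introns of
  # multi-exonic transcripts
  mono <- tx[tx$n_exons == 1, , drop = FALSE]
  introns <- derive_introns(ex[ex$transcript_id %in%
                                 tx$transcript_id[tx$n_exons > 1], ,
                               drop = FALSE])
  drop_b <- character(0)
  if (nrow(mono) && nrow(introns)) {
    gi <- as_granges(introns[c("chrom", "start", "end", "strand")])
    gm <- as_granges(mono[c("chrom", "start", "end", "strand")])
    hits <- GenomicRanges::findOverlaps(gm, gi, type = "within",
                                        ignore.strand = FALSE)
    drop_b <- unique(mono$transcript_id[S4Vectors::queryHits(hits)])
  }
  report$removed_intronic <- length(drop_b)
  ex <- ex[!ex$transcript_id %in% drop_b, , drop = FALSE]
  tx <- tx[!tx$transcript_id %in% drop_b, , drop = FALSE]
  # (c) 3'-merge mono-exonic transcripts downstream of multi-exonic ends
  repeat {
    mono <- tx[tx$n_exons == 1, , drop = FALSE]
    multi <- tx[tx$n_exons > 1, , drop = FALSE]
    if (nrow(mono) == 0 || nrow(multi) == 0) break
    merged_any <- FALSE
    for (i in seq_len(nrow(multi))) {
      h <- multi[i, ]
      if (h$strand == "+") {
        cand <- mono$chrom == h$chrom & mono$strand == "+" &
          mono$start >= h$end & mono$start - h$end <= merge_window
      } else {
        cand <- mono$chrom == h$chrom & mono$strand == "-" &
          mono$end <= h$start & h$start - mono$end <= merge_window
      }
      if (!any(cand)) next
      ids <- mono$transcript_id[cand]
      # extend the host's 3'-most exon over the merged transcripts
      host_ex <- which(ex$transcript_id == h$transcript_id)
      if (h$strand == "+") {
        last_i <- host_ex[which.max(ex$end[host_ex])]
        ex$end[last_i] <- max(c(ex$end[last_i], mono$end[cand]))
      } else {
        first_i <- host_ex[which.min(ex$start[host_ex])]
        ex$start[first_i] <- min(c(ex$start[first_i], mono$start[cand]))
      }
      ex <- ex[!ex$transcript_id %in% ids, , drop = FALSE]
      tx <- derive_transcripts(ex)
      report$merged_3prime <- report$merged_3prime + length(ids)
      merged_any <- TRUE
      break
    }
    if (!merged_any) break
  }
  # (d) expression filter on mono-exonic genes, CPM vs intergenic CPM
  tx <- derive_transcripts(ex)
  genes <- derive_genes(tx)
  mono_genes <- genes$gene_id[genes$mono_exonic]
  if (length(mono_genes)) {
    cur_mono_tx <- tx$transcript_id[tx$gene_id %in% mono_genes]
    missing <- setdiff(cur_mono_tx, names(read_support$transcript_counts))
    if (length(missing))
      stop("read support missing for transcript(s): ",
           paste(head(missing, 5), collapse = ", "))
    cpm <- function(n, total) 1e6 * n / total
    # threshold from the support table's full mono-exonic distribution
    support_mono <- intersect(names(read_support$transcript_counts),
                              ann$transcripts$transcript_id[
                                ann$transcripts$n_exons == 1])
    thr <- rabt_threshold(
      cpm(read_support$transcript_counts[support_mono],
          read_support$total_reads),
      cpm(read_support$intergenic_counts,
          read_support$intergenic_total))$threshold
    report$threshold <- thr
    gene_counts <- tapply(
      read_support$transcript_counts[cur_mono_tx],
      tx$gene_id[match(cur_mono_tx, tx$transcript_id)], sum)
    low <- names(gene_counts)[
      cpm(as.numeric(gene_counts), read_support$total_reads) <= thr]
    report$removed_low_expression <- length(low)
    drop_tx <- tx$transcript_id[tx$gene_id %in% low]
    ex <- ex[!ex$transcript_id %in% drop_tx, , drop = FALSE]
  }
  list(annotation = annotation_set(ex, fpkm = ann$fpkm), report = report)
}

# junction key strings for one transcript's exon rows
junction_keys <- function(e) {
  if (nrow(e) < 2) return(character(0))
  e <- e[order(e$start), , drop = FALSE]
  paste(e$chrom[1], e$end[-nrow(e)], e$start[-1], e$strand[1], sep = ":")
}

#' Classify assembly transcripts against a reference annotation
#'
#' Simplified Cuffcompare class codes: `=` identical intron chain (for
#' mono-exonic transcripts, identical span); `c` exons contained within a
#' reference transcript's exons (same strand); `j` shares at least one
#' splice junction on the same strand; `o` generic same-strand exonic
#' overlap; `i` entirely within a reference intron on the same strand;
#' `x` exonic overlap on the opposite strand; `u` no overlap.
#' `=`, `c`, `j`, `o` mark transcripts of reference genes; `i`, `u`, `x`
#' are novel.
#'
#' @param ann query [annotation_set].
#' @param ref reference [annotation_set].
#' @return data frame: transcript_id, gene_id, category, ref_gene_id (the
#'   matched reference gene for `=`/`c`/`j`/`o`, else `NA`), novel.
#' @export
classify_vs_reference <- function(ann, ref) {
  qtx <- ann$transcripts
  out <- data.frame(transcript_id = qtx$transcript_id,
                    gene_id = qtx$gene_id,
                    category = rep("u", nrow(qtx)),
                    ref_gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(qtx) == 0 || nrow(ref$transcripts) == 0) {
    out$novel <- out$category %in% c("i", "u", "x")
    return(out)
  }
  rex_by_tx <- split(ref$exons, ref$exons$transcript_id)
  rtx <- ref$transcripts
  r_junc <- lapply(rex_by_tx, junction_keys)
  r_introns <- derive_introns(ref$exons)
  qex_by_tx <- split(ann$exons, ann$exons$transcript_id)
  for (qi in seq_len(nrow(qtx))) {
    q <- qtx[qi, ]
    qe <- qex_by_tx[[q$transcript_id]]
    qj <- junction_keys(qe)
    cand <- which(rtx$chrom == q$chrom & rtx$start < q$end &
                    rtx$end > q$start)
    best <- "u"; best_gene <- NA_character_
    rank <- c("=" = 1, "c" = 2, "j" = 3, "o" = 4, "i" = 5, "x" = 6,
              "u" = 7)
    consider <- function(code, gene) {
      if (rank[[code]] < rank[[best]]) {
        best <<- code; best_gene <<- gene
      }
    }
    for (ri in cand) {
      r <- rtx[ri, ]
      re <- rex_by_tx[[r$transcript_id]]
      exonic_overlap <- any(overlaps_any(qe, re))
      if (r$strand == q$strand) {
        rj <- r_junc[[r$transcript_id]]
        if (q$n_exons > 1 && r$n_exons > 1 &&
            length(qj) == length(rj) && all(qj == rj)) {
          consider("=", r$gene_id); next
        }
        if (q$n_exons == 1 && r$n_exons == 1 &&
            q$start == r$start && q$end == r$end) {
          consider("=", r$gene_id); next
        }
        if (exonic_overlap &&
            all(covered_bp(qe, re) == qe$end - qe$start)) {
          consider("c", r$gene_id); next
        }
        if (length(intersect(qj, rj)) > 0) {
          consider("j", r$gene_id); next
        }
        if (exonic_overlap) {
          consider("o", r$gene_id); next
        }
      } else if (exonic_overlap) {
        consider("x", NA_character_)
      }
    }
    if (best %in% c("u", "x") && nrow(r_introns)) {
      within_intron <- r_introns$chrom == q$chrom &
        r_introns$strand == q$strand &
        r_introns$start <= q$start & r_introns$end >= q$end
      if (any(within_intron)) best <- "i"
    }
    out$category[qi] <- best
    out$ref_gene_id[qi] <- best_gene
  }
  out$novel <- out$category %in% c("i", "u", "x")
  out
}

#' Call high-confidence novel genes
#'
#' Genes whose transcripts are all novel (`i`/`u`/`x`) are excluded when
#' they overlap or lie in close proximity, on the same strand, to
#' reference genes or known ncRNAs (margins `multi_margin` for
#' multi-exonic and `mono_margin` for mono-exonic genes, span to span),
#' or when a mono-exonic gene's exonic span is covered at least
#' `repeat_cover` by a single transposable element.
#'
#' @param ann query [annotation_set].
#' @param classes output of [classify_vs_reference()] for `ann`.
#' @param ref reference [annotation_set].
#' @param noncode_track stranded intervals of known ncRNAs (may be
#'   empty).
#' @param te_track TE track from [read_repeatmasker()] (may be empty).
#' @param multi_margin,mono_margin proximity margins in bp (defaults
#'   1000 and 5000).
#' @param repeat_cover single-TE coverage fraction for the repeat rule
#'   (default 0.5).
#' @return data frame: gene_id, mono_exonic, near_reference,
#'   near_noncode, repeat_monoexonic, accepted.
#' @export
call_novel_genes <- function(ann, classes, ref, noncode_track = NULL,
                             te_track = NULL, multi_margin = 1000,
                             mono_margin = 5000, repeat_cover = 0.5) {
  novel_by_gene <- tapply(classes$novel, classes$gene_id, all)
  gids <- names(novel_by_gene)[novel_by_gene]
  g <- ann$genes[ann$genes$gene_id %in% gids, , drop = FALSE]
  if (nrow(g) == 0) {
    return(data.frame(gene_id = character(), mono_exonic = logical(),
                      near_reference = logical(), near_noncode = logical(),
                      repeat_monoexonic = logical(), accepted = logical()))
  }
  margin <- ifelse(g$mono_exonic, mono_margin, multi_margin)
  expanded <- data.frame(chrom = g$chrom,
                         start = pmax(0, g$start - margin),
                         end = g$end + margin, strand = g$strand)
  rg <- ref$genes
  near_ref <- if (nrow(rg)) overlaps_any(
    expanded, data.frame(chrom = rg$chrom, start = rg$start, end = rg$end,
                         strand = rg$strand), strand_aware = TRUE)
  else rep(FALSE, nrow(g))
  near_nc <- if (!is.null(noncode_track) && nrow(noncode_track))
    overlaps_any(expanded, noncode_track, strand_aware = TRUE)
  else rep(FALSE, nrow(g))
  rep_mono <- rep(FALSE, nrow(g))
  if (!is.null(te_track) && nrow(te_track)) {
    for (i in which(g$mono_exonic)) {
      gex <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
      exonic_bp <- sum(gex$end - gex$start)
      tes <- te_track[te_track$chrom == g$chrom[i] &
                        te_track$start < g$end[i] &
                        te_track$end > g$start[i], , drop = FALSE]
      for (j in seq_len(nrow(tes))) {
        cov <- covered_bp(gex, tes[j, , drop = FALSE])
        if (sum(cov) >= repeat_cover * exonic_bp) {
          rep_mono[i] <- TRUE
          break
        }
      }
    }
  }
  data.frame(gene_id = g$gene_id, mono_exonic = g$mono_exonic,
             near_reference = near_ref, near_noncode = near_nc,
             repeat_monoexonic = rep_mono,
             accepted = !(near_ref | near_nc | rep_mono),
             stringsAsFactors = FALSE)
}

#' Find novel upstream TSSs of reference genes
#'
#' A reference gene gains a novel upstream TSS when some assembly
#' transcript matched to it (`=`/`c`/`j`/`o`) starts (i) upstream of the
#' reference gene's most upstream TSS on the same strand, (ii) in an exon
#' with no base overlap with any reference exon of that gene, and
#' (iii) outside every CGI associated with the reference TSS (+/- 100 bp).
#'
#' @param ann query [annotation_set].
#' @param classes output of [classify_vs_reference()].
#' @param ref reference [annotation_set].
#' @param cgi_track CGI intervals (may be empty).
#' @param tss_flank CGI-association flank around the reference TSS
#'   (default 100).
#' @return list: `records` (gene-level: ref_gene_id, transcript_id,
#'   tss, strand, distance) and `median_distance`.
#' @export
find_novel_upstream_tss <- function(ann, classes, ref, cgi_track = NULL,
                                    tss_flank = 100) {
  matched <- classes[!is.na(classes$ref_gene_id), , drop = FALSE]
  empty <- data.frame(ref_gene_id = character(),
                      transcript_id = character(), tss = numeric(),
                      strand = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(matched) == 0)
    return(list(records = empty, median_distance = NA_real_))
  rg <- ref$genes
  recs <- list()
  for (i in seq_len(nrow(matched))) {
    tid <- matched$transcript_id[i]
    q <- ann$transcripts[ann$transcripts$transcript_id == tid, ]
    r <- rg[rg$gene_id == matched$ref_gene_id[i], ]
    if (nrow(r) == 0 || r$strand != q$strand) next
    upstream <- if (q$strand == "+") q$tss < r$tss else q$tss > r$tss
    if (!upstream) next
    # (ii) the TSS-containing exon must not touch any reference exon of
    # the gene
    qe <- ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
    first <- if (q$strand == "+") qe[which.min(qe$start), , drop = FALSE]
    else qe[which.max(qe$end), , drop = FALSE]
    ref_ex <- ref$exons[ref$exons$gene_id == r$gene_id, , drop = FALSE]
    if (nrow(ref_ex) && any(overlaps_any(first, ref_ex))) next
    # (iii) outside reference-TSS-associated CGIs
    if (!is.null(cgi_track) && nrow(cgi_track)) {
      tss_win <- data.frame(chrom = r$chrom,
                            start = pmax(0, r$tss - tss_flank),
                            end = r$tss + tss_flank + 1)
      assoc <- cgi_track[overlaps_any(cgi_track, tss_win), , drop = FALSE]
      if (nrow(assoc)) {
        in_cgi <- any(assoc$chrom == q$chrom & assoc$start <= q$tss &
                        q$tss < assoc$end)
        if (in_cgi) next
      }
    }
    recs[[length(recs) + 1]] <-
      data.frame(ref_gene_id = r$gene_id, transcript_id = tid,
                 tss = q$tss, strand = q$strand,
                 distance = abs(q$tss - r$tss), stringsAsFactors = FALSE)
  }
  if (length(recs) == 0)
    return(list(records = empty, median_distance = NA_real_))
  recs <- do.call(rbind, recs)
  # one record per gene: the most upstream qualifying TSS
  recs <- recs[order(recs$ref_gene_id, -recs$distance), , drop = FALSE]
  recs <- recs[!duplicated(recs$ref_gene_id), , drop = FALSE]
  rownames(recs) <- NULL
  list(records = recs, median_distance = median(recs$distance))
}

#' Classify TSSs by CGI and TE association
#'
#' A TSS is CGI-associated when its first base +/- `flank` bp overlaps a
#' CGI; otherwise TE-associated when its first base overlaps a TE on the
#' same strand (family recorded); otherwise `other`.
#'
#' @param tss data frame: chrom, pos (0-based first transcribed base),
#'   strand, and any id columns.
#' @param cgi_track CGI intervals.
#' @param te_track TE track with `family` and `strand`.
#' @param flank CGI flank in bp (default 100).
#' @return input with `class` (`CGI_associated`, `TE_associated`,
#'   `other`) and `te_family` columns.
#' @export
classify_tss <- function(tss, cgi_track = NULL, te_track = NULL,
                         flank = 100) {
  n <- nrow(tss)
  cls <- rep("other", n)
  fam <- rep(NA_character_, n)
  if (n == 0) {
    tss$class <- character(0); tss$te_family <- character(0)
    return(tss)
  }
  win <- data.frame(chrom = tss$chrom, start = pmax(0, tss$pos - flank),
                    end = tss$pos + flank + 1)
  if (!is.null(cgi_track) && nrow(cgi_track))
    cls[overlaps_any(win, cgi_track)] <- "CGI_associated"
  if (!is.null(te_track) && nrow(te_track)) {
    pt <- data.frame(chrom = tss$chrom, start = tss$pos,
                     end = tss$pos + 1, strand = tss$strand)
    gp <- as_granges(pt)
    gt <- as_granges(te_track[c("chrom", "start", "end", "strand",
                                "family")])
    hits <- GenomicRanges::findOverlaps(gp, gt, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits)
    first <- !duplicated(qh)
    te_hit <- qh[first]
    te_fam <- te_track$family[S4Vectors::subjectHits(hits)[first]]
    sel <- cls[te_hit] != "CGI_associated"
    cls[te_hit[sel]] <- "TE_associated"
    fam[te_hit[sel]] <- te_fam[sel]
  }
  tss$class <- cls
  tss$te_family <- fam
  tss
}

#' TE-family TSS enrichment against intergenic occupancy
#'
#' Expected TSS-in-family counts come from random placement proportional
#' to each family's share of intergenic bp (checked by seeded Monte
#' Carlo); per family the observed/expected ratio and a binomial p value
#' are reported.
#'
#' @param te_track TE track with `family`.
#' @param intergenic_track intergenic intervals.
#' @param observed_counts named vector: observed TSS count per family.
#' @param total_tss total number of TSSs classified.
#' @param seed RNG seed.
#' @param n_draws Monte-Carlo draws (default 200).
#' @return data frame per family: occupancy, expected, expected_mc,
#'   observed, ratio, p (families with zero occupancy and zero observed
#'   are skipped).
#' @export
te_tss_expectation <- function(te_track, intergenic_track,
                               observed_counts, total_tss, seed = 1,
                               n_draws = 200) {
  set.seed(seed)
  inter <- reduce_intervals(intergenic_track)
  total_bp <- sum(inter$end - inter$start)
  fams <- unique(te_track$family)
  rows <- list()
  # pre-sample positions once: n_draws x total_tss uniform points on the
  # concatenated intergenic space
  cum <- cumsum(inter$end - inter$start)
  draw_positions <- function(n) {
    u <- runif(n) * total_bp
    idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    off <- u - c(0, cum)[idx]
    data.frame(chrom = inter$chrom[idx],
               start = floor(inter$start[idx] + off))
  }
  mc <- draw_positions(total_tss * n_draws)
  mc$end <- mc$start + 1
  mc$draw <- rep(seq_len(n_draws), each = total_tss)
  for (fam in fams) {
    fam_inter <- intersect_intervals(
      te_track[te_track$family == fam, c("chrom", "start", "end")],
      inter)
    occ_bp <- if (nrow(fam_inter))
      sum(fam_inter$end - fam_inter$start) else 0
    obs <- if (fam %in% names(observed_counts))
      observed_counts[[fam]] else 0
    if (occ_bp == 0 && obs == 0) next
    frac <- occ_bp / total_bp
    expected <- total_tss * frac
    in_fam <- overlaps_any(mc, fam_inter)
    mc_counts <- tapply(in_fam, mc$draw, sum)
    p <- if (frac > 0 && frac < 1)
      binom.test(obs, total_tss, frac)$p.value else NA_real_
    rows[[fam]] <- data.frame(
      family = fam, occupancy = frac, expected = expected,
      expected_mc = mean(mc_counts), observed = obs,
      ratio = if (expected > 0) obs / expected else NA_real_, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intergenic space of an annotation
#'
#' The genome minus all gene spans (each grown by `buffer` bp).
#'
#' @param ann an [annotation_set].
#' @param chrom_lengths named vector of chromosome lengths.
#' @param buffer bp removed around every gene span (default 0).
#' @return interval data frame of intergenic space.
#' @export
intergenic_track <- function(ann, chrom_lengths, buffer = 0) {
  whole <- data.frame(chrom = names(chrom_lengths), start = 0,
                      end = as.numeric(chrom_lengths))
  g <- ann$genes
  if (nrow(g) == 0) return(whole)
  subtract_intervals(whole, data.frame(
    chrom = g$chrom, start = pmax(0, g$start - buffer),
    end = g$end + buffer))[c("chrom", "start", "end")]
}

# strand-agnostic intersection of two interval sets (both reduced first)
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  ga <- GenomicRanges::reduce(as_granges(a[c("chrom", "start", "end")]))
  gb <- GenomicRanges::reduce(as_granges(b[c("chrom", "start", "end")]))
  out <- suppressWarnings(GenomicRanges::intersect(ga, gb))
  granges_to_df(out)[c("chrom", "start", "end")]
}

#' Restore patch transcripts above an expression threshold
#'
#' Transcripts present in a patch annotation but absent from the primary
#' one are restored when their FPKM exceeds `threshold` (the RABT
#' CDF-gap threshold).
#'
#' @param primary,patch [annotation_set]s.
#' @param fpkm named vector of patch-transcript FPKM.
#' @param threshold expression floor.
#' @return merged [annotation_set].
#' @export
reconcile_annotations <- function(primary, patch, fpkm, threshold) {
  miss <- setdiff(patch$transcripts$transcript_id,
                  primary$transcripts$transcript_id)
  keep <- miss[!is.na(fpkm[miss]) & fpkm[miss] > threshold]
  add <- patch$exons[patch$exons$transcript_id %in% keep, , drop = FALSE]
  annotation_set(rbind(primary$exons, add), fpkm = primary$fpkm)
}
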