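# CpG-island classification: position relative to the gene set,
# methylation status, transcription context, and igDMR location against
# two annotations.

#' Classify CGI location relative to an annotation
#'
#' A CGI is `tss_associated` when it overlaps any gene's most upstream
#' TSS +/- `flank` bp; else `intragenic_with_alt_tss` when, inside a gene,
#' it overlaps a non-most-upstream transcript TSS +/- `flank` bp; else
#' `intragenic` when it overlaps a gene span; else `intergenic`.
#'
#' @param cgi_track CGI intervals.
#' @param ann an [annotation_set].
#' @param flank TSS flank in bp (default 100).
#' @return CGI data frame with a `location_class` column.
#' @export
classify_cgi_location <- function(cgi_track, ann, flank = 100) {
  cgi <- cgi_track
  n <- nrow(cgi)
  cls <- rep("intergenic", n)
  if (n > 0 && nrow(ann$genes) > 0) {
    g <- ann$genes
    spans <- data.frame(chrom = g$chrom, start = g$start, end = g$end)
    cls[overlaps_any(cgi, spans)] <- "intragenic"
    tx <- ann$transcripts
    gene_tss <- setNames(g$tss, g$gene_id)
    alt <- tx[tx$tss != gene_tss[tx$gene_id], , drop = FALSE]
    if (nrow(alt)) {
      alt_win <- data.frame(chrom = alt$chrom,
                            start = pmax(0, alt$tss - flank),
                            end = alt$tss + flank + 1)
      hit_alt <- overlaps_any(cgi, alt_win)
      cls[cls == "intragenic" & hit_alt] <- "intragenic_with_alt_tss"
    }
    tss_win <- data.frame(chrom = g$chrom,
                          start = pmax(0, g$tss - flank),
                          end = g$tss + flank + 1)
    cls[overlaps_any(cgi, tss_win)] <- "tss_associated"
  }
  cgi$location_class <- factor(
    cls, levels = c("tss_associated", "intragenic_with_alt_tss",
                    "intragenic", "intergenic"))
  cgi
}

#' CGI methylation status
#'
#' Mean methylation over CpGs with at least `min_reads` reads; a CGI
#' needs at least `min_cpgs` such CpGs to be scored.  Status thresholds
#' are inclusive: hyper at >= `hyper_cut`, hypo at <= `hypo_cut`.
#'
#' @param cgi_track CGI intervals.
#' @param meth target [methylome].
#' @param min_cpgs,min_reads scoring rule (defaults 10 CpGs at 5 reads).
#' @param hyper_cut,hypo_cut status thresholds (defaults 75/25).
#' @return CGI data frame with `meth_pct`, `n_scored_cpgs` and
#'   `meth_status` (`hyper`, `hypo`, `intermediate`, `unscored`).
#' @export
cgi_meth_status <- function(cgi_track, meth, min_cpgs = 10, min_reads = 5,
                            hyper_cut = 75, hypo_cut = 25) {
  cgi <- cgi_track
  n <- nrow(cgi)
  if (n == 0) {
    cgi$meth_pct <- numeric(0); cgi$n_scored_cpgs <- integer(0)
    cgi$meth_status <- factor(character(),
                              levels = c("hyper", "hypo", "intermediate",
                                         "unscored"))
    return(cgi)
  }
  cpgs <- meth$cpgs
  cov <- cpgs$n_meth + cpgs$n_unmeth
  sc <- cpgs[cov >= min_reads, , drop = FALSE]
  mp <- rep(NA_real_, n)
  ns <- integer(n)
  if (nrow(sc)) {
    pct <- 100 * sc$n_meth / (sc$n_meth + sc$n_unmeth)
    gr <- as_granges(cgi[c("chrom", "start", "end")])
    gc <- as_granges(data.frame(chrom = sc$chrom, start = sc$pos,
                                end = sc$pos + 1))
    hits <- GenomicRanges::findOverlaps(gc, gr)
    ci <- S4Vectors::subjectHits(hits)
    pv <- pct[S4Vectors::queryHits(hits)]
    if (length(ci)) {
      nn <- tapply(pv, ci, length)
      mm <- tapply(pv, ci, mean)
      idx <- as.integer(names(mm))
      ns[idx] <- as.integer(nn)
      mp[idx] <- as.numeric(mm)
    }
  }
  status <- rep("unscored", n)
  ok <- ns >= min_cpgs
  status[ok] <- "intermediate"
  status[ok & mp >= hyper_cut] <- "hyper"
  status[ok & mp <= hypo_cut] <- "hypo"
  cgi$meth_pct <- ifelse(ok, mp, NA_real_)
  cgi$n_scored_cpgs <- ns
  cgi$meth_status <- factor(status, levels = c("hyper", "hypo",
                                               "intermediate", "unscored"))
  cgi
}

#' Transcription context of CGIs
#'
#' Flags each CGI for any-base overlap with read contigs and for overlap
#' with the first `downstream_bp` downstream of any gene's 3' end, and
#' tests (2x2 chi-squared, via [feature_enrichment()]) whether methylated
#' intergenic CGIs overlap contigs more often than unmethylated
#' intergenic ones.
#'
#' @param cgi CGI data frame carrying `location_class` and `meth_status`
#'   (see [classify_cgi_location()] and [cgi_meth_status()]).
#' @param ann an [annotation_set].
#' @param contigs contig track.
#' @param downstream_bp downstream window (default 1000).
#' @return list: `cgi` (with `overlapped_by_contig` and
#'   `downstream_of_gene` flags) and `intergenic_test` (chi-squared
#'   result, or `NULL` with a note when there are no intergenic CGIs to
#'   compare).
#' @export
cgi_transcription_context <- function(cgi, ann, contigs,
                                      downstream_bp = 1000) {
  n <- nrow(cgi)
  cgi$overlapped_by_contig <- if (n) overlaps_any(cgi, contigs)
  else logical(0)
  g <- ann$genes
  if (n && nrow(g)) {
    ds <- data.frame(
      chrom = g$chrom,
      start = ifelse(g$strand == "-", pmax(0, g$start - downstream_bp),
                     g$end),
      end = ifelse(g$strand == "-", g$start, g$end + downstream_bp))
    cgi$downstream_of_gene <- overlaps_any(cgi, ds)
  } else {
    cgi$downstream_of_gene <- logical(n)
  }
  inter <- cgi[cgi$location_class == "intergenic", , drop = FALSE]
  m <- inter[inter$meth_status == "hyper", , drop = FALSE]
  u <- inter[inter$meth_status == "hypo", , drop = FALSE]
  test <- NULL
  note <- NULL
  if (nrow(m) && nrow(u)) {
    test <- feature_enrichment(m, u, contigs, min_overlap = 0)
  } else {
    note <- "no intergenic CGIs in both methylation classes"
  }
  list(cgi = cgi, intergenic_test = test, note = note)
}

#' Classify igDMRs against two annotations and the domain map
#'
#' Each igDMR is located (tss_associated / intragenic_with_alt_tss /
#' intragenic / intergenic) independently against the reference and the
#' oocyte annotation, and annotated with the class of any overlapping
#' domain.
#'
#' @param igdmr_track igDMR intervals (optional `name` column).
#' @param ref,ann reference and oocyte [annotation_set]s.
#' @param domains domain set (may be empty).
#' @return data frame: name, chrom, start, end, ref_class, oocyte_class,
#'   domain_class (`hyper`, `hypo` or `NA`).
#' @export
classify_igdmrs <- function(igdmr_track, ref, ann, domains = NULL) {
  ig <- igdmr_track
  if (nrow(ig) == 0) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      ref_class = character(), oocyte_class = character(),
                      domain_class = character(), stringsAsFactors = FALSE))
  }
  if (!"name" %in% names(ig))
    ig$name <- sprintf("igDMR_%03d", seq_len(nrow(ig)))
  missing_ref <- !ig$chrom %in% ref$genes$chrom
  missing_ann <- !ig$chrom %in% ann$genes$chrom
  if (any(missing_ref | missing_ann))
    warning("igDMR(s) on chromosome absent from an annotation; ",
            "classified intergenic")
  ref_cls <- classify_cgi_location(ig, ref)$location_class
  ooc_cls <- classify_cgi_location(ig, ann)$location_class
  dom_cls <- rep(NA_character_, nrow(ig))
  if (!is.null(domains) && nrow(domains)) {
    gi <- as_granges(ig[c("chrom", "start", "end")])
    gd <- as_granges(domains[c("chrom", "start", "end")])
    hits <- GenomicRanges::findOverlaps(gi, gd)
    if (length(hits)) {
      # widest-overlap domain wins
      ov <- GenomicRanges::width(IRanges::pintersect(
        gi[S4Vectors::queryHits(hits)], gd[S4Vectors::subjectHits(hits)]))
      o <- order(S4Vectors::queryHits(hits), -ov)
      qh <- S4Vectors::queryHits(hits)[o]
      sh <- S4Vectors::subjectHits(hits)[o]
      first <- !duplicated(qh)
      dom_cls[qh[first]] <- domains$class[sh[first]]
    }
  }
  data.frame(name = ig$name, chrom = ig$chrom, start = ig$start,
             end = ig$end, ref_class = as.character(ref_cls),
             oocyte_class = as.character(ooc_cls),
             domain_class = dom_cls, stringsAsFactors = FALSE)
}
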