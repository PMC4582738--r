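# Annotation container: exon-structured transcripts grouped into genes.
# A gene is a transcription unit that may comprise several isoforms; its
# span runs from the most upstream start to the most downstream end over
# all member transcripts, and its expression is the sum of member FPKMs.

#' Construct an annotation set from an exon table
#'
#' @param exons data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `transcript_id`, `gene_id`.
#' @param fpkm optional long data frame (`transcript_id`, `stage`, `fpkm`)
#'   of per-transcript expression.
#' @param category optional named character vector of per-transcript
#'   Cuffcompare-style class codes.
#' @return object of class `annotation_set` with elements `exons`,
#'   `transcripts`, `genes`, `fpkm`.
#' @export
annotation_set <- function(exons, fpkm = NULL, category = NULL) {
  need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  stopifnot(all(need %in% names(exons)))
  exons <- exons[need]
  if (nrow(exons) > 0) {
    validate_intervals(exons)
    if (any(!exons$strand %in% c("+", "-", "*")))
      stop("exon strand must be '+', '-' or '*'")
    exons <- exons[order(exons$chrom, exons$transcript_id, exons$start), ,
                   drop = FALSE]
    rownames(exons) <- NULL
    ns <- tapply(exons$strand, exons$transcript_id,
                 function(s) length(unique(s)))
    if (any(ns > 1))
      stop("transcript on mixed strands: ",
           paste(names(ns)[ns > 1], collapse = ", "))
    # exons of one transcript must not overlap
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      if (length(idx) > 1 &&
          any(exons$start[idx][-1] < exons$end[idx][-length(idx)]))
        stop("overlapping exons within transcript ",
             exons$transcript_id[idx[1]])
    }
  }
  obj <- structure(list(exons = exons), class = "annotation_set")
  obj$transcripts <- derive_transcripts(exons)
  obj$genes <- derive_genes(obj$transcripts)
  obj$fpkm <- fpkm
  if (!is.null(category)) {
    obj$transcripts$category <-
      unname(category[obj$transcripts$transcript_id])
  }
  obj
}

derive_transcripts <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric(),
                      n_exons = integer(), tss = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- do.call(rbind, lapply(split(exons, exons$transcript_id), function(e) {
    data.frame(transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
               chrom = e$chrom[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end),
               n_exons = nrow(e), stringsAsFactors = FALSE)
  }))
  # TSS: first transcribed base (internal coordinates)
  agg$tss <- ifelse(agg$strand == "-", agg$end - 1, agg$start)
  agg <- agg[order(agg$chrom, agg$start, agg$transcript_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

derive_genes <- function(tx) {
  if (nrow(tx) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), n_transcripts = integer(),
                      mono_exonic = logical(), tss = numeric(),
                      stringsAsFactors = FALSE))
  }
  g <- do.call(rbind, lapply(split(tx, tx$gene_id), function(t) {
    data.frame(gene_id = t$gene_id[1], chrom = t$chrom[1],
               strand = t$strand[1], start = min(t$start),
               end = max(t$end), n_transcripts = nrow(t),
               mono_exonic = all(t$n_exons == 1), stringsAsFactors = FALSE)
  }))
  g$tss <- ifelse(g$strand == "-", g$end - 1, g$start)
  g <- g[order(g$chrom, g$start, g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d genes, %d transcripts, %d exons>\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Per-gene expression at a stage
#'
#' Gene expression is the sum of the FPKM values of all member transcripts.
#'
#' @param ann an [annotation_set] carrying an `fpkm` table.
#' @param stage stage label to extract.
#' @return named numeric vector of FPKM per `gene_id` (genes absent from
#'   the FPKM table get 0).
#' @export
gene_fpkm <- function(ann, stage) {
  out <- setNames(rep(0, nrow(ann$genes)), ann$genes$gene_id)
  if (is.null(ann$fpkm)) return(out)
  f <- ann$fpkm[ann$fpkm$stage == stage, , drop = FALSE]
  if (nrow(f) == 0) return(out)
  gid <- ann$transcripts$gene_id[match(f$transcript_id,
                                       ann$transcripts$transcript_id)]
  s <- tapply(f$fpkm, gid, sum)
  out[names(s)] <- as.numeric(s)
  out
}

# intron table for a set of transcripts (rows of ann$exons)
derive_introns <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      transcript_id = character(), stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(exons, exons$transcript_id), function(e) {
    if (nrow(e) < 2) return(NULL)
    e <- e[order(e$start), , drop = FALSE]
    data.frame(chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1],
               strand = e$strand[1], transcript_id = e$transcript_id[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      transcript_id = character(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Gene-level TSS mask intervals
#'
#' One 2-kbp interval per gene, starting at the gene's most upstream TSS
#' and extending in the direction of transcription; overlapping intervals
#' are merged.  These are the promoter regions excluded from domain
#' designation.
#'
#' @param ann an [annotation_set].
#' @param width mask width in bp (default 2000).
#' @return mask feature track (non-overlapping, sorted).
#' @export
tss_mask <- function(ann, width = 2000) {
  g <- ann$genes
  if (nrow(g) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
    attr(out, "kind") <- "mask"
    return(out)
  }
  start <- ifelse(g$strand == "-", pmax(0, g$tss - width + 1), g$tss)
  end <- ifelse(g$strand == "-", g$tss + 1, g$tss + width)
  out <- reduce_intervals(data.frame(chrom = g$chrom, start = start,
                                     end = end))
  attr(out, "kind") <- "mask"
  out
}
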