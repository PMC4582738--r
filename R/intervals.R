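# Internal interval arithmetic.  Intervals travel as plain data frames with
# columns chrom/start/end (0-based half-open) plus optional strand and
# attribute columns; GenomicRanges does the heavy lifting behind converters.

#' Construct a genomic-interval data frame
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param strand optional strand vector in `+`, `-`, `*`.
#' @param ... further per-interval columns recycled to length.
#' @return data frame with validated interval columns.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must exceed start")
  if ("strand" %in% names(df) &&
      !all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(df)
}

# data frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand)
  meta <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(meta)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[meta])
  }
  gr
}

granges_to_df <- function(gr) {
  if (length(gr) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(meta)) df <- cbind(df, meta)
  rownames(df) <- NULL
  df
}

sort_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# union (merge touching/overlapping), strand ignored
reduce_intervals <- function(df) {
  if (nrow(df) == 0) return(df[c("chrom", "start", "end")])
  df2 <- df[c("chrom", "start", "end")]
  out <- granges_to_df(GenomicRanges::reduce(as_granges(df2)))
  sort_intervals(out[c("chrom", "start", "end")])
}

# strand-aware union
reduce_intervals_stranded <- function(df) {
  if (nrow(df) == 0) return(df[c("chrom", "start", "end", "strand")])
  out <- granges_to_df(GenomicRanges::reduce(
    as_granges(df[c("chrom", "start", "end", "strand")])))
  sort_intervals(out)
}

# total bp of x covered by (reduced) y, per row of x
covered_bp <- function(x, y) {
  if (nrow(x) == 0) return(numeric(0))
  if (nrow(y) == 0) return(rep(0, nrow(x)))
  gx <- as_granges(x[c("chrom", "start", "end")])
  gy <- GenomicRanges::reduce(as_granges(y[c("chrom", "start", "end")]))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gx, gy))
  if (length(hits) == 0) return(rep(0, nrow(x)))
  inter <- IRanges::pintersect(gx[S4Vectors::queryHits(hits)],
                               gy[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(inter)
  out <- rep(0, nrow(x))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

# Subtract a (reduced) mask from each interval of x.  The result keeps all
# attribute columns of the parent row; an interval fully covered by the mask
# contributes no rows.  Implemented by intersecting x with the complement of
# the mask, so cost scales with the number of mask gaps, not |x| * |mask|.
subtract_intervals <- function(x, mask) {
  if (nrow(x) == 0 || nrow(mask) == 0) return(x)
  span <- max(c(x$end, mask$end)) + 1
  chroms <- unique(c(x$chrom, mask$chrom))
  gm <- as_granges(mask[c("chrom", "start", "end")])
  GenomeInfoDb::seqlevels(gm) <- chroms
  GenomeInfoDb::seqlengths(gm) <- rep(span, length(chroms))
  comp <- GenomicRanges::gaps(GenomicRanges::reduce(gm))
  comp <- comp[GenomicRanges::strand(comp) == "*"]
  gx <- as_granges(x[c("chrom", "start", "end")])
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gx, comp))
  if (length(hits) == 0) return(x[0, , drop = FALSE])
  inter <- IRanges::pintersect(gx[S4Vectors::queryHits(hits)],
                               comp[S4Vectors::subjectHits(hits)])
  out <- x[S4Vectors::queryHits(hits), , drop = FALSE]
  out$start <- GenomicRanges::start(inter) - 1
  out$end <- GenomicRanges::end(inter)
  rownames(out) <- NULL
  sort_intervals(out)
}

# any-base overlap indicator for rows of x against reduced y
overlaps_any <- function(x, y, strand_aware = FALSE) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  cols <- c("chrom", "start", "end", if (strand_aware) "strand")
  gx <- as_granges(x[cols])
  gy <- as_granges(y[cols])
  suppressWarnings(IRanges::overlapsAny(gx, gy,
                                        ignore.strand = !strand_aware))
}
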