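# Readers and writers for the external formats the pipeline touches.
# Everything is normalised at the boundary to 0-based half-open coordinates;
# CpGs are strand-combined units keyed by the C position on the + strand.

#' Construct a methylome table
#'
#' Per-CpG methylated/unmethylated read counts for one sample.  Records are
#' sorted by (chrom, pos) and duplicate positions are summed, matching the
#' convention of strand-merged Bismark coverage output.
#'
#' @param cpgs data frame with columns `chrom`, `pos` (0-based position of
#'   the C of the strand-combined CpG unit), `n_meth`, `n_unmeth`.
#' @param label sample label, e.g. `"FGO"` or `"NGO"`.
#' @return object of class `methylome`.
#' @export
methylome <- function(cpgs, label = "sample") {
  stopifnot(all(c("chrom", "pos", "n_meth", "n_unmeth") %in% names(cpgs)))
  if (nrow(cpgs) > 0) {
    if (any(cpgs$n_meth < 0) || any(cpgs$n_unmeth < 0))
      stop("negative read counts in methylome table")
    if (any(cpgs$pos < 0)) stop("negative CpG position")
    cpgs <- aggregate(cbind(n_meth, n_unmeth) ~ chrom + pos,
                      data = cpgs, FUN = sum)
    cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
    rownames(cpgs) <- NULL
  }
  structure(list(cpgs = cpgs[c("chrom", "pos", "n_meth", "n_unmeth")],
                 label = label),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome '%s': %d CpGs on %d chromosome(s)>\n",
              x$label, nrow(x$cpgs), length(unique(x$cpgs$chrom))))
  invisible(x)
}

# per-CpG coverage and methylation percent (NA when uncovered)
cpg_meth_pct <- function(cpgs) {
  cov <- cpgs$n_meth + cpgs$n_unmeth
  ifelse(cov > 0, 100 * cpgs$n_meth / cov, NA_real_)
}

#' Read a CpG methylation call table
#'
#' @param path file path.
#' @param dialect `"bismark_cov"` for Bismark coverage rows
#'   (chrom, start, end, meth%, count_meth, count_unmeth; 1-based) or
#'   `"bedgraph_counts"` for the same columns with a 0-based half-open
#'   start.
#' @param label sample label attached to the result.
#' @return a [methylome] object; duplicate positions are summed.
#' @export
read_cpg_table <- function(path, dialect = c("bismark_cov", "bedgraph_counts"),
                           label = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "meth_pct",
                             "n_meth", "n_unmeth"),
               colClasses = c("character", "numeric", "numeric",
                              "numeric", "numeric", "numeric")),
    error = function(e) stop("malformed CpG table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0) {
    return(methylome(data.frame(chrom = character(), pos = numeric(),
                                n_meth = numeric(), n_unmeth = numeric()),
                     label))
  }
  if (any(raw$n_meth < 0) || any(raw$n_unmeth < 0)) {
    bad <- which(raw$n_meth < 0 | raw$n_unmeth < 0)[1]
    stop("negative count at line ", bad, " of ", path)
  }
  pos <- if (dialect == "bismark_cov") raw$start - 1 else raw$start
  methylome(data.frame(chrom = raw$chrom, pos = pos,
                       n_meth = raw$n_meth, n_unmeth = raw$n_unmeth),
            label)
}

#' Write a methylome as a Bismark-style coverage file
#'
#' @param meth a [methylome].
#' @param path output path.
#' @export
write_cpg_table <- function(meth, path) {
  cpgs <- meth$cpgs
  cov <- cpgs$n_meth + cpgs$n_unmeth
  pct <- ifelse(cov > 0, 100 * cpgs$n_meth / cov, 0)
  out <- data.frame(chrom = cpgs$chrom, start = cpgs$pos + 1,
                    end = cpgs$pos + 1, meth_pct = pct,
                    n_meth = cpgs$n_meth, n_unmeth = cpgs$n_unmeth)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GTF annotation into an annotation set
#'
#' Exon rows (1-based inclusive) are grouped by `transcript_id` and
#' `gene_id`; coordinates are converted to the internal 0-based half-open
#' convention.  A transcript whose exons sit on mixed strands is an error.
#'
#' @param path GTF file path.
#' @return an [annotation_set].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0)
    return(annotation_set(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), strand = character(),
                                     transcript_id = character(),
                                     gene_id = character())))
  exons <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      transcript_id = as.character(gr$transcript_id),
                      gene_id = as.character(gr$gene_id),
                      stringsAsFactors = FALSE)
  annotation_set(exons)
}

#' Write an annotation set as GTF
#'
#' Exon coordinates round-trip exactly through [read_gtf()].
#'
#' @param ann an [annotation_set].
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  ex <- ex[order(ex$chrom, ex$gene_id, ex$transcript_id, ex$start), ,
           drop = FALSE]
  if (nrow(ex) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   ex$gene_id, ex$transcript_id)
  lines <- paste(ex$chrom, "methdomain", "exon", ex$start + 1, ex$end,
                 ".", ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval track
#'
#' BED is 0-based half-open, so coordinates pass through unchanged.  Input
#' that is not sorted by (chrom, start) is sorted with a warning.
#'
#' @param path BED3/BED6 file path.
#' @param kind track kind, e.g. `"CGI"`, `"TE"`, `"igDMR"`, `"mask"`,
#'   `"contig"`.
#' @return a feature-track data frame (`chrom`, `start`, `end`, optional
#'   `name`/`strand`) with attribute `kind`.
#' @export
read_feature_bed <- function(path, kind = "feature") {
  gr <- rtracklayer::import(path, format = "bed")
  df <- granges_to_df(gr)
  if ("name" %in% names(df)) df$name <- as.character(df$name)
  df$score <- NULL
  key_sorted <- !nrow(df) ||
    identical(order(df$chrom, df$start), seq_len(nrow(df)))
  if (!key_sorted) {
    warning("unsorted BED input '", path, "'; sorting")
    df <- sort_intervals(df)
  }
  attr(df, "kind") <- kind
  df
}

#' Write a feature track as BED
#'
#' @param track feature-track data frame.
#' @param path output path.
#' @export
write_feature_bed <- function(track, path) {
  track <- sort_intervals(track)
  if (nrow(track) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(track)) track$name else "."
  if (!is.null(track$strand)) {
    lines <- paste(track$chrom, track$start, track$end, name, 0,
                   ifelse(track$strand == "*", ".", track$strand),
                   sep = "\t")
  } else {
    lines <- paste(track$chrom, track$start, track$end, name, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a domain set as BED plus a statistics sidecar
#'
#' The BED carries (chrom, start, end, id); the `.tsv` sidecar carries the
#' per-domain metadata and any statistics columns supplied.
#'
#' @param domains domain-set data frame (see [call_domains()]).
#' @param path output BED path; the sidecar is written to `path` with
#'   `.tsv` appended.
#' @param stats optional per-domain statistics (`id` column required) to
#'   merge into the sidecar.
#' @export
write_domains <- function(domains, path, stats = NULL) {
  domains <- sort_intervals(domains)
  lines <- paste(domains$chrom, domains$start, domains$end, domains$id,
                 sep = "\t")
  writeLines(lines, path)
  side <- domains[c("id", "parent_id", "class", "chrom", "start", "end")]
  side$length <- domains$end - domains$start
  for (fl in c("merged_over_gap", "absorbed_opposite", "split_by_mask"))
    if (fl %in% names(domains)) side[[fl]] <- domains[[fl]]
  if (!is.null(stats)) {
    extra <- stats[c("id", setdiff(names(stats), names(side)))]
    side <- merge(side, extra, by = "id", sort = FALSE)
  }
  side <- side[order(side$chrom, side$start), , drop = FALSE]
  write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a domain set written by [write_domains()]
#'
#' @param path BED path (the `.tsv` sidecar must sit next to it).
#' @return domain-set data frame.
#' @export
read_domains <- function(path) {
  side <- read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  out <- side[c("chrom", "start", "end", "class", "id", "parent_id")]
  for (fl in c("merged_over_gap", "absorbed_opposite", "split_by_mask"))
    if (fl %in% names(side)) out[[fl]] <- side[[fl]]
  sort_intervals(out)
}

# RepeatMasker repClass/repFamily -> the TE family vocabulary used here.
# Unknown families pass through as "other".
te_family_map <- function(class_family) {
  fam <- rep("other", length(class_family))
  fam[grepl("MaLR", class_family)] <- "MaLR"
  fam[grepl("^LINE/L1", class_family)] <- "L1"
  fam[grepl("^LINE/L2", class_family)] <- "L2"
  fam[grepl("^SINE/B2", class_family)] <- "S2"
  fam[grepl("^SINE/B4", class_family)] <- "S4"
  fam[grepl("^LTR/ERV1", class_family)] <- "ERV1"
  fam[grepl("^LTR/ERVK", class_family)] <- "ERVK"
  fam[grepl("^LTR/ERVL$", class_family) |
        grepl("^LTR/ERVL\\b", class_family) &
        !grepl("MaLR", class_family)] <- "ERVL"
  fam
}

#' Read RepeatMasker output into a TE track
#'
#' Supports the native `.out` layout (three header lines, whitespace
#' separated) and a pre-digested TSV with columns chrom, start, end,
#' strand, name, class_family.  Families are mapped to the vocabulary
#' L1, L2, S2, S4, ERV1, ERVK, ERVL, MaLR; anything else becomes `other`.
#'
#' @param path file path.
#' @param format `"out"` or `"tsv"`.
#' @return TE feature track with columns chrom, start, end, strand, name,
#'   family.
#' @export
read_repeatmasker <- function(path, format = c("out", "tsv")) {
  format <- match.arg(format)
  if (format == "out") {
    lines <- readLines(path)
    lines <- lines[-seq_len(min(3, length(lines)))]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      out <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        name = character(), family = character())
      attr(out, "kind") <- "TE"
      return(out)
    }
    fields <- strsplit(trimws(lines), "\\s+")
    chrom <- vapply(fields, `[`, "", 5)
    start <- as.numeric(vapply(fields, `[`, "", 6)) - 1
    end <- as.numeric(vapply(fields, `[`, "", 7))
    strand <- ifelse(vapply(fields, `[`, "", 9) == "C", "-", "+")
    name <- vapply(fields, `[`, "", 10)
    class_family <- vapply(fields, `[`, "", 11)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    chrom <- tab$chrom; start <- tab$start; end <- tab$end
    strand <- tab$strand; name <- tab$name
    class_family <- tab$class_family
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand, name = name,
                    family = te_family_map(class_family),
                    stringsAsFactors = FALSE)
  out <- sort_intervals(out)
  attr(out, "kind") <- "TE"
  out
}
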