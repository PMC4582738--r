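# Seeded generators for methylomes, annotations, feature tracks and read
# coverage with planted truth.  The methylome model is deliberately
# simple: domain-structured target methylation (high ~90 %, low ~10 %),
# beta-distributed per-CpG methylation probability around the domain
# target (emulating the strongly bimodal per-CpG methylation of oocyte
# methylomes), Poisson read depth, binomial methylated counts.

#' Methylome simulation spec
#'
#' @param chrom_lengths named vector of chromosome lengths (default two
#'   10-Mbp chromosomes).
#' @param cpg_rate CpG placement rate per bp (default 1/100); geometric
#'   inter-CpG gaps.
#' @param cpg_positions optional explicit positions (list per chrom) that
#'   override `cpg_rate`.
#' @param domain_plan data frame (chrom, start, end, target_meth in
#'   percent) of planted domains; CpGs outside the plan fall back to
#'   `background_meth`.
#' @param coverage_mean Poisson mean read depth (default 15).
#' @param coverage_fixed fixed depth overriding the Poisson model.
#' @param dense_regions optional intervals (e.g. a CGI track) that get
#'   extra CpGs at `dense_rate`, emulating CpG-island density.
#' @param dense_rate CpG rate inside `dense_regions` (default 1/10).
#' @param beta_concentration concentration of the per-CpG Beta noise
#'   (default 50).
#' @param background_meth percent methylation outside planted domains
#'   (default 10).
#' @param seed RNG seed.
#' @return a `methylome_spec` list.
#' @export
methylome_spec <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                           cpg_rate = 1 / 100, cpg_positions = NULL,
                           domain_plan = NULL, coverage_mean = 15,
                           coverage_fixed = NULL,
                           dense_regions = NULL, dense_rate = 1 / 10,
                           beta_concentration = 50,
                           background_meth = 10, seed = 1) {
  if (is.null(cpg_positions) && cpg_rate <= 0)
    stop("cpg_rate must be positive")
  if (!is.null(domain_plan))
    stopifnot(all(domain_plan$target_meth >= 0),
              all(domain_plan$target_meth <= 100))
  structure(list(chrom_lengths = chrom_lengths, cpg_rate = cpg_rate,
                 cpg_positions = cpg_positions, domain_plan = domain_plan,
                 coverage_mean = coverage_mean,
                 coverage_fixed = coverage_fixed,
                 dense_regions = dense_regions, dense_rate = dense_rate,
                 beta_concentration = beta_concentration,
                 background_meth = background_meth, seed = seed),
            class = "methylome_spec")
}

#' Random alternating domain plan
#'
#' Tiles each chromosome with alternating hyper/hypo segments whose
#' lengths are log-normal (median `median_len`), truncated below at
#' `min_len`.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param median_len median segment length in bp (default 30 kbp).
#' @param sdlog log-scale spread (default 0.6).
#' @param min_len minimum segment length (default 10 kbp).
#' @param hyper_meth,hypo_meth segment targets in percent (defaults
#'   90/10).
#' @param seed RNG seed.
#' @return domain-plan data frame (chrom, start, end, target_meth,
#'   class).
#' @export
random_domain_plan <- function(chrom_lengths, median_len = 30000,
                               sdlog = 0.6, min_len = 10000,
                               hyper_meth = 90, hypo_meth = 10,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (ch in names(chrom_lengths)) {
    pos <- 0
    cls <- sample(c("hyper", "hypo"), 1)
    while (pos < chrom_lengths[[ch]]) {
      len <- max(min_len, round(rlnorm(1, log(median_len), sdlog)))
      end <- min(pos + len, chrom_lengths[[ch]])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = pos, end = end,
        target_meth = if (cls == "hyper") hyper_meth else hypo_meth,
        class = cls, stringsAsFactors = FALSE)
      pos <- end
      cls <- if (cls == "hyper") "hypo" else "hyper"
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a methylome with planted domains
#'
#' @param spec a [methylome_spec].
#' @param label sample label for the resulting methylome.
#' @return list: `methylome` (a [methylome]) and `truth` (the domain
#'   plan used).
#' @export
simulate_methylome <- function(spec, label = "sim") {
  set.seed(spec$seed)
  pieces <- list()
  for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]
    if (!is.null(spec$cpg_positions)) {
      pos <- spec$cpg_positions[[ch]]
      if (is.null(pos)) next
    } else {
      n_exp <- ceiling(len * spec$cpg_rate * 1.2) + 10
      gaps <- rgeom(n_exp, spec$cpg_rate) + 1
      pos <- cumsum(gaps)
      while (pos[length(pos)] < len) {
        gaps <- rgeom(n_exp, spec$cpg_rate) + 1
        pos <- c(pos, pos[length(pos)] + cumsum(gaps))
      }
      pos <- pos[pos < len]
    }
    if (!is.null(spec$dense_regions)) {
      dr <- spec$dense_regions[spec$dense_regions$chrom == ch, ,
                               drop = FALSE]
      extra <- unlist(lapply(seq_len(nrow(dr)), function(i) {
        w <- dr$end[i] - dr$start[i]
        gaps <- rgeom(ceiling(w * spec$dense_rate * 1.5) + 5,
                      spec$dense_rate) + 1
        p <- dr$start[i] + cumsum(gaps)
        p[p < dr$end[i]]
      }))
      pos <- sort(unique(c(pos, extra)))
      pos <- pos[pos < len]
    }
    n <- length(pos)
    if (n == 0) next
    target <- rep(spec$background_meth / 100, n)
    plan <- spec$domain_plan
    if (!is.null(plan)) {
      pl <- plan[plan$chrom == ch, , drop = FALSE]
      if (nrow(pl)) {
        idx <- findInterval(pos, pl$start)
        ok <- idx >= 1 & idx <= nrow(pl)
        inside <- ok & pos < pl$end[pmax(idx, 1)]
        target[inside] <- pl$target_meth[idx[inside]] / 100
      }
    }
    t_cl <- pmin(pmax(target, 1e-4), 1 - 1e-4)
    p <- rbeta(n, spec$beta_concentration * t_cl,
               spec$beta_concentration * (1 - t_cl))
    cov <- if (!is.null(spec$coverage_fixed))
      rep(spec$coverage_fixed, n) else rpois(n, spec$coverage_mean)
    n_meth <- rbinom(n, cov, p)
    pieces[[ch]] <- data.frame(chrom = ch, pos = pos, n_meth = n_meth,
                               n_unmeth = cov - n_meth,
                               stringsAsFactors = FALSE)
  }
  cpgs <- do.call(rbind, pieces)
  if (is.null(cpgs))
    cpgs <- data.frame(chrom = character(), pos = numeric(),
                       n_meth = numeric(), n_unmeth = numeric())
  list(methylome = methylome(cpgs, label), truth = spec$domain_plan)
}

#' Domain plan coupled to a transcription plan
#'
#' Reduced transcribed blocks (gene spans) become hyper targets with
#' probability `coupling`; everything else is hypo.  The returned plan's
#' `class` column records the planted status.
#'
#' @param ann an [annotation_set] whose gene spans drive methylation.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param coupling probability a transcribed block is methylated
#'   (default 0.9).
#' @param hyper_meth,hypo_meth targets in percent (defaults 90/10).
#' @param seed RNG seed.
#' @return domain-plan data frame; attribute `coupled` marks which rows
#'   are transcribed blocks.
#' @export
coupled_domain_plan <- function(ann, chrom_lengths, coupling = 0.9,
                                hyper_meth = 90, hypo_meth = 10,
                                seed = 1) {
  set.seed(seed)
  g <- ann$genes
  blocks <- reduce_intervals(data.frame(chrom = g$chrom, start = g$start,
                                        end = g$end))
  hyper <- runif(nrow(blocks)) < coupling
  blocks$target_meth <- ifelse(hyper, hyper_meth, hypo_meth)
  blocks$class <- ifelse(hyper, "hyper", "hypo")
  blocks$transcribed <- TRUE
  attr(blocks, "coupled") <- hyper
  blocks
}

#' Annotation simulation spec
#'
#' @param n_genes number of reference genes.
#' @param exon_mean mean additional exons per gene (Poisson; every gene
#'   has at least one exon).
#' @param fpkm_meanlog,fpkm_sdlog log-normal expression parameters.
#' @param n_novel_multi,n_novel_mono planted novel genes.
#' @param n_upstream planted novel upstream TSSs.
#' @param upstream_dist_range distance range (bp) of planted upstream
#'   TSSs from the reference TSS.
#' @param te_density elements per bp per family (named vector).
#' @param cgi_promoter_prob probability a reference promoter carries a
#'   CGI.
#' @param n_intergenic_cgi CGIs planted in intergenic space (default
#'   40).
#' @param novel_margin_factor placement margin of planted novel genes as
#'   a multiple of the exclusion-rule distances (default 2).
#' @param seed RNG seed.
#' @return an `annotation_spec` list.
#' @export
annotation_spec <- function(n_genes = 120, exon_mean = 3,
                            fpkm_meanlog = 0, fpkm_sdlog = 1.2,
                            n_novel_multi = 15, n_novel_mono = 15,
                            n_upstream = 15,
                            upstream_dist_range = c(4000, 8000),
                            te_density = c(MaLR = 1 / 2e5,
                                           ERVK = 1 / 4e5,
                                           L1 = 1 / 3e5),
                            cgi_promoter_prob = 0.6,
                            n_intergenic_cgi = 40,
                            novel_margin_factor = 2, seed = 1) {
  structure(as.list(environment()), class = "annotation_spec")
}

# place n non-overlapping spans of the given lengths, keeping min_gap bp
# clear of `occupied`; returns data frame or errors after bounded retries
place_spans <- function(chrom_lengths, lengths, occupied, min_gap,
                        max_tries = 5000) {
  out <- list()
  occ <- occupied
  chroms <- names(chrom_lengths)
  pr <- chrom_lengths / sum(chrom_lengths)
  for (len in lengths) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = pr)
      if (chrom_lengths[[ch]] <= len + 2) next
      st <- floor(runif(1, 0, chrom_lengths[[ch]] - len))
      cand <- data.frame(chrom = ch, start = st, end = st + len)
      grown <- data.frame(chrom = ch, start = max(0, st - min_gap),
                          end = st + len + min_gap)
      if (is.null(occ) || nrow(occ) == 0 ||
          !any(overlaps_any(grown, occ))) {
        out[[length(out) + 1]] <- cand
        occ <- rbind(occ, cand[c("chrom", "start", "end")])
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not place span of length ", len,
                    "; density infeasible")
  }
  list(spans = do.call(rbind, out), occupied = occ)
}

# exon table for one transcript given its span and exon count
make_exons <- function(chrom, start, end, strand, n_exons, tx_id,
                       gene_id) {
  span <- end - start
  if (n_exons == 1)
    return(data.frame(chrom = chrom, start = start, end = end,
                      strand = strand, transcript_id = tx_id,
                      gene_id = gene_id, stringsAsFactors = FALSE))
  # cut the span at 2*(n-1) sorted points: odd pieces are exons
  cuts <- sort(sample(seq(start + 1, end - 1), 2 * (n_exons - 1)))
  bounds <- c(start, cuts, end)
  starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
             transcript_id = tx_id, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Simulate reference and oocyte annotations with planted features
#'
#' Places non-overlapping reference genes, copies them into an oocyte
#' assembly, and plants: novel upstream TSSs (a separate novel first
#' exon at 4-8 kbp upstream splicing into the remaining reference
#' exons), novel multi- and mono-exonic genes far from all reference
#' genes (margin = `novel_margin_factor` times the exclusion-rule
#' distances), a promoter CGI track, and a TE track that avoids planted
#' novel genes.
#'
#' @param spec an [annotation_spec].
#' @param chrom_lengths named vector of chromosome lengths.
#' @return list: `reference`, `oocyte` ([annotation_set]s), `tracks`
#'   (cgi, te), `truth` (novel_gene_ids, upstream data frame), `fpkm`
#'   (named per-gene vector for the oocyte annotation).
#' @export
simulate_annotation <- function(spec, chrom_lengths = c(chr1 = 1e7,
                                                        chr2 = 1e7)) {
  set.seed(spec$seed)
  # reference genes: lengths 5-60 kbp, gap >= 12 kbp so planted-novel
  # margins stay feasible
  glens <- pmin(pmax(round(rlnorm(spec$n_genes, log(2e4), 0.6)), 5000),
                60000)
  placed <- place_spans(chrom_lengths, glens, NULL, min_gap = 12000)
  spans <- placed$spans
  occupied <- placed$occupied
  strands <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  ref_ex <- list()
  for (i in seq_len(spec$n_genes)) {
    n_ex <- 1 + rpois(1, spec$exon_mean)
    ref_ex[[i]] <- make_exons(spans$chrom[i], spans$start[i],
                              spans$end[i], strands[i], n_ex,
                              sprintf("REF_T%04d", i),
                              sprintf("REF_G%04d", i))
  }
  ref <- annotation_set(do.call(rbind, ref_ex))
  # oocyte assembly: copy of every reference transcript
  ooc_ex <- do.call(rbind, ref_ex)
  ooc_ex$transcript_id <- sub("^REF_T", "OOC_T", ooc_ex$transcript_id)
  ooc_ex$gene_id <- sub("^REF_G", "OOC_G", ooc_ex$gene_id)
  # planted novel upstream TSSs on multi-exonic reference genes
  multi_idx <- which(vapply(ref_ex, nrow, 0L) >= 2)
  up_idx <- sample(multi_idx, min(spec$n_upstream, length(multi_idx)))
  upstream_truth <- list()
  for (k in seq_along(up_idx)) {
    i <- up_idx[k]
    e <- ref_ex[[i]]
    d <- round(runif(1, spec$upstream_dist_range[1],
                     spec$upstream_dist_range[2]))
    st <- e$strand[1]
    if (st == "+") {
      new_start <- e$start[1] - d
      if (new_start < 0) next
      first <- data.frame(chrom = e$chrom[1], start = new_start,
                          end = new_start + 400, strand = st,
                          stringsAsFactors = FALSE)
      rest <- e[-1, c("chrom", "start", "end", "strand")]
    } else {
      new_tss <- (e$end[nrow(e)] - 1) + d
      if (new_tss + 1 > chrom_lengths[[e$chrom[1]]]) next
      first <- data.frame(chrom = e$chrom[1], start = new_tss - 399,
                          end = new_tss + 1, strand = st,
                          stringsAsFactors = FALSE)
      rest <- e[-nrow(e), c("chrom", "start", "end", "strand")]
    }
    if (nrow(rest) == 0) next
    tx_id <- sprintf("OOC_TU%03d", k)
    add <- rbind(first, rest)
    add$transcript_id <- tx_id
    add$gene_id <- sub("^REF_G", "OOC_G", e$gene_id[1])
    ooc_ex <- rbind(ooc_ex, add)
    upstream_truth[[length(upstream_truth) + 1]] <-
      data.frame(ref_gene_id = e$gene_id[1],
                 oocyte_gene_id = add$gene_id[1],
                 transcript_id = tx_id, distance = d,
                 stringsAsFactors = FALSE)
  }
  # planted novel genes, margin = factor * rule distance
  margin_multi <- spec$novel_margin_factor * 1000
  margin_mono <- spec$novel_margin_factor * 5000
  novel_ids <- character(0)
  if (spec$n_novel_multi > 0) {
    lens <- round(runif(spec$n_novel_multi, 3000, 8000))
    pl <- place_spans(chrom_lengths, lens, occupied, margin_multi + 2000)
    occupied <- pl$occupied
    for (i in seq_len(nrow(pl$spans))) {
      gid <- sprintf("NOV_MULTI%03d", i)
      ooc_ex <- rbind(ooc_ex, make_exons(
        pl$spans$chrom[i], pl$spans$start[i], pl$spans$end[i],
        sample(c("+", "-"), 1), 1 + sample(1:3, 1),
        paste0(gid, "_T1"), gid))
      novel_ids <- c(novel_ids, gid)
    }
  }
  if (spec$n_novel_mono > 0) {
    lens <- round(runif(spec$n_novel_mono, 500, 2000))
    pl <- place_spans(chrom_lengths, lens, occupied, margin_mono + 2000)
    occupied <- pl$occupied
    for (i in seq_len(nrow(pl$spans))) {
      gid <- sprintf("NOV_MONO%03d", i)
      ooc_ex <- rbind(ooc_ex, make_exons(
        pl$spans$chrom[i], pl$spans$start[i], pl$spans$end[i],
        sample(c("+", "-"), 1), 1, paste0(gid, "_T1"), gid))
      novel_ids <- c(novel_ids, gid)
    }
  }
  ooc <- annotation_set(ooc_ex)
  # promoter CGIs on reference genes (small, so planted upstream TSSs at
  # >= 4 kbp stay outside them)
  rg <- ref$genes
  has_cgi <- runif(nrow(rg)) < spec$cgi_promoter_prob
  cgi <- data.frame(chrom = rg$chrom[has_cgi],
                    start = pmax(0, rg$tss[has_cgi] - 250),
                    end = rg$tss[has_cgi] + 250)
  attr(cgi, "kind") <- "CGI"
  # TE track avoiding planted novel genes (keeps the repeat rule clean)
  te_rows <- list()
  novel_spans <- ooc$genes[ooc$genes$gene_id %in% novel_ids, , drop = FALSE]
  for (fam in names(spec$te_density)) {
    n_fam <- rpois(1, spec$te_density[[fam]] * sum(chrom_lengths))
    for (j in seq_len(n_fam)) {
      for (try in 1:200) {
        ch <- sample(names(chrom_lengths), 1)
        len <- round(runif(1, 300, 5000))
        st <- floor(runif(1, 0, chrom_lengths[[ch]] - len))
        cand <- data.frame(chrom = ch, start = st, end = st + len)
        if (nrow(novel_spans) == 0 ||
            !any(overlaps_any(cand, novel_spans))) {
          cand$strand <- sample(c("+", "-"), 1)
          cand$name <- sprintf("%s_%03d", fam, j)
          cand$family <- fam
          te_rows[[length(te_rows) + 1]] <- cand
          break
        }
      }
    }
  }
  te <- if (length(te_rows)) sort_intervals(do.call(rbind, te_rows))
  else data.frame(chrom = character(), start = numeric(),
                  end = numeric(), strand = character(),
                  name = character(), family = character())
  attr(te, "kind") <- "TE"
  fpkm <- setNames(rlnorm(nrow(ooc$genes), spec$fpkm_meanlog,
                          spec$fpkm_sdlog), ooc$genes$gene_id)
  if (spec$n_intergenic_cgi > 0) {
    pl <- place_spans(chrom_lengths,
                      rep(500, spec$n_intergenic_cgi), occupied,
                      min_gap = 1000)
    cgi <- rbind(cgi, pl$spans[c("chrom", "start", "end")])
    cgi <- sort_intervals(cgi)
    attr(cgi, "kind") <- "CGI"
  }
  up_truth <- if (length(upstream_truth)) do.call(rbind, upstream_truth)
  else data.frame(ref_gene_id = character(), oocyte_gene_id = character(),
                  transcript_id = character(), distance = numeric())
  list(reference = ref, oocyte = ooc,
       tracks = list(cgi = cgi, te = te),
       truth = list(novel_gene_ids = novel_ids, upstream = up_truth),
       fpkm = fpkm)
}

#' Simulate stranded read coverage proportional to expression
#'
#' Reads per gene follow `FPKM = reads * 1e9 / (exonic_length *
#' total_reads)`; read starts are uniform over exonic bases, each read
#' clipped to its exon.  Reads are split randomly across datasets.
#'
#' @param ann an [annotation_set].
#' @param fpkm named per-gene FPKM vector.
#' @param total_reads library size driving the FPKM-to-count conversion
#'   (default 1e6).
#' @param datasets dataset labels reads are split over.
#' @param read_len read length in bp (default 100).
#' @param seed RNG seed.
#' @return list: `reads` (chrom, start, end, strand, dataset) and
#'   `fpkm` (data frame gene_id, exonic_len, n_reads, fpkm_planted,
#'   fpkm_recovered).
#' @export
simulate_read_coverage <- function(ann, fpkm, total_reads = 1e6,
                                   datasets = c("NGO", "GO1", "GO2",
                                                "FGO"),
                                   read_len = 100, seed = 1) {
  set.seed(seed)
  reads <- list()
  tab <- list()
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    gex <- ann$exons[ann$exons$gene_id == g$gene_id, , drop = FALSE]
    gex <- reduce_intervals(gex)
    exonic_len <- sum(gex$end - gex$start)
    f <- if (g$gene_id %in% names(fpkm)) fpkm[[g$gene_id]] else 0
    n_reads <- rpois(1, f * exonic_len * total_reads / 1e9)
    if (n_reads > 0) {
      cum <- cumsum(gex$end - gex$start)
      u <- floor(runif(n_reads) * exonic_len)
      idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      st <- gex$start[idx] + (u - c(0, cum)[idx])
      en <- pmin(st + read_len, gex$end[idx])
      reads[[length(reads) + 1]] <- data.frame(
        chrom = gex$chrom[idx], start = st, end = en, strand = g$strand,
        dataset = sample(datasets, n_reads, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    tab[[i]] <- data.frame(
      gene_id = g$gene_id, exonic_len = exonic_len, n_reads = n_reads,
      fpkm_planted = f,
      fpkm_recovered = n_reads * 1e9 / (exonic_len * total_reads),
      stringsAsFactors = FALSE)
  }
  rd <- if (length(reads)) do.call(rbind, reads)
  else data.frame(chrom = character(), start = numeric(),
                  end = numeric(), strand = character(),
                  dataset = character())
  list(reads = rd, fpkm = do.call(rbind, tab))
}
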