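# Segmentation of a CpG methylome into hypermethylated (HyperD) and
# hypomethylated (HypoD) domains:
#   1. sliding probes of `window_n_cpgs` consecutive covered CpGs with a
#      step of `step_n_cpgs`, scored from CpGs with >= `min_reads_per_cpg`
#      reads (>= `min_scored_cpgs` such CpGs to score a probe);
#   2. probes above `hyper_cut` / below `hypo_cut` merged into raw domains,
#      overlaps between opposite classes split at the midpoint;
#   3. refinement: merge same-class neighbours closer than `merge_gap`,
#      absorb opposite-class domains shorter than `opposite_absorb_max`
#      lying between same-class flanks, drop domains shorter than
#      `min_domain_len`, merge again;
#   4. optional exclusion masking (CGIs, promoters, pre-methylated
#      regions) with parent-domain lineage.

#' Segmentation parameters
#'
#' @param window_n_cpgs probe size in consecutive covered CpGs.
#' @param step_n_cpgs probe step in CpGs.
#' @param min_reads_per_cpg coverage needed for a CpG to count toward a
#'   probe's methylation level.
#' @param min_scored_cpgs minimum qualifying CpGs to score a probe.
#' @param hyper_cut,hypo_cut methylation-percent cutoffs for hyper/hypo
#'   probe seeds; seeds use strict inequalities (> and <).
#' @param merge_gap same-class domains closer than this (bp) are merged.
#' @param opposite_absorb_max opposite-class domains shorter than this (bp)
#'   between two same-class domains are absorbed.
#' @param min_domain_len domains shorter than this (bp) are removed during
#'   refinement (mask-split fragments may be shorter).
#' @param preset `"paper_50_10"` (default sizes) or `"paper_10_5"`
#'   (10-CpG probes, 5-CpG step); a preset overrides the two window
#'   arguments.
#' @return a `seg_params` list.
#' @export
seg_params <- function(window_n_cpgs = 50, step_n_cpgs = 10,
                       min_reads_per_cpg = 5, min_scored_cpgs = 3,
                       hyper_cut = 75, hypo_cut = 25,
                       merge_gap = 2000, opposite_absorb_max = 1000,
                       min_domain_len = 2000, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper_50_10", "paper_10_5"))
    if (preset == "paper_50_10") {
      window_n_cpgs <- 50; step_n_cpgs <- 10
    } else {
      window_n_cpgs <- 10; step_n_cpgs <- 5
    }
  }
  p <- list(window_n_cpgs = window_n_cpgs, step_n_cpgs = step_n_cpgs,
            min_reads_per_cpg = min_reads_per_cpg,
            min_scored_cpgs = min_scored_cpgs,
            hyper_cut = hyper_cut, hypo_cut = hypo_cut,
            merge_gap = merge_gap,
            opposite_absorb_max = opposite_absorb_max,
            min_domain_len = min_domain_len)
  stopifnot(p$step_n_cpgs <= p$window_n_cpgs,
            p$hypo_cut < p$hyper_cut,
            p$merge_gap > 0, p$opposite_absorb_max > 0,
            p$min_domain_len > 0)
  structure(p, class = "seg_params")
}

#' Build methylation probes over CpGs with data
#'
#' Probes cover runs of `window_n_cpgs` consecutive CpGs that have at
#' least one read, advancing by `step_n_cpgs`; a trailing stretch shorter
#' than one probe produces no probe.  A probe's genomic extent runs from
#' its first member CpG to one past its last.  Its methylation level is
#' the mean per-CpG methylation over member CpGs with
#' `min_reads_per_cpg` coverage, defined only when at least
#' `min_scored_cpgs` such CpGs exist (otherwise `NA`).
#'
#' @param meth a [methylome].
#' @param params a [seg_params].
#' @return data frame: chrom, start, end, member_cpg_count,
#'   scored_cpg_count, meth_pct.
#' @export
make_windows <- function(meth, params = seg_params()) {
  cpgs <- meth$cpgs
  cov <- cpgs$n_meth + cpgs$n_unmeth
  cpgs <- cpgs[cov > 0, , drop = FALSE]
  w <- params$window_n_cpgs
  s <- params$step_n_cpgs
  pieces <- lapply(split(cpgs, cpgs$chrom), function(cc) {
    n <- nrow(cc)
    if (n < w) return(NULL)
    covc <- cc$n_meth + cc$n_unmeth
    pct <- 100 * cc$n_meth / covc
    scored <- covc >= params$min_reads_per_cpg
    csum_pct <- cumsum(c(0, ifelse(scored, pct, 0)))
    csum_n <- cumsum(c(0, as.numeric(scored)))
    starts <- seq(1, n - w + 1, by = s)
    ends <- starts + w - 1
    n_sc <- csum_n[ends + 1] - csum_n[starts]
    mpct <- ifelse(n_sc >= params$min_scored_cpgs,
                   (csum_pct[ends + 1] - csum_pct[starts]) / n_sc,
                   NA_real_)
    data.frame(chrom = cc$chrom[1],
               start = cc$pos[starts], end = cc$pos[ends] + 1,
               member_cpg_count = w, scored_cpg_count = as.integer(n_sc),
               meth_pct = mpct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), member_cpg_count = integer(),
                      scored_cpg_count = integer(), meth_pct = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Merge probe seeds into raw domains
#'
#' Probes above `hyper_cut` are hyper seeds, below `hypo_cut` hypo seeds;
#' unscored and intermediate probes are ignored.  Overlapping or bookended
#' same-class seeds are unioned; where a hyper run overlaps a hypo run the
#' shared span is cut at its (floored) midpoint, left part to the left
#' domain.
#'
#' @param windows output of [make_windows()].
#' @param params a [seg_params].
#' @return raw domain-set data frame: chrom, start, end, class (sorted,
#'   non-overlapping).
#' @export
raw_domains <- function(windows, params = seg_params()) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  scored <- windows[!is.na(windows$meth_pct), , drop = FALSE]
  hyper <- scored[scored$meth_pct > params$hyper_cut, , drop = FALSE]
  hypo <- scored[scored$meth_pct < params$hypo_cut, , drop = FALSE]
  runs <- rbind(
    if (nrow(hyper)) cbind(reduce_intervals(hyper), class = "hyper"),
    if (nrow(hypo)) cbind(reduce_intervals(hypo), class = "hypo"))
  if (is.null(runs) || nrow(runs) == 0) return(empty)
  runs <- sort_intervals(runs)
  # resolve overlaps between opposite-class runs at the floored midpoint
  out <- runs[0, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, , drop = FALSE]
    if (nrow(out) > 0) {
      j <- nrow(out)
      if (out$chrom[j] == r$chrom && r$start < out$end[j]) {
        ov_end <- min(out$end[j], r$end)
        mid <- floor((r$start + ov_end) / 2)
        out$end[j] <- mid
        r$start <- mid
        if (out$end[j] <= out$start[j]) out <- out[-j, , drop = FALSE]
        if (r$end <= r$start) next
      }
    }
    out <- rbind(out, r)
  }
  rownames(out) <- NULL
  out
}

# Merge same-class neighbours with gap < merge_gap.  Domains are sorted
# and non-overlapping, so chain merging is transitive and a single grouped
# pass suffices.
merge_same_class <- function(d, merge_gap) {
  if (nrow(d) < 2) return(d)
  joins <- d$chrom[-1] == d$chrom[-nrow(d)] &
    d$class[-1] == d$class[-nrow(d)] &
    (d$start[-1] - d$end[-nrow(d)]) < merge_gap
  grp <- cumsum(c(TRUE, !joins))
  gap_nonzero <- c(FALSE, joins & (d$start[-1] - d$end[-nrow(d)]) > 0)
  first <- !duplicated(grp)
  out <- d[first, , drop = FALSE]
  out$end <- as.numeric(tapply(d$end, grp, max))
  if ("merged_over_gap" %in% names(d)) {
    out$merged_over_gap <- as.logical(
      tapply(d$merged_over_gap | gap_nonzero, grp, any))
    out$absorbed_opposite <- as.logical(
      tapply(d$absorbed_opposite, grp, any))
  }
  rownames(out) <- NULL
  out
}

#' Refine raw domains
#'
#' Applies, in order: (1) merge same-class neighbours with a gap below
#' `merge_gap`; (2) absorb an opposite-class domain shorter than
#' `opposite_absorb_max` lying between two same-class domains (the small
#' domain is deleted and its span incorporated); (3) remove domains
#' shorter than `min_domain_len`; (4) merge same-class neighbours again.
#' The operation is idempotent.
#'
#' @param raw sorted, non-overlapping domain-set data frame.
#' @param params a [seg_params].
#' @return refined domain set with `id`, `parent_id` and provenance flags.
#' @export
refine_domains <- function(raw, params = seg_params()) {
  d <- sort_intervals(raw)
  if (!"merged_over_gap" %in% names(d))
    d$merged_over_gap <- rep(FALSE, nrow(d))
  if (!"absorbed_opposite" %in% names(d))
    d$absorbed_opposite <- rep(FALSE, nrow(d))
  # pass 1: merge over small gaps
  d <- merge_same_class(d, params$merge_gap)
  # pass 2: absorb small opposite-class domains between same-class flanks
  repeat {
    if (nrow(d) < 3) break
    changed <- FALSE
    i <- 2
    while (i < nrow(d)) {
      same_chrom <- d$chrom[i - 1] == d$chrom[i] &&
        d$chrom[i] == d$chrom[i + 1]
      if (same_chrom && d$class[i - 1] == d$class[i + 1] &&
          d$class[i] != d$class[i - 1] &&
          (d$end[i] - d$start[i]) < params$opposite_absorb_max) {
        d$end[i - 1] <- d$end[i + 1]
        d$absorbed_opposite[i - 1] <- TRUE
        d$merged_over_gap[i - 1] <- d$merged_over_gap[i - 1] ||
          d$merged_over_gap[i + 1]
        d <- d[-c(i, i + 1), , drop = FALSE]
        rownames(d) <- NULL
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  # pass 3: drop small domains
  d <- d[(d$end - d$start) >= params$min_domain_len, , drop = FALSE]
  # pass 4: merge again
  d <- merge_same_class(d, params$merge_gap)
  rownames(d) <- NULL
  if (nrow(d)) {
    d$id <- sprintf("%s_%05d",
                    ifelse(d$class == "hyper", "HyperD", "HypoD"),
                    stats::ave(seq_len(nrow(d)), d$class,
                               FUN = seq_along))
    d$parent_id <- d$id
    d$split_by_mask <- FALSE
  } else {
    d$id <- character(0); d$parent_id <- character(0)
    d$split_by_mask <- logical(0)
  }
  d[c("chrom", "start", "end", "class", "id", "parent_id",
      "merged_over_gap", "absorbed_opposite", "split_by_mask")]
}

#' Call domains from a methylome
#'
#' Convenience wrapper: [make_windows()] then [raw_domains()] then
#' [refine_domains()].
#'
#' @inheritParams make_windows
#' @return refined domain set.
#' @export
call_domains <- function(meth, params = seg_params()) {
  refine_domains(raw_domains(make_windows(meth, params), params), params)
}

#' Mask of regions pre-methylated in control methylomes
#'
#' Tiles the genome in 1-kbp windows and scores each window per control as
#' the mean CpG methylation over CpGs with at least `min_reads` reads,
#' requiring at least `min_cpgs` such CpGs.  A window enters the mask when
#' it reaches `cutoff` percent in any control; adjacent masked windows are
#' merged.
#'
#' @param controls list of control [methylome]s (e.g. NGO and
#'   DNMT3A/3L-deficient oocytes).
#' @param chrom_lengths named vector of chromosome lengths; if `NULL`,
#'   inferred from the last CpG per chromosome.
#' @param window_bp tile width (default 1000).
#' @param min_reads,min_cpgs scoring requirements per window.
#' @param cutoff mask threshold in percent (default 50, inclusive).
#' @return mask feature track.
#' @export
premethylated_mask <- function(controls, chrom_lengths = NULL,
                               window_bp = 1000, min_reads = 3,
                               min_cpgs = 3, cutoff = 50) {
  stopifnot(length(controls) >= 1)
  if (is.null(chrom_lengths)) {
    last <- lapply(controls, function(m)
      tapply(m$cpgs$pos, m$cpgs$chrom, max))
    chroms <- unique(unlist(lapply(last, names)))
    chrom_lengths <- vapply(chroms, function(ch)
      max(vapply(last, function(l)
        if (ch %in% names(l)) l[[ch]] + 1 else 0, 0)), 0)
  }
  masked <- list()
  for (ctrl in controls) {
    cpgs <- ctrl$cpgs
    cov <- cpgs$n_meth + cpgs$n_unmeth
    ok <- cov >= min_reads
    cpgs <- cpgs[ok, , drop = FALSE]
    if (nrow(cpgs) == 0) next
    pct <- 100 * cpgs$n_meth / (cpgs$n_meth + cpgs$n_unmeth)
    bin <- floor(cpgs$pos / window_bp)
    key <- paste(cpgs$chrom, bin, sep = ":")
    n <- tapply(pct, key, length)
    m <- tapply(pct, key, mean)
    hit <- names(m)[n >= min_cpgs & m >= cutoff]
    if (length(hit) == 0) next
    parts <- strsplit(hit, ":", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1)
    b <- as.numeric(vapply(parts, `[`, "", 2))
    masked[[length(masked) + 1]] <-
      data.frame(chrom = chrom, start = b * window_bp,
                 end = pmin((b + 1) * window_bp,
                            unname(chrom_lengths[chrom])),
                 stringsAsFactors = FALSE)
  }
  if (length(masked) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  } else {
    out <- reduce_intervals(do.call(rbind, masked))
  }
  attr(out, "kind") <- "mask"
  out
}

#' Subtract exclusion masks from a domain set
#'
#' CGIs, promoter (TSS) regions and pre-methylated control regions are
#' excluded from the domains.  Each surviving fragment keeps its class and
#' inherits the `parent_id` of the unsplit domain; fragments shorter than
#' `min_domain_len` are retained but flagged `split_by_mask`.  Domains
#' fully covered by the mask are recorded in the `dropped` attribute.
#'
#' @param domains refined domain set (with `id` column).
#' @param masks list of mask feature tracks (combined by union).
#' @return masked domain set; attribute `dropped` holds parents that were
#'   removed entirely.
#' @export
apply_masks <- function(domains, masks) {
  mask <- do.call(rbind, lapply(masks, function(m)
    m[c("chrom", "start", "end")]))
  if (is.null(mask) || nrow(mask) == 0) {
    attr(domains, "dropped") <- domains[0, , drop = FALSE]
    return(domains)
  }
  mask <- reduce_intervals(mask)
  frags <- subtract_intervals(domains, mask)
  if (nrow(frags)) {
    frags$parent_id <- frags$id
    n_frag <- table(frags$id)
    trimmed <- frags$start != domains$start[match(frags$id, domains$id)] |
      frags$end != domains$end[match(frags$id, domains$id)]
    frags$split_by_mask <- as.integer(n_frag[frags$id]) > 1 | trimmed
    idx <- stats::ave(seq_len(nrow(frags)), frags$id, FUN = seq_along)
    frags$id <- ifelse(frags$split_by_mask,
                       sprintf("%s.%d", frags$parent_id, idx), frags$id)
  }
  dropped <- domains[!domains$id %in% frags$parent_id, , drop = FALSE]
  frags <- sort_intervals(frags)
  attr(frags, "dropped") <- dropped
  frags
}

#' Per-domain statistics
#'
#' @param domains domain set.
#' @param meth the target [methylome].
#' @param genome_seq optional named list/vector of chromosome sequences
#'   (plain strings) for CpG density and GC content; when absent, density
#'   falls back to the methylome's CpG positions and GC is `NA`.
#' @param min_reads coverage for a CpG to enter the methylation summary
#'   (default 5).
#' @return data frame with one row per domain: id, class, length, n_cpgs,
#'   mean_meth, frac_meth (CpGs >= 75 %), frac_unmeth (CpGs <= 25 %),
#'   cpg_density (CpGs per 100 bp), gc_content.
#' @export
domain_stats <- function(domains, meth, genome_seq = NULL, min_reads = 5) {
  cpgs <- meth$cpgs
  cov <- cpgs$n_meth + cpgs$n_unmeth
  scored <- cpgs[cov >= min_reads, , drop = FALSE]
  pct <- 100 * scored$n_meth / (scored$n_meth + scored$n_unmeth)
  gd <- as_granges(domains[c("chrom", "start", "end")])
  gc <- as_granges(data.frame(chrom = scored$chrom, start = scored$pos,
                              end = scored$pos + 1))
  hits <- GenomicRanges::findOverlaps(gc, gd)
  di <- S4Vectors::subjectHits(hits)
  pi <- pct[S4Vectors::queryHits(hits)]
  n <- numeric(nrow(domains)); mm <- rep(NA_real_, nrow(domains))
  fhi <- rep(NA_real_, nrow(domains)); flo <- rep(NA_real_, nrow(domains))
  if (length(di)) {
    tab <- tapply(pi, di, function(x)
      c(length(x), mean(x), mean(x >= 75), mean(x <= 25)))
    idx <- as.integer(names(tab))
    m <- do.call(rbind, tab)
    n[idx] <- m[, 1]; mm[idx] <- m[, 2]; fhi[idx] <- m[, 3]
    flo[idx] <- m[, 4]
  }
  len <- domains$end - domains$start
  dens <- gc_pct <- rep(NA_real_, nrow(domains))
  if (!is.null(genome_seq)) {
    for (i in seq_len(nrow(domains))) {
      seqstr <- genome_seq[[domains$chrom[i]]]
      if (is.null(seqstr)) next
      sub <- substr(seqstr, domains$start[i] + 1, domains$end[i])
      n_cg <- lengths(gregexpr("CG", sub, fixed = TRUE))
      if (attr(regexpr("CG", sub, fixed = TRUE), "match.length") == -1)
        n_cg <- 0
      n_gc_base <- nchar(gsub("[^GCgc]", "", sub))
      dens[i] <- 100 * n_cg / nchar(sub)
      gc_pct[i] <- 100 * n_gc_base / nchar(sub)
    }
  } else {
    all_gc <- as_granges(data.frame(chrom = cpgs$chrom, start = cpgs$pos,
                                    end = cpgs$pos + 1))
    cnt <- GenomicRanges::countOverlaps(gd, all_gc)
    dens <- 100 * cnt / len
  }
  data.frame(id = domains$id, class = domains$class, length = len,
             n_cpgs = as.integer(n), mean_meth = mm, frac_meth = fhi,
             frac_unmeth = flo, cpg_density = dens, gc_content = gc_pct,
             stringsAsFactors = FALSE)
}

#' Partition genomic CpGs into methylome categories
#'
#' Assigns every CpG of the methylome to exactly one category, in priority
#' order: `hyper` (in a HyperD), `hypo` (in a HypoD), `tss_cgi` (in the
#' promoter/CGI exclusion mask), `control_meth` (in the >=50 %-in-control
#' mask), `intermediate` (25-75 % methylated in the target, at
#' `min_reads` coverage), `other`.
#'
#' @param meth target [methylome].
#' @param domains domain set (pre- or post-masking).
#' @param tss_cgi_mask,control_mask mask feature tracks (may be empty).
#' @param min_reads coverage for the intermediate call (default 5).
#' @return list with `per_cpg` (factor of categories) and `fractions`
#'   (named vector summing to 1).
#' @export
cpg_partition <- function(meth, domains, tss_cgi_mask = NULL,
                          control_mask = NULL, min_reads = 5) {
  cpgs <- meth$cpgs
  lv <- c("hyper", "hypo", "tss_cgi", "control_meth", "intermediate",
          "other")
  if (nrow(cpgs) == 0) {
    return(list(per_cpg = factor(character(), levels = lv),
                fractions = setNames(rep(NA_real_, 6), lv)))
  }
  gcpg <- data.frame(chrom = cpgs$chrom, start = cpgs$pos,
                     end = cpgs$pos + 1)
  cat <- rep("other", nrow(cpgs))
  cov <- cpgs$n_meth + cpgs$n_unmeth
  pct <- ifelse(cov >= min_reads,
                100 * cpgs$n_meth / pmax(cov, 1), NA_real_)
  cat[!is.na(pct) & pct >= 25 & pct <= 75] <- "intermediate"
  if (!is.null(control_mask) && nrow(control_mask))
    cat[overlaps_any(gcpg, control_mask)] <- "control_meth"
  if (!is.null(tss_cgi_mask) && nrow(tss_cgi_mask))
    cat[overlaps_any(gcpg, tss_cgi_mask)] <- "tss_cgi"
  if (nrow(domains)) {
    hypo <- domains[domains$class == "hypo", , drop = FALSE]
    hyper <- domains[domains$class == "hyper", , drop = FALSE]
    cat[overlaps_any(gcpg, hypo)] <- "hypo"
    cat[overlaps_any(gcpg, hyper)] <- "hyper"
  }
  per <- factor(cat, levels = lv)
  fr <- as.numeric(table(per)) / length(per)
  names(fr) <- lv
  list(per_cpg = per, fractions = fr)
}
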