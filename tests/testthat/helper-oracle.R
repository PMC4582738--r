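# Independent oracles: direct, quadratic transliterations of the
# segmentation procedure and brute-force reimplementations of overlap
# and CDF-gap computations.  These deliberately avoid the package's
# vectorised helpers.

# --- naive domain caller ----------------------------------------------

naive_windows <- function(meth, params) {
  out <- list()
  for (ch in unique(meth$cpgs$chrom)) {
    cc <- meth$cpgs[meth$cpgs$chrom == ch, , drop = FALSE]
    cc <- cc[cc$n_meth + cc$n_unmeth > 0, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    n <- nrow(cc)
    i <- 1
    while (i + params$window_n_cpgs - 1 <= n) {
      idx <- i:(i + params$window_n_cpgs - 1)
      vals <- c()
      for (k in idx) {
        cov <- cc$n_meth[k] + cc$n_unmeth[k]
        if (cov >= params$min_reads_per_cpg)
          vals <- c(vals, 100 * cc$n_meth[k] / cov)
      }
      mp <- if (length(vals) >= params$min_scored_cpgs) mean(vals)
      else NA_real_
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = cc$pos[idx[1]],
        end = cc$pos[idx[length(idx)]] + 1, meth_pct = mp)
      i <- i + params$step_n_cpgs
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), meth_pct = numeric()))
  do.call(rbind, out)
}

# merge overlapping/bookended same-class windows by repeated pairwise
# scanning
naive_merge_runs <- function(wins) {
  runs <- wins
  repeat {
    merged <- FALSE
    if (nrow(runs) < 2) break
    for (i in seq_len(nrow(runs) - 1)) {
      for (j in (i + 1):nrow(runs)) {
        if (runs$chrom[i] == runs$chrom[j] &&
            runs$start[j] <= runs$end[i] &&
            runs$start[i] <= runs$end[j]) {
          runs$start[i] <- min(runs$start[i], runs$start[j])
          runs$end[i] <- max(runs$end[i], runs$end[j])
          runs <- runs[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  runs[order(runs$chrom, runs$start), , drop = FALSE]
}

naive_raw_domains <- function(wins, params) {
  hyper <- wins[!is.na(wins$meth_pct) & wins$meth_pct > params$hyper_cut,
                c("chrom", "start", "end"), drop = FALSE]
  hypo <- wins[!is.na(wins$meth_pct) & wins$meth_pct < params$hypo_cut,
               c("chrom", "start", "end"), drop = FALSE]
  runs <- rbind(
    if (nrow(hyper)) cbind(naive_merge_runs(hyper), class = "hyper"),
    if (nrow(hypo)) cbind(naive_merge_runs(hypo), class = "hypo"))
  if (is.null(runs) || nrow(runs) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character()))
  runs <- runs[order(runs$chrom, runs$start, runs$end), , drop = FALSE]
  # split overlapped regions between opposite classes into halves
  repeat {
    cut <- FALSE
    if (nrow(runs) >= 2) {
      for (i in seq_len(nrow(runs) - 1)) {
        j <- i + 1
        if (runs$chrom[i] == runs$chrom[j] &&
            runs$start[j] < runs$end[i]) {
          ov_end <- min(runs$end[i], runs$end[j])
          mid <- floor((runs$start[j] + ov_end) / 2)
          runs$end[i] <- mid
          runs$start[j] <- mid
          runs <- runs[runs$end > runs$start, , drop = FALSE]
          runs <- runs[order(runs$chrom, runs$start, runs$end), ,
                       drop = FALSE]
          cut <- TRUE
          break
        }
      }
    }
    if (!cut) break
  }
  rownames(runs) <- NULL
  runs
}

naive_refine <- function(d, params) {
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  merge_pass <- function(d) {
    repeat {
      done <- TRUE
      if (nrow(d) >= 2) {
        for (i in seq_len(nrow(d) - 1)) {
          if (d$chrom[i] == d$chrom[i + 1] &&
              d$class[i] == d$class[i + 1] &&
              d$start[i + 1] - d$end[i] < params$merge_gap) {
            d$end[i] <- max(d$end[i], d$end[i + 1])
            d <- d[-(i + 1), , drop = FALSE]
            done <- FALSE
            break
          }
        }
      }
      if (done) break
    }
    d
  }
  d <- merge_pass(d)
  repeat {
    done <- TRUE
    if (nrow(d) >= 3) {
      for (i in 2:(nrow(d) - 1)) {
        if (d$chrom[i - 1] == d$chrom[i] &&
            d$chrom[i] == d$chrom[i + 1] &&
            d$class[i - 1] == d$class[i + 1] &&
            d$class[i] != d$class[i - 1] &&
            d$end[i] - d$start[i] < params$opposite_absorb_max) {
          d$end[i - 1] <- d$end[i + 1]
          d <- d[-c(i, i + 1), , drop = FALSE]
          done <- FALSE
          break
        }
      }
    }
    if (done) break
  }
  d <- d[d$end - d$start >= params$min_domain_len, , drop = FALSE]
  d <- merge_pass(d)
  rownames(d) <- NULL
  d
}

naive_call_domains <- function(meth, params) {
  naive_refine(naive_raw_domains(naive_windows(meth, params), params),
               params)
}

# --- brute-force comparators ------------------------------------------

bf_overlap_fraction <- function(domain, intervals) {
  covered <- logical(domain$end - domain$start)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] != domain$chrom) next
    a <- max(intervals$start[i], domain$start)
    b <- min(intervals$end[i], domain$end)
    if (b > a) covered[(a - domain$start + 1):(b - domain$start)] <- TRUE
  }
  mean(covered)
}

bf_cdf_gap <- function(tx, inter) {
  grid <- sort(unique(c(tx, inter)))
  best <- -Inf; thr <- NA
  for (g in grid) {
    diff <- mean(inter <= g) - mean(tx <= g)
    if (diff > best) { best <- diff; thr <- g }
  }
  list(threshold = thr, cdf_gap = best)
}

bf_chisq <- function(counts) {
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - e)^2 / e)
}

# per-base/brute classification of one query transcript against a
# reference annotation (shares the simplified class-code rules)
bf_classify_one <- function(qe, ref) {
  q_strand <- qe$strand[1]
  q_chrom <- qe$chrom[1]
  q_span <- c(min(qe$start), max(qe$end))
  qe <- qe[order(qe$start), , drop = FALSE]
  q_junc <- if (nrow(qe) > 1)
    paste(qe$end[-nrow(qe)], qe$start[-1]) else character(0)
  q_bases <- unlist(mapply(function(s, e) seq(s, e - 1), qe$start,
                           qe$end, SIMPLIFY = FALSE))
  best <- "u"
  rank <- c("=" = 1, "c" = 2, "j" = 3, "o" = 4, "i" = 5, "x" = 6,
            "u" = 7)
  for (tid in unique(ref$exons$transcript_id)) {
    re <- ref$exons[ref$exons$transcript_id == tid, , drop = FALSE]
    if (re$chrom[1] != q_chrom) next
    re <- re[order(re$start), , drop = FALSE]
    r_bases <- unlist(mapply(function(s, e) seq(s, e - 1), re$start,
                             re$end, SIMPLIFY = FALSE))
    ex_ov <- length(intersect(q_bases, r_bases)) > 0
    code <- NULL
    if (re$strand[1] == q_strand) {
      r_junc <- if (nrow(re) > 1)
        paste(re$end[-nrow(re)], re$start[-1]) else character(0)
      if (nrow(qe) > 1 && nrow(re) > 1 && identical(q_junc, r_junc))
        code <- "="
      else if (nrow(qe) == 1 && nrow(re) == 1 &&
               qe$start == re$start && qe$end == re$end)
        code <- "="
      else if (ex_ov && all(q_bases %in% r_bases))
        code <- "c"
      else if (length(intersect(q_junc, r_junc)) > 0)
        code <- "j"
      else if (ex_ov)
        code <- "o"
      # intronic containment
      if (is.null(code) && nrow(re) > 1) {
        for (k in seq_len(nrow(re) - 1)) {
          if (re$end[k] <= q_span[1] && q_span[2] <= re$start[k + 1]) {
            code <- "i"
            break
          }
        }
      }
    } else if (ex_ov) {
      code <- "x"
    }
    if (!is.null(code) && rank[[code]] < rank[[best]]) best <- code
  }
  best
}
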