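test_that("probes tile covered CpGs with the expected step", {
  m <- uniform_meth(120, spacing = 100, pct = 100, cov = 10)
  w <- make_windows(m, seg_params())
  expect_equal(nrow(w), 8)
  # probe i starts at member CpG index (i-1)*step
  expect_equal(w$start, seq(0, 7000, by = 1000))
  # genomic extent runs to one past the last member CpG
  expect_equal(w$end, seq(4900, 11900, by = 1000) + 1)
  expect_true(all(w$meth_pct == 100))
  # trailing stretch below one probe size yields nothing
  expect_equal(nrow(make_windows(uniform_meth(49), seg_params())), 0)
})

test_that("probe scoring honours coverage and minimum-position rules", {
  # 50 CpGs but only 2 at >= 5 reads -> unscored probe
  cov <- c(rep(2, 48), 10, 10)
  m <- mk_meth(seq(0, by = 50, length.out = 50), n_meth = cov,
               n_unmeth = 0)
  w <- make_windows(m, seg_params())
  expect_equal(w$scored_cpg_count, 2L)
  expect_true(is.na(w$meth_pct))
  # low-coverage CpGs still count as members, not toward the mean
  cov2 <- rep(c(10, 2), 25)
  m2 <- mk_meth(seq(0, by = 50, length.out = 50),
                n_meth = ifelse(cov2 >= 5, cov2, 0),
                n_unmeth = ifelse(cov2 >= 5, 0, cov2))
  w2 <- make_windows(m2, seg_params())
  expect_equal(w2$meth_pct, 100)  # the 2-read unmethylated CpGs ignored
})

test_that("opposite-class probe runs are split at the midpoint", {
  wins <- data.frame(
    chrom = "chr1",
    start = c(0, 2000, 4000, 8000),
    end = c(4000, 6000, 8000, 12000),
    member_cpg_count = 50, scored_cpg_count = 50,
    meth_pct = c(100, 100, 0, 0))
  d <- raw_domains(wins, seg_params())
  expect_equal(d$start, c(0, 5000))
  expect_equal(d$end, c(5000, 12000))
  expect_equal(d$class, c("hyper", "hypo"))
})

test_that("domain calling handles all-one-class and no-seed inputs", {
  wins <- data.frame(chrom = "chr1", start = seq(0, 9000, 1000),
                     end = seq(1000, 10000, 1000),
                     member_cpg_count = 50, scored_cpg_count = 50,
                     meth_pct = 90)
  d <- raw_domains(wins, seg_params())
  expect_equal(d[c("start", "end", "class")],
               data.frame(start = 0, end = 10000, class = "hyper"))
  wins$meth_pct <- 50
  expect_equal(nrow(raw_domains(wins, seg_params())), 0)
  # boundary probes exactly at the cutoffs are not seeds
  wins$meth_pct <- 75
  expect_equal(nrow(raw_domains(wins, seg_params())), 0)
})

test_that("refinement merges, absorbs and drops as specified", {
  p <- seg_params()
  d1 <- data.frame(chrom = "chr1", start = c(0, 6500),
                   end = c(5000, 9000), class = "hyper")
  r1 <- refine_domains(d1, p)
  expect_equal(r1[c("start", "end")], data.frame(start = 0, end = 9000))
  expect_true(r1$merged_over_gap)

  d2 <- data.frame(chrom = "chr1", start = c(0, 5000, 5800),
                   end = c(5000, 5800, 9000),
                   class = c("hyper", "hypo", "hyper"))
  r2 <- refine_domains(d2, p)
  expect_equal(r2[c("start", "end", "class")],
               data.frame(start = 0, end = 9000, class = "hyper"))
  expect_true(r2$absorbed_opposite)

  d3 <- data.frame(chrom = "chr1", start = 0, end = 1800,
                   class = "hyper")
  expect_equal(nrow(refine_domains(d3, p)), 0)

  # a 2-kbp gap is not merged (strict inequality)
  d4 <- data.frame(chrom = "chr1", start = c(0, 7000),
                   end = c(5000, 12000), class = "hyper")
  expect_equal(nrow(refine_domains(d4, p)), 2)
})

test_that("refinement is idempotent on random domain sets", {
  set.seed(42)
  p <- seg_params()
  for (i in 1:200) {
    d <- random_domain_set()
    r1 <- refine_domains(d, p)
    r2 <- refine_domains(r1[c("chrom", "start", "end", "class")], p)
    expect_equal(r2[c("chrom", "start", "end", "class")],
                 r1[c("chrom", "start", "end", "class")])
  }
})

test_that("refined domains are sorted, disjoint and well separated", {
  set.seed(7)
  p <- seg_params()
  for (i in 1:50) {
    r <- refine_domains(random_domain_set(), p)
    if (nrow(r) < 2) next
    same <- r$chrom[-1] == r$chrom[-nrow(r)]
    gaps <- r$start[-1] - r$end[-nrow(r)]
    expect_true(all(gaps[same] >= 0))
    same_cls <- same & r$class[-1] == r$class[-nrow(r)]
    expect_true(all(gaps[same_cls] >= p$merge_gap))
    expect_true(all(r$end - r$start >= p$min_domain_len))
  }
})

test_that("pre-methylated control mask follows the 1-kbp scoring rule", {
  # three CpGs in one kbp window at 2/3, 3/3, 1/3 -> mean 66.7 % masked
  ctrl <- mk_meth(c(100, 400, 800), c(2, 3, 1), c(1, 0, 2))
  msk <- premethylated_mask(list(ctrl), c(chr1 = 2000))
  expect_equal(msk[c("start", "end")], data.frame(start = 0, end = 1000))
  # only two CpGs at >= 3 reads -> window unscored, not masked
  ctrl2 <- mk_meth(c(100, 400, 800), c(3, 3, 1), c(0, 0, 1))
  expect_equal(nrow(premethylated_mask(list(ctrl2), c(chr1 = 2000))), 0)
  # fully unmethylated control -> empty mask
  ctrl3 <- mk_meth(c(100, 400, 800), c(0, 0, 0), c(5, 5, 5))
  expect_equal(nrow(premethylated_mask(list(ctrl3), c(chr1 = 2000))), 0)
  # ANY-control rule: second control triggers the mask
  expect_equal(nrow(premethylated_mask(list(ctrl3, ctrl),
                                       c(chr1 = 2000))), 1)
})

test_that("TSS mask extends downstream of the most upstream TSS", {
  ann <- mk_ann(list(
    list(tx = "t1", gene = "g1", chrom = "chr1", strand = "+",
         exons = list(c(10000, 11000))),
    list(tx = "t2", gene = "g2", chrom = "chr1", strand = "-",
         exons = list(c(40000, 50001)))))
  msk <- tss_mask(ann)
  expect_equal(msk$start, c(10000, 48001))
  expect_equal(msk$end, c(12000, 50001))
  # two genes sharing a TSS merge into one interval
  ann2 <- mk_ann(list(
    list(tx = "a", gene = "ga", chrom = "chr1", strand = "+",
         exons = list(c(100, 500))),
    list(tx = "b", gene = "gb", chrom = "chr1", strand = "+",
         exons = list(c(100, 900)))))
  expect_equal(nrow(tss_mask(ann2)), 1)
})

test_that("mask subtraction keeps lineage and logs dropped parents", {
  d <- data.frame(chrom = "chr1", start = c(0, 50000),
                  end = c(30000, 52000), class = c("hyper", "hypo"),
                  id = c("HyperD_00001", "HypoD_00001"),
                  parent_id = c("HyperD_00001", "HypoD_00001"),
                  merged_over_gap = FALSE, absorbed_opposite = FALSE,
                  split_by_mask = FALSE)
  # no masks: identity
  same <- apply_masks(d, list())
  expect_equal(same$id, d$id)
  cgi <- mk_track("chr1", 10000, 11000, kind = "CGI")
  out <- apply_masks(d, list(cgi))
  frag <- out[out$parent_id == "HyperD_00001", ]
  expect_equal(frag$start, c(0, 11000))
  expect_equal(frag$end, c(10000, 30000))
  expect_true(all(frag$split_by_mask))
  expect_true(all(frag$class == "hyper"))
  # untouched domain keeps its id
  expect_true("HypoD_00001" %in% out$id)
  # full coverage drops the parent into the log
  big <- mk_track("chr1", 49000, 53000, kind = "mask")
  out2 <- apply_masks(d, list(big))
  expect_false("HypoD_00001" %in% out2$parent_id)
  expect_equal(attr(out2, "dropped")$id, "HypoD_00001")
})

test_that("domain statistics and sequence-based density are exact", {
  d <- data.frame(chrom = "chr1", start = 0, end = 6,
                  class = "hyper", id = "HyperD_00001")
  m <- mk_meth(c(0, 2, 4), c(10, 10, 10), c(0, 0, 0))
  st <- domain_stats(d, m, genome_seq = list(chr1 = "CGCGCG"))
  expect_equal(st$mean_meth, 100)
  expect_equal(st$frac_meth, 1)
  expect_equal(st$cpg_density, 50)
  expect_equal(st$gc_content, 100)
  # domain without covered CpGs is flagged missing
  d2 <- rbind(d, data.frame(chrom = "chr1", start = 100, end = 200,
                            class = "hypo", id = "HypoD_00001"))
  st2 <- domain_stats(d2, m)
  expect_true(is.na(st2$mean_meth[2]))
})

test_that("CpG category partition is exhaustive and exclusive", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_block_methylome(150)
    d <- call_domains(m, seg_params(window_n_cpgs = 10,
                                    step_n_cpgs = 5))
    msk <- mk_track("chr1", c(0, 5000), c(2000, 5600), kind = "mask")
    ctl <- mk_track("chr1", 10000, 12000, kind = "mask")
    part <- cpg_partition(m, d, msk, ctl)
    expect_equal(sum(part$fractions), 1, tolerance = 1e-9)
    expect_equal(length(part$per_cpg), nrow(m$cpgs))
    expect_false(any(is.na(part$per_cpg)))
  }
})
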