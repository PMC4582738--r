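test_that("size-matched intergenic sampling is exact and seeded", {
  ann <- mk_ann(list(list(tx = "t1", gene = "g1", chrom = "chr1",
                          strand = "+", exons = list(c(40000, 60000)))))
  sizes <- c(500, 500, 2000)
  a <- sample_size_matched_intergenic(c(chr1 = 1e5), ann, sizes, 2,
                                      seed = 3)
  b <- sample_size_matched_intergenic(c(chr1 = 1e5), ann, sizes, 2,
                                      seed = 3)
  expect_identical(a, b)
  expect_equal(sort(a$end - a$start), sort(rep(sizes, 2)))
  expect_false(any(overlaps_any(
    a, data.frame(chrom = "chr1", start = 39000, end = 61000))))
  # saturated genome cannot place anything
  full <- mk_ann(list(list(tx = "t", gene = "g", chrom = "chr1",
                           strand = "+", exons = list(c(0, 1e5)))))
  expect_error(sample_size_matched_intergenic(
    c(chr1 = 1e5), full, 100, 1, seed = 1, max_tries = 50),
    "could not place")
})

test_that("CDF-gap threshold matches brute force on random samples", {
  r <- rabt_threshold(rep(10, 50), rep(0.01, 50))
  expect_equal(r$threshold, 0.01)
  expect_equal(r$cdf_gap, 1)
  r2 <- rabt_threshold(c(0, 1, 2, 3), c(0.5, 1.5))
  bf2 <- bf_cdf_gap(c(0, 1, 2, 3), c(0.5, 1.5))
  expect_equal(r2$threshold, bf2$threshold)
  expect_warning(r3 <- rabt_threshold(rep(2, 5), rep(2, 5)),
                 "degenerate")
  expect_equal(r3$cdf_gap, 0)
  set.seed(31)
  for (i in 1:100) {
    tx <- round(rlnorm(sample(5:60, 1), 0, 2), 3)
    iv <- round(rlnorm(sample(5:60, 1), -2, 1), 3)
    got <- rabt_threshold(tx, iv)
    want <- bf_cdf_gap(tx, iv)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$cdf_gap, want$cdf_gap)
  }
})

make_curation_fixture <- function() {
  txs <- list(
    # multi-exonic host gene on +
    list(tx = "host", gene = "ghost", chrom = "chr1", strand = "+",
         exons = list(c(1000, 2000), c(8000, 10000))),
    # (a) unstranded mono-exonic
    list(tx = "nostrand", gene = "gns", chrom = "chr1", strand = "*",
         exons = list(c(30000, 30500))),
    # (b) mono inside the host intron, same strand; and opposite strand
    list(tx = "intronic", gene = "gint", chrom = "chr1", strand = "+",
         exons = list(c(3000, 4000))),
    list(tx = "intronic_rev", gene = "gintr", chrom = "chr1",
         strand = "-", exons = list(c(5000, 6000))),
    # (c) mono 1.5 kbp downstream of the host 3' end
    list(tx = "tail", gene = "gtail", chrom = "chr1", strand = "+",
         exons = list(c(11500, 12500))),
    # (d) well-separated mono genes, one weak one strong
    list(tx = "weak", gene = "gweak", chrom = "chr1", strand = "+",
         exons = list(c(50000, 51000))),
    list(tx = "strong", gene = "gstrong", chrom = "chr1", strand = "+",
         exons = list(c(70000, 71000))))
  support <- list(
    transcript_counts = c(host = 500, nostrand = 5, intronic = 5,
                          intronic_rev = 40, tail = 50, weak = 2,
                          strong = 400),
    total_reads = 1e6,
    intergenic_counts = c(rep(1, 20), rep(3, 10)),
    intergenic_total = 1e6)
  list(ann = mk_ann(txs), support = support)
}

test_that("mono-exonic curation applies the four rules in order", {
  fx <- make_curation_fixture()
  cur <- curate_monoexonic(fx$ann, fx$support)
  ids <- cur$annotation$transcripts$transcript_id
  expect_false("nostrand" %in% ids)        # (a)
  expect_false("intronic" %in% ids)        # (b) same strand
  expect_true("intronic_rev" %in% ids)     # (b) opposite strand kept
  expect_false("tail" %in% ids)            # (c) merged into host
  host_end <- cur$annotation$transcripts$end[ids == "host"]
  expect_equal(host_end, 12500)            # host 3' exon extended
  expect_false("weak" %in% ids)            # (d) below intergenic cutoff
  expect_true("strong" %in% ids)
  expect_equal(cur$report$removed_no_strand, 1L)
  expect_equal(cur$report$removed_intronic, 1L)
  expect_equal(cur$report$merged_3prime, 1L)
  expect_equal(cur$report$removed_low_expression, 1L)
})

test_that("curation is stable under re-application", {
  fx <- make_curation_fixture()
  once <- curate_monoexonic(fx$ann, fx$support)
  twice <- curate_monoexonic(once$annotation, fx$support)
  expect_equal(twice$annotation$exons, once$annotation$exons)
  expect_equal(twice$report$removed_low_expression, 0L)
})

test_that("curation demands read support for surviving transcripts", {
  fx <- make_curation_fixture()
  fx$support$transcript_counts <-
    fx$support$transcript_counts[names(fx$support$transcript_counts) !=
                                   "strong"]
  expect_error(curate_monoexonic(fx$ann, fx$support), "read support")
})

test_that("class codes follow the simplified Cuffcompare semantics", {
  ref <- mk_ann(list(
    list(tx = "r1", gene = "rg1", chrom = "chr1", strand = "+",
         exons = list(c(1000, 2000), c(5000, 6000), c(8000, 9000)))))
  qry <- mk_ann(list(
    # identical intron chain
    list(tx = "same", gene = "q1", chrom = "chr1", strand = "+",
         exons = list(c(900, 2000), c(5000, 6000), c(8000, 9100))),
    # contained in exons
    list(tx = "cont", gene = "q2", chrom = "chr1", strand = "+",
         exons = list(c(1200, 1800))),
    # shares one junction but extends beyond the reference exon
    list(tx = "junc", gene = "q3", chrom = "chr1", strand = "+",
         exons = list(c(500, 2000), c(5000, 5500))),
    # generic same-strand exonic overlap
    list(tx = "olap", gene = "q4", chrom = "chr1", strand = "+",
         exons = list(c(1500, 2400))),
    # intronic, same strand
    list(tx = "intr", gene = "q5", chrom = "chr1", strand = "+",
         exons = list(c(3000, 4000))),
    # exonic overlap, opposite strand
    list(tx = "anti", gene = "q6", chrom = "chr1", strand = "-",
         exons = list(c(1500, 2400))),
    # no overlap
    list(tx = "far", gene = "q7", chrom = "chr1", strand = "+",
         exons = list(c(50000, 51000)))))
  cl <- classify_vs_reference(qry, ref)
  got <- setNames(cl$category, cl$transcript_id)
  expect_equal(unname(got[c("same", "cont", "junc", "olap", "intr",
                            "anti", "far")]),
               c("=", "c", "j", "o", "i", "x", "u"))
  expect_equal(cl$novel, cl$category %in% c("i", "u", "x"))
  expect_equal(cl$ref_gene_id[cl$transcript_id == "same"], "rg1")
})

test_that("class codes agree with the per-base brute comparator", {
  set.seed(13)
  for (trial in 1:25) {
    n_ref <- sample(2:5, 1)
    mk_random_tx <- function(id, gene) {
      n_ex <- sample(1:4, 1)
      anchor <- sample(seq(0, 30000, by = 500), 1)
      bounds <- anchor + sort(sample(seq(0, 8000, by = 100),
                                     2 * n_ex))
      list(tx = id, gene = gene, chrom = "chr1",
           strand = sample(c("+", "-"), 1),
           exons = lapply(seq_len(n_ex), function(k)
             c(bounds[2 * k - 1], bounds[2 * k])))
    }
    ref_txs <- lapply(seq_len(n_ref), function(i)
      mk_random_tx(paste0("r", i), paste0("rg", i)))
    qry_txs <- lapply(1:4, function(i)
      mk_random_tx(paste0("q", i), paste0("qg", i)))
    ref <- tryCatch(mk_ann(ref_txs), error = function(e) NULL)
    qry <- tryCatch(mk_ann(qry_txs), error = function(e) NULL)
    if (is.null(ref) || is.null(qry)) next
    cl <- classify_vs_reference(qry, ref)
    for (i in seq_len(nrow(cl))) {
      qe <- qry$exons[qry$exons$transcript_id == cl$transcript_id[i], ]
      expect_equal(cl$category[i], bf_classify_one(qe, ref),
                   info = paste("trial", trial, cl$transcript_id[i]))
    }
  }
})

test_that("novel-gene exclusion rules respect strand and margins", {
  ref <- mk_ann(list(
    list(tx = "r1", gene = "rg1", chrom = "chr1", strand = "+",
         exons = list(c(10000, 20000), c(22000, 24000)))))
  qry <- mk_ann(list(
    # multi-exonic 800 bp downstream, same strand: excluded
    list(tx = "n1", gene = "near", chrom = "chr1", strand = "+",
         exons = list(c(24800, 25200), c(25600, 26000))),
    # same distance, opposite strand: accepted
    list(tx = "n2", gene = "near_rev", chrom = "chr1", strand = "-",
         exons = list(c(124800, 125200), c(125600, 126000))),
    # mono-exonic coextensive with a MaLR element: excluded
    list(tx = "n3", gene = "repeaty", chrom = "chr1", strand = "+",
         exons = list(c(200000, 200800))),
    # clean multi-exonic far away: accepted
    list(tx = "n4", gene = "clean", chrom = "chr1", strand = "+",
         exons = list(c(300000, 300500), c(301000, 301500)))))
  # a +-strand reference gene near near_rev proves the strand filter
  ref2 <- mk_ann(list(
    list(tx = "r1", gene = "rg1", chrom = "chr1", strand = "+",
         exons = list(c(10000, 20000), c(22000, 24000))),
    list(tx = "r2", gene = "rg2", chrom = "chr1", strand = "+",
         exons = list(c(120000, 124000)))))
  te <- mk_track("chr1", 200000, 200800, strand = "+", kind = "TE",
                 name = "MTA_Mm", family = "MaLR")
  cl <- classify_vs_reference(qry, ref2)
  calls <- call_novel_genes(qry, cl, ref2, te_track = te)
  got <- setNames(calls$accepted, calls$gene_id)
  expect_false(got[["near"]])
  expect_true(got[["near_rev"]])
  expect_false(got[["repeaty"]])
  expect_true(got[["clean"]])
  expect_true(calls$near_reference[calls$gene_id == "near"])
  expect_true(calls$repeat_monoexonic[calls$gene_id == "repeaty"])
})

test_that("novel upstream TSSs satisfy all three clauses", {
  ref <- mk_ann(list(
    list(tx = "r1", gene = "rg1", chrom = "chr1", strand = "+",
         exons = list(c(10000, 11000), c(15000, 16000)))))
  cgi <- mk_track("chr1", 9900, 10300, kind = "CGI")
  qry <- mk_ann(list(
    # novel first exon 5 kbp upstream splicing into ref exon 2
    list(tx = "up", gene = "q1", chrom = "chr1", strand = "+",
         exons = list(c(5000, 5400), c(15000, 16000)))))
  cl <- classify_vs_reference(qry, ref)
  res <- find_novel_upstream_tss(qry, cl, ref, cgi)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$distance, 5000)
  expect_equal(res$median_distance, 5000)
  # start inside the reference first exon: not novel
  qry2 <- mk_ann(list(
    list(tx = "in1", gene = "q1", chrom = "chr1", strand = "+",
         exons = list(c(10200, 11000), c(15000, 16000)))))
  cl2 <- classify_vs_reference(qry2, ref)
  expect_equal(nrow(find_novel_upstream_tss(qry2, cl2, ref,
                                            cgi)$records), 0)
  # start in a novel exon but inside the promoter CGI: rejected
  big_cgi <- mk_track("chr1", 4000, 10300, kind = "CGI")
  expect_equal(nrow(find_novel_upstream_tss(qry, cl, ref,
                                            big_cgi)$records), 0)
})

test_that("TSS classification prefers CGI, then same-strand TE", {
  cgi <- mk_track("chr1", 1000, 1500, kind = "CGI")
  te <- mk_track("chr1", c(5000, 8000), c(6000, 9000),
                 strand = c("+", "-"), kind = "TE",
                 name = c("MTA", "IAP"), family = c("MaLR", "ERVK"))
  tss <- data.frame(chrom = "chr1", pos = c(1550, 5500, 8500, 20000),
                    strand = c("+", "+", "+", "+"))
  out <- classify_tss(tss, cgi, te)
  expect_equal(out$class, c("CGI_associated", "TE_associated", "other",
                            "other"))
  expect_equal(out$te_family[2], "MaLR")
  # 150 bp away from the CGI edge is beyond the flank
  out2 <- classify_tss(data.frame(chrom = "chr1", pos = 1650,
                                  strand = "+"), cgi, te)
  expect_equal(out2$class, "other")
})

test_that("TE TSS expectation reflects intergenic occupancy", {
  # family occupies 10 % of a 1-Mbp intergenic space
  inter <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  te <- mk_track("chr1", seq(0, 9e5, by = 1e5),
                 seq(0, 9e5, by = 1e5) + 1e4, strand = "+",
                 kind = "TE", name = paste0("m", 1:10), family = "MaLR")
  res <- te_tss_expectation(te, inter, c(MaLR = 100), total_tss = 1000,
                            seed = 2, n_draws = 50)
  expect_equal(res$occupancy, 0.1)
  expect_equal(res$ratio, 1)
  expect_equal(res$expected_mc, 100, tolerance = 0.1)
  expect_true(res$p > 0.05)
  res3 <- te_tss_expectation(te, inter, c(MaLR = 300), total_tss = 1000,
                             seed = 2, n_draws = 50)
  expect_equal(res3$ratio, 3)
  expect_lt(res3$p, 1e-10)
  # absent family with no observations is skipped
  te$family <- "ERVK"
  res0 <- te_tss_expectation(te, inter, c(MaLR = 0), total_tss = 1000,
                             seed = 2, n_draws = 10)
  expect_false("MaLR" %in% res0$family)
})

test_that("patch transcripts above the threshold are restored", {
  primary <- mk_ann(list(list(tx = "p1", gene = "g1", chrom = "chr1",
                              strand = "+", exons = list(c(0, 1000)))))
  patch <- mk_ann(list(
    list(tx = "p1", gene = "g1", chrom = "chr1", strand = "+",
         exons = list(c(0, 1000))),
    list(tx = "hot", gene = "g2", chrom = "chr1", strand = "+",
         exons = list(c(5000, 6000))),
    list(tx = "cold", gene = "g3", chrom = "chr1", strand = "+",
         exons = list(c(9000, 9500)))))
  out <- reconcile_annotations(primary, patch,
                               c(hot = 2, cold = 0.01), threshold = 0.5)
  expect_setequal(out$transcripts$transcript_id, c("p1", "hot"))
})
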