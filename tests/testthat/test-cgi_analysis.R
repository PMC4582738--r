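mk_cgi_ann <- function() {
  # gene with an alternative internal transcript TSS
  mk_ann(list(
    list(tx = "t1", gene = "g1", chrom = "chr1", strand = "+",
         exons = list(c(10000, 11000), c(20000, 21000))),
    list(tx = "t1b", gene = "g1", chrom = "chr1", strand = "+",
         exons = list(c(15000, 16000), c(20000, 21000)))))
}

test_that("CGI location classes are disjoint and exhaustive", {
  ann <- mk_cgi_ann()
  cgi <- mk_track("chr1",
                  c(9900, 14950, 18000, 50000),
                  c(10300, 15300, 18500, 50500), kind = "CGI")
  out <- classify_cgi_location(cgi, ann)
  expect_equal(as.character(out$location_class),
               c("tss_associated", "intragenic_with_alt_tss",
                 "intragenic", "intergenic"))
  expect_equal(sum(table(out$location_class)), nrow(cgi))
  expect_false(any(is.na(out$location_class)))
})

test_that("CGI methylation status follows the 10-CpG/5-read rule", {
  cgi <- mk_track("chr1", c(0, 3000, 6000), c(2000, 5000, 8000),
                  kind = "CGI")
  pos1 <- seq(0, 1900, by = 100)        # 20 CpGs at 100 %
  pos2 <- seq(3000, 3800, by = 100)     # 9 scorable CpGs only
  pos3 <- seq(6000, 7900, by = 100)     # 20 CpGs at 50 %
  m <- mk_meth(c(pos1, pos2, pos3),
               c(rep(10, 20), rep(5, 9), rep(5, 20)),
               c(rep(0, 20), rep(5, 9), rep(5, 20)))
  out <- cgi_meth_status(cgi, m)
  expect_equal(as.character(out$meth_status),
               c("hyper", "unscored", "intermediate"))
  # inclusive thresholds
  m75 <- mk_meth(pos1, rep(6, 20), rep(2, 20))
  expect_equal(as.character(cgi_meth_status(cgi[1, ], m75)$meth_status),
               "hyper")
  m25 <- mk_meth(pos1, rep(2, 20), rep(6, 20))
  expect_equal(as.character(cgi_meth_status(cgi[1, ], m25)$meth_status),
               "hypo")
})

test_that("raising CpG methylation never lowers a CGI call", {
  set.seed(21)
  cgi <- mk_track("chr1", 0, 5000, kind = "CGI")
  rank <- c(hypo = 1, intermediate = 2, hyper = 3)
  for (i in 1:20) {
    pos <- seq(0, 4900, by = 250)
    nm <- rbinom(20, 10, runif(1))
    m_lo <- mk_meth(pos, nm, 10 - nm)
    bump <- pmin(nm + sample(0:3, 20, TRUE), 10)
    m_hi <- mk_meth(pos, bump, 10 - bump)
    s_lo <- as.character(cgi_meth_status(cgi, m_lo)$meth_status)
    s_hi <- as.character(cgi_meth_status(cgi, m_hi)$meth_status)
    expect_gte(rank[[s_hi]], rank[[s_lo]])
  }
})

test_that("transcription context flags contigs and downstream windows", {
  ann <- mk_cgi_ann()
  cgi <- mk_track("chr1", c(30000, 21500, 50000),
                  c(30400, 21900, 50500), kind = "CGI")
  cgi <- classify_cgi_location(cgi, ann)
  pos <- seq(29000, 31000, by = 100)
  m <- mk_meth(pos, 10, 0)
  cgi <- cgi_meth_status(cgi, m)
  contigs <- mk_track("chr1", 29500, 31000, strand = "+",
                      kind = "contig")
  ctx <- cgi_transcription_context(cgi, ann, contigs)
  flags <- ctx$cgi
  # CGI fully inside a contig
  expect_true(flags$overlapped_by_contig[flags$start == 30000])
  # CGI starting 500 bp after the gene 3' end (gene ends at 21000)
  expect_true(flags$downstream_of_gene[flags$start == 21500])
  expect_false(flags$downstream_of_gene[flags$start == 50000])
  # no intergenic CGIs in both methylation classes -> note, no test
  expect_null(ctx$intergenic_test)
  expect_match(ctx$note, "intergenic")
})

test_that("methylated intergenic CGIs are tested against contigs", {
  ann <- mk_cgi_ann()
  # 40 intergenic CGIs: 20 methylated (10 in contigs), 20 unmethylated
  # (2 in contigs)
  starts <- seq(100000, by = 5000, length.out = 40)
  cgi <- mk_track("chr1", starts, starts + 1000, kind = "CGI")
  cgi <- classify_cgi_location(cgi, ann)
  pos <- unlist(lapply(starts, function(s) seq(s, s + 900, by = 50)))
  meth <- rep(c(10, 0), each = 20 * 19)
  m <- mk_meth(pos, meth, 10 - meth)
  cgi <- cgi_meth_status(cgi, m)
  in_ctg <- c(starts[1:10], starts[21:22])
  contigs <- mk_track("chr1", in_ctg - 100, in_ctg + 1200, strand = "+",
                      kind = "contig")
  ctx <- cgi_transcription_context(cgi, ann, contigs)
  expect_equal(unname(ctx$intergenic_test$counts[, "overlap"]),
               c(10, 2))
  expect_lt(ctx$intergenic_test$p, 0.01)
})

test_that("igDMRs are located against both annotations and domains", {
  ref <- mk_ann(list(
    list(tx = "r1", gene = "rg1", chrom = "chr1", strand = "+",
         exons = list(c(10000, 11000), c(20000, 21000)))))
  # oocyte assembly adds an upstream TSS so the reference promoter
  # becomes intragenic
  ooc <- mk_ann(list(
    list(tx = "o1", gene = "og1", chrom = "chr1", strand = "+",
         exons = list(c(4000, 4400), c(20000, 21000)))))
  domains <- data.frame(chrom = "chr1", start = c(3000, 40000),
                        end = c(25000, 60000),
                        class = c("hyper", "hyper"),
                        id = c("HyperD_00001", "HyperD_00002"))
  ig <- mk_track("chr1", c(9950, 50000), c(10400, 50800),
                 kind = "igDMR", name = c("Peg_like", "lonely"))
  out <- classify_igdmrs(ig, ref, ooc, domains)
  expect_equal(out$ref_class, c("tss_associated", "intergenic"))
  expect_equal(out$oocyte_class, c("intragenic", "intergenic"))
  expect_equal(out$domain_class, c("hyper", "hyper"))
  # empty track gives an empty result
  expect_equal(nrow(classify_igdmrs(ig[0, ], ref, ooc, domains)), 0)
})
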