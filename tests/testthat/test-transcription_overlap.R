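test_that("contigs require three same-strand reads in one dataset", {
  r2 <- data.frame(chrom = "chr1", start = c(100, 150),
                   end = c(200, 250), strand = "+", dataset = "A")
  expect_equal(nrow(build_contigs(r2)), 0)
  r3 <- data.frame(chrom = "chr1", start = c(100, 150, 180),
                   end = c(200, 250, 300), strand = "+", dataset = "A")
  ct <- build_contigs(r3)
  expect_equal(ct[c("start", "end")], data.frame(start = 180, end = 200))
  # opposite strands do not stack
  r3$strand <- c("+", "+", "-")
  expect_equal(nrow(build_contigs(r3)), 0)
  # depth reached in one dataset only still yields a contig
  mix <- rbind(r3, r3, transform(r3, dataset = "B", strand = "+"))
  mix$strand <- "+"
  mix$dataset <- c("A", "B", "A", "B", "A", "B", "B", "B", "B")
  expect_equal(nrow(build_contigs(mix)), 1)
})

test_that("overlap fraction equals union arithmetic and brute force", {
  d <- data.frame(chrom = "chr1", start = 0, end = 1000)
  tx <- data.frame(chrom = "chr1", start = c(0, 300), end = c(400, 700))
  expect_equal(overlap_fraction(d, tx), 0.7)
  expect_equal(overlap_fraction(d, tx[0, ]), 0)
  inside <- data.frame(chrom = "chr1", start = 0, end = 5000)
  expect_equal(overlap_fraction(d, inside), 1)
  set.seed(5)
  for (i in 1:50) {
    dd <- data.frame(chrom = "chr1", start = 0,
                     end = sample(500:10000, 1))
    n <- sample(1:8, 1)
    s <- sample(0:9000, n, replace = TRUE)
    iv <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     start = s, end = s + sample(50:3000, n, TRUE))
    expect_equal(overlap_fraction(dd, iv), bf_overlap_fraction(dd, iv))
  }
  expect_error(overlap_fraction(
    data.frame(chrom = "chr1", start = 5, end = 5), tx), "zero-length")
})

test_that("HyperD cascade assigns the first sufficient tier", {
  doms <- data.frame(chrom = "chr1",
                     start = c(0, 10000, 20000),
                     end = c(1000, 11000, 21000),
                     class = "hyper",
                     id = c("a", "b", "c"))
  ref <- data.frame(chrom = "chr1", start = 0, end = 1000, fpkm = 5)
  asm <- data.frame(chrom = "chr1", start = 10000, end = 10300)
  ctg <- data.frame(chrom = "chr1", start = 10300, end = 10600)
  ex <- explain_hyperds(doms, ref, asm, ctg)
  expect_equal(as.character(ex$per_domain$tier),
               c("reference_expressed", "assembly_plus_contigs",
                 "unexplained"))
  expect_equal(ex$per_domain$frac_reference[1], 1)
  # the unexplained domain has < 5 % transcription: untranscribed
  expect_true(ex$per_domain$untranscribed[3])
  expect_false(ex$per_domain$untranscribed[2])
  # sub-threshold reference expression does not count
  ref$fpkm <- 0.0001
  ex2 <- explain_hyperds(doms, ref, asm, ctg)
  expect_equal(as.character(ex2$per_domain$tier)[1], "unexplained")
})

test_that("cascade fractions are monotone and tiers partition domains", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    st <- sort(sample(seq(0, 1e6, by = 5000), n))
    doms <- data.frame(chrom = "chr1", start = st, end = st + 4000,
                       class = "hyper", id = paste0("d", seq_len(n)))
    rnd_iv <- function(k) {
      s <- sample(0:1e6, k, replace = TRUE)
      data.frame(chrom = "chr1", start = s,
                 end = s + sample(500:20000, k, TRUE))
    }
    ref <- rnd_iv(5); ref$fpkm <- runif(5, 0, 2)
    ex <- explain_hyperds(doms, ref, rnd_iv(5), rnd_iv(5), rnd_iv(3))
    pd <- ex$per_domain
    expect_true(all(pd$frac_reference <= pd$frac_assembly + 1e-12))
    expect_true(all(pd$frac_assembly <=
                      pd$frac_assembly_contigs + 1e-12))
    expect_true(all(pd$frac_assembly_contigs <=
                      pd$frac_partial_meth + 1e-12))
    expect_false(any(is.na(pd$tier)))
    expect_equal(sum(ex$summary$tier_fractions), 1, tolerance = 1e-9)
  }
})

test_that("HypoD cascade distinguishes low-FPKM and alt-promoter", {
  doms <- data.frame(chrom = "chr1",
                     start = c(0, 10000, 20000, 30000),
                     end = c(1000, 11000, 21000, 31000),
                     class = "hypo", id = c("a", "b", "c", "d"))
  asm <- data.frame(chrom = "chr1",
                    start = c(0, 9500, 19500),
                    end = c(2000, 12000, 22000),
                    gene_id = c("g_low", "g_hi", "g_hi2"))
  fpkm <- c(g_low = 0.2, g_hi = 4, g_hi2 = 4)
  alt <- data.frame(chrom = "chr1", start = 19800, end = 21800)
  ex <- explain_hypods(doms, asm, fpkm, alt)
  expect_equal(as.character(ex$per_domain$tier),
               c("low_fpkm_gene", "unexplained_transcribed",
                 "alt_downstream_promoter", "untranscribed"))
  expect_equal(ex$per_domain$transcribed, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(ex$summary$tier_fractions), 1, tolerance = 1e-9)
})

test_that("FPKM bins locate the unmethylated-majority crossover", {
  # genes below 0.5 FPKM unmethylated, above methylated
  n <- 60
  fpkm <- seq(0.05, 2.95, length.out = n)
  starts <- seq(0, by = 20000, length.out = n)
  genes <- data.frame(chrom = "chr1", start = starts,
                      end = starts + 10000,
                      gene_id = paste0("g", 1:n), fpkm = fpkm)
  pos <- unlist(lapply(seq_len(n), function(i)
    seq(starts[i], starts[i] + 9000, by = 1000)))
  meth_level <- rep(ifelse(fpkm < 0.5, 0, 10), each = 10)
  m <- mk_meth(pos, meth_level, 10 - meth_level)
  rel <- fpkm_meth_relation(genes, m)
  expect_equal(rel$threshold, 0.5)
  expect_true(all(rel$bins$frac_unmeth[rel$bins$upper <= 0.5] == 1))
  # all genes unmethylated: threshold is the last populated bin edge
  m2 <- mk_meth(pos, 0, 10)
  rel2 <- fpkm_meth_relation(genes, m2, fpkm_max = 5)
  expect_equal(rel2$threshold, max(rel2$bins$upper))
  expect_error(fpkm_meth_relation(genes[0, ], m), "no scorable")
})

test_that("escapee confirmation uses the running-window rule", {
  # uniformly unmethylated 20-kbp gene at FPKM 5: confirmed
  g1 <- data.frame(chrom = "chr1", start = 0, end = 20000,
                   gene_id = "esc", fpkm = 5)
  m1 <- mk_meth(seq(0, 19900, by = 250), 0, 10)
  e1 <- detect_escapees(g1, m1)
  expect_true(e1$confirmed)
  # 40-kbp gene, 10-kbp internal block at 90 %: screened in on the
  # average but rejected by the windows
  pos <- seq(0, 39900, by = 250)
  block <- pos >= 15000 & pos < 25000
  m2 <- mk_meth(pos, ifelse(block, 9, 0), ifelse(block, 1, 10))
  g2 <- data.frame(chrom = "chr1", start = 0, end = 40000,
                   gene_id = "blocky", fpkm = 5)
  e2 <- detect_escapees(g2, m2)
  expect_equal(nrow(e2), 1)  # passes the stage-1 screen
  expect_false(e2$confirmed)
  # low expression never screens in
  g3 <- data.frame(chrom = "chr1", start = 0, end = 20000,
                   gene_id = "low", fpkm = 0.4)
  expect_equal(nrow(detect_escapees(g3, m1)), 0)
})

test_that("feature enrichment matches the closed-form chi-squared", {
  unit <- function(n, offset)
    data.frame(chrom = "chr1", start = offset + (0:(n - 1)) * 2000,
               end = offset + (0:(n - 1)) * 2000 + 1000,
               class = "hyper", id = paste0("u", offset + 1:n))
  ga <- unit(100, 0)
  gb <- unit(100, 1e6)
  # feature covers 90 of group a, 10 of group b
  feat <- rbind(data.frame(chrom = "chr1", start = 0, end = 179000),
                data.frame(chrom = "chr1", start = 1e6, end = 1e6 + 19000))
  fe <- feature_enrichment(ga, gb, feat)
  expect_equal(fe$counts, matrix(c(90, 10, 10, 90), 2, byrow = TRUE,
                                 dimnames = dimnames(fe$counts)))
  expect_equal(fe$chisq, 128)
  expect_equal(fe$chisq, bf_chisq(fe$counts))
  expect_false(fe$low_expected)
  # identical groups: no signal
  fe0 <- feature_enrichment(ga, ga, feat)
  expect_equal(fe0$chisq, 0)
  expect_equal(fe0$p, 1)
  expect_error(feature_enrichment(ga[0, ], gb, feat), "non-empty")
})
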