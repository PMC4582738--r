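#!/usr/bin/env Rscript

# Stage 4: transcript-annotation curation and TSS characterisation.
#
# Classifies oocyte transcripts against the reference (simplified
# Cuffcompare codes), calls high-confidence novel genes and novel
# upstream TSSs (scored against the planted truth), classifies TSSs by
# CGI/TE association, tests TE-family TSS enrichment against
# intergenic occupancy, and demonstrates the RABT expression threshold
# on size-matched intergenic regions.

library(methdomain)

sim <- file.path("results", "sim")
out <- file.path("results", "curation")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
lens <- c(chr1 = 1e7, chr2 = 1e7)

ann <- read_gtf(file.path(sim, "oocyte.gtf"))
ref <- read_gtf(file.path(sim, "reference.gtf"))
cgi <- read_feature_bed(file.path(sim, "cgi.bed"), "CGI")
te <- read_feature_bed(file.path(sim, "te.bed"), "TE")
te$family <- sub("_\\d+$", "", te$name)
fpkm_tab <- read.table(file.path(sim, "fpkm.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
truth_novel <- readLines(file.path(sim, "truth_novel_genes.txt"))
truth_up <- read.table(file.path(sim, "truth_upstream_tss.tsv"),
                       header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)

cl <- classify_vs_reference(ann, ref)
cat("class codes:", paste(sprintf("%s=%d", names(table(cl$category)),
                                  table(cl$category)), collapse = " "),
    "\n")
write.table(cl, file.path(out, "class_codes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

calls <- call_novel_genes(ann, cl, ref, te_track = te)
accepted <- calls$gene_id[calls$accepted]
cat(sprintf("novel genes: %d accepted; precision %.2f recall %.2f vs %d planted\n",
            length(accepted),
            length(intersect(accepted, truth_novel)) /
              max(1, length(accepted)),
            length(intersect(accepted, truth_novel)) /
              max(1, length(truth_novel)),
            length(truth_novel)))
write.table(calls, file.path(out, "novel_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

up <- find_novel_upstream_tss(ann, cl, ref, cgi)
got_g <- sub("^OOC_G", "REF_G", up$records$ref_gene_id)
cat(sprintf("novel upstream TSSs: %d found (median distance %.0f bp); recall %.2f of %d planted\n",
            nrow(up$records), up$median_distance,
            length(intersect(got_g, truth_up$ref_gene_id)) /
              max(1, nrow(truth_up)), nrow(truth_up)))
write.table(up$records, file.path(out, "upstream_tss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

g <- ann$genes
tss <- classify_tss(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                               pos = g$tss, strand = g$strand),
                    cgi, te)
cat("gene TSS classes:",
    paste(sprintf("%s=%d", names(table(tss$class)), table(tss$class)),
          collapse = " "), "\n")
write.table(tss, file.path(out, "tss_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

inter <- intergenic_track(ref, lens)
obs <- table(tss$te_family[tss$class == "TE_associated"])
enr <- te_tss_expectation(te, inter, setNames(as.numeric(obs),
                                              names(obs)),
                          total_tss = nrow(tss), seed = 6)
print(enr[c("family", "occupancy", "expected", "observed", "ratio",
            "p")])
write.table(enr, file.path(out, "te_tss_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# RABT-style threshold: assembled-gene FPKM vs random size-matched
# intergenic regions (which get a small noise FPKM background)
samp <- sample_size_matched_intergenic(
  lens, ref, sizes = rep(c(1000, 3000, 10000), each = 20),
  n_per_size = 1, seed = 5)
set.seed(7)
inter_fpkm <- rlnorm(nrow(samp), -4, 0.8)
thr <- rabt_threshold(fpkm_tab$fpkm_recovered[fpkm_tab$n_reads > 0],
                      inter_fpkm)
cat(sprintf("RABT CDF-gap threshold: %.4f (gap %.3f)\n",
            thr$threshold, thr$cdf_gap))
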