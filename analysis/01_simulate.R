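#!/usr/bin/env Rscript

# Stage 1: build the simulated study inputs.
#
# Generates a two-chromosome (2 x 10 Mbp) genome: a reference
# annotation, an oocyte assembly carrying planted novel genes and novel
# upstream TSSs, a promoter-CGI and a TE track, stranded read coverage
# proportional to expression, and two methylomes -- a target methylome
# whose hypermethylated blocks follow transcribed units with coupling
# 0.9 (emulating a fully grown oocyte), and a lowly methylated control
# (emulating a non-growing oocyte).  Everything is written through the
# package's format writers so later stages consume files, as a real run
# would.

library(methdomain)

seed <- 1
out <- file.path("results", "sim")        # small tables and truth
raw <- file.path("scratch", "sim")         # bulky raw inputs (regenerable)
dir.create(out, showWarnings = FALSE, recursive = TRUE)
dir.create(raw, showWarnings = FALSE, recursive = TRUE)
lens <- c(chr1 = 1e7, chr2 = 1e7)

ann_sim <- simulate_annotation(annotation_spec(seed = seed), lens)
plan <- coupled_domain_plan(ann_sim$oocyte, lens, coupling = 0.9,
                            seed = seed + 1)
fgo <- simulate_methylome(methylome_spec(
  chrom_lengths = lens, domain_plan = plan, coverage_mean = 15,
  dense_regions = ann_sim$tracks$cgi, seed = seed + 2),
  label = "FGO_sim")
ngo <- simulate_methylome(methylome_spec(
  chrom_lengths = lens, background_meth = 5, coverage_mean = 15,
  dense_regions = ann_sim$tracks$cgi, seed = seed + 3),
  label = "NGO_sim")
reads <- simulate_read_coverage(ann_sim$oocyte, ann_sim$fpkm,
                                total_reads = 2e6, seed = seed + 4)

write_cpg_table(fgo$methylome, file.path(raw, "fgo.cov"))
write_cpg_table(ngo$methylome, file.path(raw, "ngo.cov"))
write_gtf(ann_sim$oocyte, file.path(out, "oocyte.gtf"))
write_gtf(ann_sim$reference, file.path(out, "reference.gtf"))
write_feature_bed(ann_sim$tracks$cgi, file.path(out, "cgi.bed"))
write_feature_bed(ann_sim$tracks$te, file.path(out, "te.bed"))
write.table(reads$reads, file.path(raw, "reads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(reads$fpkm, file.path(out, "fpkm.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(plan, file.path(out, "truth_domains.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(ann_sim$truth$novel_gene_ids),
           file.path(out, "truth_novel_genes.txt"))
write.table(ann_sim$truth$upstream,
            file.path(out, "truth_upstream_tss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d chromosomes, %s bp total\n", length(lens),
            format(sum(lens), big.mark = ",")))
cat(sprintf("target methylome: %d CpGs; control: %d CpGs\n",
            nrow(fgo$methylome$cpgs), nrow(ngo$methylome$cpgs)))
cat(sprintf("annotation: %d reference genes; %d oocyte genes (%d planted novel, %d planted upstream TSSs)\n",
            nrow(ann_sim$reference$genes), nrow(ann_sim$oocyte$genes),
            length(ann_sim$truth$novel_gene_ids),
            nrow(ann_sim$truth$upstream)))
cat(sprintf("read coverage: %d stranded reads over %d datasets\n",
            nrow(reads$reads), length(unique(reads$reads$dataset))))
cat("tables written to", out, "; raw inputs to", raw, "\n")
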