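#!/usr/bin/env Rscript

# Stage 3: correlate domains with transcription.
#
# Builds read contigs (>= 3 same-strand reads in at least one dataset),
# runs the tiered explanation cascades for HyperDs and HypoDs, bins
# gene-body methylation by FPKM to locate the unmethylated-majority
# crossover, screens for genes escaping gene-body methylation, and
# tests ERVK enrichment in untranscribed HyperDs.

library(methdomain)

sim <- file.path("results", "sim")
out <- file.path("results", "transcription")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fgo <- read_cpg_table(file.path("scratch", "sim", "fgo.cov"), label = "FGO_sim")
ann <- read_gtf(file.path(sim, "oocyte.gtf"))
ref <- read_gtf(file.path(sim, "reference.gtf"))
te <- read_feature_bed(file.path(sim, "te.bed"), "TE")
reads <- read.table(file.path("scratch", "sim", "reads.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
fpkm_tab <- read.table(file.path(sim, "fpkm.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
fpkm <- setNames(fpkm_tab$fpkm_recovered, fpkm_tab$gene_id)
domains <- read_domains(file.path("results", "domains", "domains.bed"))

contigs <- build_contigs(reads)
cat(sprintf("%d contigs from %d reads\n", nrow(contigs), nrow(reads)))

g <- ann$genes
gene_spans <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                         gene_id = g$gene_id,
                         fpkm = unname(fpkm[g$gene_id]))
ref_spans <- data.frame(chrom = ref$genes$chrom,
                        start = ref$genes$start, end = ref$genes$end,
                        fpkm = 1)

hyper <- domains[domains$class == "hyper", , drop = FALSE]
hypo <- domains[domains$class == "hypo", , drop = FALSE]
hx <- explain_hyperds(hyper, ref_spans, gene_spans, contigs)
cat("HyperD tiers (%):",
    paste(sprintf("%s %.1f", names(hx$summary$tier_fractions),
                  100 * hx$summary$tier_fractions), collapse = ", "),
    "\n")
cat(sprintf("untranscribed HyperDs (<5%% overlap): %d (%.1f%%), length-weighted overlap %.1f%%\n",
            hx$summary$n_untranscribed,
            100 * hx$summary$untranscribed_fraction,
            100 * hx$summary$length_weighted_overlap))
px <- explain_hypods(hypo, gene_spans, fpkm, alt_tss_windows(ann))
cat("HypoD tiers (%):",
    paste(sprintf("%s %.1f", names(px$summary$tier_fractions),
                  100 * px$summary$tier_fractions), collapse = ", "),
    "\n")
write.table(hx$per_domain, file.path(out, "hyperd_explain.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(px$per_domain, file.path(out, "hypod_explain.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rel <- fpkm_meth_relation(gene_spans, fgo)
cat(sprintf("FPKM-methylation crossover threshold: %.1f (unmethylated genes dominate below it)\n",
            rel$threshold))
write.table(rel$bins, file.path(out, "fpkm_meth_bins.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

esc <- detect_escapees(gene_spans, fgo)
cat(sprintf("escapee screen: %d candidates, %d confirmed by running windows\n",
            nrow(esc), sum(esc$confirmed)))
write.table(esc, file.path(out, "escapees.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

untr <- hyper[hx$per_domain$untranscribed, , drop = FALSE]
trans_hypo <- hypo[!px$per_domain$transcribed, , drop = FALSE]
if (nrow(untr) && nrow(trans_hypo)) {
  fe <- feature_enrichment(untr, trans_hypo,
                           te[te$family == "ERVK", , drop = FALSE])
  cat(sprintf("ERVK in untranscribed HyperDs vs silent HypoDs: chi-squared %.2f, p %.3g%s\n",
              fe$chisq, fe$p,
              if (fe$low_expected) " (low expected counts)" else ""))
}
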