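#!/usr/bin/env Rscript

# Stage 5: CpG islands and igDMR-like elements.
#
# Classifies CGIs by position relative to the oocyte gene set, calls
# their methylation status (10 CpGs at >= 5 reads), flags transcription
# context (contigs; first kbp downstream of genes), tests methylated
# vs unmethylated intergenic CGIs for contig overlap, and locates a
# set of igDMR-like elements (methylated promoter-overlapping CGIs)
# against both annotations and the domain map.

library(methdomain)

sim <- file.path("results", "sim")
out <- file.path("results", "cgi")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fgo <- read_cpg_table(file.path("scratch", "sim", "fgo.cov"), label = "FGO_sim")
ann <- read_gtf(file.path(sim, "oocyte.gtf"))
ref <- read_gtf(file.path(sim, "reference.gtf"))
cgi <- read_feature_bed(file.path(sim, "cgi.bed"), "CGI")
reads <- read.table(file.path("scratch", "sim", "reads.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
domains <- read_domains(file.path("results", "domains", "domains.bed"))

cgi <- classify_cgi_location(cgi, ann)
cgi <- cgi_meth_status(cgi, fgo)
cat("CGI locations:",
    paste(sprintf("%s=%d", names(table(cgi$location_class)),
                  table(cgi$location_class)), collapse = " "), "\n")
cat("CGI methylation:",
    paste(sprintf("%s=%d", names(table(cgi$meth_status)),
                  table(cgi$meth_status)), collapse = " "), "\n")

contigs <- build_contigs(reads)
ctx <- cgi_transcription_context(cgi, ann, contigs)
cgi <- ctx$cgi
if (!is.null(ctx$intergenic_test)) {
  cat(sprintf("methylated vs unmethylated intergenic CGIs on contig overlap: chi-squared %.2f, p %.3g\n",
              ctx$intergenic_test$chisq, ctx$intergenic_test$p))
} else {
  cat("intergenic CGI contrast skipped:", ctx$note, "\n")
}
write.table(as.data.frame(cgi), file.path(out, "cgi_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# igDMR-like elements: methylated CGIs at reference promoters
ig <- cgi[cgi$meth_status == "hyper" &
            as.character(classify_cgi_location(
              cgi, ref)$location_class) == "tss_associated", ,
          drop = FALSE][c("chrom", "start", "end")]
if (nrow(ig)) {
  igc <- classify_igdmrs(ig, ref, ann, domains)
  cat(sprintf("igDMR-like elements: %d; reference classes: %s; oocyte classes: %s\n",
              nrow(igc),
              paste(sprintf("%s=%d", names(table(igc$ref_class)),
                            table(igc$ref_class)), collapse = " "),
              paste(sprintf("%s=%d", names(table(igc$oocyte_class)),
                            table(igc$oocyte_class)), collapse = " ")))
  write.table(igc, file.path(out, "igdmr_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
} else {
  cat("no methylated promoter CGIs in this simulation\n")
}
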