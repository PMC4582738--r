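#!/usr/bin/env Rscript

# Stage 2: segment the target methylome into HyperDs and HypoDs.
#
# Reads the stage-1 files, builds 50-CpG probes (10-CpG step), merges
# seed probes into domains, refines them (gap merge, opposite-class
# absorption, small-domain removal), subtracts the exclusion masks
# (CGIs, 2-kbp promoter windows, regions already >= 50 % methylated in
# the control), and reports recovery against the planted truth.

library(methdomain)

sim <- file.path("results", "sim")
out <- file.path("results", "domains")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fgo <- read_cpg_table(file.path("scratch", "sim", "fgo.cov"), label = "FGO_sim")
ngo <- read_cpg_table(file.path("scratch", "sim", "ngo.cov"), label = "NGO_sim")
ann <- read_gtf(file.path(sim, "oocyte.gtf"))
cgi <- read_feature_bed(file.path(sim, "cgi.bed"), "CGI")
truth <- read.table(file.path(sim, "truth_domains.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

params <- seg_params(preset = "paper_50_10")
windows <- make_windows(fgo, params)
domains <- refine_domains(raw_domains(windows, params), params)
cat(sprintf("%d probes -> %d domains (%d HyperD, %d HypoD)\n",
            nrow(windows), nrow(domains),
            sum(domains$class == "hyper"),
            sum(domains$class == "hypo")))

# the coupled truth plans hyper blocks explicitly; everything outside
# them is background hypomethylation, so the hypo truth is the
# complement of the hyper blocks
lens <- c(chr1 = 1e7, chr2 = 1e7)
hyper_truth <- truth[truth$class == "hyper", , drop = FALSE]
hypo_truth <- do.call(rbind, lapply(names(lens), function(ch) {
  h <- hyper_truth[hyper_truth$chrom == ch, , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  bounds <- c(0, rbind(h$start, h$end), lens[[ch]])
  gaps <- matrix(bounds, ncol = 2, byrow = TRUE)
  data.frame(chrom = ch, start = gaps[, 1], end = gaps[, 2],
             class = "hypo")[gaps[, 2] > gaps[, 1], ]
}))
full_truth <- rbind(hyper_truth[c("chrom", "start", "end", "class")],
                    hypo_truth)
jac <- jaccard_by_class(domains, full_truth)
cat(sprintf("recovery vs planted truth: Jaccard hyper %.3f, hypo %.3f\n",
            jac[["hyper"]], jac[["hypo"]]))

tssm <- tss_mask(ann)
prem <- premethylated_mask(list(ngo), c(chr1 = 1e7, chr2 = 1e7))
masked <- apply_masks(domains, list(cgi, tssm, prem))
cat(sprintf("masking: %d fragments from %d parents (%d dropped)\n",
            nrow(masked), length(unique(masked$parent_id)),
            nrow(attr(masked, "dropped"))))

stats <- domain_stats(masked, fgo)
write_domains(masked, file.path(out, "domains.bed"), stats = stats)

part <- cpg_partition(fgo, masked,
                      tss_cgi_mask = rbind(cgi[c("chrom", "start", "end")],
                                           tssm[c("chrom", "start", "end")]),
                      control_mask = prem)
write.table(data.frame(category = names(part$fractions),
                       fraction = as.numeric(part$fractions)),
            file.path(out, "cpg_partition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CpG partition (%):",
    paste(sprintf("%s %.1f", names(part$fractions),
                  100 * part$fractions), collapse = ", "), "\n")
len <- masked$end - masked$start
cat(sprintf("HyperD mean %.1f kbp (median %.1f); HypoD mean %.1f kbp (median %.1f)\n",
            mean(len[masked$class == "hyper"]) / 1e3,
            median(len[masked$class == "hyper"]) / 1e3,
            mean(len[masked$class == "hypo"]) / 1e3,
            median(len[masked$class == "hypo"]) / 1e3))
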