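# End-to-end orchestration: simulate (or load) -> window/segment ->
# mask -> transcription overlap -> CGI analysis -> report bundle.

#' Default pipeline configuration
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param preset segmentation preset (`"paper_50_10"` or
#'   `"paper_10_5"`).
#' @param chrom_lengths simulated genome (default two 10-Mbp
#'   chromosomes).
#' @param coupling transcription-to-methylation coupling probability of
#'   the simulated methylome.
#' @param n_genes reference genes to simulate.
#' @param coverage_mean Poisson read depth of the simulated methylome.
#' @param inputs optional named list of file paths (`meth`,
#'   `controls` (vector), `gtf`, `ref_gtf`, `cgi`, `igdmr`) replacing
#'   the simulation stage.
#' @param params optional [seg_params] overriding `preset`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("methdomain_run_"),
                            seed = 1, preset = "paper_50_10",
                            chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                            coupling = 0.9, n_genes = 120,
                            coverage_mean = 15, inputs = NULL,
                            params = NULL) {
  cfg <- list(out_dir = out_dir, seed = seed, preset = preset,
              chrom_lengths = chrom_lengths, coupling = coupling,
              n_genes = n_genes, coverage_mean = coverage_mean,
              inputs = inputs,
              params = if (is.null(params)) seg_params(preset = preset)
              else params)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs[c("meth", "controls", "gtf", "ref_gtf",
                                 "cgi", "igdmr")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Stages run in dependency order: simulate (or load) inputs, build
#' probes and domains, apply exclusion masks, explain domains against
#' transcription, classify CGIs, and write the report bundle (domain
#' BED + TSV, explanation TSV, CGI TSV, JSON summary, log).  Re-running
#' with an identical configuration reproduces the bundle.
#'
#' @param cfg a [pipeline_config] (or a YAML file path of its fields).
#' @return invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    y$chrom_lengths <- unlist(y$chrom_lengths)
    cfg <- do.call(pipeline_config, y)
  }
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }
  seed <- cfg$seed

  if (is.null(cfg$inputs)) {
    say("stage simulate: genome %s bp, seed %d",
        format(sum(cfg$chrom_lengths), big.mark = ","), seed)
    aspec <- annotation_spec(n_genes = cfg$n_genes, seed = seed)
    sim_ann <- simulate_annotation(aspec, cfg$chrom_lengths)
    plan <- coupled_domain_plan(sim_ann$oocyte, cfg$chrom_lengths,
                                coupling = cfg$coupling,
                                seed = seed + 1)
    mspec <- methylome_spec(chrom_lengths = cfg$chrom_lengths,
                            domain_plan = plan,
                            coverage_mean = cfg$coverage_mean,
                            dense_regions = sim_ann$tracks$cgi,
                            seed = seed + 2)
    sim_meth <- simulate_methylome(mspec, label = "FGO_sim")
    meth <- sim_meth$methylome
    controls <- list(simulate_methylome(
      methylome_spec(chrom_lengths = cfg$chrom_lengths,
                     domain_plan = NULL, background_meth = 5,
                     coverage_mean = cfg$coverage_mean,
                     dense_regions = sim_ann$tracks$cgi,
                     seed = seed + 3), label = "NGO_sim")$methylome)
    ann <- sim_ann$oocyte
    ref <- sim_ann$reference
    cgi <- sim_ann$tracks$cgi
    igdmr <- cgi[0, , drop = FALSE]
    fpkm <- sim_ann$fpkm
    rc <- simulate_read_coverage(ann, fpkm, seed = seed + 4)
    reads <- rc$reads
    truth <- list(plan = plan, annotation = sim_ann$truth)
  } else {
    say("stage load: reading inputs")
    meth <- read_cpg_table(cfg$inputs$meth)
    controls <- lapply(cfg$inputs$controls, read_cpg_table)
    ann <- read_gtf(cfg$inputs$gtf)
    ref <- read_gtf(cfg$inputs$ref_gtf)
    cgi <- read_feature_bed(cfg$inputs$cgi, "CGI")
    igdmr <- if (!is.null(cfg$inputs$igdmr))
      read_feature_bed(cfg$inputs$igdmr, "igDMR") else cgi[0, ]
    fpkm <- setNames(rep(1, nrow(ann$genes)), ann$genes$gene_id)
    reads <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        dataset = character())
    truth <- NULL
  }

  say("stage call: preset %s", cfg$preset)
  windows <- make_windows(meth, cfg$params)
  say("  %d probes", nrow(windows))
  raw <- raw_domains(windows, cfg$params)
  domains <- refine_domains(raw, cfg$params)
  say("  %d raw runs -> %d refined domains (%d hyper, %d hypo)",
      nrow(raw), nrow(domains), sum(domains$class == "hyper"),
      sum(domains$class == "hypo"))

  say("stage mask")
  tssm <- tss_mask(ann)
  prem <- premethylated_mask(controls, cfg$chrom_lengths)
  masked <- apply_masks(domains, list(cgi, tssm, prem))
  say("  %d fragments after masking (%d parents dropped)",
      nrow(masked), nrow(attr(masked, "dropped")))

  say("stage explain")
  contigs <- build_contigs(reads)
  genes <- ann$genes
  genes$fpkm <- unname(fpkm[genes$gene_id])
  gene_spans <- data.frame(chrom = genes$chrom, start = genes$start,
                           end = genes$end, gene_id = genes$gene_id,
                           fpkm = genes$fpkm)
  ref_spans <- data.frame(chrom = ref$genes$chrom,
                          start = ref$genes$start, end = ref$genes$end,
                          fpkm = 1)
  hyper <- masked[masked$class == "hyper", , drop = FALSE]
  hypo <- masked[masked$class == "hypo", , drop = FALSE]
  hyp_ex <- if (nrow(hyper)) explain_hyperds(hyper, ref_spans,
                                             gene_spans, contigs)
  else NULL
  alt_win <- alt_tss_windows(ann)
  hypo_ex <- if (nrow(hypo)) explain_hypods(hypo, gene_spans,
                                            fpkm, alt_win)
  else NULL

  say("stage cgi")
  cgi_cls <- classify_cgi_location(cgi, ann)
  cgi_cls <- cgi_meth_status(cgi_cls, meth)
  escapees <- detect_escapees(gene_spans, meth)
  stats <- domain_stats(masked, meth)
  part <- cpg_partition(meth, masked,
                        tss_cgi_mask = reduce_intervals(rbind(
                          cgi[c("chrom", "start", "end")],
                          tssm[c("chrom", "start", "end")])),
                        control_mask = prem)

  say("stage report")
  write_domains(masked, file.path(cfg$out_dir, "domains.bed"),
                stats = stats)
  if (!is.null(hyp_ex))
    write.table(hyp_ex$per_domain,
                file.path(cfg$out_dir, "hyperd_explain.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hypo_ex))
    write.table(hypo_ex$per_domain,
                file.path(cfg$out_dir, "hypod_explain.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cgi_cls),
              file.path(cfg$out_dir, "cgi_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  len <- masked$end - masked$start
  summary <- list(
    seed = seed, preset = cfg$preset,
    n_domains = nrow(masked),
    n_hyperd = sum(masked$class == "hyper"),
    n_hypod = sum(masked$class == "hypo"),
    mean_hyperd_len = mean(len[masked$class == "hyper"]),
    median_hyperd_len = median(len[masked$class == "hyper"]),
    mean_hypod_len = mean(len[masked$class == "hypo"]),
    median_hypod_len = median(len[masked$class == "hypo"]),
    cpg_fractions = as.list(part$fractions),
    hyperd_tier_fractions = if (!is.null(hyp_ex))
      as.list(hyp_ex$summary$tier_fractions) else NULL,
    hypod_tier_fractions = if (!is.null(hypo_ex))
      as.list(hypo_ex$summary$tier_fractions) else NULL,
    cgi_location_counts = as.list(table(cgi_cls$location_class)),
    cgi_status_counts = as.list(table(cgi_cls$meth_status)),
    n_escapees = sum(escapees$confirmed))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
  invisible(list(summary = summary, domains = masked, truth = truth,
                 windows = windows, explain_hyper = hyp_ex,
                 explain_hypo = hypo_ex, cgi = cgi_cls,
                 escapees = escapees, log = log_lines))
}
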