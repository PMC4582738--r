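---
title: "Methods: methylome domain segmentation and its correlation with transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome domain segmentation and its correlation with transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In growing mouse oocytes, de novo DNA methylation is laid down while the
cell is transcriptionally highly active, and gene bodies — rather than
promoters — are the main substrate of methylation.  The genome of a fully
grown oocyte is partitioned into large blocks of concordant CpG
methylation: hypermethylated domains (HyperDs, around 90 % methylated)
and hypomethylated domains (HypoDs, around 10 %).  If transcription
drives methylation, HyperDs should coincide with active transcription
units, methylated CpG islands (CGIs) should be intragenic, and genes
expressed below some threshold should fail to methylate.  `methdomain`
implements the computational side of that analysis as a reusable,
testable pipeline: domain segmentation from per-CpG bisulfite counts,
exclusion masking, tiered overlap of domains with transcription
evidence, curation of a de novo transcriptome assembly, and CGI/igDMR
classification — together with a seeded simulator that generates all
inputs with planted truth.

## The segmentation model

The caller never models methylation probabilistically; it is a windowing
and merging procedure whose parameters are biological length scales.

1. **Probes.**  Within each chromosome, CpGs with at least one read are
   taken in order and grouped into probes of `window_n_cpgs = 50`
   consecutive CpGs, advancing by `step_n_cpgs = 10`.  A probe's
   methylation is the mean per-CpG methylation over member CpGs covered
   by at least `min_reads_per_cpg = 5` reads, and is defined only when
   at least `min_scored_cpgs = 3` such CpGs exist.  A trailing stretch
   shorter than one probe yields no probe.  An alternative preset
   (`paper_10_5`) uses 10-CpG probes with a 5-CpG step for a
   finer-grained map.
2. **Seeds and raw domains.**  Probes above `hyper_cut = 75` % are
   hyper seeds, below `hypo_cut = 25` % hypo seeds (strict
   inequalities; intermediate and unscored probes are ignored).
   Overlapping or bookended same-class seeds are unioned; where a hyper
   run overlaps a hypo run the shared span is cut at its floored
   midpoint, left part to the left domain.
3. **Refinement**, in this exact order: (i) merge same-class neighbours
   whose gap is below `merge_gap = 2` kbp; (ii) delete an opposite-class
   domain shorter than `opposite_absorb_max = 1` kbp sitting between two
   same-class domains, incorporating its span; (iii) remove domains
   shorter than `min_domain_len = 2` kbp; (iv) merge again.  The whole
   refinement is idempotent, which the tests check on a thousand random
   inputs.
4. **Exclusion masking.**  For correlation with transcription, CGIs,
   2-kbp promoter windows downstream of each gene's most upstream TSS,
   and 1-kbp tiles that are already ≥ 50 % methylated in any control
   methylome (non-growing oocytes, DNMT3A/3L-deficient oocytes; each
   tile scored from ≥ 3 CpGs with ≥ 3 reads) are subtracted from the
   domains.  Fragments keep their class and their parent domain's
   identifier, and fragments below 2 kbp survive masking — lineage, not
   length, is what matters after this point.

Two readings of the procedure were genuinely open and are resolved as
follows.  Seed selection uses strict inequalities (the > 75 / < 25
wording of the procedure), while CpG- and CGI-level status calls use
inclusive thresholds (≥ 75 / ≤ 25); both cutoffs are plain parameters.
Masking is applied *after* refinement, so domain counts can be read
either pre-masking or post-masking through the parent lineage.
Gaps are measured as `next.start − prev.end` on half-open intervals, and
the midpoint split uses `floor((s + e) / 2)` as a deterministic
tie-break.

## Transcription overlap

Domain-versus-transcription overlap is strand-agnostic (DNA methylation
is strand-symmetric); read-contig construction is strand-aware.  A
*contig* is a maximal run with at least three same-strand reads in at
least one dataset.

HyperDs are explained by a cumulative evidence cascade — expressed
reference genes (FPKM > 0.001), plus the oocyte assembly, plus contigs,
plus regions of partial methylation in the controls — and each domain is
assigned the first tier whose cumulative overlap exceeds half of its
length.  A domain whose assembly-plus-contig overlap is below 5 % is
flagged untranscribed.  Cumulative fractions are monotone along the
cascade and the tier assignment partitions the domains; both are tested
properties.

HypoDs overlapping the assembly for more than half their length are
*transcribed* and subdivided: if the majority of their transcribed bases
come from genes below 0.5 FPKM they are attributed to weak
transcription; else if they are mostly covered by 2-kbp windows
downstream of alternative/downstream TSSs they are attributed to
internal promoters; the remainder stays unexplained.  The 0.5 FPKM
value itself is recoverable from the data: gene bodies (scored from
≥ 3 CpGs at ≥ 3 reads) are binned by FPKM in 0.1-wide bins and the
threshold is the upper edge of the last bin in which unmethylated genes
(< 25 %) outnumber methylated ones (> 75 %).

*Escapees* — expressed genes that stay unmethylated — are screened as
genes with FPKM > 1, length ≥ 10 kbp and gene-body methylation < 25 %,
then confirmed with a running-window scan.  The window geometry
(10-kbp windows, 5-kbp step, every scored window below 25 %, at least
80 % of windows scored) is this package's concretisation of a running
window strategy; the published analyses do not pin these numbers down,
so all four are arguments.

Enrichment contrasts (for instance ERVK elements in untranscribed
HyperDs) use Pearson's chi-squared on the 2×2 overlap table without
continuity correction — counts in this setting are large — and the
result carries a flag when any expected cell drops below 5.

## Assembly curation

The curation stage consumes already-assembled annotations (GTF); it does
not re-run an assembler.  Mono-exonic transcripts, the most
artefact-prone class, pass four rules in order: (a) drop transcripts
without strand information; (b) drop those lying wholly inside an
intron of a multi-exonic transcript on the same strand (nascent-RNA
remnants); (c) merge those starting within 2 kbp downstream of a
multi-exonic transcript's 3′ end into that transcript, iterating to a
fixpoint so chains of fragments collapse; (d) drop mono-exonic genes
whose depth-normalised read count (counts per million) fails a
threshold derived from random size-matched intergenic regions.  The
rule-(d) threshold is the *CDF-gap* point: both empirical distributions
are evaluated on the pooled grid and the threshold maximises
`CDF(intergenic) − CDF(transcripts)`, ties toward the smaller value —
the same construction used to strip non-transcribed reference
transcripts from reference-guided assemblies.  Because the threshold is
derived from the read-support table rather than from the surviving
annotation, re-running the curation on its own output changes nothing.

Transcripts are classified against the reference with simplified
Cuffcompare semantics (`=`, `c`, `j`, `o` reference; `i`, `u`, `x`
novel), and novel genes are accepted only when far enough, on the same
strand, from reference genes and known ncRNAs (± 1 kbp multi-exonic,
± 5 kbp mono-exonic, measured span to span) and, for mono-exonic genes,
not ≥ 50 % covered by a single transposable element.  The 50 % single-TE
coverage rule is a package choice — "representing an expressed
independent repeat" has no published number — and is configurable.
Novel upstream TSSs of reference genes require a start (i) upstream of
the reference gene's most upstream TSS on the same strand, (ii) in an
exon that shares no base with the gene's reference exons, and
(iii) outside every CGI associated with the reference TSS (± 100 bp).
TSSs are CGI-associated if their first base ± 100 bp touches a CGI,
else TE-associated if the first base lies in a same-strand TE, and
TE-family enrichment is judged against each family's share of
intergenic bases (seeded Monte-Carlo placement plus a binomial test).

## CGIs and igDMRs

CGIs are classified into four disjoint location classes: overlapping a
gene's most upstream TSS ± 100 bp; intragenic but overlapping an
internal transcript TSS ± 100 bp; otherwise intragenic; otherwise
intergenic.  The published location rule defines three classes; the
fourth (alternative/downstream TSS) is derived from transcript-level
TSSs with the same ± 100 bp flank, chosen for symmetry.  Methylation
status needs ten CpGs at five reads and uses inclusive thresholds.
igDMRs are located independently against the reference and the oocyte
annotation — the informative pattern is an igDMR that is a promoter in
the reference but intragenic in the oocyte assembly, or intergenic in
both yet inside a HyperD.

## What the simulator emulates — and what it does not

The generator is first-class, tested code; its defaults are the study
conditions used everywhere.

* **Methylome** (`simulate_methylome`): two 10-Mbp chromosomes, CpGs as
  a geometric renewal process at 1/100 bp (optionally densified to
  1/10 bp inside a CGI track), domain-structured targets (90 % / 10 %),
  per-CpG Beta noise with concentration 50 — reproducing the strongly
  bimodal per-CpG methylation of real oocyte methylomes — and
  Binomial(Poisson(15)) counts.  Mean domain length 30 kbp (log-normal,
  minimum 10 kbp) in the alternating plan; in *coupled mode* the hyper
  blocks are the transcribed blocks of an annotation, each methylated
  with probability 0.9.
* **Annotation** (`simulate_annotation`): 120 non-overlapping reference
  genes (5–60 kbp, ≥ 12 kbp apart), an oocyte assembly that copies
  them and plants 15 novel upstream TSSs (4–8 kbp upstream, in a novel
  first exon splicing back into the gene), 15 + 15 novel multi-/
  mono-exonic genes placed at twice the exclusion-rule margins, a
  promoter CGI for 60 % of genes plus 40 intergenic CGIs, and a TE
  landscape that avoids the planted novel genes so the repeat rule has
  an unambiguous answer.
* **Reads** (`simulate_read_coverage`): read counts per gene follow the
  FPKM identity `reads = FPKM · L · N / 10⁹`; starts are uniform over
  exonic bases and clipped to the exon.

What passing tests on this material shows is that the *rules* are
implemented faithfully and recover planted structure at the stated
margins (domain Jaccard ≥ 0.95; curation precision/recall ≥ 0.95;
assembly-tier explanation ≥ 0.85 under 0.9 coupling).  What it cannot
show: the simulator has no dose–response between expression level and
methylation (coupling is all-or-none, so the FPKM crossover of the
binned analysis is only exercised by a purpose-built fixture), no
partially methylated control structure, no sequencing or mapping error,
no strand bias, and CpG placement outside CGIs is homogeneous where
real genomes are not.  Conclusions about real data still require real
data.

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open everywhere; GTF and Bismark
coverage are converted at the boundary, and CpGs are strand-combined
units keyed by the C position on the plus strand, matching merged
Bismark coverage practice.  Duplicate CpG rows are summed on load.
Windows never bridge chromosomes.  Empty inputs return empty,
well-typed results rather than errors wherever a downstream stage could
legitimately see them (empty methylome, empty mask, empty igDMR track);
errors are reserved for contract violations (negative counts,
zero-length domains, mixed-strand transcripts, missing read support,
infeasible placement densities).  The chi-squared statistic is defined
as 0 with p = 1 when a margin of the 2×2 table is empty.  All
simulation is seeded, and the pipeline derives stage seeds from one
master seed so a configuration reproduces its whole report bundle
byte for byte.

Problem sizes used by the test-suite and the acceptance script — a
2 × 10 Mbp genome (~200,000 CpGs), 500 random chromosomes of ≤ 300 CpGs
for the oracle-equivalence check, 1000 random refinement inputs, and
100 CDF-gap trials — were chosen so the full run completes in a few
minutes on one core while keeping every statistical bound comfortably
away from its noise floor.

## Known limitations

The midpoint split and absorption rules are order-deterministic but not
the only defensible reading of the published procedure; both the strict
and inclusive threshold variants are exposed as parameters.  The
curation stage expresses the re-integration of assembler-dropped
transcripts as a generic patch-restore rule
(`reconcile_annotations`) rather than reproducing any assembler's
internals.  GC content requires caller-supplied sequences; no genome
FASTA handling beyond plain per-chromosome strings is attempted.
Repeat-expression quantification, coding-potential prediction and
ortholog/GO analyses are out of scope.
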