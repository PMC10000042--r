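# medseqr

Cell-free DNA (cfDNA) methylation analysis for MeD-seq data — sequencing
libraries produced by the methylation-dependent restriction enzyme **LpnPI**
— with a reference-panel methylation score and survival association, as used
to ask whether circulating tumor DNA methylation predicts disease
progression in renal cell carcinoma (RCC) patients under watchful waiting.

The package is aimed at computational biologists working with
methylation-dependent restriction enzyme sequencing of liquid biopsies. It
covers the full chain from reads to clinical statistics, and ships a
synthetic cohort simulator so that every stage is testable without access
to patient data.

## The method

**Assay model.** LpnPI binds (hydroxy)methylated cytosines in the contexts
G**mC**GC, C**mC**G and **mC**GG and cuts 16 bp upstream, releasing a 32 bp
fragment centred on the recognized cytosine; the enzyme is blocked when a
cut would create a fragment shorter than 32 bp. Fragments are sequenced as
50 bp single-end reads, so genuine digestion products show a recognition
context 13–17 bp from a read end. Processing is:

1. adapter trimming, then the 13–17 bp **LpnPI filter** (`lpnpi_filter()`);
2. unique placement on the genome (`place_reads()`: built-in exact mapper
   for synthetic genomes, or SAM/BAM ingestion with MAPQ ≥ 20) and
   assignment of a count to each individual LpnPI site (`count_sites()`);
3. summarization into 2 kb windows around transcription start sites,
   keeping windows with data in ≥ 75% of samples, normalization to each
   sample's filter-passing read total and a square-root transform
   (`build_tss_windows()`, `summarize_regions()`, `presence_filter()`,
   `normalize_and_sqrt()`).

**Marker panel.** Differentially methylated regions (DMRs) between patients
and healthy blood donors (HBDs) are called with a two-group empirical-Bayes
moderated *t*-statistic: the pooled region variance *s²* (d residual df) is
shrunk towards a prior (*d₀*, *s₀²*) fitted by method of moments on the log
sample variances, giving the moderated variance
*s̃² = (d₀s₀² + d s²)/(d₀ + d)* and *t = Δx̄ / (s̃·√(1/n₁+1/n₂))* on
*d₀ + d* df. Regions at Benjamini–Hochberg FDR < 0.1 are intersected with a
literature marker list to form the panel (`moderated_t()`, `bh_fdr()`,
`select_dmrs()`, `intersect_markers()`).

**Methylation score.** For each sample, per panel region
*z_r = (x_r − μ_r)/σ_r* against the HBD reference panel (mean and n−1 SD of
the HBD values), and the score is *S = Σ_r z_r²*. HBDs are scored
leave-one-out; the positivity cutoff is the upper limit of the 95% interval
of the HBD scores, *T = mean + 1.96·SD*; a sample is methylation-positive
iff *S > T* (`reference_stats()`, `methylation_score()`,
`positivity_threshold()`, `call_positive()`).

**Clinical association.** Group comparisons (Fisher exact, chi-square,
Mann–Whitney U) and time-to-event analysis of watchful-waiting time and
progression-free survival: Kaplan–Meier curves, the log-rank test, and
univariate Cox proportional hazards with Breslow ties and Wald intervals
(`fisher_exact_2x2()`, `cox_univariate()`, `logrank()`, `km_curve()`).

**Simulator.** `simulate_genome()` builds a CpG-free background with
planted LpnPI sites around each TSS (so all recognition contexts are known),
`make_methylome()` sets baseline/tumor methylation probabilities,
`simulate_reads()` performs per-molecule in silico digestion with blocking
and mixes tumor and leukocyte methylomes at a per-patient tumor fraction,
and `simulate_cohort()` adds exponential survival times whose hazard
increases with tumor fraction.

## Worked example

```r
library(medseqr)

genome    <- simulate_genome(n_tss = 30, spacing = 5000, seed = 424)
markers   <- sprintf("tss%03d", c(3, 8, 13, 18, 23, 28))
methylome <- make_methylome(genome, marker_tss = markers,
                            baseline_prob = 0.1, effect = 0.8)
lit <- data.frame(chrom = "chrS",
                  start = genome$tss$pos[c(3, 8, 13, 18, 23, 28)] - 1000L,
                  end   = genome$tss$pos[c(3, 8, 13, 18, 23, 28)] + 1000L,
                  name  = sprintf("MARK%02d", 1:6))

spec <- cohort_spec(n_patients = 24, n_hbd = 8,
                    tumor_fraction = rep(c(0.3, 0.02), 12),
                    depth = 1500, hazard_coefficient = log(3),
                    censoring_rate = 0.1, seed = 101)
sim <- simulate_cohort(spec, genome, methylome)
res <- run_medseq_pipeline(sim, genome, lit)

nrow(res$panel)     # 6     -- all planted markers recovered as DMRs
res$scoring$threshold
res$cox_pfs
```

Printed on this run:

```
[1] 6
[1] 63.54971
<cox_fit> methylation score positive: HR 12.91 (95% CI 2.70-61.82), p = 0.001369, 21 events/24
```

i.e. the six hypermethylated marker windows pass the FDR < 0.1 moderated-t
screen and the literature intersection, and patients whose Z²-sum score
exceeds the HBD-derived cutoff progress markedly faster — the direction the
method is designed to detect (the magnitude reflects the strong planted
effect, not a clinical estimate).

A thin command-line front-end over the same functions is installed at
`inst/cli/medseqr.R` (subcommands `simulate`, `process-reads`, `matrix`,
`dmr`, `score`, `associate`).

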