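---
title: "MeD-seq cfDNA methylation scoring: model, assumptions and design choices"
author: "medseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MeD-seq cfDNA methylation scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medseqr)
```

## The problem

Cell-free DNA in blood carries a small tumor-derived fraction whose
methylation patterns differ from the leukocyte background that dominates
cfDNA. MeD-seq interrogates those patterns with the methylation-dependent
restriction enzyme LpnPI, which binds (hydroxy)methylated cytosines in the
contexts GmCGC, CmCG and mCGG, cuts 16 bp upstream, and releases a 32 bp
fragment centred on the recognized cytosine. Because the enzyme is blocked
by fragments shorter than 32 bp, methylation-dense DNA is not
over-digested. Read yield at a site is therefore a monotone readout of the
methylation level at that site. `medseqr` implements the full analysis —
read filtering, per-site counting, TSS-window matrices, marker selection, a
reference-panel methylation score, and survival association — together with
a simulator that generates data with exactly the statistical structure the
analysis assumes.

## Digestion and read model

`digest()` scans methylated sites left to right and accepts a cut only when
the recognized cytosine lies at least 32 bp from the previously accepted
one; unmethylated sites never cut, and sites within 16 bp of a molecule end
are dropped (with a counter) rather than emitted as truncated fragments.
The scanning order is a modelling choice — the enzyme kinetics are not
ordered — but a deterministic greedy scan makes blocking reproducible and
testable. An accepted cut yields the fragment `[pos - 16, pos + 16)`.

Simulated reads are the plus-strand fragment sequence followed by a fixed
18 bp adapter, giving 50 bp reads with the recognized cytosine 16 bp from
the fragment-side end — inside the 13–17 bp filter window with margin for
over-trimming. Every CpG carries a recognized cytosine on both strands
(CmCG pairs with mCGG at the complementary G; GmCGC is its own reverse
complement), so recognition sites occur in plus/minus pairs one base apart.
The simulator draws one methylation state per CpG pair per molecule
(symmetric CpG methylation); blocking then emits a single fragment per
methylated CpG, anchored at the plus-strand member.

The filter offset convention is a documented choice: the distance is the
0-based gap between the read end and the recognized cytosine, inclusive
bounds 13–17 on either end, both strands scanned. Reads with several
compliant sites are counted once, to the site closest to the 5' end.

## What the simulator emulates — and what it does not

The synthetic chromosome has a CpG-free background (a Markov generator that
never emits G after C), so every LpnPI context is planted deliberately:
`sites_per_tss` sites spread over ±800 bp of each TSS, spaced widely enough
(~145 bp) that blocking between neighbouring planted sites is negligible.
This mirrors the CpG depletion of real genomes and makes ground truth exact
— an off-target read drawn from site-free sequence can essentially never
pass the filter, so the realized off-target pass rate directly measures
filter specificity.

Per-sample methylation is a two-component mixture: effective site
probability `(1 - f) * baseline + f * tumor`, with `f` the tumor fraction
(0 for healthy blood donors). Defaults are baseline 0.1 everywhere and
tumor 0.9 at hypermethylated marker windows (an effect of +0.8), i.e. a
strong, cleanly localized marker signal; `depth` is calibrated so a fully
healthy sample yields the requested number of filter-passing reads, and
more methylated samples yield proportionally more, as in the real assay.
Tumor fractions in serum are left as a parameter (`tumor_fraction`, or a
Beta(0.8, 8) draw concentrated near zero) because their real-world
distribution is poorly characterized.

Not modelled: sequencing errors, base qualities, paired ends, fragment-size
variation of cfDNA, multiple chromosomes, duplicate reads, and
hydroxymethylation as a separate state (the enzyme does not distinguish
it). Passing tests on this generator therefore demonstrate correctness of
the pipeline's logic and statistics under its assumptions, not robustness
to real-data artefacts such as mapping bias or error-induced filter
leakage.

Survival times are exponential with hazard `h0 * exp(beta * x)` where
`x` is the standardized `log1p(100 f)` — a monotone transform that keeps
hazard ratios finite at `f = 0` — and `h0 = log(2)/12` gives a 12-month
median at the cohort centre. Censoring is independent exponential,
calibrated to the requested censoring rate.

## Matrix construction

TSS windows are strand-ignorant `[TSS - 1000, TSS + 1000)` intervals
(0-based half-open), clipped and flagged at chromosome ends. Overlapping
windows each count shared sites; no deduplication of same-gene windows is
attempted. "Containing data" in the presence filter means a nonzero raw
count — zero and missing are indistinguishable in count data — and the
comparison is `>=`, so a region present in exactly 75% of samples is kept.
Normalization divides by each sample's total of filter-passing reads (not
the matrix row sum) times a scale constant of 1e6; the scale is
conventional (counts per million) and cancels in the Z-scores downstream.
The square root stabilizes the right-skewed count distribution. The
pipeline order raw → presence filter → normalize → sqrt is fixed and
recorded in the object's `state_history`.

## Differential methylation

The DMR statistic is a two-group empirical-Bayes moderated t. Per region,
the pooled variance `s^2` on `d = n1 + n2 - 2` df is shrunk towards a prior
`(d0, s0^2)` estimated by method of moments on `log s^2` across regions
(Smyth's estimator: excess spread of the log variances beyond
`trigamma(d/2)` determines `d0` through the inverse trigamma; no excess
spread gives `d0 = Inf` and collapses every variance to the mean sample
variance). The statistic uses `d0 + d` df. DMR calls are made on the
sqrt-transformed matrix — the transform order implies the transformed scale
is the analysis scale — and use a strict `q < 0.1` cut. The panel is the
overlap (>= 1 bp, the least restrictive defensible rule) between DMRs and a
literature marker list; a synthetic 53-region placeholder list ships in
`inst/extdata/synthetic_literature_markers.bed` for examples, matching the
deterministic TSS grid of the simulator.

With the prior off (`prior = "none"`), the statistic reduces exactly to the
ordinary pooled two-sample t — the identity the test suite checks to 1e-10
— and the empirical-Bayes path is cross-checked against an independent
reference implementation on heteroskedastic data.

## The methylation score

Z-scores are computed against the per-region mean and n−1 SD of the HBD
panel, squared and summed. Three choices deserve comment:

* **Leave-one-out HBD scores.** Scoring an HBD against a panel containing
  itself deflates its score (its value pulls the reference mean towards
  itself). Each HBD is therefore scored against the other n−1 donors before
  the cutoff is computed.
* **The cutoff** is `mean + 1.96 SD` of the HBD scores — a normal-range
  upper bound, not a confidence interval of the mean. With 10 donors a
  CI-of-the-mean bound would sit inside the HBD score cloud and flag half
  the donors; a positivity cutoff must bound the donor distribution itself.
* **Degenerate regions.** Zero-SD reference regions are excluded from the
  sum (avoiding infinite Z) and reported; panel regions missing in a sample
  contribute 0, which can only shrink a score, never inflate it. A score
  exactly at the cutoff is negative.

For a null sample from the same population as an n-donor reference, each
region contributes `E[z^2] = (1 + 1/n)(n - 1)/(n - 3)`; the suite checks the
Monte-Carlo mean of the score against this closed form within 15%.

## Survival statistics

Standard estimators are used behind the module surface: Cox proportional
hazards with Breslow tie handling (Efron available) and Wald 95% intervals,
the log-rank test, the product-limit estimator, Fisher's exact test,
Pearson chi-square without continuity correction, and the Mann–Whitney U
test (exact for small untied samples, otherwise normal approximation with
tie correction). Median follow-up is offered both as reverse Kaplan–Meier
and as a plain median, since the estimator behind such summaries is often
unstated. Perfect separation in the Cox fit is flagged as non-convergence
rather than silently reported.

## Numerical choices and degenerate inputs

* All randomness flows through one explicit seed per call; the caller's RNG
  state is restored afterwards.
* The inverse trigamma uses Newton iteration with asymptotic start values
  (relative tolerance 1e-10).
* Zero-variance regions with a zero prior yield `p = NA` and are excluded
  from BH ranking; NA q-values propagate.
* Ambiguous (multi-hit) and unmapped reads are dropped and counted
  separately; placed reads with no site at a window-compliant offset
  increment a mismatch counter. The identity
  `counted + ambiguous + unmapped + mismatch = filtered` is asserted in the
  suite.
* Adapter trimming is exact-match with a minimum overlap of 3 and iterates
  to a fixed point, making it idempotent; reads trimmed to length zero are
  flagged discarded.

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to make their Monte-Carlo
error small relative to the margins being asserted: filter concordance on
10,000 on-target plus 10,000 random reads; type-I error over 50 null
replicates of a 10 vs 10, 500-region matrix; score specificity averaged
over 20 reference panels of 10 donors with 250 fresh null samples each
(a single panel's cutoff is itself a random quantity, so one panel's
specificity estimate is noisy);
Cox recovery as the mean over 20 replicates of n = 500; and the end-to-end
check over 50 replicate cohorts (24 patients, 8 HBDs, depth 1500, one
30-TSS genome shared across replicates with fresh read and cohort draws).

## Known limitations

The exact mapper requires perfect sequence identity, so it is only suitable
for synthetic genomes; real data should be aligned externally and ingested
via SAM/BAM, where "unambiguously mapped" is operationalized as mapped,
not secondary/supplementary, MAPQ >= 20. The moderated t supports two
groups only, not arbitrary design matrices. The cohort-level findings of
any particular study (specific marker panels, hazard ratios, positivity
rates) depend on their data and are not reproduced by the synthetic
pipeline; what the package establishes is that every stage computes what it
claims on data whose ground truth is known.
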