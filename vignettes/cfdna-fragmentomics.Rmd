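---
title: "Whole-genome cfDNA fragmentomics: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome cfDNA fragmentomics: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffeatures)
```

## Background

Cell-free DNA (cfDNA) in plasma is released predominantly by apoptotic,
nucleosome-protected cleavage, which leaves a characteristic fragment-size
distribution: a dominant mononucleosomal mode near 167 bp, a ~10 bp
periodicity on its left shoulder, and a dinucleosomal shoulder near 334 bp.
Tumour-derived cfDNA perturbs this picture in several measurable ways:
fragments are shorter on average, coverage redistributes along the genome
with somatic copy number, nucleosome protection is lost around the
transcription start sites (TSS) of genes active in the tissue of origin,
and the diversity of fragment lengths around active promoters increases.
Pre-analytical accidents leave their own signature: hemolysis contaminates
plasma with long genomic DNA (rising steeply above 150 bp) and an excess of
very short reads.

`cffeatures` extracts these whole-genome features from coordinate-sorted
aligned fragments and combines them in a cross-validated
cancer-versus-healthy classifier. Every stage is testable without patient
data through a seeded fragment simulator that carries ground truth for each
simulated entity.

## Conventions

Coordinates are 0-based half-open (BED convention) everywhere; BAM's
1-based positions are converted on read. A *fragment* is the outer span of
a properly paired sequencing template; single-end and improper pairs are
excluded, because fragment length is the core measurand. Default filters:
mapping quality >= 30, duplicates removed, lengths 30-1000 bp for binned
profiles but 30 bp-unbounded for QC histograms so that long
hemolysis-derived fragments remain visible. These read-filter settings are
package choices, configurable per call.

## Size QC and the hemolysis flag

`size_histogram()` counts fragment lengths at 1-bp resolution, pooling
lengths >= 1000 bp into an overflow class. `size_fractions()` reports the
fractions in the 30-80, 80-150, 150-220, 220-1000 and >= 1000 bp ranges.
Published range labels share their endpoints, so each range is half-open
`[lo, hi)`: a 150 bp fragment belongs to the 150-220 range. The five
fractions partition every retained fragment and sum to one.

`hemolysis_flag()` computes the genome-wide ratio of short (100-150 bp) to
long (151-220 bp) fragment counts and flags the sample when the ratio falls
strictly below 0.05. The threshold is configurable; the choice of *which*
size ratio the rule applies to is a documented interpretation (the same
short/long family used by the binned profiles), not a fixed fact of the
underlying protocol, and samples with no long-window fragments are flagged
with reason "degenerate size profile" rather than given an undefined ratio.

## Binned fragmentation profiles

The genome is tiled into 5 Mb half-open bins (`make_bins()`), the scale at
which fragment-size-ratio profiles are conventionally reported. A terminal
remainder is kept, flagged partial, only when it spans at least half a bin;
smaller remainders would contribute high-variance counts. Fragments are
assigned to bins by their midpoint, which gives every fragment exactly one
bin without overlap bookkeeping.

Per bin and per sample, `sample_profile()` counts short (100-150 bp) and
long (151-220 bp) fragments — 150 bp is assigned to the short window so the
windows stay disjoint; the assignment is configurable — and GC-corrects
short, long and total counts separately with a loess fit of count on bin GC
fraction (span 0.75, degree 2). The corrected value is
`value - fit(gc) + mean(fit)`; using the mean of the fitted values as the
restored level preserves the total exactly, and a constant GC covariate
makes the correction the identity. Whether short and long counts should be
corrected separately or the ratio corrected directly is not standardised in
the field; separate correction is implemented because the two size classes
have genuinely different GC composition.

From the corrected counts come the per-bin ratio (short/long), the
normalized ratio (per-sample mean-centering only — "mean ratio = 0" is a
statement about the mean, so no variance scaling is applied by default;
z-scaling sits behind the `scale_ratio` flag), and the fragment fraction
(corrected totals normalised to sum to one, which also makes downstream
copy-number scores library-size invariant). Bins with no long fragments or
non-positive corrected counts are masked.

`cohort_similarity()` computes pairwise Pearson correlations across samples
and each sample's correlation to the healthy-median reference profile
(per-bin median over healthy samples). Bins masked in any sample are
dropped cohort-wide so every correlation shares the same support; groups
are compared with a two-sided Wilcoxon rank-sum test.

## Copy-number scores

`cnv_scores()` scores each bin as `log2(fraction / panel median fraction)`
with a panel z-score alongside, the standard shallow-WGS formulation; the
healthy cohort doubles as the reference panel (>= 3 samples). Bins with
zero panel median or zero panel spread are masked. In healthy plasma the
scores concentrate around zero; copy-number-altered tumours disperse them,
which `cohort_variance_test()` quantifies as a rank-sum test on per-sample
score variances.

`call_amplified_genes()` maps genes to the bins overlapping their spans,
scores each sample at each gene by the mean `log2_ratio` over those bins,
compares cancer and healthy per gene (two-sided Wilcoxon), adjusts across
genes with Benjamini-Hochberg, and calls a gene amplified when `q < 0.05`
*and* the cancer mean exceeds the healthy mean. The per-gene
rank-sum-plus-BH procedure is this package's operationalisation of
"significantly amplified genes"; segmentation and absolute copy number are
out of scope. Because fractions sum to one, genuine amplifications push
unaffected bins slightly below the panel median, and the direction
condition then keeps those bins from ever being called amplified — a useful
structural guard on the false-call rate.

## TSS relative coverage and chromatin state

For each gene, three relative coverages are computed from strand-oriented
windows around the TSS (`tss_relative_coverages()`):

* `ndr_rc` — mean depth in the nucleosome-depleted region window
  (default -150..+50) over mean depth in the reference flanks
  (±(1000..3000));
* `k2_rc` — the same for the ±1000 "2K" window;
* `conventional_rc` — the 2K depth over the genome-wide mean depth, the
  natural third normaliser when three distinct quantities are named.

The window extents are defaults consistent with the TSS-coverage
literature, configurable per call; no published coordinates are being
reproduced. Genes within 3 kb of a chromosome edge are skipped and
reported; genes with zero reference depth are reported missing. Duplicate
TSS annotations collapse to the most upstream TSS by strand.

`classify_chromatin_state()` calls a gene *permissive* (open) when both
`ndr_rc` and `k2_rc` are below 1.0 in a strict majority of samples, and
*nonpermissive* (closed) when both exceed 1.5 in a strict majority —
"in more patients" is read as a majority statement. Genes meeting neither
conjunction are *indeterminate*. Neutral genes sit by construction at
relative coverage ~1, exactly on the open threshold, so their calls are
dominated by sampling noise; recovery of simulated truth is therefore
evaluated on the genes with a defined open/closed state.

## Promoter fragmentation entropy

`promoter_entropy()` tallies fragments whose midpoints fall within ±1000 bp
of the TSS and whose lengths lie in 100-220 bp into 5-bp length bins
(K = 24), then reports the Shannon entropy in bits with a 0.5 pseudocount
per bin. The pseudocount is a deliberately simple shrinkage toward uniform;
the Bayesian (Dirichlet-multinomial) treatment used elsewhere in the
literature is out of scope, and the pseudocount, window, bin width and
length range are all configuration. Genes with fewer than 20 supporting
fragments report missing entropy — below that the pseudocount, not the
data, would dominate. Entropy is bounded by `[0, log2 K]` and reported both
raw and normalised by `log2 K`.

## TF-site occupancy profiles

`composite_profile()` averages coverage across a TF's binding sites in a
±1000 bp window at 10 bp steps (strand-oriented when strands are given),
normalises by the mean over the outer 25% of positions on each side, and
summarises the centre as the mean normalised coverage over ±50 bp. Flank
normalisation makes the profile invariant to uniform depth rescaling.
At least 10 usable sites are required; site lists are user inputs, not a
bundled catalog. Because coverage at the site centre also receives
contributions from fragments whose midpoints lie outside the depleted
centre, the central score is a smoothed version of the underlying midpoint
depletion — slightly attenuated toward 1 — which is the expected behaviour
of a coverage-based occupancy summary.

## Multimodal classifier

`assemble_features()` aligns per-modality blocks (size fractions, per-bin
normalized ratios + r-to-healthy-median, fraction r-to-reference,
copy-number summaries, mean TSS coverages, mean PFE, TF central scores)
into one matrix with recorded block membership, dropping or mean-imputing
samples with missing modalities and removing constant columns. Whether the
classifier should see five, six or seven blocks is historically ambiguous
in the field's own reports; the block list is configuration, and all blocks
built from available inputs are used by default.

`train_eval_sgd()` trains a linear model with logistic loss by stochastic
gradient descent (decaying learning rate `eta0/(1 + eta0*lambda*t)`,
L2 penalty `lambda = 1e-3`, 50 epochs, unregularised intercept) and
evaluates it twice: a stratified 70/30 train/test split with ROC, AUC and a
confusion matrix at probability 0.5, and stratified 10-fold
cross-validation pooling out-of-fold scores into a single ROC/AUC.
Standardisation is fitted inside each training split/fold only, so no test
information reaches the model; the test suite verifies that a deliberately
leaky variant (feature selection on all data) inflates permuted-label AUC
while the shipped path does not. A fixed seed fixes the folds, the split
and the SGD shuffling, making reports bit-identical across runs.
`per_modality_consistency()` trains one classifier per block on identical
folds and reports per-sample agreement and the majority vote;
`benchmark_methods()` runs alternative classifiers (regularised logistic
regression, random forest, RBF SVM, and any user-supplied fit/predict
pair) on identical folds.

## The simulator

`sim_config()`/`simulate_cohort()` generate seeded cohorts on a miniature
genome so the full pipeline runs in minutes. Defaults, chosen once as the
package's study conditions:

* genome: three 30 Mb chromosomes, 5 Mb bins (18 bins); 30 000 fragments
  per sample — enough that bin-level counts resolve the injected effects
  while a 100-sample cohort simulates in about a minute;
* size mixtures: healthy = 76% mononucleosome N(167, 10) + 7%
  dinucleosome N(334, 20) + 10% short N(145, 10) + 5% sub-80 bp + 2% long
  tail; cancer raises the short component to 22%; hemolysis replaces most
  of the cfDNA signal with genomic DNA rising from 150 bp
  (150 + Gamma(2, 120), 57%) plus excess 30-60 bp reads. These weights
  place the healthy genome-wide short/long ratio near 0.14, the cancer
  ratio near 0.28, and the hemolysis ratio near 0.04 — on the healthy/
  diseased side of the 0.05 flag with a margin large compared to sampling
  noise;
* a shared sinusoidal per-bin modulation of the short-fragment weight
  (amplitude 0.3) gives every sample a common "fragmentation landscape",
  and cancer samples additionally draw mean-one log-normal per-bin
  distortions (sd 0.25) that make their ratio profiles heterogeneous; the
  per-sample field is renormalised to mean one so genome-wide size masses
  stay at their configured values;
* per-bin GC follows a 0.35-0.60 gradient assigned in a scrambled
  (coprime-stride) bin order — decoupling GC from genomic position so that
  GC correction cannot silently absorb positional structure — with an
  exponential sampling preference of strength 1;
* copy number: three bins amplified at copy ratio 1.5 and tumour fraction
  0.25 (multiplier 1.125) in cancer samples;
* genes: 180 evenly spaced TSSs in equal thirds up/down/neutral.
  Upregulated genes are open: promoter fragments thinned to 0.4, with 35%
  of surviving promoter fragments redrawing their length uniformly on
  100-220 bp (the expression-entropy coupling). Downregulated genes are
  closed: promoter coverage boosted 1.8x. Expression values are set per
  label with a deterministic within-group spread;
* two TF site sets (200 sites each) placed past the gene zone, centrally
  depleted to 0.70/0.80 in healthy and 0.45/0.55 in cancer samples.

Two derived configurations serve analyses that need different geometry:
a null/copy-number layout (one 100 Mb chromosome, 200 kb bins -> 500 bins)
for z-score calibration, and a promoter-focused layout (one 4.5 Mb
chromosome, 600 genes, 300 000 fragments ≈ 11x coverage) for TSS state
recovery and PFE contrasts, where per-gene coverage, not bin counts, is
the limiting resource. The test suite states these sizes explicitly; all
are configurable upward.

What the simulator does *not* emulate: sequence content (no reads, no
FASTQ), alignment artefacts, mappability gaps, the ~10.4 bp intra-peak
phasing ladder, chromatin domains beyond the sinusoidal landscape, and
inter-individual biological variation beyond the injected effects. Passing
tests therefore demonstrate that the estimators recover the effects they
target under controlled conditions — not that real plasma data will show
effects of this size.

## Numerical choices and degenerate inputs

* Ties/boundaries: half-open intervals everywhere; midpoint
  `floor((start+end)/2)`; strict `<` for the hemolysis flag; strict
  majority (> 0.5) for state calls.
* GC correction falls back to the identity when GC is constant, and errors
  below 10 usable bins rather than fitting loess to a handful of points.
* Entropy uses the `0 log 0 = 0` convention with zero pseudocount.
* Empty samples load as valid empty objects with warnings; empty
  histograms and zero-total profiles are errors where a fraction would be
  undefined.
* Wilcoxon tests use the normal approximation (`exact = FALSE`)
  throughout, so cohort-scale p-values saturate at the approximation's
  floor for complete separations.
* Per-sample seeds derive deterministically from the master seed; all
  derived seeds stay below 2^31.

## Pipeline

`run_pipeline()` wires the stages (simulate/load -> qc -> fragmentation ->
cnv/tss/pfe/tfbs -> ml) behind a validated YAML/list config with the
defaults above (hemolysis threshold 0.05, windows 100-150/151-220, 5 Mb
bins, state thresholds 1.0/1.5, 10 folds). Every stage writes TSVs with
comment headers; `manifest.json` records the tool version, config snapshot,
input checksums, per-stage signatures, runtimes and output checksums.
Stages whose parameters and inputs are unchanged are skipped on rerun, and
a rerun changes no output checksum. The pipeline's default simulated cohort
is kept small (12 + 12 samples) so an end-to-end run completes in a couple
of minutes; `inst/scripts/cffeatures-run.R` is the command-line wrapper.

## Known limitations

* The hemolysis rule's ratio definition is an interpretation (see above);
  if an orthogonal definition (e.g. the 30-80 bp fraction) is preferred,
  the flag must be recomputed from the histogram, which is always exported.
* The CNV module scores bins and genes; it does not segment, estimate
  tumour fraction, or call deletions (the machinery would be symmetric,
  but only amplification calls are implemented).
* The classifier is linear by design; `benchmark_methods()` exists
  precisely because no single method is claimed optimal.
* The healthy-median reference and the healthy CNV panel are built from
  the cohort's own healthy samples; in deployment they should come from a
  fixed external panel to keep evaluation strictly out-of-sample.
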