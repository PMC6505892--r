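---
title: "Modelling enhancer-driven activation of T-DNA flanking genes"
author: "activTag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enhancer-driven activation of T-DNA flanking genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Activation tagging inserts a T-DNA carrying four tandem copies of the
CaMV 35S enhancer into a plant genome. Genes tens of kilobases away from
the insertion can be transcriptionally up-regulated, but which flanking
genes actually respond must normally be confirmed gene by gene with
RT-PCR. activTag models that outcome from sequence alone: given a genome,
gene models, and an insertion position, it scores every flanking gene as
activated (`Ac`) or not (`NAc`) with a confidence.

## The three regions

For each (gene, insertion) record three coding-strand sequences are
extracted, each standing for a mechanistic hypothesis about
enhancer-promoter communication:

* **UPS1K** -- the 1000 bases immediately 5' of the translation start
  site (TLS, the first base of the start codon; the TLS base itself is
  excluded). This is the core-promoter proxy: direct promoter-enhancer
  interaction.
* **DISTANCE** -- the genomic interval between the TLS and the insertion
  junction, inclusive of both endpoints (length = distance + 1). This is
  the scanning-model proxy; its length, the enhancer-to-TLS distance
  `x`, is also the covariate of the distance model below.
* **MIDDLE** -- the 301 bp window centred on the central nucleotide of
  DISTANCE (the whole interval when it is shorter than 301 nt). This is
  the looping-model proxy.

Coordinates are 1-based inclusive throughout (the GFF3 convention).
Three conventions were genuinely open and are fixed as follows: the
insertion junction coordinate stands in for the enhancer position (the
offset of the enhancer tetramer inside the T-DNA is generally unknown;
a fixed offset is available via `distance.enhancer_offset`); the central
nucleotide of an even-length interval is `ceiling(L/2)` (deterministic,
biased by at most 1 nt); and DISTANCE includes both endpoints, so its
length is `x + 1`.

## Feature encodings

Four feature families encode the regions. All encoders are
deterministic, and windows containing `N` are skipped consistently.

* **k-mer counts** (`countNgrams`): raw overlapping counts of all
  3-6-mers, 64 + 256 + 1024 + 4096 = 5440 dimensions per region. Counts
  are intentionally not length-normalised: for DISTANCE the sequence
  length itself carries class information.
* **Motif occurrences** (`scanMotifs`, `encodeMotifs`): each position
  weight matrix in the library is scanned on both strands with log2-odds
  scores against a 0-order background; per-window p-values come from the
  exact distribution of the score-discretized PWM score under that
  background (a dynamic program over columns, the construction used by
  FIMO-style scanners; occurrence threshold p <= 1e-4 by default). Each
  motif contributes six channels -- count, mean score, plus/minus strand
  fractions, density (width x count / occupied span, defined as 1 for a
  single occurrence), and mean occurrence-to-TLS distance -- so a
  2,087-motif library yields 12,522 dimensions. The distance channel is
  measured from the occurrence start to the TLS; measuring to the
  insertion site instead is ill-defined on the promoter, where the
  insertion usually lies outside the scanned sequence.
* **Physicochemical profile** (`encodeNpc`): a table of dinucleotide
  properties is centred, scaled and reduced to 15 principal components
  (15 is the maximal rank for 16 centred observations; each component's
  largest-magnitude loading is made positive so the reduction is
  deterministic). A sequence is encoded as count(dinucleotide) x
  component value / number of valid windows: 16 x 15 = 240 dimensions.
* **CpG islands** (`detectCpgIslands`, `encodeCgi`): 100 nt sliding
  windows pass at GC% >= 50 and length-corrected observed/expected CpG
  >= 0.6; overlapping or adjacent passing windows merge, and merged
  segments shorter than 200 nt are dropped. The five encoded channels
  are island count, total length / promoter length, distance from the
  TLS to the nearest island start, mean per-island CpG percentage, and a
  plain observed/expected ratio #CG / (#C x #G) pooled over islands.
  The plain ratio deliberately omits the length factor used during
  detection; both quantities are reported, the detection-side one inside
  the island table.

On the promoter all four families apply; on DISTANCE and MIDDLE only the
k-mer and physicochemical families do (motif and CpG-island statistics
are promoter concepts), giving the 8 admissible (region, feature)
layer-1 models.

### Pattern filtering

The k-mer and motif count spaces are large and mostly uninformative, so
a per-column two-sided Welch t-test between `Ac` and `NAc` training
records retains columns with p < 0.05 (`selectPatterns`). Welch rather
than pooled-variance: class sizes and variances are not guaranteed
comparable. No multiple-testing correction is applied -- the filter is a
screening device, not an inference; under label permutation it admits
~5% of columns, which the test suite checks. Columns with zero variance
in both classes are excluded with p recorded as 1. Masks are fit on the
training subset only and frozen into the model.

## The distance model

Activation probability decays with enhancer-to-TLS distance. A logistic
model `pi(x) = plogis(beta0 + beta1 x)` is fit to the training records
(`fitDistanceLogistic`); the frozen default coefficients are
`beta0 = 1.448`, `beta1 = -7.099e-05` per bp (`publishedDistanceModel`),
under which `pi(0) ~= 0.810` and `pi` crosses 0.5 near 20.4 kb.

The fitted probability weights each record's feature vectors
elementwise before classification (`distance.weighting = "multiply"`).
The same gene observed at two different insertion distances therefore
receives two different encodings, which disambiguates repeated sequences
with different expression outcomes. Appending `pi` as an extra feature
(`"append"`) and disabling weighting (`"none"`) are available
alternatives; multiplication is the default because it acts on every
feature family without changing any dimension.

## The two-layer classifier

**Layer 1.** One RBF-kernel support-vector machine per admissible
(region, feature) pair: mask (k-mer/motif families), weight by `pi`,
z-score standardise, then fit with hyperparameters chosen by a seeded
stratified 3-fold grid search over cost in 2^{-3}, 2^2, 2^7 and gamma in
2^{-7}, 2^{-2}, 2^3 (three points spanning each documented range; the
response surface is smooth enough at these problem sizes that a denser
grid changes selections rarely, and the 3 x 3 grid keeps a full training
run on one CPU in minutes). Probability calibration is a Platt-style
logistic fit on out-of-fold decision values from the same folds --
implemented in the package, seeded, and therefore bit-reproducible,
which the calibration built into libsvm is not (it shuffles folds with
an unseeded internal RNG).

**Layer 2.** A Gaussian naive Bayes integrator over the calibrated
layer-1 probabilities of one feature combination. The integrator is fit
on *out-of-fold* layer-1 probabilities (stacked generalization): a
stratified 5-fold pass refits masks and layer-1 models per fold
(reusing the hyperparameters found on the full subset) and collects
each record's probabilities from the fold that held it out. Training
the integrator on resubstitution probabilities instead would hand it
near-binary inputs whose per-class Gaussians have vanishing variance;
on the broader probabilities of unseen records such an integrator
collapses to the class prior. All 15 non-empty feature subsets are then
scored by cross-validating the integrator over the same out-of-fold
matrix, with metrics pooled over the concatenated held-out predictions
(fold-level confusion tables are tiny and unstable at these sample
sizes). The combination with the highest cross-validated AUC becomes
the model's integrator; AUC is preferred to accuracy because class
ratios vary across protocols.

**Subsets and selection.** Positives are ranked by mean pairwise local
alignment similarity (match +1, mismatch -1, linear gap -2, computed
exactly) and split into two groups of `group_size = min(#negatives,
floor(#positives/2))`; each group joins the same negatives, giving two
balanced training subsets (1:1 positive:negative, the ratio at which
the layer-1 models behave best; configurable via `pn_ratio`). Extra
positives -- the lowest-similarity ones -- are dropped and logged;
surplus negatives are subsampled with the run seed. Each subset trains
its own two-layer model; the final model is the one with the higher
overfitting-aware quality score: for each of AUC, sensitivity and
specificity, cross-validation x exchange-testing / self-consistency,
summed over the three metrics (`modelSelectionScore`). Ties go to the
higher cross-validated AUC.

**Evaluation protocols** (`protocolSuite`): cross-validation,
self-consistency (a model on its own training records, an upper bound
and overfitting diagnostic), exchange-testing (each subset model on the
other subset's records; the shared negatives are part of that design),
and independent testing on a held-out study whose record identifiers
must not overlap the training subsets.

## The synthetic study generator

`generateStudy` builds a fully synthetic activation-tagging study: i.i.d.
genomes at GC 0.43 (rice-like euchromatin), one gene plus one insertion
per 70 kb cassette (so gene bodies never overlap), enhancer-to-TLS
distances uniform on 100-30,000 bp, intragenic insertions at rate 0.05,
and labels drawn from the frozen logistic. Signal is then planted: two
10-mer consensus motifs are written into the promoter and MIDDLE regions
of activated records with probability 0.8 per motif per region, and of
non-activated records with probability 0.2; CpG-rich blocks are planted
at rate 0.15 in both classes, so the CpG-island family is deliberately a
null feature. Every planted position is recorded in a manifest and is
verifiable by string comparison.

The default study size is 360 training records (giving two balanced
subsets of ~224 after similarity grouping) with a 120-record independent
study for testing; these sizes keep a complete seeded training run --
region extraction, encoding, similarity grouping, both subset models
and all evaluation protocols -- around four minutes on one CPU while
leaving per-fold counts large enough for stable estimates.

What the generator emulates: the distance-activation relationship,
motif enrichment in activated promoters, strand and location geometry,
and the class imbalance of real surveys. What it does not: genome
composition beyond GC content, repeats, gene density, chromatin, or any
correlation structure among promoters. A model that passes the
synthetic end-to-end test has demonstrably learned planted distance +
motif signal through the full pipeline; that is evidence the machinery
works, not evidence about real activation-tagging data.

## Numerical choices and degenerate inputs

* PWM columns get a 1e-4 pseudocount before log-odds, so scores stay
  finite while consensus scores change negligibly.
* The p-value lattice uses ~8192 bins across the score range; the
  test suite bounds the discretization error against exhaustive
  enumeration of all 8-mers.
* Grid-search ties break to the first (smallest cost, then gamma) grid
  point; subset-split ties break by record id; combo ties break to the
  earlier enumeration position.
* A record whose DISTANCE interval is shorter than 2 nt cannot be
  encoded for that region; the affected layer-1 models abstain with
  probability 0.5 rather than fail.
* Undefined metrics (empty denominators) are reported as `NA`, never
  silently 0; layer-2 falls back to the class prior when every input
  column is constant.
* Integrator inputs are clipped to the per-column range seen during
  integrator training. Outside that range the larger-variance class's
  Gaussian dominates both tails, so un-clipped extreme probabilities
  (e.g. a model scoring its own training records) would be ranked by
  variance rather than direction.
* All randomness flows from explicit seeds through an internal
  RNG-scoping helper; user RNG state is never disturbed.

## Known limitations

* Real promoters are not i.i.d. sequence; absolute performance numbers
  on synthetic studies say nothing about field accuracy.
* The enhancer-position-equals-junction convention misplaces the
  enhancer by up to the T-DNA's internal offset.
* The similarity split is exact but quadratic; studies with thousands
  of positives would need a sparser strategy.
* Only one insertion per record is modelled; joint effects of multiple
  T-DNA copies are out of scope.
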