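---
title: "Models and methods behind stresscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stresscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stresscape` analyses stress-response time-course transcriptomics in
marine picocyanobacteria: differential expression across light, UV and
temperature shifts and diel cycles, signed co-expression modules
correlated to physiological traits, PLS/VIP filtering, exclusive DE
condition sets, detection of adjacent co-expressed gene runs
("cyanorons"), and PAM-fluorometry physiology. This vignette documents
the models, the defaults and why they were chosen, the numerical
decisions, and what the synthetic validation does and does not
demonstrate.

## The experiment design

The design generator expands a condition table into per-sample rows.
The default table encodes seven acclimation/shift combinations — LL
cultures shifted to high light (LLHL), UV (LLUV), low (LLLT) or high
temperature (LLHT), and HL cultures shifted to UV (HLUV), LT (HLLT) or
HT (HLHT) — each sampled at five time points in triplicate, plus two
12 h/12 h light/dark cycles at 21 and 27 °C sampled at eight clock times
in quadruplicate. Naively this sums to 7×5×3 + 2×8×4 = 169 samples. In
practice a single control culture per acclimation is split at time zero
and shared by all of that acclimation's shift conditions; with this
shared-T0 convention the design comprises 154 distinct transcriptomes.
Both conventions are supported through the `share_t0` flag because the
arithmetic difference matters for any downstream bookkeeping; the shared
convention is the default. Shift contrasts are taken against the
acclimation T0; diel contrasts against the 6 a.m. sample of the same
cycle, which is treated as an ordinary sample of the design, not a
separate control.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is validated.

**Counts.** Gene counts are negative binomial with mean

    mu_gj = baseline_g * 2^(planted log2FC) * exp(lambda_g * f_mj) * s_j

and variance `mu + alpha*mu^2`. Per-gene dispersions `alpha` are drawn
log-uniform on [0.01, 0.5], the range typical of bacterial RNA-seq with
three or four biological replicates; baselines are log-normal around 150
counts (floored at 5); library-size factors `s_j` are log-normal(0,
0.15) so that normalisation is genuinely exercised. `lambda_g` is the
gene's loading (uniform 0.8–1.2) on its module's latent factor `f_m`.

**Latent factors.** Module factors are AR(1) series (ρ = 0.7, marginal
SD 0.7 on the natural-log scale) over the ordered time points within
each condition, shared by replicates of the same culture state and
centred per module. The autocorrelation makes expression time courses
smooth, as stress-response kinetics are; module detection is therefore
validated on time-structured samples, not i.i.d. draws.

**Planted effects.** Per condition, a fraction (default 12%) of genes
receives a log2 fold change of magnitude 1–3 (random sign) switching on
at a random onset time and persisting — a step response, the simplest
shape consistent with induction kinetics. Planted cyanorons are 4–8
adjacent genes given one module label, a one-gene buffer so runs stay
maximal, and a concordant ±2 log2FC at every time point of one stress.
Traits are linear read-outs of the factors
(`trait = loadings %*% factors + N(0, noise_sd)`, default noise 0.3)
with each trait loading ±1.2 on one module and weakly (N(0, 0.1)) on the
rest.

**Determinism.** Every stochastic stage draws from a stream derived from
the master seed and a stage label via a fixed string-hash splitter, so
adding or re-ordering stages never perturbs another stage's draws, and
any generator called twice with the same seed is bit-identical.

## Physiology calculators

`Fv/Fm = (Fm − F0)/Fm` is computed exactly and errors on signal
inversion (`F0 > Fm`) rather than returning a negative yield, since
inversion indicates a failed dark acclimation or DCMU step.

Short-term repair assays fit `y = a·exp(−k·t)` to the control and the
lincomycin-treated series by Levenberg–Marquardt least squares seeded
from a log-linear regression (grid-seeded retries when values are
non-positive); the repair rate is `k_inhibited − k_control`. The
intercept `a` is left free rather than pinned to the T0 measurement:
this costs one degree of freedom but absorbs any offset in the first
reading. On noiseless exponentials the fit is exact to better than
1e-8.

Long-term assays monitor paired aliquots at 0, 0.25, 0.5 and 1 h. Three
to four points under-determine a two-parameter exponential at realistic
noise, so each arm's decline rate is the negated slope of a linear
regression pooled over replicates, and the rate is the decline-rate
difference (inhibited − control; positive = repair active).

Simulated fluorescence is clipped to [0, 1] after adding noise; clipped
points are kept, not censored — the truncation is documented and at the
default noise (SD 0.02 on yields near 0.6) essentially never binds.

Emission-peak heights are window maxima: PE in 565–575 nm, PC in
645–655 nm, and the terminal acceptor in 680 ± 5 nm (a window rather
than the single 680 nm reading, so that a 1-nm grid shift cannot halve
the height). Ratios are refused when the denominator window carries no
signal (below 1e-9 of the spectrum maximum).

## Differential expression

The DE engine is a documented re-specification, not a parity clone, of
the negative-binomial Wald workflow: acceptance is calibration and power
on synthetic truth, not identical gene lists with any particular
published tool.

* **Normalisation** is median-of-ratios over genes expressed in every
  sample, with no post-hoc rescaling. Genes failing the all-nonzero rule
  are excluded from factor estimation only, never from testing.
* **Dispersion** is method-of-moments per gene on normalised counts
  pooled across replicate groups, `alpha = max(0, (s² − mu)/mu²)`,
  shrunk halfway toward a trend of dispersion versus log mean and
  floored at 1e-8. The trend is a lowess fit *without* robustness
  iterations: moment estimates of dispersion are legitimately
  right-skewed, and a robust (median-type) trend systematically
  understates dispersion, which at three replicates inflates the Wald
  type-I error from ~5.5% to ~8%.
* **The Wald statistic** uses log2 of group means of normalised counts
  with a pseudocount of 0.5 (zeros are common at genome scale; no
  independent filtering and no fold-change shrinkage are applied), a
  delta-method standard error from the NB variance, and two-sided normal
  tails. With known dispersions the null type-I fraction at p ≤ 0.05 is
  0.051; with estimated dispersions about 0.056 (20 null repeats, 2,634
  genes, 3 vs 3).
* **BH adjustment** is implemented from its step-up definition and
  tested to 1e-12 against a brute-force implementation and
  `stats::p.adjust`.
* **The DE rule** is `padj ≤ 0.05` and `|log2FC| ≥ 1`, with per-contrast
  up/down/ns summaries.

## The co-expression network

Expression enters the network as `log2(normalised count + 1)`; the
transform is not prescribed by convention and this choice is the
simplest variance-compressing one.

The adjacency is signed by default, `a_ij = ((1 + r_ij)/2)^β` with
β = 12; the unsigned `|r|^β` form is available because the field's
descriptions of "signed" networks sometimes mix in absolute-value
language, and the two differ exactly where anti-correlated regulons are
involved. The scale-free fit bins connectivity into 10 bins and reports
the R² of `log10(frequency)` on `log10(mean k)`, negated if the slope is
positive.

Module detection clusters the topological-overlap dissimilarity
(`1 − TOM`; plain `1 − a` as an option) with average linkage and a
static cut. Two conventions exist for "cut height 0.25": cutting the
*gene* dendrogram at 0.25 of its height, and merging *module
eigengenes* closer than 0.25. On TOM dissimilarities, whose merge
heights concentrate near the top of the tree (here the smallest merge
was at 0.56 of the maximum), a 0.25 gene-tree cut leaves every gene a
singleton and hence unassigned, so the first convention is unusable.
`stresscape` therefore cuts the gene tree statically at `tree_cut`
(default 0.95) of its maximum merge height, sends clusters smaller than
`min_size` (30) to gray, and then iteratively merges modules whose
eigengenes are closer than `cut_height` (0.25) — the conventional
eigengene-merge threshold. All three knobs are exposed; the procedure
has no stochastic step and identical inputs give identical output.
Submodules re-cluster each module's genes at `sub_cut` (0.97) of the
module subtree, with subclusters under 10 genes pooled into a residual
submodule.

Eigengenes are the first principal component of the standardised member
genes, scaled to unit variance and oriented so the mean correlation with
members is non-negative.

## Trait integration

Module–trait association is pairwise-complete Pearson correlation with
the Student t p-value on n − 2 degrees of freedom; pairs with fewer than
4 overlapping samples are flagged untestable. P-values are BH-adjusted
across the module × trait grid before thresholding at 10⁻³ (raw
thresholding available), since a 3-module × 10-trait grid at 10⁻³
without adjustment is already fairly strict but the adjusted form is
what "adjusted p-value" implies.

VIP scores come from a NIPALS PLS1 of one trait on a module's
standardised member genes, two components by default (one captures a
single dominant axis; two allow a secondary response without fitting
noise at typical module sizes). The implementation satisfies
`mean(VIP²) = 1` to 1e-10 on every fitted model, returns exactly 1 for a
single predictor, and matches the mixOmics VIP implementation to 1e-6 —
mixOmics serves only as an independent cross-check in the tests, never
as the implementation. Whether a multi-trait response would be
preferable is undecidable from convention alone; per-trait PLS1 keeps
each trait's gene ranking interpretable and is what is reported.

DE condition sets use standard UpSet semantics: a gene hits a condition
if it is DE at ≥ 1 of its time points, and its exclusive set is exactly
its hit set, so sets partition the ever-DE genes; an inclusive
("at least these conditions") mode is provided. Direction is ignored
for membership but retained in output.

## Cyanorons

A cyanoron is a maximal run of ≥ 4 genes with consecutive genome indices
sharing one module label, supported by a time point when *every* member
has log2FC > 1, or every member < −1, at that time, and called when
supported time points reach ⌈T/2⌉ for the stress. Two readings of the
threshold phrase "log2FC > 1 or < 1" are possible; the literal one is
vacuous (every value is > 1 or < 1), so the down-concordant reading
`< −1` is used and the threshold is configurable. Concordance is
required within each time point across all members — a run where
members pass thresholds at different times is not concordant. Maximal
runs only are reported (sub-runs of a qualifying run are not emitted);
gray genes never form runs; strand is carried through but ignored for
adjacency, as nothing in the definition involves it. Detection is
validated by exact agreement with a brute-force enumerator over all
windows, by monotonicity in both thresholds, by perfect recovery of
planted runs from noiseless planted effects, and by a permutation null
(< 0.5 false calls per 2,634-gene genome at independent N(0, 0.5)
log2FCs). Predicted operons are generated and written alongside but are
deliberately not part of the call rule; they are reported side by side.

## Pipeline, formats, reproducibility

`run_all()` executes simulate → DE → network → integrate → cyanorons →
physiology as toggled in a YAML-serialisable config. Coordinates are
GFF3 1-based inclusive on the way in, BED 0-based half-open on the way
out, and the 0-based genome-order index is the canonical adjacency key.
Every output file opens with a `#` header naming the producing stage,
parameters and seed; the run manifest records an MD5 per output, and two
runs with the same config and seed are bit-identical. The package's
functions, the pipeline driver and this vignette are the interface; no
separate shell entry point is shipped.

## Problem sizes and what the validation shows

The test suite and acceptance script run at deliberately modest sizes
chosen to keep each check sharp: null calibration at 2,634 genes × 3 vs
3 replicates × 20 repeats; power at 1,000 genes with 100 planted
effects over 50 repeats; module recovery at 300 genes × 154 samples with
three planted modules at low dispersion (0.05), matching the
"orthogonal latent blocks, low noise" regime that defines the recovery
claim; cyanoron oracle equivalence on twenty 200-gene toy genomes; and
the full default pipeline at 2,634 genes × 154 samples, twice, for
bit-identity.

Known limitations worth stating plainly:

* The generator omits batch effects beyond library size, rRNA carryover,
  read-level artefacts and real sequence content; passing tests show the
  *algorithms* recover planted structure under the stated noise model,
  not that any real dataset will be as clean.
* With most genes responding through module factors, median-of-ratios
  normalisation absorbs part of the factor signal (the classic
  composition problem). In the full count pipeline this caps
  eigengene–factor correlation around 0.93–0.97 at default noise; the
  eigengene operator itself recovers a planted factor at |r| > 0.99
  under profile noise 0.3.
* Module recovery at full default dispersion (log-uniform up to 0.5)
  fragments weakly-loaded genes into gray; planted-run recovery through
  the *estimated* module labels and fold changes is therefore
  substantially below the noiseless sensitivity of 1 — the acceptance
  script reports both numbers side by side.
* Numbers that characterise a real 154-sample dataset — per-condition DE
  percentages, the sizes of real modules — depend on that data and are
  outside what synthetic validation can or should reproduce.
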