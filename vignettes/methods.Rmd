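---
title: "Methods: co-expression networks and causal orienting for multi-condition RI transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks and causal orienting for multi-condition RI transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The setting

Recombinant inbred (RI) panels such as the BXD set are fixed homozygous
mosaics of two parental genomes. Because each strain can be re-measured
indefinitely, strain means serve as genetically replicable observations,
and the same genetic panel can be profiled under several treatments. This
package analyses such a design: log2 strain-mean expression matrices for
four conditions — control (NOS), restraint stress (RSS), ethanol (NOE),
and stress followed by ethanol (RSE) — together with a biallelic marker
map, behavioral phenotypes measured per condition, and a scored
protein-interaction network.

All matrices are assumed already normalized and log2-transformed. An
optional per-matrix z-score utility (`zscore_expression()`) is provided;
whether standardization was applied per condition or globally is recorded
in the object, since correlation-based steps are invariant to per-gene
standardization but mean-based steps (the expression floor, pattern
means) are not — the pipeline therefore applies the floor and the pattern
analysis on the unstandardized scale.

# Variable-gene selection

For each gene, across the strains of one condition, we compute the mean,
the sample standard deviation (n − 1 denominator) and the coefficient of
variation CV = sd/mean. The CV is only meaningful for positive means; on
the log2 intensity scale of these data all expressed genes are far from
zero, and genes with non-positive means are flagged rather than selected.

The empirical CV distribution in this kind of data is well described by
two overlapping normal populations: a tight low-CV bulk (genes whose
variation across strains is essentially technical) and a broader high-CV
population (genes with real strain variation). `fit_cv_mixture()` fits
this two-component normal mixture by EM: initialization by a median
split, convergence when the log-likelihood gain falls below `tol = 1e-8`
(≤ 500 iterations), and up to five jittered restarts if a component
degenerates (σ → 0). The log-likelihood is asserted to be non-decreasing
at every iteration; a decrease aborts the fit rather than silently
returning a bad optimum. Components are relabeled so that component 2 is
the higher-mean, "variable" population.

A gene is selected when its posterior responsibility for the variable
component exceeds 0.5 **and** its mean log2 expression is at least 8.
The responsibility rule is the standard EM decision boundary for
"right side of the distribution"; the density-crossing threshold is
offered as an alternative (`rule = "crossing"`) and gives nearly
identical selections when the components are well separated. The mean
floor of 8 log2 units is the conventional expressed/not-expressed cutoff
for these intensity data. Selections are made per condition and merged by
union (`merge_conditions()`), with per-condition provenance retained.

# Co-expression networks

`adjacency()` builds the unsigned weighted network
a_ij = |cor(x_i, x_j)|^β with pairwise-complete Pearson correlations.
Unsigned is the classic default for this family of methods and is what we
use throughout; a signed transform ((1 + r)/2)^β is available by flag.
Correlations with fewer than 3 shared strains, or involving a
zero-variance gene, are set to 0 with a warning.

The power β is chosen by the scale-free topology criterion
(`scan_powers()` + `pick_power()`): per candidate β, connectivities
k_i = Σ_j a_ij are binned into 10 equal-width bins, and log10 of the bin
frequency is regressed on log10 of the bin-mean k; the fit index is R²
signed by the negated slope, so only downward-sloping (scale-free-like)
fits count. The smallest β reaching R² ≥ 0.8 is chosen. When no power
reaches the target — common on strongly modular synthetic data, whose
degree distribution is bimodal rather than scale-free — the fallback is
the best-fitting power among those keeping mean connectivity ≥ 1.
Without that floor the fallback can drift to extreme powers where the
network is shredded into isolated nodes and module detection degenerates;
with it, the chosen power lands in the moderate range a practitioner
would pick by eye from the scan table.

`tom_similarity()` computes the standard unsigned topological overlap
TOM_ij = (ℓ_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij),
ℓ_ij = Σ_{u≠i,j} a_iu a_uj, as a dense matrix product; it is verified
against a literal triple-loop evaluation in the tests. Modules are
detected by average-linkage hierarchical clustering of 1 − TOM with a
static branch cut at 99% of the maximum merge height
(`detect_modules()`); clusters smaller than 30 genes go to the reserved
grey bucket. We chose static-height cutting as the default — the planted
and real module structures of interest separate from the background well
before that height, and the static rule is transparent and fully
deterministic; the cut height and minimum size are both configurable. An
adaptive hybrid cutter would admit smaller, fainter modules at extra
complexity; at the module sizes this analysis targets (≥ 30 genes) the
static rule recovers the planted partitions essentially gene-for-gene
(adjusted Rand ≥ 0.8 seed-averaged, usually ≥ 0.98).

Module eigengenes are the first principal component of the
gene-standardized module submatrix, scaled to unit variance, with the
sign fixed so the eigengene correlates non-negatively with the module's
average standardized expression. kME is the gene–eigengene correlation;
intramodular connectivity k_in is the sum of a gene's adjacency to its
module co-members. Module labels M1, M2, … are assigned in decreasing
size order; label identity is arbitrary and only partitions are ever
compared.

The combined cross-condition network concatenates the four condition
matrices column-wise with condition-tagged strain names
(`combine_conditions()`). This treats strain-condition pairs as
exchangeable samples for correlation purposes, which is the natural
reading of a "combined dataset" of four conditions over one panel.

# Module-level statistics

For each module, E_ij is the mean expression of the module's genes in
strain i under condition j. `anova_pattern()` fits the one-way
fixed-effects model E_ij = μ + T_i + ε_ij, ε ~ N(0, σ²), and reports the
F test (df = c − 1, N − c). Note that the shared strain factor of a
module inflates the within-condition variance, so this test is
conservative for condition shifts; it answers "do the condition means
differ relative to strain-to-strain spread".

`classify_pattern()` assigns the four response patterns from the
condition means, using deltas against the NOS control and a minimum call
threshold δ_min = 0.1 log2 units (configurable; such pattern calls are
usually made qualitatively, and 0.1 is small relative to the 0.5-unit
planted shifts but large relative to the standard error of a 41-strain
condition mean). Pattern 1: NOE up, RSS and RSE at control; pattern 2:
NOE down, RSS and RSE at control; pattern 3: RSS and NOE up, RSE above
both; pattern 4: RSS up, NOE and RSE not up. Profiles matching none of
these are reported "unclassified" rather than force-assigned — in
particular ambiguous RSS-up/NOE-up ties between patterns 1 and 4.

Eigengene–trait association uses Pearson correlation over shared strains
with the exact two-sided t-based p-value (df = n − 2), and the
conventional |p| < 0.1 display mask for heat maps. Gene-set
over-representation (`enrichment_fisher()`) builds the explicit 2×2
table (in both / module only / set only / neither) over a stated
universe — by default the genes entering the network, not the whole
platform — and uses Fisher's exact test, two-sided by default with the
one-sided over-representation p reported alongside; significance at
p < 0.05, with an optional Benjamini–Hochberg column (raw thresholds are
the defaults, matching common practice for these displays).

# Preservation and specificity

`module_overlap()` tests every non-grey module pair across two
conditions by Fisher's exact test on shared gene counts, in the
intersection of the two networks' gene universes (the conservative
choice when the networks were built on different gene lists). The
one-sided over-representation p is the decision value — preservation is
a directional "degree of overlap" question — with the two-sided p
reported alongside; the significance threshold is p < 0.01. A module is
condition-specific (`call_specific_modules()`) when no module of any
other condition overlaps it significantly. Because "n modules preserved"
is ambiguous, `count_preserved()` reports both conventions: modules with
at least one significant counterpart, and the number of significant
pairs.

# QTL scanning and causal orienting

Marker–trait association uses ordinary least squares of the trait on the
0/1 marker code (RI strains are homozygous, so there is no dominance
term), summarized as LRS = n·ln(RSS₀/RSS₁) with LOD = LRS/(2 ln 10); a
perfect fit is capped at LRS = 10⁶ and flagged so rankings stay total.
eQTL scans add a cis flag for markers on the gene's chromosome within a
10-map-unit window (the window is a documented default, not a value
inherited from any particular study).

Causal orienting considers the five single-anchor trivariate structures
relating a genotype G, a gene (or eigengene) X and a phenotype Y:
the causal chain G→X→Y, the reactive chain G→Y→X, the common cause
X←G→Y, and the two collider forms G→X←Y and G→Y←X. After standardizing
all three variables, each model leaves exactly one testable constraint
on the correlation matrix (e.g. r_GY = r_GX·r_XY for the causal chain;
r_GY = 0 for the first collider). `fit_sem_model()` estimates the free
correlations by minimizing the ML discrepancy
F_ML = ln|Σ(θ)| − ln|S| + tr(S·Σ(θ)⁻¹) − 3 (Nelder–Mead from the sample
correlations, relative tolerance 1e-12), and tests fit by
χ² = (n − 1)·F_ML with 1 degree of freedom. Calibration of these
p-values under each true generating model is verified by
Kolmogorov–Smirnov tests in the suite.

The LEO score is log10 of the causal-chain p-value over the best
alternative's p-value; 0.5 (a 3.2-fold ratio) is the evidence threshold,
and only the forward orientation is screened. Zero p-values are floored
at the smallest representable double and flagged. `screen_causal_genes()`
fixes the anchor marker (typically the trait's peak-LRS marker), orients
every gene × phenotype pair, scores genes by their maximum LEO, and
ranks them. An optional kME floor restricts the screen to well-connected
module members; it is off by default.

One caveat the synthetic experiments make explicit: when a trait is
driven by a module's latent factor, an individual member gene is a noisy
proxy of that factor, so the exact chain constraint holds for the
eigengene but only approximately for single genes (attenuated by the
squared factor loading). Gene-level LEO scores are therefore
conservative at realistic panel sizes; this mirrors the practice of
orienting module eigengenes and then inspecting member genes.

# The synthetic-data generator

`synthetic_design()` fixes the study conditions: 41 strains, 3000 genes,
200 markers over 5 chromosomes (~2.5 cM spacing), eight planted modules
of sizes 150–50 covering all four response patterns twice with
within-module correlation ρ = 0.7, a condition-shift magnitude δ = 0.5
log2 units, a CV mixture of N(0.05, 0.01²) (weight 0.7) and
N(0.15, 0.03²) (weight 0.3), a grand mean of 9.0 log2 units with 15% of
the invariable background genes assigned means below 8, and two planted
forward-causal chains (marker → module factor → trait, b₁ = b₂ = 0.8,
unit trait noise). These values are the generator's definition of a
realistic study of this type: strain and marker counts match the real
panels' order of magnitude (genes scaled down ~15× for tractability),
ρ = 0.7 gives modules as tight as strong real modules, δ = 0.5 is a
plausible treatment effect on the log2 scale, and the CV components
reproduce the bimodal CV histograms seen in strain-mean intensity data.
The defaults are fixed; experiments vary them only through an explicit
design object.

Genotypes follow an independent Markov chain per strain and chromosome:
first allele Bernoulli(0.5), then recombination between adjacent markers
with the Haldane probability r = (1 − e^{−2d/100})/2 for d cM. (True RI
genomes have roughly fourfold-inflated map expansion from repeated
inbreeding; this does not affect any statistic tested here and is
ignored.) Each module carries a latent strain factor shared across the
four conditions — a genetic strain effect — so member genes correlate
within every condition while condition shifts move the means; causal
modules add b₁ × marker code to the factor. Phenotypes are wired
according to each triplet's true model (chain, reactive, common-cause or
collider), with pure-noise traits as negative controls. The low-mean
fraction is drawn from the invariable background only, so the mean-floor
and CV decisions stay orthogonal and the truth flags remain
interpretable. The PPI layer plants high-confidence (score > 700) edges
on a fraction (default 0.15) of within-module pairs and adds random
edges scored uniformly on [150, 1000].

What the generator does **not** emulate: probe-level noise, sex and
batch structure, per-condition strain dropout (balanced panels by
default; an unbalanced option exists at the design level and is flagged
in the truth record), correlated background structure, and non-Gaussian
expression tails. Passing recovery tests therefore demonstrate the
statistical machinery is correct and calibrated under the declared
model, not that real data meet that model.

# Numerical choices and degenerate inputs

* Pairwise-complete correlations throughout; fewer than 3 shared strains
  gives correlation 0 with a warning.
* EM: degenerate components trigger up to 5 jittered restarts, then an
  error; constant input is reported as degenerate rather than fit.
* TOM on 1–2 genes and empty edge sets are handled explicitly; writers
  produce valid empty documents.
* Static branch cutting breaks no ties by randomness; outputs are
  deterministic functions of the input, and exports sort nodes and edges
  lexicographically so repeated runs diff clean.
* The pipeline fans one global seed out to fixed per-stage offsets, so
  every stage can be reproduced in isolation.
* Problem sizes in the test suite: oracle equivalence on instances up to
  n = 12 (TOM) and N = 60 (Fisher); mixture recovery at n = 2000;
  module/pattern recovery on the default 3000-gene design over 5 and 3
  seeds respectively; SEM calibration at 500 replicates per model and
  orientation recovery at 100 replicates per model (n = 200, effects
  0.8). These sizes make the full suite run in a few minutes while
  keeping every binomial tolerance meaningful.

# Known limitations

* No block-wise approximation: dense TOM limits networks to ~20k genes.
* No consensus networks across conditions and no GO-graph-aware
  enrichment (flat GMT sets only).
* The causal screen implements the five single-anchor models only — no
  edge-weight variants, no multi-marker anchors, no search over network
  neighborhoods — and only the forward orientation is thresholded.
* Fisher-based preservation measures gene-set overlap, not connectivity
  preservation; permutation statistics of the Z-summary family are out
  of scope.
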