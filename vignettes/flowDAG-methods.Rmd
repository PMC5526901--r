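---
title: "Methods: automated gating and quantification of rare multimer-binding T cells"
author: "flowDAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated gating and quantification of rare multimer-binding T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what the
synthetic evaluation does and does not demonstrate.

# The analysis problem

MHC multimer staining makes antigen-specific CD8+ T cells visible as a
(usually small) event cloud that is CD3+, CD8+ and multimer-bright after
the sample has been reduced to live single lymphocytes. Two properties
make automation hard: the target population can sit anywhere between
~5% and 0.0001% of lymphocytes, and staining intensities differ strongly
between instruments, antibody panels and laboratories, so no fixed
intensity cutoff transfers across files. `flowDAG` composes four stages,
each exposed as ordinary functions on S4 objects (`EventTable`,
`ClusterModel`, `PopulationCall`):

1. *prefilter* — density-contour gating of lymphocytes, singlets and
   viable cells (`dagFilter`);
2. *cluster* — grid-based density clustering of the marker channels
   (`gridDensityCluster`, optionally via a consensus template,
   `buildTemplate`/`assignToCentroids`);
3. *annotate* — relative 1–4 expression categorization plus a fixed
   cutoff rule (`categorizeExpression`, `callMultimerPopulation`,
   `computeFrequencies`);
4. *evaluate* — CV and CV-equality testing, paired comparisons and
   limit-of-detection tabulation (`cv`, `cvEqualityTest`, `pairedTTest`,
   `pearsonR2`, `lodReport`).

# DAG prefiltering

Each `GateStep` names a 2D projection and a rectangle in the projection's
analysis units. The density on the projection is a `bins × bins`
histogram over the observed range padded by 1% per side, smoothed with a
separable Gaussian kernel (`smoothing` bins standard deviation, truncated
at 3σ, zero-padded) and normalized to total mass 1. Contour lines are
traced at `nLevels` evenly spaced levels in `(0, max)`; polylines that
touch the grid boundary are open and discarded. Among the closed contours
whose vertices all lie inside the rectangle, the one with the largest
shoelace area is kept (ties resolved toward the lower level); events
inside it — even-odd rule, boundary counting as inside — pass to the next
step.

Open choices and their resolutions:

* *"Largest" contour.* Interpreted as maximal enclosed area among fully
  contained closed contours, not lowest level per se: area is what
  "largest" means visually, and it is robust to the level schedule. For a
  unimodal blob the two readings coincide.
* *Estimator defaults.* `bins = 128`, `smoothing = 2`, `nLevels = 32`.
  With 32 levels the lowest traced level sits at 1/33 of the peak, so the
  selected contour of a well-formed population retains ≈97% of its mass
  per step (for a 2D Gaussian, mass inside the iso-density contour at
  level *c* is `1 − c/fmax`; the unit tests verify this to 2% including
  the smoothing-widened σ). Three steps therefore retain ≈91% of live
  single lymphocytes — and because numerator and denominator shrink by the
  same factor, the reported frequency is unbiased against this loss.
* *Failure behavior.* If no closed contour fits the rectangle, the
  rectangle itself is the gate and a warning is logged
  (`fallbackUsed` in the retention report).
* *Scales.* Scatter channels are gated raw; fluorescence (including the
  viability dye) is arcsinh-transformed (`x → asinh(x/cofactor)`,
  cofactor 150) before gating and clustering. The transform is optional
  and never applied to scatter.
* *Panels without a viability stain* simply omit the viability step
  (`defaultGateSequence(viability = FALSE)`).

DAG is fully deterministic: identical input and configuration give
identical output.

# Grid-based density clustering

Clustering channels are min–max scaled to `[0, 1]` (the range is frozen
in the model so later samples are assigned in the identical space), each
channel is split into `bins` intervals, and hyper-bins with at least
`minDensity` events are *dense*. Dense bins are organized into clusters
by hill-climbing: each dense bin links to the Chebyshev-radius-1 neighbor
with the highest strictly greater count; bins with no such neighbor look
one shell further (radius 2) before becoming mode roots. Events in each
root's basin seed a centroid; every event (dense or not) is assigned to
its nearest centroid (Euclidean, scaled space; ties to the lowest
index), centroids are re-estimated once from that assignment, and a final
nearest-centroid pass defines the reported counts — which makes
`assignToCentroids(fittedTable, model)` reproduce the model's counts
exactly.

Why mode-seeking rather than merging all touching dense bins into
connected components: at large event counts the marker-space background
becomes contiguous — intensity tails put a handful of events into almost
every bin between two populations — so plain connected components collapse
all abundant populations into one component represented by a single,
badly placed centroid. Nearest-centroid assignment then bleeds thousands
of boundary events into whatever small seed sits nearest, and a
~100-event population is destroyed by its own re-estimation step (we
observed exactly this at 10⁶-event samples). Splitting components at
density saddles gives every population mode its own centroid; the
assignment becomes locally accurate and rare modes survive. The radius-2
fallback absorbs isolated Poisson fluctuations on a population's fringe
(which would otherwise become spurious one-bin clusters) while leaving
truly isolated modes alone — a real rare population sits behind an empty
gap wider than two bins on the multimer axis, a tail fluctuation does
not.

Defaults, and why: `bins = 12` and `minDensity = max(5, round(n/1e5))`.
These were calibrated on the package's own design point: a 0.01%
population in 10⁶-event samples yields ~55–90 labeled events after
prefiltering, spread over ~35 hyper-bins in the 3D marker space; at 12
bins per axis its densest bin holds 9–19 events, safely above the
threshold (5–8 in this regime), while the inter-population gaps remain
several bins wide so modes do not fuse. A finer grid (16+ bins) dilutes
the rarest populations below any workable threshold; a much coarser one
erodes the gaps. Both parameters are exposed on every clustering
function.

Known bias: the rare cluster's basin also captures the few background
events in the adjacent tail (the midpoint between centroids lies in
near-empty space, but not perfectly empty). At the 0.01% design point
this adds roughly 10–20% to the recovered count; at ≥0.1% it is
negligible. The acceptance script's rare-population value reflects this.

`buildTemplate` fits the same model on a consensus built by
`subsampleConcat` (default 250,000 events per sample, the customary
consensus size for template clustering) and caps the cluster count at
100. The model serializes to JSON.

# Annotation and quantification

The cluster-level 1–4 categorization is deliberately *relative*: each
channel's observed event range (the model's frozen range) is split into
four equal-width intervals on the analysis scale, and each cluster gets
the interval of its centroid (1 = negative … 4 = high). A cluster is
multimer-positive iff CD3 > 1 (rule skipped when the panel has no CD3),
CD8 > 1, multimer > 2, and — for dump-channel panels — dump = 1. The rule
is monotone in the multimer level and applied identically to every
sample; no per-sample tuning is available by design, so the method's
failure mode on poorly separated data (relative levels shift when the
range is dominated by background) is preserved and measurable rather
than hidden. How the original grid-density tools computed their levels
is not documented anywhere we could verify; equal-width intervals of the
observed range are the simplest deterministic, scale-covariant choice.

Frequencies: the primary denominator is live single lymphocytes (the
DAG-kept event count). The CD8-based denominator is reported only when a
CD8+ count is supplied explicitly — a single low CD8 cutoff does not
transfer across heterogeneous stainings, which is precisely why the
lymphocyte denominator is primary. Duplicates are averaged
arithmetically; a single available run passes through unchanged.
`detected` means at least `thresholdEvents` (default 10) events in the
called clusters; well-separated stainings can meaningfully be followed
below that, which is why the threshold is a parameter.

# Evaluation statistics

* `cv`: sample SD (n−1) over mean, ×100.
* `cvEqualityTest`: the Feltz–Miller asymptotic test. With
  `mᵢ = nᵢ − 1` and group CVs `cᵢ` (fractions), pooled
  `c = Σmᵢcᵢ/Σmᵢ`, the statistic
  `D = Σmᵢ(cᵢ − c)² / (c²(0.5 + c²))` is χ² with k−1 df under equal
  CVs. Its type-I error at the panel's group size (n = 28, CV ≈ 0.3) is
  verified by simulation to be 0.05 ± 0.02.
* `pairedTTest`, `pearsonR2`: thin, contract-checked wrappers over
  `stats::t.test`/`stats::cor.test`, with an optional `log10` transform
  as the skewness sensitivity analysis (automatic Box–Cox selection is
  out of scope). Identical paired vectors return t = 0, p = 1.
* `lodReport`: orders dilution steps by decreasing theoretical frequency
  `f0·d^-(k-1)`, flags detection per duplicate, and reports the smallest
  theoretical frequency detected in *all* duplicates, alongside the
  0.001% conventional threshold line.

# The synthetic generator

`simulateDonor` draws population sizes multinomially (so downstream
detection statistics see true sampling noise; realized labels are always
carried per event) and channel intensities lognormally:
`x = m·exp(σZ)` with `σ² = log(1 + cv²)`, i.e. `m` is the population's
median. Forward-scatter height is tied to area (singlets
`FSC-H = 0.95·FSC-A` with 5% jitter; doublets `FSC-A = 2·FSC-H`), which
is what makes the singlet gate informative. Laboratory heterogeneity
enters as per-channel multiplicative gain shifts and a spread multiplier
(`labProfile`), and panels may swap CD3 for a dump channel or omit the
viability stain.

The *frequencies* of the donor presets define the emulated scenario —
proficiency donors at 0.3/0.02/1.5/0.01% of live single
lymphocytes with CD8-based values 1.13/0.09/5.33/0.04%, the spike-in 1
donor at 1.7%, spike-in 2 at 0.87% (CMV, PE channel); the CD8 fraction of
each preset is set so both denominators are simultaneously correct. The
*intensities* (medians and cvs of every population/channel) were never
published and are package choices: the default `"distinct"` separation
places the multimer+ population ~4 intensity decades above background
with tight spread, emulating a high-avidity staining with clean
background; `"noisy_lab"` dims and broadens it. The second spike-in's
low-frequency FLU response on the APC channel is not modeled (one
multimer+ population per donor); the CMV/PE response is.

What passing tests show — and what they do not: the synthetic samples
have lognormal, unimodal populations with honest sampling noise and
between-lab shifts, but no spectral spillover residue, no acquisition
drift, no doublet smear along gates, and background that is genuinely
unimodal. Recovery and false-positive results here demonstrate the
pipeline's *mechanics* (gating mass, mode survival, rule behavior,
denominators) under controlled truth; they do not certify performance on
real heterogeneous panel data, where separation quality is the known
dominant factor.

# Orchestration, determinism and problem sizes

`runPipeline` executes one YAML/list configuration end to end in three
modes: `single-stage` (per-sample DAG → cluster → annotate), `template`
(DAG all samples → consensus → one template → assign each sample), and
`two-stage` (no DAG: stage-1 clustering on FSC-A/SSC-A/viability with
rule-based selection of clusters whose scaled scatter centroids fall in a
configured lymphocyte rectangle — an automated stand-in for the manual
cluster picking that stage otherwise requires — then stage-2 clustering
of CD8 × multimer within the selection). Every output CSV carries the
seed and an MD5 hash of the resolved configuration (excluding the output
path), and identical config + seed reproduce all CSVs byte for byte.
Schema validation runs before any computation and names the offending
role or field. Negative-control runs whose called frequency exceeds 20%
of live single lymphocytes are flagged in the log as rule-based outliers.

All randomness flows from one integer seed through fixed sub-seed
derivation (kept below 2³¹); the package restores the caller's RNG state.

Problem sizes used by the shipped tests were chosen to keep the full
suite within a few minutes on one CPU while leaving every statistical
check adequately powered: samples of 2×10⁵ events for recovery checks
(10⁶ for the 0.01% rare-population case), 5×10⁴-event negative controls
across 100 seeds for the false-positive rate, an 8-lab × 3-donor panel
for the pipeline-vs-truth correlation (r ≥ 0.95), and 10 replicate
6-lab panels for the CV non-inflation check. These are desk-scale stand-ins
for the emulated 28-laboratory panel; the generator and pipeline accept
arbitrary sizes.

# Known limitations

* FCS support is deliberately minimal: delimited TEXT of versions
  2.0/3.0/3.1, datatypes F/D/I, list mode only; keyword escaping by
  delimiter doubling and ANALYSIS segments are ignored; spillover
  matrices are never applied (a `$SPILLOVER` keyword only warns — input
  is assumed compensated).
* The 1–4 categorization is range-relative; a sample whose multimer
  range is set by a single bright outlier shifts every cluster's level
  down. This is inherent to the fixed-cutoff design the package
  reproduces.
* Rare-population estimates carry a small positive bias from background
  tail events in the rare mode's basin (see above).
* The two-stage mode's lymphocyte rectangle is specified in scaled
  coordinates and is a heuristic replacement for expert cluster
  selection; it is the least standardized of the three modes.
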