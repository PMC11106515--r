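---
title: "Methods: differential Hi-C architecture analysis with hicdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential Hi-C architecture analysis with hicdelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hicdelta compares the three-dimensional chromatin architecture of two
conditions - in the motivating application, a hormone-secreting pituitary
tumour against normal pituitary tissue - from binned Hi-C contact matrices,
and couples each structural layer to differential gene expression. This
vignette describes the models and algorithms, the tunable parameters and
their defaults, what the synthetic benchmark generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## Data model

A `genome_spec` fixes an ordered chromosome set, lengths and one bin size;
bins are 0-based half-open (`[i*res, (i+1)*res)`), and genomic positions map
to bins by floor division. A `contact_matrix` stores counts once per
unordered bin pair with a symmetric query contract, alongside per-bin
balancing weights and a valid-bin mask. The triplet text exchange format is
tab-separated with a `#chromA binA chromB binB count` header. All analyses
below run on this one container; coarser grids (100 kb compartments, 1 Mb
comparison maps) are produced by `coarsen()`, which aggregates counts by
integer bin division.

## Balancing and decay statistics

`ice_balance()` performs iterative correction: one multiplicative weight per
bin, updated by dividing by the normalized balanced coverage until the
coefficient of variation of balanced row sums over valid bins falls below
`tol` (default `1e-5`, `max_iter = 200`). Bins with zero coverage, plus the
lowest 2% of nonzero-coverage bins (`mask_quantile = 0.02`), are masked
first; weights are mean-normalized to 1 over valid bins and undefined on
masked bins. Non-convergence is reported as a warning, never silently.

`compute_expected()` averages balanced values over *all* valid bin pairs at
each separation - zero pixels included, masked bins excluded from numerator
and denominator - per chromosome or pooled. The interaction decay exponent
(IDE) is the OLS slope of `log10(expected)` on `log10(separation)`; the
default fit range is 50 kb to 10 Mb, and the benchmark analyses use
50 kb - 2 Mb because the simulated chromosomes are 5 Mb. At least three
positive strata are required.

Cross-sample maps (the log2-ratio map and the gained/lost O/E ratios)
first scale both matrices to equal total mass; the log2-ratio map adds a
pseudocount of 1 (in count units, after scaling) and reports the union of
nonzero pixels.

## Reproducibility (SCC)

`scc()` implements the stratum-adjusted correlation coefficient: both maps
are smoothed with an edge-truncated mean filter (half-window `h = 1` bin),
pixels are stratified by separation up to `s_max` (default 5 Mb), and the
per-stratum Pearson correlations are combined with weights
`N_k * sqrt(var_A(k) * var_B(k))`; zero-variance strata are skipped. SCC is
computed on raw counts by default (the usual convention; a `balanced` flag
overrides). The genome-level SCC pools strata across chromosomes by their
weights. The train/test selection of the smoothing parameter used by the
original reproducibility tool is out of scope; `h` is fixed.

## A/B compartments

Per chromosome, the balanced cis block is divided by its distance expected
(`oe_transform()`), bin-bin Pearson correlations are computed
pairwise-complete (`correlation_matrix()`), and the compartment signal is the
leading principal component of that correlation block: columns are centred
and the dominant eigenvector of the resulting covariance found by power
iteration to `1e-12` (`compartment_eigenvector()`), which the test suite
checks against a dense eigendecomposition to `1e-8`. The sign is oriented so
that PC1 correlates positively with gene density - the active A state is the
gene-dense one - and bins are labelled A (`PC1 > 0`), B (`PC1 < 0`) or
unassigned (`NaN`, or exactly 0: the sign rule leaves zero undefined, so we
refuse to guess). Orientation fails loudly if the density correlation is
exactly zero.

Two optional knobs exist for real data: `ignore_diags` excludes short-range
diagonals from the correlation, and `n_pcs` considers more than one leading
component, choosing the one most density-correlated. Both default off: on
the benchmark both variants measurably *reduced* label accuracy (sparse TSS
density makes the selection itself noisy), and plain PC1 was the most robust
estimator. Compartments are called at 100 kb in the analysis workflow, per
field convention; the calling functions are resolution-agnostic.

Switch classification is per-bin from the two labelled tracks (`A-to-A`,
`B-to-B`, `A-to-B`, `B-to-A`, `unassigned` if either side is), with
percentages over assigned bins.

## Insulation and TAD boundaries

The diamond insulation score of bin `i` is the mean balanced value over the
`w x w` square spanning `(i-w..i-1) x (i+1..i+w)` - the contacts crossing
`i` - with `w` = window / resolution. The default window is 500 kb at 10 kb
resolution. The reported score is `log2(raw / chromosome mean)`, so the
track is invariant to global rescaling and the chromosome mean of
`2^log2IS` is 1. Bins within `w` of a chromosome edge, masked bins, and
empty diamonds are `NaN`.

Boundaries are local minima with topographic prominence at least
`min_strength` (default 0.1 log2 units): from each minimum, walk outward to
the nearest strictly lower point (or the end of the contiguous valid
segment); the saddle is the running maximum, and prominence is the smaller
rise of the two sides. Topographic prominence is used rather than the span
between immediately adjacent minima because a shallow noise dimple next to
a deep minimum would otherwise truncate its span and veto a genuine
boundary.

TADs are consecutive-boundary intervals (half-open, in bp); intervals
shorter than 3 bins are dropped from the interval list, while the
adjacent-boundary spacing statistic uses all consecutive pairs. Boundary
sets from two samples are matched greedily by distance within a 1-bin
tolerance, giving a disjoint conserved/specific partition.

The differential rule follows the published thresholds exactly: candidate
positions (by default the union of called boundaries, merged at 1-bin
tolerance) are *excluded* when the log2 insulation score is above zero in
both samples (high-confidence filter) or undefined in either; otherwise a
position is *enhanced* when `tumour - normal < -0.4` (the tumour insulates
more; boundary scores are minima, so more negative means stronger) and
*weakened* when the difference exceeds `+0.4`. The sign convention -
"enhanced" = more negative tumour score - is stated explicitly because
published profile plots imply it without defining it. Pileups are
`NaN`-aware element-wise means of score windows centred on a position set.

## Loop calling

Loops are focal pixels enriched against four local expecteds, in the
HiCCUPS geometry with peak half-width `p = 2` and outer half-width `w = 5`
at 10 kb: the donut (the square annulus between radii `p+1..w` with the
width-`2p+1` horizontal and vertical stripes removed, i.e. the four corner
blocks), the two stripes themselves (peak region excluded), and the
`(w-p) x (w-p)` lower-left block toward the diagonal. Each neighborhood's
balanced sum is scaled by the ratio of the pixel's distance-expected to the
neighborhood's summed distance-expected and mapped to raw-count space
through the balancing weights, giving a Poisson rate for the observed raw
count.

Every cis pixel with a nonzero count in the separation band (default
50 kb - 2 Mb; the lower edge is clamped to `p + w + 1` bins, since closer
pixels overlap their own neighborhood) and a full, unmasked neighborhood is
tested with Poisson upper-tail p-values. Multiple testing uses
lambda-chunked BH: within each neighborhood family, pixels are grouped into
multiplicative chunks of their expected rate (factor `2^(1/3)`) and
BH-corrected within each chunk. Plain genome-wide BH was evaluated first
and rejected: with many true loops present the BH threshold relaxes and
borderline Poisson excursions in thin-count chunks ride through, which
chunking prevents by keeping each rate regime to its own budget.

Calls require q at most `fdr = 0.1` in all four neighborhoods plus
enrichment of at least 1.75x over the donut and lower-left and 1.5x over
the stripes. Surviving pixels are clustered within a 20 kb Chebyshev
radius; the max-observed pixel represents each cluster. Single-pixel
clusters must additionally show 2x enrichment over donut and lower-left
*and* a peak shape: the mean balanced value of the 8 surrounding pixels
must be at least 1.75x the balanced donut expected. A genuine focal peak
of ~1-bin width carries this shoulder mass; isolated bright pixels
(Poisson excursions, TAD-corner edge artifacts) do not, and the filter
separates the two populations cleanly on labelled benchmark calls.

Differential classification deduplicates the union of both call sets at the
cluster radius and computes each loop's observed/donut-expected in both
samples: *gained* = called in the tumour only with tumour O/E at least
2x the normal O/E; *lost* is the mirror; everything else is *shared*, and
loops over masked bins are flagged unevaluable. APA stacks O/E windows
(half-size 10 bins) centred on a loop set; the score is the centre value
over the mean of the lower-left corner block of side `half %/% 2 + 1`.

## Expression integration

Genes carry strand-aware TSSs (start on `+`, `end - 1` on `-`). Assignment
modes: compartment category by TSS bin (unique per gene); boundary
association by body overlap with a symmetric 500 kb window, ties to the
nearest boundary; loop association by TSS within 2 bins of either anchor.
The DEG rule is `|log2FC| > 1` and adjusted p `< .05`, both strict.
Group comparisons use two-sided Wilcoxon rank-sum tests on log2 fold
changes with BH correction across group pairs; per-chromosome DEG fractions
among switching genes are simple count ratios, `NaN` where a chromosome has
no switching genes.

## The synthetic benchmark generator

No patient Hi-C or RNA-seq from the motivating study is publicly
deposited, so the package ships a seeded generator whose planted truth
stands in for it. The cis intensity of each chromosome is

`mu_ij = scale * d^alpha * phi_ij * (1 + a * G_ij) * b_i * b_j`

with separation `d`, decay exponent `alpha = -1`, a structural modifier
`phi` combining the compartment plaid `(1 + c * v_i v_j)` (`c = 0.3`),
within-TAD enrichment `t = 2`, and local boundary depletion, Gaussian loop
bumps `G` of amplitude `a = 3` and width 1 bin, and lognormal bin biases
(sd 0.2). Counts are Poisson at 2 million cis contacts per 500-bin, 5-Mb
chromosome (three chromosomes); trans contacts are uniform up to biases at
an 18% (normal) / 13% (tumour) trans fraction, so the tumour map has the
higher cis fraction. A replicate re-samples the Poisson noise only.

Design choices that required care:

* **The modifier is renormalized per separation stratum**, so the
  configured `alpha` is exactly the map's marginal decay and the decay
  module can be benchmarked against it. Loop bumps multiply *after* the
  renormalization, so a planted loop pixel's O/E is exactly `1 + a G`.
* **Boundary depletion is local.** Pixels crossing a boundary of strength
  `s` are attenuated by `(1 - s)^G` with a Gaussian locality factor
  (scale 40 bins = 400 kb) centred on the boundary corner, ramping in over
  ~3 bins at the boundary plane. Strengths are drawn from U(0.35, 0.65),
  which puts planted log2 insulation dips in the realistic -1 to -2 range.
  A cumulative per-crossing attenuation was evaluated and rejected: it
  builds genome-scale gradients that dominate the compartment plaid, which
  no real map shows - insulation is a local phenomenon.
* **Compartment structure is segment-aligned.** Segments between planted
  boundaries receive signs by a Markov chain (flip probability 0.6, giving
  ~1 Mb compartment blocks), resampled until each chromosome's A fraction
  lies in [0.35, 0.65]; compartment edges therefore coincide with domain
  boundaries, as they do in real genomes. Switched regions are whole
  segments (plus at most one contiguous partial segment per direction to
  honour the requested 20% switch fraction *exactly*), capped at 30% of any
  one chromosome, with a 60:40 A-to-B : B-to-A split. Without the
  balance and cap constraints, occasional seeds produce a nearly
  single-compartment chromosome whose gene-density orientation is a coin
  toss - an identifiability failure of the truth, not of the estimator.
* **Planted loops are recoverable by construction.** Anchor separations are
  drawn from 120 kb - 1 Mb - the scale over which loops are described as
  acting - and placements whose planted cross-boundary depletion would bury
  the peak are rejected. Shared loops (8 per chromosome) are augmented by
  12 gained (tumour-only) and 3 lost (normal-only) loops genome-wide, so
  gained far outnumber lost. Tumour-specific boundaries bisect random
  normal TADs (2 per chromosome: more, smaller TADs in the tumour), and
  6 enhanced / 2 weakened boundaries scale the transmitted cross-boundary
  fraction by 0.35 (or its inverse), placing the planted insulation delta
  near |0.7| log2 units - clearly past the 0.4 differential rule.
* **3% of bins are unmappable** (bias scaled by U(0.02, 0.2)), sampled away
  from planted boundaries and anchors. They give the low-coverage mask its
  proper target; without them the mask's bottom-2% quantile lands on the
  genuinely depleted boundary bins.
* **Expression is coupled to structure.** 400 genes are placed with a 3:1
  A:B TSS density ratio; baseline log2 means are 8.5 (A) vs 7 (B) with
  per-gene sd 1; tumour shifts of +-1.5 (switches, differential-loop
  anchors) and +-1 (differential boundaries) apply in the planted
  directions (B-to-A up, A-to-B down, enhanced up, gained up). Replicate
  noise is N(0, 0.25) on log2 counts with 3 replicates per condition, and
  the surrogate DE table comes from per-gene Welch t-tests with BH
  correction - deliberately simpler than a negative-binomial count model,
  since the integration layer only consumes the table's columns.

What the generator does **not** emulate: restriction-fragment structure and
read-level artefacts, copy-number aberrations, sub-compartment structure
(A1/A2/B1-B4), distance-dependent noise beyond Poisson counting, and any
coupling between expression and structure other than the planted mean
shifts. Passing the benchmark therefore demonstrates that the estimators
recover planted architecture of realistic scale and depth - not that they
are robust to every artefact of patient tissue Hi-C.

## Benchmark sizes and runtime

The default benchmark (three 500-bin chromosomes at 10 kb, 2 x 10^6 cis
contacts each) was chosen so the full pipeline - simulation, balancing,
both call sets, differential layers and integration - completes in well
under a minute, and the null calibrations (20 homogeneous-Poisson loop
replicates, 200 uncoupled expression replicates) in a few minutes. The
acceptance script (`scripts/acceptance.R`) re-runs everything from scratch
at these sizes.

## Known limitations

* Boundary calling reports prominence in log2 units with no significance
  model; very shallow real boundaries below `min_strength` are invisible.
* The loop caller tests only pixels with nonzero observed counts, so at
  very low depth faint loops are unreachable regardless of thresholds.
* Gained/lost classification requires the loop to be *called* in its own
  sample; its accuracy is bounded by per-sample recall, which fluctuates
  on small planted differential sets.
* The surrogate DE model is a t-test on log2 counts; dispersion shrinkage
  and count-model subtleties of real RNA-seq pipelines are out of scope,
  and the DE table is consumed, never re-estimated, by the integration
  layer.
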