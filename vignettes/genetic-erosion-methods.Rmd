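---
title: "Models and methods behind erodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`erodiv` chains three bodies of method — mitochondrial population genetics,
SDM post-processing, and genetic-erosion accounting — behind one data model.
This vignette explains each model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Data model and gap policy

All sequence statistics operate on an `alignment`: a samples × sites
character matrix over `{A,C,G,T,N,-}`. Statistics assume **complete
deletion**: `complete_deletion()` drops every column containing `-` or `N`
in any sequence before anything is computed, and records the used length
`L_used` separately from the raw length. This is the common default of the
classical diversity software family; a per-site (pairwise-deletion) variant
would keep more data but make per-locality values non-comparable, which is
why per-locality statistics reuse the *globally* filtered alignment rather
than re-filtering each subset. Concatenation of loci joins sequences by
exact sample-id string; FASTA headers are truncated at the first whitespace.

## Diversity statistics

Haplotypes are equivalence classes of identical strings. Labels H1, H2, …
follow descending total count (ties by first occurrence) purely for
presentation; no statistic depends on them. Haplotype diversity uses the
small-sample-corrected estimator `Hd = n/(n−1)(1 − Σ p_i²)`. Nucleotide
diversity is the unweighted mean of per-site pairwise differences,
`π = k/L_used` with `k` the mean pairwise difference count — the
conventional "Pi", with no additional `n/(n−1)` factor; the pairwise sums
are accumulated from per-column state counts, which is algebraically
identical to the O(n²L) pair loop the tests use as oracle. Localities with
a single sample report `Hd` and `π` as undefined (`NA`, flagged), not zero;
the across-locality mean ± SE uses only defined values, with the sample
standard deviation over localities divided by the square root of their
number.

## Neutrality tests

Tajima's D uses the standard 1989 normalizing constants; it is undefined at
`S = 0` (returned as `NA` with a warning, never as 0) and requires `n ≥ 4`.
Fu's Fs follows the 1997 definition: `θ` is estimated by the mean pairwise
difference `θ_π = k`, and `S′ = P(K ≥ k_obs)` is a tail of the Ewens
sampling formula. The unsigned Stirling numbers of the first kind that the
formula needs overflow catastrophically beyond `n ≈ 170` in linear space, so
the recurrence `|s(n,k)| = |s(n−1,k−1)| + (n−1)|s(n−1,k)|` is run entirely
in log space with `log1p`-based addition; the exponentiated pmf sums to 1
to 1e−10 up to at least `n = 716`. When `S′` is numerically 1 (e.g. a
monomorphic sample with `k_obs = 1`) a `+Inf` sentinel is returned rather
than an overflow.

## Mismatch distributions and the sudden-expansion model

Time is measured in mutational units (1 unit = 1/(2u) generations), so a
pair of sequences that coalesced `t` units ago differs at `Poisson(t)`
sites. Under sudden expansion the population had scaled size `θ₀` before
the expansion `τ` units ago and `θ₁` afterwards, giving the
piecewise-exponential pair-coalescence density used in
`expected_mismatch()`. Two evaluation routes are provided and
cross-checked: adaptive quadrature of the generative density (the reference
route, absolute tolerance 1e−10) and an analytic kernel (regularized
incomplete-gamma for the recent epoch plus a Poisson–geometric convolution
for the older one) that the fitting loops use for speed. Both collapse to
the equilibrium geometric law `F_j = θ^j/(1+θ)^{j+1}` when `τ = 0` or
`θ₀ = θ₁`, which the tests assert together with a 10⁶-draw Monte-Carlo
simulation of the pair process.

Fitting minimizes the ordinary least-squares criterion
`SSD = Σ_j (obs_j − F_j)²` over `j = 0..j_max` (the observed range). The
optimizer is deterministic: a coarse grid (`τ` linear on `[0, 2 j_max]`;
`θ₀`, `θ₁` log-spaced around the observed mean pairwise difference) followed
by Nelder–Mead refinement from the best grid points, with the
parametrization `τ = s², θ₀ = e^l, θ₁ = θ₀ + e^d` enforcing the constraints
without bounds. Classical software may use a generalized (weighted) least
squares here; its exact weighting is not published, so OLS is implemented
and the choice is flagged for sensitivity analysis. Raggedness is the sum
of squared successive differences of the spectrum over the observed classes
`1..j_max`; a terminal drop-to-zero term is deliberately not appended (a
flat spectrum has raggedness exactly 0 under this convention).

Goodness-of-fit p-values come from a parametric bootstrap: `B` coalescent
samples of `n` lineages are simulated under the fitted `(τ̂, θ̂₀, θ̂₁)`
(waiting rate `C(m,2)/θ(t)`, the epoch boundary handled by the memoryless
property), mutations fall on branches as `Poisson(length/2)`, each
replicate is refitted, and `p` is the proportion of replicates whose SSD
(or raggedness) reaches the observed value. `B = 1000` by default with a
mandatory seed; the replicate refits use a lighter grid. The calibration of
`p` under the fitted model is itself tested (rejection rate at 5% within
binomial bounds over repeated trials).

## Population structure

"Fst" between localities is implemented as AMOVA-based Φ<sub>ST</sub> on the
matrix of pairwise sequence differences — the standard for haplotype
sequence data. Variance components follow the classical sums-of-squares
decomposition; negative components are reported raw (flagged by sign, never
truncated) and percentages are computed on raw components, so the two-level
percentages always sum to 100. A three-level decomposition (groups of
localities) is available when a grouping is supplied. Permutation tests
shuffle individuals among localities (and localities among groups for the
group component) with `p = (#{perm ≥ obs} + 1)/(B + 1)`, which can never be
exactly 0. Defaults are 100,000 permutations for Φ<sub>ST</sub>/AMOVA and
10,000 for Mantel, the conventional choices; desk-scale runs pass smaller
counts explicitly.

Geographic distances default to plain Euclidean distance on decimal degrees
— geodetically incorrect but the convention of the simple distance-matrix
tools this workflow family uses, retained for comparability — with a
haversine (`great-circle`) mode provided and recommended for real
distances. The Mantel test correlates linearized genetic distance
`Φ/(1−Φ)` (entries within 1e−9 of 1 capped at a finite sentinel with a
warning) with geographic distance, one-tailed upper, because isolation by
distance predicts a positive correlation; it is backed by `vegan::mantel`.

## SDM post-processing

Suitability rasters are plain matrices with an ESRI-ASCII-grid serialization
(row 1 is the northernmost). Thresholding uses MTSS (default 0.3893): a
cell is suitable iff `value ≥ mtss`, and categories are
`[0, mtss)` unsuitable, `[mtss, 0.5)` low, `[0.5, 0.7)` moderate,
`[0.7, 1]` high — all intervals closed on the left and open on the right
except the top, a convention fixed here because interval notation in the
source material is informal. Change maps apply the obvious truth table
(stable / contraction / expansion / absent), propagate nodata, and their
categories provably partition the jointly observed cells. Areas are cell
counts × cell area (scalar, or a per-row vector for latitude correction),
reported in thousands of km². A locality survives iff the cell *containing*
its coordinate is suitable (origin-anchored containing-cell rule); a
locality on nodata counts as lost, conservatively, with a warning.
Occurrence thinning is a randomized greedy pass (records canonically sorted,
then visited in seeded random order, kept when ≥ the distance floor from
all kept records; several restarts keep the largest set), so output is
order-invariant given the seed. Collinearity filtering iteratively drops
the variable with most `|r| > 0.8` partners, breaking ties by larger mean
`|r|` then label order, which makes it deterministic and auditable by
exhaustive search at small dimension.

## Erosion accounting

A haplotype persists under a scenario iff at least one carrier individual
sits in a surviving locality. `Hd` and `π` for the surviving set are
recomputed from the pooled surviving *sequences* (not from haplotype
frequencies), so unequal within-haplotype sampling is exact. Zero-survivor
scenarios return the zero report (0 haplotypes, `Hd = 0`, `π = 0`) rather
than an error, matching how a complete-loss row is tabulated;
single-survivor subsets also report 0 with a degeneracy flag, since the
scenario table prints numeric values for every row. Pooled-individual
recomputation is the implemented choice (a locality-weighted alternative
exists but is not used); a consequence worth knowing is that `Hd` can rise
when loss removes carriers of the dominant haplotype. Proportional π loss
is floored at 0. No rounding happens inside computation;
`format_scenario_table()` applies the presentation rounding (π to 5
decimals, `Hd` to 3).

## The synthetic-data generator

The generator exists so that the full chain runs, and its statistical
assumptions can be probed, without any external data.

* **Sequences** come from an `n`-lineage coalescent with piecewise-constant
  `θ(t)` (`θ₁` until `τ`, then `θ₀`), Poisson mutations on branches, and
  infinite-sites placement onto distinct random columns of a random
  ancestral sequence. Infinite sites keeps haplotype identity exact for
  bookkeeping tests (a capacity error fires if mutations exceed `L`); the
  cost is no recurrent/back mutation, which real mtDNA has at deep
  divergences but which is negligible at the shallow, post-expansion depths
  emulated here.
* **Locality structure** draws per-locality haplotype weights
  `w_l ~ Dirichlet(α·p)` around the global frequencies `p`, then places
  each sample proportionally to its haplotype's weights. One knob `α` spans
  sorted localities (small `α`, high Φ<sub>ST</sub>) to panmixia (large
  `α`), which is what the structure tests need; it does not model explicit
  migration, drift history or spatial autocorrelation of allele
  frequencies. The gamma draws behind the Dirichlet are taken in log space
  (`Gamma(a) = Gamma(a+1)·U^{1/a}`) because shapes of order 1e−3 underflow
  `rgamma` to zero. Note that the *visibility* of the knob depends on the
  sequence model: a hyper-diverse star genealogy made of singleton
  haplotypes shows low sequence-level Φ<sub>ST</sub> even when perfectly
  sorted, so differentiation calibrations use moderate-diversity
  (constant-size, `θ = 2`) sequences.
* **Suitability surfaces** are normalized sums of Gaussian bumps at the
  localities; the future surface keeps only surviving localities' bumps and
  the containing cells of each locality are clamped to guarantee the
  realized survival flags exactly (margin above MTSS for survivors, 0.8×MTSS
  ceiling for the lost). They are smooth toy landscapes: no environmental
  covariates, no spatial error, no projection effects.

The "paper-mini" defaults in `sim_config()` are the study conditions used
throughout the tests and the acceptance script: `n = 120` sequences of
`L = 1200` sites from 20 localities, `τ = 3`, `θ₀ = 0.5`, `θ₁ = 50`
(a strong recent expansion, chosen to reproduce the qualitative signature:
dominant shared haplotype, strongly negative D and Fs, smooth unimodal
mismatch), `α = 1` (weak but significant structure), MTSS 0.3893, a 40 × 40
grid of 0.1° cells, and survival fractions declining from 0.90 (2050
RCP2.6) to 0.00 (2070 RCP8.5) so the scenario gradient spans "mostly
persists" to "complete loss". These sizes keep a full pipeline run in
seconds and the whole test suite in minutes on one CPU; they are fixed
once, not tuned per test.

## What passing tests do and do not show

The oracle tests (brute-force recomputation, closed forms, Monte-Carlo,
exhaustive audits) show the *implementations* are correct; the calibration
tests (neutral means of D and Fs near 0, expansion means strongly negative,
uniform permutation p-values, τ recovery within ±30% on average) show the
*statistical machinery* behaves as theory predicts **on data satisfying the
generator's assumptions** — panmictic or Dirichlet-structured, non-recombining,
infinite-sites, equilibrium or single-sudden-expansion histories. Real
mitochondrial data can violate several of these (selection, recurrent
mutation, complex demography), and SDM rasters carry model error the toy
surfaces do not; passing tests therefore validate the pipeline's arithmetic
and logic, not the biological adequacy of the models for any particular
dataset.

## Known limitations

* Tajima's D / Fu's Fs significance is not simulated by default (the
  bootstrap machinery covers the mismatch statistics only).
* The three-level AMOVA requires a user-supplied grouping; no grouping
  search is attempted.
* Mismatch fitting is OLS; a generalized-least-squares weighting would
  change SSD scale (not the fitted τ much) and is not implemented.
* Raster support is single-band ESRI ASCII only, with either a scalar cell
  area or a per-row vector; equal-area reprojection is out of scope.
* The erosion model is removal-only: no gene flow, recolonization or
  forward-time genetic forecasting.
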