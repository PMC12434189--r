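# erodiv

Quantifying climate-driven **genetic erosion** from mitochondrial haplotype
data and species-distribution-model (SDM) output.

Many range-restricted species — karst-endemic amphibians are the motivating
case — carry a mitochondrial signature of recent, post-glacial expansion: one
dominant haplotype shared across most sampling localities, a halo of rare
derived haplotypes, strongly negative neutrality tests, and a smooth unimodal
mismatch distribution. When climate projections remove suitable habitat from
some of those localities, the sequences sampled there are lost with them, and
with the sequences a measurable share of the species' haplotypes and
nucleotide diversity. `erodiv` implements that whole desk-scale analysis
chain as one tested R package:

1. **Sequence statistics** — haplotype collapsing; haplotype diversity
   `Hd = n/(n-1) (1 - Σ p_i²)`; nucleotide diversity
   `π = Σ_{i<j} d_ij / [C(n,2) L]`; segregating sites `S`.
2. **Neutrality tests** — Tajima's `D = (k - S/a₁)/√(e₁S + e₂S(S-1))` and
   Fu's `Fs = ln(S′/(1-S′))` with `S′ = P(K ≥ k_obs | θ_π)` under the Ewens
   sampling formula, computed with log-space Stirling numbers so it is stable
   at sample sizes in the hundreds.
3. **Mismatch demography** — observed pairwise-difference spectra; the
   sudden-expansion model `F_j = ∫ Pois(j; t) f(t) dt` with a
   piecewise-exponential pair-coalescence density over `(τ, θ₀, θ₁)`;
   least-squares fitting (SSD), Harpending's raggedness index, and parametric
   bootstrap p-values from a piecewise-constant coalescent simulator.
4. **Population structure** — AMOVA-based pairwise Φ<sub>ST</sub> with
   permutation tests, two- and three-level AMOVA, geographic distances
   (Euclidean-on-degrees or haversine), and a Mantel test of isolation by
   distance on linearized Φ<sub>ST</sub>/(1-Φ<sub>ST</sub>) (via `vegan`).
5. **SDM post-processing** — occurrence thinning, collinearity-based variable
   selection, MTSS thresholding and suitability categories, current-vs-future
   change maps (absent / contraction / expansion / stable), area accounting
   in 10³ km², and per-locality survival flags.
6. **Erosion accounting** — per-scenario recomputation of haplotype counts,
   `Hd` and `π` on the sequences from surviving localities, with proportional
   losses and a Current + 2050/2070 × RCP2.6–8.5 scenario table.
7. **Synthetic data** — a coalescent generator (expansion-shaped alignments,
   Dirichlet-structured locality sampling, paired current/future suitability
   rasters with controlled survival fractions) so every stage runs and is
   testable without any download.

## Worked example

```r
library(erodiv)

cfg <- sim_config(seed = 1)                     # "paper-mini": 120 seqs, 20 localities
make_fixture_bundle(cfg, "bundle")
pc  <- pipeline_config("bundle", "out", seed = 1,
                       phist_permutations = 999L, amova_permutations = 999L,
                       mantel_permutations = 9999L, bootstrap_B = 200L)
res <- run_pipeline(pc)
```

The pipeline logs its stage counts:

```
read 120 sequences x 1200 sites, 120 samples in 20 localities, 60 occurrences
collapsed to 43 haplotypes
neutrality: S=63 k=2.509 D=-2.489 Fs=-45.758; mismatch SSD=0.00269 (p=0.055)
structure: Phi_ST=0.150 (among 15.0%), Mantel R=0.019 (p=0.418)
thinning retained 54 of 60 occurrence records
...
2070_RCP8.5: 0/20 localities survive, 0/43 haplotypes persist
```

The strongly negative Tajima's D and Fu's Fs and the small, non-significant
SSD are the expansion signature the generator builds in; Φ<sub>ST</sub> shows
the weak-but-real locality structure; and the scenario table
(`format_scenario_table(res$scenario_table)`) is the Table-1-style summary:

```
    time scenario nucleotide_diversity n_haplotypes haplotype_diversity
 Current  Current              0.00209           43               0.927
    2050   RCP2.6              0.00217           40               0.935
    2050   RCP4.5              0.00204           36               0.912
    2050   RCP6.0              0.00219           34               0.942
    2050   RCP8.5              0.00215           29               0.944
    2070   RCP2.6              0.00174           26               0.892
    2070   RCP4.5              0.00155           11               0.799
    2070   RCP6.0              0.00213            9               0.886
    2070   RCP8.5              0.00000            0               0.000
```

Each scenario row is `Hd`/`π`/haplotype count recomputed on the surviving
subset; note `Hd` can *rise* under loss (2050 RCP8.5) because removing
carriers of the dominant haplotype evens out the remaining frequencies, while
the terminal scenario loses every locality and hence all diversity.
`loss_percentages(res$erosion[["2070_RCP4.5"]])` prints the Figure-6-style
percentages: `75.0%` of localities and `74.4%` of haplotypes lost.

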