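---
title: "Comparing Z-chromosome and autosomal diversity under non-equilibrium demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing Z-chromosome and autosomal diversity under non-equilibrium demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In female-heterogametic (ZW) systems such as Lepidoptera, the Z chromosome
spends two thirds of its time in males and, with an even sex ratio, has an
effective population size three quarters that of the autosomes. At
demographic equilibrium, Z-linked nucleotide diversity is therefore expected
to be 0.75 of autosomal diversity. Deviations from that benchmark are often
read as evidence of selection or of sex-linked barriers to gene flow, but
population size changes alone move the ratio: a smaller population relaxes
to its new equilibrium faster, so the Z responds to expansions and
contractions more quickly than the autosomes. This package provides the
machinery to (i) measure windowed diversity and divergence from genotype
data with hemizygosity-aware handling of females, (ii) simulate the
corresponding null expectations under explicit demography, and (iii) test
whether absolute divergence on the Z is elevated between connected
population pairs, the signature of reduced effective migration on the Z.

## Statistics

All statistics are computed in non-overlapping fixed windows (default
50 kb) from haplotype-by-site allele matrices:

* within-population diversity `pi_i`: mean pairwise difference per site
  over all haplotype pairs;
* `pi_S = w pi_1 + (1 - w) pi_2` with `w = n1/(n1 + n2)` by default;
* pooled diversity `pi_T` over all pairs in the combined sample;
* Hudson's `FST = (pi_T - pi_S)/pi_T`;
* absolute divergence `dXY`: mean pairwise difference per site over all
  between-population pairs (`n1 x n2` pairs);
* net divergence `da = dXY - pi_S` (negative values are preserved — they
  indicate diversity growth since the split);
* Tajima's `D` per population with the standard 1989 constants.

Two conventions deserve explanation because the field's tools differ:

* **Missing data.** Every pair of haplotypes is normalized by its own count
  of jointly-called sites, rather than dividing all pairs by one window
  denominator. Per-pair denominators keep the estimators unbiased when
  genotype-level missingness is uneven across individuals.
* **Weighting of `pi_S`.** The sample-size weight `w = n1/(n1+n2)` is the
  default; an `equal` option gives both populations weight one half.

Windows enter the analysis only if, in each population separately, at least
10% of window positions are genotyped in at least 75% of the individuals.
Failing windows are retained as all-`NaN` rows so window bookkeeping stays
complete.

Genotypes are filtered before any statistic: depth must lie in [10, 100]
and variant genotype calls need genotype quality of at least 30. Sex is
inferred from Z heterozygosity (hemizygous ZW females are nearly devoid of
heterozygous Z calls); the implemented rule calls a sample female when its
Z heterozygosity falls below 0.1 times the cohort's median male level, with
at least 100 genotyped Z variant sites required. The factor and floor are
package choices — only the use of Z heterozygosity itself is standard — and
both are exposed as configuration. On Z windows each female is reduced to a
single haplotype row; residual heterozygous female Z calls are artifacts
(e.g. W-derived reads) and are set to missing.

### Invariant sites

Per-site statistics need callable-site denominators, not just variants. The
loader accepts an all-sites VCF, or a variants-only VCF with
`assume_callable = TRUE`, in which case unlisted positions are treated as
callable and invariant and each pair's denominator is the window span minus
its jointly-missing variant positions. The synthetic generator emits
variants-only VCFs, so the pipeline uses the second mode; its known
limitation is that missingness at invariant positions is invisible, which
biases diversity down by roughly the genotype missingness rate (a few
percent under the default emulation). Truth tolerances in the generator
account for this.

## The coalescent engine

The simulator is a structured coalescent with recombination (Hudson's
ancestral recombination graph with tracked ancestral material), written in
C++ for the replicate counts the study design requires. Lineages coalesce
within demes at rate `k(k-1)/2` per `2N(t)` generations, migrate backwards
at the per-generation, per-lineage rate `m`, and recombine at the physical
rate times the span of ancestral material they carry; segments whose
marginal subtree reaches the full sample are dropped, so resolved material
stops recombining and mutating. Output is a tskit-style edge table;
infinite-sites mutations are dropped per edge as a Poisson process with
real-valued positions.

Design choices:

* **Time and rates in generations.** Sizes are diploid `N(t)`; migration is
  a per-generation probability, so Z scaling of `N` leaves time-based
  parameters untouched, which is what makes Z and autosome runs comparable.
* **Z chromosome as a separate run** with all sizes multiplied by 0.75 and
  migration by `1 - d` (the Z migration-reduction factor).
* **Size-change convention.** A model with change magnitude `x` at time `t`
  has size `Ne` before the change (forward in time) and `x * Ne` from `t`
  until the present: `x > 1` is an expansion. The stated `Ne` is the
  pre-change size. This convention was fixed by matching closed-form
  pairwise coalescence expectations to the simulated-ratio extremes the
  design is meant to reproduce (see below); the ms-family `-eN` convention
  inverts easily, so the package states it explicitly.
* **Infinite sites** rather than a finite-site substitution model: at the
  divergences relevant here (at most a few percent per site) multiple hits
  are negligible, and infinite sites keeps every site strictly biallelic.
* **Recombination rate** is `rho/(4 Ne)` per bp per generation with
  `rho = 0.01` by default, using the class-scaled base size, so both
  chromosome classes run at the same population-scaled rate.
* The engine accepts any number of demes with an arbitrary migration matrix
  and one common merge time; the documented models use one or two demes,
  and the multi-deme path serves the synthetic transect generator.

Validation is by closed forms (pair TMRCA `2Ne`; total tree length
`4Ne sum 1/i`; `E[pi] = 4 Ne mu`; isolation `E[dXY] = 2 mu (T + 2 Ne)`),
by the neutral site-frequency spectrum, and by two-sample
Kolmogorov–Smirnov comparison of `S` and `pi` distributions against
msprime on three parameter sets (constant size, expansion, split with
migration).

## Simulated study designs

Two response surfaces reproduce the study's simulation designs, both with
five diploid individuals sampled per population:

* **Single size change** (`run_size_change_grid`): magnitude
  `x in {0.01, 0.1, 1, 10, 100}`, change time `t` on a 10-point log grid
  from 1e3 to 4e6 generations, `Ne` 3e6 (autosome) / 2.25e6 (Z),
  `mu = 2e-9`. The per-cell summary is the ratio of mean diversities
  `mean pi_Z / mean pi_A`. Under this design the ratio ranges from about
  0.41 (extreme contraction, intermediate `t`) to about 0.85 (extreme
  expansion, late `t`) around the equilibrium 0.75, and Tajima's `D` is
  negative after expansions and positive after contractions, with the
  response peaking on the changed population's own coalescent timescale:
  for a contraction to `N_p`, around a few times `2 N_p` generations; for
  an expansion, at the latest simulated times, because any `t` within the
  grid is recent relative to the enlarged population's timescale.
* **Two populations with split and migration** (`run_two_pop_grid`): split
  times 1–2 million generations, symmetric migration `m` from 0 to 1e-6
  per generation, Z migration reduced by factor `d`, `Ne` 2e6 / 1.5e6.
  With `d > 0`, `dXY(Z)/dXY(A)` is elevated relative to the `m = 0`
  baseline, and the elevation grows with `m` — reduced effective migration
  on the Z is only visible when there is migration to reduce.

The default window length for simulated windows is the study's 50 kb; the
shipped grids and the reproduction script run 5-kb windows with
correspondingly more replicates, which leaves all expectations unchanged
while keeping a full grid under a few minutes on one core. Replicate
defaults are 300 per cell (the study design); the reproduction script uses
more (600 equilibrium windows, 4000 per grid cell) purely to shrink
Monte-Carlo error, because grid extremes are order statistics over noisy
cells and contraction cells are nearly recombination-free on their own
coalescent timescale (per-window diversity there has a coefficient of
variation near 2).

## Resampling layer

* **Block jackknife** (default 1-Mb blocks, much longer than linkage
  disequilibrium): the weighted delete-m form (Busing) because terminal
  genome blocks hold unequal window counts; with equal blocks it reduces to
  the classical delete-one formula, and with one window per block to
  `sd/sqrt(n)`. The point estimate is always the plain mean.
* **Mantel tests** are re-implemented: Pearson correlation of upper
  triangles with joint row/column permutation of the second matrix,
  one-sided (positive) by default to match the directional hypotheses; all
  `n!` permutations are enumerated when that is no more than the requested
  permutation count, making small-matrix p values exact. The reported
  `r_squared` is the square of the Mantel correlation.
* **Direction of ratio tests.** Both proxies for migration opportunity —
  geographic distance and autosomal `dXY` — *decrease* with opportunity,
  so `ratio_vs_proxy_test` negates the proxy before the one-sided test: a
  positive correlation then reads "higher Z/A ratio where gene flow is
  easier".

Geographic distances are haversine on a sphere of radius 6371 km, from
per-population mean coordinates (or per-individual coordinates for
individual-level matrices). Population-pair ratios use genome-wide mean
`dXY` values, not per-window ratios, because windows are not pairable
across chromosome classes.

## Synthetic studies

`generate_study()` emits a complete, self-contained study from known truth:
populations on a 1-D transect with migration decaying geometrically with
transect distance (an isolation-by-distance emulation; real geography is
not modeled), two autosomal contigs and one Z contig tiled with independent
windows, hemizygous female Z genotypes written homozygous-diploid the way
variant callers emit them, and per-genotype DP/GQ values drawn to straddle
the filter thresholds. `truth.json` records all parameters plus closed-form
expectations where they exist (equilibrium diversity, `m = 0` divergence),
with tolerances sized from the windows' Monte-Carlo error and the
invariant-site missingness bias discussed above. What passing recovery
tests show is that the pipeline is internally consistent under the
generator's assumptions (free recombination between windows, no selection,
no reference or mapping artifacts); they cannot certify behaviour on real
alignments.

## Degenerate inputs and numerical conventions

`FST` is `NaN` when `pi_T = 0`; pairwise statistics are `NaN` when no pair
shares a called site, with the window flagged rather than dropped;
Tajima's `D` is `NaN` for `S = 0` or fewer than four haplotypes, and under
missingness uses only sites called in at least 75% of haplotypes so the
frequency-spectrum constants stay meaningful. Site thinning is greedy
left-to-right with a fixed minimum gap (default 500 bp) and requires
coverage in every population. All internal coordinates are 0-based
half-open; VCF positions are converted at the boundary. Multi-allelic
sites are reduced to their two most frequent alleles, the rest set
missing, since every statistic here is pairwise-difference based. All
randomness flows from explicit integer seeds through a Lehmer substream
spawner, so every table is reproducible from its manifest.

## Known limitations

* Variants-only input hides missingness at invariant sites (bias discussed
  above); provide an all-sites VCF when exact denominators matter.
* The transect generator ties all populations to one common merge time, so
  at desk scale the Z/A ratio between *distant* transect pairs sits near
  the isolation baseline while close pairs are pulled toward metapopulation
  diversity — connectivity geometry, not Z migration reduction, dominates
  the ratio-versus-distance trend in such joint fixtures. Detection of
  reduced effective Z migration is therefore validated on the
  two-population split design (`run_two_pop_grid`), where the
  `dXY(Z)/dXY(A)` elevation grows with `m`, matching how the study's own
  simulated comparisons are constructed.
* The simulator has no selection, no gene conversion, and one merge time
  for all demes; the two-deme models are the validated surface.
* Longitude means are naive near the antimeridian (flagged with a
  warning).
* Tajima's D under missingness treats the row count as the sample size at
  retained sites, an approximation that vanishes with complete data.
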