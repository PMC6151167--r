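# zdiv

Z-chromosome versus autosome diversity and divergence under
non-equilibrium demography.

## What it is for

With an even sex ratio, a ZW sex chromosome has an effective population
size three quarters that of the autosomes, so Z-linked nucleotide
diversity is expected to be `0.75 x` autosomal diversity — *at
equilibrium*. Population size changes break that benchmark: the smaller Z
relaxes to its new equilibrium faster, so recent expansions push the Z/A
diversity ratio above 0.75 and contractions pull it below, confounding
naive comparisons of divergence between sex chromosomes and autosomes.
`zdiv` is for population geneticists who want to (a) measure windowed
diversity and divergence from resequencing genotypes with proper handling
of hemizygous females, (b) simulate the matching demographic null
expectations, and (c) test for reduced effective migration on the Z by
relating `dXY(Z)/dXY(A)` ratios to geographic proximity.

The statistic layer computes, per non-overlapping window:

* within-population diversity `pi_i` (mean pairwise differences per site),
* `pi_S = w pi_1 + (1 - w) pi_2` with `w = n1/(n1+n2)`,
* pooled diversity `pi_T`, Hudson's `FST = (pi_T - pi_S)/pi_T`,
* absolute divergence `dXY` (mean over the `n1 x n2` between-population
  pairs), net divergence `da = dXY - pi_S`, and Tajima's `D`,

with per-genotype DP/GQ filtering, the window inclusion rule (>= 10% of
positions genotyped in >= 75% of individuals, per population), 1-Mb
block-jackknife standard errors, 500-bp site thinning for individual-level
`dXY` matrices, and permutation Mantel tests. The simulation layer is a
structured coalescent with recombination (ancestral recombination graph,
written in C++) supporting one size change or a two-population split with
migration, with the Z simulated at `0.75 Ne` and migration reduced by a
factor `d`.

## Worked example

Simulate equilibrium 5-kb windows for a large constant-size population and
check diversity against `theta = 4 Ne mu = 0.024`:

```r
library(zdiv)
m  <- demographic_model(Ne = 3e6, mu = 2e-9, locus_length = 5000)
ss <- simulate_sites(m, "autosome", n_reps = 5, seed = 42)
sapply(ss, function(s) ncol(s$alleles))
#> [1] 326 362 302 400 386
sapply(ss, function(s) mean_pairwise_diff(s$alleles) * ncol(s$alleles) / 5000)
#> [1] 0.02491 0.02452 0.02169 0.02748 0.02572
```

Each window carries a few hundred segregating sites and per-site diversity
scatters around 0.024, as expected. The size-change response surface shows
how demography moves the Z/A ratio and Tajima's `D` (three magnitudes, two
change times, 200 replicates per cell):

```r
g <- run_size_change_grid(x_grid = c(0.01, 1, 100), t_grid = c(1e5, 4e6),
                          n_reps = 200, seed = 9)
g[, c("x", "t", "ratio_z_a", "mean_d_auto")]
#>       x     t ratio_z_a mean_d_auto
#> 1 1e-02 1e+05     0.368      0.5340
#> 2 1e+00 1e+05     0.778     -0.0699
#> 3 1e+02 1e+05     0.754     -0.0576
#> 4 1e-02 4e+06     0.760     -0.0786
#> 5 1e+00 4e+06     0.752     -0.0449
#> 6 1e+02 4e+06     0.847     -1.1500
```

Read it row by row: a 100-fold contraction 1e5 generations ago crushes the
ratio to 0.37 with strongly positive `D`; no change stays at the 0.75
equilibrium with `D ~ 0`; a 100-fold expansion has barely registered at
`t = 1e5` but by `t = 4e6` has lifted the ratio to 0.85 with strongly
negative `D`. Contractions act fast and fade; expansions act slowly and
persist.

The empirical path runs from a VCF instead: `load_genotypes()` +
`window_stats()` + `block_jackknife()`, then `thin_sites()` +
`pairwise_individual_dxy()` + `za_ratio_matrix()` +
`ratio_vs_proxy_test()`. The whole chain, including a synthetic study
generated from known truth, is wired together by:

```r
run_pipeline("all", system.file("extdata", "smoke.yaml", package = "zdiv"),
             out_dir = "smoke_out")
```

which exits with an error if any recovered statistic misses its recorded
truth tolerance, and writes window tables, jackknife summaries, dXY and
ratio matrices, binned ratio series, Mantel tests and a run manifest under
`smoke_out/`. A thin command-line front end wraps the same function:
`Rscript $(Rscript -e 'cat(system.file("cli","zdiv.R",package="zdiv"))') all --config smoke.yaml`.

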