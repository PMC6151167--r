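# Windowed diversity and divergence statistics against hand counts and
# brute-force oracles.

test_that("toy two-population fixture reproduces hand-enumerated values", {
  p1 <- mean_pairwise_diff(toy_pop1)
  p2 <- mean_pairwise_diff(toy_pop2)
  pt <- pi_total(toy_pop1, toy_pop2)
  ps <- pi_s(p1, p2, 2, 2)
  dx <- dxy(toy_pop1, toy_pop2)
  expect_equal(p1, 0.1)
  expect_equal(p2, 0.1)
  expect_equal(ps, 0.1)
  expect_equal(pt, 0.2)
  expect_equal(fst_hudson(pt, ps), 0.5)
  expect_equal(dx, 0.25)
  expect_equal(d_a(dx, ps), 0.15)
})

test_that("mean pairwise difference matches the exhaustive-pair oracle", {
  for (seed in 1:8) {
    m <- random_alleles(6, 40, miss = if (seed %% 2) 0.25 else 0, seed = seed)
    expect_equal(mean_pairwise_diff(m), oracle_pi(m), tolerance = 1e-12)
  }
  # explicit pair subsets
  m <- random_alleles(5, 30, miss = 0.2, seed = 99)
  pairs <- rbind(c(1, 2), c(3, 5))
  expect_equal(mean_pairwise_diff(m, pairs),
               oracle_pi(m, list(c(1, 2), c(3, 5))), tolerance = 1e-12)
})

test_that("degenerate inputs follow the NaN contracts", {
  ident <- matrix(0L, 4, 12)
  expect_equal(mean_pairwise_diff(ident), 0)
  allmiss <- matrix(NA_integer_, 3, 10)
  expect_true(is.nan(mean_pairwise_diff(allmiss)))
  # two haplotypes: pi_total equals the single pairwise difference
  a <- matrix(c(0L, 1L, 0L, 0L, 1L, 0L), 1, 6)
  b <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L), 1, 6)
  expect_equal(pi_total(a, b), 2 / 6)
  expect_true(is.nan(fst_hudson(0, 0)))
  expect_equal(fst_hudson(0.2, 0.2), 0)
  expect_equal(d_a(0.01, 0.02), -0.01)
})

test_that("dxy agrees with the cross-pair oracle and its identities", {
  for (seed in 11:14) {
    m1 <- random_alleles(4, 30, miss = 0.2, seed = seed)
    m2 <- random_alleles(3, 30, miss = 0.2, seed = seed + 100)
    expect_equal(dxy(m1, m2), oracle_dxy(m1, m2), tolerance = 1e-12)
    expect_equal(dxy(m1, m2), dxy(m2, m1), tolerance = 1e-12)
  }
  # a population of identical haplotypes copied: within = between = 0
  m <- matrix(0L, 2, 8)
  expect_equal(dxy(m, m), mean_pairwise_diff(m))
  # single haplotype each: 3 differences over 10 sites
  h1 <- matrix(c(1L, 1L, 1L, rep(0L, 7)), 1, 10)
  h2 <- matrix(0L, 1, 10)
  expect_equal(dxy(h1, h2), 0.3)
})

test_that("merging two copies of one population collapses differentiation", {
  m <- random_alleles(5, 60, seed = 42)
  p1 <- mean_pairwise_diff(m)
  expect_equal(pi_total(m, m), dxy(m, m) * (25 / 45) + p1 * (20 / 45),
               tolerance = 1e-12)
  ps <- pi_s(p1, p1, 5, 5)
  # FST for a population against itself is ~0 (dxy includes self-pairs,
  # which only lifts pi_T above pi_S by the within/between pair mix)
  expect_equal(ps, p1)
  expect_equal(d_a(p1, p1), 0)
})

test_that("Tajima's D matches the independent constants oracle", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    S <- sample(5:60, 1)
    m <- matrix(0L, n, S)
    for (s in seq_len(S)) {
      k <- sample(1:(n - 1), 1)
      m[sample(n, k), s] <- 1L
    }
    expect_equal(tajimas_d(m), oracle_tajima_d(m), tolerance = 1e-12)
  }
})

test_that("Tajima's D degenerate contracts hold", {
  expect_true(is.nan(tajimas_d(matrix(0L, 10, 20))))       # S = 0
  expect_true(is.nan(tajimas_d(random_alleles(3, 20))))    # n < 4
})

test_that("Tajima's D is centred near zero for neutral constant-size data", {
  ss <- cached("neutral300", {
    m <- demographic_model(n_samples = 10, Ne = 1e5, locus_length = 5000,
                           mu = 2e-8)
    simulate_sites(m, "autosome", n_reps = 300, seed = 2024)
  })
  d <- vapply(ss, function(s) tajimas_d(s$alleles), numeric(1))
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.1)
})

test_that("window filter enforces the per-population coverage rule", {
  meta <- two_pop_meta(2, 2)
  owner <- rep(meta$sample, each = 2)
  span <- 1000

  full <- make_window(matrix(0L, 8, 50), owner, end = span,
                      positions = seq(0, 49), assume_callable = FALSE)
  full$alleles[1, 1] <- 1L  # one variant so statistics are defined
  ws <- window_stats(full, c("A", "B"), meta,
                     stat_config(window_span = span))
  expect_false(ws$passed_filter)  # 50/1000 positions genotyped is below 10%

  # under assume_callable the unlisted positions are implicitly genotyped
  full$assume_callable <- TRUE
  ws <- window_stats(full, c("A", "B"), meta,
                     stat_config(window_span = span))
  expect_true(ws$passed_filter)
  expect_equal(ws$da, ws$dxy - ws$pi_s, tolerance = 1e-12)
  expect_equal(ws$fst, 1 - ws$pi_s / ws$pi_t, tolerance = 1e-12)

  # 4% of positions genotyped: fails in both populations
  sparse <- make_window(matrix(NA_integer_, 8, 200), owner, end = span,
                        positions = seq(0, 199))
  sparse$alleles[, 1:40] <- 0L
  ws <- window_stats(sparse, c("A", "B"), meta,
                     stat_config(window_span = span))
  expect_false(ws$passed_filter)
  expect_true(is.nan(ws$pi_1))

  # passing in one population but failing in the other fails the window
  half <- make_window(matrix(NA_integer_, 8, 200), owner, end = span,
                      positions = seq(0, 199))
  half$alleles[1:4, ] <- 0L   # population A covered, B empty
  ws <- window_stats(half, c("A", "B"), meta,
                     stat_config(window_span = span))
  expect_false(ws$passed_filter)
})

test_that("window statistics are invariant to population relabeling", {
  meta <- two_pop_meta(3, 3)
  owner <- rep(meta$sample, each = 2)
  w <- make_window(random_alleles(12, 80, miss = 0.1, seed = 5), owner,
                   end = 1000, positions = seq(0, 79),
                   assume_callable = TRUE)
  ab <- window_stats(w, c("A", "B"), meta, stat_config(window_span = 1000))
  ba <- window_stats(w, c("B", "A"), meta, stat_config(window_span = 1000))
  expect_equal(ab$pi_t, ba$pi_t)
  expect_equal(ab$fst, ba$fst)
  expect_equal(ab$dxy, ba$dxy)
  expect_equal(ab$da, ba$da)
  expect_equal(ab$pi_1, ba$pi_2)
})

test_that("site thinning follows the greedy gap rule and coverage rule", {
  meta <- two_pop_meta(1, 1)
  owner <- rep(meta$sample, each = 2)
  al <- matrix(0L, 4, 3)
  al[1, ] <- 1L
  w <- make_window(al, owner, start = 0, end = 1000,
                   positions = c(100, 400, 700))
  th <- thin_sites(list(w), meta, min_gap = 500)
  expect_equal(th$positions, c(100, 700))

  # site with coverage only in one population is dropped
  al2 <- al
  al2[3:4, 3] <- NA_integer_  # pop B missing at position 700
  w2 <- make_window(al2, owner, start = 0, end = 1000,
                    positions = c(100, 400, 700))
  th2 <- thin_sites(list(w2), meta, min_gap = 500)
  expect_equal(th2$positions, 100)

  # empty input
  th0 <- thin_sites(list(), meta, min_gap = 500)
  expect_length(th0$positions, 0)
})

test_that("individual dXY matrix matches a brute-force recount", {
  meta <- two_pop_meta(2, 2)
  owner <- rep(meta$sample, each = 2)
  al <- random_alleles(8, 20, miss = 0.15, seed = 31)
  thin <- list(positions = seq(0, 19) * 600, chromosome = rep("chr1", 20),
               alleles = al, haplotype_owner = owner)
  M <- pairwise_individual_dxy(thin)
  expect_true(isSymmetric(M))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    mi <- al[(2 * i - 1):(2 * i), , drop = FALSE]
    mj <- al[(2 * j - 1):(2 * j), , drop = FALSE]
    expect_equal(M[i, j], oracle_dxy(mi, mj), tolerance = 1e-12)
  }
  # identical homozygous individuals have zero distance and heterozygosity
  hom <- matrix(0L, 4, 10)
  thin2 <- list(positions = seq(0, 9) * 600, chromosome = rep("chr1", 10),
                alleles = hom, haplotype_owner = owner[1:4])
  M2 <- pairwise_individual_dxy(thin2)
  expect_equal(unname(M2), matrix(0, 2, 2))
})

test_that("simulated equilibrium diversity recovers theta", {
  ss <- cached("theta300", {
    m <- demographic_model(n_samples = 10, Ne = 3e6, locus_length = 5000)
    simulate_sites(m, "autosome", n_reps = 300, seed = 77)
  })
  L <- 5000
  pis <- vapply(ss, function(s) {
    if (ncol(s$alleles) == 0) return(0)
    mean_pairwise_diff(s$alleles) * ncol(s$alleles) / L
  }, numeric(1))
  theta <- 4 * 3e6 * 2e-9
  expect_lt(abs(mean(pis) - theta) / theta, 0.05)
})
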