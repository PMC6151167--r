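# Coalescent engine against closed-form expectations and an independent
# simulator. Tolerances reflect Monte-Carlo error at the replicate counts
# used (fixed seeds make the runs reproducible).

test_that("pairwise TMRCA matches the constant-size closed form", {
  m <- demographic_model(n_samples = 2, Ne = 1e4, rho = 0,
                         locus_length = 1000)
  tm <- vapply(1:1000, function(i)
    ts_branch_stats(simulate_genealogies(m, seed = i))$tmrca, numeric(1))
  expect_lt(abs(mean(tm) - 2e4) / 2e4, 0.1)
})

test_that("total branch length matches 4 Ne sum(1/i)", {
  m <- demographic_model(n_samples = 10, Ne = 1e4, rho = 0,
                         locus_length = 1000)
  tl <- vapply(1:600, function(i)
    ts_branch_stats(simulate_genealogies(m, seed = i + 5000))$total_length,
    numeric(1))
  expected <- 4e4 * sum(1 / (1:9))
  expect_lt(abs(mean(tl) - expected) / expected, 0.1)
})

test_that("Z-class scaling shortens pairwise coalescence by three quarters", {
  m <- demographic_model(n_samples = 2, Ne = 1e4, rho = 0,
                         locus_length = 1000)
  ta <- vapply(1:1500, function(i)
    ts_branch_stats(simulate_genealogies(m, "autosome", seed = i))$tmrca,
    numeric(1))
  tz <- vapply(1:1500, function(i)
    ts_branch_stats(simulate_genealogies(m, "Z", seed = i + 9000))$tmrca,
    numeric(1))
  expect_lt(abs(mean(tz) / mean(ta) - 0.75), 0.075)
})

test_that("mutation dropping recovers theta and respects mu = 0", {
  m <- demographic_model(n_samples = 2, Ne = 3e6, locus_length = 5000)
  ts <- simulate_genealogies(m, seed = 4)
  expect_equal(ncol(drop_mutations(ts, mu = 0, seed = 1)$alleles), 0L)

  ss <- simulate_sites(m, "autosome", n_reps = 300, seed = 31)
  pis <- vapply(ss, function(s) ncol(s$alleles) / 5000 *
                  (if (ncol(s$alleles) > 0) mean_pairwise_diff(s$alleles)
                   else 0), numeric(1))
  theta <- 4 * 3e6 * 2e-9
  expect_lt(abs(mean(pis) - theta) / theta, 0.05)
})

test_that("site frequency spectrum is proportional to 1/i", {
  ss <- cached("theta300", {
    m <- demographic_model(n_samples = 10, Ne = 3e6, locus_length = 5000)
    simulate_sites(m, "autosome", n_reps = 300, seed = 77)
  })
  counts <- Reduce(`+`, lapply(ss, function(s) {
    if (ncol(s$alleles) == 0) return(rep(0, 9))
    tabulate(colSums(s$alleles), nbins = 9)
  }))
  expected <- (1 / (1:9)) / sum(1 / (1:9)) * sum(counts)
  # relative deviation per class stays small at this sample size
  expect_lt(max(abs(counts - expected) / expected), 0.1)
})

test_that("statistic means are invariant to recombination, variance is not", {
  m0 <- demographic_model(n_samples = 6, Ne = 1e6, rho = 0,
                          locus_length = 5000, mu = 2e-8)
  m1 <- demographic_model(n_samples = 6, Ne = 1e6, rho = 0.01,
                          locus_length = 5000, mu = 2e-8)
  pi_of <- function(m, seed) vapply(simulate_sites(m, "autosome", 400, seed),
                                    function(s) if (ncol(s$alleles) == 0) 0
                                    else mean_pairwise_diff(s$alleles) *
                                      ncol(s$alleles) / 5000, numeric(1))
  p0 <- pi_of(m0, 1); p1 <- pi_of(m1, 2)
  expect_lt(abs(mean(p0) - mean(p1)) / mean(p1), 0.1)
  expect_gt(var(p0), var(p1))  # recombination averages trees within windows
})

test_that("two-population isolation matches the dXY closed form", {
  m <- demographic_model(n_samples = 10, Ne = 2e6, split_time = 1e6,
                         locus_length = 5000)
  ss <- simulate_sites(m, "autosome", n_reps = 250, seed = 11)
  dx <- vapply(ss, function(s) {
    a1 <- s$alleles[1:10, , drop = FALSE]
    a2 <- s$alleles[11:20, , drop = FALSE]
    if (ncol(s$alleles) == 0) return(0)
    dxy(a1, a2) * ncol(s$alleles) / 5000
  }, numeric(1))
  expected <- 2 * 2e-9 * (1e6 + 2 * 2e6)
  expect_lt(abs(mean(dx) - expected) / expected, 0.05)
})

test_that("simulated statistics are exchangeable under deme relabeling", {
  m <- demographic_model(n_samples = 10, Ne = 2e6, split_time = 1e6,
                         migration = 5e-7, locus_length = 5000)
  ss <- simulate_sites(m, "autosome", n_reps = 5, seed = 8)
  for (s in ss) {
    a1 <- s$alleles[1:10, , drop = FALSE]
    a2 <- s$alleles[11:20, , drop = FALSE]
    if (ncol(s$alleles) == 0) next
    expect_equal(dxy(a1, a2), dxy(a2, a1))
    expect_equal(pi_total(a1, a2), pi_total(a2, a1))
  }
})

test_that("tree sequences are structurally valid", {
  m <- demographic_model(n_samples = 8, Ne = 1e5, rho = 0.01,
                         locus_length = 2000)
  for (seed in 1:5) {
    ts <- simulate_genealogies(m, seed = seed)
    e <- ts$edges
    expect_true(all(e$left < e$right))
    expect_true(all(ts$node_time[e$parent + 1] >
                      ts$node_time[e$child + 1] - 1e-9))
    # every position is covered by exactly n_samples - 1 coalescences:
    # each marginal tree is binary with 2n - 2 edges
    mids <- (c(0, sort(unique(c(e$left, e$right)))) +
               c(sort(unique(c(e$left, e$right))), 2000)) / 2
    mids <- mids[mids > 0 & mids < 2000]
    for (x in mids[seq(1, length(mids), length.out = min(8, length(mids)))]) {
      cover <- e$left <= x & x < e$right
      expect_equal(sum(cover), 2L * ts$n_samples - 2L)
    }
  }
})

test_that("distributions of S and pi match an independent coalescent engine", {
  script <- test_path("msprime_oracle.py")
  out_json <- tempfile(fileext = ".json")
  status <- system2("python", c(script, out_json), stdout = TRUE,
                    stderr = TRUE)
  ref <- jsonlite::read_json(out_json, simplifyVector = TRUE)

  run_set <- function(model, reps, seed) {
    ss <- simulate_sites(model, "autosome", reps, seed)
    list(S = vapply(ss, function(s) ncol(s$alleles), numeric(1)),
         pi = vapply(ss, function(s) if (ncol(s$alleles) == 0) 0 else
           mean_pairwise_diff(s$alleles) * ncol(s$alleles), numeric(1)))
  }
  sets <- list(
    constant = demographic_model(n_samples = 10, Ne = 1e5, mu = 2e-8,
                                 rho = 0.01, locus_length = 5000),
    expansion = demographic_model(n_samples = 10, Ne = 1e5, mu = 2e-8,
                                  rho = 0.01, locus_length = 5000,
                                  size_change = list(x = 10, t = 1e5)),
    split = demographic_model(n_samples = 10, Ne = 1e5, mu = 2e-8,
                              rho = 0.01, locus_length = 5000,
                              split_time = 2e5, migration = 1e-6))
  for (nm in names(sets)) {
    mine <- run_set(sets[[nm]], 300, seed = match(nm, names(sets)) * 1000)
    expect_gt(suppressWarnings(
      stats::ks.test(mine$S, ref[[nm]]$S))$p.value, 0.01)
    expect_gt(suppressWarnings(
      stats::ks.test(mine$pi, ref[[nm]]$pi))$p.value, 0.01)
  }
})
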