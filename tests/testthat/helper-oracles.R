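# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit loops, from-scratch constants, and
# exhaustive enumeration, so each test compares two independent routes to
# the same quantity.

# mean per-pair-normalized pairwise difference by explicit double loops
oracle_pi <- function(m, pairs = NULL) {
  n <- nrow(m)
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  vals <- sapply(pairs, function(p) {
    a <- m[p[1L], ]; b <- m[p[2L], ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    sum(a[ok] != b[ok]) / sum(ok)
  })
  if (all(is.na(vals))) NaN else mean(vals, na.rm = TRUE)
}

oracle_dxy <- function(m1, m2) {
  vals <- c()
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
    a <- m1[i, ]; b <- m2[j, ]
    ok <- !is.na(a) & !is.na(b)
    vals <- c(vals, if (!any(ok)) NA_real_ else sum(a[ok] != b[ok]) / sum(ok))
  }
  if (all(is.na(vals))) NaN else mean(vals, na.rm = TRUE)
}

# Tajima's D with constants recomputed from scratch (complete-data matrices)
oracle_tajima_d <- function(m) {
  n <- nrow(m)
  if (n < 4) return(NaN)
  freq <- colSums(m)
  seg <- freq > 0 & freq < n
  S <- sum(seg)
  if (S == 0) return(NaN)
  k <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(m[i, ] != m[j, ])
    npairs <- npairs + 1
  }
  k <- k / npairs
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# classical delete-one-block jackknife for equal-sized blocks
oracle_jackknife_se_equal <- function(block_means) {
  g <- length(block_means)
  leave_out <- sapply(seq_len(g), function(j) mean(block_means[-j]))
  sqrt((g - 1) / g * sum((leave_out - mean(leave_out))^2))
}

# exhaustive-permutation one-sided Mantel p (identity included)
oracle_mantel_exact_p <- function(A, B) {
  n <- nrow(A)
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  perm_all <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (s in perm_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], s)
    out
  }
  rs <- sapply(perm_all(seq_len(n)), function(p) {
    Bp <- B[p, p]
    cor(A[ut], Bp[ut])
  })
  mean(rs >= r_obs - 1e-12)
}

# the 10-site two-population toy: pop1 = {AAAAAAAAAA, AAAAAAAAAT},
# pop2 = {TTAAAAAAAA, TTAAAAAAAT}, coded 0 = A, 1 = T
toy_pop1 <- rbind(rep(0L, 10), c(rep(0L, 9), 1L))
toy_pop2 <- rbind(c(1L, 1L, rep(0L, 8)), c(1L, 1L, rep(0L, 7), 1L))

# a random allele matrix with optional missingness
random_alleles <- function(n, S, miss = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * S, 1L, runif(1, 0.1, 0.9)), n, S)
  if (miss > 0) m[matrix(runif(n * S) < miss, n, S)] <- NA_integer_
  m
}

# minimal genotype_window constructor for unit tests
make_window <- function(alleles, owner, chromosome = "chr1", start = 0,
                        end = 1000, positions = NULL, class = "autosome",
                        assume_callable = FALSE) {
  if (is.null(positions))
    positions <- seq(start, length.out = ncol(alleles))
  structure(list(chromosome = chromosome, start = start, end = end,
                 alleles = alleles, site_positions = positions,
                 haplotype_owner = owner,
                 ploidy = table(owner), class = class,
                 assume_callable = assume_callable),
            class = "genotype_window")
}

two_pop_meta <- function(n1 = 2, n2 = 2) {
  data.frame(sample = c(sprintf("a%d", seq_len(n1)),
                        sprintf("b%d", seq_len(n2))),
             population = rep(c("A", "B"), c(n1, n2)),
             sex = "male", lat = 0, lon = 0, stringsAsFactors = FALSE)
}

# cache for expensive shared simulations (computed once per test run)
.zdiv_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .zdiv_cache)) assign(key, force(expr), .zdiv_cache)
  get(key, .zdiv_cache)
}
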