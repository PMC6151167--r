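#' Simulate marginal genealogies under a demographic model
#'
#' Runs a structured coalescent with recombination (an ancestral
#' recombination graph with tracked ancestral material) and returns the
#' marginal tree sequence as an edge table: each edge records the sequence
#' interval over which a parent-child relationship holds, together with node
#' times in generations. Lineages coalesce at rate `k(k-1)/2` per `2N(t)`
#' generations within each deme, migrate at the model's per-generation rate,
#' and recombine at the physical rate times the length of ancestral material
#' they carry; at the split time (backwards) the demes merge.
#'
#' @param model a [demographic_model()].
#' @param chrom_class `"autosome"` or `"Z"`; Z runs use the scaled sizes and
#'   migration from [scale_model()].
#' @param seed integer seed for the simulation's random stream.
#' @return an object of class `tree_sequence`: a list with `edges`
#'   (data.frame `left`, `right`, `parent`, `child`), `node_time`
#'   (generations), `n_samples` and `locus_length`.
#' @examples
#' ts <- simulate_genealogies(demographic_model(Ne = 1e4, locus_length = 1e3),
#'                            seed = 1)
#' ts_branch_stats(ts)
#' @export
simulate_genealogies <- function(model, chrom_class = "autosome", seed = 1L) {
  stopifnot(inherits(model, "demographic_model"))
  sc <- scale_model(model, chrom_class)
  raw <- arg_simulate_cpp(sc$n_per_deme, sc$epoch_start, sc$epoch_sizes,
                          sc$merge_time, sc$mig, sc$rec_rate,
                          sc$locus_length, as.integer(seed))
  structure(
    list(edges = data.frame(left = raw$left, right = raw$right,
                            parent = raw$parent, child = raw$child),
         node_time = raw$node_time,
         n_samples = raw$n_samples,
         locus_length = sc$locus_length),
    class = "tree_sequence")
}

#' Drop infinite-sites mutations onto a tree sequence
#'
#' Mutations occur as a Poisson process with intensity `mu` per bp per
#' generation along every branch over the interval it spans; each mutation
#' creates a unique segregating site at a real-valued position, carried by
#' the sample leaves below the mutated branch.
#'
#' @param ts a `tree_sequence` from [simulate_genealogies()].
#' @param mu mutation rate per bp per generation.
#' @param seed integer seed.
#' @return an object of class `seg_sites`: a list with `positions` (bp,
#'   ascending) and `alleles`, a haplotype-by-site 0/1 matrix.
#' @export
drop_mutations <- function(ts, mu, seed = 1L) {
  stopifnot(inherits(ts, "tree_sequence"), mu >= 0)
  raw <- drop_mutations_cpp(ts$edges$left, ts$edges$right, ts$edges$parent,
                            ts$edges$child, ts$node_time, ts$n_samples,
                            mu, as.integer(seed))
  structure(list(positions = raw$positions, alleles = raw$alleles,
                 locus_length = ts$locus_length),
            class = "seg_sites")
}

#' Simulate segregating-site matrices for replicate windows
#'
#' Convenience wrapper running [simulate_genealogies()] and
#' [drop_mutations()] for `n_reps` independent windows. Per-replicate seeds
#' are spawned deterministically from `seed`.
#'
#' @inheritParams simulate_genealogies
#' @param n_reps number of independent replicate windows.
#' @return a list of `seg_sites` objects.
#' @export
simulate_sites <- function(model, chrom_class = "autosome", n_reps = 1L,
                           seed = 1L) {
  seeds <- spawn_seeds(seed, 2L * n_reps)
  lapply(seq_len(n_reps), function(i) {
    ts <- simulate_genealogies(model, chrom_class, seed = seeds[2L * i - 1L])
    drop_mutations(ts, model$mu, seed = seeds[2L * i])
  })
}

# deterministic substream seeds below 2^31, independent of the global RNG
spawn_seeds <- function(seed, n) {
  x <- as.double(seed %% 2147483647L)
  if (x <= 0) x <- x + 2147483646
  out <- numeric(n)
  for (i in seq_len(n)) {
    # Lehmer / Park-Miller step
    x <- (16807 * x) %% 2147483647
    out[i] <- x
  }
  as.integer(out)
}

#' Sequence-weighted branch statistics of a tree sequence
#'
#' Computes the total branch length and time to the most recent common
#' ancestor, each averaged along the sequence with weights proportional to
#' the interval spanned by each marginal tree.
#'
#' @param ts a `tree_sequence`.
#' @return list with `total_length` and `tmrca`, both in generations.
#' @export
ts_branch_stats <- function(ts) {
  e <- ts$edges
  L <- ts$locus_length
  blen <- ts$node_time[e$parent + 1L] - ts$node_time[e$child + 1L]
  total_length <- sum(blen * (e$right - e$left)) / L
  bp <- sort(unique(c(0, e$left, e$right, L)))
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  w <- diff(bp)
  tm <- vapply(mid, function(x) {
    cover <- e$left <= x & x < e$right
    if (!any(cover)) return(NA_real_)
    max(ts$node_time[e$parent[cover] + 1L])
  }, numeric(1))
  list(total_length = total_length,
       tmrca = sum(tm * w, na.rm = TRUE) / sum(w[!is.na(tm)]))
}

# summary statistics of one simulated window; population labels follow the
# model's sample layout (pop 1 rows first)
sim_window_stats <- function(ss, n1, n2 = 0L) {
  L <- ss$locus_length
  m <- ss$alleles
  if (n2 == 0L) {
    list(pi = pairwise_diff_count(m)$mean_diff / L,
         tajima_d = tajimas_d(m))
  } else {
    a1 <- m[seq_len(n1), , drop = FALSE]
    a2 <- m[n1 + seq_len(n2), , drop = FALSE]
    p1 <- pairwise_diff_count(a1)$mean_diff / L
    p2 <- pairwise_diff_count(a2)$mean_diff / L
    pt <- pairwise_diff_count(m)$mean_diff / L
    dxy <- cross_diff_count(a1, a2)$mean_diff / L
    ps <- pi_s(p1, p2, n1, n2)
    list(pi1 = p1, pi2 = p2, pi_t = pt, pi_s = ps,
         fst = fst_hudson(pt, ps), dxy = dxy, da = d_a(dxy, ps))
  }
}

#' Single-population size-change response surface
#'
#' Simulates, for every combination of size-change magnitude `x` and time
#' `t`, replicate windows for the autosomal and Z parameterizations and
#' summarizes mean nucleotide diversity, mean Tajima's D, and the Z/A
#' diversity ratio (computed as the ratio of mean diversities).
#'
#' @param x_grid magnitudes of the size change (present size / size before
#'   the change, forward in time). Default `c(0.01, 0.1, 1, 10, 100)`.
#' @param t_grid change times in generations. Default 10 points log-spaced
#'   between 1e3 and 4e6.
#' @param model base [demographic_model()] (its `size_change` field is
#'   overwritten cell by cell).
#' @param n_reps replicate windows per cell and chromosome class.
#' @param seed master seed; every cell and replicate derives its own stream.
#' @return data.frame with one row per `(x, t)` cell: `mean_pi_auto`,
#'   `mean_pi_z`, `ratio_z_a`, `mean_d_auto`, `mean_d_z`.
#' @export
run_size_change_grid <- function(x_grid = c(0.01, 0.1, 1, 10, 100),
                                 t_grid = 10^seq(3, log10(4e6), length.out = 10),
                                 model = demographic_model(Ne = 3e6,
                                                           locus_length = 5000),
                                 n_reps = 300L, seed = 1L) {
  cells <- expand.grid(x = x_grid, t = t_grid, KEEP.OUT.ATTRS = FALSE)
  seeds <- spawn_seeds(seed, nrow(cells))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    m <- model
    m$size_change <- list(x = cells$x[i], t = cells$t[i])
    cs <- spawn_seeds(seeds[i], 2L)
    out <- Map(function(cls, s) {
      reps <- simulate_sites(m, cls, n_reps, seed = s)
      st <- lapply(reps, sim_window_stats, n1 = m$n_samples[1L])
      c(pi = mean(vapply(st, `[[`, numeric(1), "pi")),
        d = mean(vapply(st, `[[`, numeric(1), "tajima_d"), na.rm = TRUE))
    }, list(autosome = "autosome", Z = "Z"), list(cs[1L], cs[2L]))
    data.frame(x = cells$x[i], t = cells$t[i],
               mean_pi_auto = out$autosome[["pi"]],
               mean_pi_z = out$Z[["pi"]],
               ratio_z_a = out$Z[["pi"]] / out$autosome[["pi"]],
               mean_d_auto = out$autosome[["d"]],
               mean_d_z = out$Z[["d"]])
  })
  do.call(rbind, res)
}

#' Two-population split-and-migration response surface
#'
#' Simulates pairs of populations that split `T` generations ago and are
#' connected by symmetric migration `m`, with migration reduced by a factor
#' `d` on the Z chromosome, and summarizes the divergence statistics per
#' parameter combination.
#'
#' @param split_times split times `T` in generations.
#' @param m_grid per-generation migration probabilities.
#' @param d_grid Z migration reduction fractions.
#' @param model base two-population [demographic_model()] template; `Ne`,
#'   sample sizes, `mu`, `rho` and `locus_length` are taken from it.
#' @param n_reps replicate windows per cell and chromosome class.
#' @param seed master seed.
#' @return data.frame with one row per `(T, m, d)` cell: mean `dxy_auto`,
#'   `dxy_z`, `ratio_z_a = mean dxy_Z / mean dxy_A`, `fst_auto`, `da_auto`,
#'   `pi_s_auto`, and the Z-chromosome counterparts.
#' @export
run_two_pop_grid <- function(split_times = c(1e6, 2e6),
                             m_grid = c(0, 2.5e-7, 5e-7, 7.5e-7, 1e-6),
                             d_grid = 0.6,
                             model = demographic_model(Ne = 2e6,
                                                       split_time = 1e6,
                                                       locus_length = 5000),
                             n_reps = 300L, seed = 1L) {
  cells <- expand.grid(T = split_times, m = m_grid, d = d_grid,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- spawn_seeds(seed, nrow(cells))
  n1 <- model$n_samples[1L]
  n2 <- if (length(model$n_samples) > 1L) model$n_samples[2L] else n1
  res <- lapply(seq_len(nrow(cells)), function(i) {
    m <- model
    m$split_time <- cells$T[i]
    m$migration <- cells$m[i]
    m$z_migration_reduction <- cells$d[i]
    m$n_samples <- c(n1, n2)
    cs <- spawn_seeds(seeds[i], 2L)
    per_class <- Map(function(cls, s) {
      reps <- simulate_sites(m, cls, n_reps, seed = s)
      st <- lapply(reps, sim_window_stats, n1 = n1, n2 = n2)
      vapply(c("dxy", "fst", "da", "pi_s", "pi_t"), function(nm)
        mean(vapply(st, `[[`, numeric(1), nm), na.rm = TRUE), numeric(1))
    }, list(autosome = "autosome", Z = "Z"), list(cs[1L], cs[2L]))
    data.frame(T = cells$T[i], m = cells$m[i], d = cells$d[i],
               dxy_auto = per_class$autosome[["dxy"]],
               dxy_z = per_class$Z[["dxy"]],
               ratio_z_a = per_class$Z[["dxy"]] / per_class$autosome[["dxy"]],
               fst_auto = per_class$autosome[["fst"]],
               fst_z = per_class$Z[["fst"]],
               da_auto = per_class$autosome[["da"]],
               da_z = per_class$Z[["da"]],
               pi_s_auto = per_class$autosome[["pi_s"]],
               pi_s_z = per_class$Z[["pi_s"]])
  })
  do.call(rbind, res)
}
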