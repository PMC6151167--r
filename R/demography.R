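#' Specify a demographic model for the coalescent simulator
#'
#' Captures the two study designs simulated here: a single population
#' that underwent one instantaneous size change, and a pair of populations
#' that split from a common ancestor and exchange migrants. The Z chromosome
#' is simulated as a separate run of the same model with its effective size
#' multiplied by `z_scale` (three-quarters for a ZW system with an even sex
#' ratio) and its migration rate multiplied by `1 - z_migration_reduction`.
#' Time is expressed in generations and migration as a per-generation,
#' per-lineage probability, so those parameters are left untouched by the
#' Z scaling.
#'
#' @param n_samples integer vector, haplotypes sampled per population.
#'   The default, 10 per population, corresponds to five diploid individuals.
#' @param Ne autosomal effective population size (diploid individuals). For
#'   the size-change design this is the size *before* the change (looking
#'   forward in time); the present-day size is `x * Ne`.
#' @param z_scale multiplier applied to all effective sizes on the Z
#'   (default 0.75).
#' @param mu mutation rate per bp per generation (default 2e-9).
#' @param rho population recombination rate 4*Ne*r per bp (default 0.01).
#'   The physical rate r is derived as `rho / (4 * Ne)` using the class-scaled
#'   base size, so both chromosome classes are simulated at the same
#'   population-scaled recombination rate.
#' @param locus_length simulated window length in bp (default 50000).
#' @param size_change `NULL`, or `list(x = magnitude, t = generations)`:
#'   forward in time the population changed from size `Ne` to `x * Ne`,
#'   `t` generations before the present. `x > 1` is an expansion.
#' @param split_time `NULL` for a single population, otherwise the time in
#'   generations at which two sampled populations merge (backwards) into an
#'   ancestral population of size `Ne`.
#' @param migration symmetric per-generation migration probability between
#'   the two populations (ignored for a single population).
#' @param z_migration_reduction fraction `d` in `[0, 1]` by which migration
#'   is reduced on the Z chromosome.
#' @return an object of class `demographic_model`.
#' @examples
#' demographic_model(Ne = 3e6, size_change = list(x = 100, t = 1e5))
#' demographic_model(Ne = 2e6, split_time = 1e6, migration = 1e-6,
#'                   z_migration_reduction = 0.6)
#' @export
demographic_model <- function(n_samples = 10L,
                              Ne = 3e6,
                              z_scale = 0.75,
                              mu = 2e-9,
                              rho = 0.01,
                              locus_length = 50000,
                              size_change = NULL,
                              split_time = NULL,
                              migration = 0,
                              z_migration_reduction = 0) {
  n_samples <- as.integer(n_samples)
  stopifnot(all(n_samples >= 1), Ne > 0, mu >= 0, rho >= 0,
            locus_length > 0, z_scale > 0, z_scale <= 1,
            migration >= 0,
            z_migration_reduction >= 0, z_migration_reduction <= 1)
  if (!is.null(size_change)) {
    stopifnot(is.list(size_change), size_change$x > 0, size_change$t > 0)
    if (!is.null(split_time))
      stop("size_change and split_time cannot be combined in this model")
  }
  two_pop <- !is.null(split_time)
  if (two_pop) {
    stopifnot(split_time > 0)
    if (length(n_samples) == 1L) n_samples <- rep(n_samples, 2L)
    stopifnot(length(n_samples) == 2L)
  } else {
    stopifnot(length(n_samples) == 1L)
  }
  structure(
    list(n_samples = n_samples, Ne = Ne, z_scale = z_scale, mu = mu,
         rho = rho, locus_length = locus_length, size_change = size_change,
         split_time = split_time, migration = migration,
         z_migration_reduction = z_migration_reduction),
    class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model\n")
  cat(sprintf("  samples (haplotypes): %s\n",
              paste(x$n_samples, collapse = " + ")))
  cat(sprintf("  Ne (autosomal): %g, z_scale: %g\n", x$Ne, x$z_scale))
  cat(sprintf("  mu: %g /bp/gen, rho: %g /bp, locus: %g bp\n",
              x$mu, x$rho, x$locus_length))
  if (!is.null(x$size_change))
    cat(sprintf("  size change: x = %g at t = %g generations\n",
                x$size_change$x, x$size_change$t))
  if (!is.null(x$split_time))
    cat(sprintf("  split: T = %g generations, m = %g (Z reduction d = %g)\n",
                x$split_time, x$migration, x$z_migration_reduction))
  invisible(x)
}

#' Apply the chromosome-class scaling to a demographic model
#'
#' For the Z chromosome, all effective sizes are multiplied by `z_scale`
#' and migration by `1 - z_migration_reduction`; time- and rate-parameters
#' expressed in generations are unchanged. Autosomes pass through untouched.
#'
#' @param model a [demographic_model()].
#' @param chrom_class `"autosome"` or `"Z"`.
#' @return a list with the epoch structure used by the simulation engine:
#'   `n_per_deme`, `epoch_start`, `epoch_sizes`, `merge_time`, `mig`,
#'   `rec_rate` (per bp per generation), `locus_length`.
#' @export
scale_model <- function(model, chrom_class = c("autosome", "Z")) {
  chrom_class <- match.arg(chrom_class)
  scale <- if (chrom_class == "Z") model$z_scale else 1
  Ne <- model$Ne * scale
  m <- model$migration
  if (chrom_class == "Z") m <- m * (1 - model$z_migration_reduction)

  if (is.null(model$split_time)) {
    n_deme <- 1L
    n_per_deme <- model$n_samples[1L]
    if (is.null(model$size_change)) {
      epoch_start <- 0
      epoch_sizes <- matrix(Ne, 1, 1)
    } else {
      # backwards: present size x*Ne until t, ancestral Ne beyond
      epoch_start <- c(0, model$size_change$t)
      epoch_sizes <- matrix(c(model$size_change$x * Ne, Ne), 2, 1)
    }
    merge_time <- Inf
    mig <- matrix(0, 1, 1)
  } else {
    n_deme <- 2L
    n_per_deme <- model$n_samples
    epoch_start <- 0
    epoch_sizes <- matrix(Ne, 1, 2)
    merge_time <- model$split_time
    mig <- matrix(c(0, m, m, 0), 2, 2)
  }
  list(n_per_deme = as.integer(n_per_deme),
       epoch_start = epoch_start,
       epoch_sizes = epoch_sizes,
       merge_time = merge_time,
       mig = mig,
       rec_rate = model$rho / (4 * Ne),
       locus_length = model$locus_length)
}
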