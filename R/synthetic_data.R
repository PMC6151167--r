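# Synthetic study generator: emits complete pipeline inputs (VCF, population
# map, chromosome classes, truth parameters) from known demographic truth.
# Populations sit on a one-dimensional transect with migration decaying
# geometrically with the number of steps separating them, an
# isolation-by-distance emulation. Hemizygous female Z genotypes are written
# as homozygous diploid calls, the way variant callers emit them, so the
# haploidization path is always exercised.

#' Specify a synthetic study
#'
#' @param n_populations number of populations on the transect (2-20).
#' @param n_individuals diploid individuals per population (3-10).
#' @param female_fraction fraction of individuals that are ZW females.
#' @param Ne autosomal effective size per population.
#' @param split_time generations back at which all populations merge into
#'   the common ancestor (size `Ne`).
#' @param migration per-generation migration probability between adjacent
#'   populations.
#' @param migration_decay geometric factor applied per additional transect
#'   step (migration between populations `i` and `j` is
#'   `migration * migration_decay^(|i-j|-1)`).
#' @param z_migration_reduction fraction `d` by which migration is reduced
#'   on the Z.
#' @param z_scale Z effective-size multiplier (default 0.75).
#' @param mu,rho,locus_length as in [demographic_model()].
#' @param n_windows_autosome windows across the two autosomal contigs.
#' @param n_windows_z windows on the Z contig.
#' @param spacing_km transect spacing between adjacent populations.
#' @param missingness independent per-genotype missingness rate.
#' @param dp_mean,dp_sd normal parameters for emulated read depth (values
#'   straddle the DP filter range).
#' @param gq_shape1,gq_shape2 beta shape parameters for emulated genotype
#'   quality on 0-99 (values straddle the GQ threshold).
#' @param seed master seed; all outputs are deterministic in it.
#' @return object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_populations = 2L,
                                 n_individuals = 5L,
                                 female_fraction = 0.3,
                                 Ne = 1e6,
                                 split_time = 1e6,
                                 migration = 0,
                                 migration_decay = 0.3,
                                 z_migration_reduction = 0,
                                 z_scale = 0.75,
                                 mu = 2e-9,
                                 rho = 0.01,
                                 locus_length = 5000,
                                 n_windows_autosome = 60L,
                                 n_windows_z = 40L,
                                 spacing_km = 500,
                                 missingness = 0.02,
                                 dp_mean = 45, dp_sd = 18,
                                 gq_shape1 = 5, gq_shape2 = 0.6,
                                 seed = 1L) {
  stopifnot(n_populations >= 2L, n_populations <= 20L,
            n_individuals >= 2L, n_individuals <= 10L,
            female_fraction >= 0, female_fraction <= 1,
            missingness >= 0, missingness < 1,
            Ne > 0, split_time > 0, migration >= 0,
            z_migration_reduction >= 0, z_migration_reduction <= 1)
  structure(as.list(environment()), class = "synthetic_study_spec")
}

# per-sample Z haplotype counts: males two, females one
z_haplotypes <- function(sexes) ifelse(sexes == "female", 1L, 2L)

#' Generate a complete synthetic study
#'
#' Simulates every window under the spec's multi-population demography
#' (autosomal contigs at `Ne`, the Z contig at `z_scale * Ne` with migration
#' reduced by `z_migration_reduction`), emits a variants-only VCF with
#' emulated DP/GQ, a population map with sexes and transect coordinates, a
#' chromosome-class table and a `truth.json` recording the generating
#' parameters and closed-form expectations where they exist.
#'
#' @param spec a [synthetic_study_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the four output paths.
#' @export
generate_study <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pops <- sprintf("pop%d", seq_len(spec$n_populations))
  meta <- do.call(rbind, lapply(seq_along(pops), function(i) {
    nfem <- round(spec$female_fraction * spec$n_individuals)
    sex <- c(rep("female", nfem),
             rep("male", spec$n_individuals - nfem))
    data.frame(sample = sprintf("%s_ind%d", pops[i],
                                seq_len(spec$n_individuals)),
               population = pops[i], sex = sex,
               lat = 0, lon = (i - 1) * spec$spacing_km / 111.195,
               stringsAsFactors = FALSE)
  }))

  contigs <- data.frame(
    chrom = c("chr1", "chr2", "chrZ"),
    class = c("autosome", "autosome", "Z"),
    n_windows = c(ceiling(spec$n_windows_autosome / 2),
                  floor(spec$n_windows_autosome / 2),
                  spec$n_windows_z),
    stringsAsFactors = FALSE)

  seeds <- spawn_seeds(spec$seed, 4L)
  vcf_path <- file.path(dir, "genotypes.vcf")
  map_path <- file.path(dir, "population_map.tsv")
  cls_path <- file.path(dir, "chrom_classes.tsv")
  truth_path <- file.path(dir, "truth.json")

  utils::write.table(meta, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(contigs[c("chrom", "class")], cls_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
                     contigs$n_windows * spec$locus_length),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", meta$sample), collapse = "\t"))

  rng_state <- spawn_seeds(seeds[1L], nrow(contigs))
  for (ci in seq_len(nrow(contigs))) {
    cls <- contigs$class[ci]
    hap_per_sample <- if (cls == "Z") z_haplotypes(meta$sex) else
      rep(2L, nrow(meta))
    n_per_deme <- vapply(pops, function(p)
      sum(hap_per_sample[meta$population == p]), integer(1))
    sc <- study_engine_args(spec, cls, n_per_deme)
    wseeds <- spawn_seeds(rng_state[ci], 3L * contigs$n_windows[ci])
    for (w in seq_len(contigs$n_windows[ci])) {
      ts <- arg_simulate_cpp(sc$n_per_deme, sc$epoch_start, sc$epoch_sizes,
                             sc$merge_time, sc$mig, sc$rec_rate,
                             spec$locus_length, wseeds[3L * w - 2L])
      mm <- drop_mutations_cpp(ts$left, ts$right, ts$parent, ts$child,
                               ts$node_time, ts$n_samples, spec$mu,
                               wseeds[3L * w - 1L])
      lines <- c(lines,
                 vcf_window_rows(mm, spec, meta, hap_per_sample,
                                 contigs$chrom[ci],
                                 (w - 1L) * spec$locus_length,
                                 wseeds[3L * w]))
    }
  }
  writeLines(lines, vcf_path)

  truth <- list(
    parameters = unclass(spec)[setdiff(names(unclass(spec)), "")],
    expected = study_truth_expectations(spec))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(vcf = vcf_path, population_map = map_path,
                 chrom_classes = cls_path, truth = truth_path))
}

# engine arguments for the k-deme transect demography of a study spec
study_engine_args <- function(spec, cls, n_per_deme) {
  k <- spec$n_populations
  scale <- if (cls == "Z") spec$z_scale else 1
  m0 <- spec$migration *
    (if (cls == "Z") 1 - spec$z_migration_reduction else 1)
  mig <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) mig[i, j] <- m0 * spec$migration_decay^(abs(i - j) - 1)
  }
  Ne <- spec$Ne * scale
  list(n_per_deme = as.integer(n_per_deme),
       epoch_start = 0,
       epoch_sizes = matrix(Ne, 1, k),
       merge_time = spec$split_time,
       mig = mig,
       rec_rate = spec$rho / (4 * Ne))
}

# VCF body rows for one simulated window
vcf_window_rows <- function(mm, spec, meta, hap_per_sample, chrom, offset,
                            seed) {
  S <- length(mm$positions)
  if (S == 0L) return(character(0))
  # integer positions, unique and ascending within the window
  p <- floor(mm$positions)
  for (i in seq_len(S)[-1L]) if (p[i] <= p[i - 1L]) p[i] <- p[i - 1L] + 1L
  keep <- p < spec$locus_length
  p <- p[keep]
  al <- mm$alleles[, keep, drop = FALSE]
  S <- length(p)
  if (S == 0L) return(character(0))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  nsam <- nrow(meta)
  row_start <- cumsum(c(0L, hap_per_sample))[seq_len(nsam)]
  gt <- matrix("", nsam, S)
  for (s in seq_len(nsam)) {
    if (hap_per_sample[s] == 2L) {
      a <- al[row_start[s] + 1L, ]
      b <- al[row_start[s] + 2L, ]
      gt[s, ] <- paste(a, b, sep = "/")
    } else {
      a <- al[row_start[s] + 1L, ]
      gt[s, ] <- paste(a, a, sep = "/")  # hemizygous emitted as homozygous
    }
  }
  dp <- matrix(pmax(0L, round(stats::rnorm(nsam * S, spec$dp_mean,
                                           spec$dp_sd))), nsam, S)
  gq <- matrix(round(99 * stats::rbeta(nsam * S, spec$gq_shape1,
                                       spec$gq_shape2)), nsam, S)
  miss <- matrix(stats::runif(nsam * S) < spec$missingness, nsam, S)
  gt[miss] <- "./."
  cells <- matrix(paste(gt, dp, gq, sep = ":"), nsam, S)

  vapply(seq_len(S), function(j) {
    paste(c(chrom, offset + p[j] + 1L, ".", "A", "T", ".", "PASS", ".",
            "GT:DP:GQ", cells[, j]), collapse = "\t")
  }, character(1))
}

# closed-form expectations recorded in truth.json (only where they exist)
study_truth_expectations <- function(spec) {
  out <- list(
    za_pi_ratio = list(value = spec$z_scale, tol_abs = 0.1,
                       comment = "ratio of mean pi, Z over autosomes"))
  if (spec$migration == 0) {
    pi_a <- 4 * spec$Ne * spec$mu
    out$pi_autosome <- list(value = pi_a, tol_rel = 0.15,
                            comment = "mean within-population diversity, autosomes")
    out$pi_z <- list(value = spec$z_scale * pi_a, tol_rel = 0.15,
                     comment = "mean within-population diversity, Z")
    out$dxy_autosome <- list(
      value = 2 * spec$mu * (spec$split_time + 2 * spec$Ne),
      tol_rel = 0.15,
      comment = "mean dXY between populations, autosomes, m = 0")
    out$dxy_z <- list(
      value = 2 * spec$mu * (spec$split_time + 2 * spec$z_scale * spec$Ne),
      tol_rel = 0.15,
      comment = "mean dXY between populations, Z, m = 0")
  }
  out
}

#' Mask genotypes at random in a window
#'
#' Sets genotype calls to missing independently at the given rate,
#' preserving the window's ploidy structure (both haplotypes of a diploid
#' call are masked together).
#'
#' @param window a `genotype_window`.
#' @param rate missingness rate in `[0, 1)`.
#' @param seed integer seed.
#' @return the window with additional missing genotypes.
#' @export
inject_missingness <- function(window, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || ncol(window$alleles) == 0L) return(window)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  samples <- unique(window$haplotype_owner)
  S <- ncol(window$alleles)
  for (s in samples) {
    rows <- which(window$haplotype_owner == s)
    mask <- stats::runif(S) < rate
    window$alleles[rows, mask] <- NA_integer_
  }
  window
}
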