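# Pipeline orchestration: the synth / stats / ratios stages behind one
# function with a config file, a manifest, and deterministic seeding. The
# `all` subcommand chains the stages on a synthetic study and verifies the
# recovered statistics against the generator's recorded truth.

#' Default pipeline configuration
#'
#' @return nested list of all configuration keys with their defaults;
#'   any subset can be overridden by the YAML config file.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "zdiv_out",
    synth = formals(synthetic_study_spec)[
      setdiff(names(formals(synthetic_study_spec)), "seed")],
    stats = list(
      vcf = NULL, population_map = NULL, chrom_classes = NULL,
      window_span = 50000, assume_callable = FALSE,
      min_fraction_genotyped = 0.10, min_fraction_individuals = 0.75,
      pi_s_weight_rule = "sample_size", thin_distance = 500,
      dp_min = 10, dp_max = 100, gq_min = 30,
      sex_min_sites = 100, sex_threshold_factor = 0.1,
      block_span = 1e6),
    ratios = list(bin_km = 500, bin_dxy = 1.25e-3, n_permutations = 999),
    simulate = list(
      scenario = "size-change",
      n_reps = 300,
      Ne = NULL, locus_length = 5000,
      x_grid = c(0.01, 0.1, 1, 10, 100),
      t_grid = NULL,
      split_times = c(1e6, 2e6),
      m_grid = c(0, 2.5e-7, 5e-7, 7.5e-7, 1e-6),
      d_grid = 0.6),
    truth_check = TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

read_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(base), collapse = ", "))
  for (k in intersect(names(user), c("synth", "stats", "ratios"))) {
    bad <- setdiff(names(user[[k]]), names(base[[k]]))
    if (length(bad) > 0L)
      stop("unknown ", k, " config key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(names(base[[k]]), collapse = ", "))
  }
  merge_config(base, user)
}

pipeline_log <- function(...) message("[zdiv] ", sprintf(...))

#' Run the analysis pipeline
#'
#' Subcommands: `"synth"` generates a synthetic study; `"stats"` computes
#' windowed statistics, jackknife summaries and thinned individual dXY
#' matrices from a VCF; `"ratios"` computes Z/A ratio matrices, binned
#' summaries and Mantel tests from the stats outputs; `"all"` chains
#' synth, stats and ratios on a synthetic study and checks the recovered
#' values against the generator's truth, raising an error on violation.
#' Every output directory receives a `manifest.json` with the config
#' snapshot, seeds, input checksums and package version.
#'
#' The standalone `"simulate"` subcommand runs one of the two simulation
#' designs ([run_size_change_grid()] or [run_two_pop_grid()]) and writes the
#' per-cell summary table.
#'
#' @param subcommand one of `"synth"`, `"stats"`, `"ratios"`, `"simulate"`,
#'   `"all"`.
#' @param config path to a YAML config file, or a config list; `NULL` for
#'   defaults (see [default_config()]).
#' @param seed optional override of the config seed.
#' @param out_dir optional override of the config output directory.
#' @return invisibly, a list of result objects and output paths.
#' @export
run_pipeline <- function(subcommand = c("all", "synth", "stats", "ratios",
                                        "simulate"),
                         config = NULL, seed = NULL, out_dir = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage_dirs <- file.path(cfg$out_dir, c("synth", "stats", "ratios",
                                         "simulate"))
  preexisting <- stage_dirs[dir.exists(stage_dirs)]
  res <- list(config = cfg)
  ok <- FALSE
  on.exit(if (!ok) {
    created <- setdiff(stage_dirs[dir.exists(stage_dirs)], preexisting)
    if (length(created) > 0L) {
      pipeline_log("failed; removing partial outputs: %s",
                   paste(created, collapse = ", "))
      unlink(created, recursive = TRUE)
    }
  })

  if (subcommand == "simulate") {
    res$simulate <- pipeline_simulate(cfg)
  }

  if (subcommand %in% c("synth", "all")) {
    pipeline_log("generating synthetic study (seed %d)", cfg$seed)
    spec <- do.call(synthetic_study_spec,
                    c(lapply(cfg$synth, function(x)
                      if (is.language(x)) eval(x) else x),
                      list(seed = cfg$seed)))
    paths <- generate_study(spec, file.path(cfg$out_dir, "synth"))
    res$synth <- paths
    cfg$stats$vcf <- paths$vcf
    cfg$stats$population_map <- paths$population_map
    cfg$stats$chrom_classes <- paths$chrom_classes
    cfg$stats$window_span <- spec$locus_length
    cfg$stats$assume_callable <- TRUE
    cfg$stats$thin_distance <- max(50, spec$locus_length / 100)
    cfg$stats$block_span <- 20 * spec$locus_length
  }

  if (subcommand %in% c("stats", "all")) {
    res$stats <- pipeline_stats(cfg)
  }

  if (subcommand %in% c("ratios", "all")) {
    res$ratios <- pipeline_ratios(cfg, res$stats)
  }

  if (subcommand == "all" && isTRUE(cfg$truth_check)) {
    res$truth_check <- check_truth(res, file.path(cfg$out_dir, "synth",
                                                  "truth.json"))
  }

  manifest <- list(
    subcommand = subcommand,
    config = cfg,
    seed = cfg$seed,
    inputs = pipeline_checksums(cfg),
    tool_version = as.character(utils::packageVersion("zdiv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
  ok <- TRUE
  invisible(res)
}

pipeline_simulate <- function(cfg) {
  sc <- cfg$simulate
  if (!sc$scenario %in% c("size-change", "two-pop"))
    stop("simulate scenario must be 'size-change' or 'two-pop'")
  out_dir <- file.path(cfg$out_dir, "simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (sc$scenario == "size-change") {
    model <- demographic_model(Ne = if (is.null(sc$Ne)) 3e6 else sc$Ne,
                               locus_length = sc$locus_length)
    tg <- if (is.null(sc$t_grid)) 10^seq(3, log10(4e6), length.out = 10)
          else sc$t_grid
    pipeline_log("size-change grid: %d x %d cells, %d reps",
                 length(sc$x_grid), length(tg), sc$n_reps)
    tab <- run_size_change_grid(sc$x_grid, tg, model,
                                n_reps = as.integer(sc$n_reps),
                                seed = cfg$seed)
  } else {
    model <- demographic_model(Ne = if (is.null(sc$Ne)) 2e6 else sc$Ne,
                               split_time = sc$split_times[1L],
                               locus_length = sc$locus_length)
    pipeline_log("two-pop grid: %d cells, %d reps",
                 length(sc$split_times) * length(sc$m_grid) *
                   length(sc$d_grid), sc$n_reps)
    tab <- run_two_pop_grid(sc$split_times, sc$m_grid, sc$d_grid, model,
                            n_reps = as.integer(sc$n_reps), seed = cfg$seed)
  }
  path <- file.path(out_dir, paste0(sub("-", "_", sc$scenario),
                                    "_grid.tsv"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(table = tab, path = path)
}

pipeline_checksums <- function(cfg) {
  files <- unlist(cfg$stats[c("vcf", "population_map", "chrom_classes")])
  files <- files[!is.na(files) & nzchar(files)]
  if (length(files) == 0L) return(list())
  files <- files[file.exists(files)]
  if (length(files) == 0L) return(list())
  as.list(tools::md5sum(files))
}

pipeline_stats <- function(cfg) {
  sc <- cfg$stats
  for (f in c("vcf", "population_map", "chrom_classes")) {
    if (is.null(sc[[f]]) || !file.exists(sc[[f]]))
      stop("stats input not found: ", f, " = ",
           if (is.null(sc[[f]])) "<missing>" else sc[[f]])
  }
  meta <- read_population_map(sc$population_map)
  classes <- read_chrom_classes(sc$chrom_classes)
  pipeline_log("loading genotypes from %s", sc$vcf)
  windows <- load_genotypes(sc$vcf, meta, classes,
                            genotype_filters(sc$dp_min, sc$dp_max, sc$gq_min),
                            window_span = sc$window_span,
                            assume_callable = sc$assume_callable)
  zw <- Filter(function(w) w$class == "Z", windows)
  sexes <- infer_sex(zw, meta, min_sites = sc$sex_min_sites,
                     threshold_factor = sc$sex_threshold_factor)
  windows <- lapply(windows, function(w)
    if (w$class == "Z") haploidize_female_z(w, sexes) else w)

  cfgstat <- stat_config(window_span = sc$window_span,
                         min_fraction_genotyped = sc$min_fraction_genotyped,
                         min_fraction_individuals = sc$min_fraction_individuals,
                         pi_s_weight_rule = sc$pi_s_weight_rule,
                         thin_distance = sc$thin_distance)
  pops <- unique(meta$population)
  pairs <- utils::combn(pops, 2L, simplify = FALSE)
  pipeline_log("windowed statistics for %d windows x %d population pairs",
               length(windows), length(pairs))
  tab <- do.call(rbind, lapply(windows, function(w) {
    out <- do.call(rbind, lapply(pairs, function(p)
      window_stats(w, p, meta, cfgstat)))
    out$class <- w$class
    out
  }))

  jack <- jackknife_summary(tab, sc$block_span)

  auto <- Filter(function(w) w$class == "autosome", windows)
  zwh <- Filter(function(w) w$class == "Z", windows)
  thin_a <- thin_sites(auto, meta, min_gap = sc$thin_distance)
  thin_z <- thin_sites(zwh, meta, min_gap = sc$thin_distance)
  dxy_a <- pairwise_individual_dxy(thin_a)
  dxy_z <- pairwise_individual_dxy(thin_z)

  out_dir <- file.path(cfg$out_dir, "stats")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tab, file.path(out_dir, "window_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(jack, file.path(out_dir, "jackknife_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_square_tsv(dxy_a, file.path(out_dir, "dxy_individual_autosome.tsv"))
  write_square_tsv(dxy_z, file.path(out_dir, "dxy_individual_z.tsv"))
  list(windows = tab, jackknife = jack, dxy_auto = dxy_a, dxy_z = dxy_z,
       meta = meta, sexes = sexes, out_dir = out_dir)
}

# genome-wide block-jackknife means per class and statistic
jackknife_summary <- function(tab, block_span) {
  stats_cols <- c("pi_1", "pi_2", "pi_s", "pi_t", "fst", "dxy", "da",
                  "tajima_d_1", "tajima_d_2")
  out <- list()
  for (cls in unique(tab$class)) {
    sub <- tab[tab$class == cls & tab$passed_filter, ]
    if (nrow(sub) == 0L) next
    for (st in stats_cols) {
      v <- sub[[st]]
      if (sum(is.finite(v)) < 2L) next
      jk <- tryCatch(block_jackknife(v, sub$chromosome, sub$start,
                                     block_span),
                     error = function(e) NULL)
      if (is.null(jk)) next
      out[[length(out) + 1L]] <- data.frame(
        class = cls, statistic = st, mean = jk$mean, se = jk$se,
        ci95_low = jk$ci95_low, ci95_high = jk$ci95_high,
        n_blocks = jk$n_blocks, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

write_square_tsv <- function(M, path) {
  df <- data.frame(sample = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

pipeline_ratios <- function(cfg, stats_res) {
  if (is.null(stats_res))
    stop("ratios stage requires the stats outputs; run 'stats' or 'all'")
  meta <- stats_res$meta
  ratio <- za_ratio_matrix(stats_res$dxy_auto, stats_res$dxy_z)
  coords <- meta[c("sample", "lat", "lon")]
  km <- geographic_distance_matrix(coords)
  km <- km[rownames(ratio), rownames(ratio)]
  series <- ratio_series(ratio, km = km, dxy_a = stats_res$dxy_auto)
  by_km <- bin_series(series, "km", cfg$ratios$bin_km)
  by_dxy <- bin_series(series, "dxy_a", cfg$ratios$bin_dxy)
  mantel <- NULL
  if (nrow(ratio) >= 4L) {
    mantel <- list(
      vs_distance = ratio_vs_proxy_test(
        ratio, km, n_permutations = cfg$ratios$n_permutations,
        seed = cfg$seed),
      vs_dxy_auto = ratio_vs_proxy_test(
        ratio, stats_res$dxy_auto,
        n_permutations = cfg$ratios$n_permutations, seed = cfg$seed))
  } else {
    pipeline_log("fewer than 4 individuals; Mantel tests skipped")
  }
  out_dir <- file.path(cfg$out_dir, "ratios")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_square_tsv(ratio, file.path(out_dir, "za_ratio_individual.tsv"))
  utils::write.table(series, file.path(out_dir, "ratio_series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(by_km, file.path(out_dir, "ratio_by_km.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(by_dxy, file.path(out_dir, "ratio_by_dxy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mantel)) {
    mt <- do.call(rbind, lapply(names(mantel), function(nm) {
      m <- mantel[[nm]]
      data.frame(test = nm, r = m$r, r_squared = m$r_squared,
                 p_value = m$p_value, n_permutations = m$n_permutations,
                 seed = m$seed, stringsAsFactors = FALSE)
    }))
    utils::write.table(mt, file.path(out_dir, "mantel_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(ratio = ratio, series = series, by_km = by_km, by_dxy = by_dxy,
       mantel = mantel, out_dir = out_dir)
}

# compare recovered statistics against the generator's recorded truth
check_truth <- function(res, truth_path) {
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  jk <- res$stats$jackknife
  pick <- function(cls, st) {
    r <- jk[jk$class == cls & jk$statistic == st, ]
    if (nrow(r) == 0L) NA_real_ else mean(r$mean)
  }
  measured <- list(
    pi_autosome = mean(c(pick("autosome", "pi_1"), pick("autosome", "pi_2"))),
    pi_z = mean(c(pick("Z", "pi_1"), pick("Z", "pi_2"))),
    dxy_autosome = pick("autosome", "dxy"),
    dxy_z = pick("Z", "dxy"))
  measured$za_pi_ratio <- measured$pi_z / measured$pi_autosome

  checks <- list()
  for (nm in names(truth$expected)) {
    exp <- truth$expected[[nm]]
    got <- measured[[nm]]
    if (is.null(got) || !is.finite(got)) next
    tol <- if (!is.null(exp$tol_abs)) exp$tol_abs else
      exp$tol_rel * abs(exp$value)
    pass <- abs(got - exp$value) <= tol
    checks[[nm]] <- data.frame(quantity = nm, expected = exp$value,
                               measured = got, tolerance = tol,
                               pass = pass, stringsAsFactors = FALSE)
  }
  checks <- do.call(rbind, checks)
  if (!is.null(checks) && any(!checks$pass)) {
    bad <- checks[!checks$pass, ]
    stop("truth check failed: ",
         paste(sprintf("%s (expected %.4g, got %.4g, tol %.2g)",
                       bad$quantity, bad$expected, bad$measured,
                       bad$tolerance), collapse = "; "))
  }
  pipeline_log("truth check passed for %d quantities",
               if (is.null(checks)) 0L else nrow(checks))
  checks
}
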