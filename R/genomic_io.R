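# Genotype input: VCF parsing (via vcfR), per-genotype quality filtering,
# fixed-window iteration, sex inference from Z heterozygosity and enforcement
# of female hemizygosity on the Z. Internally all coordinates are 0-based
# half-open; VCF's 1-based positions are converted at the boundary.

#' Read a population map
#'
#' Tab-separated table with header `sample  population  sex  lat  lon`.
#' Sex may be `male`, `female` or `unknown`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample`, `population`, `sex`, `lat`,
#'   `lon`.
#' @export
read_population_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "population", "sex", "lat", "lon")
  if (!all(need %in% names(m)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample)) stop("duplicate sample ids in population map")
  bad <- !m$sex %in% c("male", "female", "unknown")
  if (any(bad)) stop("invalid sex values: ", paste(unique(m$sex[bad]),
                                                   collapse = ", "))
  if (any(stats::na.omit(abs(m$lat) > 90)) ||
      any(stats::na.omit(abs(m$lon) > 180)))
    stop("coordinates out of range")
  m[need]
}

#' Read a chromosome-class table
#'
#' Tab-separated table with header `chrom  class`, class in
#' `{autosome, Z}`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `chrom`, `class`.
#' @export
read_chrom_classes <- function(path) {
  cc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "class") %in% names(cc)))
    stop("chromosome-class table must have columns: chrom, class")
  if (!all(cc$class %in% c("autosome", "Z")))
    stop("chromosome class must be 'autosome' or 'Z'")
  if (anyDuplicated(cc$chrom)) stop("duplicate chromosome in class table")
  cc[c("chrom", "class")]
}

#' Genotype quality thresholds
#'
#' Per-genotype filters: calls with depth outside `[dp_min, dp_max]` are set
#' to missing, and variant genotype calls with genotype quality below
#' `gq_min` are set to missing.
#'
#' @param dp_min,dp_max depth bounds (defaults 10 and 100).
#' @param gq_min genotype-quality minimum for variant calls (default 30).
#' @export
genotype_filters <- function(dp_min = 10, dp_max = 100, gq_min = 30) {
  stopifnot(dp_min <= dp_max)
  list(dp_min = dp_min, dp_max = dp_max, gq_min = gq_min)
}

# parse a vcfR GT character matrix into two per-haplotype allele matrices
# (integer codes into the site's allele list; NA = missing)
parse_gt <- function(gt) {
  gt[is.na(gt)] <- "./."
  clean <- sub(":.*$", "", gt)
  h1 <- sub("[/|].*$", "", clean)
  h2 <- ifelse(grepl("[/|]", clean), sub("^[^/|]*[/|]", "", clean), h1)
  to_int <- function(x) {
    x[x == "." | x == ""] <- NA
    suppressWarnings(matrix(as.integer(x), nrow = nrow(gt),
                            dimnames = dimnames(gt)))
  }
  list(h1 = to_int(h1), h2 = to_int(h2))
}

#' Load genotypes from a VCF into fixed windows
#'
#' Reads a VCF (plain or bgzipped), applies per-genotype quality filters,
#' reduces multi-allelic sites to their two most frequent alleles (all other
#' calls set missing), and emits non-overlapping fixed windows per
#' chromosome in genomic order. Both variant and invariant rows are kept:
#' invariant sites count toward callable-site denominators. When the input
#' is variants-only, set `assume_callable = TRUE` so window span is used as
#' the callable denominator.
#'
#' @param vcf_path VCF file.
#' @param meta sample metadata from [read_population_map()]; every sample
#'   listed must be present in the VCF.
#' @param classes chromosome classes from [read_chrom_classes()]; every
#'   chromosome in the VCF must be listed.
#' @param filters a [genotype_filters()] list.
#' @param window_span window length in bp (default 50000).
#' @param assume_callable logical; `TRUE` for variants-only VCFs whose
#'   unlisted positions are taken as callable and invariant.
#' @return list of `genotype_window` objects, each with fields
#'   `chromosome`, `start`, `end`, `alleles` (haplotype-by-site over
#'   `{0, 1, NA}`), `site_positions` (0-based), `haplotype_owner`,
#'   `ploidy` (named per-sample row counts), `class`, `assume_callable`.
#' @export
load_genotypes <- function(vcf_path, meta, classes,
                           filters = genotype_filters(),
                           window_span = 50000,
                           assume_callable = FALSE) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-variant VCFs collapse to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt[, -1L, drop = FALSE]
  vcf_samples <- colnames(gt_raw)
  missing_samples <- setdiff(meta$sample, vcf_samples)
  if (length(missing_samples) > 0L)
    stop("sample(s) in metadata absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt_raw <- gt_raw[, meta$sample, drop = FALSE]

  chroms <- unique(fix[, "CHROM"])
  unmapped <- setdiff(chroms, classes$chrom)
  if (length(unmapped) > 0L)
    stop("chromosome(s) without a class assignment: ",
         paste(unmapped, collapse = ", "))

  fmt <- vcf@gt[, 1L]
  dp <- extract_format_num(gt_raw, fmt, "DP")
  gq <- extract_format_num(gt_raw, fmt, "GQ")
  ph <- parse_gt(gt_raw)
  h1 <- ph$h1; h2 <- ph$h2

  # depth filter
  bad_dp <- !is.na(dp) & (dp < filters$dp_min | dp > filters$dp_max)
  h1[bad_dp] <- NA; h2[bad_dp] <- NA
  # GQ filter on variant genotype calls
  is_var_call <- (!is.na(h1) & h1 > 0L) | (!is.na(h2) & h2 > 0L)
  bad_gq <- is_var_call & !is.na(gq) & gq < filters$gq_min
  h1[bad_gq] <- NA; h2[bad_gq] <- NA

  # reduce multi-allelic sites to the two most frequent alleles
  multi <- grepl(",", fix[, "ALT"])
  for (i in which(multi)) {
    al <- c(h1[i, ], h2[i, ])
    tab <- sort(table(al), decreasing = TRUE)
    top <- as.integer(names(tab))[seq_len(min(2L, length(tab)))]
    remap <- function(x) {
      out <- match(x, top) - 1L
      out
    }
    h1[i, ] <- remap(h1[i, ])
    h2[i, ] <- remap(h2[i, ])
  }
  h1[!multi & !is.na(h1) & h1 > 1L] <- NA
  h2[!multi & !is.na(h2) & h2 > 1L] <- NA

  pos0 <- as.numeric(fix[, "POS"]) - 1  # to 0-based
  chrom <- fix[, "CHROM"]
  samples <- meta$sample
  owner <- rep(samples, each = 2L)

  windows <- list()
  for (ch in chroms) {
    idx <- which(chrom == ch)
    idx <- idx[order(pos0[idx])]
    cls <- classes$class[match(ch, classes$chrom)]
    maxpos <- max(pos0[idx])
    n_win <- floor(maxpos / window_span) + 1L
    for (w in seq_len(n_win)) {
      lo <- (w - 1L) * window_span
      hi <- w * window_span
      sel <- idx[pos0[idx] >= lo & pos0[idx] < hi]
      al <- matrix(NA_integer_, nrow = length(owner), ncol = length(sel))
      if (length(sel) > 0L) {
        al[seq(1L, by = 2L, length.out = length(samples)), ] <-
          t(h1[sel, , drop = FALSE])
        al[seq(2L, by = 2L, length.out = length(samples)), ] <-
          t(h2[sel, , drop = FALSE])
      }
      windows[[length(windows) + 1L]] <- structure(
        list(chromosome = ch, start = lo, end = hi, alleles = al,
             site_positions = pos0[sel], haplotype_owner = owner,
             ploidy = stats::setNames(rep(2L, length(samples)), samples),
             class = cls, assume_callable = assume_callable),
        class = "genotype_window")
    }
  }
  windows
}

# pull one numeric FORMAT field out of a vcfR genotype matrix
extract_format_num <- function(gt_raw, fmt, key) {
  out <- matrix(NA_real_, nrow = nrow(gt_raw), ncol = ncol(gt_raw),
                dimnames = dimnames(gt_raw))
  keys <- strsplit(fmt, ":", fixed = TRUE)
  pos <- vapply(keys, function(k) match(key, k), integer(1))
  has <- !is.na(pos)
  if (!any(has)) return(out)
  for (p in unique(pos[has])) {
    rows <- which(has & pos == p)
    part <- gt_raw[rows, , drop = FALSE]
    spl <- strsplit(part, ":", fixed = TRUE)
    vals <- vapply(spl, function(x)
      if (length(x) >= p) suppressWarnings(as.numeric(x[p])) else NA_real_,
      numeric(1))
    out[rows, ] <- matrix(vals, nrow = length(rows))
  }
  out
}

#' Infer sample sex from Z-chromosome heterozygosity
#'
#' ZW females are hemizygous on the Z, so their fraction of heterozygous
#' calls among genotyped Z variant sites is near zero, while diploid males
#' show ordinary levels. A sample is called female when its Z heterozygosity
#' falls below `threshold_factor` times the cohort's median male
#' heterozygosity (the male reference level is taken as the median of the
#' upper half of the cohort). A declared sex in the metadata, when not
#' `"unknown"`, overrides inference.
#'
#' @param z_windows list of Z-class `genotype_window`s.
#' @param meta sample metadata.
#' @param min_sites minimum genotyped Z variant sites required (default
#'   100); below it the sample is returned as `"unknown"` with a warning.
#' @param threshold_factor multiple of the median male Z heterozygosity
#'   below which a sample is called female (default 0.1).
#' @return named character vector (`male`/`female`/`unknown`) per sample.
#' @export
infer_sex <- function(z_windows, meta, min_sites = 100,
                      threshold_factor = 0.1) {
  samples <- meta$sample
  het <- stats::setNames(rep(NA_real_, length(samples)), samples)
  nsite <- stats::setNames(rep(0, length(samples)), samples)
  for (s in samples) {
    nhet <- 0; ncall <- 0
    for (w in z_windows) {
      rows <- which(w$haplotype_owner == s)
      if (length(rows) < 2L || ncol(w$alleles) == 0L) next
      a <- w$alleles[rows[1:2], , drop = FALSE]
      called <- !is.na(a[1L, ]) & !is.na(a[2L, ])
      ncall <- ncall + sum(called)
      nhet <- nhet + sum(a[1L, called] != a[2L, called])
    }
    nsite[s] <- ncall
    if (ncall > 0) het[s] <- nhet / ncall
  }
  usable <- nsite >= min_sites & !is.na(het)
  out <- stats::setNames(rep("unknown", length(samples)), samples)
  if (any(usable)) {
    hv <- het[usable]
    male_ref <- stats::median(hv[hv >= stats::median(hv)])
    thr <- threshold_factor * male_ref
    out[names(hv)] <- ifelse(hv < thr, "female", "male")
  }
  if (any(!usable)) {
    warning("too few genotyped Z sites to infer sex for: ",
            paste(samples[!usable], collapse = ", "),
            "; excluded from Z-class statistics")
  }
  declared <- meta$sex != "unknown"
  out[meta$sample[declared]] <- meta$sex[declared]
  out
}

#' Enforce female hemizygosity on a Z-chromosome window
#'
#' Each female contributes a single haplotype row: her homozygous calls
#' carry over as the single allele, and residual heterozygous calls
#' (W-mapping or genotyping artifacts, impossible on a hemizygous Z) are set
#' to missing. Autosomal windows are returned unchanged.
#'
#' @param window a `genotype_window`.
#' @param sexes named character vector per sample (from [infer_sex()] or
#'   declared metadata); samples of unknown sex are dropped from the window.
#' @return a `genotype_window` with one haplotype row per female.
#' @export
haploidize_female_z <- function(window, sexes) {
  if (!identical(window$class, "Z")) return(window)
  samples <- unique(window$haplotype_owner)
  keep_rows <- integer(0)
  new_owner <- character(0)
  ploidy <- integer(0)
  al <- window$alleles
  for (s in samples) {
    rows <- which(window$haplotype_owner == s)
    sx <- sexes[[s]]
    if (is.null(sx) || is.na(sx) || sx == "unknown") next
    if (sx == "female" && length(rows) >= 2L) {
      a <- al[rows[1L], ]
      b <- al[rows[2L], ]
      merged <- ifelse(!is.na(a) & !is.na(b) & a == b, a, NA_integer_)
      # one called allele with the other missing: keep the called one
      merged <- ifelse(is.na(merged) & xor(is.na(a), is.na(b)),
                       ifelse(is.na(a), b, a), merged)
      al[rows[1L], ] <- merged
      keep_rows <- c(keep_rows, rows[1L])
      new_owner <- c(new_owner, s)
      ploidy <- c(ploidy, 1L)
    } else {
      keep_rows <- c(keep_rows, rows)
      new_owner <- c(new_owner, rep(s, length(rows)))
      ploidy <- c(ploidy, length(rows))
    }
  }
  window$alleles <- al[keep_rows, , drop = FALSE]
  window$haplotype_owner <- new_owner
  window$ploidy <- stats::setNames(ploidy, unique(new_owner))
  window
}
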