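# Pairwise-difference machinery. Alleles are haplotype-by-site matrices over
# {0, 1, NA}; all per-site statistics use per-pair denominators: each pair of
# haplotypes is normalized by the number of sites at which both are called,
# which keeps the estimators unbiased under genotype-level missingness.

# mean raw difference count and mean jointly-callable site count over all
# within-matrix pairs (or a supplied subset of pairs)
pairwise_diff_count <- function(alleles, pairs = NULL) {
  n <- nrow(alleles)
  if (n < 2L) stop("need at least two haplotypes")
  v <- !is.na(alleles)
  a1 <- alleles == 1L
  a1[!v] <- FALSE
  a0 <- alleles == 0L
  a0[!v] <- FALSE
  D <- tcrossprod(a1 * 1, a0 * 1)
  D <- D + t(D)
  J <- tcrossprod(v * 1)
  if (is.null(pairs)) {
    ut <- upper.tri(D)
    dd <- D[ut]; jj <- J[ut]
  } else {
    dd <- D[pairs]; jj <- J[pairs]
  }
  list(mean_diff = mean(dd), mean_callable = mean(jj),
       per_pair = dd / ifelse(jj > 0, jj, NA_real_),
       diff = dd, callable = jj)
}

# between-matrix version (all n1 x n2 cross pairs)
cross_diff_count <- function(a, b) {
  va <- !is.na(a); vb <- !is.na(b)
  a1 <- (a == 1L) & va; a0 <- (a == 0L) & va
  b1 <- (b == 1L) & vb; b0 <- (b == 0L) & vb
  # pad to common site set: caller must supply matrices over the same sites
  stopifnot(ncol(a) == ncol(b))
  D <- tcrossprod(a1 * 1, b0 * 1) + tcrossprod(a0 * 1, b1 * 1)
  J <- tcrossprod(va * 1, vb * 1)
  list(mean_diff = mean(D), mean_callable = mean(J),
       per_pair = as.vector(D) / ifelse(as.vector(J) > 0, as.vector(J),
                                        NA_real_),
       diff = as.vector(D), callable = as.vector(J))
}

#' Mean pairwise difference per site (nucleotide diversity)
#'
#' For every pair of haplotype rows, differences are counted over the sites
#' at which both members are called and divided by that pair's callable site
#' count; the result is the unweighted mean over pairs. With complete data
#' and all (invariant plus variant) sites present this is the classical
#' nucleotide diversity pi.
#'
#' @param alleles haplotype-by-site matrix over `{0, 1, NA}`.
#' @param pairs optional two-column matrix of haplotype row indices selecting
#'   which pairs enter the mean; default all within-matrix pairs.
#' @return differences per site; `NaN` when no pair has a jointly called
#'   site.
#' @examples
#' m <- rbind(rep(0, 10), c(1, rep(0, 9)))
#' mean_pairwise_diff(m)  # 0.1
#' @export
mean_pairwise_diff <- function(alleles, pairs = NULL) {
  pc <- pairwise_diff_count(alleles, pairs)
  if (all(is.na(pc$per_pair))) return(NaN)
  mean(pc$per_pair, na.rm = TRUE)
}

#' Total nucleotide diversity of two pooled populations
#'
#' Mean pairwise difference per site over all pairs drawn from the pooled
#' sample of both populations.
#'
#' @param alleles1,alleles2 haplotype-by-site matrices over the same sites.
#' @return differences per site.
#' @export
pi_total <- function(alleles1, alleles2) {
  mean_pairwise_diff(rbind(alleles1, alleles2))
}

#' Weighted average within-population diversity
#'
#' The weighted average of the two within-population diversities used as the
#' ancestral-diversity proxy in `da` and in Hudson's FST. The default weight
#' is proportional to sample size, `w = n1 / (n1 + n2)`; `rule = "equal"`
#' gives both populations weight one half.
#'
#' @param pi1,pi2 within-population diversities.
#' @param n1,n2 haplotype sample sizes.
#' @param rule `"sample_size"` (default) or `"equal"`.
#' @return differences per site.
#' @export
pi_s <- function(pi1, pi2, n1, n2, rule = c("sample_size", "equal")) {
  rule <- match.arg(rule)
  w <- if (rule == "sample_size") n1 / (n1 + n2) else 0.5
  w * pi1 + (1 - w) * pi2
}

#' Hudson's FST from total and within-population diversity
#'
#' `FST = (pi_T - pi_S) / pi_T`; `NaN` when `pi_T` is zero.
#'
#' @param pi_t total (pooled) nucleotide diversity.
#' @param pi_s_val weighted within-population diversity.
#' @export
fst_hudson <- function(pi_t, pi_s_val) {
  ifelse(is.finite(pi_t) & pi_t > 0, (pi_t - pi_s_val) / pi_t, NaN)
}

#' Absolute divergence dXY between two populations
#'
#' Mean over all between-population haplotype pairs of per-pair normalized
#' differences (Nei and Li's absolute divergence).
#'
#' @param alleles1,alleles2 haplotype-by-site matrices over the same sites.
#' @return differences per site.
#' @export
dxy <- function(alleles1, alleles2) {
  cc <- cross_diff_count(alleles1, alleles2)
  if (all(is.na(cc$per_pair))) return(NaN)
  mean(cc$per_pair, na.rm = TRUE)
}

#' Net divergence da
#'
#' `da = dXY - pi_S`, the divergence accumulated since the populations
#' split, using the mean within-population diversity as an estimate of
#' ancestral diversity. Negative values are preserved: they indicate
#' diversity growth after the split.
#'
#' @param dxy_val absolute divergence.
#' @param pi_s_val weighted within-population diversity.
#' @export
d_a <- function(dxy_val, pi_s_val) dxy_val - pi_s_val

#' Tajima's D
#'
#' Standardized difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta, using Tajima's (1989) constants.
#' Negative values indicate an excess of rare alleles (expansion or sweep),
#' positive values a deficit (contraction or structure). Sites called in
#' fewer than `min_called` of the haplotypes are excluded so the
#' frequency-spectrum constants stay meaningful under missingness; with
#' complete data all sites are used.
#'
#' @param alleles haplotype-by-site matrix over `{0, 1, NA}` (variant sites;
#'   invariant columns contribute nothing).
#' @param min_called minimum fraction of haplotypes called for a site to be
#'   used (default 0.75).
#' @return dimensionless; `NaN` when there are no segregating sites or fewer
#'   than four haplotypes.
#' @export
tajimas_d <- function(alleles, min_called = 0.75) {
  n <- nrow(alleles)
  if (n < 4L) return(NaN)
  called <- colSums(!is.na(alleles))
  keep <- called >= min_called * n
  if (!any(keep)) return(NaN)
  m <- alleles[, keep, drop = FALSE]
  ones <- colSums(m == 1L, na.rm = TRUE)
  ns <- colSums(!is.na(m))
  seg <- ones > 0L & ones < ns
  S <- sum(seg)
  if (S == 0L) return(NaN)
  # mean pairwise difference count, per-site unbiased under missingness
  p <- ones[seg] / ns[seg]
  pihat <- sum(2 * p * (1 - p) * ns[seg] / (ns[seg] - 1))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Statistic configuration
#'
#' Bundles the window-inclusion filters and weighting conventions used
#' throughout the windowed analysis.
#'
#' @param window_span window length in bp (default 50000).
#' @param min_fraction_genotyped minimum fraction of window positions an
#'   individual must have genotyped to count as covered (default 0.10).
#' @param min_fraction_individuals minimum fraction of individuals per
#'   population that must be covered for the window to pass (default 0.75).
#' @param pi_s_weight_rule `"sample_size"` or `"equal"` (see [pi_s()]).
#' @param thin_distance minimum spacing in bp for the thinned genome-wide
#'   site subsample (default 500).
#' @export
stat_config <- function(window_span = 50000,
                        min_fraction_genotyped = 0.10,
                        min_fraction_individuals = 0.75,
                        pi_s_weight_rule = c("sample_size", "equal"),
                        thin_distance = 500) {
  pi_s_weight_rule <- match.arg(pi_s_weight_rule)
  stopifnot(window_span > 0,
            min_fraction_genotyped > 0, min_fraction_genotyped <= 1,
            min_fraction_individuals > 0, min_fraction_individuals <= 1,
            thin_distance > 0)
  structure(list(window_span = window_span,
                 min_fraction_genotyped = min_fraction_genotyped,
                 min_fraction_individuals = min_fraction_individuals,
                 pi_s_weight_rule = pi_s_weight_rule,
                 thin_distance = thin_distance),
            class = "stat_config")
}

# fraction of window positions genotyped, per individual
individual_coverage <- function(window, samples) {
  span <- window$end - window$start
  vapply(samples, function(s) {
    rows <- which(window$haplotype_owner == s)
    if (length(rows) == 0L) return(0)
    called <- colSums(!is.na(window$alleles[rows, , drop = FALSE])) > 0
    n_var_called <- sum(called)
    if (isTRUE(window$assume_callable)) {
      # variants-only input: implicit invariant positions are callable
      (span - (ncol(window$alleles) - n_var_called)) / span
    } else {
      n_var_called / span
    }
  }, numeric(1))
}

#' Windowed diversity and divergence statistics for a population pair
#'
#' Applies the window-inclusion filter (a minimum fraction of positions
#' genotyped in a minimum fraction of individuals, in each population
#' separately) and, for passing windows, computes the full statistic set:
#' per-population diversity, weighted within-population diversity, pooled
#' diversity, Hudson's FST, dXY, da, and per-population Tajima's D. Failing
#' windows are retained as all-`NaN` records for bookkeeping.
#'
#' @param window a `genotype_window` (see [load_genotypes()]).
#' @param pops character vector of the two population labels to compare.
#' @param meta sample metadata (see [read_population_map()]).
#' @param cfg a [stat_config()].
#' @return one-row data.frame (class `window_stats` attached to the full
#'   table when rows are bound): coordinates, callable-site count, the
#'   statistics, haplotype sample sizes and `passed_filter`.
#' @export
window_stats <- function(window, pops, meta, cfg = stat_config()) {
  stopifnot(length(pops) == 2L)
  span <- window$end - window$start
  out <- data.frame(chromosome = window$chromosome, start = window$start,
                    end = window$end, pop1 = pops[1L], pop2 = pops[2L],
                    n_callable_sites = NA_real_,
                    pi_1 = NaN, pi_2 = NaN, pi_s = NaN, pi_t = NaN,
                    fst = NaN, dxy = NaN, da = NaN,
                    tajima_d_1 = NaN, tajima_d_2 = NaN,
                    n1 = NA_integer_, n2 = NA_integer_,
                    passed_filter = FALSE, stringsAsFactors = FALSE)
  sam <- split(meta$sample, meta$population)
  passed <- vapply(pops, function(p) {
    ss <- intersect(sam[[p]], unique(window$haplotype_owner))
    if (length(ss) == 0L) return(FALSE)
    cov <- individual_coverage(window, ss)
    mean(cov >= cfg$min_fraction_genotyped) >= cfg$min_fraction_individuals
  }, logical(1))
  if (!all(passed)) return(out)

  rows1 <- which(window$haplotype_owner %in% sam[[pops[1L]]])
  rows2 <- which(window$haplotype_owner %in% sam[[pops[2L]]])
  a1 <- window$alleles[rows1, , drop = FALSE]
  a2 <- window$alleles[rows2, , drop = FALSE]
  n1 <- length(rows1); n2 <- length(rows2)
  if (n1 < 2L || n2 < 2L) return(out)

  pi1 <- window_pi(a1, span, window$assume_callable)
  pi2 <- window_pi(a2, span, window$assume_callable)
  pit <- window_pi(rbind(a1, a2), span, window$assume_callable)
  dv <- window_dxy(a1, a2, span, window$assume_callable)
  ps <- pi_s(pi1, pi2, n1, n2, cfg$pi_s_weight_rule)

  out$n_callable_sites <- if (isTRUE(window$assume_callable)) span else
    pairwise_diff_count(rbind(a1, a2))$mean_callable
  out$pi_1 <- pi1; out$pi_2 <- pi2; out$pi_s <- ps; out$pi_t <- pit
  out$fst <- fst_hudson(pit, ps)
  out$dxy <- dv
  out$da <- d_a(dv, ps)
  out$tajima_d_1 <- tajimas_d(a1)
  out$tajima_d_2 <- tajimas_d(a2)
  out$n1 <- n1; out$n2 <- n2
  out$passed_filter <- TRUE
  out
}

# per-site diversity for a window; under assume_callable, positions absent
# from the matrix are implicitly called identical in all haplotypes, so each
# pair's denominator is the window span minus its jointly-missing variant
# positions
window_pi <- function(a, span, assume_callable = FALSE) {
  if (nrow(a) < 2L) return(NaN)
  pc <- pairwise_diff_count(a)
  if (isTRUE(assume_callable)) {
    denom <- span - (ncol(a) - pc$callable)
    if (all(denom <= 0)) return(NaN)
    mean(pc$diff / denom)
  } else {
    if (all(is.na(pc$per_pair))) return(NaN)
    mean(pc$per_pair, na.rm = TRUE)
  }
}

window_dxy <- function(a1, a2, span, assume_callable = FALSE) {
  cc <- cross_diff_count(a1, a2)
  if (isTRUE(assume_callable)) {
    denom <- span - (ncol(a1) - cc$callable)
    if (all(denom <= 0)) return(NaN)
    mean(cc$diff / denom)
  } else {
    if (all(is.na(cc$per_pair))) return(NaN)
    mean(cc$per_pair, na.rm = TRUE)
  }
}

#' Thin genome-wide sites to a minimum spacing
#'
#' Greedy left-to-right selection along the genome: a site is kept iff its
#' position is at least `min_gap` beyond the last kept site on the same
#' chromosome and at least one individual is genotyped in each population.
#' With variants-only input and `assume_callable`, every position is
#' implicitly callable, so the kept set is a regular grid whose variant
#' members carry the observed genotypes and whose invariant members are
#' reference-homozygous for all haplotypes.
#'
#' @param windows list of `genotype_window`s in genomic order.
#' @param meta sample metadata.
#' @param pops population labels that must each have coverage at a kept
#'   site; default all populations in `meta`.
#' @param min_gap minimum spacing in bp (default 500).
#' @return a list with `positions`, `chromosome`, `alleles`
#'   (haplotype-by-site), and `haplotype_owner`, suitable for
#'   [pairwise_individual_dxy()].
#' @export
thin_sites <- function(windows, meta, pops = NULL, min_gap = 500) {
  if (length(windows) == 0L)
    return(list(positions = numeric(0), chromosome = character(0),
                alleles = NULL, haplotype_owner = character(0)))
  if (is.null(pops)) pops <- unique(meta$population)
  sam <- split(meta$sample, meta$population)

  owner <- windows[[1L]]$haplotype_owner
  pop_rows <- lapply(pops, function(p) which(owner %in% sam[[p]]))

  kept_pos <- list(); kept_chr <- list(); kept_cols <- list()
  last <- -Inf
  last_chr <- ""
  for (w in windows) {
    if (!identical(w$haplotype_owner, owner))
      stop("thin_sites requires a consistent haplotype layout across windows")
    if (w$chromosome != last_chr) {
      last <- -Inf
      last_chr <- w$chromosome
    }
    ac <- isTRUE(w$assume_callable)
    vp <- w$site_positions
    p <- w$start
    while (p < w$end) {
      cand <- if (ac) max(p, last + min_gap) else NA
      if (ac) {
        if (cand >= w$end) break
        # genotypes at this position: variant column if present, else invariant
        j <- match(cand, vp)
        col <- if (!is.na(j)) w$alleles[, j] else rep(0L, length(owner))
        ok <- all(vapply(pop_rows, function(r) any(!is.na(col[r])), logical(1)))
        if (ok) {
          kept_pos[[length(kept_pos) + 1L]] <- cand
          kept_chr[[length(kept_chr) + 1L]] <- w$chromosome
          kept_cols[[length(kept_cols) + 1L]] <- col
          last <- cand
        }
        p <- cand + min_gap
      } else {
        # all-sites input: walk the observed positions
        idx <- which(vp >= max(p, last + min_gap))
        if (length(idx) == 0L) break
        found <- FALSE
        for (j in idx) {
          if (vp[j] < last + min_gap) next
          col <- w$alleles[, j]
          ok <- all(vapply(pop_rows, function(r) any(!is.na(col[r])),
                           logical(1)))
          if (ok) {
            kept_pos[[length(kept_pos) + 1L]] <- vp[j]
            kept_chr[[length(kept_chr) + 1L]] <- w$chromosome
            kept_cols[[length(kept_cols) + 1L]] <- col
            last <- vp[j]
            found <- TRUE
          }
        }
        break
      }
    }
  }
  if (length(kept_pos) == 0L)
    return(list(positions = numeric(0), chromosome = character(0),
                alleles = matrix(integer(0), nrow = length(owner), ncol = 0),
                haplotype_owner = owner))
  list(positions = unlist(kept_pos),
       chromosome = unlist(kept_chr),
       alleles = do.call(cbind, kept_cols),
       haplotype_owner = owner)
}

#' Pairwise dXY between individuals over a thinned site set
#'
#' Treats each individual's haplotypes as a miniature population and
#' computes the per-site absolute divergence between every pair of
#' individuals; the diagonal holds within-individual heterozygosity (and is
#' `NA` for individuals contributing a single haplotype).
#'
#' @param thinned output of [thin_sites()].
#' @param samples individuals to include; default all owners present.
#' @return symmetric matrix with sample ids as dimnames; `NaN` entries (with
#'   a warning) where a pair shares no jointly callable site.
#' @export
pairwise_individual_dxy <- function(thinned, samples = NULL) {
  if (is.null(samples)) samples <- unique(thinned$haplotype_owner)
  if (length(thinned$positions) == 0L) stop("thinned site set is empty")
  n <- length(samples)
  M <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  rows <- lapply(samples, function(s) which(thinned$haplotype_owner == s))
  any_nan <- FALSE
  for (i in seq_len(n)) {
    ai <- thinned$alleles[rows[[i]], , drop = FALSE]
    if (nrow(ai) >= 2L) M[i, i] <- mean_pairwise_diff(ai)
    for (j in seq_len(n)[-seq_len(i)]) {
      aj <- thinned$alleles[rows[[j]], , drop = FALSE]
      cc <- cross_diff_count(ai, aj)
      val <- if (all(is.na(cc$per_pair))) NaN else mean(cc$per_pair, na.rm = TRUE)
      if (is.nan(val)) any_nan <- TRUE
      M[i, j] <- M[j, i] <- val
    }
  }
  if (any_nan)
    warning("some individual pairs share no jointly callable thinned site")
  M
}
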