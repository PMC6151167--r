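# Z/A inference layer: population coordinates and great-circle distances,
# elementwise Z/A ratio matrices, binned summaries, and the directional
# Mantel tests relating the dXY(Z)/dXY(A) ratio to geographic proximity or
# autosomal divergence.

#' Population coordinates as the mean of member sample coordinates
#'
#' @param meta sample metadata with `population`, `lat`, `lon`.
#' @return data.frame `population`, `lat`, `lon`; populations without any
#'   coordinates are excluded with a warning. Populations whose samples
#'   straddle the antimeridian trigger a warning (the naive arithmetic mean
#'   is used).
#' @export
population_coordinates <- function(meta) {
  pops <- unique(meta$population)
  out <- lapply(pops, function(p) {
    mm <- meta[meta$population == p, ]
    ok <- is.finite(mm$lat) & is.finite(mm$lon)
    if (!any(ok)) return(NULL)
    if (diff(range(mm$lon[ok])) > 180)
      warning("population ", p,
              " straddles the antimeridian; naive coordinate mean used")
    data.frame(population = p, lat = mean(mm$lat[ok]),
               lon = mean(mm$lon[ok]), stringsAsFactors = FALSE)
  })
  dropped <- pops[vapply(out, is.null, logical(1))]
  if (length(dropped) > 0L)
    warning("population(s) without coordinates excluded: ",
            paste(dropped, collapse = ", "))
  do.call(rbind, out)
}

#' Great-circle distance matrix in kilometres
#'
#' Haversine distances on a spherical Earth of radius 6371 km.
#'
#' @param coords data.frame with `lat`, `lon` in decimal degrees and a label
#'   column (`population` or `sample`, first non-coordinate column used).
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
geographic_distance_matrix <- function(coords) {
  lab_col <- setdiff(names(coords), c("lat", "lon"))[1L]
  labs <- coords[[lab_col]]
  n <- length(labs)
  rad <- pi / 180
  lat <- coords$lat * rad
  lon <- coords$lon * rad
  M <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    dlat <- lat[j] - lat[i]
    dlon <- lon[j] - lon[i]
    h <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat[j]) * sin(dlon / 2)^2
    d <- 2 * 6371 * asin(pmin(1, sqrt(h)))
    M[i, j] <- M[j, i] <- d
  }
  M
}

#' Elementwise Z/A ratio of two pairwise matrices
#'
#' @param dxy_a,dxy_z symmetric dXY matrices with identical labels,
#'   typically from [pairwise_individual_dxy()] on the autosomal and Z
#'   thinned site sets.
#' @return matrix of `dxy_z / dxy_a`; `NaN` where the autosomal entry is 0.
#' @export
za_ratio_matrix <- function(dxy_a, dxy_z) {
  if (!identical(dim(dxy_a), dim(dxy_z)) ||
      !identical(rownames(dxy_a), rownames(dxy_z)))
    stop("dXY matrices must have identical labels")
  out <- dxy_z / dxy_a
  out[is.finite(dxy_a) & dxy_a == 0] <- NaN
  out
}

#' Bin pairwise series and summarize per bin
#'
#' Left-closed bins of fixed width starting at zero along the chosen axis;
#' per-bin median, quartiles and count. Empty bins up to the data maximum
#' are reported with `n = 0`.
#'
#' @param series data.frame with at least the axis column and a `ratio`
#'   column (see [ratio_series()]).
#' @param axis name of the column to bin on (e.g. `"km"` or `"dxy_a"`).
#' @param width bin width in axis units.
#' @return data.frame `bin_start`, `bin_end`, `n`, `median`, `q25`, `q75`.
#' @export
bin_series <- function(series, axis, width) {
  stopifnot(width > 0, axis %in% names(series))
  x <- series[[axis]]
  y <- series$ratio
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      n = integer(0), median = numeric(0),
                      q25 = numeric(0), q75 = numeric(0)))
  nb <- floor(max(x) / width) + 1L
  idx <- pmin(floor(x / width), nb - 1L)
  out <- lapply(seq_len(nb) - 1L, function(b) {
    yy <- y[idx == b]
    if (length(yy) == 0L)
      data.frame(bin_start = b * width, bin_end = (b + 1) * width, n = 0L,
                 median = NA_real_, q25 = NA_real_, q75 = NA_real_)
    else
      data.frame(bin_start = b * width, bin_end = (b + 1) * width,
                 n = length(yy), median = stats::median(yy),
                 q25 = unname(stats::quantile(yy, 0.25)),
                 q75 = unname(stats::quantile(yy, 0.75)))
  })
  do.call(rbind, out)
}

#' Assemble a pairwise ratio series from matrices
#'
#' Vectorizes the upper triangles of aligned pairwise matrices into a tidy
#' per-pair table for binning and plotting.
#'
#' @param ratio Z/A ratio matrix.
#' @param km geographic distance matrix (km), same labels.
#' @param dxy_a autosomal dXY matrix, same labels.
#' @return data.frame `label1`, `label2`, `ratio`, `km`, `dxy_a`.
#' @export
ratio_series <- function(ratio, km = NULL, dxy_a = NULL) {
  ut <- which(upper.tri(ratio), arr.ind = TRUE)
  out <- data.frame(label1 = rownames(ratio)[ut[, 1L]],
                    label2 = colnames(ratio)[ut[, 2L]],
                    ratio = ratio[ut], stringsAsFactors = FALSE)
  if (!is.null(km)) out$km <- km[ut]
  if (!is.null(dxy_a)) out$dxy_a <- dxy_a[ut]
  out
}

#' Mantel test of the Z/A ratio against a proxy for migration
#'
#' Tests whether the dXY(Z)/dXY(A) ratio is higher between pairs with more
#' opportunity for gene flow. Both proxies considered here - geographic
#' distance and autosomal dXY - decrease with migration opportunity, so the
#' proxy is negated before the one-sided test: a positive Mantel r then
#' means the ratio is elevated at short distances (or low autosomal
#' divergence), the signature of reduced effective migration on the Z.
#'
#' @param ratio Z/A ratio matrix.
#' @param proxy distance or autosomal dXY matrix with the same labels.
#' @param n_permutations,seed passed to [mantel_test()].
#' @param direction `"decreasing"` (default; proxy negated as above) or
#'   `"increasing"`.
#' @param alternative passed to [mantel_test()].
#' @return a `mantel_result`.
#' @export
ratio_vs_proxy_test <- function(ratio, proxy, n_permutations = 999,
                                seed = 1L,
                                direction = c("decreasing", "increasing"),
                                alternative = "greater") {
  direction <- match.arg(direction)
  p <- if (direction == "decreasing") -proxy else proxy
  mantel_test(ratio, p, n_permutations = n_permutations, seed = seed,
              alternative = alternative)
}
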