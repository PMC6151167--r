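#' Block-jackknife mean and standard error for windowed statistics
#'
#' Delete-one-block jackknife over large genomic blocks (default 1 Mb,
#' chosen to exceed the scale of linkage disequilibrium), so that the
#' standard error is robust to autocorrelation between neighbouring
#' windows. Blocks hold unequal window counts (chromosome ends, failed
#' windows), so the weighted delete-m jackknife of Busing et al. is used;
#' with equal blocks it reduces to the classical delete-one formula. The
#' point estimate is the plain mean over windows.
#'
#' @param values per-window statistic values; `NaN`/`NA` windows are
#'   excluded.
#' @param chromosome,start window coordinates aligned with `values`.
#' @param block_span block length in bp (default 1e6).
#' @return object of class `jackknife_estimate`: list with `mean`, `se`,
#'   `ci95_low`, `ci95_high`, `n_blocks`, `block_span`, `n_windows`.
#' @export
block_jackknife <- function(values, chromosome, start, block_span = 1e6) {
  keep <- is.finite(values)
  values <- values[keep]
  chromosome <- chromosome[keep]
  start <- start[keep]
  n <- length(values)
  block <- paste(chromosome, floor(start / block_span), sep = ":")
  blocks <- unique(block)
  g <- length(blocks)
  if (g < 2L)
    stop("need at least two non-empty blocks; use a smaller block_span")
  theta <- mean(values)
  mj <- as.numeric(table(block)[blocks])
  theta_minus <- vapply(blocks, function(b) mean(values[block != b]),
                        numeric(1))
  hj <- n / mj
  theta_j <- g * theta - sum((1 - mj / n) * theta_minus)
  pseudo <- hj * theta - (hj - 1) * theta_minus
  var_j <- mean((pseudo - theta_j)^2 / (hj - 1))
  se <- sqrt(var_j)
  structure(list(mean = theta, se = se,
                 ci95_low = theta - 1.96 * se,
                 ci95_high = theta + 1.96 * se,
                 n_blocks = g, block_span = block_span, n_windows = n),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf(
    "mean %.6g  se %.3g  95%% CI [%.6g, %.6g]  (%d blocks of %g bp, %d windows)\n",
    x$mean, x$se, x$ci95_low, x$ci95_high, x$n_blocks, x$block_span,
    x$n_windows))
  invisible(x)
}

#' Permutation Mantel test for two pairwise matrices
#'
#' Pearson correlation of the vectorized upper triangles, with significance
#' from joint row/column permutations of the second matrix. The default is
#' one-sided in the positive direction (larger observed correlation than
#' permuted); pairs with missing entries in either matrix are dropped from
#' every correlation.
#'
#' When the label count is small enough that all `n!` permutations number no
#' more than `n_permutations`, the test enumerates them exhaustively and the
#' p value is exact (the fraction of all permutations, identity included,
#' reaching the observed correlation).
#'
#' @param A,B symmetric matrices with identical dimnames.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return object of class `mantel_result`: list with `r`, `r_squared`,
#'   `p_value`, `n_permutations`, `seed`, `alternative`, `exact`.
#' @export
mantel_test <- function(A, B, n_permutations = 999, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == ncol(A),
            nrow(B) == ncol(B), nrow(A) == nrow(B))
  if (!is.null(dimnames(A)) && !is.null(dimnames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("matrix labels do not match")
  if (max(abs(A - t(A)), na.rm = TRUE) > 1e-8 ||
      max(abs(B - t(B)), na.rm = TRUE) > 1e-8)
    stop("matrices must be symmetric")
  n <- nrow(A)
  if (n < 4L) stop("need at least 4 labels for a permutation Mantel test")
  ut <- upper.tri(A)
  a <- A[ut]
  r_of <- function(Bm) {
    b <- Bm[ut]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  r_obs <- r_of(B)
  if (!is.finite(r_obs)) stop("observed Mantel correlation is undefined")
  stat <- function(r) if (alternative == "greater") r else abs(r)
  exact <- factorial(n) <= n_permutations
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) r_of(B[p, p]), numeric(1))
    p <- mean(stat(r_perm) >= stat(r_obs) - 1e-12, na.rm = TRUE)
    n_used <- length(perms)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    r_perm <- vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      r_of(B[p, p])
    }, numeric(1))
    p <- (1 + sum(stat(r_perm) >= stat(r_obs), na.rm = TRUE)) /
      (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, r_squared = r_obs^2, p_value = p,
                 n_permutations = n_used, seed = seed,
                 alternative = alternative, exact = exact),
            class = "mantel_result")
}

# all permutations of 1..n as a list (n is small when this is reached)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (r^2 = %.4f), p = %.4g (%s, %d permutations)\n",
              x$r, x$r_squared, x$p_value, x$alternative, x$n_permutations))
  invisible(x)
}
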