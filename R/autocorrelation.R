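#' Moran's I for one distance band
#'
#' The cross-product statistic
#' `I = (n / S0) * sum_{i != j} w_ij z_i z_j / sum_i z_i^2` with binary
#' weights `w_ij = 1` when `d_lo < dist(i, j) <= d_hi`, `z` the centered
#' values, and `S0` the total weight.  Unordered pairs are counted twice in
#' the symmetric double sum.
#'
#' @param values Numeric vector; must have nonzero variance.
#' @param coords Two-column matrix of point coordinates (km).
#' @param d_lo,d_hi Band edges: pairs with `d_lo < d <= d_hi` are included.
#' @return Moran's I for the band.
#' @export
morans_i <- function(values, coords, d_lo, d_hi) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (stats::var(values) == 0) {
    stop("Moran's I is undefined for constant values")
  }
  pr <- band_pairs(coords, c(d_lo, d_hi))[[1L]]
  if (!nrow(pr)) stop("no pairs of points fall inside the distance band")
  z <- values - mean(values)
  cross <- 2 * sum(z[pr[, 1L]] * z[pr[, 2L]])
  s0 <- 2 * nrow(pr)
  (n / s0) * cross / sum(z * z)
}

#' Enumerate point pairs per distance band
#'
#' Chunked pairwise-distance sweep that returns, for each band
#' `(breaks[k], breaks[k+1]]`, the matrix of unordered index pairs
#' `(i < j)` whose distance falls inside it.  Memory stays bounded for the
#' ~10^4-point subsamples used for residual correlograms.
#'
#' @param coords Two-column coordinate matrix.
#' @param breaks Ascending numeric vector of band edges.
#' @return A list of two-column integer matrices, one per band.
#' @export
band_pairs <- function(coords, breaks) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  nb <- length(breaks) - 1L
  stopifnot(nb >= 1L, !is.unsorted(breaks))
  acc <- replicate(nb, list(), simplify = FALSE)
  chunk <- max(1L, floor(4e6 / max(n, 1L)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- .dist_chunk(coords, idx)
    # keep i < j only
    jmat <- matrix(rep(seq_len(n), each = length(idx)), nrow = length(idx))
    imat <- matrix(rep(idx, times = n), nrow = length(idx))
    keep <- jmat > imat & d > breaks[1L] & d <= breaks[nb + 1L]
    if (!any(keep)) next
    di <- d[keep]
    bin <- findInterval(di, breaks, left.open = TRUE, rightmost.closed = FALSE)
    ii <- imat[keep]
    jj <- jmat[keep]
    for (k in unique(bin)) {
      sel <- bin == k
      acc[[k]] <- c(acc[[k]], list(cbind(ii[sel], jj[sel])))
    }
  }
  lapply(acc, function(parts) {
    if (!length(parts)) {
      matrix(integer(0), ncol = 2L)
    } else {
      do.call(rbind, parts)
    }
  })
}

#' Distance-binned Moran's I correlogram of residuals with a null envelope
#'
#' Subsamples up to `n_sample` residuals without replacement, computes
#' Moran's I per distance bin, and builds a 95% null envelope from the
#' 2.5/97.5 percentiles of I over `n_perm` random relabelings of the
#' residuals to the sampled locations.  Bins with no point pairs are
#' reported with `NA` statistics.
#'
#' @param residuals Numeric residuals keyed by position in `coords`.
#' @param coords Two-column coordinate matrix aligned with `residuals`.
#' @param max_dist Largest band edge (km).
#' @param bin_width Band width (km); bins are `(0,5], (5,10], ...` by
#'   default.
#' @param n_sample Subsample size (uses all residuals when fewer exist).
#' @param n_perm Number of permutations for the envelope (>= 99).
#' @param seed Integer seed for subsampling and permutation.
#' @return A data frame of class `"correlogram"` with columns `bin_lo`,
#'   `bin_hi`, `I`, `envelope_lo`, `envelope_hi`, `n_pairs`; attributes
#'   `n_cells`, `seed`, `max_dist`.
#' @export
residual_correlogram <- function(residuals, coords, max_dist = 60,
                                 bin_width = 5, n_sample = 10000,
                                 n_perm = 199, seed = 1L) {
  stopifnot(length(residuals) == nrow(as.matrix(coords)))
  if (n_perm < 99) stop("n_perm must be at least 99")
  set.seed(seed)
  n_all <- length(residuals)
  if (n_sample < n_all) {
    take <- sample.int(n_all, n_sample)
    residuals <- residuals[take]
    coords <- as.matrix(coords)[take, , drop = FALSE]
  } else {
    coords <- as.matrix(coords)
  }
  n <- length(residuals)
  breaks <- seq(0, max_dist, by = bin_width)
  pairs <- band_pairs(coords, breaks)
  z <- residuals - mean(residuals)
  ssq <- sum(z * z)
  if (ssq == 0) stop("Moran's I is undefined for constant residuals")
  stat <- function(zv) {
    vapply(pairs, function(pr) {
      if (!nrow(pr)) return(NA_real_)
      (n / (2 * nrow(pr))) * 2 * sum(zv[pr[, 1L]] * zv[pr[, 2L]]) / ssq
    }, numeric(1))
  }
  I_obs <- stat(z)
  perm <- matrix(NA_real_, n_perm, length(pairs))
  for (p in seq_len(n_perm)) {
    perm[p, ] <- stat(z[sample.int(n)])
  }
  env <- apply(perm, 2L, stats::quantile, probs = c(0.025, 0.975),
               na.rm = TRUE, names = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)],
                    bin_hi = breaks[-1L],
                    I = I_obs,
                    envelope_lo = env[1L, ],
                    envelope_hi = env[2L, ],
                    n_pairs = vapply(pairs, nrow, integer(1)))
  attr(out, "n_cells") <- n
  attr(out, "seed") <- seed
  attr(out, "max_dist") <- max_dist
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Distance at which residual spatial autocorrelation vanishes
#'
#' Scans bins outward from distance zero and returns the upper edge of the
#' last significant bin (I outside the null envelope) before the first
#' non-significant bin.  Returns 0 when the first bin is already inside the
#' envelope; empty bins count as non-significant.  If every bin is
#' significant the maximum distance is returned with a warning.
#'
#' @param cg A [residual_correlogram()] result.
#' @return Distance in km.
#' @export
first_nonsignificant_distance <- function(cg) {
  stopifnot(inherits(cg, "correlogram"), nrow(cg) >= 1L)
  sig <- !is.na(cg$I) & (cg$I < cg$envelope_lo | cg$I > cg$envelope_hi)
  first_inside <- which(!sig)
  if (!length(first_inside)) {
    warning("all bins significant; returning max_dist")
    return(cg$bin_hi[nrow(cg)])
  }
  k <- first_inside[1L]
  if (k == 1L) return(0)
  cg$bin_hi[k - 1L]
}

#' Write a correlogram as CSV
#' @param cg A correlogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlogram_csv <- function(cg, path) {
  utils::write.csv(as.data.frame(cg), path, row.names = FALSE)
  invisible(path)
}
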