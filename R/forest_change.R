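#' Gap-fill a per-year forest classification series
#'
#' Single-pass temporal gap fill of classified forest maps: a missing entry
#' becomes `"forest"` if, in the original (unfilled) series, both the
#' previous and the following year are forest, `"nonforest"` if both are
#' nonforest, and stays missing otherwise.  The first and last years are
#' never filled, and filled values never cascade into later decisions.
#'
#' @param x A character vector of classifications in
#'   `{"forest", "nonforest", NA}` ordered by year, or a cells x years
#'   character matrix.
#' @return The filled vector or matrix, same shape as `x`.
#' @export
gap_fill_series <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 3L) stop("at least 3 years are required")
    out <- x
    for (j in 2L:(ncol(x) - 1L)) {
      miss <- is.na(x[, j])
      both_f <- miss & !is.na(x[, j - 1L]) & !is.na(x[, j + 1L]) &
        x[, j - 1L] == "forest" & x[, j + 1L] == "forest"
      both_n <- miss & !is.na(x[, j - 1L]) & !is.na(x[, j + 1L]) &
        x[, j - 1L] == "nonforest" & x[, j + 1L] == "nonforest"
      out[both_f, j] <- "forest"
      out[both_n, j] <- "nonforest"
    }
    return(out)
  }
  if (length(x) < 3L) stop("at least 3 years are required")
  bad <- !is.na(x) & !x %in% c("forest", "nonforest")
  if (any(bad)) stop("classifications must be 'forest', 'nonforest' or NA")
  drop(gap_fill_series(matrix(x, nrow = 1L)))
}

#' Gap-fill missing forest fractions in a landscape
#'
#' Applies the temporal agreement rule at the level of aggregated forest
#' fractions: a missing year-cell fraction is filled with the mean of its
#' two temporal neighbors when both are observed and both fall on the same
#' side of the 0.5 forest/nonforest threshold (the fraction analogue of
#' "forest in both the previous and following years").  First and last
#' years are never filled; decisions use only original values.
#'
#' @param landscape A landscape data frame with `forest_<year>` columns.
#' @return The landscape with fillable entries replaced.
#' @export
gap_fill_landscape <- function(landscape) {
  .assert_landscape(landscape)
  years <- .years_of(landscape)
  if (length(years) < 3L) stop("at least 3 years are required")
  cols <- .forest_col(years)
  f <- as.matrix(landscape[, cols])
  out <- f
  for (j in 2L:(length(cols) - 1L)) {
    prev <- f[, j - 1L]
    nxt <- f[, j + 1L]
    agree <- is.na(f[, j]) & !is.na(prev) & !is.na(nxt) &
      ((prev >= 0.5) == (nxt >= 0.5))
    out[agree, j] <- (prev[agree] + nxt[agree]) / 2
  }
  landscape[, cols] <- out
  landscape
}

#' Aggregate a fine classification raster to coarse forest fractions
#'
#' Blocks of `k` x `k` fine cells are reduced to the fraction of forest
#' among the non-missing fine cells in the block; an all-missing block is
#' `NA`.  Trailing partial blocks (dimensions not divisible by `k`) are
#' averaged over the fine cells available, since real country boundaries
#' are never block-aligned.
#'
#' @param fine A matrix coded `1` = forest, `0` = nonforest, `NA` = missing.
#' @param k Aggregation factor (number of fine cells per coarse cell edge).
#' @return A `ceiling(nrow/k)` x `ceiling(ncol/k)` matrix of fractions.
#' @export
aggregate_to_grid <- function(fine, k) {
  if (!is.matrix(fine) || !length(fine)) stop("fine must be a non-empty matrix")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  bad <- !is.na(fine) & !fine %in% c(0, 1)
  if (any(bad)) stop("fine raster must be coded 0, 1 or NA")
  bi <- (seq_len(nrow(fine)) - 1L) %/% k + 1L
  bj <- (seq_len(ncol(fine)) - 1L) %/% k + 1L
  grp <- outer(bi, (bj - 1L) * max(bi), "+")
  forest <- tapply(ifelse(is.na(fine), 0, fine), grp, sum)
  avail <- tapply(!is.na(fine), grp, sum)
  frac <- ifelse(avail > 0, forest / avail, NA_real_)
  matrix(frac[as.character(sort(unique(as.vector(grp))))],
         nrow = max(bi), ncol = max(bj))
}

#' Net forest loss per cell between two years
#'
#' Loss is the start-year forest fraction minus the end-year fraction, so
#' negative values mean forest gain.  Cells with an unresolved missing
#' fraction in either year are flagged unusable and carry `NA` loss.
#'
#' @param landscape A landscape data frame.
#' @param start_year,end_year Year labels; default to the first and last
#'   years of the landscape.
#' @return A data frame of class `"loss_table"` with columns `cell_id`,
#'   `loss`, `usable`, `forest_start`.
#' @export
compute_loss <- function(landscape, start_year = NULL, end_year = NULL) {
  .assert_landscape(landscape)
  years <- .years_of(landscape)
  if (is.null(start_year)) start_year <- years[1L]
  if (is.null(end_year)) end_year <- years[length(years)]
  if (!all(c(start_year, end_year) %in% years)) {
    stop("start_year and end_year must be years of the landscape")
  }
  fs <- landscape[[.forest_col(start_year)]]
  fe <- landscape[[.forest_col(end_year)]]
  usable <- !is.na(fs) & !is.na(fe)
  out <- data.frame(cell_id = landscape$cell_id,
                    loss = ifelse(usable, fs - fe, NA_real_),
                    usable = usable,
                    forest_start = fs,
                    protected = landscape$protected)
  attr(out, "start_year") <- start_year
  attr(out, "end_year") <- end_year
  attr(out, "cell_size") <- attr(landscape, "cell_size")
  class(out) <- c("loss_table", "data.frame")
  out
}

#' Group summaries of net forest loss
#'
#' Mean loss over usable cells per group with a normal-approximation 95%
#' confidence interval, plus start-year forest area.  Groups with no usable
#' cells are omitted with a warning.
#'
#' @param loss A [compute_loss()] table.
#' @param groups A vector of group labels aligned with `loss` rows (e.g.
#'   region, `pa_id`, IUCN category, or a constant for a national summary).
#' @return A data frame with one row per group: `group`, `n_cells`,
#'   `mean_loss`, `ci_halfwidth`, `forest_start_km2`.
#' @export
summarize_loss <- function(loss, groups) {
  stopifnot(inherits(loss, "loss_table"), length(groups) == nrow(loss))
  cs <- attr(loss, "cell_size")
  if (is.null(cs)) cs <- 1
  keep <- loss$usable & !is.na(groups)
  dropped <- setdiff(unique(groups[!is.na(groups)]), unique(groups[keep]))
  if (length(dropped)) {
    warning("groups with no usable cells omitted: ",
            paste(dropped, collapse = ", "))
  }
  g <- groups[keep]
  l <- loss$loss[keep]
  fs <- loss$forest_start[keep]
  means <- tapply(l, g, mean)
  ns <- tapply(l, g, length)
  sds <- tapply(l, g, stats::sd)
  sds[is.na(sds)] <- 0  # single-cell groups
  area <- tapply(ifelse(is.na(fs), 0, fs), g, sum) * cs^2
  data.frame(group = names(means),
             n_cells = as.integer(ns),
             mean_loss = as.numeric(means),
             ci_halfwidth = as.numeric(1.96 * sds / sqrt(ns)),
             forest_start_km2 = as.numeric(area),
             row.names = NULL)
}
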