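#' Normalized difference between treated and control samples
#'
#' The standardized mean difference in percent,
#' `100 * (mean_t - mean_c) / sqrt((var_t + var_c) / 2)`, with variances on
#' the n-1 denominator.  Absolute values above 25 flag possible covariate
#' imbalance.  When both variances are zero the statistic is 0 for equal
#' means and signed infinity otherwise.
#'
#' @param treated,control Numeric vectors of covariate values.
#' @return The normalized difference in percent.
#' @export
normalized_difference <- function(treated, control) {
  if (!length(treated) || !length(control)) {
    stop("both samples must be non-empty")
  }
  mt <- mean(treated)
  mc <- mean(control)
  vt <- if (length(treated) > 1L) stats::var(treated) else 0
  vc <- if (length(control) > 1L) stats::var(control) else 0
  pool <- sqrt((vt + vc) / 2)
  if (pool == 0) {
    if (mt == mc) return(0)
    return(sign(mt - mc) * Inf)
  }
  100 * (mt - mc) / pool
}

# Expand covariate columns to a numeric matrix (factors/characters as 0/1
# dummies, one column per level, full encoding).
.dummy_expand <- function(data, covariates) {
  cols <- list()
  for (v in covariates) {
    x <- data[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    if (is.numeric(x) || is.logical(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      for (lev in sort(unique(as.character(x)))) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(as.character(x) == lev)
      }
    }
  }
  do.call(cbind, cols)
}

#' Covariate balance before and after matching
#'
#' Normalized differences per covariate (categoricals dummy-by-dummy) in
#' two phases: `before` compares all treated against all eligible controls;
#' `after` compares the matched treated cells against their matched
#' controls.  Covariates with `|ND| > 25` are flagged imbalanced; the
#' balanced fraction per phase is attached as attribute
#' `"balanced_fraction"`.
#'
#' @param landscape A landscape data frame.
#' @param pairs A `"matched_pairs"` object (may be empty; then only the
#'   `before` phase is computed).
#' @param covariates Covariate columns (default all `cov_*`).
#' @param eligible Optional logical eligibility mask for the `before` pool.
#' @return A data frame of class `"balance_table"`: `covariate`, `phase`,
#'   `mean_treated`, `mean_control`, `sd_treated`, `sd_control`,
#'   `normalized_difference`, `imbalanced`.
#' @export
balance_table <- function(landscape, pairs, covariates = NULL,
                          eligible = NULL) {
  .assert_landscape(landscape)
  if (is.null(covariates)) {
    covariates <- grep("^cov_", names(landscape), value = TRUE)
  }
  if (is.null(eligible)) eligible <- rep(TRUE, nrow(landscape))
  X <- .dummy_expand(landscape, covariates)
  one_phase <- function(ti, ci, phase) {
    rows <- lapply(colnames(X), function(cv) {
      xt <- X[ti, cv]
      xc <- X[ci, cv]
      nd <- normalized_difference(xt, xc)
      data.frame(covariate = cv, phase = phase,
                 mean_treated = mean(xt), mean_control = mean(xc),
                 sd_treated = stats::sd(xt), sd_control = stats::sd(xc),
                 normalized_difference = nd,
                 imbalanced = is.infinite(nd) || abs(nd) > 25)
    })
    do.call(rbind, rows)
  }
  ti0 <- which(landscape$protected & eligible)
  ci0 <- which(!landscape$protected & eligible)
  out <- one_phase(ti0, ci0, "before")
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    ti1 <- match(pairs$treated_id, landscape$cell_id)
    ci1 <- match(pairs$control_id, landscape$cell_id)
    out <- rbind(out, one_phase(ti1, ci1, "after"))
  }
  bf <- tapply(!out$imbalanced, out$phase, mean)
  attr(out, "balanced_fraction") <- bf
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Fraction of balanced covariates after matching
#'
#' Convenience accessor for the share of covariates with `|ND| <= 25` in
#' the after-matching phase of a [balance_table()].
#'
#' @param bt A balance table.
#' @return A single number in `[0, 1]`, or `NA` if no after phase exists.
#' @export
balanced_fraction <- function(bt) {
  bf <- attr(bt, "balanced_fraction")
  if (is.null(bf) || !"after" %in% names(bf)) return(NA_real_)
  as.numeric(bf[["after"]])
}
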