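#' Fit a propensity-score model for protection
#'
#' Maximum-likelihood logistic regression of protection status on the
#' matching covariates, with categorical covariates expanded to dummy
#' variables.  Covariates constant within the eligible sample are dropped
#' with a warning.  Under complete separation the fit falls back to a
#' ridge-penalized logistic model (small penalty) with a warning so that
#' finite scores are always returned.
#'
#' @param data A landscape (or any data frame with a logical `protected`
#'   column and a `cell_id` column).
#' @param covariates Character vector of covariate column names; factor or
#'   character columns are dummy-encoded.
#' @param eligible Logical vector marking rows eligible for matching
#'   (default: all).  Cells with unusable outcomes should be excluded here.
#' @return An object of class `"propensity_fit"`: a list with `scores`
#'   (one per eligible cell, in (0, 1)), `score_sd` (SD over the pooled
#'   eligible sample), `coefficients`, `cell_id`, `treated`, and the
#'   eligible `data` rows.
#' @export
fit_propensity <- function(data, covariates, eligible = NULL) {
  stopifnot(is.data.frame(data), "protected" %in% names(data))
  if (is.null(eligible)) eligible <- rep(TRUE, nrow(data))
  d <- data[eligible, , drop = FALSE]
  if (!any(d$protected) || all(d$protected)) {
    stop("need at least one treated and one control cell among eligibles")
  }
  miss <- setdiff(covariates, names(d))
  if (length(miss)) stop("covariates not found: ", paste(miss, collapse = ", "))
  keep <- covariates[vapply(covariates, function(v) {
    x <- d[[v]]
    ok <- length(unique(x)) > 1L
    if (!ok) warning("dropping constant covariate: ", v)
    ok
  }, logical(1))]
  if (!length(keep)) stop("no non-constant covariates left")
  X <- stats::model.matrix(
    stats::reformulate(keep),
    data = d)[, -1L, drop = FALSE]
  y <- as.numeric(d$protected)
  fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                                         family = stats::binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10)
  coefs <- fit$coefficients
  if (separated) {
    warning("(near-)complete separation detected; ",
            "using a ridge-penalized logistic fit")
    if (ncol(X) >= 2L && requireNamespace("glmnet", quietly = TRUE)) {
      rf <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
      p <- as.vector(stats::predict(rf, newx = X, type = "response"))
      coefs <- c(`(Intercept)` = as.numeric(rf$a0),
                 stats::setNames(as.numeric(rf$beta), rownames(rf$beta)))
    } else {
      # poor-man's ridge: IRLS with an L2 penalty
      lambda <- 1e-3 * nrow(X)
      Xi <- cbind(1, X)
      b <- rep(0, ncol(Xi))
      for (it in 1:50) {
        eta <- drop(Xi %*% b)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-8)
        pen <- diag(c(0, rep(lambda, ncol(X))))
        bn <- solve(crossprod(Xi, w * Xi) + pen,
                    crossprod(Xi, w * eta + (y - mu)))
        if (max(abs(bn - b)) < 1e-10) { b <- bn; break }
        b <- bn
      }
      p <- stats::plogis(drop(Xi %*% b))
      coefs <- stats::setNames(drop(b), c("(Intercept)", colnames(X)))
    }
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  out <- list(scores = p,
              score_sd = stats::sd(p),
              coefficients = coefs,
              cell_id = d$cell_id,
              treated = d$protected,
              covariates = keep,
              data = d)
  class(out) <- "propensity_fit"
  out
}

#' Greedy 1:1 nearest-neighbor matching on the propensity score
#'
#' Pairs each treated cell with a unique (never reused) control cell of
#' nearest propensity score, greedily and without replacement.  Treated
#' cells are processed in descending score order (ties broken by ascending
#' `cell_id`); each takes the unused control minimizing the absolute score
#' difference (ties broken by ascending control `cell_id`).  A pair is
#' rejected — the treated cell stays unmatched — when the nearest distance
#' exceeds the caliper of `caliper_sd` standard deviations of the pooled
#' score distribution.
#'
#' @param fit A [fit_propensity()] object.
#' @param caliper_sd Caliper width in score SD units (default 0.25).
#' @return An object of class `"matched_pairs"`: data frame with columns
#'   `pair_id`, `treated_id`, `control_id`, `distance`, plus attributes
#'   `caliper` (absolute), `score_sd`, `n_unmatched_treated`, `procedure`.
#' @export
nearest_neighbor_match <- function(fit, caliper_sd = 0.25) {
  stopifnot(inherits(fit, "propensity_fit"))
  caliper <- caliper_sd * fit$score_sd
  t_idx <- which(fit$treated)
  c_idx <- which(!fit$treated)
  if (!length(t_idx)) stop("fit has no treated cells")
  ord <- t_idx[order(-fit$scores[t_idx], fit$cell_id[t_idx])]
  if (!length(c_idx)) {
    warning("no control cells; all treated left unmatched")
    out <- data.frame(pair_id = integer(0), treated_id = integer(0),
                      control_id = integer(0), distance = numeric(0))
    attr(out, "caliper") <- caliper
    attr(out, "score_sd") <- fit$score_sd
    attr(out, "n_unmatched_treated") <- length(t_idx)
    attr(out, "procedure") <- "national"
    class(out) <- c("matched_pairs", "data.frame")
    return(out)
  }
  ctrl_scores <- fit$scores[c_idx]
  ctrl_ids <- fit$cell_id[c_idx]
  used <- rep(FALSE, length(c_idx))
  tid <- cid <- integer(0)
  dist <- numeric(0)
  for (i in ord) {
    if (all(used)) break
    d <- abs(ctrl_scores - fit$scores[i])
    d[used] <- Inf
    dmin <- min(d)
    if (dmin > caliper) next
    cands <- which(d == dmin)
    j <- cands[which.min(ctrl_ids[cands])]
    used[j] <- TRUE
    tid <- c(tid, fit$cell_id[i])
    cid <- c(cid, ctrl_ids[j])
    dist <- c(dist, dmin)
  }
  out <- data.frame(pair_id = seq_along(tid), treated_id = tid,
                    control_id = cid, distance = dist)
  attr(out, "caliper") <- caliper
  attr(out, "score_sd") <- fit$score_sd
  attr(out, "n_unmatched_treated") <- length(t_idx) - length(tid)
  attr(out, "procedure") <- "national"
  class(out) <- c("matched_pairs", "data.frame")
  stopifnot(!anyDuplicated(out$control_id), !anyDuplicated(out$treated_id),
            all(out$distance <= caliper + 1e-15))
  out
}

# Default matching covariates of a landscape: continuous cov_* columns plus
# the region label as a dummy-encoded factor (regions enter the national
# model as dummies, not as an exact-matching constraint).
default_matching_covariates <- function(landscape, include_region = TRUE) {
  covs <- grep("^cov_", names(landscape), value = TRUE)
  if (include_region && length(unique(landscape$region_id)) > 1L) {
    covs <- c(covs, "region_id")
  }
  covs
}

#' National propensity-score matching
#'
#' Fits the propensity model on all eligible cells (treated = protected,
#' controls = never-protected) and runs greedy nearest-neighbor matching
#' with the caliper.  Cells whose loss outcome is unusable can be excluded
#' via `loss`.
#'
#' @param landscape A landscape data frame.
#' @param covariates Covariate columns; default all `cov_*` plus region
#'   dummies.
#' @param caliper_sd Caliper in pooled-score SD units.
#' @param loss Optional [compute_loss()] table; unusable cells are dropped
#'   from both groups.
#' @return A `"matched_pairs"` object with `procedure = "national"` and the
#'   propensity fit attached as attribute `"fit"`.
#' @export
match_national <- function(landscape, covariates = NULL, caliper_sd = 0.25,
                           loss = NULL) {
  .assert_landscape(landscape)
  if (is.null(covariates)) {
    covariates <- default_matching_covariates(landscape)
  }
  eligible <- rep(TRUE, nrow(landscape))
  if (!is.null(loss)) {
    eligible <- loss$usable[match(landscape$cell_id, loss$cell_id)]
    eligible[is.na(eligible)] <- FALSE
  }
  fit <- fit_propensity(landscape, covariates, eligible)
  pairs <- nearest_neighbor_match(fit, caliper_sd)
  attr(pairs, "fit") <- fit
  pairs
}

#' Regional matching procedures
#'
#' The three procedures compared for regional effectiveness estimates:
#' \describe{
#'   \item{subsetting}{partition the national matched pairs by the treated
#'     cell's region; a pair may span regions.}
#'   \item{exact_subsetting}{keep the national propensity fit but restrict
#'     each treated cell's candidate controls to its own region, so every
#'     pair is within-region.}
#'   \item{submatching}{an independent propensity fit and matching run per
#'     region (region dummies excluded from the per-region fit).}
#' }
#'
#' @param landscape A landscape data frame.
#' @param covariates Covariate columns (default as in [match_national()]).
#' @param procedure One of `"subsetting"`, `"exact_subsetting"`,
#'   `"submatching"`.
#' @param caliper_sd Caliper in pooled-score SD units.
#' @param loss Optional loss table for eligibility.
#' @return A named list of `"matched_pairs"` objects, one per region that
#'   yielded pairs; regions with treated cells but no eligible controls
#'   give an empty element with a warning.
#' @export
match_regional <- function(landscape, covariates = NULL,
                           procedure = c("subsetting", "exact_subsetting",
                                         "submatching"),
                           caliper_sd = 0.25, loss = NULL) {
  .assert_landscape(landscape)
  procedure <- match.arg(procedure)
  regions <- sort(unique(landscape$region_id))
  region_of <- function(ids) {
    landscape$region_id[match(ids, landscape$cell_id)]
  }
  empty_pairs <- function(fit) {
    out <- data.frame(pair_id = integer(0), treated_id = integer(0),
                      control_id = integer(0), distance = numeric(0))
    attr(out, "caliper") <- NA_real_
    attr(out, "n_unmatched_treated") <- NA_integer_
    class(out) <- c("matched_pairs", "data.frame")
    out
  }
  eligible <- rep(TRUE, nrow(landscape))
  if (!is.null(loss)) {
    eligible <- loss$usable[match(landscape$cell_id, loss$cell_id)]
    eligible[is.na(eligible)] <- FALSE
  }

  if (procedure == "subsetting") {
    national <- match_national(landscape, covariates, caliper_sd, loss)
    out <- lapply(regions, function(r) {
      p <- as.data.frame(national)[region_of(national$treated_id) == r, ,
                                   drop = FALSE]
      attr(p, "caliper") <- attr(national, "caliper")
      attr(p, "score_sd") <- attr(national, "score_sd")
      attr(p, "procedure") <- "subsetting"
      class(p) <- c("matched_pairs", "data.frame")
      p
    })
    names(out) <- regions
    return(out)
  }

  if (procedure == "exact_subsetting") {
    if (is.null(covariates)) {
      covariates <- default_matching_covariates(landscape)
    }
    fit <- fit_propensity(landscape, covariates, eligible)
    fit_region <- landscape$region_id[match(fit$cell_id,
                                            landscape$cell_id)]
    out <- lapply(regions, function(r) {
      sub <- fit
      in_r <- fit_region == r
      sub$scores <- fit$scores[in_r]
      sub$cell_id <- fit$cell_id[in_r]
      sub$treated <- fit$treated[in_r]
      sub$data <- fit$data[in_r, , drop = FALSE]
      # caliper still based on the national pooled score SD
      if (!any(sub$treated)) return(NULL)
      if (!any(!sub$treated)) {
        warning("region ", r, ": treated cells but no controls")
        return(empty_pairs(sub))
      }
      p <- nearest_neighbor_match(sub, caliper_sd)
      attr(p, "procedure") <- "exact_subsetting"
      p
    })
    names(out) <- regions
    return(Filter(Negate(is.null), out))
  }

  # submatching: fully independent per-region fits; region dummies dropped
  out <- lapply(regions, function(r) {
    in_r <- landscape$region_id == r & eligible
    sub <- landscape[in_r, , drop = FALSE]
    if (!any(sub$protected)) return(NULL)
    if (all(sub$protected) || !any(!sub$protected)) {
      warning("region ", r, ": treated cells but no controls")
      return(empty_pairs(NULL))
    }
    covs <- covariates
    if (is.null(covs)) {
      covs <- default_matching_covariates(sub, include_region = FALSE)
    } else {
      covs <- setdiff(covs, "region_id")
    }
    fit <- fit_propensity(sub, covs)
    p <- nearest_neighbor_match(fit, caliper_sd)
    attr(p, "procedure") <- "submatching"
    attr(p, "fit") <- fit
    p
  })
  names(out) <- regions
  Filter(Negate(is.null), out)
}

#' Write matched pairs as CSV
#' @param pairs A `"matched_pairs"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}
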