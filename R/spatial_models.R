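#' Specification of an outcome model
#'
#' Models follow the four-variant design for absorbing residual spatial
#' autocorrelation in matched forest-loss analyses: model 1 is the plain
#' linear mixed model (protection fixed effect; municipality and matched
#' pair as crossed random intercepts); model 2 adds the mean neighborhood
#' loss within one buffer radius as a fixed effect; model 3 adds two
#' nested buffer terms (radii strictly decreasing); model 4 is a spatial
#' error model on a random subsample with row-standardized distance-band
#' weights.
#'
#' @param model_id 1, 2, 3 or 4.
#' @param buffer_radii Numeric radii in km (model 2: one; model 3: two,
#'   strictly decreasing).
#' @param sar_max_dist Distance-band cutoff (km) for the model-4 weights.
#' @param subsample Model-4 subsample size (default 10000).
#' @param seed Seed for the model-4 subsample.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(model_id, buffer_radii = NULL, sar_max_dist = NULL,
                       subsample = 10000L, seed = 1L) {
  model_id <- as.integer(model_id)
  stopifnot(model_id %in% 1:4)
  if (model_id == 1L && length(buffer_radii)) {
    stop("model 1 takes no buffer radii")
  }
  if (model_id == 2L && length(buffer_radii) != 1L) {
    stop("model 2 takes exactly one buffer radius")
  }
  if (model_id == 3L) {
    if (length(buffer_radii) != 2L) stop("model 3 takes two buffer radii")
    if (diff(buffer_radii) >= 0) {
      stop("model 3 radii must be strictly decreasing")
    }
  }
  if (length(buffer_radii) && any(buffer_radii <= 0)) {
    stop("buffer radii must be positive")
  }
  if (model_id == 4L && (is.null(sar_max_dist) || sar_max_dist <= 0)) {
    stop("model 4 requires a positive sar_max_dist")
  }
  structure(list(model_id = model_id, buffer_radii = buffer_radii,
                 sar_max_dist = sar_max_dist,
                 subsample = as.integer(subsample),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Mean neighborhood loss within a radius
#'
#' For each focal point, the mean loss over all usable cells within
#' `0 < d <= radius` km; the focal cell itself (distance 0) is excluded.
#' Neighborhoods draw on every usable cell of the landscape, not only
#' matched cells.  Points with no neighbor get `NA` and should be dropped
#' downstream.
#'
#' @param loss A [compute_loss()] table for the full landscape.
#' @param coords Two-column coordinate matrix aligned with `loss` rows.
#' @param radius Buffer radius in km; must be positive.
#' @param at Optional two-column matrix of focal coordinates (default: all
#'   `loss` cells).
#' @return A data frame `cell_id` (NA when `at` is supplied), `radius`,
#'   `buffer_mean`.
#' @export
buffer_mean_loss <- function(loss, coords, radius, at = NULL) {
  if (radius <= 0) stop("radius must be positive")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(loss))
  usable <- which(loss$usable)
  ucoord <- coords[usable, , drop = FALSE]
  uloss <- loss$loss[usable]
  focal <- if (is.null(at)) coords else as.matrix(at)
  nf <- nrow(focal)
  out <- numeric(nf)
  chunk <- max(1L, floor(4e6 / max(length(usable), 1L)))
  for (start in seq(1L, nf, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nf)
    dx <- outer(focal[idx, 1L], ucoord[, 1L], "-")
    dy <- outer(focal[idx, 2L], ucoord[, 2L], "-")
    d2 <- dx * dx + dy * dy
    inb <- d2 > 0 & d2 <= radius^2
    s <- inb %*% uloss
    cnt <- rowSums(inb)
    out[idx] <- ifelse(cnt > 0, s / cnt, NA_real_)
  }
  data.frame(cell_id = if (is.null(at)) loss$cell_id else NA_integer_,
             radius = radius, buffer_mean = out)
}

#' Assemble the matched-cell model frame
#'
#' One row per matched cell (treated and control), with the loss outcome,
#' protection indicator, municipality and pair identifiers and coordinates
#' — the input to [fit_outcome_model()].
#'
#' @param landscape A landscape data frame.
#' @param loss A [compute_loss()] table aligned with the landscape.
#' @param pairs A `"matched_pairs"` object.
#' @return A data frame with columns `cell_id`, `loss`, `protected` (0/1),
#'   `municipality_id`, `pair_id`, `x`, `y`.
#' @export
matched_model_data <- function(landscape, loss, pairs) {
  stopifnot(nrow(pairs) > 0L)
  ids <- c(pairs$treated_id, pairs$control_id)
  prot <- rep(c(1, 0), each = nrow(pairs))
  pid <- rep(pairs$pair_id, 2L)
  ri <- match(ids, landscape$cell_id)
  li <- match(ids, loss$cell_id)
  data.frame(cell_id = ids,
             loss = loss$loss[li],
             protected = prot,
             municipality_id = landscape$municipality_id[ri],
             pair_id = paste0("P", pid),
             x = landscape$x[ri],
             y = landscape$y[ri])
}

# Row-standardized distance-band weights ("W scheme": each neighbor of a
# point with k neighbors gets weight 1/k, so sparsely connected points
# carry more leverage per link).  Returns a sparse dgCMatrix plus the
# eigenvalues of the similar symmetric matrix D^-1/2 B D^-1/2, which equal
# the eigenvalues of W.
.sar_weights <- function(coords, max_dist) {
  n <- nrow(coords)
  pr <- band_pairs(coords, c(0, max_dist))[[1L]]
  if (!nrow(pr)) stop("no neighbor pairs within sar_max_dist")
  B <- Matrix::sparseMatrix(i = c(pr[, 1L], pr[, 2L]),
                            j = c(pr[, 2L], pr[, 1L]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(B)
  isolated <- deg == 0
  W <- Matrix::Diagonal(n, x = ifelse(deg > 0, 1 / deg, 0)) %*% B
  S <- Matrix::Diagonal(n, x = ifelse(deg > 0, 1 / sqrt(deg), 0)) %*% B %*%
    Matrix::Diagonal(n, x = ifelse(deg > 0, 1 / sqrt(deg), 0))
  ev <- eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
  list(W = W, eigenvalues = ev, isolated = isolated)
}

# Maximum-likelihood spatial error model y = Xb + u, u = lambda W u + e,
# by concentrated likelihood over lambda with the eigenvalue log-det.
.fit_sar_error <- function(y, X, W, ev) {
  n <- length(y)
  lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -0.999
  hi <- 1 / max(ev) - 1e-6
  conc <- function(lambda) {
    A <- Matrix::Diagonal(n) - lambda * W
    yt <- as.vector(A %*% y)
    Xt <- as.matrix(A %*% X)
    b <- stats::lm.fit(Xt, yt)
    s2 <- sum(b$residuals^2) / n
    sum(log(1 - lambda * ev)) - n / 2 * log(s2)
  }
  opt <- stats::optimize(conc, c(lo, hi), maximum = TRUE, tol = 1e-7)
  lambda <- opt$maximum
  A <- Matrix::Diagonal(n) - lambda * W
  yt <- as.vector(A %*% y)
  Xt <- as.matrix(A %*% X)
  b <- stats::lm.fit(Xt, yt)
  s2 <- sum(b$residuals^2) / n
  vc <- s2 * solve(crossprod(Xt))
  list(lambda = lambda, coefficients = b$coefficients,
       vcov = vc, sigma2 = s2,
       innovations = b$residuals,
       response_residuals = y - as.vector(X %*% b$coefficients))
}

#' Fit an outcome model for the protection effect on forest loss
#'
#' Models 1-3 are Gaussian linear mixed models of the loss proportion on
#' the protection indicator with crossed random intercepts for municipality
#' and matched pair, estimated by REML; buffer covariates (mean
#' neighborhood loss within each spec radius, computed over all usable
#' landscape cells) enter as fixed effects.  Model 4 is a spatial error
#' model on a random subsample with row-standardized distance-band weights,
#' estimated by maximum likelihood.  The p-value of the protection
#' coefficient uses the large-sample normal approximation of
#' coefficient/SE.
#'
#' @param md A [matched_model_data()] frame.
#' @param spec A [model_spec()].
#' @param loss Full-landscape [compute_loss()] table (needed for buffer
#'   terms of models 2-4; the weights of model 4 use only `md` cells).
#' @param coords Coordinates aligned with `loss` (needed for models 2-3).
#' @param buffer_pool Which usable landscape cells feed the neighborhood
#'   means: `"unprotected"` (default) or `"all"`.  With `"all"`, the
#'   neighborhoods of protected cells are themselves rich in protected
#'   cells, so the buffer term carries part of the protection effect and
#'   attenuates its coefficient; restricting the pool to unprotected cells
#'   keeps the buffer a pure measure of ambient deforestation pressure.
#' @return An object of class `"outcome_fit"`: `model_id`, `coefficient`
#'   (protection effect), `se`, `p_value`, `stars`, `var_municipality`,
#'   `var_pair`, `residuals` (named by `cell_id`), `converged`, `n`,
#'   `spec`, and for model 4 `lambda`.
#' @export
fit_outcome_model <- function(md, spec, loss = NULL, coords = NULL,
                              buffer_pool = c("unprotected", "all")) {
  buffer_pool <- match.arg(buffer_pool)
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(md) < 4L) stop("need at least 2 matched pairs")
  dat <- md
  buf_terms <- character(0)
  if (length(spec$buffer_radii)) {
    if (is.null(loss) || is.null(coords)) {
      stop("models with buffer terms need the landscape loss table and ",
           "coordinates")
    }
    pool <- loss
    if (buffer_pool == "unprotected" && "protected" %in% names(loss)) {
      pool$usable <- loss$usable & !loss$protected
    }
    for (r in spec$buffer_radii) {
      bm <- buffer_mean_loss(pool, coords, r,
                             at = cbind(dat$x, dat$y))$buffer_mean
      nm <- paste0("buf_", gsub("\\.", "_", format(r, trim = TRUE)))
      dat[[nm]] <- bm
      buf_terms <- c(buf_terms, nm)
    }
    drop <- !stats::complete.cases(dat[, buf_terms, drop = FALSE])
    if (any(drop)) {
      warning(sum(drop), " cells without buffer neighbors dropped")
      dat <- dat[!drop, , drop = FALSE]
    }
  }

  if (spec$model_id == 4L) {
    set.seed(spec$seed)
    if (nrow(dat) > spec$subsample) {
      dat <- dat[sample.int(nrow(dat), spec$subsample), , drop = FALSE]
    }
    wts <- .sar_weights(cbind(dat$x, dat$y), spec$sar_max_dist)
    if (any(wts$isolated)) {
      warning(sum(wts$isolated), " isolated cells dropped from SAR fit")
      dat <- dat[!wts$isolated, , drop = FALSE]
      wts <- .sar_weights(cbind(dat$x, dat$y), spec$sar_max_dist)
    }
    X <- cbind(`(Intercept)` = 1, protected = dat$protected)
    sf <- .fit_sar_error(dat$loss, X, wts$W, wts$eigenvalues)
    coef <- sf$coefficients[["protected"]]
    se <- sqrt(sf$vcov["protected", "protected"])
    p <- 2 * stats::pnorm(-abs(coef / se))
    out <- list(model_id = 4L, coefficient = coef, se = se, p_value = p,
                stars = .stars(p), var_municipality = NA_real_,
                var_pair = NA_real_, lambda = sf$lambda,
                residuals = stats::setNames(sf$innovations, dat$cell_id),
                coords = cbind(dat$x, dat$y),
                converged = TRUE, n = nrow(dat), spec = spec)
    class(out) <- "outcome_fit"
    return(out)
  }

  form <- stats::as.formula(paste(
    "loss ~ protected",
    if (length(buf_terms)) paste("+", paste(buf_terms, collapse = " + "))
    else "",
    "+ (1 | municipality_id) + (1 | pair_id)"))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  co <- lme4::fixef(fit)[["protected"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["protected", "protected"])
  p <- 2 * stats::pnorm(-abs(co / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vget <- function(g) {
    v <- vc$vcov[vc$grp == g & vc$var1 == "(Intercept)"]
    if (length(v)) v else 0
  }
  out <- list(model_id = spec$model_id, coefficient = co, se = se,
              p_value = p, stars = .stars(p),
              var_municipality = vget("municipality_id"),
              var_pair = vget("pair_id"),
              residuals = stats::setNames(stats::residuals(fit),
                                          dat$cell_id),
              coords = cbind(dat$x, dat$y),
              converged = converged, n = nrow(dat), spec = spec,
              fit = fit)
  class(out) <- "outcome_fit"
  out
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("model %d: protection effect %.5f (SE %.5f) p=%.3g%s, n=%d\n",
              x$model_id, x$coefficient, x$se, x$p_value, x$stars, x$n))
  invisible(x)
}

#' Iterative selection of buffer radii from residual correlograms
#'
#' Implements the buffer-sizing rule: fit model 1, read off the distance
#' `d1` at which its residual spatial autocorrelation vanishes, and set the
#' model-2 buffer (and the model-4 weight cutoff) to `d1 - step`.  Then fit
#' model 2 with that buffer, read off its distance `d2`, and set the second
#' buffer of model 3 to `d2 - step`.  The iteration stops, reporting the
#' last completed model as final, whenever a radius would be non-positive.
#'
#' @param md A [matched_model_data()] frame.
#' @param loss Full-landscape loss table.
#' @param coords Coordinates aligned with `loss`.
#' @param step Buffer decrement in km (default 5).
#' @param max_dist,bin_width,n_sample,n_perm Correlogram settings.
#' @param seed Seed for correlogram subsampling/permutation.
#' @param correlogram_fn Optional override taking `(residuals, coords)` and
#'   returning a `"correlogram"`; used mainly for testing the selection
#'   rule against prescribed correlograms.
#' @return A list: `specs` (list of `"model_spec"` for the selected
#'   models), `distances` (named vector `d1`, `d2` where computed),
#'   `final_model` (the largest feasible model id), `fits` (models 1 and 2
#'   fits reused by the caller).
#' @export
select_buffer_distances <- function(md, loss = NULL, coords = NULL,
                                    step = 5, max_dist = 60, bin_width = 5,
                                    n_sample = 10000, n_perm = 199,
                                    seed = 1L, correlogram_fn = NULL) {
  if (is.null(correlogram_fn)) {
    correlogram_fn <- function(res, xy) {
      residual_correlogram(res, xy, max_dist = max_dist,
                           bin_width = bin_width, n_sample = n_sample,
                           n_perm = n_perm, seed = seed)
    }
  }
  fit1 <- fit_outcome_model(md, model_spec(1L), loss, coords)
  cg1 <- correlogram_fn(unname(fit1$residuals), fit1$coords)
  d1 <- first_nonsignificant_distance(cg1)
  r1 <- d1 - step
  if (r1 <= 0) {
    return(list(specs = list(model_spec(1L)),
                distances = c(d1 = d1), final_model = 1L,
                fits = list(fit1)))
  }
  spec2 <- model_spec(2L, buffer_radii = r1, sar_max_dist = r1)
  fit2 <- fit_outcome_model(md, spec2, loss, coords)
  cg2 <- correlogram_fn(unname(fit2$residuals), fit2$coords)
  d2 <- first_nonsignificant_distance(cg2)
  r2 <- d2 - step
  if (r2 <= 0 || r2 >= r1) {
    return(list(specs = list(model_spec(1L), spec2),
                distances = c(d1 = d1, d2 = d2), final_model = 2L,
                fits = list(fit1, fit2)))
  }
  spec3 <- model_spec(3L, buffer_radii = c(r1, r2), sar_max_dist = r1)
  list(specs = list(model_spec(1L), spec2, spec3),
       distances = c(d1 = d1, d2 = d2), final_model = 3L,
       fits = list(fit1, fit2))
}

#' Fit and compare outcome models by residual spatial autocorrelation
#'
#' Fits each spec, computes its residual correlogram, and tabulates the
#' protection coefficient alongside the distance at which residual
#' autocorrelation vanishes; models are ranked by that distance (smaller =
#' better correction).  Model 4 is skipped unless `include_sar = TRUE`,
#' mirroring its exclusion from the default comparison on computational
#' grounds.
#'
#' @param md A [matched_model_data()] frame.
#' @param specs List of `"model_spec"`.
#' @param loss,coords Full-landscape loss table and coordinates.
#' @param max_dist,bin_width,n_sample,n_perm,seed Correlogram settings.
#' @param include_sar Include model-4 specs (default `FALSE`).
#' @return A data frame (one row per model): `model_id`, `coefficient`,
#'   `se`, `p_value`, `stars`, `sac_distance`, `rank`; fitted objects in
#'   attribute `"fits"`, correlograms in `"correlograms"`.
#' @export
compare_models <- function(md, specs, loss = NULL, coords = NULL,
                           max_dist = 60, bin_width = 5, n_sample = 10000,
                           n_perm = 199, seed = 1L, include_sar = FALSE) {
  stopifnot(length(specs) >= 1L)
  if (!include_sar) {
    specs <- Filter(function(s) s$model_id != 4L, specs)
  }
  fits <- list()
  cgs <- list()
  rows <- list()
  for (s in specs) {
    f <- fit_outcome_model(md, s, loss, coords)
    cg <- residual_correlogram(unname(f$residuals), f$coords,
                               max_dist = max_dist, bin_width = bin_width,
                               n_sample = n_sample, n_perm = n_perm,
                               seed = seed)
    d <- first_nonsignificant_distance(cg)
    key <- as.character(s$model_id)
    fits[[key]] <- f
    cgs[[key]] <- cg
    rows[[key]] <- data.frame(model_id = s$model_id,
                              coefficient = f$coefficient, se = f$se,
                              p_value = f$p_value, stars = f$stars,
                              sac_distance = d)
  }
  out <- do.call(rbind, rows)
  out$rank <- rank(out$sac_distance, ties.method = "min")
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "correlograms") <- cgs
  out
}
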