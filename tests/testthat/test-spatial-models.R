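test_that("model specs validate their structure", {
  expect_error(model_spec(2), "one buffer")
  expect_error(model_spec(3, c(5, 30)), "decreasing")
  expect_error(model_spec(3, c(30, 5, 1)), "two buffer")
  expect_error(model_spec(2, -3), "positive")
  expect_error(model_spec(4), "sar_max_dist")
  expect_error(model_spec(1, 10), "no buffer")
  s <- model_spec(3, c(30, 5), sar_max_dist = 30)
  expect_equal(s$buffer_radii, c(30, 5))
})

test_that("buffer means follow the exclusion rule and the naive oracle", {
  expect_error(buffer_mean_loss(data.frame(), cbind(1, 1), 0), "positive")
  # uniform loss -> buffer mean equals that loss everywhere
  xy <- cbind(rep(1:5, 5), rep(1:5, each = 5))
  lt <- data.frame(cell_id = 1:25, loss = rep(0.2, 25),
                   usable = rep(TRUE, 25))
  bm <- buffer_mean_loss(lt, xy, 2)
  expect_equal(bm$buffer_mean, rep(0.2, 25))
  # focal cell's own loss is irrelevant: single neighbor dominates
  lt2 <- data.frame(cell_id = 1:2, loss = c(9.9, 0.4),
                    usable = c(TRUE, TRUE))
  bm2 <- buffer_mean_loss(lt2, cbind(c(0, 1), c(0, 0)), 1.5)
  expect_equal(bm2$buffer_mean[1], 0.4)
  # random landscapes against the brute-force oracle, several radii
  set.seed(9)
  n <- 120
  xy <- cbind(runif(n, 0, 15), runif(n, 0, 15))
  lt3 <- data.frame(cell_id = 1:n, loss = rnorm(n, 0.05, 0.1),
                    usable = runif(n) > 0.15)
  lt3$loss[!lt3$usable] <- NA
  for (r in c(1, 3, 8)) {
    expect_equal(buffer_mean_loss(lt3, xy, r)$buffer_mean,
                 oracle_buffer_mean(lt3, xy, r), tolerance = 1e-12)
  }
})

test_that("mixed model collapses to OLS when random effects vanish", {
  # outcomes generated with NO municipality/pair structure and no spatial
  # noise: REML variances go to ~0 and the coefficient equals OLS
  set.seed(10)
  n_pair <- 60
  md <- data.frame(cell_id = 1:(2 * n_pair),
                   protected = rep(c(1, 0), each = n_pair),
                   municipality_id = sample(paste0("M", 1:6), 2 * n_pair,
                                            TRUE),
                   pair_id = rep(paste0("P", 1:n_pair), 2),
                   x = runif(2 * n_pair, 0, 30),
                   y = runif(2 * n_pair, 0, 30))
  md$loss <- 0.03 - 0.05 * md$protected + rnorm(2 * n_pair, 0, 0.01)
  fit <- fit_outcome_model(md, model_spec(1))
  ols <- coef(lm(loss ~ protected, data = md))[["protected"]]
  expect_equal(fit$coefficient, ols, tolerance = 1e-6)
  expect_lt(fit$var_municipality, 1e-6)
  expect_lt(fit$var_pair, 1e-6)
  expect_equal(sort(names(fit$residuals)), sort(as.character(md$cell_id)))
})

test_that("model 1 recovers the generative effect without confounding", {
  covered <- logical(20)
  for (s in 1:20) {
    sim <- small_landscape(seed = s, nx = 25, ny = 25, effect = -0.05,
                           sac_sd = 0, siting = c(elevation = 0))
    L <- sim$landscape
    loss <- compute_loss(L)
    p <- match_national(L, loss = loss)
    md <- matched_model_data(L, loss, p)
    fit <- fit_outcome_model(md, model_spec(1))
    covered[s] <- abs(fit$coefficient - (-0.05)) <= 1.96 * fit$se
  }
  expect_gte(mean(covered), 0.9)
})

test_that("buffer selection applies the 5-km decrement rule", {
  sim <- small_landscape(seed = 13, nx = 20, ny = 20)
  L <- sim$landscape
  loss <- compute_loss(L)
  md <- matched_model_data(L, loss, match_national(L, loss = loss))
  coords <- cbind(L$x, L$y)

  # prescribed correlograms: model 1 significant to 35 km, model 2 to 10 km
  calls <- 0
  fn <- function(res, xy) {
    calls <<- calls + 1
    fake_correlogram(if (calls == 1) 35 else 10)
  }
  sel <- select_buffer_distances(md, loss, coords, correlogram_fn = fn)
  expect_equal(sel$final_model, 3L)
  expect_equal(sel$specs[[2]]$buffer_radii, 30)
  expect_equal(sel$specs[[3]]$buffer_radii, c(30, 5))
  expect_equal(sel$specs[[3]]$sar_max_dist, 30)
  expect_equal(unname(sel$distances), c(35, 10))

  # d1 = 5 -> radius 0 -> stop at model 1
  sel1 <- select_buffer_distances(md, loss, coords,
                                  correlogram_fn = function(res, xy)
                                    fake_correlogram(5))
  expect_equal(sel1$final_model, 1L)
  expect_length(sel1$specs, 1L)
})

test_that("SAR error model estimates a sensible effect and lambda", {
  set.seed(14)
  sim <- small_landscape(seed = 14, nx = 25, ny = 25, effect = -0.05,
                         sac_sd = 0.04)
  L <- sim$landscape
  loss <- compute_loss(L)
  p <- match_national(L, loss = loss)
  md <- matched_model_data(L, loss, p)
  fit <- fit_outcome_model(md, model_spec(4, sar_max_dist = 10,
                                          subsample = 300, seed = 1))
  expect_equal(fit$model_id, 4L)
  expect_true(is.finite(fit$coefficient) && is.finite(fit$se))
  expect_gt(fit$lambda, 0)        # positive SAC in the errors
  expect_lt(fit$lambda, 1)
  expect_lt(fit$coefficient, 0)   # effect direction recovered
  # determinism for a fixed spec seed
  fit2 <- fit_outcome_model(md, model_spec(4, sar_max_dist = 10,
                                           subsample = 300, seed = 1))
  expect_identical(fit$coefficient, fit2$coefficient)
})

test_that("buffer terms shrink the spurious effect under SAC-only noise", {
  # needs a domain comfortably larger than the park scale, else the null
  # SAC contrast is dominated by a handful of park blocks
  deltas <- sapply(1:6, function(s) {
    sim <- small_landscape(seed = 100 + s, nx = 40, ny = 40, effect = 0,
                           sac_sd = 0.05)
    L <- sim$landscape
    loss <- compute_loss(L)
    p <- suppressWarnings(match_national(L, loss = loss))
    md <- matched_model_data(L, loss, p)
    coords <- cbind(L$x, L$y)
    f1 <- fit_outcome_model(md, model_spec(1))
    f3 <- fit_outcome_model(md, model_spec(3, c(10, 5)), loss, coords)
    c(m1 = abs(f1$coefficient), m3 = abs(f3$coefficient))
  })
  expect_lt(mean(deltas["m3", ]), mean(deltas["m1", ]))
})

test_that("compare_models ranks by residual autocorrelation distance", {
  sim <- small_landscape(seed = 21, nx = 25, ny = 25, sac_sd = 0.05)
  L <- sim$landscape
  loss <- compute_loss(L)
  md <- matched_model_data(L, loss, match_national(L, loss = loss))
  coords <- cbind(L$x, L$y)
  specs <- list(model_spec(1), model_spec(2, 15),
                model_spec(3, c(15, 5)),
                model_spec(4, sar_max_dist = 15, subsample = 200))
  cmp <- suppressWarnings(
    compare_models(md, specs, loss, coords, max_dist = 25,
                   n_sample = 500, n_perm = 99, seed = 4))
  expect_setequal(cmp$model_id, 1:3)  # model 4 excluded by default
  expect_equal(cmp$rank, rank(cmp$sac_distance, ties.method = "min"))
  cmp4 <- suppressWarnings(
    compare_models(md, specs[c(1, 4)], loss, coords, max_dist = 25,
                   n_sample = 500, n_perm = 99, seed = 4,
                   include_sar = TRUE))
  expect_true(4 %in% cmp4$model_id)
  # reproducible bit-for-bit under a fixed seed
  cmp_re <- suppressWarnings(
    compare_models(md, specs, loss, coords, max_dist = 25,
                   n_sample = 500, n_perm = 99, seed = 4))
  keep <- c("model_id", "coefficient", "se", "p_value", "sac_distance")
  expect_identical(cmp[, keep], cmp_re[, keep])
})
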