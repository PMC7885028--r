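test_that("config validation rejects degenerate parameters", {
  expect_error(simulation_config(pa_fraction = 0), "pa_fraction")
  expect_error(simulation_config(pa_fraction = 1), "pa_fraction")
  expect_error(simulation_config(grid_nx = 1, grid_ny = 2), "4 cells")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(years = c(2000, 2015)), "3 years")
  expect_error(simulation_config(sac_noise_range = 0), "sac_noise_range")
  expect_error(simulation_config(
    covariate_specs = list(a = list(range = -1, variance = 1))), "range")
  expect_error(simulation_config(pa_siting_coefs = c(bogus = 1)), "bogus")
})

test_that("gaussian_random_field honors its contracts", {
  expect_error(gaussian_random_field(10, 10, range_km = 0, variance = 1),
               "range_km")
  # degenerate variance -> all-zero surface
  expect_equal(gaussian_random_field(8, 8, 10, 0), matrix(0, 8, 8))
  # determinism for a fixed seed
  expect_identical(gaussian_random_field(15, 15, 10, 1, seed = 42),
                   gaussian_random_field(15, 15, 10, 1, seed = 42))
  # approximate marginal variance
  f <- gaussian_random_field(60, 60, 5, 2, seed = 1)
  expect_gt(stats::var(as.vector(f)), 1.2)
  expect_lt(stats::var(as.vector(f)), 3.2)
})

test_that("GRF correlation decays with distance at the range scale", {
  # averaged over 20 seeds on a 30x30 grid with range 10 km: lag-1
  # correlation must clearly exceed the correlation at distance > 25 km
  # (pre-build estimates: ~0.86 near vs ~0.11 far)
  near <- far <- numeric(20)
  for (s in 1:20) {
    g <- gaussian_random_field(30, 30, 10, 1, seed = s)
    near[s] <- stats::cor(as.vector(g[1:29, ]), as.vector(g[2:30, ]))
    far[s] <- stats::cor(as.vector(g[1:4, ]), as.vector(g[27:30, ]))
  }
  expect_gt(mean(near), 0.5)
  expect_lt(mean(far), 0.35)
  expect_gt(mean(near), mean(far))
})

test_that("generated landscapes satisfy their structural invariants", {
  sim <- small_landscape(seed = 3)
  L <- sim$landscape
  expect_false(anyDuplicated(L$cell_id) > 0)
  expect_setequal(unique(diff(sort(unique(L$x)))), 1)
  fcols <- grep("^forest_", names(L), value = TRUE)
  expect_length(fcols, 4L)
  f <- as.matrix(L[, fcols])
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  expect_true(all(!is.na(L$pa_id[L$protected])))
  expect_true(all(is.na(L$pa_id[!L$protected])))
  expect_true(all(!is.na(L$iucn_cat[L$protected])))
  # ground truth aligned one-to-one
  expect_identical(sim$ground_truth$cell_id, L$cell_id)
  # protected fraction near the 10% target
  expect_gt(mean(L$protected), 0.05)
  expect_lt(mean(L$protected), 0.18)
})

test_that("zero siting coefficients produce unconfounded protection", {
  diffs <- sapply(1:5, function(s) {
    L <- small_landscape(seed = s, nx = 25, ny = 25,
                         siting = c(elevation = 0))$landscape
    mean(L$cov_elevation[L$protected]) - mean(L$cov_elevation[!L$protected])
  })
  # covariate sd is 1; Monte-Carlo error of the group-mean difference
  expect_lt(abs(mean(diffs)), 0.25)
})

test_that("siting coefficients drive pre-matching imbalance monotonically", {
  # latent siting noise off: this dial isolates the covariate channel
  levels <- c(0, 0.5, 1.5)
  nd <- matrix(NA_real_, 5, length(levels))
  for (s in 1:5) {
    for (k in seq_along(levels)) {
      L <- small_landscape(seed = s, nx = 25, ny = 25,
                           siting = c(elevation = levels[k]),
                           pa_siting_noise_sd = 0)$landscape
      nd[s, k] <- abs(normalized_difference(
        L$cov_elevation[L$protected], L$cov_elevation[!L$protected]))
    }
  }
  m <- colMeans(nd)
  expect_true(all(diff(m) >= 0))
  # a strong single-covariate bias exceeds the 25% imbalance threshold,
  # as national-scale siting bias does for elevation in real PA systems
  expect_true(all(nd[, 3] > 25))
})

test_that("null landscape is calibrated: no naive loss difference", {
  diffs <- sapply(1:20, function(s) {
    sim <- small_landscape(seed = s, nx = 20, ny = 20, effect = 0,
                           siting = c(elevation = 0))
    L <- sim$landscape
    loss <- compute_loss(L)
    mean(loss$loss[L$protected]) - mean(loss$loss[!L$protected])
  })
  expect_lt(abs(mean(diffs)), 0.006)
})

test_that("inject_missing blanks exactly the requested count, reproducibly", {
  L <- small_landscape(seed = 5, nx = 20, ny = 20)$landscape
  expect_error(inject_missing(L, 1), "rate")
  expect_identical(inject_missing(L, 0), L)
  L1 <- inject_missing(L, 0.058, seed = 9)
  f <- as.matrix(L1[, grep("^forest_", names(L1))])
  expect_identical(sum(is.na(f)), as.integer(round(0.058 * 400 * 4)))
  L2 <- inject_missing(L, 0.058, seed = 9)
  expect_identical(L1, L2)
})

test_that("landscapes serialize deterministically and round-trip", {
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(p1, p2)))
  write_landscape_csv(small_landscape(seed = 8, nx = 12, ny = 12)$landscape,
                      p1)
  write_landscape_csv(small_landscape(seed = 8, nx = 12, ny = 12)$landscape,
                      p2)
  expect_identical(readLines(p1), readLines(p2))  # bitwise determinism
  back <- read_landscape_csv(p1)
  orig <- small_landscape(seed = 8, nx = 12, ny = 12)$landscape
  expect_equal(back$cov_elevation, orig$cov_elevation, tolerance = 1e-12)
  expect_identical(attr(back, "years"), attr(orig, "years"))
})
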