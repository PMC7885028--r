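test_that("constant covariates are dropped; no-information fit = prevalence", {
  set.seed(1)
  n <- 50
  d <- data.frame(cell_id = 1:n,
                  protected = rep(c(TRUE, FALSE), c(5, 45)),
                  cov_a = rep(1, n), cov_b = rep(2, n))
  # every covariate constant -> nothing to fit on
  expect_error(suppressWarnings(fit_propensity(d, c("cov_a", "cov_b"))),
               "non-constant")
  # one constant covariate dropped with a warning; the other, orthogonal
  # to treatment, leaves scores at (close to) the 10% prevalence
  d$cov_b <- rep(rnorm(25), each = 2)
  d$cov_b <- sample(d$cov_b)  # shuffle: unrelated to protection
  expect_warning(fit <- fit_propensity(d, c("cov_a", "cov_b")),
                 "constant covariate")
  expect_length(fit$scores, n)
  expect_equal(mean(fit$scores), 0.10, tolerance = 1e-6)
})

test_that("identical covariates give identical scores", {
  # duplicate of every treated cell in the control pool
  d <- data.frame(cell_id = 1:20,
                  protected = rep(c(TRUE, FALSE), each = 10),
                  cov_x = rep(rnorm(10), 2))
  fit <- fit_propensity(d, "cov_x")
  expect_equal(fit$scores[1:10], fit$scores[11:20], tolerance = 1e-9)
})

test_that("logistic MLE agrees with a grid-search likelihood oracle", {
  # overlapping groups (no separation), so the MLE is finite
  d <- data.frame(cell_id = 1:6,
                  protected = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                  cov_x = c(2.0, 0.5, -1.0, 0.3, -0.5, 1.0))
  fit <- fit_propensity(d, "cov_x")
  loglik <- function(a, b) {
    p <- plogis(a + b * d$cov_x)
    sum(ifelse(d$protected, log(p), log(1 - p)))
  }
  # brute-force maximization: coarse grid, then two refinement passes
  ctr <- c(0, 0)
  width <- 6
  for (pass in 1:3) {
    grid_a <- seq(ctr[1] - width, ctr[1] + width, length.out = 241)
    grid_b <- seq(ctr[2] - width, ctr[2] + width, length.out = 241)
    ll <- outer(grid_a, grid_b, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    ctr <- c(grid_a[best[1]], grid_b[best[2]])
    width <- width / 50
  }
  expect_lt(abs(unname(fit$coefficients[1]) - ctr[1]), 1e-3)
  expect_lt(abs(unname(fit$coefficients[2]) - ctr[2]), 1e-3)
})

test_that("separation triggers the penalized fallback, not failure", {
  d <- data.frame(cell_id = 1:20,
                  protected = rep(c(TRUE, FALSE), each = 10),
                  cov_x = c(rnorm(10, 5), rnorm(10, -5)))
  expect_warning(fit <- fit_propensity(d, "cov_x"), "separation")
  expect_true(all(is.finite(fit$scores)))
  expect_true(all(fit$scores > 0 & fit$scores < 1))
})

test_that("greedy matcher handles the stated worked examples", {
  # nearest control inside the caliper is taken
  f <- fake_fit(ids = 1:3, scores = c(0.50, 0.49, 0.20),
                treated = c(TRUE, FALSE, FALSE), score_sd = 0.2)
  p <- nearest_neighbor_match(f, caliper_sd = 0.25)
  expect_equal(p$control_id, 2L)
  expect_equal(p$distance, 0.01)
  # nearest control outside the caliper leaves the treated unmatched
  f <- fake_fit(ids = 1:2, scores = c(0.90, 0.50),
                treated = c(TRUE, FALSE), score_sd = 0.10)
  p <- nearest_neighbor_match(f, caliper_sd = 0.25)
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "n_unmatched_treated"), 1L)
  # zero controls -> all unmatched with warning
  f <- fake_fit(ids = 1:2, scores = c(0.4, 0.6), treated = c(TRUE, TRUE),
                score_sd = 0.1)
  expect_warning(p <- nearest_neighbor_match(f), "no control")
  expect_equal(nrow(p), 0L)
})

test_that("crafted 3x3 instance equals the literal greedy oracle", {
  # descending-score processing order matters: the highest-scoring treated
  # claims the shared nearest control first
  t_ids <- c(10L, 11L, 12L)
  t_scores <- c(0.30, 0.70, 0.50)
  c_ids <- c(20L, 21L, 22L)
  c_scores <- c(0.52, 0.48, 0.69)
  sdp <- sd(c(t_scores, c_scores))
  f <- fake_fit(c(t_ids, c_ids), c(t_scores, c_scores),
                rep(c(TRUE, FALSE), each = 3), score_sd = sdp)
  got <- nearest_neighbor_match(f, caliper_sd = 0.25)
  want <- oracle_greedy_match(t_ids, t_scores, c_ids, c_scores,
                              0.25 * sdp)
  expect_equal(got$treated_id, want$treated_id)
  expect_equal(got$control_id, want$control_id)
  expect_equal(got$distance, want$distance)
})

test_that("matching is 1:1 without replacement and caliper-bounded", {
  for (s in 1:10) {
    set.seed(s)
    n_t <- sample(3:12, 1)
    n_c <- sample(3:25, 1)
    f <- fake_fit(ids = sample.int(1000, n_t + n_c),
                  scores = runif(n_t + n_c),
                  treated = rep(c(TRUE, FALSE), c(n_t, n_c)))
    p <- nearest_neighbor_match(f, caliper_sd = 0.25)
    expect_false(anyDuplicated(p$control_id) > 0)
    expect_false(anyDuplicated(p$treated_id) > 0)
    expect_true(all(p$distance <= attr(p, "caliper") + 1e-15))
    expect_equal(nrow(p) + attr(p, "n_unmatched_treated"), n_t)
  }
})

test_that("national matching improves covariate balance when confounded", {
  improved <- logical(5)
  for (s in 1:5) {
    sim <- small_landscape(seed = s, nx = 25, ny = 25)
    L <- sim$landscape
    loss <- compute_loss(L)
    p <- match_national(L, loss = loss)
    bt <- balance_table(L, p)
    m <- tapply(abs(bt$normalized_difference), bt$phase, mean)
    improved[s] <- m[["after"]] < m[["before"]]
    # matched controls are never protected
    expect_true(all(!L$protected[match(p$control_id, L$cell_id)]))
  }
  expect_true(all(improved))
})

test_that("matching reduces the treated/control score gap", {
  gaps <- sapply(1:5, function(s) {
    L <- small_landscape(seed = s, nx = 25, ny = 25)$landscape
    p <- match_national(L)
    fit <- attr(p, "fit")
    sc <- fit$scores[match(c(p$treated_id, p$control_id), fit$cell_id)]
    post <- abs(mean(sc[seq_len(nrow(p))]) - mean(sc[-seq_len(nrow(p))]))
    pre <- abs(mean(fit$scores[fit$treated]) -
                 mean(fit$scores[!fit$treated]))
    c(pre = pre, post = post)
  })
  expect_true(all(gaps["post", ] < gaps["pre", ]))
})

test_that("regional procedures obey their definitions", {
  sim <- small_landscape(seed = 4, nx = 30, ny = 30)
  L <- sim$landscape
  loss <- compute_loss(L)
  region_of <- function(ids) L$region_id[match(ids, L$cell_id)]

  ex <- match_regional(L, procedure = "exact_subsetting", loss = loss)
  for (r in names(ex)) {
    p <- ex[[r]]
    if (!nrow(p)) next
    expect_true(all(region_of(p$treated_id) == r))
    expect_true(all(region_of(p$control_id) == r))
  }

  sub <- match_regional(L, procedure = "subsetting", loss = loss)
  nat <- match_national(L, loss = loss)
  expect_equal(sum(vapply(sub, nrow, integer(1))), nrow(nat))
  # subsetting partitions national pairs by the treated cell's region
  for (r in names(sub)) {
    if (!nrow(sub[[r]])) next
    expect_true(all(region_of(sub[[r]]$treated_id) == r))
  }

  subm <- match_regional(L, procedure = "submatching", loss = loss)
  for (r in names(subm)) {
    p <- subm[[r]]
    if (!nrow(p)) next
    expect_true(all(region_of(p$treated_id) == r))
    expect_true(all(region_of(p$control_id) == r))
    expect_false(anyDuplicated(p$control_id) > 0)
  }
})

test_that("subsetting can pair across regions where exact subsetting cannot", {
  # two regions; the only close-score control for the region-A treated cell
  # sits in region B, so the national match crosses the border
  L <- data.frame(
    cell_id = 1:8,
    x = c(1, 2, 3, 4, 11, 12, 13, 14),
    y = rep(1, 8),
    region_id = rep(c("A", "B"), each = 4),
    municipality_id = rep(c("M1", "M2"), each = 4),
    protected = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    cov_z = c(2.0, -3.0, -3.1, -2.9, 1.9, -1.0, -1.2, -0.8))
  attr(L, "years") <- c(2000, 2005, 2015)
  class(L) <- c("landscape", "data.frame")
  # the crafted instance is separable by design; the ridge fallback warns
  sub <- suppressWarnings(
    match_regional(L, covariates = "cov_z", procedure = "subsetting",
                   caliper_sd = 2))
  pA <- sub[["A"]]
  expect_equal(nrow(pA), 1L)
  expect_equal(L$region_id[match(pA$control_id, L$cell_id)], "B")
})
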