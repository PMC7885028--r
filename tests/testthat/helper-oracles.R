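# Independent reference implementations used as oracles.  These follow the
# stated rules literally and naively (double loops, explicit greedy order)
# and are kept free of any code path they are used to check.

# Literal greedy 1:1 nearest-neighbor matcher: treated in descending score
# (ties: ascending id); each takes the unused control minimizing |score
# difference| (ties: ascending control id); reject when the minimum
# distance exceeds the absolute caliper.
oracle_greedy_match <- function(t_ids, t_scores, c_ids, c_scores, caliper) {
  ord <- order(-t_scores, t_ids)
  used <- rep(FALSE, length(c_ids))
  rows <- list()
  for (k in ord) {
    if (!length(c_ids)) break
    d <- abs(c_scores - t_scores[k])
    d[used] <- Inf
    dmin <- suppressWarnings(min(d))
    if (!is.finite(dmin) || dmin > caliper) next
    cand <- which(d == dmin)
    j <- cand[which.min(c_ids[cand])]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(treated_id = t_ids[k],
                                            control_id = c_ids[j],
                                            distance = dmin)
  }
  if (!length(rows)) {
    return(data.frame(treated_id = integer(0), control_id = integer(0),
                      distance = numeric(0)))
  }
  do.call(rbind, rows)
}

# Build a "propensity_fit" carrier from explicit scores, so the matcher can
# be exercised on crafted instances.
fake_fit <- function(ids, scores, treated, score_sd = stats::sd(scores)) {
  structure(list(scores = scores, score_sd = score_sd, cell_id = ids,
                 treated = treated,
                 coefficients = NULL, covariates = character(0),
                 data = data.frame(cell_id = ids)),
            class = "propensity_fit")
}

# Naive O(n^2) Moran's I for one distance band.
oracle_morans_i <- function(values, coords, d_lo, d_hi) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d > d_lo && d <= d_hi) {
        num <- num + z[i] * z[j]
        s0 <- s0 + 1
      }
    }
  }
  (n / s0) * num / sum(z^2)
}

# Naive buffer mean: for each focal point, average loss of usable cells
# with 0 < d <= radius.
oracle_buffer_mean <- function(loss, coords, radius) {
  n <- nrow(coords)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq_len(n)) {
      if (!loss$usable[j]) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d > 0 && d <= radius) acc <- c(acc, loss$loss[j])
    }
    if (length(acc)) out[i] <- mean(acc)
  }
  out
}

# Direct normalized-difference formula, coded independently.
oracle_nd <- function(t, c) {
  100 * (mean(t) - mean(c)) / sqrt((stats::var(t) + stats::var(c)) / 2)
}

# Small confounded landscape used across tests.
small_landscape <- function(seed, nx = 30, ny = 30, effect = -0.011,
                            sac_sd = 0.03, siting = NULL, ...) {
  if (is.null(siting)) {
    siting <- c(elevation = 0.8, slope = 0.5, dist_road = 0.7,
                pop_density = -0.4, initial_forest = 0.5)
  }
  cfg <- simulation_config(grid_nx = nx, grid_ny = ny, seed = seed,
                           pa_siting_coefs = siting,
                           true_protection_effect = effect,
                           sac_noise_sd = sac_sd, ...)
  generate_landscape(cfg)
}

# A synthetic correlogram with significance (I outside the envelope) for
# all bins with upper edge <= sig_up_to; used to drive the selection rule.
fake_correlogram <- function(sig_up_to, max_dist = 60, bin_width = 5) {
  lo <- seq(0, max_dist - bin_width, by = bin_width)
  hi <- lo + bin_width
  out <- data.frame(bin_lo = lo, bin_hi = hi,
                    I = ifelse(hi <= sig_up_to, 0.5, 0),
                    envelope_lo = -0.1, envelope_hi = 0.1,
                    n_pairs = 100L)
  class(out) <- c("correlogram", "data.frame")
  out
}

# Pool per-region matched pairs into one model frame with unique pair ids.
pool_regional_md <- function(landscape, loss, regional_pairs) {
  mds <- lapply(names(regional_pairs), function(r) {
    p <- regional_pairs[[r]]
    if (is.null(p) || !nrow(p)) return(NULL)
    md <- matched_model_data(landscape, loss, p)
    md$pair_id <- paste0(r, "_", md$pair_id)
    md
  })
  do.call(rbind, Filter(Negate(is.null), mds))
}
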