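# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Stage seeds are a deterministic function of the master seed and a stage
#' label, so that each pipeline stage is reproducible independently of the
#' order in which stages run.  The result is always a valid 32-bit R integer.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Pairwise Euclidean distances from a chunk of points to all points.
# coords: n x 2 matrix. idx: row indices of the chunk.
.dist_chunk <- function(coords, idx) {
  dx <- outer(coords[idx, 1L], coords[, 1L], "-")
  dy <- outer(coords[idx, 2L], coords[, 2L], "-")
  sqrt(dx * dx + dy * dy)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Standardize a vector to mean 0, sd 1 (sd 0 -> zeros).
.standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

.forest_col <- function(year) paste0("forest_", year)

.years_of <- function(landscape) attr(landscape, "years")

.assert_landscape <- function(landscape) {
  stopifnot(is.data.frame(landscape))
  need <- c("cell_id", "x", "y", "region_id", "municipality_id", "protected")
  miss <- setdiff(need, names(landscape))
  if (length(miss)) {
    stop("landscape is missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(landscape)
}
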