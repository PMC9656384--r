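# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are deterministic without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral /
# Fibonacci lattice). Returns an n x 3 matrix of unit vectors.
unit_sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Rowwise euclidean norms.
row_norms <- function(m) sqrt(rowSums(m * m))

# Squared distances between one point `p` (length 3) and the rows of `m`.
dist2_point <- function(p, m) {
  dx <- m[, 1] - p[1]; dy <- m[, 2] - p[2]; dz <- m[, 3] - p[3]
  dx * dx + dy * dy + dz * dz
}

# Full squared-distance matrix between rows of a and rows of b (nm or A,
# caller's units). Kept simple: sizes in this package are a few thousand.
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Minimum-image displacement components for an orthorhombic box (vector of 3
# lengths); `d` is an n x 3 matrix of raw displacements.
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Centered moving average with window `w` frames; ends use the available
# partial window so the output has no NA and the same length as `x`.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Statistical mode of an integer-like vector (smallest value on ties).
int_mode <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

# Largest-remainder apportionment of `n` items to fractions `p` (sums to 1).
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
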