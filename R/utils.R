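# Internal helpers: classed conditions, seeded evaluation, numeric plumbing.

baa_stop <- function(subclass, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "baa_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

baa_warn <- function(subclass, msg) {
  warning(structure(
    class = c(subclass, "baa_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

max_intensity <- function(bit_depth) 2^bit_depth - 1

# Row/column weight matrix for exact area-average 1-D resampling from n_in
# to n_out cells (n_out <= n_in). Rows sum to 1.
area_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * r
    b <- i * r
    j0 <- floor(a) + 1
    j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      lo <- max(a, j - 1)
      hi <- min(b, j)
      if (hi > lo) w[i, j] <- (hi - lo) / r
    }
  }
  w
}

# Exact area-average downsampling of a matrix to target x target.
area_downsample <- function(m, target) {
  wr <- area_weights(nrow(m), target)
  wc <- area_weights(ncol(m), target)
  wr %*% m %*% t(wc)
}

# Nearest-neighbour index map from n_out positions back into n_in positions.
nn_index <- function(n_in, n_out) {
  pmin(n_in, pmax(1L, floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L))
}
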