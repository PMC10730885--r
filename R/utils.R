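#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are unaffected.
#'
#' @param seed non-negative integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Box-window mean and SD via integral images with reflect padding.
# Returns list(mean, sd) of the same shape as `x`; the window is the square
# of side 2*radius+1 centred on each pixel, and sd is the population
# (divide-by-n) standard deviation of the window, clamped at 0.
box_mean_sd <- function(x, radius) {
  stopifnot(is.matrix(x), radius >= 1)
  n <- 2L * radius + 1L
  xp <- reflect_pad(x, radius)
  s1 <- win_sum(xp, n)
  s2 <- win_sum(xp * xp, n)
  m <- s1 / (n * n)
  v <- s2 / (n * n) - m * m
  v[v < 0] <- 0
  list(mean = m, sd = sqrt(v))
}

# Reflect-pad a matrix by `r` pixels on each side (edge pixel not repeated,
# i.e. "symmetric about the border pixel" reflection a b c -> b a | a b c).
reflect_pad <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(r < nr, r < nc)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  x[ri, ci, drop = FALSE]
}

# Sliding-window sums of an (already padded) matrix; returns the matrix of
# sums of every n x n window, size (nrow-n+1) x (ncol-n+1).
win_sum <- function(xp, n) {
  cs <- apply(xp, 2L, cumsum)
  cs <- rbind(0, cs)
  colsum <- cs[(n + 1L):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - n), , drop = FALSE]
  cs2 <- t(apply(colsum, 1L, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (n + 1L):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - n), drop = FALSE]
}

# Centre-crop a matrix to size k x k.
center_crop <- function(x, k) {
  stopifnot(k <= nrow(x), k <= ncol(x))
  r0 <- (nrow(x) - k) %/% 2L
  c0 <- (ncol(x) - k) %/% 2L
  x[(r0 + 1L):(r0 + k), (c0 + 1L):(c0 + k), drop = FALSE]
}
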