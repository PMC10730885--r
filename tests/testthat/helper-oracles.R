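# Brute-force sliding-window Phansalkar threshold (O(N w^2)), with the same
# reflect padding as the fast implementation.  Independent oracle for the
# integral-image path.
phansalkar_brute <- function(img, params) {
  r <- params$window_radius
  nr <- nrow(img); nc <- ncol(img)
  ri <- function(i) { i <- ifelse(i < 1, 2 - i, i); ifelse(i > nr, 2 * nr - i, i) }
  ci <- function(j) { j <- ifelse(j < 1, 2 - j, j); ifelse(j > nc, 2 * nc - j, j) }
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    w <- img[ri(i + (-r:r)), ci(j + (-r:r))]
    m <- mean(w)
    s <- sqrt(mean((w - m)^2))
    out[i, j] <- m * (1 + params$p * exp(-params$q * m) +
                        params$k * (s / params$R - 1))
  }
  out
}

# All-pairs AUC oracle: fraction of (disease, control) pairs ranked
# concordantly, ties counted one half.
auc_brute <- function(values, labels, direction = "low") {
  sc <- if (direction == "low") -values else values
  d <- sc[as.logical(labels)]; c0 <- sc[!as.logical(labels)]
  tot <- 0
  for (x in d) tot <- tot + sum(x > c0) + 0.5 * sum(x == c0)
  tot / (length(d) * length(c0))
}

# A preset with simulator controls set directly (no calibration).
toy_preset <- function(v = 0.3, h = 0, group = "control") {
  p <- default_presets()[[group]]
  p$void_param <- v
  p$heterogeneity_param <- h
  p
}
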