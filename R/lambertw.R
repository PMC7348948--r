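# Principal-branch Lambert W, vectorised, restricted to x >= 0 (the only
# regime the depletion model can produce). Halley iteration from w0 = log1p(x),
# which is within ~0.6 of W0 everywhere on [0, Inf).
lambert_w0 <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("lambert_w0(): argument must be finite and >= 0 (got ",
         paste(head(x[!is.finite(x) | x < 0], 3L), collapse = ", "), ")")
  }
  w <- log1p(x)
  for (i in seq_len(50L)) {
    e <- exp(w)
    f <- w * e - x
    w1 <- w - f / (e * (w + 1) - (w + 2) * f / (2 * w + 2))
    delta <- abs(w1 - w)
    w <- w1
    if (all(delta <= 1e-15 * (abs(w) + 1e-300))) break
  }
  w[x == 0] <- 0
  w
}

# W0(exp(y)) for large y, where exp(y) would overflow: solves w + log(w) = y
# by Newton. Only called with y > 1, where the equation has a unique root > 1.
lambert_w0_log <- function(y) {
  w <- y - log(y)
  for (i in seq_len(50L)) {
    d <- (w + log(w) - y) * w / (w + 1)
    w <- w - d
    if (all(abs(d) <= 1e-15 * abs(w))) break
  }
  w
}
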