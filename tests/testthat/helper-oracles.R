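# Independent oracles and fixture builders, kept separate from the
# package's own estimation paths.

# Pratt algebraic circle fit: minimises the algebraic distance
# a(x^2+y^2) + b x + c y + d subject to b^2 + c^2 - 4 a d = 1.
# Generalised eigenproblem M v = eta B v; the solution is the eigenvector
# of the smallest non-negative eigenvalue.
prattCircle <- function(x, y) {
  z <- x^2 + y^2
  A <- cbind(z, x, y, 1)
  M <- crossprod(A) / length(x)
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4, byrow = TRUE)
  E <- eigen(solve(B, M))
  ev <- Re(E$values); V <- Re(E$vectors)
  ok <- which(ev > -1e-8)   # exact fits give an (numerically) zero eigenvalue
  v <- V[, ok[which.min(ev[ok])]]
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  h <- -b / (2 * a); k <- -cc / (2 * a)
  r <- sqrt(h^2 + k^2 - d / a)
  list(h = h, cy = k, r = r)
}

# Exact points on an upper (apex toward smaller row) arc in image
# coordinates: c1 = cy - sqrt(r^2 - (col - h)^2).
arcBands <- function(cols, h, cy, r, sigma1 = 1) {
  data.frame(col = cols, c1 = cy - sqrt(r^2 - (cols - h)^2),
             sigma1 = sigma1)
}

# Flat sweep with a square stimulus step and exponential decay, built
# directly (not via the package generators).
expDecaySweep <- function(tau_ms, peak_pA = 100, rate = 1e4,
                          pre_s = 0.05, step_s = 0.3, noise = 0,
                          baseline = 0) {
  total <- pre_s + step_s + 0.05
  tgrid <- seq(0, total - 1 / rate, by = 1 / rate)
  onset <- as.integer(pre_s * rate) + 1L
  offset <- as.integer((pre_s + step_s) * rate)
  cur <- rep(baseline, length(tgrid))
  idx <- onset:offset
  cur[idx] <- cur[idx] - peak_pA * exp(-(tgrid[idx] - tgrid[onset]) * 1e3 / tau_ms)
  if (noise > 0) cur <- cur + rnorm(length(cur), 0, noise)
  SweepTrace(tgrid, cur, -20, "pressure", onset, offset)
}

# Per-test temporary directory, cleaned up with the test.
withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
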