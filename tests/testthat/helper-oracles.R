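# Independent scalar-loop oracles for the fusion blocks: everything is
# computed entry by entry with explicit quadruple loops over
# (row, col, channel, sample), sharing no code with the package's
# vectorised implementations.

metaBlockLoopOracle <- function(x, M, Wf, w0f, Wg, w0g) {
  d <- dim(x)
  out <- array(NA_real_, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    f <- w0f[c]; g <- w0g[c]
    for (j in seq_len(nrow(Wf))) {
      f <- f + M[n, j] * Wf[j, c]
      g <- g + M[n, j] * Wg[j, c]
    }
    for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
      t <- tanh(f * x[h, w, c, n])
      out[h, w, c, n] <- 1 / (1 + exp(-(t + g)))
    }
  }
  out
}

metaNetLoopOracle <- function(x, M, W1, b1, W2, b2) {
  d <- dim(x)
  out <- array(NA_real_, d)
  for (n in seq_len(d[4])) {
    hid <- numeric(length(b1))
    for (j in seq_along(b1)) {
      a <- b1[j]
      for (i in seq_len(nrow(W1))) a <- a + M[n, i] * W1[i, j]
      hid[j] <- max(a, 0)
    }
    for (c in seq_len(d[3])) {
      a <- b2[c]
      for (j in seq_along(hid)) a <- a + hid[j] * W2[j, c]
      s <- 1 / (1 + exp(-a))
      for (h in seq_len(d[1])) for (w in seq_len(d[2]))
        out[h, w, c, n] <- s * x[h, w, c, n]
    }
  }
  out
}

poolLoopOracle <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[4], d[3])
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    out[n, c] <- mean(x[, , c, n])
  out
}

convLoopOracle <- function(x, w, b, stride, pad) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
  out <- array(0, c(Ho, Wo, wd[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(wd[4]))
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      acc <- b[co]
      for (ci in seq_len(d[3])) for (kx in seq_len(wd[2])) for (ky in seq_len(wd[1])) {
        hi <- (ho - 1) * stride - pad + ky
        wi <- (wo - 1) * stride - pad + kx
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          acc <- acc + x[hi, wi, ci, n] * w[ky, kx, ci, co]
      }
      out[ho, wo, co, n] <- acc
    }
  out
}

relErr <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))

randomFeatureMap <- function(h, w, k, n)
  array(stats::rnorm(h * w * k * n), c(h, w, k, n))
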