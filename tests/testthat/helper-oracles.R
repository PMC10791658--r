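## Independent FBP oracle: same mathematical definition as the package's
## filtered back-projection, but written naively (explicit DFT matrices,
## per-pixel backprojection loops) and sharing no code with the
## implementation it checks.
oracle_fbp <- function(sino, angles_deg, filter = "hamming", spacing = 1) {
  n <- nrow(sino)
  np <- 2^ceiling(log2(2 * n))
  k <- 0:(np - 1)
  Fm <- exp(-2i * pi * outer(k, k) / np)
  Fi <- exp(2i * pi * outer(k, k) / np) / np
  f <- c(0:(np %/% 2), -((np - np %/% 2 - 1):1)) / np
  H <- abs(f)
  if (filter == "hamming") H <- H * (0.54 + 0.46 * cos(2 * pi * f))
  offs <- (seq_len(n) - (n + 1) / 2) * spacing
  out <- matrix(0, n, n)
  for (a in seq_along(angles_deg)) {
    p <- c(sino[, a], rep(0, np - n))
    filt <- Re(Fi %*% (H * (Fm %*% p)))[1:n] / spacing
    w <- angles_deg[a] * pi / 180
    for (i in 1:n) for (j in 1:n) {
      t_val <- offs[i] * sin(w) + offs[j] * cos(w)
      pos <- (t_val - offs[1]) / spacing + 1
      i0 <- floor(pos)
      if (i0 >= 1 && i0 < n) {
        fr <- pos - i0
        out[i, j] <- out[i, j] + (1 - fr) * filt[i0] + fr * filt[i0 + 1]
      } else if (i0 == n && pos == n) {
        out[i, j] <- out[i, j] + filt[n]
      }
    }
  }
  out * pi / length(angles_deg)
}
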