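# Brute-force reference implementations, independent of the package's
# vectorized code paths.

bruteMae <- function(a, b, m) {
  s <- 0; n <- 0
  for (i in seq_along(a)) if (m[i]) { s <- s + abs(a[i] - b[i]); n <- n + 1 }
  s / n
}

brutePsnr <- function(a, b, m, dr = 4096) {
  s <- 0; n <- 0
  for (i in seq_along(a)) if (m[i]) { s <- s + (a[i] - b[i])^2; n <- n + 1 }
  10 * log10(dr^2 / (s / n))
}

bruteSsim <- function(a, b, m, w = 7, k1 = 0.01, k2 = 0.03, dr = 4096) {
  d <- dim(a); r <- (w - 1) / 2
  c1 <- (k1 * dr)^2; c2 <- (k2 * dr)^2
  vals <- c()
  for (i in (1 + r):(d[1] - r)) for (j in (1 + r):(d[2] - r))
    for (k in (1 + r):(d[3] - r)) {
      if (!m[i, j, k]) next
      pa <- a[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      pb <- b[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      mua <- mean(pa); mub <- mean(pb)
      va <- mean(pa^2) - mua^2; vb <- mean(pb^2) - mub^2
      cab <- mean(pa * pb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + c1) * (2 * cab + c2)) /
                  ((mua^2 + mub^2 + c1) * (va + vb + c2)))
    }
  mean(vals)
}

bruteDice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

# Surface voxels by explicit 6-neighbor loop (volume edge counts as outside).
bruteSurface <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!m[i, j, k]) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else FALSE,
      if (i < d[1]) m[i + 1, j, k] else FALSE,
      if (j > 1) m[i, j - 1, k] else FALSE,
      if (j < d[2]) m[i, j + 1, k] else FALSE,
      if (k > 1) m[i, j, k - 1] else FALSE,
      if (k < d[3]) m[i, j, k + 1] else FALSE)
    out[i, j, k] <- !all(nb)
  }
  out
}

bruteHausdorff <- function(a, b, spacing) {
  a <- bruteSurface(a); b <- bruteSurface(b)
  pa <- which(a, arr.ind = TRUE); pb <- which(b, arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing, `*`); pb <- sweep(pb, 2, spacing, `*`)
  dmat <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                                nrow(pa) + seq_len(nrow(pb)),
                                                drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
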