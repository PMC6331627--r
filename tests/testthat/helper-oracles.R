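# brute-force reference implementations, deliberately naive

oracle_autocorr <- function(frame, k) {
  L <- length(frame)
  s <- 0
  for (m in seq_len(L - k)) s <- s + frame[m] * frame[m + k]
  s
}

oracle_dft <- function(x) {
  N <- length(x)
  X <- complex(N)
  for (k in 0:(N - 1)) {
    acc <- 0 + 0i
    for (m in 0:(N - 1)) acc <- acc + x[m + 1] * exp(-2i * pi * k * m / N)
    X[k + 1] <- acc
  }
  X
}

oracle_conv2d <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  kr <- nrow(kernel); kc <- ncol(kernel)
  r0 <- (kr - 1) %/% 2; c0 <- (kc - 1) %/% 2
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    s <- 0
    for (u in 1:kr) for (v in 1:kc) {
      rr <- r + r0 - u + 1; cc <- c + c0 - v + 1
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        s <- s + kernel[u, v] * image[rr, cc]
    }
    out[r, c] <- s
  }
  out
}

oracle_glcm <- function(image, dr, dc, g) {
  nr <- nrow(image); nc <- ncol(image)
  P <- matrix(0, g, g)
  for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- image[r, c] + 1; j <- image[r2, c2] + 1
      P[i, j] <- P[i, j] + 1        # ordered pair
      P[j, i] <- P[j, i] + 1        # symmetric accumulation
    }
  }
  P / sum(P)
}

oracle_haralick <- function(P, classic = FALSE) {
  g <- nrow(P)
  energy <- 0; inertia <- 0; entropy <- 0; sij <- 0
  for (i in 1:g) for (j in 1:g) {
    p <- P[i, j]
    energy <- energy + p^2
    inertia <- inertia + (i - j)^2 * (if (classic) p else p^2)
    if (p > 0) entropy <- entropy - p * log10(p)
    sij <- sij + i * j * p
  }
  pi_ <- rowSums(P); pj <- colSums(P)
  u1 <- sum((1:g) * pi_); u2 <- sum((1:g) * pj)
  d1 <- sqrt(sum(((1:g) - u1)^2 * pi_)); d2 <- sqrt(sum(((1:g) - u2)^2 * pj))
  corr <- if (d1 * d2 == 0) 0 else (sij - u1 * u2) / (d1 * d2)
  c(energy = energy, inertia = inertia, correlation = corr,
    entropy = entropy)
}

oracle_entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# plug-in IG from a contingency table (rows = feature value, cols = class)
oracle_ig <- function(tab) {
  n <- sum(tab)
  h <- oracle_entropy2(colSums(tab) / n)
  cond <- 0
  for (r in seq_len(nrow(tab)))
    cond <- cond + sum(tab[r, ]) / n * oracle_entropy2(tab[r, ] / sum(tab[r, ]))
  h - cond
}

jaccard_interval <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}

# small fast recording for pipeline-level tests
toy_synth_spec <- function(seed, burst_rate = 4, n_cycles = 2)
  synth_spec(n_cycles = n_cycles, cycle_s = 2, gap_s = 1.2,
             burst_rate = burst_rate, seed = seed)
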