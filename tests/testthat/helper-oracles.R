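# Independent brute-force oracles used across tests.

# chi-square statistic on a 2x2 table from the textbook formula
chisq_2x2_oracle <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# Benjamini-Hochberg q-values from the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p down
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided Mann-Whitney p for small samples by full enumeration
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  u_obs <- sum(rank(all_v)[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(idx, 2, function(i) {
    sum(rank(all_v)[i]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# direct double-loop spatial correlation of one image (mean-subtracted,
# normalized by overlap count and squared mean)
acf_direct_oracle <- function(img, xi, psi) {
  mu <- mean(img)
  H <- nrow(img); W <- ncol(img)
  s <- 0; n <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + psi; c2 <- c + xi
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      s <- s + (img[r, c] - mu) * (img[r2, c2] - mu)
      n <- n + 1
    }
  }
  s / n / mu^2
}

# shared small movie fixture for tracking tests (built once per run)
sim_small_movie <- function(seed = 42, ...) {
  cfg <- spt_sim_config(field_px = 64, n_frames = 30, density = 0.2,
                        read_noise_sd = 0, shot_noise = FALSE,
                        camera_baseline = 0, bleach_rate = 0,
                        seed = seed, ...)
  simulate_spt_movie(cfg)
}
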