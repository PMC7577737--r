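# Independent oracles used across tests. These re-derive quantities by the
# most literal route available (double-sum DFT, explicit step-up enumeration)
# and must stay independent of the package's computational paths.

# brute-force 2D power spectrum: literal double-sum DFT, O(n^4)
brute_spectrum <- function(data) {
  nx <- nrow(data); nt <- ncol(data)
  P <- matrix(0, nx, nt)
  for (kx in 0:(nx - 1)) for (kt in 0:(nt - 1)) {
    s <- 0i
    for (x in 0:(nx - 1)) for (t in 0:(nt - 1))
      s <- s + data[x + 1, t + 1] *
        exp(-2i * pi * (kx * x / nx + kt * t / nt))
    P[kx + 1, kt + 1] <- Mod(s)^2
  }
  P
}

# brute-force quadrant maximum from an unshifted power matrix
brute_quadrant_max <- function(P, fs, direction, band = NULL) {
  nx <- nrow(P); nt <- ncol(P)
  kx <- corticalwaves:::signed_bins(nx)
  tf <- corticalwaves:::signed_bins(nt) * fs / nt
  rows <- if (direction == "FW") which(kx < 0) else which(kx > 0 & kx < nx / 2)
  cols <- which(tf > 0 & tf < fs / 2)
  if (!is.null(band)) cols <- cols[tf[cols] >= band[1] & tf[cols] <= band[2]]
  max(P[rows, cols])
}

# literal Benjamini-Hochberg step-up: enumerate every threshold
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# a wave map of seeded white noise
noise_map <- function(n_elec = 5, n_samp = 250, fs = 250, seed = 1) {
  set.seed(seed)
  wave_map(matrix(rnorm(n_elec * n_samp), n_elec), fs = fs)
}

# reduced study configuration used by the pipeline-scale tests: 250 Hz,
# midline-only channels, 2 min pre / 6 min post with 2-minute target blocks
reduced_config <- function(seed, pre_minutes = 2, post_minutes = 6, ...) {
  study_sim_config(fs = 250, n_channels = 5, pre_minutes = pre_minutes,
                   post_minutes = post_minutes,
                   target_block_minutes = min(2, post_minutes), seed = seed,
                   ...)
}

# estimate the log-log spectral slope of one channel over 1-45 Hz
spectral_slope <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= 1 & f <= 45
  coef(lm(log10(sp[keep]) ~ log10(f[keep])))[[2]]
}
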