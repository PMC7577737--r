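#' Time-by-electrode map
#'
#' One windowed segment of a recording restricted to an ordered electrode
#' array: rows are electrodes (posterior first), columns are samples. The 2D
#' spectrum of this map carries travelling-wave energy in its signed-frequency
#' quadrants.
#'
#' @param data numeric matrix, electrodes x samples, >= 3 rows, finite.
#' @param fs sampling rate in Hz.
#' @param t_start start time of the window in seconds relative to injection.
#' @return an object of class `wave_map`.
#' @export
wave_map <- function(data, fs, t_start = 0) {
  if (!is.matrix(data) || !is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 3L) stop("a wave map needs at least 3 electrodes")
  if (!all(is.finite(data))) stop("wave map data must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(data = unname(data), fs = as.numeric(fs),
                 t_start = as.numeric(t_start)),
            class = "wave_map")
}

#' Surrogate-shuffle specification
#'
#' The null distribution for the wave statistic is obtained by shuffling the
#' electrode (row) order of each map, which destroys spatial structure --
#' including wave direction -- while preserving each channel's temporal
#' spectrum. Shuffles are drawn uniformly with replacement from all row
#' orderings (the identity permutation is permitted); with `exhaustive =
#' TRUE` all `n_elec!` orderings are averaged instead, giving a deterministic
#' surrogate independent of `n_shuffles` and `seed` (available for arrays of
#' up to 6 electrodes).
#'
#' @param n_shuffles number of shuffles to average (default 100).
#' @param seed integer master seed; per-window seeds are derived from it.
#' @param exhaustive average all permutations instead of sampling.
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(n_shuffles = 100, seed = 1L, exhaustive = FALSE) {
  if (!is.finite(n_shuffles) || n_shuffles < 1) stop("n_shuffles must be >= 1")
  structure(list(n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
                 exhaustive = isTRUE(exhaustive)),
            class = "surrogate_spec")
}

#' Frequency bands
#'
#' Half-open `[low, high)` band edges tile the 1-45 Hz axis so that every
#' spectral bin belongs to exactly one band; the last band includes its upper
#' edge. The delta band starts at 1 Hz (the analysis band-pass corner; 1 s
#' windows resolve 1 Hz anyway) and theta/alpha upper edges are 8/13 Hz so
#' the conventional ranges tile without gaps.
#'
#' @param delta,theta,alpha,beta numeric `c(low, high)` edges in Hz.
#' @return an object of class `band_definition`.
#' @export
band_definition <- function(delta = c(1, 4), theta = c(4, 8),
                            alpha = c(8, 13), beta = c(13, 30)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha, beta = beta)
  if (any(vapply(bands, function(b) b[2] <= b[1], logical(1))))
    stop("each band needs low < high")
  for (i in seq_len(length(bands) - 1L))
    if (bands[[i + 1L]][1] < bands[[i]][2])
      stop("bands must be ascending and non-overlapping")
  structure(bands, class = "band_definition")
}

#' Net wave amount in decibel
#'
#' `10 * log10(w / wss)`: the observed quadrant maximum relative to the mean
#' of its electrode-shuffled surrogates. 0 dB means no net wave beyond what
#' the channels' temporal spectra alone produce.
#'
#' @param w observed quadrant maximum power (> 0); vectorized.
#' @param wss mean surrogate maximum power (> 0); vectorized.
#' @return decibel value(s).
#' @export
wave_db <- function(w, wss) {
  if (any(!is.finite(w)) || any(!is.finite(wss)) || any(w <= 0) || any(wss <= 0))
    stop("wave powers must be positive and finite")
  10 * log10(w / wss)
}

# ---- internal spectral machinery ------------------------------------------

# signed DFT bin indices for length n: 0, 1, ..., floor(n/2), -(ceil(n/2)-1), ..., -1
signed_bins <- function(n) {
  half <- n %/% 2L
  c(0L:half, if (n > half + 1L) -((n - half - 1L):1L))
}

dft_matrix <- function(n) exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)

# all permutations of 1:n, identity first
all_permutations <- function(n) {
  f <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(f(v[-i]), function(p) c(v[i], p))))
  }
  matrix(unlist(f(seq_len(n))), nrow = n)
}

PERM_TABLE_MAX <- 720L  # table mode for n_elec <= 6

# quadrant context shared across windows of equal geometry
quad_ctx <- function(n_elec, n_samp, fs, band = c(1, 45)) {
  kx <- signed_bins(n_elec)
  kt <- signed_bins(n_samp)
  tf <- kt * fs / n_samp
  # positive-spatial-frequency rows; exclude the sign-ambiguous spatial Nyquist
  pos_rows <- which(kx > 0 & (n_elec %% 2L == 1L | kx < n_elec / 2))
  cols <- which(tf > 0 & tf < fs / 2)
  if (!is.null(band)) cols <- cols[tf[cols] >= band[1] & tf[cols] <= band[2]]
  if (!length(cols)) stop("no temporal-frequency bins left in the band")
  if (!length(pos_rows)) stop("no nonzero spatial-frequency bins")
  W <- dft_matrix(n_elec)
  table_mode <- factorial(n_elec) <= PERM_TABLE_MAX
  perms <- if (table_mode) all_permutations(n_elec) else NULL
  Amat <- NULL
  if (table_mode) {
    # selector matrix over the product table: row j picks, for each position
    # x (ascending), the product term with source row perms[x, j]; the fixed
    # ascending-x summation order makes permutations of identical rows give
    # bit-identical spectra (the exact-zero null of the dB statistic)
    np <- ncol(perms)
    Amat <- matrix(0, np, n_elec * n_elec)
    for (j in seq_len(np))
      Amat[j, (seq_len(n_elec) - 1L) * n_elec + perms[, j]] <- 1
  }
  list(n_elec = n_elec, n_samp = n_samp, fs = fs,
       kx = kx, tf = tf, pos_rows = pos_rows, cols = cols,
       freqs = tf[cols], W = W, Wpos = W[pos_rows, , drop = FALSE],
       table_mode = table_mode, n_perm = if (table_mode) ncol(perms) else NA_integer_,
       perms = perms, Amat = Amat, flip = rev(seq_len(n_elec)))
}

# row-wise FFT of a map restricted to ctx$cols: n_elec x n_band complex
time_fft <- function(data, ctx, cols = ctx$cols) {
  t(stats::mvfft(t(data)))[, cols, drop = FALSE]
}

# per-permutation quadrant power over the positive-spatial rows: for each
# permutation q the spectrum value is sum_x Wpos[r, x] * V[q(x), ], realized
# as a 0/1 selector product over the precomputed table Wpos[r, x] * V[y, ].
# Every permutation sums its terms in the same ascending-x order, so maps
# with identical rows give bit-identical values for every permutation (the
# exact-zero null of the dB statistic). Returns np x m matrix of per-perm
# quadrant maxima over the positive rows, per column of V.
posk_P <- function(Vflat, ctx) {
  nx <- ctx$n_elec
  m <- ncol(Vflat)
  pf <- NULL
  for (r in seq_along(ctx$pos_rows)) {
    Tm <- matrix(0i, nx * nx, m)
    for (x in seq_len(nx))
      Tm[(x - 1L) * nx + seq_len(nx), ] <- ctx$Wpos[r, x] * Vflat
    Fr <- ctx$Amat %*% Re(Tm)
    Fi <- ctx$Amat %*% Im(Tm)
    P <- Fr * Fr + Fi * Fi
    pf <- if (is.null(pf)) P else pmax(pf, P)
  }
  pf
}

# table-mode quadrant summary for one window (V: nx x nb):
# list(per_perm = n_perm vector of maxima over (rows, cols), per_freq =
# n_perm x nb matrix, raw, peak_col)
posk_all <- function(V, ctx) {
  pf <- posk_P(V, ctx)                            # np x nb
  mc <- max.col(pf, ties.method = "first")
  list(per_freq = pf, per_perm = pf[cbind(seq_len(ctx$n_perm), mc)],
       raw = pf[1L, ][mc[1L]], peak_col = mc[1L])
}

# fallback for large arrays: identity plus sampled row permutations
posk_sampled <- function(V, ctx, draws_rows) {
  qmax <- function(rows_idx) {
    P <- Mod(ctx$Wpos %*% V[rows_idx, , drop = FALSE])^2
    mc <- which.max(apply(P, 2, max))
    c(max(P), mc)
  }
  id <- qmax(seq_len(ctx$n_elec))
  surr <- vapply(draws_rows, function(q) qmax(q)[1L], numeric(1))
  list(raw = id[1L], peak_col = id[2L], surr_mean = mean(surr))
}

derive_seed <- function(seed, i) {
  as.integer((((as.double(seed) %% 2147483647) * 48271 + i * 16807) %%
                2147483647))
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", genv, inherits = FALSE))
    get(".Random.seed", genv) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  } else assign(".Random.seed", old, genv))
  set.seed(seed)
  force(code)
}

draw_shuffles <- function(ctx, spec, window_seed) {
  if (spec$exhaustive) {
    if (!ctx$table_mode)
      stop("exhaustive surrogates need n_elec! <= ", PERM_TABLE_MAX)
    return(seq_len(ctx$n_perm))
  }
  with_seed(window_seed, {
    if (ctx$table_mode) sample.int(ctx$n_perm, spec$n_shuffles, replace = TRUE)
    else lapply(seq_len(spec$n_shuffles), function(i) sample.int(ctx$n_elec))
  })
}

# ---- 2D spectrum -----------------------------------------------------------

#' Two-dimensional power spectrum of a wave map
#'
#' Squared magnitude of the unnormalized 2D discrete Fourier transform of the
#' time-by-electrode map, with signed spatial frequencies (cycles per
#' electrode step) on the rows and signed temporal frequencies (Hz) on the
#' columns. Parseval's identity holds:
#' `sum(power) = n_elec * n_samples * sum(data^2)`.
#'
#' The quadrant convention, calibrated against generated plane waves, is that
#' forward (posterior-to-anterior) propagation puts energy in the quadrant
#' with negative spatial and positive temporal frequency (and its point
#' mirror). Negative-spatial-frequency rows are computed by running the
#' positive-frequency code path on the electrode-flipped map -- numerically
#' identical in exact arithmetic, and guaranteeing that flipping the
#' electrode order swaps the quadrants bit-exactly.
#'
#' @param map a [wave_map()].
#' @return an object of class `wave_spectrum`: list with `power`
#'   (n_elec x n_samples), `spatial_freqs` (cycles/electrode, signed, rows),
#'   `temporal_freqs` (Hz, signed, columns), `fs`, `convention`.
#' @export
spectrum_2d <- function(map) {
  if (!inherits(map, "wave_map")) stop("`map` must be a wave_map")
  if (!all(is.finite(map$data))) stop("non-finite values in wave map")
  nx <- nrow(map$data); nt <- ncol(map$data)
  kx <- signed_bins(nx)
  kt <- signed_bins(nt)
  W <- dft_matrix(nx)
  V <- t(stats::mvfft(t(map$data)))       # n_elec x n_samples complex
  pos <- which(kx > 0)
  P <- matrix(0, nx, nt)
  P[kx == 0, ] <- Mod(W[kx == 0, , drop = FALSE] %*% V)^2
  P[pos, ] <- Mod(W[pos, , drop = FALSE] %*% V)^2
  neg <- which(kx < 0)
  if (length(neg)) {
    Vf <- V[rev(seq_len(nx)), , drop = FALSE]
    Pf <- Mod(W[pos, , drop = FALSE] %*% Vf)^2
    # row for spatial bin -k comes from bin +k of the flipped map
    P[neg, ] <- Pf[match(-kx[neg], kx[pos]), , drop = FALSE]
  }
  structure(list(power = P, spatial_freqs = kx / nx,
                 temporal_freqs = kt * map$fs / nt, fs = map$fs,
                 n_elec = nx, n_samples = nt,
                 convention = "forward = spatial < 0 & temporal > 0"),
            class = "wave_spectrum")
}

#' @export
print.wave_spectrum <- function(x, ...) {
  cat(sprintf("<wave_spectrum> %d spatial x %d temporal bins (fs %g Hz)\n  %s\n",
              x$n_elec, x$n_samples, x$fs, x$convention))
  invisible(x)
}

#' Maximum quadrant power of a 2D wave spectrum
#'
#' The maximum power over bins with strictly nonzero spatial AND strictly
#' nonzero temporal frequency in the requested direction's quadrant,
#' optionally restricted to a temporal band. Bins on the zero-frequency lines
#' are excluded: a spatially uniform component is not a travelling wave and a
#' temporal DC offset is not an oscillation. Sign-ambiguous Nyquist bins are
#' excluded likewise. Forward and backward quadrants are point mirrors of
#' each other.
#'
#' @param spectrum a [spectrum_2d()] result.
#' @param direction `"FW"` (posterior-to-anterior) or `"BW"`.
#' @param band optional temporal band `c(low, high)` in Hz; `NULL` uses all
#'   nonzero temporal frequencies below Nyquist. Default 1-45 Hz, the
#'   preprocessing filter band.
#' @return list with `power`, `temporal_hz`, `spatial_cpe` (signed cycles
#'   per electrode of the peak bin).
#' @export
quadrant_max <- function(spectrum, direction = c("FW", "BW"), band = c(1, 45)) {
  direction <- match.arg(direction)
  sf <- spectrum$spatial_freqs
  tf <- spectrum$temporal_freqs
  nx <- spectrum$n_elec
  rows <- if (direction == "FW") which(sf < 0) else
    which(sf > 0 & (nx %% 2L == 1L | sf < 0.5))
  if (nx %% 2L == 0L && direction == "FW") rows <- rows[sf[rows] > -0.5]
  cols <- which(tf > 0 & tf < spectrum$fs / 2)
  if (!is.null(band)) cols <- cols[tf[cols] >= band[1] & tf[cols] <= band[2]]
  if (!length(cols) || !length(rows))
    stop("no bins left in the quadrant after exclusions")
  sub <- spectrum$power[rows, cols, drop = FALSE]
  i <- arrayInd(which.max(sub), dim(sub))
  list(power = sub[i], temporal_hz = tf[cols[i[2]]],
       spatial_cpe = sf[rows[i[1]]])
}

# ---- window-level quantification ------------------------------------------

#' Mean surrogate quadrant maximum for one map
#'
#' Recomputes the quadrant maximum after each of `n_shuffles` uniform row
#' (electrode) shuffles and returns the arithmetic mean -- the denominator of
#' the decibel wave statistic. Deterministic given the seed; the identical
#' shuffle sequence serves both directions of a given window.
#'
#' @param map a [wave_map()].
#' @param direction `"FW"` or `"BW"`.
#' @param spec a [surrogate_spec()].
#' @param band temporal band in Hz (default 1-45).
#' @return mean surrogate maximum power (scalar).
#' @export
surrogate_maxima <- function(map, direction = c("FW", "BW"),
                             spec = surrogate_spec(), band = c(1, 45)) {
  direction <- match.arg(direction)
  est <- quantify_window(map, spec, band)
  if (direction == "FW") est$fw_surr else est$bw_surr
}

#' Quantify forward and backward waves in one map
#'
#' Computes the raw forward/backward quadrant maxima, their electrode-shuffle
#' surrogate means, the net wave amounts in decibel, and the temporal
#' frequency of each quadrant peak. The forward side of every quantity is
#' obtained by running the positive-spatial-frequency code path on the
#' electrode-flipped map, so flipping the electrode order of the input swaps
#' the forward and backward results bit-exactly (surrogates included, for a
#' fixed seed).
#'
#' @param map a [wave_map()].
#' @param spec a [surrogate_spec()].
#' @param band temporal band in Hz (default 1-45).
#' @return one-row data frame of class `wave_estimates` with columns
#'   `t_start`, `fw_raw`, `bw_raw`, `fw_surr`, `bw_surr`, `fw_db`, `bw_db`,
#'   `fw_peak_hz`, `bw_peak_hz`.
#' @export
quantify_window <- function(map, spec = surrogate_spec(), band = c(1, 45)) {
  if (!inherits(map, "wave_map")) stop("`map` must be a wave_map")
  ctx <- quad_ctx(nrow(map$data), ncol(map$data), map$fs, band)
  V <- time_fft(map$data, ctx)
  draws <- draw_shuffles(ctx, spec, spec$seed)
  est <- quant_core(V, ctx, draws)
  est$t_start <- map$t_start
  as_wave_estimates(est, map$fs, band, spec)
}

# shared core: V restricted to band columns; draws as from draw_shuffles()
quant_core <- function(V, ctx, draws) {
  Vf <- V[ctx$flip, , drop = FALSE]
  if (ctx$table_mode) {
    bw <- posk_all(V, ctx)
    fw <- posk_all(Vf, ctx)
    fw_surr <- mean(fw$per_perm[draws])
    bw_surr <- mean(bw$per_perm[draws])
  } else {
    draws_cols <- draws                    # explicit permutations
    bw <- posk_sampled(V, ctx, draws_cols)
    fw <- posk_sampled(Vf, ctx, draws_cols)
    fw_surr <- fw$surr_mean; bw_surr <- bw$surr_mean
  }
  data.frame(t_start = NA_real_,
             fw_raw = fw$raw, bw_raw = bw$raw,
             fw_surr = fw_surr, bw_surr = bw_surr,
             fw_db = wave_db(fw$raw, fw_surr),
             bw_db = wave_db(bw$raw, bw_surr),
             fw_peak_hz = ctx$freqs[fw$peak_col],
             bw_peak_hz = ctx$freqs[bw$peak_col])
}

as_wave_estimates <- function(df, fs, band, spec) {
  df <- df[, c("t_start", "fw_raw", "bw_raw", "fw_surr", "bw_surr",
               "fw_db", "bw_db", "fw_peak_hz", "bw_peak_hz")]
  structure(df, class = c("wave_estimates", "data.frame"),
            fs = fs, band = band, n_shuffles = spec$n_shuffles,
            exhaustive = spec$exhaustive)
}

#' @export
print.wave_estimates <- function(x, ...) {
  cat(sprintf("<wave_estimates> %d windows, band %s Hz, %s surrogates\n",
              nrow(x), paste(attr(x, "band"), collapse = "-"),
              if (isTRUE(attr(x, "exhaustive"))) "exhaustive"
              else attr(x, "n_shuffles")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more windows\n")
  invisible(x)
}

#' Quantify travelling waves across a whole recording
#'
#' Slides windows over the (optionally array-selected) recording and applies
#' [quantify_window()] to each. Surrogate shuffles are redrawn per window
#' from a per-window seed derived from the master seed, so any window can be
#' reproduced in isolation.
#'
#' @param rec an [recording()].
#' @param array optional [electrode_array()] to select and order channels;
#'   `NULL` uses the recording as-is (rows already in spatial order).
#' @param window a [window_spec()].
#' @param surrogates a [surrogate_spec()].
#' @param band temporal band in Hz (default 1-45).
#' @return a `wave_estimates` data frame, one row per window.
#' @export
quantify_recording <- function(rec, array = NULL, window = window_spec(),
                               surrogates = surrogate_spec(), band = c(1, 45)) {
  validate_recording(rec)
  if (!is.null(array)) rec <- select_array(rec, array)
  nw <- window$length_s * rec$fs
  ns <- window$step_s * rec$fs
  if (abs(nw - round(nw)) > 1e-8 || abs(ns - round(ns)) > 1e-8)
    stop("window length and step x fs must be integer numbers of samples")
  nw <- as.integer(round(nw)); ns <- as.integer(round(ns))
  starts <- window_starts(ncol(rec$data), nw, ns)
  ctx <- quad_ctx(nrow(rec$data), nw, rec$fs, band)
  if (ctx$table_mode) {
    est <- quantify_batched(rec, starts, nw, ctx, surrogates)
  } else {
    est <- do.call(rbind, lapply(seq_along(starts), function(i) {
      m <- wave_map(rec$data[, (starts[i] + 1L):(starts[i] + nw), drop = FALSE],
                    rec$fs, rec$t0 + starts[i] / rec$fs)
      V <- time_fft(m$data, ctx)
      draws <- draw_shuffles(ctx, surrogates,
                             derive_seed(surrogates$seed, i))
      e <- quant_core(V, ctx, draws)
      e$t_start <- m$t_start
      e
    }))
  }
  as_wave_estimates(est, rec$fs, band, surrogates)
}

# vectorized path: batches windows (and the full permutation table) through
# single complex matrix products; surrogate draws then just index the
# per-permutation maxima
quantify_batched <- function(rec, starts, nw, ctx, spec, chunk = 64L) {
  nb <- length(ctx$cols)
  nx <- ctx$n_elec
  npos <- length(ctx$pos_rows)
  np <- ctx$n_perm
  n_win <- length(starts)
  out <- vector("list", ceiling(n_win / chunk))
  side_vals <- function(Vflat, k) {
    # Vflat: nx x (nb*k); returns list(raw, peak, per-perm maxima np x k)
    pf <- posk_P(Vflat, ctx)                             # np x (nb*k)
    dim(pf) <- c(np, nb, k)
    id <- pf[1, , ]; dim(id) <- c(nb, k)                 # identity permutation
    peak <- max.col(t(id), ties.method = "first")
    raw <- id[cbind(peak, seq_len(k))]
    pm <- aperm(pf, c(1, 3, 2)); dim(pm) <- c(np * k, nb)
    mx <- pm[cbind(seq_len(np * k), max.col(pm, ties.method = "first"))]
    dim(mx) <- c(np, k)
    list(raw = raw, peak = peak, perm_max = mx)
  }
  ci <- 0L
  for (lo in seq.int(1L, n_win, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_win)
    k <- hi - lo + 1L
    idx <- outer(seq_len(nw), starts[lo:hi], `+`)        # nw x k sample index
    Varr <- array(0i, dim = c(nx, nb, k))
    for (ch in seq_len(nx)) {
      segs <- matrix(rec$data[ch, idx], nw, k)
      Varr[ch, , ] <- stats::mvfft(segs)[ctx$cols, , drop = FALSE]
    }
    Vflat <- Varr; dim(Vflat) <- c(nx, nb * k)
    bw <- side_vals(Vflat, k)
    Vflatf <- Varr[ctx$flip, , , drop = FALSE]; dim(Vflatf) <- c(nx, nb * k)
    fw <- side_vals(Vflatf, k)
    fw_surr <- numeric(k); bw_surr <- numeric(k)
    if (spec$exhaustive) {
      fw_surr <- colMeans(fw$perm_max)
      bw_surr <- colMeans(bw$perm_max)
    } else {
      for (j in seq_len(k)) {
        draws <- draw_shuffles(ctx, spec, derive_seed(spec$seed, lo + j - 1L))
        fw_surr[j] <- mean(fw$perm_max[draws, j])
        bw_surr[j] <- mean(bw$perm_max[draws, j])
      }
    }
    ci <- ci + 1L
    out[[ci]] <- data.frame(
      t_start = rec$t0 + starts[lo:hi] / rec$fs,
      fw_raw = fw$raw, bw_raw = bw$raw,
      fw_surr = fw_surr, bw_surr = bw_surr,
      fw_db = wave_db(fw$raw, fw_surr), bw_db = wave_db(bw$raw, bw_surr),
      fw_peak_hz = ctx$freqs[fw$peak], bw_peak_hz = ctx$freqs[bw$peak])
  }
  do.call(rbind, out)
}

#' Net wave amount at each temporal frequency
#'
#' Instead of one maximum per quadrant, takes for each nonzero temporal
#' frequency the maximum quadrant power over nonzero spatial frequencies, and
#' converts it to decibel against the per-frequency surrogate mean computed
#' from the same shuffles.
#'
#' @param map a [wave_map()].
#' @param spec a [surrogate_spec()].
#' @param band temporal band in Hz (default 1-45).
#' @return data frame with columns `freq_hz`, `fw_raw`, `fw_surr`, `fw_db`,
#'   `bw_raw`, `bw_surr`, `bw_db`.
#' @export
per_frequency_waves <- function(map, spec = surrogate_spec(), band = c(1, 45)) {
  if (!inherits(map, "wave_map")) stop("`map` must be a wave_map")
  ctx <- quad_ctx(nrow(map$data), ncol(map$data), map$fs, band)
  if (!ctx$table_mode)
    stop("per-frequency surrogates are implemented for n_elec <= 6")
  V <- time_fft(map$data, ctx)
  draws <- draw_shuffles(ctx, spec, spec$seed)
  bw <- posk_all(V, ctx)
  fw <- posk_all(V[ctx$flip, , drop = FALSE], ctx)
  fw_surr <- colMeans(fw$per_freq[draws, , drop = FALSE])
  bw_surr <- colMeans(bw$per_freq[draws, , drop = FALSE])
  data.frame(freq_hz = ctx$freqs,
             fw_raw = fw$per_freq[1L, ], fw_surr = fw_surr,
             fw_db = wave_db(fw$per_freq[1L, ], fw_surr),
             bw_raw = bw$per_freq[1L, ], bw_surr = bw_surr,
             bw_db = wave_db(bw$per_freq[1L, ], bw_surr))
}

#' Histogram of quadrant peak frequencies by band
#'
#' Counts the windows whose forward (or backward) quadrant peak falls in each
#' frequency band. Peaks exactly on a band edge belong to the upper band
#' (half-open `[low, high)` convention); the last band includes its upper
#' edge. Windows peaking outside the union of bands are not counted.
#'
#' @param estimates a `wave_estimates` data frame.
#' @param direction `"FW"` or `"BW"`.
#' @param bands a [band_definition()].
#' @return named integer vector of per-band window counts.
#' @export
peak_band_histogram <- function(estimates, direction = c("FW", "BW"),
                                bands = band_definition()) {
  direction <- match.arg(direction)
  if (!nrow(estimates)) stop("empty estimates")
  if (!inherits(bands, "band_definition")) stop("`bands` must be a band_definition")
  peaks <- if (direction == "FW") estimates$fw_peak_hz else estimates$bw_peak_hz
  counts <- vapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    hi_ok <- if (i == length(bands)) peaks <= b[2] else peaks < b[2]
    sum(peaks >= b[1] & hi_ok)
  }, integer(1))
  names(counts) <- names(bands)
  counts
}
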