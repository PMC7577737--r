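#' Configuration of the simulated drug-versus-placebo EEG study
#'
#' Defaults emulate the structure of a 13-subject pharmaco-EEG experiment:
#' two sessions per subject (placebo first, drug second), eyes-closed resting
#' EEG at 1000 Hz with 32 channels, recordings from 5 minutes before to 20
#' minutes after injection, a backward-dominant alpha baseline, and a drug
#' effect that raises forward waves and lowers (but does not abolish)
#' backward waves, at full strength by minute 2 and back to half by minute
#' 10. The decibel targets are group means of the 5-minute post-injection
#' block; per-subject targets are drawn around them with the given
#' between-subject SDs. Baseline (pre-injection) targets reuse the placebo
#' post-block means, since placebo leaves the pre/post pattern unchanged.
#'
#' @param n_subjects number of subjects (default 13).
#' @param fs sampling rate in Hz (default 1000).
#' @param n_channels total channels (default 32; must include or equal the
#'   5 midline electrodes).
#' @param pre_minutes,post_minutes recording minutes before/after injection.
#' @param fw_db_targets,bw_db_targets named `c(placebo_post=, dmt_post=)`
#'   group-mean decibel targets for the post-injection block.
#' @param between_subject_sd named `c(fw=, bw=)` SDs of per-subject targets.
#' @param onset_minutes minutes over which the drug effect ramps 0 to full.
#' @param plateau_minutes minute at which the plateau ends and decay starts.
#' @param half_life_minutes exponential decay half-life of the effect.
#' @param target_block_minutes length of the post block the targets refer to.
#' @param wave_cpe spatial frequency of the simulated waves (cycles per
#'   electrode step).
#' @param diluent_amplitude,diluent_phases amplitude and fixed per-electrode
#'   phases of the directionless carrier component that sets the surrogate
#'   floor; calibration solves the wave amplitudes against it.
#' @param modulation_depth,modulation_period_s depth and period of the slow
#'   antiphase amplitude modulation of forward versus backward waves (drives
#'   their negative moment-by-moment coupling).
#' @param band_mix_baseline,band_mix_drug per-band probabilities that a given
#'   minute's carrier sits in delta/theta/alpha/beta, at baseline and under
#'   full drug effect (drug shifts mass from alpha toward delta/theta).
#' @param carrier_hz per-band carrier frequencies (integer Hz keeps windows
#'   on the spectral grid).
#' @param noise_amplitude RMS of 1/f noise added to the midline channels
#'   (0 disables it); `noise_exponent` its spectral slope.
#' @param background_amplitude RMS of the 1/f background on non-midline
#'   channels.
#' @param rating_noise_sd SD of the noise on minute-wise intensity ratings.
#' @param rating_scale intensity ratings live on `[0, rating_scale]`.
#' @param rating_effect_db forward-effect size (dB) mapped to the full
#'   rating scale.
#' @param n_vas_items number of end-of-session visual-analogue-scale items.
#' @param vas_noise_sd SD of the per-item VAS noise.
#' @param noise_exponent spectral slope of the added 1/f noise.
#' @param seed master seed for the study.
#' @return an object of class `study_sim_config`.
#' @export
study_sim_config <- function(n_subjects = 13, fs = 1000, n_channels = 32,
                             pre_minutes = 5, post_minutes = 20,
                             fw_db_targets = c(placebo_post = -0.20,
                                               dmt_post = 0.19),
                             bw_db_targets = c(placebo_post = 0.51,
                                               dmt_post = 0.18),
                             between_subject_sd = c(fw = 0.29, bw = 0.25),
                             onset_minutes = 2, plateau_minutes = 5,
                             half_life_minutes = 5,
                             target_block_minutes = 5,
                             wave_cpe = 0.2,
                             diluent_amplitude = 1,
                             diluent_phases = 2 * pi * c(0.13, 0.71, 0.39,
                                                         0.93, 0.55),
                             modulation_depth = 0.12,
                             modulation_period_s = 40,
                             band_mix_baseline = c(delta = 0.08, theta = 0.08,
                                                   alpha = 0.76, beta = 0.08),
                             band_mix_drug = c(delta = 0.38, theta = 0.27,
                                               alpha = 0.30, beta = 0.05),
                             carrier_hz = c(delta = 2, theta = 6,
                                            alpha = 10, beta = 20),
                             noise_amplitude = 0.2, noise_exponent = 1,
                             background_amplitude = 1,
                             rating_noise_sd = 1, rating_scale = 10,
                             rating_effect_db = 1,
                             n_vas_items = 20, vas_noise_sd = 0.3,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, fs > 0, pre_minutes >= 0, post_minutes >= 1,
            all(between_subject_sd > 0), onset_minutes > 0,
            plateau_minutes >= onset_minutes, half_life_minutes > 0,
            modulation_depth >= 0, modulation_depth < 1,
            noise_amplitude >= 0, all(band_mix_baseline >= 0),
            all(band_mix_drug >= 0), rating_noise_sd >= 0)
  if (n_channels < 5) stop("n_channels must be at least 5 (the midline array)")
  structure(cfg, class = "study_sim_config")
}

#' @export
print.study_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<study_sim_config> %d subjects, %g Hz, %d channels, ",
                     "%g min pre / %g min post\n"),
              x$n_subjects, x$fs, x$n_channels, x$pre_minutes, x$post_minutes))
  cat(sprintf("  FW targets (dB): placebo %.2f, drug %.2f (sd %.2f)\n",
              x$fw_db_targets[["placebo_post"]], x$fw_db_targets[["dmt_post"]],
              x$between_subject_sd[["fw"]]))
  cat(sprintf("  BW targets (dB): placebo %.2f, drug %.2f (sd %.2f)\n",
              x$bw_db_targets[["placebo_post"]], x$bw_db_targets[["dmt_post"]],
              x$between_subject_sd[["bw"]]))
  invisible(x)
}

# drug-effect time profile: 0 pre-injection, linear ramp to 1 over the onset,
# plateau, then exponential decay (half-life in minutes)
effect_level <- function(t_s, cfg) {
  on <- cfg$onset_minutes * 60
  pl <- cfg$plateau_minutes * 60
  hl <- cfg$half_life_minutes * 60
  ifelse(t_s < 0, 0,
         ifelse(t_s < on, t_s / on,
                ifelse(t_s < pl, 1, 2^(-(t_s - pl) / hl))))
}

# mean effect level within minute bin b (covering [60b, 60(b+1)) seconds)
minute_effect <- function(b, cfg) {
  tt <- 60 * b + seq(0.5, 59.5, by = 1)
  mean(effect_level(tt, cfg))
}

midline_5 <- c("Oz", "POz", "Pz", "Cz", "FCz")

montage_32 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FCz", "FC2", "FC6",
                "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CPz", "CP2", "CP6",
                "P7", "P3", "Pz", "P4", "P8",
                "POz", "O1", "Oz", "O2", "Iz")

sim_channel_labels <- function(n) {
  if (n == 5) return(midline_5)
  if (n >= 30 && all(midline_5 %in% montage_32[seq_len(n)]))
    return(montage_32[seq_len(n)])
  c(midline_5, paste0("BG", seq_len(n - 5)))
}

# ---- amplitude calibration -------------------------------------------------

# decibel response of the three-component carrier mixture at one temporal
# frequency: forward wave (amplitude af), backward wave (ab), and the fixed
# scattered-phase diluent. Complex row amplitudes stand in for the carrier
# column of the window FFT (the constant factor cancels in the dB ratio);
# surrogates are the exhaustive permutation average, so the response is
# deterministic and smooth in (af, ab). Because the generator modulates the
# two wave amplitudes in antiphase over a slow cycle, the response is the
# window-average over that cycle: one column per modulation phase, evaluated
# in a single permutation-table pass.
mixture_db <- function(af, ab, cfg, cal, au = 1) {
  mod <- cal$mod_phases
  nph <- length(mod)
  np <- length(af)                                  # vectorized over pairs
  af_c <- rep(af, each = nph) * (1 + mod)           # column = (pair, phase)
  ab_c <- rep(ab, each = nph) * (1 - mod)
  V <- outer(exp(-1i * cal$theta), af_c) + outer(exp(1i * cal$theta), ab_c) +
    matrix(au * cfg$diluent_amplitude * exp(1i * cfg$diluent_phases),
           nrow = 5, ncol = np * nph)
  per_pair <- function(pf) {
    db <- wave_db(pf[1L, ], colMeans(pf))
    colMeans(matrix(db, nph, np))                   # average over the cycle
  }
  fw <- per_pair(posk_P(V[cal$ctx$flip, , drop = FALSE], cal$ctx))
  bw <- per_pair(posk_P(V, cal$ctx))
  if (np == 1L) c(fw = fw, bw = bw) else rbind(fw = fw, bw = bw)
}

calib_context <- function(cfg, n_phases = 16L) {
  n <- 5L
  # single carrier column: a minimal quadrant context at an arbitrary on-grid
  # frequency; only the spatial machinery matters
  ctx <- quad_ctx(n, 8L, 8, band = NULL)
  mod <- if (cfg$modulation_depth > 0)
    cfg$modulation_depth * sin(2 * pi * (seq_len(n_phases) - 1) / n_phases)
  else 0
  list(ctx = ctx, theta = 2 * pi * cfg$wave_cpe * (0:(n - 1)),
       mod_phases = mod)
}

#' Solve wave amplitudes for target decibel levels
#'
#' Finds forward/backward plane-wave amplitudes such that the noise-free
#' three-component carrier mixture of the study generator yields the
#' requested forward and backward net wave amounts, using damped Newton
#' iteration on the log-amplitudes (grid-initialized; exhaustive-permutation
#' surrogates make the objective deterministic).
#'
#' @param fw_db,bw_db target net wave amounts in decibel.
#' @param cfg a [study_sim_config()] (supplies the diluent and the spatial
#'   frequency).
#' @param tol convergence tolerance in dB.
#' @return named vector `c(af, ab)` of amplitudes.
#' @export
calibrate_amplitudes <- function(fw_db, bw_db, cfg = study_sim_config(),
                                 tol = 1e-4, init = NULL) {
  cal <- calib_context(cfg)
  target <- c(fw_db, bw_db)
  solve_at <- function(au, z0 = NULL) {
    fx <- function(z) mixture_db(exp(z[1]), exp(z[2]), cfg, cal, au) - target
    if (is.null(z0)) {
      grid <- log(c(0.02, 0.08, 0.2, 0.5, 1, 2, 4, 8, 16))
      pairs <- expand.grid(ga = grid, gb = grid)
      vals <- mixture_db(exp(pairs$ga), exp(pairs$gb), cfg, cal, au)
      err <- (vals["fw", ] - target[1])^2 + (vals["bw", ] - target[2])^2
      z0 <- unname(unlist(pairs[which.min(err), ]))
    }
    z <- z0
    r <- fx(z)
    h <- 1e-5
    stall <- 0L
    for (it in 1:40) {
      if (max(abs(r)) < tol) break
      probe <- mixture_db(exp(c(z[1] + h, z[1])), exp(c(z[2], z[2] + h)),
                          cfg, cal, au)
      J <- cbind((probe[, 1] - target - r) / h, (probe[, 2] - target - r) / h)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) step <- -r * 0.1
      step <- pmax(pmin(step, 1.5), -1.5)
      lambda <- 1
      repeat {
        z2 <- z + lambda * step
        r2 <- fx(z2)
        if (sum(r2^2) < sum(r^2) || lambda < 1e-3) break
        lambda <- lambda / 2
      }
      # bail out early when the iteration stalls at an unreachable target
      stall <- if (sum(r2^2) > 0.98 * sum(r^2)) stall + 1L else 0L
      z <- z2; r <- r2
      if (stall >= 3L) break
    }
    list(z = z, err = max(abs(r)))
  }
  # warm start from a previous nearby solution when available
  if (!is.null(init)) {
    sol <- solve_at(init[["au"]], log(unname(init[c("af", "ab")])))
    if (sol$err <= max(tol, 1e-3))
      return(c(af = exp(sol$z[1]), ab = exp(sol$z[2]), au = init[["au"]]))
  }
  # the diluent level is a free scale: walk a ladder until the target pair
  # becomes reachable
  for (au in c(1, 1.5, 2.5, 4, 6, 0.6, 0.35, 0.2)) {
    sol <- solve_at(au)
    if (sol$err <= max(tol, 1e-3))
      return(c(af = exp(sol$z[1]), ab = exp(sol$z[2]), au = au))
  }
  stop(sprintf(paste0("calibration failed: targets fw=%.3f bw=%.3f dB ",
                      "unreachable (residual %.3g dB)"),
               fw_db, bw_db, sol$err))
}

# per-study memo of calibration solves (targets recur across minutes)
calib_cache <- function() {
  env <- new.env(parent = emptyenv())
  function(fw_db, bw_db, cfg, init = NULL) {
    key <- sprintf("%.5f|%.5f", fw_db, bw_db)
    if (is.null(env[[key]]))
      env[[key]] <- tryCatch(calibrate_amplitudes(fw_db, bw_db, cfg,
                                                  init = init),
                             error = function(e) e)
    if (inherits(env[[key]], "error")) stop(env[[key]])
    env[[key]]
  }
}

# the three-component mixture has a physical envelope (e.g. both directions
# cannot sit far below their surrogate null simultaneously); rare tail draws
# outside it are saturated along the segment toward a reachable anchor pair
calibrate_reachable <- function(fw_db, bw_db, anchor, cfg, cache,
                                init = NULL) {
  try1 <- tryCatch(cache(fw_db, bw_db, cfg, init), error = function(e) NULL)
  if (!is.null(try1))
    return(list(fw = fw_db, bw = bw_db, amps = try1))
  lo <- 0; hi <- 1; best <- NULL
  for (i in 1:6) {
    mid <- (lo + hi) / 2
    fw_m <- anchor[1] + mid * (fw_db - anchor[1])
    bw_m <- anchor[2] + mid * (bw_db - anchor[2])
    sol <- tryCatch(cache(fw_m, bw_m, cfg, init), error = function(e) NULL)
    if (is.null(sol)) hi <- mid
    else { lo <- mid; best <- list(fw = fw_m, bw = bw_m, amps = sol) }
  }
  if (is.null(best)) {
    amps <- cache(anchor[1], anchor[2], cfg)   # anchor must be reachable
    best <- list(fw = anchor[1], bw = anchor[2], amps = amps)
  }
  best
}

# ---- session and study generation -----------------------------------------

#' Generate one simulated session
#'
#' Produces a continuous multichannel recording spanning
#' `pre_minutes + post_minutes`. The 5 midline channels carry, per minute,
#' one carrier frequency (band drawn from the baseline/drug mixture) composed
#' of a forward plane wave, a backward plane wave and a fixed scattered-phase
#' diluent; wave amplitudes are calibrated per minute so the pipeline
#' recovers that minute's target decibel levels, and a slow antiphase
#' modulation couples forward and backward amplitudes negatively. Remaining
#' channels carry 1/f background noise. With `condition = "dmt"` the targets
#' follow the onset/plateau/decay effect profile; under placebo they stay at
#' baseline throughout.
#'
#' @param condition `"placebo"` or `"dmt"`.
#' @param targets list with per-subject decibel targets `fw_base`, `bw_base`,
#'   `fw_post`, `bw_post` (post-block means; see
#'   `target_block_minutes`).
#' @param cfg a [study_sim_config()].
#' @param seed integer seed for this session.
#' @param cache internal calibration memo (created if missing).
#' @return an [recording()] with `t0 = -pre_minutes * 60`.
#' @export
gen_session <- function(condition = c("placebo", "dmt"), targets,
                        cfg = study_sim_config(), seed = 1L, cache = NULL) {
  condition <- match.arg(condition)
  if (is.null(cache)) cache <- calib_cache()
  fs <- cfg$fs
  n_min <- cfg$pre_minutes + cfg$post_minutes
  n <- as.integer(round(n_min * 60 * fs))
  labels <- sim_channel_labels(cfg$n_channels)
  mid <- match(midline_5, labels)
  t0 <- -cfg$pre_minutes * 60
  # mean effect over the block the post targets refer to
  block_bins <- seq_len(cfg$target_block_minutes) - 1L
  gbar <- mean(vapply(block_bins, minute_effect, numeric(1), cfg = cfg))
  anchor0 <- c(cfg$fw_db_targets[["placebo_post"]],
               cfg$bw_db_targets[["placebo_post"]])
  base <- calibrate_reachable(targets$fw_base, targets$bw_base, anchor0,
                              cfg, cache)
  amps_prev <- base$amps
  dfw <- if (condition == "dmt") (targets$fw_post - base$fw) / gbar else 0
  dbw <- if (condition == "dmt") (targets$bw_post - base$bw) / gbar else 0
  theta <- 2 * pi * cfg$wave_cpe * (0:4)
  data <- matrix(0, cfg$n_channels, n)
  with_seed(seed, {
    psi <- stats::runif(1, 0, 2 * pi)   # modulation phase
    minute_bins <- seq.int(-cfg$pre_minutes, cfg$post_minutes - 1L)
    bands <- names(cfg$band_mix_baseline)
    for (b in minute_bins) {
      g <- if (condition == "dmt") minute_effect(b, cfg) else 0
      mix <- (1 - g) * cfg$band_mix_baseline + g * cfg$band_mix_drug
      band <- sample(bands, 1L, prob = mix)
      f <- cfg$carrier_hz[[band]]
      amps <- calibrate_reachable(base$fw + g * dfw, base$bw + g * dbw,
                                  c(base$fw, base$bw), cfg, cache,
                                  init = amps_prev)$amps
      amps_prev <- amps
      i0 <- as.integer(round((b * 60 - t0) * fs))
      tt <- (i0 + seq_len(60 * fs) - 1L) / fs + t0    # absolute seconds
      mod <- cfg$modulation_depth *
        sin(2 * pi * tt / cfg$modulation_period_s + psi)
      af_t <- amps[["af"]] * (1 + mod)
      ab_t <- amps[["ab"]] * (1 - mod)
      wt <- 2 * pi * f * tt
      for (e in seq_along(mid)) {
        data[mid[e], i0 + seq_len(60 * fs)] <-
          af_t * cos(wt - theta[e]) + ab_t * cos(wt + theta[e]) +
          amps[["au"]] * cfg$diluent_amplitude *
            cos(wt + cfg$diluent_phases[e])
      }
    }
    if (cfg$noise_amplitude > 0) {
      nz <- gen_noise(fs, n_min * 60, length(mid), cfg$noise_exponent,
                      cfg$noise_amplitude,
                      seed = derive_seed(seed, 7001L))
      data[mid, ] <- data[mid, ] + nz$data
    }
    bg <- setdiff(seq_len(cfg$n_channels), mid)
    if (length(bg) && cfg$background_amplitude > 0) {
      nz <- gen_noise(fs, n_min * 60, length(bg), cfg$noise_exponent,
                      cfg$background_amplitude,
                      seed = derive_seed(seed, 7002L))
      data[bg, ] <- nz$data
    }
  })
  recording(data, fs = fs, labels = labels, t0 = t0)
}

#' Generate a full simulated drug-versus-placebo study
#'
#' Draws per-subject decibel targets from normal distributions around the
#' configured group means, generates both sessions for every subject,
#' minute-wise intensity ratings (a clipped affine map of that minute's
#' simulated forward-wave effect plus noise, so the intensity-forward
#' correlation is positive by construction), and end-of-session
#' visual-analogue-scale items positively loaded on each subject's mean
#' post-injection forward effect.
#'
#' @param cfg a [study_sim_config()].
#' @param out_dir if non-`NULL`, sessions are written as container files in
#'   this directory and the dataset stores file paths instead of in-memory
#'   recordings (loaded on demand by [run_study()]).
#' @return an object of class `study_dataset`: list with `subjects`,
#'   `sessions` (per subject, `placebo`/`dmt` recordings or paths),
#'   `ratings` (subject, minute, intensity), `vas` (subject, item, score),
#'   `meta` (subject, dose_mg), `effects` (the drawn per-subject targets,
#'   ground truth for recovery checks), and `config`.
#' @export
gen_study <- function(cfg = study_sim_config(), out_dir = NULL) {
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  cache <- calib_cache()
  draws <- with_seed(cfg$seed, {
    list(fw_base = stats::rnorm(cfg$n_subjects,
                                cfg$fw_db_targets[["placebo_post"]],
                                cfg$between_subject_sd[["fw"]]),
         bw_base = stats::rnorm(cfg$n_subjects,
                                cfg$bw_db_targets[["placebo_post"]],
                                cfg$between_subject_sd[["bw"]]),
         fw_dmt = stats::rnorm(cfg$n_subjects,
                               cfg$fw_db_targets[["dmt_post"]],
                               cfg$between_subject_sd[["fw"]]),
         bw_dmt = stats::rnorm(cfg$n_subjects,
                               cfg$bw_db_targets[["dmt_post"]],
                               cfg$between_subject_sd[["bw"]]),
         loadings = stats::runif(cfg$n_vas_items, 0.5, 1.5),
         rating_noise = matrix(stats::rnorm(cfg$n_subjects * cfg$post_minutes,
                                            0, cfg$rating_noise_sd),
                               cfg$n_subjects),
         vas_noise = matrix(stats::rnorm(cfg$n_subjects * cfg$n_vas_items,
                                         0, cfg$vas_noise_sd),
                            cfg$n_subjects))
  })
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  sessions <- vector("list", cfg$n_subjects)
  names(sessions) <- subjects
  for (s in seq_len(cfg$n_subjects)) {
    targets <- list(fw_base = draws$fw_base[s], bw_base = draws$bw_base[s],
                    fw_post = draws$fw_dmt[s], bw_post = draws$bw_dmt[s])
    ses <- list(
      placebo = gen_session("placebo", targets, cfg,
                            seed = derive_seed(cfg$seed, 2L * s - 1L),
                            cache = cache),
      dmt = gen_session("dmt", targets, cfg,
                        seed = derive_seed(cfg$seed, 2L * s), cache = cache))
    if (!is.null(out_dir)) {
      for (cond in names(ses)) {
        path <- file.path(out_dir, sprintf("%s_%s.eegwav", subjects[s], cond))
        write_recording(ses[[cond]], path)
        ses[[cond]] <- path
      }
    }
    sessions[[s]] <- ses
  }
  # intensity rating for minute m reflects the forward effect over (m-1, m]
  gm <- vapply(seq_len(cfg$post_minutes) - 1L, minute_effect, numeric(1),
               cfg = cfg)
  ratings <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(s) {
    eff <- gm * (draws$fw_dmt[s] - draws$fw_base[s])
    raw <- cfg$rating_scale * eff / cfg$rating_effect_db + draws$rating_noise[s, ]
    data.frame(subject = subjects[s], minute = seq_len(cfg$post_minutes),
               intensity = pmin(pmax(raw, 0), cfg$rating_scale))
  }))
  vas <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(s) {
    eff <- draws$fw_dmt[s] - draws$fw_base[s]
    data.frame(subject = subjects[s],
               item = sprintf("item%02d", seq_len(cfg$n_vas_items)),
               score = draws$loadings * eff + draws$vas_noise[s, ])
  }))
  doses <- rep(rep(c(7, 14, 18, 20), c(3, 4, 1, 5)),
               length.out = cfg$n_subjects)
  structure(list(subjects = subjects, sessions = sessions, ratings = ratings,
                 vas = vas,
                 meta = data.frame(subject = subjects, dose_mg = doses),
                 effects = data.frame(subject = subjects,
                                      fw_base = draws$fw_base,
                                      bw_base = draws$bw_base,
                                      fw_post_dmt = draws$fw_dmt,
                                      bw_post_dmt = draws$bw_dmt),
                 config = cfg),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects x 2 sessions (placebo, dmt)\n",
              length(x$subjects)))
  cat(sprintf("  ratings: %d subject-minutes; VAS: %d subject-items\n",
              nrow(x$ratings), nrow(x$vas)))
  invisible(x)
}

# resolve a session entry that may be an in-memory recording or a file path
session_recording <- function(dataset, subject, condition) {
  entry <- dataset$sessions[[subject]][[condition]]
  if (is.null(entry))
    stop("subject ", subject, " is missing the ", condition, " session")
  if (is.character(entry)) read_recording(entry) else entry
}
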