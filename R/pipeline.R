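#' Analysis configuration
#'
#' Bundles every tunable of the study-level pipeline: electrode array, window
#' and surrogate specifications, frequency bands, filter corners, FDR level,
#' the minute range for the forward-backward coupling analysis, pre/post
#' comparison block length, and the master seed.
#'
#' @param array an [electrode_array()] (default: the midline five).
#' @param window a [window_spec()].
#' @param surrogates a [surrogate_spec()].
#' @param bands a [band_definition()].
#' @param band temporal band for quadrant maxima, Hz.
#' @param filter_low,filter_high band-pass corners in Hz; `NULL` skips
#'   filtering.
#' @param rereference apply the common average reference before analysis.
#' @param q FDR level for minute-wise tests.
#' @param coupling_minutes post-injection minute range for the
#'   forward-backward coupling and VAS correlations.
#' @param block_s length in seconds of the pre- and post-injection
#'   comparison blocks (default 300 s = 5 min).
#' @param spectra_every if > 0, average [per_frequency_waves()] over every
#'   k-th window (0 skips the per-frequency analysis).
#' @param seed master seed; per-session surrogate seeds derive from it.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(array = standard_arrays()$midline,
                            window = window_spec(),
                            surrogates = surrogate_spec(),
                            bands = band_definition(),
                            band = c(1, 45),
                            filter_low = 1, filter_high = 45,
                            rereference = TRUE,
                            q = 0.05, coupling_minutes = c(2, 5),
                            block_s = 300, spectra_every = 0L,
                            seed = 1L) {
  structure(list(array = array, window = window, surrogates = surrogates,
                 bands = bands, band = band, filter_low = filter_low,
                 filter_high = filter_high, rereference = rereference,
                 q = q, coupling_minutes = coupling_minutes,
                 block_s = block_s, spectra_every = as.integer(spectra_every),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# per-subject minute-bin means; bin b covers t_start in [60b, 60(b+1))
subject_minute_means <- function(estimates_by_subject) {
  do.call(rbind, lapply(names(estimates_by_subject), function(s) {
    e <- estimates_by_subject[[s]]
    bin <- floor(e$t_start / 60)
    agg <- stats::aggregate(cbind(fw_db, bw_db) ~ bin, data.frame(e, bin = bin),
                            mean)
    data.frame(subject = s, minute = as.integer(agg$bin),
               fw_db = agg$fw_db, bw_db = agg$bw_db)
  }))
}

#' Minute-by-minute group series with FDR flags
#'
#' Aggregates each subject's window estimates into minute-bin means (bin `b`
#' covers `t_start` in `[60b, 60(b+1))` seconds; windows belong to the bin
#' containing their start), then tests the group mean against zero per minute
#' and direction with one-sample t-tests, correcting within each direction's
#' series by Benjamini-Hochberg at level `q`.
#'
#' @param estimates_by_subject named list of `wave_estimates`, one per
#'   subject (>= 2 subjects).
#' @param q FDR level.
#' @return list with `table` (minute, n, per-direction mean/se/t/p/adjusted
#'   p/significance flag) and `subject_minutes` (per-subject minute means).
#' @export
minute_series <- function(estimates_by_subject, q = 0.05) {
  if (length(estimates_by_subject) < 2L) stop("need at least 2 subjects")
  sm <- subject_minute_means(estimates_by_subject)
  out <- do.call(rbind, lapply(sort(unique(sm$minute)), function(b) {
    v <- sm[sm$minute == b, ]
    row <- data.frame(minute = b, n = nrow(v))
    for (dir in c("fw", "bw")) {
      x <- v[[paste0(dir, "_db")]]
      tt <- one_sample_t(x)
      row[[paste0(dir, "_mean")]] <- mean(x)
      row[[paste0(dir, "_se")]] <- stats::sd(x) / sqrt(length(x))
      row[[paste0(dir, "_t")]] <- tt$statistic
      row[[paste0(dir, "_p")]] <- tt$p_value
    }
    row
  }))
  for (dir in c("fw", "bw")) {
    fdr <- bh_fdr(out[[paste0(dir, "_p")]], q)
    out[[paste0(dir, "_p_adj")]] <- fdr$p_adjusted
    out[[paste0(dir, "_sig")]] <- fdr$rejected
  }
  list(table = out, subject_minutes = sm)
}

#' Pre/post block summary
#'
#' Mean forward and backward net wave amounts per subject in the blocks
#' immediately preceding and following injection.
#'
#' @param estimates_by_subject named list of `wave_estimates`.
#' @param block_s block length in seconds (default 300).
#' @return data frame: subject, block (`pre`/`post`), fw_db, bw_db.
#' @export
block_summary <- function(estimates_by_subject, block_s = 300) {
  do.call(rbind, lapply(names(estimates_by_subject), function(s) {
    e <- estimates_by_subject[[s]]
    blocks <- list(pre = e$t_start >= -block_s & e$t_start < 0,
                   post = e$t_start >= 0 & e$t_start < block_s)
    do.call(rbind, lapply(names(blocks), function(b) {
      sel <- blocks[[b]]
      if (!any(sel)) return(NULL)
      data.frame(subject = s, block = b, fw_db = mean(e$fw_db[sel]),
                 bw_db = mean(e$bw_db[sel]))
    }))
  }))
}

#' Correlations between wave amounts and subjective ratings
#'
#' Three complementary views of the wave-experience relationship under the
#' drug: (a) across time points, the correlation between the group-mean
#' intensity rating and the group-mean wave amount per minute; (b) for each
#' minute, the across-subject correlation between intensity and wave amount
#' (uncorrected and BH-adjusted p-values are both reported); (c) for each
#' visual-analogue-scale item, the across-subject correlation between the
#' item score and the subject's mean wave amount over `coupling_minutes`,
#' with a one-sample t-test across items on the forward-wave correlations.
#' The intensity rating reported at minute `m` is aligned with wave minute
#' bin `m - 1` (the minute it describes).
#'
#' @param subject_minutes per-subject minute means (from [minute_series()])
#'   for the drug condition.
#' @param ratings data frame with columns subject, minute, intensity.
#' @param vas optional data frame with columns subject, item, score.
#' @param coupling_minutes minute range for the per-item analysis.
#' @param q FDR level for the per-minute correlations.
#' @return list with `time_course`, `per_minute`, `per_item`,
#'   `item_summary` (NULL when `vas` is NULL).
#' @export
rating_correlations <- function(subject_minutes, ratings, vas = NULL,
                                coupling_minutes = c(2, 5), q = 0.05) {
  sm <- subject_minutes
  sm$rating_minute <- sm$minute + 1L
  m <- merge(sm, ratings,
             by.x = c("subject", "rating_minute"),
             by.y = c("subject", "minute"))
  if (!nrow(m)) stop("no overlap between wave minutes and rating minutes")
  # (a) time-course correlation on group minute means (NA when degenerate,
  # e.g. fewer than 3 aligned minutes)
  gm <- stats::aggregate(cbind(fw_db, bw_db, intensity) ~ rating_minute, m,
                         mean)
  safe_r <- function(x, y)
    tryCatch(pearson_r(x, y), error = function(e)
      list(r = NA_real_, p_value = NA_real_))
  fw_tc <- safe_r(gm$intensity, gm$fw_db)
  bw_tc <- safe_r(gm$intensity, gm$bw_db)
  time_course <- data.frame(
    direction = c("FW", "BW"),
    r = c(fw_tc$r, bw_tc$r),
    p_value = c(fw_tc$p_value, bw_tc$p_value),
    n_minutes = nrow(gm))
  # (b) per-minute across-subject correlations
  per_minute <- do.call(rbind, lapply(sort(unique(m$rating_minute)),
                                      function(mm) {
    v <- m[m$rating_minute == mm, ]
    if (nrow(v) < 3L || stats::sd(v$intensity) == 0) return(NULL)
    fw <- pearson_r(v$intensity, v$fw_db)
    bw <- pearson_r(v$intensity, v$bw_db)
    data.frame(minute = mm, n = nrow(v), fw_r = fw$r, fw_p = fw$p_value,
               bw_r = bw$r, bw_p = bw$p_value)
  }))
  if (!is.null(per_minute) && nrow(per_minute)) {
    per_minute$fw_p_adj <- bh_fdr(per_minute$fw_p, q)$p_adjusted
    per_minute$bw_p_adj <- bh_fdr(per_minute$bw_p, q)$p_adjusted
  }
  per_item <- NULL; item_summary <- NULL
  if (!is.null(vas)) {
    sel <- sm$minute >= coupling_minutes[1] & sm$minute < coupling_minutes[2]
    subj <- stats::aggregate(cbind(fw_db, bw_db) ~ subject, sm[sel, ], mean)
    per_item <- do.call(rbind, lapply(unique(vas$item), function(it) {
      v <- merge(vas[vas$item == it, ], subj, by = "subject")
      fw <- safe_r(v$score, v$fw_db)
      bw <- safe_r(v$score, v$bw_db)
      data.frame(item = it, fw_r = fw$r, fw_p = fw$p_value,
                 bw_r = bw$r, bw_p = bw$p_value)
    }))
    safe_t <- function(x) tryCatch(one_sample_t(x), error = function(e) NULL)
    item_summary <- list(fw = safe_t(per_item$fw_r),
                         bw = safe_t(per_item$bw_r))
  }
  list(time_course = time_course, per_minute = per_minute,
       per_item = per_item, item_summary = item_summary)
}

#' Run the full travelling-wave study analysis
#'
#' For every subject and condition: optional band-pass and average reference,
#' midline-array selection, sliding-window wave quantification; then the
#' study-level products: pre/post block summary, minute-by-minute series
#' with FDR flags per condition, forward-backward coupling per subject,
#' rating and VAS correlations, peak-frequency band histograms, and
#' (optionally) per-frequency wave spectra. Deterministic given the master
#' seed in `config`.
#'
#' @param dataset a `study_dataset` (from [gen_study()] or assembled from
#'   real recordings).
#' @param config an [analysis_config()].
#' @return an object of class `wave_study` with elements `estimates`
#'   (per subject per condition), `blocks`, `series` (per condition),
#'   `coupling`, `ratings_cor`, `histograms`, `spectra`, `config`.
#' @export
run_study <- function(dataset, config = analysis_config()) {
  if (!inherits(dataset, "study_dataset")) stop("`dataset` must be a study_dataset")
  conditions <- c("placebo", "dmt")
  estimates <- list()
  for (s_i in seq_along(dataset$subjects)) {
    s <- dataset$subjects[[s_i]]
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      rec <- tryCatch(session_recording(dataset, s, cond),
                      error = function(e)
                        stop("stage load [", s, "/", cond, "]: ",
                             conditionMessage(e)))
      res <- tryCatch({
        if (!is.null(config$filter_low) && !is.null(config$filter_high))
          rec <- bandpass(rec, config$filter_low, config$filter_high)
        if (isTRUE(config$rereference) && nrow(rec$data) > 1L)
          rec <- rereference_average(rec)
        surr <- config$surrogates
        surr$seed <- derive_seed(config$seed, 2L * s_i + ci)
        quantify_recording(rec, array = config$array, window = config$window,
                           surrogates = surr, band = config$band)
      }, error = function(e)
        stop("stage quantify [", s, "/", cond, "]: ", conditionMessage(e)))
      estimates[[cond]][[s]] <- res
    }
  }
  blocks <- do.call(rbind, lapply(conditions, function(cond) {
    b <- block_summary(estimates[[cond]], config$block_s)
    data.frame(condition = cond, b)
  }))
  series <- lapply(estimates, minute_series, q = config$q)
  coupling <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(names(estimates[[cond]]), function(s) {
      e <- estimates[[cond]][[s]]
      post <- tryCatch(fw_bw_coupling(e, config$coupling_minutes),
                       error = function(err) list(r = NA_real_,
                                                  p_value = NA_real_, n = 0L))
      data.frame(condition = cond, subject = s, r = post$r,
                 p_value = post$p_value, n_windows = post$n)
    }))
  }))
  ratings_cor <- NULL
  if (!is.null(dataset$ratings))
    ratings_cor <- rating_correlations(series$dmt$subject_minutes,
                                       dataset$ratings, dataset$vas,
                                       config$coupling_minutes, config$q)
  histograms <- lapply(estimates, function(by_subj) {
    phases <- list(pre = function(t) t < 0, post = function(t) t >= 0)
    lapply(phases, function(ph) {
      pooled <- do.call(rbind, lapply(by_subj, function(e) e[ph(e$t_start), ]))
      list(fw = peak_band_histogram(pooled, "FW", config$bands),
           bw = peak_band_histogram(pooled, "BW", config$bands))
    })
  })
  spectra <- NULL
  if (config$spectra_every > 0L)
    spectra <- study_spectra(dataset, config)
  structure(list(estimates = estimates, blocks = blocks, series = series,
                 coupling = coupling, ratings_cor = ratings_cor,
                 histograms = histograms, spectra = spectra, config = config),
            class = "wave_study")
}

# per-frequency wave spectra averaged over a subsample of windows
study_spectra <- function(dataset, config) {
  lapply(c(placebo = "placebo", dmt = "dmt"), function(cond) {
    acc <- list(pre = NULL, post = NULL)
    n_acc <- c(pre = 0, post = 0)
    freqs <- NULL
    for (s in dataset$subjects) {
      rec <- session_recording(dataset, s, cond)
      if (!is.null(config$filter_low))
        rec <- bandpass(rec, config$filter_low, config$filter_high)
      rec <- select_array(rec, config$array)
      maps <- slide_windows(rec, config$window)
      for (i in seq(1, length(maps), by = config$spectra_every)) {
        ph <- if (maps[[i]]$t_start < 0) "pre" else "post"
        pf <- per_frequency_waves(maps[[i]], config$surrogates, config$band)
        freqs <- pf$freq_hz
        v <- cbind(fw_db = pf$fw_db, bw_db = pf$bw_db)
        acc[[ph]] <- if (is.null(acc[[ph]])) v else acc[[ph]] + v
        n_acc[[ph]] <- n_acc[[ph]] + 1
      }
    }
    lapply(stats::setNames(names(acc), names(acc)), function(ph) {
      if (is.null(acc[[ph]])) return(NULL)
      data.frame(freq_hz = freqs, acc[[ph]] / n_acc[[ph]])
    })
  })
}

#' @export
print.wave_study <- function(x, ...) {
  cat("<wave_study>\n")
  ag <- stats::aggregate(cbind(fw_db, bw_db) ~ condition + block, x$blocks,
                         mean)
  cat(sprintf("  block means (dB), %g s blocks:\n", x$config$block_s))
  for (i in seq_len(nrow(ag)))
    cat(sprintf("    %-8s %-5s FW %6.3f  BW %6.3f\n", ag$condition[i],
                ag$block[i], ag$fw_db[i], ag$bw_db[i]))
  invisible(x)
}

#' @export
summary.wave_study <- function(object, ...) {
  x <- object
  cat("Travelling-wave study summary\n")
  print(x)
  post <- x$blocks[x$blocks$block == "post", ]
  for (cond in unique(post$condition)) {
    v <- post[post$condition == cond, ]
    tf <- one_sample_t(v$fw_db); tb <- one_sample_t(v$bw_db)
    cat(sprintf("  post %s: FW t(%g)=%.2f p=%.4g; BW t(%g)=%.2f p=%.4g\n",
                cond, tf$df, tf$statistic, tf$p_value, tb$df, tb$statistic,
                tb$p_value))
  }
  cp <- x$coupling[x$coupling$condition == "dmt" & is.finite(x$coupling$r), ]
  if (nrow(cp))
    cat(sprintf("  FW-BW coupling (drug, minutes %g-%g): mean r = %.3f\n",
                x$config$coupling_minutes[1], x$config$coupling_minutes[2],
                mean(cp$r)))
  if (!is.null(x$ratings_cor)) {
    tc <- x$ratings_cor$time_course
    cat(sprintf("  intensity correlation across minutes: FW r = %.3f, BW r = %.3f\n",
                tc$r[tc$direction == "FW"], tc$r[tc$direction == "BW"]))
  }
  invisible(x)
}
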