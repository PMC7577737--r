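test_that("plane-wave generator realizes the requested component", {
  comp <- wave_component(10, 0.2, amplitude = 2, phase0 = 0.5)
  rec <- gen_plane_wave(100, 2, 5, comp)
  expect_identical(dim(rec$data), c(5L, 200L))
  t <- (0:199) / 100
  expect_equal(rec$data[3, ],
               2 * cos(2 * pi * 10 * t - 2 * pi * 0.2 * 2 + 0.5))
  # zero spatial frequency: all electrodes identical, no net wave
  flat <- gen_plane_wave(100, 1, 5, wave_component(10, 0))
  expect_true(all(flat$data == rep(flat$data[1, ], each = 5)))
  e <- quantify_window(wave_map(flat$data + 1e-8, 100), surrogate_spec(20, 1))
  expect_identical(e$fw_db, 0)
  # negating the spatial frequency mirrors the electrode axis
  fwd <- gen_plane_wave(100, 1, 5, wave_component(10, 0.2))
  bwd <- gen_plane_wave(100, 1, 5, wave_component(10, -0.2,
                                                  phase0 = -2 * pi * 0.2 * 4))
  expect_equal(bwd$data, fwd$data[5:1, ], tolerance = 1e-12)
  expect_error(gen_plane_wave(100, 1, 5, wave_component(60, 0.2)), "Nyquist")
  expect_error(wave_component(10, 0.7), "Nyquist")
})

test_that("1/f noise has the requested spectral slope and is reproducible", {
  for (case in list(c(0, 0, 0.1), c(1, -1, 0.15))) {
    rec <- gen_noise(250, 60, 2, exponent = case[1], amplitude = 1, seed = 31)
    slope <- mean(c(spectral_slope(rec$data[1, ], 250),
                    spectral_slope(rec$data[2, ], 250)))
    expect_lt(abs(slope - case[2]), case[3])
  }
  a <- gen_noise(250, 5, 3, 1, 2, seed = 8)
  b <- gen_noise(250, 5, 3, 1, 2, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, gen_noise(250, 5, 3, 1, 2, seed = 9)$data))
  # RMS scaling
  expect_equal(sqrt(rowMeans(a$data^2)), rep(2, 3), tolerance = 1e-9)
})

test_that("standing waves carry equal raw power in both quadrants", {
  rec <- gen_standing_wave(250, 1, 5, 10, amplitude = 2)
  e <- quantify_window(wave_map(rec$data, 250), surrogate_spec(100, 3))
  expect_equal(e$fw_raw, e$bw_raw, tolerance = 1e-12)
  # both directions beat their shuffled null
  nz <- gen_noise(250, 1, 5, 0, 0.3, seed = 32)
  en <- quantify_window(wave_map(rec$data + nz$data, 250),
                        surrogate_spec(100, 3))
  expect_gt(en$fw_db, 0.5)
  expect_gt(en$bw_db, 0.5)
  expect_lt(abs(en$fw_db - en$bw_db), 1.5)
  # zero amplitude on one direction degenerates to a plane wave
  one <- gen_standing_wave(250, 1, 5, 10, amplitude = 0)
  expect_true(all(one$data == 0))
})

test_that("calibration reproduces requested decibel targets", {
  cfg <- reduced_config(seed = 41)
  cal <- corticalwaves:::calib_context(cfg)
  for (target in list(c(-0.20, 0.51), c(0.19, 0.18), c(0.6, 0.05))) {
    amps <- calibrate_amplitudes(target[1], target[2], cfg)
    got <- corticalwaves:::mixture_db(amps[["af"]], amps[["ab"]], cfg, cal,
                                      amps[["au"]])
    expect_equal(unname(got), target, tolerance = 1e-3)
  }
  # pathologically deep double-negative targets are unreachable
  expect_error(calibrate_amplitudes(-3, -3, reduced_config(seed = 1)),
               "calibration failed")
})

test_that("noise-free sessions recover per-subject targets within 0.05 dB", {
  cfg <- reduced_config(seed = 42, noise_amplitude = 0)
  targets <- list(fw_base = -0.20, bw_base = 0.51,
                  fw_post = 0.19, bw_post = 0.18)
  rec <- gen_session("dmt", targets, cfg, seed = 7)
  est <- quantify_recording(rec, array = standard_arrays()$midline,
                            surrogates = surrogate_spec(100, 5))
  post <- est$t_start >= 0 & est$t_start < 120
  pre <- est$t_start < 0
  expect_lt(abs(mean(est$fw_db[post]) - 0.19), 0.05)
  expect_lt(abs(mean(est$bw_db[post]) - 0.18), 0.05)
  expect_lt(abs(mean(est$fw_db[pre]) + 0.20), 0.05)
  expect_lt(abs(mean(est$bw_db[pre]) - 0.51), 0.05)
})

test_that("placebo sessions show no pre/post change", {
  cfg <- reduced_config(seed = 43)
  targets <- list(fw_base = -0.20, bw_base = 0.51,
                  fw_post = 0.19, bw_post = 0.18)
  rec <- gen_session("placebo", targets, cfg, seed = 11)
  est <- quantify_recording(rec, array = standard_arrays()$midline,
                            surrogates = surrogate_spec(100, 6))
  post <- est$t_start >= 0 & est$t_start < 120
  pre <- est$t_start < 0
  for (col in c("fw_db", "bw_db")) {
    se <- sqrt(var(est[[col]][pre]) / sum(pre) +
                 var(est[[col]][post]) / sum(post))
    expect_lt(abs(mean(est[[col]][pre]) - mean(est[[col]][post])), 2 * se)
  }
  # drug sessions ramp the forward waves up after onset
  recd <- gen_session("dmt", targets, cfg, seed = 11)
  estd <- quantify_recording(recd, array = standard_arrays()$midline,
                             surrogates = surrogate_spec(100, 6))
  plateau <- estd$t_start >= 120 & estd$t_start < 300
  expect_gt(mean(estd$fw_db[plateau]), mean(estd$fw_db[estd$t_start < 0]))
})

test_that("session generation is a pure function of parameters and seed", {
  cfg <- reduced_config(seed = 44, post_minutes = 2, pre_minutes = 1)
  targets <- list(fw_base = -0.2, bw_base = 0.5, fw_post = 0.2,
                  bw_post = 0.2)
  a <- gen_session("dmt", targets, cfg, seed = 3)
  b <- gen_session("dmt", targets, cfg, seed = 3)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, gen_session("dmt", targets, cfg, 4)$data))
})

test_that("study generator assembles the full design", {
  cfg <- reduced_config(seed = 45, n_subjects = 3, post_minutes = 3,
                        pre_minutes = 1)
  study <- gen_study(cfg)
  expect_length(study$subjects, 3)
  expect_setequal(names(study$sessions[[1]]), c("placebo", "dmt"))
  expect_identical(nrow(study$ratings), 9L)          # 3 subjects x 3 minutes
  expect_identical(nrow(study$vas), 60L)             # 3 x 20 items
  expect_true(all(study$ratings$intensity >= 0 &
                    study$ratings$intensity <= cfg$rating_scale))
  expect_identical(study$meta$dose_mg, c(7, 7, 7))
  # vanishing between-subject spread collapses the drawn targets
  cfg0 <- reduced_config(seed = 46, n_subjects = 3, post_minutes = 3,
                         pre_minutes = 1,
                         between_subject_sd = c(fw = 1e-9, bw = 1e-9))
  st0 <- gen_study(cfg0)
  expect_lt(diff(range(st0$effects$fw_post_dmt)), 1e-6)
  # unbounded rating noise drowns the intensity-effect relation
  cfgn <- reduced_config(seed = 47, n_subjects = 3, post_minutes = 3,
                         pre_minutes = 1, rating_noise_sd = 1e6)
  stn <- gen_study(cfgn)
  expect_true(all(stn$ratings$intensity %in% c(0, cfgn$rating_scale)))
})

test_that("disk-backed studies round-trip through container files", {
  cfg <- reduced_config(seed = 48, n_subjects = 2, post_minutes = 2,
                        pre_minutes = 1)
  dir <- tempfile()
  study_mem <- gen_study(cfg)
  study_disk <- gen_study(cfg, out_dir = dir)
  expect_true(is.character(study_disk$sessions[[1]]$dmt))
  loaded <- corticalwaves:::session_recording(study_disk, "S01", "dmt")
  expect_identical(loaded$data, study_mem$sessions[[1]]$dmt$data)
})
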