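test_that("spatial averaging attenuates uncorrelated noise by 1/sqrt(n)", {
  set.seed(11)
  m <- beat_trace(20000, seq(300, 19500, by = 400), "maternal", 500, 20)
  chans <- t(vapply(1:4, function(i) m + rnorm(20000, 0, 4),
                    numeric(20000)))
  aux <- auxiliary_mecg(mcsignal(chans, 500))
  expect_equal(sd(aux - m), 2, tolerance = 0.1)   # sigma / sqrt(4)

  same <- mcsignal(rbind(m, m, m, m), 500)
  expect_equal(auxiliary_mecg(same), m)
  expect_warning(one <- auxiliary_mecg(mcsignal(m, 500)), "single")
  expect_equal(one, m)
})

test_that("maternal R detection is exact on clean signals", {
  rate <- 500
  locs <- round(seq(0.45, 59.5, by = 60 / 80) * rate)   # 80 bpm
  x <- beat_trace(60 * rate, locs, "maternal", rate, 25)
  ann <- detect_maternal_r(x, rate)
  m <- match_beats(locs, ann$locations, rate, tolerance_ms = 2)
  expect_equal(m$FN, 0)
  expect_equal(m$FP, 0)

  expect_length(detect_maternal_r(numeric(5000), rate)$locations, 0)
})

test_that("maternal detection stays above 99% Se/PPV at WM near 10 dB", {
  cfg <- sim_config(duration_s = 120, target_WM = 10.4, target_WF = 0,
                    seed = 21)
  rec <- generate_record(cfg)
  filt <- preprocess_signal(rec$bundle$abdominal_raw)
  ann <- detect_maternal_r(auxiliary_mecg(filt), 500)
  perf <- performance_indices(
    match_beats(rec$bundle$maternal_r, ann, 500, tolerance_ms = 40))
  expect_gte(perf[["Se"]], 99)
  expect_gte(perf[["PPV"]], 99)
})

test_that("template building averages, converges and tracks drift", {
  rate <- 500
  shape <- synth_beat_morphology("maternal", rate)
  locs <- seq(500, 29500, by = 400)
  clean <- fetalecg:::render_beats(30000, locs, shape)
  tm <- build_template(clean, locs, rate)
  i0 <- tm$fiducial
  ref <- clean[(locs[5] - (i0 - 1)):(locs[5] + length(tm$waveform) - i0)]
  expect_equal(tm$waveform, ref, tolerance = 1e-10)

  set.seed(3)
  noisy <- clean + rnorm(30000, 0, 0.3)
  tm_n <- build_template(noisy, locs, rate)
  err_many <- sd(tm_n$waveform - ref)
  err_one <- sd(noisy[(locs[5] - (i0 - 1)):
                        (locs[5] + length(tm$waveform) - i0)] - ref)
  expect_lt(err_many, err_one / 1.5)    # averaging shrinks template noise

  # amplitude ramp: final template follows the late beats, not the early ones
  ramp <- fetalecg:::render_beats(30000, locs, shape) * 0
  for (k in seq_along(locs)) {
    amp <- 1 + 0.5 * (k - 1) / (length(locs) - 1)
    one <- fetalecg:::render_beats(30000, locs[k], shape) * amp
    ramp <- ramp + one
  }
  tm_r <- build_template(ramp, locs, rate)
  expect_gt(max(tm_r$waveform), 1.3)    # tracked towards the 1.5x end

  expect_error(build_template(clean, integer(0), rate), "no complete")
})

test_that("template subtraction cancels itself and recovers scale", {
  rate <- 500
  shape <- synth_beat_morphology("maternal", rate)
  locs <- seq(500, 29500, by = 400)
  clean <- 20 * fetalecg:::render_beats(30000, locs, shape)
  tm <- build_template(clean, locs, rate)
  s <- subtract_template(clean, locs, tm)
  expect_lt(sqrt(mean(s$residual^2)), 0.01 * sqrt(mean(tm$waveform^2)))

  s2 <- subtract_template(1.2 * clean, locs, tm)
  expect_equal(mean(s2$coefficients$scale, na.rm = TRUE), 1.2,
               tolerance = 0.01)
  expect_lt(sqrt(mean(s2$residual^2)), 0.05 * sqrt(mean(clean^2)))
})

test_that("fetal content away from maternal beats is preserved", {
  rate <- 500
  n <- 60 * rate
  m_locs <- round(seq(0.45, 59.4, by = 0.75) * rate)
  f_locs <- round(seq(0.2, 59.4, by = 0.43) * rate)
  mat <- beat_trace(n, m_locs, "maternal", rate, 25)
  fet <- beat_trace(n, f_locs, "fetal", rate, 7)
  mix <- mat + fet
  tm <- build_template(mix, m_locs, rate)
  s <- subtract_template(mix, m_locs, tm)
  part <- coincidence_partition(m_locs, f_locs, rate)
  clear <- part$f_clear
  clear <- clear[clear > 50 & clear < n - 50]
  amp_in <- vapply(clear, function(r) max(abs(mix[(r - 5):(r + 5)] -
                                                mat[(r - 5):(r + 5)])),
                   numeric(1))
  amp_out <- vapply(clear, function(r) max(abs(s$residual[(r - 5):(r + 5)])),
                    numeric(1))
  expect_lt(max(abs(amp_out - amp_in) / amp_in), 0.05)

  # samples far from any maternal window pass through untouched
  tspan <- fetalecg:::template_qrs_derivative(tm)  # just for length check
  far <- setdiff(seq_len(n), unlist(lapply(m_locs, function(r)
    max(1, r - 300):min(n, r + 300))))
  expect_identical(s$residual[far], mix[far])
})

test_that("energy at maternal beats drops and derivative helps with jitter", {
  rate <- 500
  set.seed(9)
  locs <- seq(500, 29500, by = 400)
  shape <- synth_beat_morphology("maternal", rate)
  clean <- 20 * fetalecg:::render_beats(30000, locs, shape)
  tm <- build_template(clean, locs, rate)
  # +/- 1 sample fiducial jitter
  jlocs <- locs + sample(c(-1L, 0L, 1L), length(locs), replace = TRUE)
  with_d <- subtract_template(clean, jlocs, tm, derivative = TRUE)
  without <- subtract_template(clean, jlocs, tm, derivative = FALSE)
  expect_lt(sqrt(mean(with_d$residual^2)), sqrt(mean(without$residual^2)))

  # energy reduction in maternal windows
  win <- unlist(lapply(locs, function(r) (r - 25):(r + 25)))
  expect_lt(mean(with_d$residual[win]^2), mean(clean[win]^2))
})

test_that("suppress_mecg runs the full stage over channels", {
  cfg <- sim_config(duration_s = 60, target_WM = NA, target_WF = NA,
                    emg_uV = 0.5, seed = 13)
  rec <- generate_record(cfg)
  filt <- preprocess_signal(rec$bundle$abdominal_raw)
  sup <- suppress_mecg(filt)
  expect_s3_class(sup$fecg, "mcsignal")
  expect_equal(dim(sup$fecg$samples), dim(filt$samples))
  # maternal power reduced on every channel
  win <- unlist(lapply(sup$maternal_r$locations, function(r)
    max(1, r - 25):min(length(filt), r + 25)))
  for (ch in 1:4) {
    expect_lt(mean(fetalecg:::channel(sup$fecg, ch)[win]^2),
              mean(fetalecg:::channel(filt, ch)[win]^2))
  }
})
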