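test_that("instantaneous FHR converts RR and honours flags and gates", {
  rate <- 500
  # RR of 421.1 ms <-> 142.5 bpm
  expect_equal(bpm_to_rr_ms(142.5), 421.0526, tolerance = 1e-4)
  locs <- cumsum(c(1, rep(200, 10)))          # RR 400 ms at 500 Hz
  fs <- rr_to_fhr(locs, rate = rate)
  expect_equal(fs$fhr_bpm, rep(150, 10))
  expect_true(all(fs$valid))

  flags <- rep(1L, 11); flags[5] <- 0L
  fs2 <- rr_to_fhr(locs, rate = rate, flags = flags)
  expect_false(fs2$valid[4])   # interval ending at the unverified beat
  expect_false(fs2$valid[5])   # interval starting at it
  expect_true(all(fs2$valid[-(4:5)]))

  # physiologic gate masks a 30 bpm outlier interval
  locs3 <- cumsum(c(1, rep(200, 5), 1000, rep(200, 5)))
  fs3 <- rr_to_fhr(locs3, rate = rate)
  expect_false(fs3$valid[6])

  expect_length(rr_to_fhr(c(100), rate = rate)$rr_ms, 0)
})

test_that("round trip FHR -> RR is exact on valid intervals", {
  set.seed(51)
  locs <- cumsum(c(1, round(runif(50, 180, 260))))
  fs <- rr_to_fhr(locs, rate = 500)
  expect_equal(60000 / fs$fhr_bpm, fs$rr_ms)
})

test_that("4 Hz resampling holds the last valid value and measures loss", {
  locs <- cumsum(c(1, rep(214, 699)))          # ~140 bpm for ~5 min
  fs <- rr_to_fhr(locs, rate = 500)
  g <- resample_4hz(fs)
  expect_equal(g$times[2] - g$times[1], 250)
  expect_true(all(abs(g$fhr[g$valid] - 60000 / 428) < 1e-9))
  expect_lt(g$loss_pct, 2)                     # only the lead-in is invalid

  # a 30 s masked gap in a 5 min record is ~10% loss
  flags <- rep(1L, 700)
  bad <- which(fs$beat_times >= 120000 & fs$beat_times <= 150000)
  flags[bad] <- 0L
  fs2 <- rr_to_fhr(locs, rate = 500, flags = flags)
  g2 <- resample_4hz(fs2, duration_ms = 300000)
  expect_equal(g2$loss_pct, 10, tolerance = 1.5)

  expect_true(all(!resample_4hz(rr_to_fhr(c(100), rate = 500),
                                duration_ms = 10000)$valid))
})

test_that("baseline and fluctuation on constructed grids", {
  const <- list(times = seq(0, 600000, by = 250),
                fhr = rep(140, 2401), valid = rep(TRUE, 2401),
                loss_pct = 0, grid_hz = 4)
  bf <- baseline_and_fluctuation(const)
  expect_equal(bf$basal, 140, tolerance = 0.5)
  expect_equal(bf$fluctuation, 0, tolerance = 1e-9)

  tt <- seq(0, 600, by = 0.25)
  sine <- const
  sine$fhr <- 140 + 5 * sin(2 * pi * tt / 20)
  bf2 <- baseline_and_fluctuation(sine)
  expect_equal(bf2$basal, 140, tolerance = 1)
  expect_equal(bf2$fluctuation, 10, tolerance = 1.5)
})

test_that("acceleration and deceleration episodes follow the 15/15 rule", {
  grid_hz <- 4
  tt <- seq(0, 600, by = 1 / grid_hz)
  mk <- function(f) list(times = tt * 1000, fhr = f,
                         valid = rep(TRUE, length(tt)), loss_pct = 0,
                         grid_hz = grid_hz)
  flat <- mk(rep(140, length(tt)))
  eps <- detect_acc_dec(flat, 140)
  expect_equal(nrow(eps$accelerations), 0)
  expect_equal(nrow(eps$decelerations), 0)

  bump <- rep(140, length(tt))
  bump[tt >= 200 & tt <= 230] <- 160           # +20 bpm for 30 s
  eps2 <- detect_acc_dec(mk(bump), 140)
  expect_equal(nrow(eps2$accelerations), 1)
  expect_equal(eps2$accelerations$extremum_bpm, 160)
  expect_equal(nrow(eps2$decelerations), 0)

  # a dip already in progress at t = 0 is not counted
  dip <- rep(140, length(tt))
  dip[tt <= 30] <- 115
  eps3 <- detect_acc_dec(mk(dip), 140)
  expect_equal(nrow(eps3$decelerations), 0)
})

test_that("variability indices match direct evaluation of definitions", {
  # constant RR: all variability measures vanish
  locs <- cumsum(c(1, rep(210, 599)))
  fs <- rr_to_fhr(locs, rate = 500)
  vi <- variability_indices(fs)
  expect_equal(vi$stv_dawes, 0)
  expect_equal(vi$ltv_dawes, 0)
  expect_equal(vi$oscillation, 0)

  # random series: STV/LTI/STI recomputed independently in this test
  set.seed(61)
  rr_samp <- round(runif(700, 190, 230))
  locs2 <- cumsum(c(1, rr_samp))
  fs2 <- rr_to_fhr(locs2, rate = 500)
  vi2 <- variability_indices(fs2)
  rr_ms <- diff(fetalecg::index_to_ms(locs2, 500))
  t_close <- fetalecg::index_to_ms(locs2, 500)[-1]
  epoch <- floor(t_close / 3750)
  ep_rr <- tapply(rr_ms, epoch, mean)
  ids <- as.numeric(names(ep_rr))
  adj <- which(diff(ids) == 1)
  expect_equal(vi2$stv_dawes,
               mean(abs(ep_rr[adj + 1] - ep_rr[adj])),
               ignore_attr = TRUE)
  mod <- sqrt(rr_ms[-length(rr_ms)]^2 + rr_ms[-1]^2)
  expect_equal(vi2$lti, IQR(mod))
  expect_equal(vi2$sti, IQR(atan(rr_ms[-1] / rr_ms[-length(rr_ms)])))

  # STV grows monotonically with programmed beat-to-beat jitter
  stvs <- vapply(c(1, 4, 8), function(sig) {
    set.seed(71)
    tms <- generate_beat_times(140, 300, jitter_ms = sig)
    variability_indices(
      rr_to_fhr(round(tms / 2) + 1, rate = 500))$stv_dawes
  }, numeric(1))
  expect_true(all(diff(stvs) > 0))
})

test_that("fhr_report recovers programmed patterns from a simulation", {
  events <- data.frame(onset_s = c(120, 300, 480, 700, 860, 1020),
                       duration_s = 60,
                       amplitude_bpm = c(20, 22, 20, 20, 22, 20))
  events <- rbind(events,
                  data.frame(onset_s = c(200, 600), duration_s = 60,
                             amplitude_bpm = c(-20, -22)))
  prof <- fhr_profile(132, events, osc_amp_bpm = 2, osc_freq_hz = 0.1)
  set.seed(81)
  tms <- generate_beat_times(prof, 1200, jitter_ms = 2)
  locs <- round(tms / 1000 * 500) + 1
  rep <- fhr_report(locs, rate = 500, duration_ms = 1200000)
  expect_equal(rep$acc_count, 6)
  expect_equal(rep$dec_count, 2)
  expect_equal(rep$basal, 132, tolerance = 2)
  expect_lt(rep$loss_pct, 2)

  # empty input: all-missing report
  empty <- fhr_report(numeric(0), rate = 500, duration_ms = 10000)
  expect_true(is.na(empty$basal))
  expect_equal(empty$loss_pct, 100)
})

test_that("masking never increases episode counts", {
  events <- data.frame(onset_s = c(120, 300), duration_s = 60,
                       amplitude_bpm = c(20, 20))
  prof <- fhr_profile(140, events)
  set.seed(91)
  tms <- generate_beat_times(prof, 600, jitter_ms = 2)
  locs <- round(tms / 1000 * 500) + 1
  full <- fhr_report(locs, rate = 500, duration_ms = 600000)
  flags <- rep(1L, length(locs))
  flags[seq(20, length(locs), by = 9)] <- 0L
  masked <- fhr_report(beat_ann(locs, flags = flags, rate = 500),
                       duration_ms = 600000)
  expect_lte(masked$acc_count, full$acc_count)
  expect_lte(masked$dec_count, full$dec_count)
  expect_gt(masked$loss_pct, full$loss_pct)
})
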