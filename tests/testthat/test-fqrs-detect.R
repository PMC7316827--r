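test_that("normalized matched filter peaks at 1 and ignores gain", {
  rate <- 500
  tmpl <- fetalecg:::fetal_qrs_prototype(rate)
  x <- numeric(4000)
  r <- 2000
  half <- (length(tmpl) - 1) / 2
  x[(r - half):(r + half)] <- tmpl
  bank <- detection_function_bank(x, tmpl, rate)
  expect_equal(bank[[1]][r], 1, tolerance = 1e-6)

  bank_half <- detection_function_bank(0.5 * x, tmpl, rate)
  expect_equal(bank_half[[1]][r], bank[[1]][r], tolerance = 1e-6)
  expect_equal(bank_half[[2]][r], 0.5 * bank[[2]][r], tolerance = 1e-6)

  set.seed(5)
  y <- x + rnorm(4000, 0, 0.05)
  b1 <- detection_function_bank(y, tmpl, rate)
  b2 <- detection_function_bank(7.3 * y, tmpl, rate)
  expect_equal(b1[[1]], b2[[1]], tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(detection_function_bank(x, numeric(21), rate), "zero")
})

test_that("adaptive peak picking finds regular peaks and adapts to steps", {
  rate <- 500
  set.seed(8)
  locs <- seq(250, 19750, by = 215)
  df <- abs(rnorm(20000, 0, 0.03))
  df[locs] <- 1
  found <- adaptive_peaks(df, rate)
  m <- match_beats(locs, found, rate, tolerance_ms = 10)
  expect_equal(m$FN, 0)
  expect_equal(m$FP, 0)

  # amplitude halves mid-record: threshold adapts, no sustained miss run
  df2 <- abs(rnorm(20000, 0, 0.03))
  amp <- ifelse(locs < 10000, 1, 0.5)
  df2[locs] <- amp
  found2 <- adaptive_peaks(df2, rate)
  m2 <- match_beats(locs, found2, rate, tolerance_ms = 10)
  expect_lte(m2$FN, 3)

  expect_length(adaptive_peaks(numeric(5000), rate), 0)
})

test_that("RR intervals are first differences", {
  expect_equal(rr_intervals(c(0, 200, 410) + 1), c(200, 210))
  expect_length(rr_intervals(c(100)), 0)
  expect_equal(rr_intervals(seq(1, 3001, by = 300)), rep(300, 10))
})

test_that("variability functional matches its definition", {
  expect_equal(variability_functional(rep(400, 10)), 0)
  # peaks giving RR 400,410,400,410,400 (6 peaks)
  expect_equal(variability_functional(c(400, 410, 400, 410, 400)), 20)
  expect_true(is.na(variability_functional(c(400, 410))))

  set.seed(33)
  for (trial in 1:25) {
    rr <- round(runif(sample(4:40, 1), 300, 500))
    expect_equal(variability_functional(rr), brute_force_delta(rr))
  }

  # a spurious extra peak strictly increases the functional
  peaks <- cumsum(c(100, rep(c(400, 410), 8)))
  with_extra <- sort(c(peaks, peaks[8] + 150))
  expect_gt(variability_functional(rr_intervals(with_extra)),
            variability_functional(rr_intervals(peaks)))
})

test_that("optimal function selection minimizes with smallest-k ties", {
  expect_equal(select_optimal(c(5.0, 2.1, 7.3)), 2L)
  expect_equal(select_optimal(c(2.1, 2.1)), 1L)
  expect_equal(select_optimal(c(NA, 3, 2)), 3L)
  expect_error(select_optimal(c(NA_real_, NA_real_)), "longer signal")
})

test_that("periodicity quality separates periodic, noise and out-of-band", {
  rate <- 500
  n <- 20000
  locs <- seq(100, n - 100, by = round(60 / 140 * rate))   # 140 bpm
  clean <- beat_trace(n, locs, "fetal", rate)
  expect_gt(periodicity_quality(clean, rate), 0.7)

  set.seed(12)
  expect_lt(periodicity_quality(rnorm(n), rate), 0.3)

  slow <- beat_trace(n, seq(100, n - 100, by = rate), "fetal", rate) # 60 bpm
  expect_lt(periodicity_quality(slow, rate),
            periodicity_quality(clean, rate) / 2)
})

test_that("channel selection prefers the clean channel", {
  rate <- 500
  n <- 20000
  locs <- seq(100, n - 100, by = round(60 / 140 * rate))
  clean <- beat_trace(n, locs, "fetal", rate, 7)
  set.seed(4)
  chans <- rbind(rnorm(n, 0, 3), clean + rnorm(n, 0, 0.3),
                 rnorm(n, 0, 3), rnorm(n, 0, 3))
  sel <- select_best_channel(mcsignal(chans, rate))
  expect_equal(sel$channel, 2L)

  same <- mcsignal(rbind(clean, clean, clean, clean), rate)
  expect_equal(select_best_channel(same)$channel, 1L)

  noise_only <- mcsignal(matrix(rnorm(4 * n, 0, 2), nrow = 4), rate)
  expect_true(select_best_channel(noise_only)$channel %in% 1:4)
})

test_that("direct FECG detection is exact on clean signals", {
  cfg <- sim_config(duration_s = 120, target_WM = NA, target_WF = NA,
                    emg_uV = 0, mains_uV = 0, wander_uV = 0, seed = 6)
  rec <- generate_record(cfg)
  ann <- detect_direct_fqrs(rec$bundle$direct_fecg)
  perf <- performance_indices(
    match_beats(rec$truth$fd_locs, ann, 1000, tolerance_ms = 40))
  expect_equal(perf[["Se"]], 100)
  expect_equal(perf[["PPV"]], 100)

  expect_length(detect_direct_fqrs(numeric(10000))$locations, 0)
})

test_that("the RR-prediction cost rule rejects competing artifact peaks", {
  rate <- 1000
  set.seed(17)
  n <- 120 * rate
  locs <- round(seq(0.4, 119.5, by = 0.43) * rate)
  x <- beat_trace(n, locs, "fetal", rate, 30) + rnorm(n, 0, 0.5)
  # artifact spikes near 10% of beats, offset 150 ms, same amplitude
  hit <- sample(seq_along(locs), round(0.1 * length(locs)))
  art <- locs[hit] + 150
  x <- x + beat_trace(n, art[art < n - 100], "fetal", rate, 30)
  ann <- detect_direct_fqrs(x, rate)
  m <- match_beats(locs, ann$locations, rate, tolerance_ms = 40)
  expect_gte(performance_indices(m)[["Se"]], 95)
  expect_gte(performance_indices(m)[["PPV"]], 95)
})

test_that("full fetal detection selects a function and flags reliability", {
  cfg <- sim_config(duration_s = 120, seed = 14)
  rec <- generate_record(cfg)
  res <- process_record(rec$bundle)
  expect_true(res$detection$k_opt %in% 1:3)
  expect_true(all(res$fetal_r$flags %in% 0:1))
  expect_gte(res$performance[["Se"]], 95)
  expect_gte(res$performance[["PPV"]], 95)
})
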