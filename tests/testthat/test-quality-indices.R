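test_that("coincidence uses interval overlap of 100/40 ms windows", {
  # maternal at 1000, fetal at 1030 (500 Hz): [975,1025] and [1020,1040]
  p <- coincidence_partition(1000, 1030, 500)
  expect_equal(p$J, 0)
  expect_equal(p$I, 0)
  # fetal at 1100: windows disjoint
  p2 <- coincidence_partition(1000, 1100, 500)
  expect_equal(p2$J, 1)
  expect_equal(p2$I, 1)
  # no fetal beats: every maternal beat is non-coincident
  p3 <- coincidence_partition(c(100, 600, 1100), numeric(0), 500)
  expect_equal(p3$J, 3)
  expect_equal(p3$I, 0)
})

test_that("coincidence partition agrees with the all-pairs oracle", {
  set.seed(19)
  for (trial in 1:30) {
    m <- sort(sample.int(50000, sample(5:40, 1)))
    f <- sort(sample.int(50000, sample(5:60, 1)))
    got <- coincidence_partition(m, f, 500)
    want <- brute_force_coincidence(m, f, 500)
    expect_equal(got$J, want$J)
    expect_equal(got$I, want$I)
    expect_equal(got$m_clear, want$m_clear)
    expect_equal(got$f_clear, want$f_clear)
  }
})

test_that("power decomposition recovers programmed component powers", {
  # QRS-only morphologies so that no P/T energy leaks outside the QRS
  # windows: this isolates the estimator itself (the small P/T bias on
  # full PQRST beats is exercised by the calibration round-trip tests)
  rate <- 500
  n <- 300 * rate
  set.seed(23)
  m_locs <- round(seq(0.45, 299.3, by = 0.75) * rate)
  f_locs <- round(seq(0.2, 299.3, by = 0.43) * rate)
  noise <- rnorm(n, 0, 1)
  mat <- beat_trace(n, m_locs, "fetal", rate, 22)   # narrow, inside 100 ms
  fet <- beat_trace(n, f_locs, "fetal", rate, 7)
  x <- mat + fet + noise
  p <- estimate_powers(x, m_locs, f_locs, rate)
  expect_equal(p$P_N, 1, tolerance = 0.1)
  part <- coincidence_partition(m_locs, f_locs, rate)
  mw <- fetalecg:::window_mask(n, part$m_clear, 25)
  fw <- fetalecg:::window_mask(n, part$f_clear, 10)
  expect_equal(p$P_M, mean(mat[mw]^2), tolerance = 0.12)
  expect_equal(p$P_F, mean(fet[fw]^2), tolerance = 0.25)

  # doubling the fetal amplitude quadruples its power
  x2 <- mat + 2 * fet + noise
  p2 <- estimate_powers(x2, m_locs, f_locs, rate)
  expect_equal(p2$P_F / p$P_F, 4, tolerance = 0.2)
})

test_that("pure noise without annotations leaves only P_N", {
  set.seed(2)
  x <- rnorm(5000, 0, 2)
  p <- estimate_powers(x, numeric(0), numeric(0), 500)
  expect_equal(p$P_N, mean(x^2))
  expect_true(is.na(p$P_M))
  expect_true(is.na(p$P_F))
})

test_that("SNR indices follow the dB definitions", {
  w <- snr_indices(list(P_N = 1, P_M = 10, P_F = 1))
  expect_equal(w[["WM"]], 10)
  expect_equal(w[["WF"]], 0)
  expect_equal(w[["WMF"]], w[["WM"]] - w[["WF"]])
  # B1 record-mean magnitudes: WMF ~ 10.9 dB is ~3.5x in amplitude
  expect_equal(10^((14.3 - 3.4) / 20), 3.5, tolerance = 0.01)
  expect_equal(snr_indices(list(P_N = 1, P_M = 0, P_F = 2))[["WM"]], -Inf)
})

test_that("amplitude change coefficients are projections on the mean beat", {
  rate <- 500
  locs <- seq(200, 9800, by = 300)
  x <- beat_trace(10000, locs, "fetal", rate, 5)
  r <- amplitude_change_coefficients(x, locs, rate, 40)
  expect_equal(r, rep(1, length(locs)), tolerance = 1e-10)

  # one beat at twice the mean shape
  x2 <- x + beat_trace(10000, locs[5], "fetal", rate, 5)
  r2 <- amplitude_change_coefficients(x2, locs, rate, 40)
  avg_gain <- mean(r2)
  expect_equal(r2[5] / avg_gain, 2 / avg_gain * 1, tolerance = 0.05)
  expect_gt(r2[5], 1.8)

  # agrees with the explicit projection formula on arbitrary signals
  set.seed(77)
  z <- rnorm(10000)
  rz <- amplitude_change_coefficients(z, locs, rate, 40)
  half <- ms_to_samples(20, rate)
  wins <- vapply(locs, function(l) z[(l - half):(l + half)],
                 numeric(2 * half + 1))
  avg <- rowMeans(wins)
  manual <- apply(wins, 2, function(wv) sum(avg * wv) / sum(avg^2))
  expect_equal(rz, as.numeric(manual), tolerance = 1e-12)
  # a window orthogonal to the mean beat projects to zero
  expect_equal(sum(avg * (wins[, 1] - manual[1] * avg)) / sum(avg^2), 0,
               tolerance = 1e-12)
  expect_error(amplitude_change_coefficients(numeric(10000), locs, rate, 40),
               "zero-energy")
})

test_that("energy variation index matches the adopted formula", {
  expect_equal(energy_variation_index(rep(1.3, 10)), 0)
  expect_equal(energy_variation_index(c(1, 1.2, 1, 1.2)), 0.2 / 1.1,
               tolerance = 1e-12)
  set.seed(31)
  r <- runif(50, 0.5, 1.5)
  expect_equal(energy_variation_index(3.7 * r), energy_variation_index(r),
               tolerance = 1e-12)
  expect_error(energy_variation_index(c(1)), "two")
  expect_warning(bad <- energy_variation_index(c(2, 1, 1.5), "raw"),
                 "NaN")
  expect_true(is.nan(bad))
})

test_that("record report aggregates channels and tracks fetal amplitude", {
  rate <- 500
  n <- 120 * rate
  set.seed(41)
  m_locs <- round(seq(0.45, 119.3, by = 0.75) * rate)
  f_locs <- round(seq(0.2, 119.3, by = 0.43) * rate)
  base <- beat_trace(n, m_locs, "maternal", rate, 22) +
    beat_trace(n, f_locs, "fetal", rate, 7) + rnorm(n, 0, 1.5)
  x <- mcsignal(rbind(base, base, base, base), rate)
  rep1 <- record_quality_report(x, m_locs = m_locs, f_locs = f_locs)
  expect_equal(rep1$channels$WM, rep(rep1$mean[["WM"]], 4))
  expect_equal(rep1$mean[["WMF"]], rep1$mean[["WM"]] - rep1$mean[["WF"]])

  # higher fetal amplitude: WF strictly up, WMF strictly down
  base2 <- base + beat_trace(n, f_locs, "fetal", rate, 7)
  x2 <- mcsignal(rbind(base2, base2, base2, base2), rate)
  rep2 <- record_quality_report(x2, m_locs = m_locs, f_locs = f_locs)
  expect_gt(rep2$mean[["WF"]], rep1$mean[["WF"]])
  expect_lt(rep2$mean[["WMF"]], rep1$mean[["WMF"]])
})

test_that("simulator round trip recovers requested operating points", {
  for (op in list(c(10, 0), c(14, 3), c(17, 8))) {
    cfg <- sim_config(duration_s = 300, target_WM = op[1], target_WF = op[2],
                      seed = 100 + op[1])
    rec <- generate_record(cfg)
    q <- record_quality_report(rec$bundle)
    expect_equal(q$mean[["WM"]], op[1], tolerance = 1)
    expect_equal(q$mean[["WF"]], op[2], tolerance = 1)
  }
})

test_that("dataset summary aggregation reproduces published means", {
  b1 <- dataset_summary_table("b1_quality")
  m <- aggregate_record_summaries(b1, c("WM", "WF", "WEM", "WEF"))
  expect_equal(round(m[["WM"]], 1), 14.3)
  expect_equal(round(m[["WEF"]], 2), 0.52)
  b2 <- dataset_summary_table("b2_quality")
  expect_equal(round(aggregate_record_summaries(b2)[["WM"]], 1), 10.4)
})
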