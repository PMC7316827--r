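#' Synthetic heartbeat morphology
#'
#' Sum-of-Gaussians PQRST waveform in the dynamical-model tradition. The
#' maternal beat has identifiable P and T deflections and a QRS of about
#' 100 ms; the fetal beat is a narrow QRS of about 40 ms with negligible
#' energy outside it. The R apex is normalized to 1 before mixing.
#'
#' @param kind `"maternal"` or `"fetal"`.
#' @param rate sampling frequency in Hz.
#' @return list with `waveform` (numeric) and `fiducial` (index of the R
#'   apex within the waveform).
#' @export
synth_beat_morphology <- function(kind = c("maternal", "fetal"), rate = 500) {
  kind <- match.arg(kind)
  if (kind == "maternal") {
    pre <- 250; post <- 400
    # P and T at the attenuated level seen in abdominal leads after the
    # recorder's analog high-pass; large P/T would dominate the
    # out-of-QRS interference power, which real records do not show
    waves <- rbind(                      # mu(ms), amp, sd(ms)
      c(-180, 0.08, 18),                 # P
      c(-28, -0.12, 7),                  # Q
      c(0, 1.00, 10),                    # R
      c(30, -0.22, 8),                   # S
      c(200, 0.12, 32))                  # T
  } else {
    pre <- 30; post <- 30
    waves <- rbind(
      c(-9, -0.10, 3),                   # Q
      c(0, 1.00, 4),                     # R
      c(9, -0.15, 3.5))                  # S
  }
  half_pre <- ms_to_samples(pre, rate)
  half_post <- ms_to_samples(post, rate)
  t <- ((-half_pre):half_post) / rate * 1000
  v <- numeric(length(t))
  for (i in seq_len(nrow(waves)))
    v <- v + gauss_wave(t, waves[i, 1], waves[i, 2], waves[i, 3])
  v <- v / max(v)
  list(waveform = v, fiducial = half_pre + 1L)
}

#' Programmable FHR profile
#'
#' Instantaneous heart-rate profile used by the beat-time generator:
#' baseline, a list of transient episodes (raised-cosine accelerations and
#' decelerations), and a sinusoidal oscillation component.
#'
#' @param baseline_bpm baseline rate in bpm.
#' @param events data.frame with columns `onset_s`, `duration_s`,
#'   `amplitude_bpm` (positive = acceleration, negative = deceleration);
#'   `NULL` for none.
#' @param osc_amp_bpm,osc_freq_hz oscillation amplitude (half peak-to-peak)
#'   and frequency.
#' @return function of time (seconds) returning bpm.
#' @export
fhr_profile <- function(baseline_bpm = 140, events = NULL,
                        osc_amp_bpm = 0, osc_freq_hz = 0.05) {
  force(baseline_bpm); force(events); force(osc_amp_bpm); force(osc_freq_hz)
  function(t) {
    v <- rep(baseline_bpm, length(t))
    if (!is.null(events) && nrow(events)) {
      for (i in seq_len(nrow(events))) {
        on <- events$onset_s[i]; du <- events$duration_s[i]
        a <- events$amplitude_bpm[i]
        inside <- t >= on & t <= on + du
        v[inside] <- v[inside] +
          a * 0.5 * (1 - cos(2 * pi * (t[inside] - on) / du))
      }
    }
    if (osc_amp_bpm > 0)
      v <- v + osc_amp_bpm * sin(2 * pi * osc_freq_hz * t)
    v
  }
}

#' Generate beat times from a heart-rate profile
#'
#' Integrates the instantaneous rate so that a beat occurs each time the
#' accumulated phase crosses an integer, then adds Gaussian beat-to-beat
#' jitter. A constant profile of `b` bpm yields RR intervals of exactly
#' `60000/b` ms (before jitter).
#'
#' @param profile function of time in seconds returning bpm (see
#'   [fhr_profile()]), or a single bpm value.
#' @param duration_s record duration in seconds.
#' @param jitter_ms standard deviation of the beat-time jitter.
#' @param phase_s time of the first beat.
#' @return beat times in ms, strictly increasing.
#' @export
generate_beat_times <- function(profile, duration_s, jitter_ms = 0,
                                phase_s = 0.3) {
  if (is.numeric(profile)) {
    b <- profile
    profile <- function(t) rep(b, length(t))
  }
  dt <- 0.005
  tg <- seq(0, duration_s, by = dt)
  bpm <- profile(tg)
  if (any(bpm <= 30) || any(bpm >= 300))
    stop("heart-rate profile must stay within (30, 300) bpm")
  phase <- cumsum(bpm / 60) * dt
  nb <- floor(max(phase))
  if (nb < 1) return(numeric(0))
  times_s <- stats::approx(phase, tg, xout = seq_len(nb), ties = "ordered")$y
  times_s <- times_s + phase_s
  if (jitter_ms > 0)
    times_s <- times_s + stats::rnorm(nb, 0, jitter_ms / 1000)
  times_s <- sort(times_s[times_s > 0 & times_s < duration_s])
  times_s * 1000
}

#' Simulation configuration
#'
#' Collects every generative parameter of a synthetic record. Defaults
#' emulate an antenatal (B1-type) recording: 4 abdominal channels at
#' 500 Hz, maternal rate 80 bpm, fetal baseline 140 bpm with mild
#' oscillation and beat-to-beat jitter, amplitude operating point WM =
#' 14.3 dB / WF = 3.4 dB over broadband EMG, 50 Hz powerline pickup and
#' baseline wander. With the default noise floor the calibrated fetal R
#' amplitude stays under 20 microvolts, as observed antenatally.
#'
#' @param rate_abd,rate_direct abdominal / direct sampling rates (Hz).
#' @param duration_s record duration in seconds.
#' @param maternal_bpm maternal heart rate (constant profile).
#' @param maternal_jitter_ms maternal beat-to-beat jitter SD.
#' @param fetal fetal [fhr_profile()] arguments as a list:
#'   `baseline_bpm`, `events`, `osc_amp_bpm`, `osc_freq_hz`.
#' @param fetal_jitter_ms fetal beat-to-beat jitter SD.
#' @param target_WM,target_WF amplitude operating point in dB; `NA`
#'   disables calibration and uses `amp_m`/`amp_f` directly.
#' @param amp_m,amp_f fixed maternal/fetal R amplitudes in microvolts
#'   (used when targets are `NA`, e.g. noiseless records).
#' @param emg_uV EMG (20-150 Hz band-limited Gaussian) RMS per channel.
#' @param mains_uV 50 Hz powerline amplitude.
#' @param wander_uV baseline-wander amplitude (0.2-0.8 Hz sinusoids).
#' @param gain_m,gain_f per-channel gains of the maternal and fetal
#'   contributions (the 4 x 2 mixing matrix columns).
#' @param direct_amp_uV,direct_noise_uV direct-channel fetal amplitude and
#'   additive white noise RMS.
#' @param seed integer seed fixing every random draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(rate_abd = 500, rate_direct = 1000, duration_s = 600,
                       maternal_bpm = 80, maternal_jitter_ms = 8,
                       fetal = list(baseline_bpm = 140, events = NULL,
                                    osc_amp_bpm = 5, osc_freq_hz = 0.03),
                       fetal_jitter_ms = 3,
                       target_WM = 14.3, target_WF = 3.4,
                       amp_m = 25, amp_f = 7,
                       emg_uV = 2, mains_uV = 1, wander_uV = 5,
                       gain_m = c(1, 0.85, 1.15, 0.9),
                       gain_f = c(1, 0.55, 0.4, 0.7),
                       direct_amp_uV = 30, direct_noise_uV = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic annotated record
#'
#' Builds maternal and fetal beat trains, renders their morphologies
#' through the per-channel gain vectors, adds the three noise classes
#' (band-limited EMG, 50 Hz mains, baseline wander) and, unless targets
#' are `NA`, calibrates the maternal and fetal global amplitudes in a
#' closed loop so that [record_quality_report()] applied to the emitted
#' record with the ground-truth annotations reports WM and WF within the
#' requested tolerance of the targets. The direct fetal channel is a clean
#' fetal trace at 1 kHz plus small white noise. Component traces sum
#' exactly to the emitted signal, and the same seed reproduces the record
#' bit for bit.
#'
#' @param cfg a [sim_config()].
#' @param calib_tol_db calibration tolerance in dB.
#' @return list with `bundle` (a [record_bundle()] carrying the mixed
#'   abdominal signal, annotations and direct channel) and `truth`
#'   (ground-truth beat times/indices and per-channel component traces
#'   `maternal`, `fetal`, `emg`, `mains`, `wander`).
#' @export
generate_record <- function(cfg, calib_tol_db = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$rate_abd
  n <- round(cfg$duration_s * fs)
  # beat trains -------------------------------------------------------
  m_times <- generate_beat_times(cfg$maternal_bpm, cfg$duration_s,
                                 jitter_ms = cfg$maternal_jitter_ms,
                                 phase_s = 0.45)
  fet <- cfg$fetal
  fprof <- fhr_profile(fet$baseline_bpm %||% 140, fet$events,
                       fet$osc_amp_bpm %||% 0, fet$osc_freq_hz %||% 0.05)
  f_times <- generate_beat_times(fprof, cfg$duration_s,
                                 jitter_ms = cfg$fetal_jitter_ms)
  m_locs <- unique(pmin(pmax(round(m_times / 1000 * fs) + 1, 1), n))
  f_locs <- unique(pmin(pmax(round(f_times / 1000 * fs) + 1, 1), n))
  # unit-amplitude component traces -----------------------------------
  m_shape <- synth_beat_morphology("maternal", fs)
  f_shape <- synth_beat_morphology("fetal", fs)
  m_unit <- render_beats(n, m_locs, m_shape)
  f_unit <- render_beats(n, f_locs, f_shape)
  # noise classes ------------------------------------------------------
  nch <- length(cfg$gain_m)
  emg <- mains <- wander <- matrix(0, nch, n)
  tt <- (0:(n - 1)) / fs
  for (ch in seq_len(nch)) {
    if (cfg$emg_uV > 0) {
      w <- stats::rnorm(n)
      bf <- signal::butter(4, c(20, min(150, 0.45 * fs)) / (fs / 2), "pass")
      e <- as.numeric(signal::filtfilt(bf, w))
      emg[ch, ] <- e / stats::sd(e) * cfg$emg_uV
    }
    if (cfg$mains_uV > 0)
      mains[ch, ] <- cfg$mains_uV * sin(2 * pi * 50 * tt +
                                          stats::runif(1, 0, 2 * pi))
    if (cfg$wander_uV > 0) {
      fr <- stats::runif(2, 0.2, 0.8)
      ph <- stats::runif(2, 0, 2 * pi)
      wander[ch, ] <- cfg$wander_uV *
        (0.7 * sin(2 * pi * fr[1] * tt + ph[1]) +
         0.3 * sin(2 * pi * fr[2] * tt + ph[2]))
    }
  }
  noise <- emg + mains + wander
  # amplitude scaling --------------------------------------------------
  calibrated <- !is.na(cfg$target_WM) && !is.na(cfg$target_WF)
  if (calibrated) {
    if (cfg$emg_uV <= 0 && cfg$mains_uV <= 0 && cfg$wander_uV <= 0)
      stop("dB targets require a nonzero noise floor; set target_WM/",
           "target_WF to NA for noiseless records")
    if (cfg$target_WM > 40 || cfg$target_WF > 40 ||
        cfg$target_WM < -10 || cfg$target_WF < -10)
      stop("requested dB targets outside the feasible range [-10, 40] dB")
    amp <- calibrate_amplitudes(cfg, m_unit, f_unit, noise, m_locs, f_locs,
                                fs, calib_tol_db)
  } else {
    amp <- list(m = cfg$amp_m, f = cfg$amp_f)
  }
  mat <- outer(cfg$gain_m * amp$m, rep(1, n)) *
    matrix(m_unit, nch, n, byrow = TRUE)
  fetl <- outer(cfg$gain_f * amp$f, rep(1, n)) *
    matrix(f_unit, nch, n, byrow = TRUE)
  mixed <- mat + fetl + emg + mains + wander
  abd <- mcsignal(mixed, rate = fs, labels = paste0("A", seq_len(nch)),
                  origin = "synthetic")
  # direct fetal channel ----------------------------------------------
  fsd <- cfg$rate_direct
  nd <- round(cfg$duration_s * fsd)
  fd_locs <- unique(pmin(pmax(round(f_times / 1000 * fsd) + 1, 1), nd))
  fd_shape <- synth_beat_morphology("fetal", fsd)
  direct_v <- cfg$direct_amp_uV * render_beats(nd, fd_locs, fd_shape)
  if (cfg$direct_noise_uV > 0)
    direct_v <- direct_v + stats::rnorm(nd, 0, cfg$direct_noise_uV)
  direct <- mcsignal(direct_v, rate = fsd, labels = "D",
                     origin = "synthetic")
  bundle <- record_bundle(
    abd, direct_fecg = direct,
    maternal_r = beat_ann(m_locs, subject = "maternal", rate = fs),
    fetal_r = beat_ann(f_locs, flags = rep(1L, length(f_locs)),
                       subject = "fetal", rate = fs),
    meta = list(record = sprintf("SYNTH_%04d", cfg$seed),
                dataset = "synthetic", seed = cfg$seed))
  truth <- list(m_times_ms = m_times, f_times_ms = f_times,
                m_locs = m_locs, f_locs = f_locs, fd_locs = fd_locs,
                maternal = mat, fetal = fetl, emg = emg, mains = mains,
                wander = wander, amp_m = amp$m, amp_f = amp$f)
  list(bundle = bundle, truth = truth)
}

# Place a unit-amplitude waveform at each beat location (additive).
render_beats <- function(n, locs, shape) {
  v <- numeric(n)
  w <- shape$waveform
  i0 <- shape$fiducial
  Lw <- length(w)
  for (r in locs) {
    a <- r - (i0 - 1); b <- r + (Lw - i0)
    wa <- 1L; wb <- Lw
    if (a < 1) { wa <- wa + (1 - a); a <- 1 }
    if (b > n) { wb <- wb - (b - n); b <- n }
    if (a <= b) v[a:b] <- v[a:b] + w[wa:wb]
  }
  v
}

# Fixed-point calibration of global maternal/fetal amplitudes against the
# package's own power decomposition, so the across-channel mean WM/WF of
# the emitted record hits the targets.
calibrate_amplitudes <- function(cfg, m_unit, f_unit, noise, m_locs, f_locs,
                                 fs, tol_db, max_iter = 8) {
  nch <- nrow(noise)
  n <- ncol(noise)
  measure <- function(am, af) {
    wm <- wf <- numeric(nch)
    for (ch in seq_len(nch)) {
      v <- am * cfg$gain_m[ch] * m_unit + af * cfg$gain_f[ch] * f_unit +
        noise[ch, ]
      p <- estimate_powers(v, m_locs, f_locs, fs)
      w <- snr_indices(p)
      wm[ch] <- w[["WM"]]; wf[ch] <- w[["WF"]]
    }
    c(WM = mean(wm), WF = mean(wf))
  }
  # open-loop start from the component powers in their own windows
  pn0 <- mean(vapply(seq_len(nch), function(ch) {
    mask <- window_mask(n, m_locs, ms_to_samples(50, fs)) |
      window_mask(n, f_locs, ms_to_samples(20, fs))
    mean(noise[ch, !mask]^2)
  }, numeric(1)))
  msq_m <- mean(m_unit[window_mask(n, m_locs, ms_to_samples(50, fs))]^2)
  msq_f <- mean(f_unit[window_mask(n, f_locs, ms_to_samples(20, fs))]^2)
  gm2 <- mean(cfg$gain_m^2); gf2 <- mean(cfg$gain_f^2)
  am <- sqrt(pn0 * 10^(cfg$target_WM / 10) / (msq_m * gm2))
  af <- sqrt(pn0 * 10^(cfg$target_WF / 10) / (msq_f * gf2))
  for (it in seq_len(max_iter)) {
    est <- measure(am, af)
    err_m <- cfg$target_WM - est[["WM"]]
    err_f <- cfg$target_WF - est[["WF"]]
    if (is.finite(err_m) && is.finite(err_f) &&
        abs(err_m) <= tol_db && abs(err_f) <= tol_db)
      return(list(m = am, f = af))
    if (!is.finite(err_m) || !is.finite(err_f))
      stop("calibration failed: target dB values unreachable with this ",
           "noise floor (feasible roughly [-10, 40] dB)")
    am <- am * 10^(err_m / 20)
    af <- af * 10^(err_f / 20)
  }
  est <- measure(am, af)
  if (abs(cfg$target_WM - est[["WM"]]) > 2 ||
      abs(cfg$target_WF - est[["WF"]]) > 2)
    stop(sprintf(
      "calibration did not converge: reached WM %.1f / WF %.1f dB for ",
      est[["WM"]], est[["WF"]]),
      sprintf("targets %.1f / %.1f dB", cfg$target_WM, cfg$target_WF))
  list(m = am, f = af)
}
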