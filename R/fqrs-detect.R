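#' Bank of fetal QRS detection functions
#'
#' Computes K = 3 nonnegative detection functions from an MECG-suppressed
#' channel:
#' \enumerate{
#'   \item normalized matched filter: the magnitude of the correlation with
#'     the fetal QRS template divided by the local signal energy in a
#'     sliding window of the template length. Values lie in \[0, 1\]
#'     (Cauchy-Schwarz) and are invariant to channel gain, which makes this
#'     function robust to muscle-noise bursts;
#'   \item raw matched filter magnitude (linear in the signal);
#'   \item band-pass (15-45 Hz), differentiate, square, 40 ms moving
#'     integration (the classic energy detector).
#' }
#'
#' @param x numeric vector, one MECG-suppressed channel.
#' @param template fetal QRS template (numeric vector, fiducial at the
#'   center sample), e.g. from [bootstrap_fetal_template()].
#' @param rate sampling frequency in Hz.
#' @return list of K numeric vectors, each the length of `x`, with
#'   attribute `kind`.
#' @export
detection_function_bank <- function(x, template, rate) {
  if (all(template == 0)) stop("all-zero fetal template")
  cc <- matched_correlation(x, template)
  L <- length(template)
  energy <- moving_sum(x^2, L)
  te <- sum(template^2)
  # floor the local energy at 1e-4 of its maximum so near-silent spans
  # (perfect-cancellation residue) cannot reach full normalized score
  efloor <- 1e-4 * max(energy)
  nmf <- abs(cc) / sqrt(pmax(energy, efloor) * te + 1e-300)
  nmf[energy <= 0] <- 0
  mf <- abs(cc)
  bp <- bandpass(x, rate, 15, min(45, 0.45 * rate / 2 * 2))
  en <- moving_sum(c(0, diff(bp))^2, ms_to_samples(40, rate))
  out <- list(nmf, mf, en)
  attr(out[[1]], "kind") <- "normalized-matched-filter"
  attr(out[[2]], "kind") <- "matched-filter"
  attr(out[[3]], "kind") <- "bandpass-energy"
  out
}

# Correlation of x with a centered template (same length as x, zeros at
# the edges). Peak aligns with the template fiducial (center sample).
matched_correlation <- function(x, template) {
  L <- length(template)
  if (L %% 2 == 0) { template <- c(template, 0); L <- L + 1 }
  y <- stats::filter(c(rep(0, L), x, rep(0, L)), rev(template), sides = 2)
  as.numeric(y[(L + 1):(L + length(x))])
}

#' Pick peaks of a detection function with an adaptive threshold
#'
#' Local maxima are accepted when they exceed `beta` times a running
#' robust level of recently accepted peak amplitudes (exponential update,
#' weight 1/8, initialized from the 95th percentile of all local maxima).
#' A 200 ms refractory period is enforced (fetal HR <= 300 bpm), keeping
#' the larger of two competing peaks.
#'
#' @param df nonnegative detection function values.
#' @param rate sampling frequency in Hz.
#' @param beta threshold fraction of the running peak level.
#' @param refractory_ms refractory period in ms.
#' @return strictly increasing sample indices of accepted peaks.
#' @export
adaptive_peaks <- function(df, rate, beta = 0.5, refractory_ms = 200) {
  if (!length(df) || all(df <= 0)) return(numeric(0))
  adaptive_peak_pick(df, rate, refractory_ms = refractory_ms, beta = beta)
}

#' RR intervals of a candidate peak series
#'
#' @param peaks strictly increasing sample indices (or a [beat_ann()]).
#' @return numeric vector of first differences (samples); empty when fewer
#'   than 2 peaks.
#' @export
rr_intervals <- function(peaks) {
  if (inherits(peaks, "beat_ann")) peaks <- peaks$locations
  if (length(peaks) < 2) return(numeric(0))
  diff(peaks)
}

#' RR-variability functional of a detection-function peak series
#'
#' The mean absolute second difference of the RR series,
#' `sum |(RR(i+2) - RR(i+1)) - (RR(i+1) - RR(i))| / (I - 3)`, where `I` is
#' the number of detected peaks. A detection function that misses or
#' over-detects beats produces an erratic RR series and a large value; the
#' functional is the selection criterion for the optimal function.
#'
#' @param rr RR interval series (samples or ms), as from [rr_intervals()].
#' @return the functional value (same unit as `rr`), or `NA` when fewer
#'   than 4 peaks (3 intervals) are available.
#' @export
variability_functional <- function(rr) {
  if (length(rr) < 3) return(NA_real_)
  mean(abs(diff(rr, differences = 2)))
}

#' Select the optimal detection function
#'
#' @param deltas vector of [variability_functional()] values, one per
#'   detection function; `NA` entries are excluded.
#' @return index of the minimum (ties break to the smallest index).
#' @export
select_optimal <- function(deltas) {
  if (all(is.na(deltas)))
    stop("no detection function produced enough peaks; a longer signal ",
         "is required")
  which.min(deltas)
}

#' Autocorrelation periodicity quality of an FECG channel
#'
#' Splits the channel into consecutive windows and computes, per window,
#' the maximum normalized autocorrelation over the lags corresponding to a
#' physiologic fetal heart rate range. A clean quasi-periodic FECG scores
#' near 1; broadband noise or periodicity outside the range scores low.
#'
#' @param x numeric vector, one MECG-suppressed channel.
#' @param rate sampling frequency in Hz.
#' @param fhr_range searched heart-rate band in bpm.
#' @param window_s window length in seconds (must cover at least two of
#'   the longest expected RR intervals).
#' @param max_windows cap on the number of windows scored (evenly spread).
#' @return score in \[0, 1\].
#' @export
periodicity_quality <- function(x, rate, fhr_range = c(110, 180),
                                window_s = 4, max_windows = 60) {
  lag_min <- floor(60 / fhr_range[2] * rate)
  lag_max <- ceiling(60 / fhr_range[1] * rate)
  wlen <- round(window_s * rate)
  if (wlen < 2 * lag_max)
    stop("window too short for the requested heart-rate range")
  starts <- seq(1, length(x) - wlen + 1, by = wlen)
  if (!length(starts)) return(0)
  if (length(starts) > max_windows)
    starts <- starts[round(seq(1, length(starts), length.out = max_windows))]
  score <- vapply(starts, function(s) {
    seg <- x[s:(s + wlen - 1)]
    if (stats::sd(seg) < 1e-12) return(0)
    best <- 0
    for (l in lag_min:lag_max) {
      a <- seg[1:(wlen - l)]
      b <- seg[(l + 1):wlen]
      r <- suppressWarnings(stats::cor(a, b))
      if (!is.na(r) && r > best) best <- r
    }
    best
  }, numeric(1))
  mean(score)
}

#' Select the best FECG channel by periodicity quality
#'
#' @param x an [mcsignal()] of MECG-suppressed channels.
#' @param ... passed to [periodicity_quality()].
#' @return list with `channel` (index; ties break to the lowest) and
#'   `scores` (per-channel quality).
#' @export
select_best_channel <- function(x, ...) {
  stopifnot(inherits(x, "mcsignal"))
  scores <- vapply(seq_len(n_channels(x)),
                   function(i) periodicity_quality(channel(x, i), x$rate, ...),
                   numeric(1))
  list(channel = which.max(scores), scores = scores)
}

#' Bootstrap a fetal QRS template from the signal itself
#'
#' No annotated fetal template exists at run time, so one is built from
#' the data: a generic narrow QRS prototype (about 40 ms wide) drives a
#' normalized matched filter, the `n_events` strongest well-separated
#' correlation events are collected, sign-aligned and averaged, and the
#' mean is renormalized to unit R amplitude.
#'
#' @param x numeric vector, one MECG-suppressed channel.
#' @param rate sampling frequency in Hz.
#' @param n_events number of events averaged.
#' @param half_ms half-width of the template in ms.
#' @return numeric template with the fiducial at the center sample.
#' @export
bootstrap_fetal_template <- function(x, rate, n_events = 20, half_ms = 30) {
  proto <- fetal_qrs_prototype(rate)
  cc <- matched_correlation(x, proto)
  L <- length(proto)
  energy <- moving_sum(x^2, L)
  nmf <- abs(cc) / sqrt(pmax(energy * sum(proto^2), 1e-24))
  half <- ms_to_samples(half_ms, rate)
  refr <- ms_to_samples(200, rate)
  cand <- local_maxima(nmf)
  cand <- cand[cand > half & cand <= length(x) - half]
  if (!length(cand)) return(proto)
  cand <- cand[order(nmf[cand], decreasing = TRUE)]
  picked <- numeric(0)
  for (p in cand) {
    if (!length(picked) || all(abs(picked - p) >= refr)) picked <- c(picked, p)
    if (length(picked) >= n_events) break
  }
  wins <- vapply(picked, function(p)
    sign(cc[p]) * x[(p - half):(p + half)], numeric(2 * half + 1))
  tmpl <- rowMeans(wins)
  peak <- max(abs(tmpl))
  if (peak < 1e-12) return(proto)
  tmpl / peak
}

# Generic ~40 ms wide QRS prototype (sum of Gaussians), unit R amplitude.
fetal_qrs_prototype <- function(rate, half_ms = 30) {
  half <- ms_to_samples(half_ms, rate)
  t <- ((-half):half) / rate * 1000          # ms relative to R
  v <- gauss_wave(t, 0, 1, 4) + gauss_wave(t, -9, -0.1, 3) +
    gauss_wave(t, 9, -0.15, 3.5)
  v / max(abs(v))
}

gauss_wave <- function(t, mu, amp, sd) amp * exp(-((t - mu)^2) / (2 * sd^2))

#' Detect fetal QRS complexes in MECG-suppressed abdominal channels
#'
#' Full abdominal fetal QRS detection: select the best channel by
#' autocorrelation quality, bootstrap a fetal template, run the
#' K-function detection bank, pick peaks adaptively per function, score
#' each peak series with the RR-variability functional and keep the series
#' of the optimal function. Peak locations are refined to the matched
#' filter apex. Each beat gets a 0/1 reliability flag: 0 when the local
#' detection-function signal-to-noise ratio is below `snr_min` or the
#' local RR variability over a 10-beat window exceeds 3 times the record
#' median.
#'
#' @param x an [mcsignal()] of MECG-suppressed channels (or a numeric
#'   vector, used as the single channel).
#' @param rate sampling frequency in Hz (taken from `x` when an
#'   [mcsignal()]).
#' @param template optional fetal QRS template; bootstrapped when `NULL`.
#' @param beta,refractory_ms peak-picking parameters, see
#'   [adaptive_peaks()].
#' @param snr_min local SNR below which a beat is flagged unreliable.
#' @return list with `annotations` (a fetal [beat_ann()] with flags),
#'   `channel`, `quality` (per-channel scores), `k_opt`, `delta`
#'   (per-function variability functionals) and `template`.
#' @export
detect_fqrs <- function(x, rate = NULL, template = NULL, beta = 0.5,
                        refractory_ms = 200, snr_min = 2) {
  if (inherits(x, "mcsignal")) {
    sel <- select_best_channel(x)
    v <- channel(x, sel$channel)
    rate <- x$rate
  } else {
    if (is.null(rate)) stop("`rate` required for a plain vector")
    sel <- list(channel = 1L, scores = NA_real_)
    v <- as.numeric(x)
  }
  if (is.null(template)) template <- bootstrap_fetal_template(v, rate)
  bank <- detection_function_bank(v, template, rate)
  series <- lapply(bank, adaptive_peaks, rate = rate, beta = beta,
                   refractory_ms = refractory_ms)
  deltas <- vapply(series, function(p) variability_functional(rr_intervals(p)),
                   numeric(1))
  k_opt <- select_optimal(deltas)
  peaks <- series[[k_opt]]
  # refine to the apex of the matched-filter magnitude (smooth, zero-lag)
  mf <- abs(matched_correlation(v, template))
  peaks <- sort(unique(refine_apex(mf, peaks, ms_to_samples(10, rate))))
  flags <- reliability_flags(bank[[k_opt]], peaks, rate, snr_min)
  ann <- beat_ann(peaks, flags = flags, subject = "fetal", rate = rate)
  list(annotations = ann, channel = sel$channel, quality = sel$scores,
       k_opt = k_opt, delta = deltas, template = template)
}

# 0/1 reliability flags: local detection-function SNR and local RR
# variability criteria.
reliability_flags <- function(df, peaks, rate, snr_min = 2,
                              delta_factor = 3) {
  n <- length(peaks)
  if (!n) return(integer(0))
  flags <- rep(1L, n)
  halfsec <- round(rate)
  for (i in seq_len(n)) {
    p <- peaks[i]
    a <- max(1, p - halfsec); b <- min(length(df), p + halfsec)
    noise <- stats::median(df[a:b])
    if (noise > 0 && df[p] / noise < snr_min) flags[i] <- 0L
  }
  if (n >= 11) {
    rr <- diff(peaks)
    local_delta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      lo <- max(1, i - 5); hi <- min(length(rr), i + 4)
      local_delta[i] <- variability_functional(rr[lo:hi])
    }
    med <- stats::median(local_delta, na.rm = TRUE)
    if (!is.na(med) && med > 0)
      flags[!is.na(local_delta) & local_delta > delta_factor * med] <- 0L
  }
  flags
}

#' Detect fetal QRS complexes in a direct (scalp) FECG signal
#'
#' Normalized matched filtering with a bootstrapped template, followed by a
#' sequential decision rule: among candidate correlation peaks in the
#' search window after the last accepted beat, the one minimizing
#' `|RR_pred - RR_candidate|` is accepted, where `RR_pred` is the running
#' median of the last five accepted RR intervals. At 1 kHz this yields the
#' reference annotations with 1 ms resolution.
#'
#' @param x single-channel [mcsignal()] or numeric vector (direct FECG).
#' @param rate sampling frequency in Hz (default 1000).
#' @param threshold minimum normalized correlation for a candidate.
#' @return a fetal [beat_ann()].
#' @export
detect_direct_fqrs <- function(x, rate = 1000, threshold = 0.35) {
  if (inherits(x, "mcsignal")) { rate <- x$rate; x <- channel(x, 1) }
  x <- as.numeric(x)
  if (!length(x) || all(abs(x) < 1e-12))
    return(beat_ann(numeric(0), subject = "fetal", rate = rate))
  template <- bootstrap_fetal_template(x, rate)
  cc <- matched_correlation(x, template)
  L <- length(template)
  nmf <- abs(cc) / sqrt(pmax(moving_sum(x^2, L) * sum(template^2), 1e-24))
  cand <- local_maxima(nmf)
  cand <- cand[nmf[cand] >= threshold]
  if (!length(cand))
    return(beat_ann(numeric(0), subject = "fetal", rate = rate))
  # seed the cycle-length predictor from the dominant candidate spacing
  gaps <- diff(cand)
  gaps <- gaps[gaps >= ms_to_samples(180, rate) &
                 gaps <= ms_to_samples(1000, rate)]
  rr0 <- if (length(gaps)) stats::median(gaps) else ms_to_samples(430, rate)
  # first beat: earliest clearly strong candidate
  strong <- 0.5 * stats::quantile(nmf[cand], 0.95, names = FALSE)
  acc <- cand[nmf[cand] >= strong][1]
  if (is.na(acc)) acc <- cand[1]
  rr_hist <- rr0
  repeat {
    last <- acc[length(acc)]
    rr_pred <- stats::median(utils::tail(rr_hist, 5))
    win <- c(last + round(0.55 * rr_pred), last + round(1.5 * rr_pred))
    pool <- cand[cand >= win[1] & cand <= win[2]]
    if (!length(pool)) {
      # gap: resynchronize at the next strong candidate without letting
      # the skipped span corrupt the predictor
      nxt <- cand[cand > win[2]][1]
      if (is.na(nxt)) break
      acc <- c(acc, nxt)
      next
    }
    nxt <- pool[which.min(abs((pool - last) - rr_pred))]
    rr_hist <- c(rr_hist, nxt - last)
    acc <- c(acc, nxt)
  }
  acc <- sort(unique(refine_apex(abs(cc), acc, ms_to_samples(5, rate))))
  beat_ann(acc, subject = "fetal", rate = rate)
}
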