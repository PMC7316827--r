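#' Auxiliary maternal ECG by spatial averaging
#'
#' Averages the abdominal channels sample-for-sample. Maternal QRS
#' complexes are in phase across electrodes and survive; fetal beats and
#' EMG, being uncorrelated in phase/gain across electrodes, are attenuated
#' by about `1/sqrt(n_channels)`. The result is used only for locating
#' maternal R waves and is never subtracted itself.
#'
#' @param x an [mcsignal()] with the (preprocessed) abdominal channels.
#' @return numeric vector, the channel-mean signal.
#' @export
auxiliary_mecg <- function(x) {
  stopifnot(inherits(x, "mcsignal"))
  if (n_channels(x) < 2) {
    warning("single channel: auxiliary MECG is the channel itself")
    return(channel(x, 1))
  }
  colMeans(x$samples)
}

#' Detect maternal R waves
#'
#' Adaptive-threshold detection on an energy detection function (band-passed
#' derivative, squared, integrated over 80 ms), with a 300 ms refractory
#' period (maternal HR <= 200 bpm) and apex refinement on the input signal.
#' Gaps longer than 5 s without a detection are reported via a message and
#' detection continues.
#'
#' @param aux numeric vector, the auxiliary MECG (see [auxiliary_mecg()]).
#' @param rate sampling frequency in Hz.
#' @param beta threshold as a fraction of the running peak level.
#' @return a maternal [beat_ann()].
#' @export
detect_maternal_r <- function(aux, rate, beta = 0.5) {
  if (all(abs(aux) < 1e-12))
    return(beat_ann(numeric(0), subject = "maternal", rate = rate))
  bp <- bandpass(aux, rate, low = 5, high = 30)
  df <- moving_sum(c(0, diff(bp))^2, ms_to_samples(80, rate))
  locs <- adaptive_peak_pick(df, rate, refractory_ms = 300, beta = beta)
  if (length(locs) >= 2) {
    gaps <- diff(locs) / rate
    if (any(gaps > 5))
      message(sprintf("maternal detection: %d gap(s) longer than 5 s",
                      sum(gaps > 5)))
  }
  # refine fiducial to the R apex of the raw auxiliary signal
  half <- ms_to_samples(60, rate)
  locs <- refine_apex(aux, locs, half)
  locs <- sort(unique(locs))
  beat_ann(locs, subject = "maternal", rate = rate)
}

# Centered moving sum over w samples.
moving_sum <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1
  y <- stats::filter(c(rep(0, w), x, rep(0, w)), rep(1, w), sides = 2)
  as.numeric(y[(w + 1):(w + length(x))])
}

bandpass <- function(x, rate, low, high, order = 2) {
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Move each candidate to the extremum of |x| within +/- half samples.
refine_apex <- function(x, locs, half) {
  n <- length(x)
  vapply(locs, function(r) {
    a <- max(1, r - half); b <- min(n, r + half)
    a + which.max(abs(x[a:b])) - 1L
  }, numeric(1))
}

# Shared adaptive peak picking: local maxima above beta * running level of
# accepted peak amplitudes (exponential update, weight 1/8), refractory
# enforced by keeping the larger peak.
adaptive_peak_pick <- function(df, rate, refractory_ms, beta = 0.5,
                               update_weight = 1 / 8, searchback = TRUE) {
  cand <- local_maxima(df)
  if (!length(cand)) return(numeric(0))
  refr <- ms_to_samples(refractory_ms, rate)
  # learning phase: the first beats set the initial running level
  head_max <- max(df[seq_len(min(length(df), 2 * round(rate)))])
  level <- if (head_max > 0) head_max
           else stats::quantile(df[cand], 0.95, names = FALSE)
  if (level <= 0) return(numeric(0))
  acc <- numeric(0)
  acc_amp <- numeric(0)
  for (i in seq_along(cand)) {
    p <- cand[i]; a <- df[p]
    if (a < beta * level) next
    if (length(acc) && p - acc[length(acc)] < refr) {
      if (a > acc_amp[length(acc)]) {      # keep the larger of the pair
        acc[length(acc)] <- p
        acc_amp[length(acc)] <- a
        level <- (1 - update_weight) * level + update_weight * a
      }
      next
    }
    acc <- c(acc, p); acc_amp <- c(acc_amp, a)
    level <- (1 - update_weight) * level + update_weight * a
  }
  # search-back: a beat attenuated by a coinciding event can fall under
  # the main threshold; re-examine gaps much longer than the running RR
  # with a halved threshold
  if (searchback && length(acc) >= 4) {
    rrmed <- stats::median(diff(acc))
    amed <- stats::median(acc_amp)
    inserted <- numeric(0)
    for (i in seq_len(length(acc) - 1)) {
      if (acc[i + 1] - acc[i] <= 1.6 * rrmed) next
      pool <- cand[cand > acc[i] + refr & cand < acc[i + 1] - refr]
      pool <- pool[df[pool] >= 0.5 * beta * amed]
      if (length(pool)) inserted <- c(inserted, pool[which.max(df[pool])])
    }
    acc <- sort(c(acc, inserted))
  }
  acc
}

#' Build and update a maternal PQRST heartbeat template
#'
#' The template spans `pre_R` ms before to `post_R` ms after the R
#' fiducial, covering the full P-QRS-T cycle. It is built from per-sample
#' medians over blocks of `n_init` beat windows: the median is essential
#' because fetal QRS complexes ride on the maternal cycle at effectively
#' random offsets, and a plain mean would absorb them into the template
#' and re-inject them (inverted) at subtraction time. The first block
#' initializes the template; each further block median is blended in
#' exponentially, `T <- (1 - w) T + w median(block)`, so the template
#' tracks slow MECG shape changes with a memory of a few blocks. Windows
#' clipped by the signal edges are skipped.
#'
#' @param x numeric vector (one abdominal channel).
#' @param r_locs maternal R sample indices (vector or [beat_ann()]).
#' @param rate sampling frequency in Hz.
#' @param pre_R,post_R window extents in ms.
#' @param update_weight exponential blend weight `w` in (0, 1] applied per
#'   block.
#' @param n_init beats per median block.
#' @return an object of class `heartbeat_template` with fields `waveform`,
#'   `fiducial` (index of R within the waveform), `pre_R`, `post_R`,
#'   `rate`, `beats_absorbed`, `update_weight`.
#' @export
build_template <- function(x, r_locs, rate, pre_R = 250, post_R = 450,
                           update_weight = 1 / 2, n_init = 16) {
  if (inherits(r_locs, "beat_ann")) r_locs <- r_locs$locations
  a <- ms_to_samples(pre_R, rate)
  b <- ms_to_samples(post_R, rate)
  usable <- r_locs[r_locs - a >= 1 & r_locs + b <= length(x)]
  if (!length(usable)) stop("no complete beat windows available")
  wins <- vapply(usable, function(r) x[(r - a):(r + b)],
                 numeric(a + b + 1))
  blocks <- split(seq_along(usable),
                  ceiling(seq_along(usable) / n_init))
  # a trailing fragment of under half a block is merged into the previous
  nb <- length(blocks)
  if (nb > 1 && length(blocks[[nb]]) < n_init / 2) {
    blocks[[nb - 1]] <- c(blocks[[nb - 1]], blocks[[nb]])
    blocks[[nb]] <- NULL
  }
  block_median <- function(idx) {
    if (length(idx) == 1) return(wins[, idx])
    apply(wins[, idx, drop = FALSE], 1, stats::median)
  }
  tmpl <- block_median(blocks[[1]])
  for (bl in blocks[-1])
    tmpl <- (1 - update_weight) * tmpl + update_weight * block_median(bl)
  structure(list(waveform = tmpl, fiducial = a + 1L, pre_R = pre_R,
                 post_R = post_R, rate = rate,
                 beats_absorbed = length(usable),
                 update_weight = update_weight),
            class = "heartbeat_template")
}

#' @export
print.heartbeat_template <- function(x, ...) {
  cat(sprintf(
    "<heartbeat_template> %d samples (-%g/+%g ms @ %g Hz), %d beats absorbed\n",
    length(x$waveform), x$pre_R, x$post_R, x$rate, x$beats_absorbed))
  invisible(x)
}

# First derivative of the QRS portion of the template, zero elsewhere.
template_qrs_derivative <- function(tmpl, qrs_half_ms = 50) {
  d <- c(0, diff(tmpl$waveform))
  q <- ms_to_samples(qrs_half_ms, tmpl$rate)
  keep <- seq(max(1, tmpl$fiducial - q),
              min(length(d), tmpl$fiducial + q))
  out <- numeric(length(d))
  out[keep] <- d[keep]
  out
}

#' Subtract the maternal template from one channel
#'
#' For each maternal beat, the amplitude coefficient and the coefficient on
#' the first derivative of the QRS template are fitted by least squares on
#' the QRS +/- 50 ms window only (scaling is driven by QRS energy; T-wave
#' fitting is unstable), then `scale * template + derivative_scale * dQRS`
#' is subtracted over the full heart-cycle window. The derivative term
#' compensates sub-sample fiducial jitter at 500 Hz. Samples between beat
#' windows pass through unchanged. When the RR interval is shorter than the
#' template span, the window is truncated at the midpoint between
#' fiducials.
#'
#' @param x numeric vector (one abdominal channel).
#' @param r_locs maternal R sample indices (vector or [beat_ann()]).
#' @param tmpl a [build_template()] result.
#' @param qrs_half_ms half-width in ms of the least-squares fit window.
#' @param derivative logical; include the first-derivative correction term
#'   (disable only to quantify its benefit).
#' @return list with `residual` (the FECG estimate) and `coefficients`
#'   (data.frame: beat, location, scale, derivative_scale).
#' @export
subtract_template <- function(x, r_locs, tmpl, qrs_half_ms = 50,
                              derivative = TRUE) {
  if (inherits(r_locs, "beat_ann")) r_locs <- r_locs$locations
  stopifnot(inherits(tmpl, "heartbeat_template"))
  w <- tmpl$waveform
  dz <- template_qrs_derivative(tmpl, qrs_half_ms)
  if (!derivative) dz[] <- 0
  i0 <- tmpl$fiducial
  Lw <- length(w)
  q <- ms_to_samples(qrs_half_ms, tmpl$rate)
  res <- x
  n <- length(x)
  m <- length(r_locs)
  coef <- data.frame(beat = seq_len(m), location = r_locs,
                     scale = NA_real_, derivative_scale = NA_real_)
  for (i in seq_len(m)) {
    r <- r_locs[i]
    lo <- r - (i0 - 1)            # signal index of waveform sample 1
    hi <- r + (Lw - i0)
    # truncate at midpoints to neighbours when cycles overlap
    if (i > 1) lo <- max(lo, floor((r + r_locs[i - 1]) / 2) + 1)
    if (i < m) hi <- min(hi, floor((r + r_locs[i + 1]) / 2))
    lo <- max(lo, 1); hi <- min(hi, n)
    if (hi <= lo) next
    widx <- (lo:hi) - r + i0      # waveform indices of the kept span
    # fit on the QRS +/- qrs_half window (intersected with kept span)
    fa <- max(lo, r - q); fb <- min(hi, r + q)
    fidx <- (fa:fb) - r + i0
    X <- cbind(w[fidx], dz[fidx])
    y <- res[fa:fb]
    denom <- crossprod(X)
    if (abs(det(denom)) < 1e-12) {
      ab <- c(sum(X[, 1] * y) / max(sum(X[, 1]^2), 1e-12), 0)
    } else {
      ab <- as.numeric(solve(denom, crossprod(X, y)))
    }
    res[lo:hi] <- res[lo:hi] - ab[1] * w[widx] - ab[2] * dz[widx]
    coef$scale[i] <- ab[1]
    coef$derivative_scale[i] <- ab[2]
  }
  list(residual = res, coefficients = coef)
}

#' Suppress the maternal ECG in a multichannel abdominal signal
#'
#' Full MECG-suppression stage: spatial averaging to an auxiliary MECG,
#' maternal R-wave detection on it, then per-channel template construction
#' and amplitude-scaled subtraction with the first-derivative correction.
#' Optionally, beats whose correlation with the running template falls
#' below `arrhythmia_cor` seed an alternate template pool and are
#' subtracted with whichever template matches better (maternal arrhythmia
#' handling for labour data).
#'
#' @param x an [mcsignal()] with preprocessed abdominal channels.
#' @param maternal_r optional known maternal [beat_ann()]; detected from
#'   the auxiliary MECG when `NULL`.
#' @param pre_R,post_R,update_weight,n_init template parameters, see
#'   [build_template()].
#' @param arrhythmia_templates logical; enable the alternate template pool.
#' @param arrhythmia_cor correlation threshold seeding the alternate pool.
#' @return list with `fecg` (the suppressed [mcsignal()]), `maternal_r`
#'   (the annotations used) and `coefficients` (per-channel list of
#'   per-beat subtraction coefficients).
#' @export
suppress_mecg <- function(x, maternal_r = NULL, pre_R = 250, post_R = 450,
                          update_weight = 1 / 16, n_init = 16,
                          arrhythmia_templates = FALSE,
                          arrhythmia_cor = 0.8) {
  stopifnot(inherits(x, "mcsignal"))
  if (is.null(maternal_r))
    maternal_r <- detect_maternal_r(auxiliary_mecg(x), x$rate)
  out <- x
  coefs <- vector("list", n_channels(x))
  names(coefs) <- x$labels
  for (ch in seq_len(n_channels(x))) {
    v <- channel(x, ch)
    if (!length(maternal_r$locations)) {
      coefs[[ch]] <- data.frame()
      next
    }
    tmpl <- build_template(v, maternal_r, x$rate, pre_R, post_R,
                           update_weight, n_init)
    if (arrhythmia_templates) {
      sub <- subtract_with_arrhythmia(v, maternal_r$locations, tmpl,
                                      arrhythmia_cor)
    } else {
      sub <- subtract_template(v, maternal_r, tmpl)
    }
    out$samples[ch, ] <- sub$residual
    coefs[[ch]] <- sub$coefficients
  }
  list(fecg = out, maternal_r = maternal_r, coefficients = coefs)
}

# Alternate-template variant: beats poorly correlated with the main template
# are pooled and subtracted with their own running template.
subtract_with_arrhythmia <- function(v, r_locs, tmpl, cor_thresh) {
  a <- tmpl$fiducial - 1L
  b <- length(tmpl$waveform) - tmpl$fiducial
  ok <- r_locs - a >= 1 & r_locs + b <= length(v)
  cors <- rep(1, length(r_locs))
  for (i in which(ok)) {
    seg <- v[(r_locs[i] - a):(r_locs[i] + b)]
    cors[i] <- suppressWarnings(stats::cor(seg, tmpl$waveform))
  }
  cors[is.na(cors)] <- 0
  alt_idx <- which(cors < cor_thresh & ok)
  main_idx <- setdiff(seq_along(r_locs), alt_idx)
  res <- v
  coef <- data.frame(beat = seq_along(r_locs), location = r_locs,
                     scale = NA_real_, derivative_scale = NA_real_,
                     template = "main")
  if (length(main_idx)) {
    s <- subtract_template(res, r_locs[main_idx], tmpl)
    res <- s$residual
    coef$scale[main_idx] <- s$coefficients$scale
    coef$derivative_scale[main_idx] <- s$coefficients$derivative_scale
  }
  if (length(alt_idx) >= 1) {
    alt_tmpl <- try(build_template(v, r_locs[alt_idx], tmpl$rate,
                                   tmpl$pre_R, tmpl$post_R,
                                   tmpl$update_weight), silent = TRUE)
    if (!inherits(alt_tmpl, "try-error")) {
      s <- subtract_template(res, r_locs[alt_idx], alt_tmpl)
      res <- s$residual
      coef$scale[alt_idx] <- s$coefficients$scale
      coef$derivative_scale[alt_idx] <- s$coefficients$derivative_scale
      coef$template[alt_idx] <- "alternate"
    }
  }
  list(residual = res, coefficients = coef)
}
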