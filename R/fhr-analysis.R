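#' Instantaneous fetal heart rate series from beat annotations
#'
#' Converts R-wave annotations to per-interval instantaneous FHR,
#' `FHR_i = 60000 / RR_i(ms)`. Intervals adjacent to a beat flagged
#' unreliable (flag 0) are masked, as are intervals outside the
#' physiologic gate.
#'
#' @param ann a [beat_ann()] (its `rate` and `flags` are used) or a
#'   numeric vector of sample indices.
#' @param rate sampling frequency in Hz (when `ann` is a vector).
#' @param flags optional 0/1 reliability flags (when `ann` is a vector).
#' @param gate_bpm physiologic FHR gate; intervals outside are masked.
#' @return an object of class `fhr_series`: `beat_times` (ms), `rr_ms`,
#'   `fhr_bpm` and logical `valid` per interval.
#' @export
rr_to_fhr <- function(ann, rate = NULL, flags = NULL,
                      gate_bpm = c(50, 250)) {
  if (inherits(ann, "beat_ann")) {
    rate <- ann$rate
    flags <- ann$flags
    locs <- ann$locations
  } else locs <- as.numeric(ann)
  if (is.null(rate)) stop("`rate` is required")
  empty <- structure(list(beat_times = numeric(0), rr_ms = numeric(0),
                          fhr_bpm = numeric(0), valid = logical(0),
                          rate = rate),
                     class = "fhr_series")
  if (length(locs) < 2) return(empty)
  bt <- index_to_ms(locs, rate)
  rr <- diff(bt)
  fhr <- 60000 / rr
  valid <- fhr >= gate_bpm[1] & fhr <= gate_bpm[2]
  if (!is.null(flags)) {
    bad <- which(flags == 0)
    valid[bad[bad <= length(rr)]] <- FALSE       # interval after a bad beat
    valid[bad[bad > 1] - 1] <- FALSE             # interval before a bad beat
  }
  structure(list(beat_times = bt, rr_ms = rr, fhr_bpm = fhr, valid = valid,
                 rate = rate),
            class = "fhr_series")
}

#' @export
print.fhr_series <- function(x, ...) {
  cat(sprintf("<fhr_series> %d intervals, %d valid (%.1f%%), mean %.1f bpm\n",
              length(x$rr_ms), sum(x$valid),
              if (length(x$valid)) 100 * mean(x$valid) else 0,
              if (any(x$valid)) mean(x$fhr_bpm[x$valid]) else NA))
  invisible(x)
}

#' Resample an FHR series onto the 4 Hz monitoring grid
#'
#' Zero-order hold of the most recent valid interval value onto a 250 ms
#' grid (the cardiotocography standard): the value of interval i holds
#' from the beat that closes it until the next beat. Grid points falling
#' in masked spans, or before the first complete interval, are invalid.
#' Signal loss is the invalid fraction of the timeline.
#'
#' @param fs an [rr_to_fhr()] result.
#' @param duration_ms grid extent in ms; defaults to the last beat time.
#' @param grid_hz grid rate (4 Hz standard).
#' @return list with `times` (ms), `fhr` (bpm, `NA` where invalid),
#'   `valid` and `loss_pct`.
#' @export
resample_4hz <- function(fs, duration_ms = NULL, grid_hz = 4) {
  stopifnot(inherits(fs, "fhr_series"))
  if (is.null(duration_ms))
    duration_ms <- if (length(fs$beat_times)) max(fs$beat_times) else 0
  step <- 1000 / grid_hz
  times <- seq(0, duration_ms, by = step)
  if (!length(fs$rr_ms)) {
    return(list(times = times, fhr = rep(NA_real_, length(times)),
                valid = rep(FALSE, length(times)), loss_pct = 100,
                grid_hz = grid_hz))
  }
  # interval i (between beats i and i+1) is the latest known value for
  # t in [beat_times[i+1], beat_times[i+2])
  idx <- findInterval(times, fs$beat_times[-1])
  fhr <- rep(NA_real_, length(times))
  valid <- rep(FALSE, length(times))
  inside <- idx >= 1 & idx <= length(fs$rr_ms)
  take <- pmin(pmax(idx, 1), length(fs$rr_ms))
  ok <- inside & fs$valid[take]
  fhr[ok] <- fs$fhr_bpm[take[ok]]
  valid[ok] <- TRUE
  list(times = times, fhr = fhr, valid = valid,
       loss_pct = 100 * mean(!valid), grid_hz = grid_hz)
}

#' Basal FHR and fluctuation from the 4 Hz grid
#'
#' The basal rate is the histogram mode (1 bpm bins) of a low-pass trend
#' of the grid (25 s running mean), with two exclusion iterations that
#' drop samples further than `exclude_bpm` from the current estimate so
#' acceleration/deceleration excursions do not drag the mode. Fluctuation
#' is the mean minute-wise peak-to-peak deviation of the grid around the
#' trend.
#'
#' @param grid a [resample_4hz()] result.
#' @param trend_s running-mean window for the trend, seconds.
#' @param exclude_bpm exclusion band for the mode iterations.
#' @return list `basal` (bpm), `fluctuation` (bpm), `trend` (per grid
#'   sample).
#' @export
baseline_and_fluctuation <- function(grid, trend_s = 25, exclude_bpm = 10) {
  v <- grid$fhr
  if (all(is.na(v))) return(list(basal = NA_real_, fluctuation = NA_real_,
                                 trend = v))
  k <- round(trend_s * grid$grid_hz)
  trend <- runmean_na(v, k)
  hist_mode <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    br <- seq(floor(min(x)) - 0.5, ceiling(max(x)) + 0.5, by = 1)
    h <- hist(x, breaks = br, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  basal <- hist_mode(trend)
  for (it in 1:2) {
    keep <- trend[!is.na(trend) & abs(trend - basal) <= exclude_bpm]
    if (length(keep) >= 4) basal <- hist_mode(keep)
  }
  # refine within the winning 1 bpm bin by the mean of included samples
  near <- trend[!is.na(trend) & abs(trend - basal) <= 1]
  if (length(near)) basal <- mean(near)
  dev <- v - trend
  fluct <- minute_p2p(dev, grid$grid_hz)
  list(basal = basal, fluctuation = fluct, trend = trend)
}

# Mean minute-wise peak-to-peak of a grid series (NA-aware; minutes with
# under half their samples valid are skipped).
minute_p2p <- function(v, grid_hz) {
  per_min <- 60 * grid_hz
  n <- length(v)
  if (n < per_min / 2) return(NA_real_)
  starts <- seq(1, n, by = per_min)
  vals <- vapply(starts, function(s) {
    seg <- v[s:min(n, s + per_min - 1)]
    if (sum(!is.na(seg)) < per_min / 2) return(NA_real_)
    diff(range(seg, na.rm = TRUE))
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Detect acceleration and deceleration episodes
#'
#' An acceleration is an excursion of at least `amp_bpm` above the basal
#' rate lasting at least `dur_s`; a deceleration is the mirror image.
#' Invalid grid samples break an episode. Episodes truncated by the record
#' boundaries (already in progress at the start, or still in progress at
#' the end) are not counted.
#'
#' @param grid a [resample_4hz()] result.
#' @param basal basal FHR in bpm (see [baseline_and_fluctuation()]).
#' @param amp_bpm,dur_s episode thresholds (guideline convention:
#'   15 bpm / 15 s).
#' @return list with data.frames `accelerations` and `decelerations`
#'   (onset_s, duration_s, extremum_bpm).
#' @export
detect_acc_dec <- function(grid, basal, amp_bpm = 15, dur_s = 15) {
  episodes <- function(sgn) {
    above <- sgn * (grid$fhr - basal) >= amp_bpm
    above[is.na(above)] <- FALSE
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      extremum_bpm = numeric(0))
    for (k in keep) {
      dur <- r$lengths[k] / grid$grid_hz
      if (dur < dur_s) next
      if (starts[k] == 1 || ends[k] == length(above)) next  # truncated
      seg <- grid$fhr[starts[k]:ends[k]]
      out <- rbind(out, data.frame(
        onset_s = grid$times[starts[k]] / 1000, duration_s = dur,
        extremum_bpm = if (sgn > 0) max(seg, na.rm = TRUE)
                       else min(seg, na.rm = TRUE)))
    }
    out
  }
  list(accelerations = episodes(1), decelerations = episodes(-1))
}

#' Instantaneous FHR variability indices
#'
#' Computes the classical time-domain variability set from a beat-interval
#' series, excluding masked spans:
#' \itemize{
#'   \item `stv_dawes` (ms): mean absolute difference between consecutive
#'     3.75 s epoch mean RR values (16 epochs per minute);
#'   \item `ltv_dawes` (ms): mean of the minute-wise range (max - min) of
#'     epoch mean RR;
#'   \item `oscillation` (bpm): mean minute-wise peak-to-peak of the 4 Hz
#'     FHR grid;
#'   \item `lti` (de Haan, ms): interquartile range of the modulus
#'     `sqrt(RR_i^2 + RR_{i+1}^2)`;
#'   \item `sti` (de Haan, rad): interquartile range of the phase angle
#'     `arctan(RR_{i+1} / RR_i)`;
#'   \item `ii` (Yeh interval index): minute-wise coefficient of variation
#'     of RR, averaged over minutes;
#'   \item `di` (Yeh differential index): minute-wise standard deviation
#'     of `1000 (RR_i - RR_{i+1}) / (RR_i + RR_{i+1})`, averaged.
#' }
#'
#' @param fs an [rr_to_fhr()] result.
#' @param grid optional precomputed [resample_4hz()] grid.
#' @param epoch_s epoch length in seconds (Dawes-Redman convention 3.75).
#' @return named list of the indices.
#' @export
variability_indices <- function(fs, grid = NULL, epoch_s = 3.75) {
  stopifnot(inherits(fs, "fhr_series"))
  if (is.null(grid)) grid <- resample_4hz(fs)
  nidx <- list(ltv_dawes = NA_real_, stv_dawes = NA_real_,
               oscillation = NA_real_, lti = NA_real_, sti = NA_real_,
               ii = NA_real_, di = NA_real_)
  if (sum(fs$valid) < 2) return(nidx)
  # epoch mean RR: assign each interval to the epoch of its closing beat
  t_close <- fs$beat_times[-1]
  epoch <- floor(t_close / (epoch_s * 1000))
  rr <- fs$rr_ms
  ok <- fs$valid
  ep_ids <- sort(unique(epoch[ok]))
  ep_rr <- vapply(ep_ids, function(e) mean(rr[ok & epoch == e]), numeric(1))
  # STV: differences between temporally adjacent epochs only
  adj <- which(diff(ep_ids) == 1)
  stv <- if (length(adj)) mean(abs(ep_rr[adj + 1] - ep_rr[adj])) else NA_real_
  # LTV: minute-wise epoch range (minutes holding >= 8 of 16 epochs)
  per_min <- round(60 / epoch_s)
  minute <- ep_ids %/% per_min
  ltv_vals <- vapply(unique(minute), function(m) {
    v <- ep_rr[minute == m]
    if (length(v) < per_min / 2) return(NA_real_)
    diff(range(v))
  }, numeric(1))
  ltv <- if (all(is.na(ltv_vals))) NA_real_ else mean(ltv_vals, na.rm = TRUE)
  osc <- minute_p2p(grid$fhr, grid$grid_hz)
  # beat-pair indices over consecutive valid intervals
  pair <- which(ok[-length(ok)] & ok[-1])
  lti <- sti <- NA_real_
  if (length(pair) >= 4) {
    modulus <- sqrt(rr[pair]^2 + rr[pair + 1]^2)
    lti <- stats::IQR(modulus)
    sti <- stats::IQR(atan(rr[pair + 1] / rr[pair]))
  }
  # minute-wise Yeh indices on valid intervals
  minute_i <- floor(t_close / 60000)
  ii_vals <- di_vals <- c()
  for (m in unique(minute_i)) {
    sel <- ok & minute_i == m
    v <- rr[sel]
    if (length(v) >= 10) {
      ii_vals <- c(ii_vals, stats::sd(v) / mean(v))
      idx <- which(sel)
      pr <- idx[idx + 1 <= length(rr) & c(sel[-1], FALSE)[idx]]
      if (length(pr) >= 5) {
        d <- 1000 * (rr[pr] - rr[pr + 1]) / (rr[pr] + rr[pr + 1])
        di_vals <- c(di_vals, stats::sd(d))
      }
    }
  }
  list(ltv_dawes = ltv, stv_dawes = stv, oscillation = osc,
       lti = lti, sti = sti,
       ii = if (length(ii_vals)) mean(ii_vals) else NA_real_,
       di = if (length(di_vals)) mean(di_vals) else NA_real_)
}

#' Clinical FHR variability report
#'
#' Composes the full per-record FHR analysis: signal loss, basal rate,
#' fluctuation, acceleration/deceleration counts, oscillation and the
#' instantaneous variability indices.
#'
#' @param ann fetal [beat_ann()] (flags honoured) or sample-index vector.
#' @param rate sampling frequency in Hz (when `ann` is a vector).
#' @param flags optional flags (when `ann` is a vector).
#' @param duration_ms record duration for the 4 Hz grid; defaults to the
#'   last beat time.
#' @param acc_bpm,acc_s episode thresholds, see [detect_acc_dec()].
#' @return an object of class `fhr_report` (also a named list):
#'   `loss_pct`, `basal`, `fluctuation`, `acc_count`, `dec_count`,
#'   `oscillation`, `ltv_dawes`, `stv_dawes`, `lti`, `sti`, `ii`, `di`,
#'   plus `episodes`.
#' @export
fhr_report <- function(ann, rate = NULL, flags = NULL, duration_ms = NULL,
                       acc_bpm = 15, acc_s = 15) {
  fs <- rr_to_fhr(ann, rate = rate, flags = flags)
  grid <- resample_4hz(fs, duration_ms = duration_ms)
  empty <- structure(list(loss_pct = 100, basal = NA_real_,
                          fluctuation = NA_real_, acc_count = NA_integer_,
                          dec_count = NA_integer_, oscillation = NA_real_,
                          ltv_dawes = NA_real_, stv_dawes = NA_real_,
                          lti = NA_real_, sti = NA_real_, ii = NA_real_,
                          di = NA_real_, episodes = NULL),
                     class = "fhr_report")
  if (!any(grid$valid)) return(empty)
  bf <- baseline_and_fluctuation(grid)
  eps <- if (is.na(bf$basal)) list(accelerations = NULL, decelerations = NULL)
         else detect_acc_dec(grid, bf$basal, amp_bpm = acc_bpm, dur_s = acc_s)
  vi <- variability_indices(fs, grid = grid)
  structure(c(list(loss_pct = grid$loss_pct, basal = bf$basal,
                   fluctuation = bf$fluctuation,
                   acc_count = NROW(eps$accelerations),
                   dec_count = NROW(eps$decelerations)),
              vi[c("oscillation", "ltv_dawes", "stv_dawes", "lti", "sti",
                   "ii", "di")],
              list(episodes = eps)),
            class = "fhr_report")
}

#' @export
print.fhr_report <- function(x, ...) {
  cat("<fhr_report>\n")
  cat(sprintf("  signal loss     %.1f %%\n", x$loss_pct))
  cat(sprintf("  basal FHR       %.1f bpm\n", x$basal))
  cat(sprintf("  fluctuation     %.1f bpm\n", x$fluctuation))
  cat(sprintf("  accelerations   %d\n", x$acc_count))
  cat(sprintf("  decelerations   %d\n", x$dec_count))
  cat(sprintf("  oscillation     %.1f bpm\n", x$oscillation))
  cat(sprintf("  LTV (Dawes)     %.1f ms\n", x$ltv_dawes))
  cat(sprintf("  STV (Dawes)     %.2f ms\n", x$stv_dawes))
  cat(sprintf("  LTI %.1f  STI %.4f  II %.4f  DI %.2f\n",
              x$lti, x$sti, x$ii, x$di))
  invisible(x)
}

#' @export
as.data.frame.fhr_report <- function(x, ...) {
  data.frame(loss_pct = x$loss_pct, basal = x$basal,
             fluctuation = x$fluctuation, acc_count = x$acc_count,
             dec_count = x$dec_count, oscillation = x$oscillation,
             ltv_dawes = x$ltv_dawes, stv_dawes = x$stv_dawes,
             lti = x$lti, sti = x$sti, ii = x$ii, di = x$di)
}
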