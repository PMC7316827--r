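#' Partition beats by maternal/fetal coincidence
#'
#' A maternal QRS window (100 ms full width, centered on the R fiducial)
#' is coincident when it overlaps any fetal QRS window (40 ms); the
#' relation is symmetric. Coincident beats corrupt per-beat power and
#' shape estimates and are excluded from them.
#'
#' @param m_locs,f_locs maternal and fetal R sample indices (vectors or
#'   [beat_ann()]), at the same rate.
#' @param rate sampling frequency in Hz.
#' @param m_width,f_width full window widths in ms.
#' @return list with `m_clear`, `f_clear` (non-coincident sample indices),
#'   counts `J` (non-coincident maternal) and `I` (non-coincident fetal),
#'   and the coincident subsets.
#' @export
coincidence_partition <- function(m_locs, f_locs, rate,
                                  m_width = 100, f_width = 40) {
  if (inherits(m_locs, "beat_ann")) m_locs <- m_locs$locations
  if (inherits(f_locs, "beat_ann")) f_locs <- f_locs$locations
  mh <- ms_to_samples(m_width / 2, rate)
  fh <- ms_to_samples(f_width / 2, rate)
  # centered intervals overlap iff |center difference| <= sum of half-widths
  tol <- mh + fh
  m_coinc <- rep(FALSE, length(m_locs))
  f_coinc <- rep(FALSE, length(f_locs))
  if (length(m_locs) && length(f_locs)) {
    fs <- sort(f_locs)
    pos <- findInterval(m_locs, fs)
    for (side in 0:1) {
      idx <- pmin(pmax(pos + side, 1), length(fs))
      m_coinc <- m_coinc | abs(m_locs - fs[idx]) <= tol
    }
    ms <- sort(m_locs)
    pos <- findInterval(f_locs, ms)
    for (side in 0:1) {
      idx <- pmin(pmax(pos + side, 1), length(ms))
      f_coinc <- f_coinc | abs(f_locs - ms[idx]) <= tol
    }
  }
  list(m_clear = m_locs[!m_coinc], f_clear = f_locs[!f_coinc],
       m_coincident = m_locs[m_coinc], f_coincident = f_locs[f_coinc],
       J = sum(!m_coinc), I = sum(!f_coinc))
}

# Logical mask of samples inside centered windows around beat locations.
window_mask <- function(n, locs, half) {
  mask <- logical(n)
  for (r in locs) {
    a <- max(1, r - half); b <- min(n, r + half)
    if (a <= b) mask[a:b] <- TRUE
  }
  mask
}

#' Decompose an abdominal channel into interference/maternal/fetal powers
#'
#' Assuming P and T waves are small and signal and interference are
#' uncorrelated, the mean interference power `P_N` is the mean square of
#' the signal outside every maternal (100 ms) and fetal (40 ms) QRS
#' window; `P_M` is the mean square inside non-coincident maternal windows
#' minus `P_N` (clipped at 0 and flagged when the subtraction goes
#' negative), and `P_F` analogously over non-coincident fetal windows.
#'
#' @param x numeric vector, one preprocessed abdominal channel.
#' @param m_locs,f_locs maternal/fetal annotations (vectors or
#'   [beat_ann()]).
#' @param rate sampling frequency in Hz.
#' @param m_width,f_width full QRS window widths in ms.
#' @return an object of class `power_decomposition`: `P_N`, `P_M`, `P_F`
#'   (microvolt^2; `NA` when no usable beats), counts `J`, `I`, and
#'   `clipped` flags.
#' @export
estimate_powers <- function(x, m_locs, f_locs, rate,
                            m_width = 100, f_width = 40) {
  if (inherits(m_locs, "beat_ann")) m_locs <- m_locs$locations
  if (inherits(f_locs, "beat_ann")) f_locs <- f_locs$locations
  n <- length(x)
  mh <- ms_to_samples(m_width / 2, rate)
  fh <- ms_to_samples(f_width / 2, rate)
  in_m <- window_mask(n, m_locs, mh)
  in_f <- window_mask(n, f_locs, fh)
  out <- !(in_m | in_f)
  if (!any(out)) stop("no samples outside QRS windows; cannot estimate P_N")
  P_N <- mean(x[out]^2)
  part <- coincidence_partition(m_locs, f_locs, rate, m_width, f_width)
  msq_in <- function(locs, half) {
    mask <- window_mask(n, locs, half)
    if (!any(mask)) return(NA_real_)
    mean(x[mask]^2)
  }
  raw_M <- if (part$J > 0) msq_in(part$m_clear, mh) - P_N else NA_real_
  raw_F <- if (part$I > 0) msq_in(part$f_clear, fh) - P_N else NA_real_
  clipped <- c(M = isTRUE(raw_M < 0), F = isTRUE(raw_F < 0))
  structure(list(P_N = P_N,
                 P_M = if (is.na(raw_M)) NA_real_ else max(raw_M, 0),
                 P_F = if (is.na(raw_F)) NA_real_ else max(raw_F, 0),
                 J = part$J, I = part$I, clipped = clipped),
            class = "power_decomposition")
}

#' @export
print.power_decomposition <- function(x, ...) {
  cat(sprintf(
    "<power_decomposition> P_N %.3g  P_M %.3g  P_F %.3g uV^2 (J=%d, I=%d)\n",
    x$P_N, x$P_M, x$P_F, x$J, x$I))
  invisible(x)
}

#' SNR indices from a power decomposition
#'
#' `WM = 10 log10(P_M / P_N)` and `WF = 10 log10(P_F / P_N)` in dB;
#' `WMF = WM - WF` estimates how many times the maternal QRS amplitude
#' exceeds the fetal one (`10^(WMF/20)` as an amplitude ratio). A zero or
#' clipped power yields `-Inf`.
#'
#' @param p a [estimate_powers()] result, or a list with `P_N`, `P_M`,
#'   `P_F`.
#' @return named vector `c(WM, WF, WMF)` in dB.
#' @export
snr_indices <- function(p) {
  stopifnot(p$P_N > 0)
  db <- function(num) {
    if (is.na(num)) return(NA_real_)
    if (num <= 0) return(-Inf)
    10 * log10(num / p$P_N)
  }
  WM <- db(p$P_M); WF <- db(p$P_F)
  c(WM = WM, WF = WF, WMF = WM - WF)
}

#' Per-beat amplitude change coefficients
#'
#' Projects each QRS complex onto the mean QRS shape:
#' `r_i = sum(QRS_avg * QRS_i) / sum(QRS_avg^2)` over a centered window of
#' `width_ms` (100 ms maternal, 40 ms fetal). Identical beats give
#' `r_i = 1`; a beat at twice the mean amplitude gives 2.
#'
#' @param x numeric vector, one channel.
#' @param beat_locs beat sample indices (vector or [beat_ann()]); normally
#'   the non-coincident subset from [coincidence_partition()].
#' @param rate sampling frequency in Hz.
#' @param width_ms full window width in ms.
#' @return numeric vector of `r_i`, one per usable (non-edge) beat.
#' @export
amplitude_change_coefficients <- function(x, beat_locs, rate, width_ms) {
  if (inherits(beat_locs, "beat_ann")) beat_locs <- beat_locs$locations
  half <- ms_to_samples(width_ms / 2, rate)
  usable <- beat_locs[beat_locs - half >= 1 & beat_locs + half <= length(x)]
  if (!length(usable)) stop("no complete beat windows")
  wins <- vapply(usable, function(r) x[(r - half):(r + half)],
                 numeric(2 * half + 1))
  avg <- rowMeans(wins)
  denom <- sum(avg^2)
  if (denom < 1e-20) stop("zero-energy mean QRS complex")
  as.numeric(crossprod(wins, avg)) / denom
}

#' QRS energy-variation index (WEM / WEF)
#'
#' Normalized variation of the per-beat projection coefficients: the root
#' mean squared successive difference of `r_i` divided by their mean.
#' Zero when amplitude and shape are perfectly stable. `method =
#' "raw"` uses plain (unsquared) successive differences under the root
#' instead; its radicand can be negative, in which case `NaN` is returned
#' with a warning.
#'
#' @param r coefficients from [amplitude_change_coefficients()].
#' @param method `"squared"` (default) or `"raw"`.
#' @return the index (dimensionless, >= 0 for `"squared"`).
#' @export
energy_variation_index <- function(r, method = c("squared", "raw")) {
  method <- match.arg(method)
  if (length(r) < 2) stop("at least two coefficients required")
  mr <- mean(r)
  if (mr <= 0) stop("mean amplitude coefficient must be positive")
  d <- diff(r)
  rad <- if (method == "squared") mean(d^2) else mean(d)
  if (rad < 0) {
    warning("negative radicand under the raw-difference form; returning NaN")
    return(NaN)
  }
  sqrt(rad) / mr
}

#' Quality report for a whole record
#'
#' Computes the power decomposition, the SNR indices WM/WF/WMF and the
#' energy-variation indices WEM/WEF for each abdominal channel, plus their
#' across-channel arithmetic mean (the per-record convention used in the
#' dataset summaries).
#'
#' @param bundle a [record_bundle()] with maternal and fetal annotations
#'   (fetal beats flagged 0 are excluded), or an [mcsignal()] plus
#'   explicit annotations.
#' @param m_locs,f_locs annotations when `bundle` is an [mcsignal()].
#' @param m_width,f_width QRS window widths in ms.
#' @return an object of class `quality_report`: data.frame `channels`
#'   (one row per channel) and numeric `mean` row.
#' @export
record_quality_report <- function(bundle, m_locs = NULL, f_locs = NULL,
                                  m_width = 100, f_width = 40) {
  if (inherits(bundle, "record_bundle")) {
    x <- bundle$abdominal_raw
    m_locs <- bundle$maternal_r
    f_locs <- bundle$fetal_r
  } else {
    x <- bundle
  }
  stopifnot(inherits(x, "mcsignal"))
  if (inherits(f_locs, "beat_ann") && !is.null(f_locs$flags))
    f_use <- f_locs$locations[f_locs$flags == 1]
  else f_use <- if (inherits(f_locs, "beat_ann")) f_locs$locations else f_locs
  m_use <- if (inherits(m_locs, "beat_ann")) m_locs$locations else m_locs
  rate <- x$rate
  part <- coincidence_partition(m_use, f_use, rate, m_width, f_width)
  rows <- lapply(seq_len(n_channels(x)), function(ch) {
    v <- channel(x, ch)
    p <- estimate_powers(v, m_use, f_use, rate, m_width, f_width)
    w <- snr_indices(p)
    wem <- if (part$J >= 2)
      energy_variation_index(
        amplitude_change_coefficients(v, part$m_clear, rate, m_width))
    else NA_real_
    wef <- if (part$I >= 2)
      energy_variation_index(
        amplitude_change_coefficients(v, part$f_clear, rate, f_width))
    else NA_real_
    data.frame(channel = x$labels[ch], WM = w[["WM"]], WF = w[["WF"]],
               WMF = w[["WMF"]], WEM = wem, WEF = wef,
               P_N = p$P_N, P_M = p$P_M, P_F = p$P_F)
  })
  channels <- do.call(rbind, rows)
  means <- colMeans(channels[, c("WM", "WF", "WMF", "WEM", "WEF")],
                    na.rm = TRUE)
  structure(list(channels = channels, mean = means, J = part$J, I = part$I),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  print(x$channels[, c("channel", "WM", "WF", "WMF", "WEM", "WEF")],
        row.names = FALSE, digits = 3)
  cat(sprintf("  mean: WM %.1f dB, WF %.1f dB, WMF %.1f dB, WEM %.2f, WEF %.2f\n",
              x$mean[["WM"]], x$mean[["WF"]], x$mean[["WMF"]],
              x$mean[["WEM"]], x$mean[["WEF"]]))
  cat(sprintf("  non-coincident beats: J = %d maternal, I = %d fetal\n",
              x$J, x$I))
  invisible(x)
}

#' Aggregate per-record summaries into dataset means
#'
#' The dataset-level summary convention: the arithmetic mean of each
#' numeric column over records. Used both for batches of
#' [record_quality_report()] / [fhr_report()] rows and for the published
#' per-record summary tables shipped in `inst/extdata`.
#'
#' @param df data.frame with one row per record.
#' @param cols columns to average; defaults to all numeric columns.
#' @return named numeric vector of column means (NA removed).
#' @export
aggregate_record_summaries <- function(df, cols = NULL) {
  if (is.null(cols)) cols <- names(df)[vapply(df, is.numeric, logical(1))]
  colMeans(df[, cols, drop = FALSE], na.rm = TRUE)
}
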