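#' Convert a duration in milliseconds to a sample count
#'
#' @param ms duration in milliseconds.
#' @param rate sampling frequency in Hz.
#' @return integer number of samples, rounded to nearest.
#' @export
ms_to_samples <- function(ms, rate) as.integer(round(ms * rate / 1000))

#' Convert sample counts or indices to milliseconds
#'
#' Sample index 1 maps to time 0 ms (indices are 1-based).
#'
#' @param samples sample counts (durations) or use [index_to_ms()] for indices.
#' @param rate sampling frequency in Hz.
#' @return time in milliseconds.
#' @export
samples_to_ms <- function(samples, rate) samples * 1000 / rate

#' @rdname samples_to_ms
#' @param index 1-based sample indices.
#' @export
index_to_ms <- function(index, rate) (index - 1) * 1000 / rate

#' Heart-rate / interval conversions
#'
#' Instantaneous heart rate in beats per minute and the RR interval in
#' milliseconds are reciprocal: `bpm = 60000 / rr_ms`.
#'
#' @param bpm heart rate in beats per minute.
#' @param rr_ms RR interval in milliseconds.
#' @return the converted value.
#' @export
bpm_to_rr_ms <- function(bpm) 60000 / bpm

#' @rdname bpm_to_rr_ms
#' @export
rr_ms_to_bpm <- function(rr_ms) 60000 / rr_ms

# Running mean that ignores NA, window of `k` samples (odd), centered.
runmean_na <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1
  n <- length(x)
  v <- ifelse(is.na(x), 0, x)
  w <- as.numeric(!is.na(x))
  kern <- rep(1, k)
  num <- stats::filter(c(rep(0, k), v, rep(0, k)), kern, sides = 2)
  den <- stats::filter(c(rep(0, k), w, rep(0, k)), kern, sides = 2)
  out <- as.numeric(num / pmax(den, 1e-12))[(k + 1):(k + n)]
  out[den[(k + 1):(k + n)] < 0.5] <- NA_real_
  out
}

# Local maxima of a numeric vector (strictly greater than left neighbour,
# >= right neighbour; endpoints excluded).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}
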