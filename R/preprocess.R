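#' Comb filter specification
#'
#' The preprocessing filter places notches at 0 Hz and every multiple of
#' 50 Hz, suppressing both slow-changing interference and powerline pickup
#' in one pass:
#'
#'   H(z) = z^-5d - (1/36) * ((1 - z^-6d) / (1 - z^-d))^2
#'
#' where `d` is the comb tap spacing in samples (10 at 500 Hz, scaling
#' linearly with the rate so the notch frequencies stay put). The quotient
#' is a finite geometric sum, so the filter is realized as an explicit
#' linear-phase FIR of order `10 d` (101 taps at 500 Hz) whose group delay
#' is exactly `5 d` samples; no pole-zero cancellation is involved.
#'
#' @param rate sampling frequency in Hz; must be a multiple of 100 so the
#'   50 Hz notches fall on integer tap spacings.
#' @return an object of class `comb_spec` with fields `base_delay`,
#'   `comb_tap_spacing`, `comb_span`, `normalizer`, `rate` and the expanded
#'   FIR `taps`.
#' @export
comb_spec <- function(rate = 500) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 ||
      rate %% 100 != 0)
    stop("comb filter requires a sampling rate that is a multiple of 100 Hz; ",
         "got ", rate)
  d <- as.integer(rate / 50)          # tap spacing: one notch every 50 Hz
  # ((1 - z^-6d)/(1 - z^-d))^2 = (sum_{j=0}^{5} z^-jd)^2: triangular weights
  cj <- c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2, 1)
  taps <- numeric(10L * d + 1L)
  taps[(0:10) * d + 1L] <- -cj / 36
  taps[5L * d + 1L] <- taps[5L * d + 1L] + 1   # the z^-5d branch
  structure(list(base_delay = 5L * d, comb_tap_spacing = d,
                 comb_span = 6L * d, normalizer = 36L, rate = rate,
                 taps = taps),
            class = "comb_spec")
}

#' @export
print.comb_spec <- function(x, ...) {
  cat(sprintf(
    "<comb_spec> rate %g Hz: delays (%d, %d, %d), 1/%d, %d FIR taps\n",
    x$rate, x$base_delay, x$comb_tap_spacing, x$comb_span, x$normalizer,
    length(x$taps)))
  invisible(x)
}

#' Complex frequency response of the comb filter
#'
#' @param spec a [comb_spec()].
#' @param freqs frequencies in Hz.
#' @return complex response `H(e^{j 2 pi f / rate})`.
#' @export
comb_response <- function(spec, freqs) {
  stopifnot(inherits(spec, "comb_spec"))
  w <- 2 * pi * freqs / spec$rate
  n <- seq_along(spec$taps) - 1
  vapply(w, function(wi) sum(spec$taps * exp(-1i * wi * n)), complex(1))
}

#' Passband edge of the comb filter
#'
#' Lowest frequency at which the magnitude response first reaches the
#' -3 dB level, found by bisection between 0 Hz and the first notch at
#' 50 Hz. Approximately 5 Hz at any supported rate.
#'
#' @param spec a [comb_spec()].
#' @return frequency in Hz.
#' @export
comb_passband_edge <- function(spec) {
  f <- function(fr) abs(comb_response(spec, fr)) - 1 / sqrt(2)
  grid <- seq(0.05, 45, by = 0.05)
  vals <- vapply(grid, f, numeric(1))
  cross <- which(vals[-1] > 0 & vals[-length(vals)] <= 0)[1]
  if (is.na(cross)) stop("no -3 dB crossing found below 45 Hz")
  stats::uniroot(f, grid[c(cross, cross + 1)], tol = 1e-6)$root
}

#' Apply the multi-notch comb filter
#'
#' Filters every channel with the linear-phase FIR realization of the comb
#' filter, compensating the group delay (`5 d` samples) so beats stay
#' time-aligned with the input. Edges are handled by reflect-padding with
#' one filter length and trimming, so the output is deterministic and the
#' same length as the input.
#'
#' @param x an [mcsignal()] or a numeric vector.
#' @param spec a [comb_spec()]; defaults to the spec for `x$rate`.
#' @return filtered signal of the same class and shape as `x`.
#' @export
comb_filter <- function(x, spec = NULL) {
  if (inherits(x, "mcsignal")) {
    if (is.null(spec)) spec <- comb_spec(x$rate)
    if (spec$rate != x$rate) stop("spec rate does not match signal rate")
    out <- x
    out$samples <- t(apply(x$samples, 1, comb_filter_vec, spec = spec))
    rownames(out$samples) <- x$labels
    return(out)
  }
  if (is.null(spec)) stop("a comb_spec is required for plain vectors")
  comb_filter_vec(x, spec)
}

comb_filter_vec <- function(v, spec) {
  L <- length(spec$taps)
  if (length(v) <= L)
    stop("signal shorter than the comb filter order (", L, " samples)")
  # reflect-pad one filter length at both ends (no edge-sample repetition)
  pad_l <- v[(L + 1):2]
  pad_r <- v[(length(v) - 1):(length(v) - L)]
  vp <- c(pad_l, v, pad_r)
  # sides = 2 centers the odd-length kernel: delay 5d is compensated exactly
  y <- stats::filter(vp, spec$taps, method = "convolution", sides = 2)
  as.numeric(y[(L + 1):(L + length(v))])
}

#' Preprocess an abdominal or direct FECG signal
#'
#' Convenience wrapper: builds the rate-adapted [comb_spec()] and applies
#' [comb_filter()].
#'
#' @param x an [mcsignal()].
#' @return the filtered [mcsignal()].
#' @export
preprocess_signal <- function(x) {
  stopifnot(inherits(x, "mcsignal"))
  comb_filter(x, comb_spec(x$rate))
}
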