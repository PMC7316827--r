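#' Match detected beats against a reference within a tolerance window
#'
#' One-to-one, order-preserving assignment between reference and test
#' annotation series: a pair can match only when the beats are no more
#' distant than the tolerance (40 ms, about one fetal QRS width), and
#' among assignments with the maximal number of matches the one with the
#' smallest total absolute offset is chosen (dynamic programming, not
#' greedy nearest-neighbour, so results are deterministic and optimal).
#' Unmatched test beats are false positives, unmatched reference beats
#' false negatives.
#'
#' @param reference,test strictly increasing sample indices (vectors or
#'   [beat_ann()]), at the same rate.
#' @param rate sampling frequency in Hz.
#' @param tolerance_ms matching tolerance (inclusive) in ms.
#' @return an object of class `beat_match`: counts `TP`, `FP`, `FN`, `N`,
#'   the matched `pairs` (data.frame ref/test indices and offset in
#'   samples) and the tolerance.
#' @export
match_beats <- function(reference, test, rate, tolerance_ms = 40) {
  if (inherits(reference, "beat_ann")) reference <- reference$locations
  if (inherits(test, "beat_ann")) test <- test$locations
  tol <- tolerance_ms * rate / 1000
  n <- length(reference); m <- length(test)
  pairs <- data.frame(ref = integer(0), test = integer(0),
                      offset = numeric(0))
  if (n && m) {
    # DP over prefixes: score = matches * BIG - total offset
    BIG <- (sum(rep(tol, min(n, m))) + 1) * 4 + 1e6
    S <- matrix(0, n + 1, m + 1)
    for (i in 1:n) {
      ri <- reference[i]
      Sprev <- S[i, ]         # row i (prefix i-1 of reference)
      Scur <- numeric(m + 1)
      Scur[1] <- Sprev[1]
      for (j in 1:m) {
        best <- max(Sprev[j + 1], Scur[j])
        d <- abs(test[j] - ri)
        if (d <= tol) {
          cand <- Sprev[j] + BIG - d
          if (cand > best) best <- cand
        }
        Scur[j + 1] <- best
      }
      S[i + 1, ] <- Scur
    }
    # backtrack
    i <- n; j <- m
    ref_idx <- integer(0); test_idx <- integer(0)
    while (i > 0 && j > 0) {
      d <- abs(test[j] - reference[i])
      if (d <= tol && S[i + 1, j + 1] == S[i, j] + BIG - d) {
        ref_idx <- c(i, ref_idx); test_idx <- c(j, test_idx)
        i <- i - 1; j <- j - 1
      } else if (S[i + 1, j + 1] == S[i, j + 1]) {
        i <- i - 1
      } else {
        j <- j - 1
      }
    }
    if (length(ref_idx))
      pairs <- data.frame(ref = ref_idx, test = test_idx,
                          offset = test[test_idx] - reference[ref_idx])
  }
  TP <- nrow(pairs)
  structure(list(TP = TP, FP = m - TP, FN = n - TP, N = n, pairs = pairs,
                 tolerance_ms = tolerance_ms, rate = rate,
                 reference = reference, test = test),
            class = "beat_match")
}

#' @export
print.beat_match <- function(x, ...) {
  cat(sprintf("<beat_match> N=%d TP=%d FP=%d FN=%d (tolerance %g ms)\n",
              x$N, x$TP, x$FP, x$FN, x$tolerance_ms))
  invisible(x)
}

#' Detection performance indices
#'
#' `PI = (N - FP - FN)/N`, `Acc = TP/(TP+FP+FN)`, `Se = TP/(TP+FN)`,
#' `PPV = TP/(TP+FP)` and their harmonic mean
#' `F1 = 2 Se PPV/(Se+PPV) = 2TP/(2TP+FN+FP)`, all in percent. Undefined
#' ratios (zero denominators) are returned as `NA`.
#'
#' @param m a [match_beats()] result, or a list with `TP`, `FP`, `FN`,
#'   `N`.
#' @return named vector `c(PI, Acc, Se, PPV, F1)` in percent.
#' @export
performance_indices <- function(m) {
  TP <- m$TP; FP <- m$FP; FN <- m$FN
  N <- if (!is.null(m$N)) m$N else TP + FN
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(PI = pct(N - FP - FN, N),
    Acc = pct(TP, TP + FP + FN),
    Se = pct(TP, TP + FN),
    PPV = pct(TP, TP + FP),
    F1 = pct(2 * TP, 2 * TP + FN + FP))
}

#' F1 and accuracy implied by sensitivity and positive predictivity
#'
#' Recovers the harmonic-mean F1 and the accuracy `TP/(TP+FP+FN)` from a
#' published (Se, PPV) operating point alone, using
#' `FN/TP = (100-Se)/Se` and `FP/TP = (100-PPV)/PPV`.
#'
#' @param se,ppv sensitivity and positive predictive value in percent.
#' @return named vector `c(F1, Acc)` in percent.
#' @export
indices_from_se_ppv <- function(se, ppv) {
  f1 <- 2 * se * ppv / (se + ppv)
  acc <- 100 / (1 + (100 - se) / se + (100 - ppv) / ppv)
  c(F1 = f1, Acc = acc)
}

#' RR-interval accuracy of matched detections
#'
#' For every pair of consecutive reference beats whose both endpoints were
#' matched, the interval error `dRR = RR_test - RR_ref` is computed. The
#' summary gives the mean signed error, the mean absolute error in ms and
#' in bpm (`|60000/RR_test - 60000/RR_ref|`) and the standard deviation.
#'
#' @param m a [match_beats()] result.
#' @return an object of class `rr_accuracy`: `mean_dRR`, `mean_abs_dRR`,
#'   `mean_abs_dRR_bpm`, `sd_dRR`, `n_intervals`.
#' @export
rr_accuracy <- function(m) {
  stopifnot(inherits(m, "beat_match"))
  empty <- structure(list(mean_dRR = NA_real_, mean_abs_dRR = NA_real_,
                          mean_abs_dRR_bpm = NA_real_, sd_dRR = NA_real_,
                          n_intervals = 0L),
                     class = "rr_accuracy")
  if (nrow(m$pairs) < 2) return(empty)
  p <- m$pairs[order(m$pairs$ref), ]
  consec <- which(diff(p$ref) == 1)
  if (!length(consec)) return(empty)
  to_ms <- 1000 / m$rate
  rr_ref <- (m$reference[p$ref[consec + 1]] -
             m$reference[p$ref[consec]]) * to_ms
  rr_test <- (m$test[p$test[consec + 1]] -
              m$test[p$test[consec]]) * to_ms
  d <- rr_test - rr_ref
  structure(list(mean_dRR = mean(d), mean_abs_dRR = mean(abs(d)),
                 mean_abs_dRR_bpm = mean(abs(60000 / rr_test -
                                             60000 / rr_ref)),
                 sd_dRR = stats::sd(d), n_intervals = length(d)),
            class = "rr_accuracy")
}

#' @export
print.rr_accuracy <- function(x, ...) {
  cat(sprintf(
    "<rr_accuracy> mean dRR %.2f ms, |dRR| %.2f ms (%.2f bpm), sd %.2f ms, n=%d\n",
    x$mean_dRR, x$mean_abs_dRR, x$mean_abs_dRR_bpm, x$sd_dRR,
    x$n_intervals))
  invisible(x)
}
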