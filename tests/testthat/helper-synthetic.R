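# Shared builders for synthetic fixtures (everything is generated in code).

# Spike train: unit impulses at the given sample indices.
spike_train <- function(n, locs, amp = 1) {
  v <- numeric(n)
  v[locs] <- amp
  v
}

# Periodic beat train rendered with a given morphology.
beat_trace <- function(n, locs, kind = "fetal", rate = 500, amp = 1) {
  shape <- synth_beat_morphology(kind, rate)
  amp * fetalecg:::render_beats(n, locs, shape)
}

# Strictly increasing random annotation locations.
random_locs <- function(n, max_idx, min_gap = 1) {
  sort(sample.int(max_idx, n)) |> (\(x) x[c(TRUE, diff(x) >= min_gap)])()
}

# Brute-force optimal one-to-one beat assignment (independent oracle for
# the DP matcher): maximize matches, then minimize total |offset|, over
# all injective pairings within tolerance.
brute_force_match <- function(reference, test, tol) {
  best <- list(tp = -1, cost = Inf)
  n <- length(reference)
  recurse <- function(i, used, tp, cost) {
    if (i > n) {
      if (tp > best$tp || (tp == best$tp && cost < best$cost))
        best <<- list(tp = tp, cost = cost)
      return(invisible())
    }
    recurse(i + 1, used, tp, cost)            # leave reference i unmatched
    for (j in seq_along(test)) {
      if (used[j]) next
      d <- abs(test[j] - reference[i])
      if (d <= tol) {
        used[j] <- TRUE
        recurse(i + 1, used, tp + 1, cost + d)
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, length(test)), 0, 0)
  best
}

# Brute-force interval-overlap coincidence oracle (all pairs).
brute_force_coincidence <- function(m_locs, f_locs, rate,
                                    m_width = 100, f_width = 40) {
  mh <- fetalecg::ms_to_samples(m_width / 2, rate)
  fh <- fetalecg::ms_to_samples(f_width / 2, rate)
  m_coinc <- vapply(m_locs, function(m)
    any(m - mh <= f_locs + fh & f_locs - fh <= m + mh), logical(1))
  f_coinc <- vapply(f_locs, function(f)
    any(f - fh <= m_locs + mh & m_locs - mh <= f + fh), logical(1))
  list(J = sum(!m_coinc), I = sum(!f_coinc),
       m_clear = m_locs[!m_coinc], f_clear = f_locs[!f_coinc])
}

# Brute-force RR-variability functional (double loop over the raw series).
brute_force_delta <- function(rr) {
  I <- length(rr) + 1
  if (I < 4) return(NA_real_)
  total <- 0
  for (i in 1:(I - 3))
    total <- total + abs((rr[i + 2] - rr[i + 1]) - (rr[i + 1] - rr[i]))
  total / (I - 3)
}
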