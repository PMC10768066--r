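# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

# artifact mask straight from the definition: loop over samples, recompute
# median and raw MAD of the valid samples each time
oracle_detect <- function(x, k = 3, eps = 0.01) {
  valid <- x[!is.na(x)]
  med <- median(valid)
  mad_raw <- median(abs(valid - med))
  thr <- max(k * mad_raw, eps)
  out <- logical(length(x))
  for (i in seq_along(x)) {
    out[i] <- is.na(x[i]) || abs(x[i] - med) > thr
  }
  out
}

# margin expansion sample by sample: a sample is flagged iff some originally
# flagged sample lies within [i - fwd, i + back] of it
oracle_expand <- function(mask, fs, pre_ms = 35, post_ms = 100) {
  back <- ceiling(pre_ms / 1000 * fs)
  fwd <- ceiling(post_ms / 1000 * fs)
  n <- length(mask)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - fwd)   # a flag up to `fwd` samples before i covers i
    hi <- min(n, i + back)  # a flag up to `back` samples after i covers i
    out[i] <- any(mask[lo:hi])
  }
  out
}

# cubic spline with Forsythe-Malcolm-Moler end conditions (the spline's third
# derivative at each boundary matches the exact cubic through the four
# nearest points), solved as a dense linear system in the knot second
# derivatives
oracle_spline <- function(xk, yk, xout) {
  n <- length(xk)
  third_deriv <- function(x4, y4) {
    x4 <- x4 - x4[1]  # local coordinates for conditioning; S''' is invariant
    co <- solve(outer(x4, 0:3, `^`), y4)  # exact cubic through 4 points
    6 * co[4]
  }
  h <- diff(xk)
  # tridiagonal system in the knot second derivatives, solved by forward
  # elimination / back substitution
  lo <- di <- up <- b <- numeric(n)
  # boundary rows: (sig2 - sig1)/h1 = S''' on the first interval, same at end
  di[1] <- -1; up[1] <- 1; b[1] <- h[1] * third_deriv(xk[1:4], yk[1:4])
  lo[n] <- -1; di[n] <- 1
  b[n] <- h[n - 1] * third_deriv(xk[(n - 3):n], yk[(n - 3):n])
  for (i in 2:(n - 1)) {
    lo[i] <- h[i - 1]
    di[i] <- 2 * (h[i - 1] + h[i])
    up[i] <- h[i]
    b[i] <- 6 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1])
  }
  for (i in 2:n) {
    w <- lo[i] / di[i - 1]
    di[i] <- di[i] - w * up[i - 1]
    b[i] <- b[i] - w * b[i - 1]
  }
  sig <- numeric(n)
  sig[n] <- b[n] / di[n]
  for (i in (n - 1):1) sig[i] <- (b[i] - up[i] * sig[i + 1]) / di[i]
  vapply(xout, function(x) {
    i <- min(max(which(xk <= x)), n - 1)
    u <- x - xk[i]
    slope <- (yk[i + 1] - yk[i]) / h[i] - h[i] * (2 * sig[i] + sig[i + 1]) / 6
    yk[i] + slope * u + sig[i] / 2 * u^2 +
      (sig[i + 1] - sig[i]) / (6 * h[i]) * u^3
  }, numeric(1))
}

# windowed maximum by explicit loop
oracle_windowed_max <- function(t, v, lo, hi) {
  best <- -Inf
  for (i in seq_along(t)) {
    if (t[i] >= lo && t[i] < hi && v[i] > best) best <- v[i]
  }
  best
}

# logistic observer for the ripple staircase: p(correct) falls with ripple
# density, crossing 0.5 at theta
logistic_observer <- function(theta, width = 0.5) {
  function(target_rpo) runif(1) < plogis(-(target_rpo - theta) / width)
}

# one-row profile with explicit latent parameters (bypasses the covariate
# links) for targeted trace/curve tests
make_profile <- function(tip = 10, amp = 5, width = 8, srt = 8, slope = 0.25,
                         baseline = 4, blink = 0.2, id = "P01") {
  data.frame(participant_id = id, age = 50, ci_duration = 40, sex = "F",
             word_recognition = 80, t_level = 30, qol_total = 65,
             matrices_correct = 18, stroop_interference = -0.1,
             stroop_control_rt = 0.75, nback_dprime = 1.5,
             smrt_threshold = 2, latent_tip_snr = tip, latent_peak_amp = amp,
             latent_curve_width = width, latent_srt = srt,
             latent_slope = slope, latent_baseline_mm = baseline,
             latent_blink_rate = blink, stringsAsFactors = FALSE)
}

# minimal one-trial events row with the standard 2 s / 2 s timeline
make_event <- function(snr = 8, onset = 2, dur = 2, id = "T001", pid = "P01") {
  data.frame(participant_id = pid, trial_id = id, snr = snr,
             noise_onset = onset - 2, sentence_onset = onset,
             sentence_offset = onset + dur, prompt_time = onset + dur + 2,
             n_keywords = 4, keywords_correct = NA_integer_,
             tlx_score = NA_real_, stringsAsFactors = FALSE)
}

# effect configuration with every covariate link and latent noise switched off
zero_link_config <- function(...) {
  effect_config(tip_slope = 0, srt_slope = 0, amp_matrices = 0, amp_qol = 0,
                smrt_word = 0, ...)
}
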