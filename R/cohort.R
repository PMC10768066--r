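# Synthetic cohort: participant profiles, trial schedules, behavior and raw
# pupil traces with known ground truth, emulating a speech-in-noise
# pupillometry study in adult cochlear-implant users (17 participants, 6 SNR
# conditions 0-20 dB in 4 dB steps, 40 sentences per condition).

#' Default simulation parameters for the synthetic cohort
#'
#' Encodes the generative model: an inverted-U (Gaussian-bump) effort curve
#' over SNR with a participant-specific tipping point that decreases with
#' clinical word recognition, a logistic intelligibility function, and nuisance
#' parameters for the pupil trace (baseline diameter, measurement noise, blink
#' statistics).
#'
#' Latent links (before noise):
#' \itemize{
#'   \item `tip_snr = tip_intercept - tip_slope * word_recognition` (dB) —
#'     higher word recognition tips at lower SNR; defaults map word
#'     recognition 50–100\% onto tipping points 17–10 dB, the monotone branch
#'     of the curvature-vs-tipping-point relation, so that the fitted
#'     quadratic coefficient decreases with word recognition as observed.
#'   \item `srt = srt_intercept - srt_slope * word_recognition` (dB), the
#'     50\%-intelligibility point.
#'   \item `peak_amp = amp_base + amp_matrices * (matrices - 18) +
#'     amp_qol * (qol - 65)` (\% relative dilation), so nonverbal intelligence
#'     and quality of life shift the overall effort level.
#'   \item `smrt = smrt_base + smrt_word * (word_recognition - 50)` (RPO).
#' }
#'
#' @param tip_intercept,tip_slope,tip_noise_sd tipping-point link (dB, dB/\%).
#' @param srt_intercept,srt_slope,srt_noise_sd speech-reception-threshold link.
#' @param slope_mean,slope_sd psychometric slope (per dB) of intelligibility.
#' @param amp_base,amp_matrices,amp_qol,amp_noise_sd peak-amplitude link (\%).
#' @param curve_width_range half-width (dB) of the effort bump, uniform draw.
#' @param word_recognition_range percent-correct-in-quiet range, uniform draw.
#' @param smrt_base,smrt_word,smrt_noise_sd spectral-ripple threshold link.
#' @param covariate_noise_sd multiplier on every `*_noise_sd` above; 0 makes
#'   all latent links deterministic.
#' @param baseline_mm_range,blink_rate_range,trace_noise_sd_mm pupil-trace
#'   nuisance parameters (mm, events/s, mm).
#' @param hippus_amp_mm,hippus_freq_range spontaneous slow pupil oscillation
#'   (hippus): sinusoid amplitude (mm) and frequency range (Hz). This is the
#'   dominant within-trial variability of real traces and sets the scale the
#'   MAD artifact threshold adapts to.
#' @param dropout_prob,dropout_dur_range probability that a trial contains a
#'   long eye-tracking dropout episode, and its duration range (s); such
#'   trials drive the interpolated-fraction exclusion rule.
#' @param ppd_noise_sd trial-to-trial SD of peak pupil dilation (\%) used by
#'   [simulate_ppd_trials()].
#' @param tlx_intercept,tlx_snr_slope,tlx_noise_sd condition-level NASA-TLX
#'   generator (score 0–100, decreasing in SNR).
#' @return a named list of class `"pupilci_effect_config"`.
#' @export
effect_config <- function(tip_intercept = 24, tip_slope = 0.14, tip_noise_sd = 1.0,
                          srt_intercept = 33, srt_slope = 0.32, srt_noise_sd = 1.0,
                          slope_mean = 0.25, slope_sd = 0.04,
                          amp_base = 6, amp_matrices = -0.15, amp_qol = 0.08,
                          amp_noise_sd = 0.8,
                          curve_width_range = c(6, 10),
                          word_recognition_range = c(50, 100),
                          smrt_base = 0.8, smrt_word = 0.04, smrt_noise_sd = 0.5,
                          covariate_noise_sd = 1,
                          baseline_mm_range = c(3.5, 5.5),
                          blink_rate_range = c(0.1, 0.3),
                          trace_noise_sd_mm = 0.02,
                          hippus_amp_mm = 0.15,
                          hippus_freq_range = c(0.1, 0.3),
                          dropout_prob = 0.12,
                          dropout_dur_range = c(2, 5),
                          ppd_noise_sd = 2.5,
                          tlx_intercept = 85, tlx_snr_slope = -2.2,
                          tlx_noise_sd = 8) {
  if (tip_slope < 0 || srt_slope < 0) {
    stop("tip_slope and srt_slope must be >= 0 (higher word recognition ",
         "implies lower tipping point and lower SRT)", call. = FALSE)
  }
  if (covariate_noise_sd < 0) stop("covariate_noise_sd must be >= 0", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "pupilci_effect_config"
  cfg
}

#' Generate synthetic participant profiles
#'
#' Draws `n` participants with demographic, audiological and cognitive
#' covariates plus the latent parameters (`latent_*` columns) that drive their
#' simulated pupil and behavioral data. The generating association between
#' word recognition and the effort-curve tipping point is negative by
#' construction (strength set in `config`).
#'
#' @param n number of participants (>= 2).
#' @param config an [effect_config()] list.
#' @param seed integer seed; identical inputs give identical output.
#' @return a data.frame with one row per participant: `participant_id`, `age`
#'   (years), `ci_duration` (months, >= 12), `sex`, `word_recognition` (\%),
#'   `t_level` (dB, free-field threshold), `qol_total` (0–100),
#'   `matrices_correct`, `stroop_interference`, `stroop_control_rt` (s),
#'   `nback_dprime`, `smrt_threshold` (RPO), and ground-truth columns
#'   `latent_tip_snr`, `latent_peak_amp`, `latent_curve_width`, `latent_srt`,
#'   `latent_slope`, `latent_baseline_mm`, `latent_blink_rate`.
#' @export
generate_profiles <- function(n, config = effect_config(), seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single number >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  k <- config$covariate_noise_sd
  local_seed(seed, {
    word_recognition <- round(stats::runif(n, config$word_recognition_range[1],
                                           config$word_recognition_range[2]), 1)
    age <- round(stats::runif(n, 27, 69))
    ci_duration <- round(stats::runif(n, 12, 59))
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(10, 7) / 17)
    t_level <- round(stats::rnorm(n, 30, 5), 1)
    qol_total <- round(clamp(stats::rnorm(n, 65, 12), 0, 100), 1)
    matrices_correct <- pmax(0L, as.integer(round(stats::rnorm(n, 18, 4))))
    stroop_interference <- round(clamp(stats::rnorm(n, -0.1, 0.08), -1, 1), 3)
    stroop_control_rt <- round(pmax(0.3, stats::rnorm(n, 0.75, 0.15)), 3)
    nback_dprime <- round(stats::rnorm(n, 1.5, 0.8), 2)

    tip_snr <- config$tip_intercept - config$tip_slope * word_recognition +
      stats::rnorm(n, 0, k * config$tip_noise_sd)
    srt <- config$srt_intercept - config$srt_slope * word_recognition +
      stats::rnorm(n, 0, k * config$srt_noise_sd)
    slope <- pmax(0.05, stats::rnorm(n, config$slope_mean, k * config$slope_sd))
    peak_amp <- pmax(0.5, config$amp_base +
                       config$amp_matrices * (matrices_correct - 18) +
                       config$amp_qol * (qol_total - 65) +
                       stats::rnorm(n, 0, k * config$amp_noise_sd))
    curve_width <- stats::runif(n, config$curve_width_range[1],
                                config$curve_width_range[2])
    smrt_threshold <- round(pmax(0.2, config$smrt_base +
                                   config$smrt_word * (word_recognition - 50) +
                                   stats::rnorm(n, 0, k * config$smrt_noise_sd)), 2)
    baseline_mm <- stats::runif(n, config$baseline_mm_range[1],
                                config$baseline_mm_range[2])
    blink_rate <- stats::runif(n, config$blink_rate_range[1],
                               config$blink_rate_range[2])

    data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      age = age, ci_duration = ci_duration, sex = sex,
      word_recognition = word_recognition, t_level = t_level,
      qol_total = qol_total, matrices_correct = matrices_correct,
      stroop_interference = stroop_interference,
      stroop_control_rt = stroop_control_rt,
      nback_dprime = nback_dprime, smrt_threshold = smrt_threshold,
      latent_tip_snr = tip_snr, latent_peak_amp = peak_amp,
      latent_curve_width = curve_width, latent_srt = srt,
      latent_slope = slope, latent_baseline_mm = baseline_mm,
      latent_blink_rate = blink_rate,
      stringsAsFactors = FALSE
    )
  })
}

#' Default trial-schedule design
#'
#' Six SNR levels (0–20 dB in 4 dB steps), two 20-sentence lists per level:
#' 240 trials per participant. Background noise starts 2 s before sentence
#' onset (the baseline window) and the response prompt comes 2 s after
#' sentence offset.
#'
#' @param snr_levels SNR grid in dB.
#' @param lists_per_snr,sentences_per_list list structure per SNR condition.
#' @param sentence_dur_range uniform range (s) of sentence durations.
#' @param n_keywords scoreable keywords per sentence.
#' @param baseline_s noise lead-in before sentence onset (s).
#' @param post_offset_s noise tail between sentence offset and prompt (s).
#' @param iti_s gap between a trial's prompt and the next trial's noise onset.
#' @return a named list of class `"pupilci_design"`.
#' @export
trial_design <- function(snr_levels = c(0, 4, 8, 12, 16, 20),
                         lists_per_snr = 2, sentences_per_list = 20,
                         sentence_dur_range = c(1.5, 3.0),
                         n_keywords = 4, baseline_s = 2.0,
                         post_offset_s = 2.0, iti_s = 2.0) {
  if (length(snr_levels) < 1 || lists_per_snr < 1 || sentences_per_list < 1) {
    stop("empty design", call. = FALSE)
  }
  d <- as.list(environment())
  class(d) <- "pupilci_design"
  d
}

#' Build a participant's randomized trial schedule
#'
#' Lists are presented as blocks (one list = one block of consecutive
#' sentences at a fixed SNR); block order is randomized. Event times are
#' session-continuous seconds from recording start.
#'
#' @param profile one-row data.frame from [generate_profiles()] (used for the
#'   participant id).
#' @param design a [trial_design()] list.
#' @param seed integer seed.
#' @return a data.frame of trial events: `participant_id`, `trial_id`, `snr`,
#'   `noise_onset`, `sentence_onset`, `sentence_offset`, `prompt_time` (s),
#'   `n_keywords`, and `keywords_correct`/`tlx_score` initialized to `NA`
#'   (filled by [simulate_behavior()]).
#' @export
build_schedule <- function(profile, design = trial_design(), seed = 1) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  local_seed(seed, {
    blocks <- rep(design$snr_levels, each = design$lists_per_snr)
    blocks <- blocks[sample.int(length(blocks))]
    snr <- rep(blocks, each = design$sentences_per_list)
    n <- length(snr)
    dur <- stats::runif(n, design$sentence_dur_range[1],
                        design$sentence_dur_range[2])
    trial_span <- design$baseline_s + dur + design$post_offset_s
    noise_onset <- cumsum(c(0, (trial_span + design$iti_s)[-n]))
    sentence_onset <- noise_onset + design$baseline_s
    sentence_offset <- sentence_onset + dur
    prompt_time <- sentence_offset + design$post_offset_s
    data.frame(
      participant_id = profile$participant_id,
      trial_id = sprintf("%s_T%03d", profile$participant_id, seq_len(n)),
      snr = snr,
      noise_onset = noise_onset, sentence_onset = sentence_onset,
      sentence_offset = sentence_offset, prompt_time = prompt_time,
      n_keywords = design$n_keywords,
      keywords_correct = NA_integer_, tlx_score = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

latent <- function(profile, what) {
  v <- profile[[paste0("latent_", what)]]
  if (is.null(v)) stop("profile lacks latent parameter '", what, "'", call. = FALSE)
  v
}

#' Expected peak pupil dilation at a given SNR
#'
#' The participant's effort curve: a Gaussian bump
#' `amp * exp(-(snr - tip)^2 / (2 w^2))`, unimodal and symmetric about the
#' tipping point `tip`, where it attains the participant's peak amplitude.
#'
#' @param snr SNR in dB (vectorized).
#' @param profile one-row profile with `latent_tip_snr`, `latent_peak_amp`,
#'   `latent_curve_width`.
#' @return expected peak pupil dilation in percent relative change (> 0).
#' @export
effort_peak <- function(snr, profile) {
  stopifnot(all(is.finite(snr)))
  amp <- latent(profile, "peak_amp")
  tip <- latent(profile, "tip_snr")
  w <- latent(profile, "curve_width")
  amp * exp(-(snr - tip)^2 / (2 * w^2))
}

#' Probability of reporting a keyword correctly at a given SNR
#'
#' Logistic psychometric function `1 / (1 + exp(-slope * (snr - srt)))`:
#' strictly increasing in SNR and equal to 0.5 at the participant's speech
#' reception threshold (SRT).
#'
#' @param snr SNR in dB (vectorized).
#' @param profile one-row profile with `latent_srt`, `latent_slope`.
#' @return probability in (0, 1).
#' @export
intelligibility <- function(snr, profile) {
  slope <- latent(profile, "slope")
  if (slope <= 0) stop("psychometric slope must be > 0", call. = FALSE)
  stats::plogis(slope * (snr - latent(profile, "srt")))
}

#' Simulate behavioral outcomes for a trial schedule
#'
#' Fills `keywords_correct` with binomial draws at the participant's
#' intelligibility and `tlx_score` with a condition-level NASA-TLX rating
#' (decreasing in SNR, clipped to 0–100, one draw per SNR condition repeated
#' across that condition's trials).
#'
#' @param trials schedule from [build_schedule()].
#' @param profile one-row profile.
#' @param config an [effect_config()] list.
#' @param seed integer seed.
#' @return `trials` with `keywords_correct` and `tlx_score` filled.
#' @export
simulate_behavior <- function(trials, profile, config = effect_config(), seed = 1) {
  stopifnot(all(trials$n_keywords >= 1))
  local_seed(seed, {
    p <- intelligibility(trials$snr, profile)
    trials$keywords_correct <- stats::rbinom(nrow(trials), trials$n_keywords, p)
    lev <- sort(unique(trials$snr))
    tlx_by_snr <- clamp(config$tlx_intercept + config$tlx_snr_slope * lev +
                          stats::rnorm(length(lev), 0, config$tlx_noise_sd),
                        0, 100)
    trials$tlx_score <- tlx_by_snr[match(trials$snr, lev)]
    trials
  })
}

#' Event-locked pupil response kernel
#'
#' Normalized task-evoked response: a gamma-density impulse kernel convolved
#' with a unit boxcar spanning the sentence. The convolution has the closed
#' form `pgamma(u) - pgamma(u - dur)` with `u` the time since sentence onset.
#'
#' @param t times (s, absolute).
#' @param sentence_onset,sentence_offset sentence span (s).
#' @param shape,scale gamma kernel parameters (scale in s).
#' @return unnormalized response values (>= 0), zero before sentence onset.
#' @keywords internal
response_kernel <- function(t, sentence_onset, sentence_offset,
                            shape = 2, scale = 0.5) {
  u <- t - sentence_onset
  dur <- sentence_offset - sentence_onset
  stats::pgamma(u, shape = shape, scale = scale) -
    stats::pgamma(u - dur, shape = shape, scale = scale)
}

#' Simulate one trial's raw pupil trace
#'
#' Diameter is `baseline_mm * (1 + r(t)) + hippus + noise`, where `r(t)` is
#' the event-locked response normalized so its maximum inside the analysis
#' window (sentence onset to prompt) equals `effort_peak(snr)/100` in relative
#' units, and the hippus term is a slow spontaneous sinusoid with random phase
#' and frequency. Blinks arrive as a Poisson process and blank out 100–300 ms
#' runs (`NA`); with probability `dropout_prob` the trial additionally
#' contains one long tracking-dropout episode.
#'
#' @param trial one-row trial events.
#' @param profile one-row profile.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @param noise_sd_mm additive Gaussian measurement noise (mm); 0 for
#'   noiseless ground-truth traces.
#' @param hippus_amp_mm hippus sinusoid amplitude (mm); 0 disables it.
#' @param hippus_freq_range hippus frequency range (Hz), uniform draw.
#' @param blink_rate blink events per second; defaults to the participant's
#'   latent rate. 0 disables blinks.
#' @param blink_dur_range blink duration range (s).
#' @param dropout_prob,dropout_dur_range long tracking-loss episode:
#'   per-trial probability and duration range (s); 0 disables.
#' @param kernel_shape,kernel_scale gamma kernel parameters.
#' @return a list of class `"pupil_trace"`: `timestamps` (s), `diameters`
#'   (mm, `NA` = missing), `fs`.
#' @export
simulate_trace <- function(trial, profile, seed = 1, fs = 120,
                           noise_sd_mm = effect_config()$trace_noise_sd_mm,
                           hippus_amp_mm = effect_config()$hippus_amp_mm,
                           hippus_freq_range = effect_config()$hippus_freq_range,
                           blink_rate = NULL,
                           blink_dur_range = c(0.1, 0.3),
                           dropout_prob = effect_config()$dropout_prob,
                           dropout_dur_range = effect_config()$dropout_dur_range,
                           kernel_shape = 2, kernel_scale = 0.5) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (is.null(blink_rate)) blink_rate <- latent(profile, "blink_rate")
  baseline_mm <- latent(profile, "baseline_mm")
  peak <- effort_peak(trial$snr, profile)

  t <- seq(trial$noise_onset, trial$prompt_time, by = 1 / fs)
  g <- response_kernel(t, trial$sentence_onset, trial$sentence_offset,
                       shape = kernel_shape, scale = kernel_scale)
  win <- t >= trial$sentence_onset & t <= trial$prompt_time
  gmax <- max(g[win])
  r <- if (gmax > 0) (peak / 100) * g / gmax else g * 0

  local_seed(seed, {
    d <- baseline_mm * (1 + r)
    if (hippus_amp_mm > 0) {
      f <- stats::runif(1, hippus_freq_range[1], hippus_freq_range[2])
      phi <- stats::runif(1, 0, 2 * pi)
      d <- d + hippus_amp_mm * sin(2 * pi * f * t + phi)
    }
    if (noise_sd_mm > 0) {
      # tracker output is low-pass: correlated noise (50 ms moving average of
      # white noise, rescaled), not sample-independent jitter
      e <- running_mean(stats::rnorm(length(t), 0, noise_sd_mm),
                        half = max(1L, round(0.05 * fs / 2)))
      d <- d + e * noise_sd_mm / stats::sd(e)
    }
    span <- trial$prompt_time - trial$noise_onset
    if (blink_rate > 0) {
      n_blinks <- stats::rpois(1, blink_rate * span)
      if (n_blinks > 0) {
        starts <- stats::runif(n_blinks, trial$noise_onset, trial$prompt_time)
        durs <- stats::runif(n_blinks, blink_dur_range[1], blink_dur_range[2])
        for (b in seq_len(n_blinks)) {
          d[t >= starts[b] & t <= starts[b] + durs[b]] <- NA_real_
        }
      }
    }
    if (dropout_prob > 0 && stats::runif(1) < dropout_prob) {
      dur <- stats::runif(1, dropout_dur_range[1], dropout_dur_range[2])
      start <- stats::runif(1, trial$noise_onset, trial$prompt_time - min(dur, span))
      d[t >= start & t <= start + dur] <- NA_real_
    }
    structure(list(timestamps = t, diameters = d, fs = fs),
              class = "pupil_trace")
  })
}

#' Simulate trial-level peak pupil dilations directly
#'
#' The generator's statistical layer: draws each trial's PPD as
#' `effort_peak(snr) + N(0, ppd_noise_sd)` without synthesizing traces. Used
#' for model-recovery and calibration studies where the physiological trace
#' layer (validated separately by the noiseless round-trip) is not needed.
#'
#' @param profiles data.frame from [generate_profiles()].
#' @param design a [trial_design()] list.
#' @param config an [effect_config()] list (supplies `ppd_noise_sd`).
#' @param seed integer seed.
#' @return a data.frame `participant_id`, `trial`, `snr`, `ppd`.
#' @export
simulate_ppd_trials <- function(profiles, design = trial_design(),
                                config = effect_config(), seed = 1) {
  per_snr <- design$lists_per_snr * design$sentences_per_list
  local_seed(seed, {
    out <- lapply(seq_len(nrow(profiles)), function(i) {
      prof <- profiles[i, ]
      snr <- rep(design$snr_levels, each = per_snr)
      data.frame(
        participant_id = prof$participant_id,
        trial = seq_along(snr),
        snr = snr,
        ppd = effort_peak(snr, prof) +
          stats::rnorm(length(snr), 0, config$ppd_noise_sd),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Simulate a full cohort (profiles, schedules, behavior, traces)
#'
#' @param n_participants cohort size.
#' @param design a [trial_design()] list.
#' @param config an [effect_config()] list.
#' @param seed global seed (fanned out per participant and stage).
#' @param fs sampling rate (Hz).
#' @param traces if `FALSE`, skip trace synthesis (profiles + events only).
#' @return a list: `profiles`, `events` (all participants' trials), `samples`
#'   (long data.frame `participant_id`, `trial_id`, `t`, `pupil_mm`; `NA` =
#'   missing sample) or `NULL` when `traces = FALSE`.
#' @export
simulate_cohort <- function(n_participants = 17, design = trial_design(),
                            config = effect_config(), seed = 1, fs = 120,
                            traces = TRUE) {
  profiles <- generate_profiles(n_participants, config, seed = sub_seed(seed, 1))
  events_list <- vector("list", n_participants)
  samples_list <- if (traces) vector("list", n_participants) else NULL
  for (i in seq_len(n_participants)) {
    prof <- profiles[i, ]
    ev <- build_schedule(prof, design, seed = sub_seed(seed, 2) + i)
    ev <- simulate_behavior(ev, prof, config, seed = sub_seed(seed, 3) + i)
    events_list[[i]] <- ev
    if (traces) {
      tr <- lapply(seq_len(nrow(ev)), function(j) {
        trace <- simulate_trace(ev[j, ], prof, seed = sub_seed(seed, 4) + i * 1000L + j,
                                fs = fs, noise_sd_mm = config$trace_noise_sd_mm,
                                hippus_amp_mm = config$hippus_amp_mm,
                                hippus_freq_range = config$hippus_freq_range,
                                dropout_prob = config$dropout_prob,
                                dropout_dur_range = config$dropout_dur_range)
        data.frame(participant_id = prof$participant_id,
                   trial_id = ev$trial_id[j],
                   t = trace$timestamps, pupil_mm = trace$diameters,
                   stringsAsFactors = FALSE)
      })
      samples_list[[i]] <- do.call(rbind, tr)
    }
  }
  list(profiles = profiles,
       events = do.call(rbind, events_list),
       samples = if (traces) do.call(rbind, samples_list) else NULL)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir directory containing `profiles.csv`, `events.csv` and
#'   optionally `samples.csv`.
#' @return a list `profiles`, `events`, `samples` (`NULL` if absent).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  samples_path <- file.path(dir, "samples.csv")
  list(profiles = rd("profiles.csv"), events = rd("events.csv"),
       samples = if (file.exists(samples_path)) rd("samples.csv") else NULL)
}

#' Write a simulated cohort to delimited text tables
#'
#' Writes `profiles.csv`, `events.csv` and (when present) `samples.csv`
#' (comma-separated, header row, UTF-8; empty field = missing sample) into
#' `dir`.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$samples)) {
    utils::write.csv(cohort$samples, file.path(dir, "samples.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}
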