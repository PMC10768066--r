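# Trial-level pupil preprocessing: MAD artifact detection, onset/offset margin
# expansion, cubic interpolation, running-average smoothing, interpolation-
# fraction exclusion, baseline correction and peak-pupil-dilation extraction.

#' Default preprocessing parameters
#'
#' @param mad_k MAD multiplier for the artifact threshold (samples deviating
#'   from the trial median by more than `mad_k` raw MADs are flagged).
#' @param mad_scale scale factor applied to the median absolute deviation;
#'   1 = raw (unscaled) MAD, 1.4826 = normal-consistent.
#' @param mad_eps floor (mm) on the threshold so constant traces flag nothing.
#' @param pre_ms,post_ms margin (ms) discarded before/after each artifact run,
#'   guarding against blink onset/offset distortion.
#' @param smooth_ms running-average window duration (ms).
#' @param excl_frac maximum tolerated interpolated fraction; trials strictly
#'   above it are excluded.
#' @param baseline_s baseline-window duration (s) before sentence onset.
#' @return a named list of class `"pupilci_prep"`.
#' @export
prep_params <- function(mad_k = 3, mad_scale = 1, mad_eps = 0.01,
                        pre_ms = 35, post_ms = 100, smooth_ms = 100,
                        excl_frac = 0.40, baseline_s = 2.0) {
  p <- as.list(environment())
  class(p) <- "pupilci_prep"
  p
}

#' Flag artifactual samples by deviation from the trial median
#'
#' A sample is flagged iff it is missing or deviates from the median of the
#' valid samples by more than `mad_k` times the (by default unscaled) median
#' absolute deviation. The threshold is floored at `mad_eps` so a constant
#' trace with one dropout flags only the dropout.
#'
#' @param diameters numeric vector (mm); `NA` = missing.
#' @param params a [prep_params()] list.
#' @return logical mask, `TRUE` = artifact.
#' @export
detect_artifacts <- function(diameters, params = prep_params()) {
  if (length(diameters) == 0) stop("empty trace", call. = FALSE)
  valid <- !is.na(diameters)
  if (!any(valid)) stop("all samples missing", call. = FALSE)
  med <- stats::median(diameters[valid])
  mad <- stats::median(abs(diameters[valid] - med)) * params$mad_scale
  thr <- max(params$mad_k * mad, params$mad_eps)
  !valid | abs(diameters - med) > thr
}

#' Expand artifact runs by pre/post margins
#'
#' Extends every maximal flagged run by `ceil(pre_ms/1000 * fs)` samples
#' backward and `ceil(post_ms/1000 * fs)` samples forward, clipped at the
#' trace edges. The result always contains the input mask.
#'
#' @param mask logical artifact mask.
#' @param fs sampling rate (Hz).
#' @param params a [prep_params()] list.
#' @return expanded logical mask.
#' @export
expand_margins <- function(mask, fs, params = prep_params()) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!any(mask)) return(mask)
  back <- ceiling(params$pre_ms / 1000 * fs)
  fwd <- ceiling(params$post_ms / 1000 * fs)
  n <- length(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- mask
  for (i in which(r$values)) {
    out[max(1L, starts[i] - back):min(n, ends[i] + fwd)] <- TRUE
  }
  out
}

#' Fill flagged samples by piecewise-cubic interpolation
#'
#' Flagged samples are replaced by a cubic interpolant through the preserved
#' samples (`stats::spline`, FMM boundary conditions — reproduces cubic
#' polynomials exactly). Gaps at the trace head or tail are filled by
#' nearest-valid extension rather than extrapolated. With fewer than 4
#' preserved samples the fill degrades to linear interpolation; with fewer
#' than 2 the trial is unusable.
#'
#' @param trace a `pupil_trace` list (`timestamps`, `diameters`, `fs`) or a
#'   numeric vector of diameters (then `timestamps` defaults to sample index).
#' @param mask logical mask of samples to replace.
#' @return a list of class `"clean_trace"`: `timestamps`, `diameters` (fully
#'   filled), `fs`, `interp_mask`, `interp_fraction`.
#' @export
interpolate_gaps <- function(trace, mask) {
  if (is.numeric(trace)) {
    trace <- list(timestamps = seq_along(trace), diameters = trace, fs = 1)
  }
  t <- trace$timestamps
  x <- trace$diameters
  stopifnot(length(t) == length(x), length(mask) == length(x))
  keep <- !mask
  if (sum(keep) < 2) stop("fewer than 2 valid samples: trial unusable", call. = FALSE)
  out <- x
  if (any(mask)) {
    first <- which(keep)[1]
    last <- which(keep)[sum(keep)]
    head_gap <- mask & seq_along(x) < first
    tail_gap <- mask & seq_along(x) > last
    interior <- mask & !head_gap & !tail_gap
    if (any(interior)) {
      if (sum(keep) >= 4) {
        out[interior] <- stats::spline(t[keep], x[keep], xout = t[interior],
                                       method = "fmm")$y
      } else {
        out[interior] <- stats::approx(t[keep], x[keep], xout = t[interior])$y
      }
    }
    out[head_gap] <- x[first]
    out[tail_gap] <- x[last]
  }
  structure(list(timestamps = t, diameters = out, fs = trace$fs,
                 interp_mask = mask, interp_fraction = mean(mask)),
            class = "clean_trace")
}

# centered moving average with shrinking windows at the edges; O(n) via cumsum
running_mean <- function(x, half) {
  n <- length(x)
  if (half == 0 || n == 1) return(x)
  cs <- cumsum(x)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Smooth a cleaned trace with a running-average filter
#'
#' Centered moving average of duration `smooth_ms` (window length
#' `round(smooth_ms/1000 * fs)` samples, forced odd); edge samples use
#' symmetric shrinking windows. Constant traces pass through unchanged.
#'
#' @param clean a `clean_trace` list.
#' @param params a [prep_params()] list.
#' @return the `clean_trace` with smoothed `diameters`.
#' @export
smooth_trace <- function(clean, params = prep_params()) {
  w <- round(params$smooth_ms / 1000 * clean$fs)
  if (w %% 2 == 0) w <- w + 1
  clean$diameters <- running_mean(clean$diameters, half = (w - 1) %/% 2)
  clean
}

#' Trial inclusion by interpolated fraction
#'
#' A trial is kept iff its interpolated fraction is at most `excl_frac`
#' (strictly greater excludes; exactly at the boundary is kept).
#'
#' @param clean a `clean_trace` list (or a bare interpolated fraction).
#' @param params a [prep_params()] list.
#' @return logical: `TRUE` = include.
#' @export
exclude_trial <- function(clean, params = prep_params()) {
  frac <- if (is.numeric(clean)) clean else clean$interp_fraction
  frac <= params$excl_frac
}

#' Baseline pupil diameter before sentence onset
#'
#' Arithmetic mean of the (smoothed) diameters in the half-open window
#' `[sentence_onset - baseline_s, sentence_onset)`.
#'
#' @param clean a `clean_trace` list.
#' @param sentence_onset sentence onset time (s).
#' @param params a [prep_params()] list.
#' @return baseline diameter in mm.
#' @export
compute_baseline <- function(clean, sentence_onset, params = prep_params()) {
  idx <- clean$timestamps >= sentence_onset - params$baseline_s &
    clean$timestamps < sentence_onset
  if (!any(idx)) stop("baseline window not covered by trace", call. = FALSE)
  mean(clean$diameters[idx])
}

#' Baseline-normalize a trace to percent relative change
#'
#' Per sample: `(observation - baseline) / baseline * 100`, restricted to the
#' analysis window `[sentence_onset, prompt_time)`.
#'
#' @param clean a `clean_trace` list.
#' @param baseline baseline diameter (mm), > 0.
#' @param sentence_onset,prompt_time analysis window bounds (s).
#' @return a list `t_rel` (s since sentence onset) and `rel` (percent).
#' @export
normalize_trace <- function(clean, baseline, sentence_onset, prompt_time) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be > 0: trial unusable", call. = FALSE)
  }
  idx <- clean$timestamps >= sentence_onset & clean$timestamps < prompt_time
  list(t_rel = clean$timestamps[idx] - sentence_onset,
       rel = (clean$diameters[idx] - baseline) / baseline * 100)
}

#' Peak pupil dilation of a normalized trace
#'
#' Maximum percent relative dilation over the analysis window (sentence onset
#' to response prompt; excursions after the prompt never contribute).
#'
#' @param rel normalized trace list from [normalize_trace()] (already
#'   restricted to the window) or a numeric vector of percent values.
#' @return PPD in percent.
#' @export
extract_ppd <- function(rel) {
  v <- if (is.list(rel)) rel$rel else rel
  if (length(v) == 0) stop("empty analysis window", call. = FALSE)
  max(v)
}

#' Preprocess one trial end to end
#'
#' Fixed order: detect artifacts, expand margins, interpolate, smooth, apply
#' the exclusion rule, compute baseline, normalize, extract PPD.
#'
#' @param trace a `pupil_trace` list.
#' @param event one-row trial-events data.frame.
#' @param params a [prep_params()] list.
#' @return a list: `metrics` (one-row data.frame `participant_id`, `trial_id`,
#'   `snr`, `baseline_mm`, `interp_fraction`, `included`, `ppd_pct`), `rel`
#'   (normalized trace, `NULL` if unusable), `clean` (the cleaned trace).
#'   Unusable trials (too few valid samples, nonpositive baseline) return
#'   `included = FALSE` with `NA` metrics instead of erroring.
#' @export
preprocess_trial <- function(trace, event, params = prep_params()) {
  pid <- if (!is.null(event$participant_id)) event$participant_id else NA_character_
  tid <- if (!is.null(event$trial_id)) event$trial_id else NA_character_
  row <- function(baseline, frac, included, ppd) {
    data.frame(participant_id = pid, trial_id = tid, snr = event$snr,
               baseline_mm = baseline, interp_fraction = frac,
               included = included, ppd_pct = ppd, stringsAsFactors = FALSE)
  }
  mask <- detect_artifacts(trace$diameters, params)
  mask <- expand_margins(mask, trace$fs, params)
  clean <- tryCatch(interpolate_gaps(trace, mask), error = function(e) NULL)
  if (is.null(clean)) {
    return(list(metrics = row(NA_real_, mean(mask), FALSE, NA_real_),
                rel = NULL, clean = NULL))
  }
  clean <- smooth_trace(clean, params)
  included <- exclude_trial(clean, params)
  baseline <- tryCatch(compute_baseline(clean, event$sentence_onset, params),
                       error = function(e) NA_real_)
  if (!is.finite(baseline) || baseline <= 0) {
    return(list(metrics = row(baseline, clean$interp_fraction, FALSE, NA_real_),
                rel = NULL, clean = clean))
  }
  rel <- normalize_trace(clean, baseline, event$sentence_onset, event$prompt_time)
  list(metrics = row(baseline, clean$interp_fraction, included,
                     extract_ppd(rel)),
       rel = rel, clean = clean)
}

#' Preprocess a whole cohort of trials
#'
#' Applies [preprocess_trial()] to every trial in a long-format sample table
#' and aggregates included trials per participant and SNR condition, aligned
#' at sentence onset.
#'
#' @param samples long data.frame `participant_id`, `trial_id`, `t`,
#'   `pupil_mm` (`NA` or empty = missing).
#' @param events trial-events data.frame (one row per trial).
#' @param params a [prep_params()] list.
#' @param fs sampling rate (Hz); inferred from timestamps when `NULL`.
#' @return a list: `trial_metrics` (one row per trial), `cell_means`
#'   (`participant_id`, `snr`, `ppd` — mean PPD over included trials; empty
#'   cells are `NA`), `condition_traces` (`participant_id`, `snr`, `t_rel`,
#'   `mean_pct`, `se_pct`, `n`; `se_pct` is `NA` when `n = 1`).
#' @export
preprocess_cohort <- function(samples, events, params = prep_params(), fs = NULL) {
  split_samples <- split(samples, samples$trial_id)
  metrics_list <- vector("list", nrow(events))
  rel_list <- vector("list", nrow(events))
  for (j in seq_len(nrow(events))) {
    ev <- events[j, ]
    s <- split_samples[[ev$trial_id]]
    if (is.null(s)) next
    s <- s[order(s$t), ]
    fsj <- if (is.null(fs)) 1 / stats::median(diff(s$t)) else fs
    trace <- structure(list(timestamps = s$t, diameters = s$pupil_mm, fs = fsj),
                       class = "pupil_trace")
    res <- preprocess_trial(trace, ev, params)
    metrics_list[[j]] <- res$metrics
    rel_list[[j]] <- res$rel
  }
  keep <- !vapply(metrics_list, is.null, logical(1))
  metrics <- do.call(rbind, metrics_list[keep])
  agg <- aggregate_condition(metrics, rel_list[keep])
  list(trial_metrics = metrics, cell_means = agg$cell_means,
       condition_traces = agg$condition_traces)
}

#' Aggregate included trials per participant and SNR condition
#'
#' Onset-aligned per-sample mean and standard error of the normalized traces,
#' plus the per-cell mean PPD. Excluded trials never contribute; empty cells
#' are reported as missing, and the per-sample SE is missing when only one
#' trial covers a sample.
#'
#' @param metrics trial-metrics data.frame (from [preprocess_trial()] rows).
#' @param rel_traces list of normalized traces parallel to `metrics` rows.
#' @return a list: `cell_means` (`participant_id`, `snr`, `ppd`, `n_trials`)
#'   and `condition_traces` (`participant_id`, `snr`, `t_rel`, `mean_pct`,
#'   `se_pct`, `n`).
#' @export
aggregate_condition <- function(metrics, rel_traces) {
  stopifnot(nrow(metrics) == length(rel_traces))
  cells <- unique(metrics[, c("participant_id", "snr")])
  cells <- cells[order(cells$participant_id, cells$snr), ]
  cm <- vector("list", nrow(cells))
  ct <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    in_cell <- metrics$participant_id == cells$participant_id[i] &
      metrics$snr == cells$snr[i] & metrics$included %in% TRUE &
      is.finite(metrics$ppd_pct)
    idx <- which(in_cell)
    cm[[i]] <- data.frame(participant_id = cells$participant_id[i],
                          snr = cells$snr[i],
                          ppd = if (length(idx)) mean(metrics$ppd_pct[idx]) else NA_real_,
                          n_trials = length(idx), stringsAsFactors = FALSE)
    if (length(idx)) {
      traces <- rel_traces[idx]
      len <- max(vapply(traces, function(r) length(r$rel), integer(1)))
      m <- matrix(NA_real_, nrow = length(idx), ncol = len)
      for (k in seq_along(traces)) {
        m[k, seq_along(traces[[k]]$rel)] <- traces[[k]]$rel
      }
      n_per <- colSums(!is.na(m))
      mean_pct <- colMeans(m, na.rm = TRUE)
      sd_pct <- apply(m, 2, stats::sd, na.rm = TRUE)
      se_pct <- ifelse(n_per > 1, sd_pct / sqrt(n_per), NA_real_)
      t_rel <- traces[[which.max(vapply(traces, function(r) length(r$rel),
                                        integer(1)))]]$t_rel
      ct[[i]] <- data.frame(participant_id = cells$participant_id[i],
                            snr = cells$snr[i], t_rel = t_rel,
                            mean_pct = mean_pct, se_pct = se_pct, n = n_per,
                            stringsAsFactors = FALSE)
    }
  }
  list(cell_means = do.call(rbind, cm),
       condition_traces = do.call(rbind, ct))
}
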