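# Individual-differences battery: adaptive spectral-ripple (SMRT) staircase,
# N-back d-prime, Stroop interference, NASA-TLX weighted workload, NCIQ
# quality-of-life scoring.

#' Initialize a 1-up/1-down spectral-ripple staircase
#'
#' Three-interval oddity task against a fixed 20-ripples-per-octave reference.
#' The target starts at 0.5 RPO; a correct response raises its ripple density
#' by one step (harder), an incorrect response lowers it. The run terminates
#' after `max_reversals` direction reversals (or `max_trials` as a safeguard).
#'
#' @param start initial target density (RPO).
#' @param step fixed step size (RPO).
#' @param reference reference density (RPO), recorded for provenance.
#' @param floor_rpo lowest presentable target density (RPO).
#' @param max_reversals reversal count at which the run stops.
#' @param max_trials trial-count safeguard.
#' @return a list of class `"smrt_staircase"` with `target_rpo`, `reversals`,
#'   `trial_log`, `terminated`, and the configuration fields.
#' @export
staircase_new <- function(start = 0.5, step = 0.2, reference = 20,
                          floor_rpo = 0.1, max_reversals = 10,
                          max_trials = 150) {
  structure(list(target_rpo = start, step = step, reference = reference,
                 floor_rpo = floor_rpo, max_reversals = max_reversals,
                 max_trials = max_trials, last_direction = 0,
                 reversals = numeric(0),
                 trial_log = data.frame(target_rpo = numeric(0),
                                        correct = logical(0)),
                 terminated = FALSE),
            class = "smrt_staircase")
}

#' Advance the staircase by one trial
#'
#' Correct responses step the target up (denser ripples, harder), incorrect
#' responses step it down, clipped at the floor. When the step direction
#' changes, the target level at which the change occurred (the pre-change
#' level) is appended to the reversal log.
#'
#' @param state an `smrt_staircase` list.
#' @param correct logical response for the current target level.
#' @return the updated state.
#' @export
staircase_step <- function(state, correct) {
  if (state$terminated) stop("staircase already terminated", call. = FALSE)
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  level <- state$target_rpo
  direction <- if (correct) 1 else -1
  if (state$last_direction != 0 && direction != state$last_direction) {
    state$reversals <- c(state$reversals, level)
  }
  state$last_direction <- direction
  state$target_rpo <- max(state$floor_rpo, level + direction * state$step)
  state$trial_log <- rbind(state$trial_log,
                           data.frame(target_rpo = level, correct = correct))
  if (length(state$reversals) >= state$max_reversals ||
      nrow(state$trial_log) >= state$max_trials) {
    state$terminated <- TRUE
  }
  state
}

#' Run a staircase against a response model
#'
#' @param respond function `f(target_rpo) -> logical`, the simulated observer.
#' @param state initial state from [staircase_new()].
#' @return the terminated state.
#' @export
run_staircase <- function(respond, state = staircase_new()) {
  while (!state$terminated) {
    state <- staircase_step(state, isTRUE(respond(state$target_rpo)))
  }
  state
}

#' SMRT threshold from a terminated staircase
#'
#' Arithmetic mean of the last six reversal levels (RPO). With fewer than six
#' reversals the threshold is missing (`NA`) with a warning.
#'
#' @param state an `smrt_staircase` list.
#' @return threshold in ripples per octave, or `NA`.
#' @export
smrt_threshold <- function(state) {
  r <- if (is.numeric(state)) state else state$reversals
  if (length(r) < 6) {
    warning("fewer than 6 reversals: threshold missing")
    return(NA_real_)
  }
  mean(utils::tail(r, 6))
}

#' N-back discriminability (d-prime)
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the log-linear correction
#' (0.5 added to each response cell, 1 to each denominator) applied always,
#' which keeps d' finite at perfect hit or zero false-alarm rates and
#' continuous elsewhere.
#'
#' @param hits,misses target-trial counts.
#' @param false_alarms,correct_rejections nontarget-trial counts.
#' @return d-prime (unitless).
#' @export
nback_dprime <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (hits + misses == 0) stop("no target trials", call. = FALSE)
  if (false_alarms + correct_rejections == 0) {
    stop("no nontarget trials", call. = FALSE)
  }
  h <- (hits + 0.5) / (hits + misses + 1)
  f <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Stroop interference and control reaction time
#'
#' Interference = mean accuracy on incongruent trials minus mean accuracy on
#' congruent trials (a proportion difference; negative = congruency cost).
#' Control RT = mean reaction time over control trials.
#'
#' @param trials data.frame with columns `block_type` (one of `"congruent"`,
#'   `"incongruent"`, `"control"`), `correct` (logical or 0/1), `rt` (s).
#' @return a list `interference`, `control_rt`.
#' @export
stroop_scores <- function(trials) {
  need <- c("congruent", "incongruent", "control")
  missing <- setdiff(need, unique(trials$block_type))
  if (length(missing)) {
    stop("missing block type(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  acc <- function(type) mean(as.numeric(trials$correct[trials$block_type == type]))
  list(interference = acc("incongruent") - acc("congruent"),
       control_rt = mean(trials$rt[trials$block_type == "control"]))
}

#' NASA-TLX weighted overall workload
#'
#' Weighted average of the six subscale ratings (mental, physical, temporal
#' demand, performance, effort, frustration), the weights being how often
#' each subscale was chosen across the 15 pairwise comparisons.
#'
#' @param weights six nonnegative counts summing to 15.
#' @param ratings six subscale ratings in \[0, 100\].
#' @return overall workload in \[0, 100\].
#' @export
tlx_weighted_score <- function(weights, ratings) {
  if (length(weights) != 6 || length(ratings) != 6) {
    stop("expected 6 weights and 6 ratings", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) != 15) {
    stop("weights must be nonnegative and sum to 15", call. = FALSE)
  }
  if (any(ratings < 0 | ratings > 100)) {
    stop("ratings must lie in [0, 100]", call. = FALSE)
  }
  sum(weights * ratings) / 15
}

#' Score the Nijmegen Cochlear Implant Questionnaire (NCIQ)
#'
#' Six subdomains (basic sound perception, advanced sound perception, speech
#' production, self-esteem, activity, social interactions) of ten items each
#' on a 1–5 scale; `NA` marks "not applicable". Item scores map linearly to
#' \{0, 25, 50, 75, 100\}; a subdomain is the mean over its applicable items
#' and the global score the mean of the available subdomains.
#'
#' @param responses 6 x 10 matrix (or data.frame) of responses in 1..5, rows =
#'   subdomains, `NA` allowed.
#' @param reverse_keyed optional logical 6 x 10 matrix marking reverse-keyed
#'   items (scored as `6 - response`); defaults to none, and the return value
#'   flags that no keying was applied.
#' @return a list: `subdomains` (length-6 vector, 0–100, `NA` when all items
#'   of a subdomain are inapplicable), `global`, `reverse_keyed_applied`.
#' @export
nciq_scores <- function(responses, reverse_keyed = NULL) {
  m <- as.matrix(responses)
  if (!all(dim(m) == c(6, 10))) stop("expected a 6 x 10 response matrix", call. = FALSE)
  if (any(!is.na(m) & (m < 1 | m > 5))) {
    stop("responses must lie in 1..5 or NA", call. = FALSE)
  }
  if (!is.null(reverse_keyed)) {
    rk <- as.matrix(reverse_keyed)
    stopifnot(all(dim(rk) == c(6, 10)))
    m[rk] <- 6 - m[rk]
  }
  item <- (m - 1) * 25
  sub <- rowMeans(item, na.rm = TRUE)
  sub[rowSums(!is.na(item)) == 0] <- NA_real_
  list(subdomains = unname(sub),
       global = if (all(is.na(sub))) NA_real_ else mean(sub, na.rm = TRUE),
       reverse_keyed_applied = !is.null(reverse_keyed))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` elementwise, for an explicit family size `m`
#' (which may exceed the number of p-values supplied).
#'
#' @param p p-values in \[0, 1\].
#' @param m family size (>= 1); defaults to `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("family size must be >= 1", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p)
}
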