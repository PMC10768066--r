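# Correlation battery between individual-difference factors and the
# psychometric shape parameters (mean PPD, quadratic coefficient), with the
# Pearson/Spearman selection rule, Bonferroni correction, Welch t-tests and
# the exploratory group-moderated regressions.

#' Choose Pearson or Spearman for a factor pair
#'
#' Spearman's rho is used when either variable is flagged bounded/ordinal
#' (e.g. a percent-correct score bounded at 0–100) or fails a Shapiro-Wilk
#' normality screen at `alpha`; otherwise Pearson's r.
#'
#' @param x,y numeric vectors (pairwise-complete).
#' @param x_bounded,y_bounded logical flags: bounded or ordinal scale.
#' @param alpha normality-screen level.
#' @return `"pearson"` or `"spearman"`.
#' @export
choose_method <- function(x, y, x_bounded = FALSE, y_bounded = FALSE,
                          alpha = 0.05) {
  if (x_bounded || y_bounded) return("spearman")
  non_normal <- function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 3 || length(v) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value < alpha
  }
  if (non_normal(x) || non_normal(y)) "spearman" else "pearson"
}

#' Correlate two variables
#'
#' Pearson's r (test statistic t) or Spearman's rho (test statistic S, the
#' sum-of-squared rank differences statistic, midranks for ties), with a
#' two-sided p-value.
#'
#' @param x,y numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return one-row data.frame `method`, `statistic` (r or rho), `test_stat`
#'   (t or S), `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 pairwise-complete observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(method = method, statistic = unname(ct$estimate),
             test_stat = unname(ct$statistic), p = ct$p.value, n = length(x),
             stringsAsFactors = FALSE)
}

# the individual-difference factor battery: profile column, display name, and
# whether the scale is bounded/ordinal (forcing Spearman)
factor_catalog <- function() {
  data.frame(
    column = c("age", "ci_duration", "word_recognition", "t_level",
               "qol_total", "tlx_mean", "prop_correct", "matrices_correct",
               "stroop_interference", "stroop_control_rt", "nback_dprime",
               "smrt_threshold"),
    factor = c("Age", "CI duration", "Word recognition", "T-level", "QoL",
               "NASA-TLX", "Sentence correct in noise", "Matrices correct",
               "Stroop interference", "Stroop control RT", "N-back d-prime",
               "SMRT threshold"),
    bounded = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Correlation battery of individual factors against shape parameters
#'
#' The 12-factor x 2-parameter grid: each factor (age, CI duration, word
#' recognition, free-field T-level, QoL, mean NASA-TLX, sentence accuracy in
#' noise, matrices, Stroop interference, Stroop control RT, N-back d-prime,
#' SMRT threshold) against each participant's mean PPD and the quadratic
#' coefficient of their PPD-vs-SNR curve. Method per [choose_method()]
#' (bounded/ordinal factors use Spearman); Bonferroni correction at family
#' size `m`.
#'
#' @param profiles profiles data.frame (see [generate_profiles()]).
#' @param shape_params data.frame from [shape_table()].
#' @param behavior optional data.frame `participant_id`, `tlx_mean`,
#'   `prop_correct` (per-participant summaries of the speech-in-noise task);
#'   their rows are skipped when absent.
#' @param m Bonferroni family size; defaults to the full 12 x 2 grid.
#' @param alpha significance level applied to the corrected p-values.
#' @return data.frame `factor`, `target`, `method`, `statistic`, `test_stat`,
#'   `p`, `p_adj`, `significant`, `n`.
#' @export
correlation_table <- function(profiles, shape_params, behavior = NULL,
                              m = 24, alpha = 0.05) {
  d <- merge(profiles, shape_params, by = "participant_id")
  if (!is.null(behavior)) d <- merge(d, behavior, by = "participant_id")
  cat <- factor_catalog()
  targets <- c(mean_ppd = "PPD", quad_coef = "Quadratic term")
  rows <- list()
  for (i in seq_len(nrow(cat))) {
    if (!cat$column[i] %in% names(d)) next
    x <- d[[cat$column[i]]]
    for (tcol in names(targets)) {
      y <- d[[tcol]]
      method <- choose_method(x, y, x_bounded = cat$bounded[i],
                              y_bounded = FALSE)
      r <- correlate(x, y, method)
      r$factor <- cat$factor[i]
      r$target <- targets[[tcol]]
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p, m = m)
  out$significant <- out$p_adj < alpha
  out[, c("factor", "target", "method", "statistic", "test_stat", "p",
          "p_adj", "significant", "n")]
}

#' Exploratory per-group regressions of shape parameters on cognition
#'
#' Within each word-recognition group, simple linear regressions of the
#' quadratic coefficient and the mean PPD on Stroop interference and N-back
#' d-prime. Uncorrected and flagged exploratory (post-hoc moderation probes,
#' not confirmatory tests).
#'
#' @param shape_params data.frame from [shape_table()].
#' @param profiles profiles data.frame.
#' @param groups data.frame `participant_id`, `wordgroup` (from
#'   [wordgroup_analysis()]).
#' @param predictors profile columns used as predictors.
#' @param outcomes shape columns used as outcomes.
#' @return data.frame `wordgroup`, `outcome`, `predictor`, `beta`, `se`, `t`,
#'   `p`, `n`, `exploratory`.
#' @export
moderated_regressions <- function(shape_params, profiles, groups,
                                  predictors = c("stroop_interference",
                                                 "nback_dprime"),
                                  outcomes = c("quad_coef", "mean_ppd")) {
  d <- merge(merge(shape_params, profiles, by = "participant_id"),
             groups, by = "participant_id")
  rows <- list()
  for (g in levels(factor(d$wordgroup))) {
    dg <- d[d$wordgroup == g, ]
    if (nrow(dg) < 3) stop("group '", g, "' has n < 3", call. = FALSE)
    for (yv in outcomes) for (xv in predictors) {
      x <- dg[[xv]]; y <- dg[[yv]]
      ok <- is.finite(x) & is.finite(y)
      if (stats::sd(x[ok]) == 0) {
        stop("constant predictor '", xv, "' in group '", g, "'", call. = FALSE)
      }
      s <- summary(stats::lm(y[ok] ~ x[ok]))$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        wordgroup = g, outcome = yv, predictor = xv,
        beta = s[2, 1], se = s[2, 2], t = s[2, 3], p = s[2, 4],
        n = sum(ok), exploratory = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @return a list `t`, `df`, `p`.
#' @export
welch_ttest <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
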