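# Group-level psychometric models: random-intercept mixed models of PPD,
# keyword accuracy and NASA-TLX against SNR; polynomial shape analysis;
# per-participant shape parameters; word-recognition median-split interaction.

snr_code <- function(snr) (snr - 10) / 10  # centered/scaled SNR for polynomials

# Wald z table for all fixed effects of a merMod
fixef_table <- function(fit) {
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  data.frame(term = names(b), beta = unname(b), se = unname(se), z = unname(z),
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
             stringsAsFactors = FALSE)
}

# uncorrected pairwise Wald z contrasts between the levels of `factor_name`
pairwise_contrasts <- function(fit, factor_name) {
  spec <- list("Tukey")
  names(spec) <- factor_name
  gl <- multcomp::glht(fit, linfct = do.call(multcomp::mcp, spec))
  s <- summary(gl, test = multcomp::adjusted("none"))
  data.frame(contrast = names(s$test$coefficients),
             beta = unname(s$test$coefficients),
             se = unname(s$test$sigma), z = unname(s$test$tstat),
             p = unname(s$test$pvalues), row.names = NULL,
             stringsAsFactors = FALSE)
}

lrt_row <- function(term, reduced, full) {
  a <- stats::anova(reduced, full)  # refits LMMs with ML
  data.frame(term = term, chisq = a$Chisq[2], df = a$Df[2],
             p = a[["Pr(>Chisq)"]][2], stringsAsFactors = FALSE)
}

model_fit <- function(family, formula_descr, fixed_effects, lrt,
                      posthoc = NULL, fit = NULL) {
  structure(list(family = family, formula_descr = formula_descr,
                 fixed_effects = fixed_effects, lrt = lrt, posthoc = posthoc,
                 singular = if (!is.null(fit)) lme4::isSingular(fit) else NA,
                 fit = fit),
            class = "pupilci_fit")
}

#' @export
print.pupilci_fit <- function(x, ...) {
  cat("Mixed-effects fit (", x$family, "): ", x$formula_descr, "\n", sep = "")
  if (isTRUE(x$singular)) cat("note: singular random-effects fit\n")
  cat("\nLikelihood-ratio tests:\n")
  print(x$lrt, row.names = FALSE)
  cat("\nFixed effects (Wald z):\n")
  print(x$fixed_effects, digits = 3, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("\nPost-hoc pairwise contrasts (uncorrected):\n")
    print(x$posthoc, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' SNR-condition model of peak pupil dilation
#'
#' Random-intercept linear mixed model of per-cell mean PPD with SNR as a
#' 6-level factor (`ppd ~ snr + (1 | participant)`), a likelihood-ratio test
#' of the SNR factor against the intercept-only model, and all pairwise Wald
#' z contrasts between SNR levels (uncorrected p, normal approximation).
#'
#' @param cell_means data.frame `participant_id`, `snr`, `ppd` (one row per
#'   participant x SNR cell; `NA` cells dropped).
#' @return a `pupilci_fit` list: `fixed_effects`, `lrt`, `posthoc`,
#'   `singular`, and the underlying `lmerMod`.
#' @export
fit_condition_model <- function(cell_means) {
  d <- stats::na.omit(cell_means[, c("participant_id", "snr", "ppd")])
  if (length(unique(d$participant_id)) < 2) {
    stop("need >= 2 participants", call. = FALSE)
  }
  d$snr_f <- factor(d$snr)
  full <- lme4::lmer(ppd ~ snr_f + (1 | participant_id), data = d, REML = TRUE)
  null <- lme4::lmer(ppd ~ 1 + (1 | participant_id), data = d, REML = TRUE)
  model_fit("linear", "ppd ~ snr(factor) + (1 | participant)",
            fixef_table(full), lrt_row("snr", null, full),
            posthoc = pairwise_contrasts(full, "snr_f"), fit = full)
}

#' Polynomial (linear + quadratic) shape model of PPD over SNR
#'
#' Random-intercept model `ppd ~ x + x^2 + (1 | participant)` with SNR coded
#' `x = (snr - 10) / 10` (centered at the middle of the 0–20 dB grid), so a
#' negative quadratic coefficient reads directly as an inverted U.
#' Likelihood-ratio tests: linear term (linear vs intercept-only) and
#' quadratic term (full vs linear).
#'
#' @inheritParams fit_condition_model
#' @return a `pupilci_fit` list; `fixed_effects` rows `snr_lin`, `snr_quad`.
#' @export
fit_polynomial_model <- function(cell_means) {
  d <- stats::na.omit(cell_means[, c("participant_id", "snr", "ppd")])
  d$x <- snr_code(d$snr)
  full <- lme4::lmer(ppd ~ x + I(x^2) + (1 | participant_id), d, REML = TRUE)
  lin <- lme4::lmer(ppd ~ x + (1 | participant_id), d, REML = TRUE)
  null <- lme4::lmer(ppd ~ 1 + (1 | participant_id), d, REML = TRUE)
  fe <- fixef_table(full)
  fe$term <- c("(Intercept)", "snr_lin", "snr_quad")
  model_fit("linear", "ppd ~ snr_c + snr_c^2 + (1 | participant), snr_c = (snr-10)/10",
            fe, rbind(lrt_row("snr_lin", null, lin),
                      lrt_row("snr_quad", lin, full)),
            fit = full)
}

#' Mixed-effects logistic model of keyword accuracy over SNR
#'
#' Binomial GLMM `cbind(correct, n - correct) ~ snr + (1 | participant)` with
#' SNR as a factor; LRT of the SNR factor and uncorrected pairwise Wald z
#' contrasts. Degenerate data (all keywords correct, or none) raise a
#' complete-separation error rather than a silent fit.
#'
#' @param trials data.frame `participant_id`, `snr`, `keywords_correct`,
#'   `n_keywords` (one row per trial).
#' @return a `pupilci_fit` list (family `"logistic"`).
#' @export
fit_accuracy_model <- function(trials) {
  d <- stats::na.omit(trials[, c("participant_id", "snr", "keywords_correct",
                                 "n_keywords")])
  tot <- sum(d$n_keywords)
  hit <- sum(d$keywords_correct)
  if (hit == 0 || hit == tot) {
    stop("complete separation: accuracy is degenerate (all ",
         if (hit == 0) "incorrect" else "correct", ")", call. = FALSE)
  }
  d$snr_f <- factor(d$snr)
  full <- lme4::glmer(cbind(keywords_correct, n_keywords - keywords_correct) ~
                        snr_f + (1 | participant_id),
                      data = d, family = stats::binomial())
  null <- lme4::glmer(cbind(keywords_correct, n_keywords - keywords_correct) ~
                        1 + (1 | participant_id),
                      data = d, family = stats::binomial())
  model_fit("logistic", "keywords correct/total ~ snr(factor) + (1 | participant)",
            fixef_table(full), lrt_row("snr", null, full),
            posthoc = pairwise_contrasts(full, "snr_f"), fit = full)
}

#' Mixed-effects logistic model of NASA-TLX workload over SNR
#'
#' The bounded 0–100 rating is rescaled to (0, 1) with the boundary shrink
#' `(y(n - 1) + 0.5) / n` and modeled on the logit scale with a
#' random-intercept linear mixed model — a logit-link regression of the
#' workload score. LRT of the SNR factor and uncorrected pairwise contrasts.
#'
#' @param ratings data.frame `participant_id`, `snr`, `tlx` (0–100; one row
#'   per participant x condition, or per trial).
#' @return a `pupilci_fit` list (family `"logistic"`); betas are on the logit
#'   scale.
#' @export
fit_tlx_model <- function(ratings) {
  d <- stats::na.omit(ratings[, c("participant_id", "snr", "tlx")])
  n <- nrow(d)
  y <- (d$tlx / 100 * (n - 1) + 0.5) / n
  d$logit_tlx <- stats::qlogis(y)
  d$snr_f <- factor(d$snr)
  full <- lme4::lmer(logit_tlx ~ snr_f + (1 | participant_id), d, REML = TRUE)
  null <- lme4::lmer(logit_tlx ~ 1 + (1 | participant_id), d, REML = TRUE)
  model_fit("logistic", "logit(tlx/100) ~ snr(factor) + (1 | participant)",
            fixef_table(full), lrt_row("snr", null, full),
            posthoc = pairwise_contrasts(full, "snr_f"), fit = full)
}

#' Per-participant psychometric shape parameters
#'
#' From one participant's six per-SNR mean PPDs: the average PPD and the
#' linear and quadratic coefficients of an ordinary least-squares quadratic
#' fit on coded SNR `x = (snr - 10) / 10`. At least 3 non-missing cells are
#' required for the polynomial; otherwise the coefficients are missing.
#'
#' @param cell_means data.frame `snr`, `ppd` for a single participant (a
#'   `participant_id` column, if present, must be constant).
#' @return one-row data.frame `participant_id`, `mean_ppd`, `linear_coef`,
#'   `quad_coef`.
#' @export
participant_shape <- function(cell_means) {
  pid <- if (!is.null(cell_means$participant_id)) {
    u <- unique(cell_means$participant_id)
    stopifnot(length(u) == 1L)
    u
  } else NA_character_
  d <- cell_means[is.finite(cell_means$ppd), , drop = FALSE]
  mean_ppd <- if (nrow(d)) mean(d$ppd) else NA_real_
  lin <- quad <- NA_real_
  if (nrow(d) >= 3) {
    x <- snr_code(d$snr)
    co <- stats::coef(stats::lm(d$ppd ~ x + I(x^2)))
    lin <- unname(co[2])
    quad <- unname(co[3])
  }
  data.frame(participant_id = pid, mean_ppd = mean_ppd,
             linear_coef = lin, quad_coef = quad, stringsAsFactors = FALSE)
}

#' Shape parameters for every participant
#'
#' @param cell_means data.frame `participant_id`, `snr`, `ppd`.
#' @return data.frame with one [participant_shape()] row per participant.
#' @export
shape_table <- function(cell_means) {
  parts <- split(cell_means, cell_means$participant_id)
  do.call(rbind, lapply(parts, participant_shape))
}

#' Median-split word-recognition group analysis
#'
#' Splits participants at the median clinical word recognition (ties join the
#' lower group), then: (1) an SNR x group interaction LRT on PPD
#' (`ppd ~ snr * group + (1 | participant)` vs the additive model), (2)
#' per-group pairwise SNR contrasts, and (3) Welch t-tests checking that the
#' groups do not differ on the other covariates.
#'
#' @param cell_means data.frame `participant_id`, `snr`, `ppd`.
#' @param profiles profiles data.frame with `participant_id`,
#'   `word_recognition` and covariates.
#' @param covariates covariate columns for the Welch battery.
#' @return a list: `groups` (`participant_id`, `wordgroup` in
#'   \{"low", "high"\}), `interaction` (a `pupilci_fit`), `per_group_posthoc`
#'   (named list of contrast tables), `covariate_tests` (data.frame
#'   `covariate`, `t`, `df`, `p`).
#' @export
wordgroup_analysis <- function(cell_means, profiles,
                               covariates = c("age", "ci_duration", "t_level",
                                              "qol_total", "matrices_correct",
                                              "stroop_interference",
                                              "stroop_control_rt",
                                              "nback_dprime", "smrt_threshold")) {
  med <- stats::median(profiles$word_recognition)
  groups <- data.frame(
    participant_id = profiles$participant_id,
    wordgroup = factor(ifelse(profiles$word_recognition <= med, "low", "high"),
                       levels = c("low", "high")),
    stringsAsFactors = FALSE
  )
  if (min(table(groups$wordgroup)) < 2) {
    stop("degenerate group sizes after median split", call. = FALSE)
  }
  d <- merge(stats::na.omit(cell_means[, c("participant_id", "snr", "ppd")]),
             groups, by = "participant_id")
  d$snr_f <- factor(d$snr)
  full <- lme4::lmer(ppd ~ snr_f * wordgroup + (1 | participant_id), d,
                     REML = TRUE)
  additive <- lme4::lmer(ppd ~ snr_f + wordgroup + (1 | participant_id), d,
                         REML = TRUE)
  inter <- model_fit("linear",
                     "ppd ~ snr(factor) * wordgroup + (1 | participant)",
                     fixef_table(full),
                     lrt_row("snr:wordgroup", additive, full), fit = full)
  per_group <- lapply(split(d, d$wordgroup), function(g) {
    g$snr_f <- droplevels(g$snr_f)
    fit <- lme4::lmer(ppd ~ snr_f + (1 | participant_id), g, REML = TRUE)
    pairwise_contrasts(fit, "snr_f")
  })
  cov_tests <- do.call(rbind, lapply(intersect(covariates, names(profiles)),
    function(v) {
      a <- profiles[[v]][groups$wordgroup == "low"]
      b <- profiles[[v]][groups$wordgroup == "high"]
      w <- welch_ttest(a, b)
      data.frame(covariate = v, t = w$t, df = w$df, p = w$p,
                 stringsAsFactors = FALSE)
    }))
  list(groups = groups, interaction = inter, per_group_posthoc = per_group,
       covariate_tests = cov_tests)
}
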