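# cell-means fixture: one row per participant x SNR with ppd = f(snr) + shift
make_cells <- function(n_part, f, shifts = rep(0, n_part), noise_sd = 0,
                       snr = c(0, 4, 8, 12, 16, 20), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_part), function(i) {
    data.frame(participant_id = sprintf("P%02d", i), snr = snr,
               ppd = f(snr) + shifts[i] + rnorm(length(snr), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
}

test_that("condition model: null when PPD is flat, closed-form beta in a balanced two-level design", {
  flat <- make_cells(8, function(s) 3, shifts = seq(0, 1.4, by = 0.2))
  fit <- suppressWarnings(suppressMessages(fit_condition_model(flat)))
  expect_lt(fit$lrt$chisq, 1e-4)
  expect_true(all(fit$posthoc$p > 0.5))

  two <- data.frame(participant_id = rep(c("A", "B"), each = 2),
                    snr = rep(c(0, 20), 2),
                    ppd = c(2, 4, 3, 5))
  f2 <- suppressWarnings(suppressMessages(fit_condition_model(two)))
  # balanced two-level design: the condition effect is the mean difference
  expect_equal(f2$posthoc$beta, 2, tolerance = 1e-6)
  expect_equal(nrow(f2$posthoc), 1)

  six <- make_cells(4, function(s) 3)
  expect_equal(nrow(suppressWarnings(suppressMessages(fit_condition_model(six)))$posthoc), 15)

  expect_error(fit_condition_model(two[two$participant_id == "A", ]),
               "participants")
})

test_that("polynomial model: exact quadratic recovery under centered coding, null quadratic for a pure line", {
  # ppd = -(snr - 10)^2 / 20 + 5 = 5 - 5 x^2 with x = (snr - 10)/10
  quad <- make_cells(6, function(s) -(s - 10)^2 / 20 + 5,
                     shifts = seq(0, 1, by = 0.2))
  fit <- suppressWarnings(suppressMessages(fit_polynomial_model(quad)))
  fe <- fit$fixed_effects
  expect_equal(fe$beta[fe$term == "snr_quad"], -5, tolerance = 1e-6)
  expect_equal(fe$beta[fe$term == "snr_lin"], 0, tolerance = 1e-6)
  expect_lt(fit$lrt$p[fit$lrt$term == "snr_quad"], 1e-6)

  # pure line plus small residual noise: quadratic term null, linear strong
  lin <- make_cells(6, function(s) 0.2 * s + 1, shifts = seq(0, 1, by = 0.2),
                    noise_sd = 0.01, seed = 4)
  fl <- suppressWarnings(suppressMessages(fit_polynomial_model(lin)))
  expect_gt(fl$lrt$p[fl$lrt$term == "snr_quad"], 0.05)
  expect_lt(abs(fl$fixed_effects$beta[fl$fixed_effects$term == "snr_quad"]), 0.05)
  expect_gt(fl$lrt$chisq[fl$lrt$term == "snr_lin"], 50)

  flat <- make_cells(6, function(s) 2, shifts = seq(0, 1, by = 0.2),
                     noise_sd = 0.01, seed = 5)
  ff <- suppressWarnings(suppressMessages(fit_polynomial_model(flat)))
  expect_lt(max(abs(ff$fixed_effects$beta[-1])), 0.05)
})

test_that("accuracy model: flat accuracy gives a null SNR effect; degenerate data raise separation errors", {
  set.seed(5)
  trials <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(participant_id = sprintf("P%02d", i),
               snr = rep(c(0, 4, 8, 12, 16, 20), each = 10),
               keywords_correct = rbinom(60, 4, 0.5), n_keywords = 4)
  }))
  fit <- suppressMessages(fit_accuracy_model(trials))
  expect_gt(fit$lrt$p, 0.05)
  expect_equal(fit$family, "logistic")

  all_right <- trials; all_right$keywords_correct <- 4
  expect_error(fit_accuracy_model(all_right), "separation")
  none <- trials; none$keywords_correct <- 0
  expect_error(fit_accuracy_model(none), "separation")
})

test_that("accuracy and TLX models recover the generated monotone SNR trends", {
  cfg <- effect_config()
  profs <- generate_profiles(10, cfg, seed = 11)
  des <- trial_design(lists_per_snr = 1, sentences_per_list = 10)
  events <- do.call(rbind, lapply(seq_len(nrow(profs)), function(i) {
    ev <- build_schedule(profs[i, ], des, seed = 100 + i)
    simulate_behavior(ev, profs[i, ], cfg, seed = 200 + i)
  }))
  acc <- suppressMessages(fit_accuracy_model(events))
  expect_lt(acc$lrt$p, 0.001)
  hi_lo <- acc$posthoc[acc$posthoc$contrast == "20 - 0", ]
  expect_gt(hi_lo$beta, 0)

  tlx <- unique(events[, c("participant_id", "snr", "tlx_score")])
  names(tlx)[3] <- "tlx"
  tf <- suppressMessages(fit_tlx_model(tlx))
  expect_lt(tf$lrt$p, 0.01)
  expect_lt(tf$posthoc$beta[tf$posthoc$contrast == "20 - 0"], 0)
})

test_that("participant shape parameters: exact constants, exact quadratic, exact line; missing-cell rules", {
  const <- data.frame(participant_id = "P01", snr = c(0, 4, 8, 12, 16, 20),
                      ppd = rep(2, 6))
  s <- participant_shape(const)
  expect_equal(s$mean_ppd, 2)
  expect_equal(s$linear_coef, 0)
  expect_equal(s$quad_coef, 0)

  snr <- c(0, 4, 8, 12, 16, 20)
  quad <- data.frame(participant_id = "P02", snr = snr,
                     ppd = -(snr - 10)^2 / 20 + 5)
  sq <- participant_shape(quad)
  expect_equal(sq$quad_coef, -5, tolerance = 1e-9)
  expect_equal(sq$linear_coef, 0, tolerance = 1e-9)

  line <- data.frame(participant_id = "P03", snr = snr, ppd = 0.3 * snr + 1)
  sl <- participant_shape(line)
  expect_equal(sl$quad_coef, 0, tolerance = 1e-9)
  expect_gt(sl$linear_coef, 0)

  two_cells <- quad[1:2, ]
  st <- participant_shape(two_cells)
  expect_true(is.na(st$quad_coef) && is.na(st$linear_coef))
  expect_equal(st$mean_ppd, mean(two_cells$ppd))

  exact3 <- quad[c(1, 3, 6), ]
  expect_equal(participant_shape(exact3)$quad_coef, -5, tolerance = 1e-9)
})

test_that("mean PPD is coding invariant and the quadratic sign survives affine SNR recoding", {
  snr <- c(0, 4, 8, 12, 16, 20)
  cells <- data.frame(participant_id = "P01", snr = snr,
                      ppd = -(snr - 12)^2 / 15 + 6 + sin(snr))
  s <- participant_shape(cells)
  # mean does not depend on any coding
  expect_equal(s$mean_ppd, mean(cells$ppd))
  # quadratic coefficient sign under raw-SNR coding matches
  raw <- coef(lm(ppd ~ snr + I(snr^2), cells))[3]
  expect_equal(sign(unname(raw)), sign(s$quad_coef))
})

test_that("word-group analysis: null interaction for a shared curve, detected interaction for split tipping points", {
  snr <- c(0, 4, 8, 12, 16, 20)
  profs <- generate_profiles(10, effect_config(), seed = 2)
  shared <- make_cells(10, function(s) -(s - 10)^2 / 30 + 4,
                       shifts = runif(10), noise_sd = 0.05, seed = 3)
  shared$participant_id <- rep(profs$participant_id, each = 6)
  wg0 <- suppressMessages(wordgroup_analysis(shared, profs))
  expect_gt(wg0$interaction$lrt$p, 0.05)
  expect_equal(sort(as.integer(table(wg0$groups$wordgroup))), c(5L, 5L))

  # tie at the median joins the lower group
  profs_tie <- profs
  profs_tie$word_recognition <- c(rep(60, 5), 60, rep(90, 4))
  wgt <- suppressMessages(wordgroup_analysis(shared, profs_tie))
  expect_equal(sum(wgt$groups$wordgroup == "low"), 6)

  # groups with tipping points at 4 vs 16 dB produce an interaction and
  # group-specific peak locations
  presets <- rbind(
    do.call(rbind, lapply(1:5, function(i) {
      p <- make_profile(tip = 16, id = sprintf("L%02d", i)); p$word_recognition <- 55; p
    })),
    do.call(rbind, lapply(1:5, function(i) {
      p <- make_profile(tip = 4, id = sprintf("H%02d", i)); p$word_recognition <- 95; p
    })))
  cells2 <- do.call(rbind, lapply(seq_len(nrow(presets)), function(i) {
    set.seed(400 + i)
    data.frame(participant_id = presets$participant_id[i], snr = snr,
               ppd = effort_peak(snr, presets[i, ]) + rnorm(6, 0, 0.3))
  }))
  wg <- suppressMessages(wordgroup_analysis(cells2, presets))
  expect_lt(wg$interaction$lrt$p, 0.05)
  low_means <- tapply(cells2$ppd[grepl("^L", cells2$participant_id)],
                      cells2$snr[grepl("^L", cells2$participant_id)], mean)
  high_means <- tapply(cells2$ppd[grepl("^H", cells2$participant_id)],
                       cells2$snr[grepl("^H", cells2$participant_id)], mean)
  expect_equal(as.numeric(names(which.max(low_means))), 16)
  expect_equal(as.numeric(names(which.max(high_means))), 4)

  # identical covariate distributions give near-zero Welch t
  presets$age <- 50
  wg2 <- suppressMessages(wordgroup_analysis(cells2, presets))
  expect_equal(wg2$covariate_tests$t[wg2$covariate_tests$covariate == "age"], 0)
})

test_that("likelihood-ratio statistics are nonnegative and adding a term never hurts the likelihood", {
  set.seed(9)
  cells <- make_cells(8, function(s) 0.1 * s + 2, shifts = rnorm(8),
                      noise_sd = 0.4)
  fit <- suppressMessages(fit_condition_model(cells))
  expect_gte(fit$lrt$chisq, 0)
  pfit <- suppressMessages(fit_polynomial_model(cells))
  expect_true(all(pfit$lrt$chisq >= -1e-8))
})
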