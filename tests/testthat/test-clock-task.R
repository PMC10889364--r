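test_that("contingency schedules satisfy their defining invariants", {
  tt <- seq(0.05, 3.95, by = 0.05)
  cons <- lapply(c("IEV", "DEV", "CEV", "CEVR"), make_contingency)
  names(cons) <- c("IEV", "DEV", "CEV", "CEVR")
  for (cc in cons) {
    p <- cc$p(tt); m <- cc$m(tt)
    expect_true(all(p >= 0 & p <= 1), info = cc$label)
    expect_true(all(m > 0), info = cc$label)
    # p and m each monotone
    expect_true(all(diff(p) >= 0) || all(diff(p) <= 0), info = cc$label)
    expect_true(all(diff(m) >= 0) || all(diff(m) <= 0), info = cc$label)
  }
  # constant expected value to within 1% on the unlearnable contingencies
  expect_equal(cons$CEV$ev(0.5) / cons$CEV$ev(3.5), 1, tolerance = 0.01)
  expect_lt(diff(range(cons$CEVR$ev(tt))) / mean(cons$CEVR$ev(tt)), 0.01)
  # learnable contingencies are strictly monotone in expected value
  expect_true(all(diff(cons$IEV$ev(tt)) > 0))
  expect_true(all(diff(cons$DEV$ev(tt)) < 0))
  expect_gt(cons$IEV$ev(3.5), cons$IEV$ev(0.5))
  # CEVR reverses the probability/magnitude trade-off of CEV
  expect_true(all(diff(cons$CEV$p(tt)) < 0))
  expect_true(all(diff(cons$CEVR$p(tt)) > 0))
  # invalid schedules error rather than silently clipping
  expect_error(make_contingency("CEV", ev_params = list(ev = 500)),
               "outside")
})

test_that("session designs encode the three study structures", {
  d1 <- session_design("fmri_original")
  expect_equal(d1$n_trials, 400L)
  expect_equal(sort(table(d1$run_contingencies)),
               sort(table(rep(c("IEV", "DEV", "CEV", "CEVR"), 2))))
  expect_equal(session_design("meg_original")$n_trials, 8L * 63L)
  d3 <- session_design("replication")
  expect_equal(d3$n_trials, 240L)
  expect_equal(d3$trial_length, 5)
  # contingency alternates in 40-trial blocks: 6 blocks, switches at the
  # start of blocks 2..6
  expect_equal(reversal_trials(d3), c(41L, 81L, 121L, 161L, 201L))
  labels <- sceptic:::.design_labels(d3)
  expect_equal(length(rle(labels)$lengths), 6L)
  expect_true(all(rle(labels)$lengths == 40L))
  expect_equal(unique(rle(labels)$values), c("IEV", "DEV"))
  expect_equal(reversal_trials(d1), integer(0))
  # scan TR profiles for the neural-design module
  expect_equal(d1$tr, 1.0)
  expect_equal(d3$tr, 0.6)
})

test_that("sessions are reproducible and reversals do not reset the agent", {
  des <- session_design("replication")
  p <- agent_params(0.1, 5, 0.3)
  l1 <- generate_session(des, p, seed = 41)
  l2 <- generate_session(des, p, seed = 41)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  expect_equal(nrow(l1), 240L)
  expect_equal(unique(l1$contingency[1:40]), "IEV")
  expect_equal(unique(l1$contingency[41:80]), "DEV")
  # feedback onset = trial onset + rt; onsets strictly increasing
  expect_equal(l1$feedback_onset, l1$trial_onset + l1$rt)
  expect_true(all(diff(l1$trial_onset) > 0))
  # replay across the reversal against a fresh continuous replay: identical
  # latents prove the weights were carried through the reversal unreset
  lat <- refit_at_group_means(l1, c(alpha = 0.1, beta = 5, gamma = 0.3),
                              rule = "selective",
                              cfg = basis_config(interval_length = 5),
                              reset_per_run = FALSE)
  ref <- replay_agent(basis_config(interval_length = 5), p, l1$rt, l1$reward,
                      rule = "selective")
  expect_equal(lat$entropy, ref$entropy, tolerance = 1e-12)
})

test_that("cohort generation respects the population spec and reproduces", {
  spec <- cohort_spec(n_subjects = 5)
  des <- session_design("fmri_original", n_runs = 1L)
  co1 <- generate_cohort(spec, des, seed = 51)
  co2 <- generate_cohort(spec, des, seed = 51)
  expect_identical(co1$truth, co2$truth)
  expect_identical(as.data.frame(co1$logs), as.data.frame(co2$logs))
  expect_equal(nrow(co1$truth), 5L)
  expect_setequal(unique(co1$logs$subject), co1$truth$subject)
  expect_true(all(co1$truth$alpha > 0 & co1$truth$alpha < 1))
  expect_true(all(co1$truth$beta > 0))
  expect_true(all(co1$truth$gamma >= 0 & co1$truth$gamma <= 1))
  # near-degenerate population SDs give essentially identical subjects
  tight <- cohort_spec(n_subjects = 4, sd = c(alpha = 1e-9, beta = 1e-9,
                                              gamma = 1e-9))
  co3 <- generate_cohort(tight, des, seed = 52)
  expect_lt(diff(range(co3$truth$alpha)), 1e-8)
  expect_lt(diff(range(co3$truth$beta)), 1e-7)
  expect_error(cohort_spec(n_subjects = 4, sd = c(alpha = 0, beta = 1,
                                                  gamma = 1)), "positive")
})

test_that("stronger selective maintenance compresses late-run entropy", {
  des <- session_design("fmri_original", n_runs = 2L,
                        run_contingencies = c("IEV", "DEV"))
  hi <- cohort_spec(n_subjects = 6,
                    mean = c(alpha = qlogis(0.1), beta = log(5),
                             gamma = qlogis(0.6)),
                    sd = c(alpha = 0.1, beta = 0.1, gamma = 0.1))
  lo <- cohort_spec(n_subjects = 6,
                    mean = c(alpha = qlogis(0.1), beta = log(5),
                             gamma = qlogis(0.02)),
                    sd = c(alpha = 0.1, beta = 0.1, gamma = 0.1))
  late <- function(co) {
    dplyr::summarise(
      dplyr::filter(co$logs, trial_in_run > 40),
      h = mean(entropy))$h
  }
  expect_lt(late(generate_cohort(hi, des, seed = 61)),
            late(generate_cohort(lo, des, seed = 61)))
})

test_that("synthetic neural responses embed the generating effect exactly", {
  des <- session_design("fmri_original", n_runs = 1L)
  lg <- generate_session(des, agent_params(0.1, 5, 0.3), seed = 71)
  em <- effect_map_bump(amplitude = 2, peak = 1)
  # noise-free, no subject intercepts: regression at the peak recovers the
  # amplitude exactly
  ep <- synth_neural(lg, em, noise_sd = 0, seed = 72, intercept_sd = 0)
  at1 <- dplyr::filter(ep, time == 1)
  z <- as.numeric(scale(lg$entropy_change))
  fit <- lm(at1$response ~ z)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-9)
  # null effect map: responses are pure noise, slope centers on zero
  ep0 <- synth_neural(lg, effect_map = NULL, noise_sd = 1, seed = 73,
                      intercept_sd = 0)
  at0 <- dplyr::filter(ep0, time == 1)
  f0 <- lm(at0$response ~ z)
  expect_lt(abs(coef(f0)[2]), 3 * summary(f0)$coefficients[2, 2])
})

test_that("effect-curve peak time is recoverable from noisy cohort data", {
  des <- session_design("fmri_original", n_runs = 1L)
  co <- generate_cohort(cohort_spec(n_subjects = 40), des, seed = 81)
  ep <- synth_neural(co$logs, effect_map_bump(amplitude = 1, peak = 1),
                     noise_sd = 0.5, seed = 82)
  joined <- dplyr::inner_join(
    ep, co$logs[c("subject", "trial", "entropy_change")],
    by = c("subject", "trial"))
  curve <- joined |>
    dplyr::group_by(time) |>
    dplyr::summarise(beta = coef(lm(response ~ entropy_change + subject,
                                    data = dplyr::pick(dplyr::everything())))[2],
                     .groups = "drop")
  expect_lte(abs(curve$time[which.max(curve$beta)] - 1), 1)
})
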