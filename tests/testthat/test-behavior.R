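test_that("RT swings are absolute first differences within run", {
  lg <- tibble::tibble(subject = "a", run = rep(1:2, each = 4),
                       rt = c(2, 2, 2, 2, 1, 3, 1, 3))
  sw <- rt_swings(lg)
  expect_equal(sw$rt_swing, c(NA, 0, 0, 0, NA, 2, 2, 2))
  # invariant to adding a constant to all RTs
  sw2 <- rt_swings(dplyr::mutate(lg, rt = rt + 0.7))
  expect_equal(sw2$rt_swing, sw$rt_swing)
})

test_that("KLD history statistic has the divergence properties", {
  # meg preset: RTs at t-3, t-2 versus the last RT
  mk <- function(rts) tibble::tibble(subject = "a", run = 1, rt = rts)
  k_same <- kld_rt_history(mk(c(1.0, 1.0, 1.0, 2.0)), cfg = test_cfg,
                           window_spec = "meg")
  expect_equal(k_same$kld[4], 0, tolerance = 1e-12)
  expect_equal(k_same$log_kld[4], log(1e-6))  # floored log transform
  # divergence grows with the separation of the windows
  k_far <- kld_rt_history(mk(c(1.0, 1.0, 3.0, 2.0)), cfg = test_cfg,
                          window_spec = "meg")$kld[4]
  k_near <- kld_rt_history(mk(c(1.0, 1.0, 1.2, 2.0)), cfg = test_cfg,
                           window_spec = "meg")$kld[4]
  expect_gt(k_far, k_near)
  expect_gt(k_near, 0)
  # nonnegative for arbitrary histories, under every preset
  set.seed(201)
  lg <- mk(runif(40, 0.05, 3.95))
  max_lag <- c(behavioral = 4L, fmri = 4L, meg = 3L)
  for (ws in c("behavioral", "fmri", "meg")) {
    kk <- kld_rt_history(lg, cfg = test_cfg, window_spec = ws)
    expect_true(all(kk$kld >= 0, na.rm = TRUE), info = ws)
    # exactly the trials without enough history are missing
    expect_true(all(is.na(kk$kld[seq_len(max_lag[[ws]])])), info = ws)
    expect_true(all(!is.na(kk$kld[-seq_len(max_lag[[ws]])])), info = ws)
  }
  # pure function of the RT sequence: subject identity is irrelevant
  kk1 <- kld_rt_history(lg, cfg = test_cfg)
  kk2 <- kld_rt_history(dplyr::mutate(lg, subject = "b"), cfg = test_cfg)
  expect_equal(kk1$kld, kk2$kld)
})

test_that("buffer regression dataset lays out lags, products and filters", {
  lg <- tibble::tibble(subject = "a", run = 1, trial = 1:2,
                       trial_in_run = 1:2,
                       rt = c(1, 2), rewarded = c(1L, 0L))
  ds <- buffer_regression_dataset(lg, k = 1)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$rt_lag1, 1)
  expect_equal(ds$reward_lag1, 1)

  des <- session_design("fmri_original", n_runs = 2L)
  full <- generate_session(des, agent_params(0.1, 5, 0.2), seed = 211)
  ds5 <- buffer_regression_dataset(full, k = 5)
  expect_equal(nrow(ds5), 2L * (50L - 5L))
  # lag columns equal the shifted series, element-wise
  one <- ds5[ds5$run == 1, ]
  src <- full[full$run == 1, ]
  for (j in 1:5) {
    expect_equal(one[[paste0("rt_lag", j)]],
                 src$rt[(6 - j):(50 - j)])
    expect_equal(one[[paste0("rt_x_reward_lag", j)]],
                 one[[paste0("rt_lag", j)]] * one[[paste0("reward_lag", j)]])
  }
  expect_equal(one$inv_trial, 1 / src$trial_in_run[6:50])
  expect_true("rt_vmax" %in% names(ds5))
  # replication novelty filter drops the first 10 trials of each block
  rep_lg <- generate_session(session_design("replication"),
                             agent_params(0.1, 5, 0.2), seed = 212)
  dsr <- buffer_regression_dataset(rep_lg, k = 3, drop_first = 10)
  pos <- (dsr$trial - 1) %% 40 + 1
  expect_true(all(pos > 10))
})

test_that("the value maximum adds predictive power beyond the choice buffer", {
  des <- session_design("fmri_original")
  # cohort replicates: pooled regression with subject intercepts, trained on
  # odd trials and scored on held-out even trials
  gains <- vapply(1:8, function(r) {
    co <- generate_cohort(cohort_spec(n_subjects = 5), des, seed = 3000 + r)
    ds <- buffer_regression_dataset(co$logs, k = 5)
    train <- ds$trial %% 2 == 1
    base_fml <- rt ~ subject + rt_lag1 + rt_lag2 + rt_lag3 + rt_lag4 +
      rt_lag5 + reward_lag1 + rt_x_reward_lag1 + inv_trial
    f0 <- lm(base_fml, data = ds[train, ])
    f1 <- lm(update(base_fml, . ~ . + rt_vmax), data = ds[train, ])
    sse <- function(f) sum((ds$rt[!train] - predict(f, ds[!train, ]))^2)
    sse(f0) - sse(f1)
  }, numeric(1))
  # held-out error drops in the majority of replicates
  expect_gt(mean(gains > 0), 0.5)
})

test_that("survival records count down the window and flag the event bin", {
  cfg <- test_cfg
  mk <- function(rt) {
    lg <- tibble::tibble(subject = "a", run = 1, trial = 1, rt = rt,
                         reward = 10, rt_bin = rt_to_bin(cfg, rt))
    vals <- matrix(seq(0, 39) / 10, nrow = 1)  # value = bin index / 10
    survival_dataset(lg, values = vals, cfg = cfg)
  }
  # response at 2.0 s: ten 100-ms records from 1000 ms, event in the last
  ds <- mk(2.0)
  expect_equal(nrow(ds), 10L)
  expect_equal(ds$start, seq(1000, 1900, by = 100))
  expect_equal(ds$stop, ds$start + 100)
  expect_equal(ds$event, c(rep(0L, 9), 1L))
  # the value covariate reads the pre-choice value function at each bin
  expect_equal(ds$value, (ds$start / 100) / 10)
  # pre-window response: no records
  expect_equal(nrow(mk(0.8)), 0L)
  # post-window response: the full 25-bin window, all censored
  ds <- mk(3.9)
  expect_equal(nrow(ds), 25L)
  expect_true(all(ds$event == 0L))
})

test_that("survival at-risk counts are nonincreasing and engine-ready", {
  des <- session_design("fmri_original", n_runs = 2L)
  lg <- generate_session(des, agent_params(0.1, 5, 0.2), seed = 231)
  lat <- refit_at_group_means(lg, c(alpha = 0.1, beta = 5, gamma = 0.2),
                              "selective")
  ds <- survival_dataset(lat)
  expect_true(all(ds$start >= 1000 & ds$stop <= 3500))
  at_risk <- table(ds$start)
  expect_true(all(diff(as.numeric(at_risk)) <= 0))
  # at most one event per trial
  ev <- dplyr::summarise(dplyr::group_by(ds, trial), n = sum(event))
  expect_true(all(ev$n <= 1))
  # the table drops straight into a Cox model with a time-varying covariate
  fit <- survival::coxph(survival::Surv(start, stop, event) ~ value,
                         data = ds)
  expect_true(is.finite(coef(fit)[["value"]]))
})
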