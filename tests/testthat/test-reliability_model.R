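# Split assignment, hierarchical latency and accuracy fits, participant
# effect extraction. Fits use small designs and short chains; the full-size
# parameter-recovery study lives in the acceptance suite.

test_that("split assignment labels halves by parity, position, session, condition", {
  sim <- simulate_dataset(tiny_params(n_participants = 4, n_items = 150,
                                      seed = 41))
  one <- sim$trials[sim$trials$participant_id == "p001" &
                      sim$trials$session == 1, ]
  eo <- assign_split(one, split_spec("even_odd"))
  expect_equal(sum(eo$half == 1), 75)
  expect_equal(eo$half, ifelse(one$trial_index %% 2 == 1, 1L, 2L))
  fs <- assign_split(one, split_spec("first_second"))
  expect_true(all(fs$half[fs$trial_index <= 75] == 1))
  expect_true(all(fs$half[fs$trial_index > 75] == 2))
  # exclusions do not renumber: dropping trial 3 keeps original parity
  dropped <- one[one$trial_index != 3, ]
  eo2 <- assign_split(dropped, split_spec("even_odd"))
  expect_equal(eo2$half, ifelse(dropped$trial_index %% 2 == 1, 1L, 2L))
  ses <- assign_split(sim$trials, split_spec("session"))
  expect_equal(ses$half, ses$session)
  con <- assign_split(sim$trials, split_spec("condition"))
  expect_equal(attr(con, "half_labels"), c("session1", "session2"))
  expect_error(assign_split(one, split_spec("session")), "two sessions")
})

test_that("prior anchors put the latency prior on the intended millisecond scale", {
  anchors <- prior_latency_anchors(model_spec())
  expect_equal(round(anchors[["median"]]), 854)
  expect_equal(round(anchors[["lower"]]), 191)
  expect_equal(round(anchors[["upper"]]), 3828)
})

test_that("session-split fit recovers the cross-session correlation direction", {
  sim <- simulate_dataset(generative_params(
    n_participants = 30, n_items = 40, rho_subj = 0.8, seed = 43))
  f <- filter_trials(sim$trials)$trials
  fit <- quiet_fit(f, split_spec("session"), tiny_spec(seed = 43))
  realized <- cor(sim$truth$subj_speed)[1, 2]
  expect_true(all(fit$correlation$draws >= -1 & fit$correlation$draws <= 1))
  expect_lte(fit$correlation$ci_low, fit$correlation$mean)
  expect_lte(fit$correlation$mean, fit$correlation$ci_high)
  expect_lt(abs(fit$correlation$mean - realized), 0.35)
  expect_gt(fit$correlation$mean, 0.2)
  # seeded refit reproduces the posterior exactly
  fit2 <- quiet_fit(f, split_spec("session"), tiny_spec(seed = 43))
  expect_equal(fit$correlation$mean, fit2$correlation$mean)
  expect_identical(fit$participant_effects, fit2$participant_effects)
})

test_that("near-noise-free even/odd split drives the correlation toward 1", {
  sim <- simulate_dataset(tiny_params(
    n_participants = 12, n_items = 30, sigma = 0.01, seed = 44))
  f <- filter_trials(sim$trials)$trials
  f1 <- f[f$session == 1, ]
  fit <- quiet_fit(f1, split_spec("even_odd"), tiny_spec(seed = 44))
  expect_gt(fit$correlation$mean, 0.9)
})

test_that("fits validate their inputs", {
  sim <- simulate_dataset(tiny_params(seed = 45))
  expect_error(fit_reliability(sim$trials, split_spec("session"), tiny_spec()),
               "correct responses")
  f <- filter_trials(sim$trials)$trials
  # a participant with no trials in one half
  drop <- !(f$participant_id == "p001" & f$session == 2)
  expect_error(fit_reliability(f[drop, ], split_spec("session"), tiny_spec()),
               "empty half")
})

test_that("accuracy fit recovers the grand intercept and flags the planted straggler", {
  sim <- simulate_dataset(generative_params(
    n_participants = 30, n_items = 50, n_low_accuracy = 1, seed = 46))
  acc <- quiet_acc(sim$trials, split_spec("session"),
                   tiny_spec(seed = 46, prior_intercept_mean = 0,
                             prior_intercept_sd = 1.5))
  # planted participant (45% accuracy) has the most negative effect
  eff1 <- extract_participant_effects(acc, "accuracy", 1)
  expect_equal(names(which.min(eff1)), sim$truth$planted$low_accuracy)
  # grand intercept within a wide recovery band of the generating 3 log-odds
  # (the planted straggler pulls the pooled intercept slightly down)
  expect_lt(abs(acc$fixed[1] - 3), 0.8)
})

test_that("participant effect extraction is condition-aware, stable, and typed", {
  sim <- simulate_dataset(generative_params(
    n_participants = 25, n_items = 40, rho_subj = 0.8, seed = 47))
  f <- filter_trials(sim$trials)$trials
  fit <- quiet_fit(f, split_spec("session"), tiny_spec(seed = 47))
  e1 <- extract_participant_effects(fit, "speed", "session1")
  e1b <- extract_participant_effects(fit, "speed", 1)
  expect_identical(e1, e1b)
  expect_equal(names(e1), sort(unique(f$participant_id)))
  # shrunken estimates track the realized per-participant truth closely
  expect_gt(cor(e1, sim$truth$subj_speed[names(e1), 1]), 0.9)
  expect_error(extract_participant_effects(fit, "speed", "bogus"), "unknown")
  expect_error(extract_participant_effects(fit, "accuracy", 1), "does not")
})
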