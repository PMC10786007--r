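# Reading, validation, classification, exclusion reporting, gating.

test_that("classification follows the no_response > disfluency > wrong_word precedence", {
  expect_equal(classify_response("dog", "dog", FALSE, TRUE), "correct")
  expect_equal(classify_response("dog", NA, FALSE, FALSE), "no_response")
  expect_equal(classify_response("dog", "d-dog dog", TRUE, TRUE), "disfluency")
  expect_equal(classify_response("dog", "cat", FALSE, TRUE), "wrong_word")
  # disfluency wins over wrong word; absence of onset wins over everything
  expect_equal(classify_response("dog", "cat", TRUE, TRUE), "disfluency")
  expect_equal(classify_response("dog", "cat", TRUE, FALSE), "no_response")
  # normalization: case, whitespace, leading article
  expect_equal(classify_response("dog", " The DOG ", FALSE, TRUE), "correct")
  expect_equal(classify_response("Anchor", "anchor", FALSE, TRUE), "correct")
  expect_error(classify_response("", "dog", FALSE, TRUE), "non-empty")
})

test_that("trial CSV write-then-read round-trips a simulated dataset", {
  sim <- simulate_dataset(tiny_params(seed = 7))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, tmp)
  back <- read_trials(tmp)
  expect_equal(nrow(back), nrow(sim$trials))
  cols <- setdiff(names(back), "latency_ms")
  a <- sim$trials[cols]; rownames(a) <- NULL
  b <- back[cols]; rownames(b) <- NULL
  expect_equal(b, a, tolerance = 1e-12)
  expect_equal(back$response_class, sim$trials$response_class)
})

test_that("malformed trial tables are rejected with informative errors", {
  sim <- simulate_dataset(tiny_params(seed = 8))
  trials <- sim$trials
  tmp <- withr::local_tempfile(fileext = ".csv")

  bad <- trials
  bad$vocal_onset_ms[1] <- bad$picture_onset_ms[1] - 10  # onset before picture
  bad$latency_ms <- NULL
  write_trials(bad, tmp)
  expect_error(read_trials(tmp), "latency")

  bad2 <- trials[, setdiff(names(trials), "item_id")]
  utils::write.csv(bad2, tmp, row.names = FALSE, na = "")
  expect_error(read_trials(tmp), "item_id")

  bad3 <- trials
  bad3$trial_index[2] <- bad3$trial_index[1]  # duplicate index in a session
  expect_error(validate_trials(bad3), "duplicate")

  bad4 <- trials
  bad4$vocal_onset_ms[trials$response_class == "correct"][1] <- NA
  expect_error(validate_trials(bad4), "no_response")
})

test_that("exclusion report reproduces printed-percent conventions and sums", {
  # 50 x 150 session-1 style table with a planted error composition
  P <- 50; I <- 150
  n <- P * I
  cls <- rep("correct", n)
  cls[1:232] <- "wrong_word"
  cls[233:273] <- "disfluency"   # 41 trials
  cls[274:366] <- "no_response"  # 93 trials
  trials <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:P), each = I),
    session = 1L, condition = "naming",
    trial_index = rep(1:I, P),
    item_id = rep(sprintf("i%03d", 1:I), P),
    target_word = "w", picture_onset_ms = 500,
    vocal_onset_ms = ifelse(cls == "no_response", NA, 1400),
    response_word = ifelse(cls == "no_response", NA,
                           ifelse(cls == "wrong_word", "x", "w")),
    disfluent = cls == "disfluency",
    response_class = cls, stringsAsFactors = FALSE
  )
  out <- filter_trials(trials)
  rep1 <- out$report
  expect_equal(rep1$percent[rep1$response_class == "wrong_word"], 3.09)
  expect_equal(rep1$percent[rep1$response_class == "disfluency"], 0.55)
  expect_equal(rep1$percent[rep1$response_class == "no_response"], 1.24)
  expect_equal(sum(rep1$count), n)
  expect_true(all(rep1$denominator == n))
  # percent * denominator / 100 matches counts at the printed 2 decimals
  expect_equal(round(rep1$percent * rep1$denominator / 100),
               rep1$count, tolerance = 0.5)
  expect_true(all(out$trials$response_class == "correct"))

  # idempotence
  again <- filter_trials(out$trials)
  expect_equal(again$trials, out$trials)
  expect_equal(sum(again$report$count[again$report$response_class != "correct"]), 0)

  expect_error(filter_trials(trials[0, ]), "empty")
})

test_that("exclusion percentages track planted generator rates at scale", {
  params <- generative_params(p_noresponse = 0.02, seed = 31)
  sim <- simulate_dataset(params)
  expect_equal(nrow(sim$trials), 50 * 150 * 2)
  rep_ <- filter_trials(sim$trials)$report
  nr <- rep_[rep_$response_class == "no_response", ]
  # binomial sampling error at n = 7500 per session: 3 SD ~ 0.5 points
  expect_true(all(abs(nr$percent - 2) < 0.6))
  # report counts agree with the generator's own bookkeeping
  expect_equal(nr$count, unname(sim$truth$planted$n_noresponse))
})

test_that("participant gating excludes below-threshold accuracy, keeps exactly 60%", {
  base <- expand.grid(trial_index = 1:10, participant_id = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  base$session <- 1L; base$condition <- "naming"
  base$item_id <- sprintf("i%02d", base$trial_index)
  base$target_word <- "w"; base$picture_onset_ms <- 500
  # a: 5/10 correct; b: 6/10 (exactly 60%); c: 10/10
  n_correct <- c(a = 5, b = 6, c = 10)
  base$response_class <- unlist(lapply(names(n_correct), function(p) {
    k <- n_correct[[p]]
    c(rep("correct", k), rep("wrong_word", 10 - k))
  }))
  base$vocal_onset_ms <- 1400
  base$response_word <- ifelse(base$response_class == "correct", "w", "x")
  base$disfluent <- FALSE
  g <- gate_participants(base, threshold = 0.60)
  expect_setequal(g$excluded, "a")
  expect_setequal(g$retained, c("b", "c"))
  expect_error(gate_participants(base, threshold = 0), "threshold")
  expect_error(gate_participants(base, threshold = 1.5), "threshold")
})

test_that("a planted low-accuracy participant is exactly the one gated out", {
  sim <- simulate_dataset(tiny_params(n_participants = 12, n_items = 40,
                                      n_low_accuracy = 1, seed = 13))
  g <- gate_participants(sim$trials)
  expect_equal(g$excluded, sim$truth$planted$low_accuracy)
  expect_equal(length(g$retained), 11)
})
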