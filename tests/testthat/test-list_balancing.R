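# Feature standardization, cosine similarity, sampled matching vs.
# exhaustive search, list partition properties, summaries.

test_that("z-scoring standardizes each feature and flags degenerate input", {
  norms2 <- data.frame(word = c("a", "b"), zipf_frequency = c(1, 3),
                       aoa = c(1, 3), h_index = c(1, 3))
  z <- zscore_features(norms2, sd_type = "population")
  expect_equal(unname(z), matrix(c(-1, 1), 2, 3), tolerance = 1e-12)

  norms <- make_norms(310)
  z <- zscore_features(norms)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  # two-pass brute-force oracle, column by column
  for (j in 1:3) {
    x <- norms[[j + 1]]
    expect_equal(unname(z[, j]), (x - mean(x)) / sd(x), tolerance = 1e-12)
  }
  bad <- norms; bad$aoa <- 5
  expect_error(zscore_features(bad), "aoa")
  expect_error(zscore_features(rbind(norms, norms)), "unique")
})

test_that("cosine similarity matches hand computation and bounds", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  u <- c(1, 2, 3); v <- c(-1, 0, 2)
  expect_equal(cosine_similarity(u, v),
               (1 * -1 + 2 * 0 + 3 * 2) / (sqrt(14) * sqrt(5)),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:2, 1:3), "length")
})

test_that("sampled matching finds the exhaustive optimum on small instances", {
  for (n in c(4, 6, 8)) {
    for (inst in 1:2) {
      norms <- make_norms(n, seed = 10 * n + inst)
      z <- zscore_features(norms)
      best_exhaustive <- max(vapply(all_matchings(n), mean_cosine_of,
                                    numeric(1), z = z))
      out <- balance_lists(norms, n_samples = 5000, seed = inst)
      expect_equal(out$matching$mean_cosine, best_exhaustive,
                   tolerance = 1e-12)
    }
  }
})

test_that("identical twins pair to mean cosine 1 and partition invariants hold", {
  base <- make_norms(3, seed = 3)
  twins <- base
  twins$word <- paste0(base$word, "_twin")
  norms <- rbind(base, twins)  # 6 items, 15 perfect matchings
  out <- balance_lists(norms, n_samples = 20000, seed = 2)
  expect_equal(out$matching$mean_cosine, 1, tolerance = 1e-12)
  # partition: disjoint, equal sizes, union = input
  expect_length(intersect(out$list_a, out$list_b), 0)
  expect_equal(length(out$list_a), length(out$list_b))
  expect_setequal(c(out$list_a, out$list_b), norms$word)
  # reproducible under seed
  again <- balance_lists(norms, n_samples = 20000, seed = 2)
  expect_identical(out$list_a, again$list_a)
  expect_error(balance_lists(make_norms(7)), "even")
})

test_that("balanced lists are closer on each feature than random splits", {
  norms <- make_norms(60, seed = 9)
  out <- balance_lists(norms, n_samples = 20000, seed = 4)
  summ <- summarize_lists(out$list_a, out$list_b, norms)
  gap <- function(col) abs(diff(summ[[col]]))
  obs <- c(gap("frequency_mean"), gap("aoa_mean"), gap("h_index_mean"))
  set.seed(11)
  rand_gaps <- replicate(200, {
    idx <- sample(60, 30)
    a <- norms[idx, ]; b <- norms[-idx, ]
    c(abs(mean(a$zipf_frequency) - mean(b$zipf_frequency)),
      abs(mean(a$aoa) - mean(b$aoa)),
      abs(mean(a$h_index) - mean(b$h_index)))
  })
  # each observed gap below the 95th percentile of random splits
  for (j in 1:3) expect_lt(obs[j], quantile(rand_gaps[j, ], 0.95))
})

test_that("list summaries are plain means/SDs in the table layout", {
  norms <- data.frame(word = letters[1:6], zipf_frequency = 1:6,
                      aoa = 1:6, h_index = 1:6)
  s <- summarize_lists(c("a", "d", "e"), c("b", "c", "f"), norms)
  expect_equal(s$frequency_mean, c(10 / 3, 11 / 3), tolerance = 1e-12)
  expect_equal(s$aoa_mean, c(10 / 3, 11 / 3), tolerance = 1e-12)
  expect_error(summarize_lists(c("a", "b"), c("b", "c"), norms), "overlap")
  expect_error(summarize_lists(c("a", "d"), c("b", "c"), norms), "partition")
})
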