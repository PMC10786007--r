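# Shared fixtures: small generative setups, sampler presets sized for unit
# tests, a brute-force matching enumerator, and a synthetic norms table.

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 10, n_items = 16, seed = 101), list(...))
  do.call(generative_params, args)
}

# sampler settings small enough for per-test fits; convergence thresholds
# scaled accordingly
tiny_spec <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(preset = "reduced", chains = 2, adapt = 200, warmup = 200,
         iter = 300, rhat_max = 1.2, min_ess = 30, seed = seed),
    list(...))
  do.call(model_spec, args)
}

quiet_fit <- function(...) suppressWarnings(fit_reliability(...))
quiet_acc <- function(...) suppressWarnings(fit_accuracy(...))

# synthetic stimulus norms: Zipf frequency, age of acquisition, H-index
make_norms <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    word = sprintf("word%03d", seq_len(n)),
    zipf_frequency = round(rnorm(n, 4.2, 0.6), 2),
    aoa = round(rnorm(n, 5.4, 1.5), 2),
    h_index = round(pmax(0, rnorm(n, 0.13, 0.16)), 3),
    stringsAsFactors = FALSE
  )
}

# all perfect matchings of items 1..n (n even), as lists of 2-column pair
# matrices; used as the exhaustive oracle for the sampling-based balancer
all_matchings <- function(n) {
  rec <- function(items) {
    if (!length(items)) return(list(matrix(integer(0), ncol = 2)))
    first <- items[1]
    out <- list()
    for (j in seq_along(items)[-1]) {
      rest <- items[-c(1, j)]
      for (sub in rec(rest)) {
        out[[length(out) + 1]] <- rbind(c(first, items[j]), sub)
      }
    }
    out
  }
  rec(seq_len(n))
}

mean_cosine_of <- function(pairs, z) {
  mean(vapply(seq_len(nrow(pairs)), function(k) {
    cosine_similarity(z[pairs[k, 1], ], z[pairs[k, 2], ])
  }, numeric(1)))
}
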