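# Stimulus-list balancing: z-scored feature vectors (Zipf frequency, age of
# acquisition, H-index name agreement), randomized cosine-similarity
# matching, and per-list summaries.

#' Z-score stimulus norm features
#'
#' Turns the per-word norms (Zipf frequency, age of acquisition, H-index)
#' into standardized feature vectors: each feature column is centered and
#' scaled to unit SD. Sample SD (denominator n-1) is the default.
#'
#' @param norms data frame with columns `word`, `zipf_frequency`, `aoa`,
#'   `h_index`; words must be unique and features complete.
#' @param sd_type `"sample"` (n-1) or `"population"` (n) SD.
#' @return numeric matrix (items x 3) with words as row names.
#' @export
zscore_features <- function(norms, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  feats <- c("zipf_frequency", "aoa", "h_index")
  missing_cols <- setdiff(c("word", feats), names(norms))
  if (length(missing_cols)) {
    stop("norms table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(norms) < 2) stop("need at least 2 items")
  if (anyDuplicated(norms$word)) stop("words must be unique")
  x <- as.matrix(norms[, feats])
  if (anyNA(x)) stop("all three features must be present for every item")
  n <- nrow(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  zero_var <- feats[s == 0]
  if (length(zero_var)) {
    stop("zero-variance feature(s): ", paste(zero_var, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, mu), 2, s, "/")
  rownames(z) <- norms$word
  z
}

#' Cosine similarity of two feature vectors
#'
#' @param u,v numeric vectors of equal length; neither all-zero.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have the same length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Balance two stimulus lists by randomized cosine-similarity matching
#'
#' Pairs up the items so that paired items have similar norm profiles, then
#' splits each pair across the two lists. Feature vectors are the z-scored
#' norms; candidate matchings are generated by shuffling the item order and
#' pairing adjacent elements; among `n_samples` random perfect matchings the
#' one with the highest mean pairwise cosine similarity is kept. Each pair
#' then contributes one item to each list, the member sent to list A chosen
#' by a per-pair fair coin. Deterministic under `seed`.
#'
#' @param norms stimulus norms data frame (see [zscore_features()]); the
#'   item count must be even and at least 4.
#' @param n_samples number of random matchings to sample (default one
#'   million, matching the scale at which near-optimal matchings are found
#'   for a few hundred items).
#' @param seed integer seed.
#' @return list with `list_a`, `list_b` (character vectors of words) and
#'   `matching` (class `matching`: data frame of pairs with their cosine
#'   similarity, plus `mean_cosine`).
#' @export
balance_lists <- function(norms, n_samples = 1e6, seed = 1) {
  n <- nrow(norms)
  if (n %% 2 != 0) stop("item count must be even")
  if (n < 4) stop("need at least 4 items")
  if (n_samples < 1) stop("n_samples must be >= 1")
  z <- zscore_features(norms)
  # full pairwise cosine matrix
  norms_len <- sqrt(rowSums(z^2))
  if (any(norms_len == 0)) stop("an item has an all-zero feature vector")
  C <- (z %*% t(z)) / tcrossprod(norms_len)
  C[C > 1] <- 1; C[C < -1] <- -1
  set.seed(seed)
  odd <- seq(1L, n, by = 2L); even <- seq(2L, n, by = 2L)
  best_mean <- -Inf; best_perm <- NULL
  for (k in seq_len(n_samples)) {
    perm <- sample.int(n)
    m <- mean(C[cbind(perm[odd], perm[even])])
    if (m > best_mean) {
      best_mean <- m
      best_perm <- perm
    }
  }
  a_idx <- best_perm[odd]; b_idx <- best_perm[even]
  # per-pair fair coin decides which member goes to list A
  flip <- runif(length(a_idx)) < 0.5
  la <- ifelse(flip, b_idx, a_idx)
  lb <- ifelse(flip, a_idx, b_idx)
  pairs <- data.frame(
    item_a = norms$word[la], item_b = norms$word[lb],
    cosine = C[cbind(la, lb)], stringsAsFactors = FALSE
  )
  matching <- structure(list(pairs = pairs, mean_cosine = best_mean),
                        class = "matching")
  list(list_a = norms$word[la], list_b = norms$word[lb], matching = matching)
}

#' @export
print.matching <- function(x, ...) {
  cat(sprintf("Matching of %d pairs, mean cosine similarity %.3f\n",
              nrow(x$pairs), x$mean_cosine))
  invisible(x)
}

#' Summarize balanced lists on the raw norm features
#'
#' Mean and SD of each raw feature (Zipf frequency, AoA, H-index) per list,
#' in the layout of a stimulus-description table.
#'
#' @param list_a,list_b character vectors of words partitioning `norms$word`.
#' @param norms stimulus norms data frame.
#' @return data frame with one row per list and columns
#'   `frequency_mean, frequency_sd, aoa_mean, aoa_sd, h_index_mean,
#'   h_index_sd`.
#' @export
summarize_lists <- function(list_a, list_b, norms) {
  if (length(intersect(list_a, list_b))) stop("lists overlap")
  if (!setequal(c(list_a, list_b), norms$word)) {
    stop("lists must partition the norms table")
  }
  one <- function(words) {
    x <- norms[match(words, norms$word), ]
    c(frequency_mean = mean(x$zipf_frequency),
      frequency_sd = sd(x$zipf_frequency),
      aoa_mean = mean(x$aoa), aoa_sd = sd(x$aoa),
      h_index_mean = mean(x$h_index), h_index_sd = sd(x$h_index))
  }
  out <- rbind(one(list_a), one(list_b))
  data.frame(list = c("A", "B"), out, stringsAsFactors = FALSE)
}
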