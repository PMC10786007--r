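# Synthetic trial-level data with the statistical structure the reliability
# analysis assumes: lognormal latencies with crossed participant and item
# random effects, a true between-session participant correlation, a logistic
# accuracy model, and planted disfluency / no-response trials.

#' Generative parameters for a simulated naming study
#'
#' Bundles the design sizes, variance components, true correlations, and
#' error rates of the simulated two-session (or two-condition) naming study.
#' Defaults emulate the study design the analysis targets: 50 participants
#' naming 150 pictures per session in two sessions, log-scale grand mean 6.75
#' (about 854 ms), between-participant SD 0.15, between-item SD 0.10 and
#' residual SD 0.30 on the log scale, a true between-session participant
#' correlation of 0.77, near-ceiling accuracy (3 log-odds, about 95%
#' correct), and small disfluency / no-response rates comparable to the
#' 0.5--1.2% observed in online naming data.
#'
#' The joint by-participant effect vector
#' `(speed_1, speed_2, accuracy_1, accuracy_2)` is multivariate normal with
#' correlations: `rho_subj` between the two speed effects, `rho_acc` between
#' the two accuracy effects, `rho_speed_acc[c]` between speed and accuracy
#' within condition `c`, and cross-lagged terms `rho_subj * rho_speed_acc`
#' (a product structure, since only the within-condition speed-accuracy
#' correlations are identified by the design). The resulting correlation
#' matrix must be positive semi-definite.
#'
#' @param n_participants,n_items design sizes per session.
#' @param conditions ordered pair of condition labels; the first maps to
#'   session 1, the second to session 2.
#' @param mu per-condition grand mean log-latency (log-ms); recycled.
#' @param sd_subj per-condition between-participant SD (log-ms); recycled.
#' @param rho_subj true correlation of participant speed effects across
#'   conditions, in `[-1, 1]`.
#' @param sd_item between-item SD (log-ms).
#' @param sigma residual SD (log-ms).
#' @param acc_alpha per-condition grand-mean accuracy (log-odds); recycled.
#' @param acc_sd_subj per-condition between-participant accuracy SD
#'   (log-odds); recycled.
#' @param rho_acc correlation of participant accuracy effects across
#'   conditions.
#' @param rho_speed_acc per-condition correlation between participant speed
#'   and accuracy effects; recycled.
#' @param p_disfluency,p_noresponse per-condition probabilities of a planted
#'   disfluency / no-response trial; recycled.
#' @param items_shared if `TRUE` both sessions use the same item list; the
#'   default `FALSE` emulates the counterbalanced two-list design (disjoint
#'   items across sessions).
#' @param response_window_ms response deadline measured from picture onset;
#'   latencies exceeding it become no-response trials.
#' @param n_low_accuracy number of planted low-accuracy participants
#'   (accuracy forced to about 45%, below the 60% gate).
#' @param seed integer seed; simulation is deterministic given the params.
#' @return object of class `generative_params`.
#' @export
generative_params <- function(n_participants = 50,
                              n_items = 150,
                              conditions = c("session1", "session2"),
                              mu = c(6.75, 6.75),
                              sd_subj = c(0.15, 0.15),
                              rho_subj = 0.77,
                              sd_item = 0.10,
                              sigma = 0.30,
                              acc_alpha = c(3, 3),
                              acc_sd_subj = c(0.5, 0.5),
                              rho_acc = 0.5,
                              rho_speed_acc = c(-0.25, -0.25),
                              p_disfluency = c(0.006, 0.006),
                              p_noresponse = c(0.010, 0.010),
                              items_shared = FALSE,
                              response_window_ms = 3000,
                              n_low_accuracy = 0,
                              seed = 1) {
  p <- list(
    n_participants = as.integer(n_participants),
    n_items = as.integer(n_items),
    conditions = as.character(conditions),
    mu = rep_len(mu, 2), sd_subj = rep_len(sd_subj, 2),
    rho_subj = rho_subj, sd_item = sd_item, sigma = sigma,
    acc_alpha = rep_len(acc_alpha, 2),
    acc_sd_subj = rep_len(acc_sd_subj, 2),
    rho_acc = rho_acc, rho_speed_acc = rep_len(rho_speed_acc, 2),
    p_disfluency = rep_len(p_disfluency, 2),
    p_noresponse = rep_len(p_noresponse, 2),
    items_shared = isTRUE(items_shared),
    response_window_ms = response_window_ms,
    n_low_accuracy = as.integer(n_low_accuracy),
    seed = as.integer(seed)
  )
  if (p$n_participants < 1 || p$n_items < 1) stop("design sizes must be >= 1")
  if (length(p$conditions) != 2) stop("'conditions' must be a pair of labels")
  if (any(c(p$sd_subj, p$sd_item, p$sigma, p$acc_sd_subj) < 0)) {
    stop("all SDs must be >= 0")
  }
  probs <- c(p$p_disfluency, p$p_noresponse)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  cors <- c(p$rho_subj, p$rho_acc, p$rho_speed_acc)
  if (any(abs(cors) > 1)) stop("correlations must be in [-1, 1]")
  R <- participant_effect_corr(p)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("participant effect correlation matrix is not positive semi-definite")
  }
  structure(p, class = "generative_params")
}

# 4x4 correlation matrix of (speed_1, speed_2, acc_1, acc_2)
participant_effect_corr <- function(p) {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- p$rho_subj
  R[3, 4] <- R[4, 3] <- p$rho_acc
  R[1, 3] <- R[3, 1] <- p$rho_speed_acc[1]
  R[2, 4] <- R[4, 2] <- p$rho_speed_acc[2]
  R[1, 4] <- R[4, 1] <- p$rho_subj * p$rho_speed_acc[2]
  R[2, 3] <- R[3, 2] <- p$rho_subj * p$rho_speed_acc[1]
  R
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf(
    "Generative params: %d participants x %d items x 2 sessions (%s / %s)\n",
    x$n_participants, x$n_items, x$conditions[1], x$conditions[2]))
  cat(sprintf("  mu = %.2f/%.2f  sd_subj = %.2f/%.2f  rho_subj = %.2f\n",
              x$mu[1], x$mu[2], x$sd_subj[1], x$sd_subj[2], x$rho_subj))
  cat(sprintf("  sd_item = %.2f  sigma = %.2f  acc_alpha = %.1f/%.1f  seed = %d\n",
              x$sd_item, x$sigma, x$acc_alpha[1], x$acc_alpha[2], x$seed))
  invisible(x)
}

#' Simulate a two-session naming dataset with known ground truth
#'
#' Generates trial records under the hierarchical lognormal model: the
#' log-latency of a trial with a vocal response is
#' `mu[c] + b_subj[p, c] + b_item[i] + eps`, `eps ~ Normal(0, sigma)`, with
#' the joint participant effect vector (speed and accuracy per condition)
#' drawn with the correlation structure of [generative_params()].
#' Correctness is drawn from the logistic accuracy model; disfluencies and
#' no-responses are planted independently at their per-condition rates
#' (precedence no_response > disfluency > wrong_word). Latencies exceeding
#' the response window are censored to no-response. Every participant sees
#' the same items within a session, each in an independently randomized
#' presentation order; trials are timed as 500 ms fixation, 2000 ms picture,
#' 1000 ms blank.
#'
#' @param params a [generative_params()] object.
#' @return list with `trials` (validated trial data frame) and `truth`
#'   (class `ground_truth`: realized `subj_speed` and `subj_acc` matrices
#'   (participants x conditions), `item_effects`, planted exclusion
#'   bookkeeping, and the params).
#' @examples
#' sim <- simulate_dataset(generative_params(n_participants = 4, n_items = 10))
#' head(sim$trials)
#' cor(sim$truth$subj_speed)
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  p <- params
  set.seed(p$seed)
  P <- p$n_participants; I <- p$n_items
  R <- participant_effect_corr(p)
  sds <- c(p$sd_subj, p$acc_sd_subj)
  Sigma <- diag(sds) %*% R %*% diag(sds)
  eff <- matrix(MASS::mvrnorm(P, mu = rep(0, 4), Sigma = Sigma), nrow = P)
  subj_speed <- eff[, 1:2, drop = FALSE]
  subj_acc <- eff[, 3:4, drop = FALSE]
  pid <- sprintf("p%03d", seq_len(P))
  rownames(subj_speed) <- rownames(subj_acc) <- pid

  n_items_total <- if (p$items_shared) I else 2L * I
  item_ids <- sprintf("i%03d", seq_len(n_items_total))
  item_effects <- setNames(rnorm(n_items_total, 0, p$sd_item), item_ids)

  low_ids <- character(0)
  if (p$n_low_accuracy > 0) {
    low_idx <- seq_len(min(p$n_low_accuracy, P))
    low_ids <- pid[low_idx]
    # force total log-odds to about 45% accuracy in every session
    for (s in 1:2) subj_acc[low_idx, s] <- qlogis(0.45) - p$acc_alpha[s]
  }

  trial_dur <- 500 + 2000 + 1000
  rows <- vector("list", 2L)
  for (s in 1:2) {
    items_s <- if (p$items_shared) item_ids else
      item_ids[((s - 1L) * I + 1L):(s * I)]
    # per-participant randomized presentation order
    order_mat <- vapply(seq_len(P), function(i) sample.int(I),
                        integer(I))
    part <- rep(seq_len(P), each = I)
    pos <- rep(seq_len(I), times = P)          # trial_index
    item <- items_s[as.vector(order_mat)]      # item shown at that position
    n <- length(part)
    log_lat <- p$mu[s] + subj_speed[part, s] + item_effects[item] +
      rnorm(n, 0, p$sigma)
    latency <- exp(log_lat)
    correct <- rbinom(n, 1, plogis(p$acc_alpha[s] + subj_acc[part, s])) == 1
    disfl <- runif(n) < p$p_disfluency[s]
    noresp <- runif(n) < p$p_noresponse[s]
    noresp <- noresp | latency > p$response_window_ms
    picture_onset <- (pos - 1) * trial_dur + 500
    target <- paste0("w_", item)
    response <- ifelse(correct, target, paste0("w_alt_", item))
    response[noresp] <- NA
    vocal_onset <- picture_onset + latency
    vocal_onset[noresp] <- NA
    cls <- rep("correct", n)
    cls[!correct] <- "wrong_word"
    cls[disfl & !noresp] <- "disfluency"
    cls[noresp] <- "no_response"
    rows[[s]] <- data.frame(
      participant_id = pid[part], session = s, condition = p$conditions[s],
      trial_index = pos, item_id = item, target_word = target,
      picture_onset_ms = picture_onset, vocal_onset_ms = vocal_onset,
      response_word = response, disfluent = disfl & !noresp,
      response_class = cls, stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, rows)
  trials$latency_ms <- trials$vocal_onset_ms - trials$picture_onset_ms
  validate_trials(trials)
  planted <- list(
    low_accuracy = low_ids,
    n_disfluency = c(by_session = tapply(
      trials$response_class == "disfluency", trials$session, sum)),
    n_noresponse = c(by_session = tapply(
      trials$response_class == "no_response", trials$session, sum))
  )
  truth <- structure(
    list(subj_speed = subj_speed, subj_acc = subj_acc,
         item_effects = item_effects, planted = planted, params = p),
    class = "ground_truth")
  list(trials = trials, truth = truth)
}

#' Expected naive split-half correlation of per-participant means
#'
#' Closed-form expectation of the Pearson correlation between
#' per-participant mean log-latencies computed on two halves of `m` trials
#' each, under the generative model. Within a condition the two halves share
#' the participant effect, so the expected correlation is
#' `sd_subj^2 / (sd_subj^2 + sigma^2 / m)`; across conditions it is
#' `rho * sd1 * sd2 / sqrt((sd1^2 + sigma^2/m) (sd2^2 + sigma^2/m))`.
#' Item effects cancel because every participant sees the same items (the
#' formula assumes a common item-to-half assignment). The value quantifies
#' the attenuation that averaging over trials imposes on the naive
#' estimator: it is strictly below the true correlation whenever
#' `sigma > 0` and approaches it as `m` grows.
#'
#' @param params a [generative_params()] object.
#' @param n_trials_per_half number of trials per half, `m >= 2`.
#' @param scheme `"within"` (two halves of one condition, condition 1's SD)
#'   or `"between"` (one half per condition).
#' @return expected Pearson correlation.
#' @export
expected_naive_split_correlation <- function(params, n_trials_per_half,
                                             scheme = c("within", "between")) {
  stopifnot(inherits(params, "generative_params"))
  scheme <- match.arg(scheme)
  m <- n_trials_per_half
  if (!is.numeric(m) || length(m) != 1 || m < 2) {
    stop("n_trials_per_half must be >= 2")
  }
  noise <- params$sigma^2 / m
  if (scheme == "within") {
    v <- params$sd_subj[1]^2
    v / (v + noise)
  } else {
    s1 <- params$sd_subj[1]; s2 <- params$sd_subj[2]
    params$rho_subj * s1 * s2 / sqrt((s1^2 + noise) * (s2^2 + noise))
  }
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `ground_truth` object from [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(
    subj_speed = as.data.frame(truth$subj_speed),
    subj_acc = as.data.frame(truth$subj_acc),
    item_effects = as.list(truth$item_effects),
    planted = truth$planted,
    params = unclass(truth$params)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
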