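# Bivariate hierarchical estimation of by-participant reliability
# correlations from trial-level naming latencies, and the companion
# hierarchical accuracy model. Both models are sampled with JAGS.
#
# The latency model is a no-intercept model on log latency: instead of an
# intercept and a slope for the half (even/odd, first/second, session, or
# condition), it estimates one intercept per half, and the by-participant
# random effects mirror that structure - one effect per half with a free
# correlation. That correlation is the reliability estimand: shrinkage from
# partial pooling removes the trial-noise attenuation that a Pearson
# correlation of per-participant means suffers from.

#' Split specification for reliability analysis
#'
#' @param scheme how analyzed trials are divided into two halves:
#'   `"even_odd"` (parity of the original presentation index),
#'   `"first_second"` (presentation index at most half the session length),
#'   `"session"` (session 1 vs. 2), or `"condition"` (the two condition
#'   labels, in sorted order).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(scheme = c("even_odd", "first_second", "session",
                                  "condition")) {
  structure(list(scheme = match.arg(scheme)), class = "split_spec")
}

#' Assign each trial to one of two halves
#'
#' Adds a `half` column (integer 1/2) and a `half_label` column. Parity and
#' first/second splits use the original presentation index: trials excluded
#' during preprocessing do not renumber the remaining ones, so a trial keeps
#' its parity after exclusions. The first/second threshold is half the
#' maximum presentation index observed in the trial's session. Odd indices
#' map to half 1 of the even/odd split.
#'
#' @param trials trial data frame (typically filtered to correct responses).
#' @param spec a [split_spec()].
#' @return `trials` with `half` and `half_label` columns.
#' @export
assign_split <- function(trials, spec = split_spec("even_odd")) {
  stopifnot(inherits(spec, "split_spec"))
  scheme <- spec$scheme
  if (scheme == "even_odd") {
    half <- ifelse(trials$trial_index %% 2 == 1, 1L, 2L)
    labels <- c("odd", "even")
  } else if (scheme == "first_second") {
    max_idx <- tapply(trials$trial_index, trials$session, max)
    cut <- max_idx[as.character(trials$session)] / 2
    half <- ifelse(trials$trial_index <= cut, 1L, 2L)
    labels <- c("first", "second")
  } else if (scheme == "session") {
    s <- sort(unique(trials$session))
    if (length(s) != 2) stop("'session' split needs exactly two sessions")
    half <- ifelse(trials$session == s[1], 1L, 2L)
    labels <- paste0("session", s)
  } else {
    cond <- sort(unique(as.character(trials$condition)))
    if (length(cond) != 2) stop("'condition' split needs exactly two conditions")
    half <- ifelse(trials$condition == cond[1], 1L, 2L)
    labels <- cond
  }
  trials$half <- half
  trials$half_label <- labels[half]
  attr(trials, "half_labels") <- labels
  trials
}

#' Sampler and prior settings for the hierarchical models
#'
#' Priors default to the regularizing choices used throughout: latency
#' intercepts Normal(6.75, 1.5) on the log scale (median 854 ms, one prior
#' SD spanning about 191 to 3828 ms), half-Normal(0, 1) for all SDs, and
#' the LKJ prior with eta = 2 on the random-effect correlation (for two
#' halves this is the density proportional to `1 - rho^2`, equivalently
#' `(rho + 1)/2 ~ Beta(2, 2)`). The `"reduced"` preset trades posterior
#' resolution for speed (fewer chains/iterations and proportionally lower
#' effective-sample-size floor) and is intended for simulation studies and
#' test suites; the `"default"` preset is for final inference.
#'
#' @param preset `"default"` (4 chains, 1000 warmup + 1000 kept draws,
#'   split-Rhat threshold 1.01, minimum ESS 400) or `"reduced"` (2 chains,
#'   400 adapt + 400 warmup + 600 kept draws, Rhat 1.05, ESS 100).
#' @param prior_intercept_mean,prior_intercept_sd Normal prior on the
#'   per-half intercepts (log-ms for latency; log-odds for accuracy, where
#'   the conventional values are 0 and 1.5).
#' @param prior_sd_scale scale of the half-Normal prior on SDs.
#' @param lkj_eta LKJ shape for the random-effect correlation.
#' @param chains,adapt,warmup,iter MCMC settings (per chain).
#' @param rhat_max,min_ess convergence thresholds for the correlation.
#' @param seed integer seed; chains use fixed per-chain RNG seeds derived
#'   from it, so runs are reproducible.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(preset = c("default", "reduced"),
                       prior_intercept_mean = 6.75,
                       prior_intercept_sd = 1.5,
                       prior_sd_scale = 1,
                       lkj_eta = 2,
                       chains = NULL, adapt = NULL, warmup = NULL,
                       iter = NULL, rhat_max = NULL, min_ess = NULL,
                       seed = 1) {
  preset <- match.arg(preset)
  def <- if (preset == "default") {
    list(chains = 4L, adapt = 1000L, warmup = 1000L, iter = 1000L,
         rhat_max = 1.01, min_ess = 400)
  } else {
    list(chains = 2L, adapt = 400L, warmup = 400L, iter = 600L,
         rhat_max = 1.05, min_ess = 100)
  }
  structure(list(
    preset = preset,
    prior_intercept_mean = prior_intercept_mean,
    prior_intercept_sd = prior_intercept_sd,
    prior_sd_scale = prior_sd_scale,
    lkj_eta = lkj_eta,
    chains = as.integer(chains %||% def$chains),
    adapt = as.integer(adapt %||% def$adapt),
    warmup = as.integer(warmup %||% def$warmup),
    iter = as.integer(iter %||% def$iter),
    rhat_max = rhat_max %||% def$rhat_max,
    min_ess = min_ess %||% def$min_ess,
    seed = as.integer(seed)
  ), class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prior-scale anchors for the latency intercept prior
#'
#' Millisecond-scale anchors implied by the log-scale Normal intercept
#' prior: the prior median latency `exp(mean)` and the latencies one prior
#' SD below and above, `exp(mean - sd)` and `exp(mean + sd)`. With the
#' default Normal(6.75, 1.5) these are about 854, 191, and 3828 ms.
#'
#' @param spec a [model_spec()].
#' @return named numeric vector `c(median, lower, upper)` in ms.
#' @export
prior_latency_anchors <- function(spec = model_spec()) {
  m <- spec$prior_intercept_mean; s <- spec$prior_intercept_sd
  c(median = exp(m), lower = exp(m - s), upper = exp(m + s))
}

# JAGS code for the bivariate no-intercept latency model. The LKJ(eta)
# prior on a 2x2 correlation matrix reduces to (rho+1)/2 ~ Beta(eta, eta).
# The bivariate participant effect is written in conditional form
# (b2 | b1 is normal) so no matrix inversion is needed; SD priors carry a
# tiny truncation floor (1e-3 on the log scale) purely to keep the
# conditional precision finite in degenerate no-variance corners.
jags_latency_model <- function() {
  "model {
  for (t in 1:N) {
    y[t] ~ dnorm(mu[h[t]] + b[subj[t], h[t]] + u[item[t]], tau_e)
  }
  for (j in 1:2) { mu[j] ~ dnorm(prior_mu, prior_mu_prec) }
  for (p in 1:P) {
    b[p, 1] ~ dnorm(0, tau_b1)
    b[p, 2] ~ dnorm(rho * (sigma_b[2] / sigma_b[1]) * b[p, 1], tau_b2c)
  }
  for (i in 1:I) { u[i] ~ dnorm(0, tau_u) }
  sigma_e ~ dnorm(0, sd_prec) T(0.001,)
  tau_e <- 1 / (sigma_e * sigma_e)
  sigma_u ~ dnorm(0, sd_prec) T(0.001,)
  tau_u <- 1 / (sigma_u * sigma_u)
  sigma_b[1] ~ dnorm(0, sd_prec) T(0.001,)
  sigma_b[2] ~ dnorm(0, sd_prec) T(0.001,)
  tau_b1 <- 1 / (sigma_b[1] * sigma_b[1])
  tau_b2c <- 1 / (sigma_b[2] * sigma_b[2] * (1 - rho * rho) + 1.0E-10)
  urho ~ dbeta(eta, eta)
  rho <- 2 * urho - 1
}"
}

jags_accuracy_model <- function() {
  "model {
  for (t in 1:N) {
    y[t] ~ dbern(ilogit(alpha[h[t]] + a[subj[t], h[t]]))
  }
  for (j in 1:2) { alpha[j] ~ dnorm(prior_mu, prior_mu_prec) }
  for (p in 1:P) {
    a[p, 1] ~ dnorm(0, tau_a1)
    a[p, 2] ~ dnorm(rho * (sigma_a[2] / sigma_a[1]) * a[p, 1], tau_a2c)
  }
  sigma_a[1] ~ dnorm(0, sd_prec) T(0.001,)
  sigma_a[2] ~ dnorm(0, sd_prec) T(0.001,)
  tau_a1 <- 1 / (sigma_a[1] * sigma_a[1])
  tau_a2c <- 1 / (sigma_a[2] * sigma_a[2] * (1 - rho * rho) + 1.0E-10)
  urho ~ dbeta(eta, eta)
  rho <- 2 * urho - 1
}"
}

# split-chain potential scale reduction (Rhat): each chain is halved, and
# the standard between/within variance ratio is computed on the half-chains.
split_rhat <- function(draws_matrix) {
  m <- nrow(draws_matrix) %/% 2L
  halves <- cbind(draws_matrix[seq_len(m), , drop = FALSE],
                  draws_matrix[m + seq_len(m), , drop = FALSE])
  k <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  B <- m * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

run_jags <- function(model_string, data, monitors, spec, inits_extra = list()) {
  inits <- lapply(seq_len(spec$chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = spec$seed * 1000L + ch), inits_extra)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = spec$adapt, quiet = TRUE)
  stats::update(jm, spec$warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = spec$iter,
                      progress.bar = "none")
}

mcmc_param_matrix <- function(samples, par) {
  do.call(cbind, lapply(samples, function(ch) as.numeric(ch[, par])))
}

#' Fit the bivariate hierarchical reliability model
#'
#' Fits, by MCMC, the no-intercept hierarchical model of log naming
#' latencies with one intercept per half, correlated by-participant effects
#' per half, crossed item effects, and the regularizing priors of
#' [model_spec()]. The posterior of the by-participant random-effect
#' correlation is the reliability estimate: for an even/odd or first/second
#' split it is a split-half reliability, for a session split a test-retest
#' reliability, and for a condition split the consistency of participant
#' speed across task variants.
#'
#' Non-convergence (split-Rhat or effective sample size of the correlation
#' beyond the spec's thresholds) is flagged in the diagnostics and raised
#' as a warning, never silently ignored.
#'
#' @param trials trial data frame filtered to correct responses (see
#'   [filter_trials()]), with positive latencies. If `half` is absent,
#'   [assign_split()] is applied first.
#' @param split a [split_spec()].
#' @param spec a [model_spec()].
#' @return object of class `reliability_fit`: `correlation` (a
#'   [posterior_summary()] of the participant-effect correlation),
#'   `participant_effects` (posterior-mean by-participant effects, one
#'   column per half, rows ordered by participant id), `fixed` (posterior
#'   means of the two intercepts), `sigmas`, `samples` (coda draws of the
#'   scalar parameters), `diagnostics`, `split`, `half_labels`.
#' @export
fit_reliability <- function(trials, split = split_spec("even_odd"),
                            spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!"half" %in% names(trials)) trials <- assign_split(trials, split)
  if (any(trials$response_class != "correct")) {
    stop("fit_reliability() expects trials filtered to correct responses")
  }
  if (anyNA(trials$latency_ms) || any(trials$latency_ms <= 0)) {
    stop("all analyzed trials must have positive latencies")
  }
  subj <- factor(trials$participant_id)
  item <- factor(trials$item_id)
  if (nlevels(subj) < 2 || nlevels(item) < 2) {
    stop("need at least 2 participants and 2 items")
  }
  tab <- table(subj, trials$half)
  if (any(tab == 0)) {
    bad <- rownames(tab)[rowSums(tab == 0) > 0]
    stop("participant(s) with an empty half: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  data <- list(
    y = log(trials$latency_ms), h = trials$half,
    subj = as.integer(subj), item = as.integer(item),
    N = nrow(trials), P = nlevels(subj), I = nlevels(item),
    prior_mu = spec$prior_intercept_mean,
    prior_mu_prec = 1 / spec$prior_intercept_sd^2,
    sd_prec = 1 / spec$prior_sd_scale^2,
    eta = spec$lkj_eta
  )
  samples <- run_jags(jags_latency_model(), data,
                      c("rho", "mu", "sigma_b", "sigma_e", "sigma_u", "b"),
                      spec)
  finish_fit(samples, "b", levels(subj), trials, spec,
             class = "reliability_fit")
}

#' Fit the hierarchical accuracy model
#'
#' Binomial-link hierarchical model of trial accuracy (correct vs. any
#' error) with one log-odds intercept per half and correlated
#' by-participant effects, using Normal(0, 1.5) intercept priors on the
#' log-odds scale, half-Normal(0, 1) SD priors, and the LKJ(2) correlation
#' prior. Trials must not be filtered: error trials carry the information.
#' Partial pooling handles participants with all-correct responses (their
#' effects shrink toward zero; no separation failure).
#'
#' @param trials trial data frame including error trials.
#' @param split a [split_spec()] (typically `"condition"` or `"session"`).
#' @param spec a [model_spec()]; default uses accuracy-scale priors
#'   (intercepts Normal(0, 1.5) on the log-odds scale).
#' @return object of class `accuracy_fit` (same shape as
#'   [fit_reliability()]'s result; `participant_effects` are log-odds).
#' @export
fit_accuracy <- function(trials, split = split_spec("condition"),
                         spec = model_spec(prior_intercept_mean = 0,
                                           prior_intercept_sd = 1.5)) {
  stopifnot(inherits(spec, "model_spec"))
  if (!"half" %in% names(trials)) trials <- assign_split(trials, split)
  subj <- factor(trials$participant_id)
  tab <- table(subj, trials$half)
  if (any(tab == 0)) stop("participant(s) with an empty half")
  data <- list(
    y = as.integer(trials$response_class == "correct"),
    h = trials$half, subj = as.integer(subj),
    N = nrow(trials), P = nlevels(subj),
    prior_mu = spec$prior_intercept_mean,
    prior_mu_prec = 1 / spec$prior_intercept_sd^2,
    sd_prec = 1 / spec$prior_sd_scale^2,
    eta = spec$lkj_eta
  )
  samples <- run_jags(jags_accuracy_model(), data,
                      c("rho", "alpha", "sigma_a", "a"), spec)
  finish_fit(samples, "a", levels(subj), trials, spec,
             class = "accuracy_fit")
}

get_half_labels <- function(trials) {
  lab <- attr(trials, "half_labels")
  if (!is.null(lab)) return(lab)
  if ("half_label" %in% names(trials)) {
    lab <- unique(trials[order(trials$half), "half_label"])
    if (length(lab) == 2) return(lab)
  }
  c("half1", "half2")
}

# shared post-processing: summarize rho, compute diagnostics, extract
# posterior-mean participant effects
finish_fit <- function(samples, eff_par, participants, trials, spec, class) {
  rho_mat <- mcmc_param_matrix(samples, "rho")
  rho_draws <- as.numeric(rho_mat)
  rhat <- split_rhat(rho_mat)
  ess <- tryCatch(as.numeric(coda::effectiveSize(samples[, "rho"])),
                  error = function(e) NA_real_)
  converged <- is.finite(rhat) && rhat <= spec$rhat_max &&
    is.finite(ess) && ess >= spec$min_ess
  diagnostics <- list(rhat = rhat, ess = ess, converged = converged,
                      rhat_max = spec$rhat_max, min_ess = spec$min_ess)
  if (!converged) {
    warning(sprintf(
      "correlation posterior flagged as not converged (split-Rhat %.3f, ESS %.0f)",
      rhat, ess), call. = FALSE)
  }
  P <- length(participants)
  all_means <- colMeans(do.call(rbind, samples))
  eff <- matrix(NA_real_, P, 2,
                dimnames = list(participants, get_half_labels(trials)))
  for (j in 1:2) {
    eff[, j] <- all_means[sprintf("%s[%d,%d]", eff_par, seq_len(P), j)]
  }
  intercept_par <- if (eff_par == "b") "mu" else "alpha"
  fixed <- all_means[sprintf("%s[%d]", intercept_par, 1:2)]
  sig_names <- grep("^sigma", names(all_means), value = TRUE)
  scalar_cols <- setdiff(colnames(samples[[1]]),
                         sprintf("%s[%d,%d]", eff_par,
                                 rep(seq_len(P), 2), rep(1:2, each = P)))
  structure(list(
    correlation = posterior_summary(
      mean(rho_draws),
      unname(quantile(rho_draws, 0.025)),
      unname(quantile(rho_draws, 0.975)),
      draws = rho_draws, diagnostics = diagnostics),
    participant_effects = eff,
    fixed = unname(fixed),
    sigmas = all_means[sig_names],
    samples = samples[, scalar_cols, drop = TRUE],
    diagnostics = diagnostics,
    split = get_half_labels(trials),
    half_labels = get_half_labels(trials),
    spec = spec
  ), class = class)
}

#' @export
print.reliability_fit <- function(x, ...) {
  cat("Hierarchical reliability fit (", paste(x$half_labels, collapse = " / "),
      ")\n", sep = "")
  cat("By-participant random-effect correlation:\n  ")
  print(x$correlation)
  invisible(x)
}

#' @export
print.accuracy_fit <- function(x, ...) {
  cat("Hierarchical accuracy fit (", paste(x$half_labels, collapse = " / "),
      ")\n", sep = "")
  cat("By-participant accuracy-effect correlation:\n  ")
  print(x$correlation)
  invisible(x)
}

#' Extract by-participant point estimates from a fitted model
#'
#' Posterior-mean by-participant effects (speed from a
#' [fit_reliability()] object, accuracy from a [fit_accuracy()] object) for
#' one condition/half, as a named vector in stable participant-id order.
#' These are the shrunken estimates that enter downstream correlations,
#' e.g. the speed-accuracy correlation via [estimate_correlation()].
#'
#' @param fit a `reliability_fit` or `accuracy_fit`.
#' @param which `"speed"` or `"accuracy"`; must match the fit type.
#' @param condition half label (see `fit$half_labels`) or index 1/2.
#' @return named numeric vector, one element per participant.
#' @export
extract_participant_effects <- function(fit, which = c("speed", "accuracy"),
                                        condition = 1) {
  which <- match.arg(which)
  ok <- (which == "speed" && inherits(fit, "reliability_fit")) ||
    (which == "accuracy" && inherits(fit, "accuracy_fit"))
  if (!ok) stop("fit type does not provide '", which, "' effects")
  if (is.character(condition)) {
    j <- match(condition, fit$half_labels)
    if (is.na(j)) stop("unknown condition '", condition, "'")
  } else {
    j <- as.integer(condition)
    if (!j %in% 1:2) stop("condition index must be 1 or 2")
  }
  eff <- fit$participant_effects[, j]
  eff[order(names(eff))]
}
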