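# End-to-end orchestration: configuration, staged execution
# (gating -> exclusion -> split assignment -> model fitting -> ROPE
# classification, optionally accuracy and speed-accuracy correlation,
# power queries), and report generation.

#' Build or load a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file containing one) with:
#' \describe{
#'   \item{trials}{path to a trial CSV, or `NULL` to simulate.}
#'   \item{simulate}{list of [generative_params()] overrides (used when
#'     `trials` is `NULL`).}
#'   \item{schemes}{character vector of split schemes to fit; within-session
#'     schemes (`even_odd`, `first_second`) are fitted per session.}
#'   \item{sampler}{list of [model_spec()] overrides (e.g.
#'     `preset: reduced`).}
#'   \item{bands}{optional numeric vector of three ROPE boundaries.}
#'   \item{accuracy}{logical; also fit the accuracy model and the
#'     speed-accuracy correlations?}
#'   \item{power}{list of power queries, each with `rho_true`, `rel_a`,
#'     `rel_b` (optional `alpha`, `power`).}
#'   \item{gate_threshold}{participant accuracy gate (default 0.6).}
#'   \item{report_by}{exclusion-report grouping, `"session"` or
#'     `"condition"`.}
#'   \item{seed}{mandatory integer seed.}
#'   \item{out_dir}{optional output directory for JSON artifacts.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return validated config of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$seed)) stop("config must set a seed")
  defaults <- list(trials = NULL, simulate = list(), schemes = "even_odd",
                   sampler = list(), bands = NULL, accuracy = FALSE,
                   power = list(), gate_threshold = 0.6,
                   report_by = "session", out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (!is.null(config$trials) && !file.exists(config$trials)) {
    stop("trials file not found: ", config$trials)
  }
  known <- c("even_odd", "first_second", "session", "condition")
  bad <- setdiff(config$schemes, known)
  if (length(bad)) stop("unknown split scheme(s): ", paste(bad, collapse = ", "))
  structure(config, class = "run_config")
}

#' Run the full reliability pipeline
#'
#' Executes, in order: data acquisition (CSV or simulation), participant
#' gating, error-trial exclusion with report, then for every requested
#' split scheme the hierarchical reliability fit and its ROPE
#' classification (within-session schemes fitted once per session);
#' optionally the hierarchical accuracy model and the speed-accuracy
#' correlation per condition; and any power queries. Per-stage JSON
#' artifacts and a combined report are written to `out_dir` when set. The
#' run is a pure function of (inputs, config, seed): rerunning with the
#' same config yields byte-identical JSON reports.
#'
#' @param config a [run_config()] (or list / YAML path coerced by it).
#' @param quiet suppress per-stage log lines.
#' @return report bundle of class `pipeline_result`: `exclusions`,
#'   `reliability` (one element per fitted model: summary, label,
#'   qualifier), `accuracy`, `speed_accuracy`, `power`, `report` (from
#'   [make_report()]), `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- run_config(config)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- "acquire"
  result <- tryCatch({
    if (!is.null(config$trials)) {
      trials <- read_trials(config$trials)
      say(stage, "read %d trials from %s", nrow(trials), config$trials)
    } else {
      params <- do.call(generative_params,
                        c(config$simulate,
                          if (is.null(config$simulate$seed))
                            list(seed = config$seed)))
      sim <- simulate_dataset(params)
      trials <- sim$trials
      say(stage, "simulated %d trials (seed %d)", nrow(trials), params$seed)
    }

    stage <- "gate"
    gate <- gate_participants(trials, config$gate_threshold)
    trials <- trials[trials$participant_id %in% gate$retained, , drop = FALSE]
    say(stage, "%d participants retained, %d excluded",
        length(gate$retained), length(gate$excluded))

    stage <- "filter"
    filtered <- filter_trials(trials, by = config$report_by)
    correct <- filtered$trials
    say(stage, "%d correct trials kept", nrow(correct))

    bands <- if (is.null(config$bands)) rope_bands() else
      rope_bands(as.numeric(config$bands))
    sampler_args <- config$sampler
    if (is.null(sampler_args$seed)) sampler_args$seed <- config$seed
    spec <- do.call(model_spec, sampler_args)

    stage <- "fit"
    fits <- list()
    for (scheme in config$schemes) {
      if (scheme %in% c("even_odd", "first_second")) {
        for (s in sort(unique(correct$session))) {
          sub <- correct[correct$session == s, , drop = FALSE]
          key <- sprintf("%s_session%d", scheme, s)
          say(stage, "fitting %s", key)
          fit <- fit_reliability(sub, split_spec(scheme), spec)
          fits[[key]] <- fit
        }
      } else {
        say(stage, "fitting %s", scheme)
        fits[[scheme]] <- fit_reliability(correct, split_spec(scheme), spec)
      }
    }

    stage <- "classify"
    reliability <- lapply(fits, function(fit) {
      cls <- classify_reliability(fit$correlation, bands)
      list(estimate = fit$correlation$mean,
           ci_lower = fit$correlation$ci_low,
           ci_upper = fit$correlation$ci_high,
           label = cls$label, qualifier = cls$qualifier,
           converged = fit$diagnostics$converged,
           rhat = fit$diagnostics$rhat, ess = fit$diagnostics$ess)
    })

    accuracy_out <- NULL
    speed_accuracy <- NULL
    if (isTRUE(config$accuracy)) {
      stage <- "accuracy"
      acc_scheme <- if ("condition" %in% config$schemes) "condition" else
        "session"
      say(stage, "fitting accuracy model (%s split)", acc_scheme)
      acc_fit <- fit_accuracy(trials, split_spec(acc_scheme),
                              model_spec(preset = spec$preset,
                                         prior_intercept_mean = 0,
                                         prior_intercept_sd = 1.5,
                                         chains = spec$chains,
                                         adapt = spec$adapt,
                                         warmup = spec$warmup,
                                         iter = spec$iter,
                                         seed = spec$seed))
      speed_fit <- fits[[acc_scheme]]
      accuracy_out <- list(
        estimate = acc_fit$correlation$mean,
        ci_lower = acc_fit$correlation$ci_low,
        ci_upper = acc_fit$correlation$ci_high,
        fixed = acc_fit$fixed)
      if (!is.null(speed_fit)) {
        speed_accuracy <- lapply(1:2, function(j) {
          est <- estimate_correlation(
            extract_participant_effects(speed_fit, "speed", j),
            extract_participant_effects(acc_fit, "accuracy", j))
          list(condition = acc_fit$half_labels[j], estimate = est$mean,
               ci_lower = est$ci_low, ci_upper = est$ci_high)
        })
      }
    }

    stage <- "power"
    power_out <- lapply(config$power, function(q) {
      alpha <- q$alpha %||% 0.05
      target <- q$power %||% 0.80
      rho_obs <- attenuate(q$rho_true, q$rel_a, q$rel_b)
      n <- required_n(rho_obs, alpha, target)
      list(rho_true = q$rho_true, rel_a = q$rel_a, rel_b = q$rel_b,
           rho_observed = rho_obs, n = n,
           achieved_power = power_at_n(rho_obs, n, alpha), method = "exact")
    })

    out <- structure(list(
      exclusions = filtered$report,
      gate = gate[c("retained", "excluded")],
      reliability = reliability,
      accuracy = accuracy_out,
      speed_accuracy = speed_accuracy,
      power = power_out,
      config = unclass(config)
    ), class = "pipeline_result")
    out$report <- make_report(out)
    out
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      result$exclusions, file.path(config$out_dir, "exclusions.json"),
      dataframe = "rows", digits = NA)
    jsonlite::write_json(
      list(reliability = result$reliability, accuracy = result$accuracy,
           speed_accuracy = result$speed_accuracy, power = result$power),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(result$report$text, file.path(config$out_dir, "report.txt"))
  }
  result
}

#' Assemble the human- and machine-readable summary report
#'
#' One row per fitted model: posterior mean, credible bounds, and the ROPE
#' label with its qualifier - the layout of a split-half/test-retest
#' reliability summary table. Row order follows the order in which models
#' were fitted and is stable across reruns.
#'
#' @param result a `pipeline_result` (with at least one completed stage).
#' @return list with `table` (data frame) and `text` (character vector of
#'   formatted lines). Every number in `text` appears in `table`.
#' @export
make_report <- function(result) {
  rel <- result$reliability
  table <- data.frame(
    model = names(rel),
    estimate = vapply(rel, function(x) round(x$estimate, 6), numeric(1)),
    ci_lower = vapply(rel, function(x) round(x$ci_lower, 6), numeric(1)),
    ci_upper = vapply(rel, function(x) round(x$ci_upper, 6), numeric(1)),
    label = vapply(rel, function(x) x$label, character(1)),
    qualifier = vapply(rel, function(x) x$qualifier, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  lines <- c(
    "Reliability summary",
    sprintf("%-28s %10s %10s %10s  %s", "model", "estimate", "ci_lower",
            "ci_upper", "interpretation"),
    sprintf("%-28s %10.6f %10.6f %10.6f  %s (%s)", table$model, table$estimate,
            table$ci_lower, table$ci_upper, table$label, table$qualifier)
  )
  list(table = table, text = lines)
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(x$report$text)
  invisible(x)
}
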