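# Common container for a posterior over a scalar (typically a correlation):
# mean, equal-tailed 95% interval, draws, diagnostics.

#' Posterior summary of a scalar parameter
#'
#' @param mean posterior mean.
#' @param ci_low,ci_high equal-tailed 95% credible bounds.
#' @param draws numeric vector of posterior draws (or deterministic
#'   quantile draws for grid posteriors).
#' @param diagnostics list of convergence diagnostics (may be empty).
#' @return object of class `posterior_summary`.
#' @export
posterior_summary <- function(mean, ci_low, ci_high, draws = numeric(0),
                              diagnostics = list()) {
  if (is.na(mean) || is.na(ci_low) || is.na(ci_high)) {
    stop("posterior summary must be finite")
  }
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop("invalid posterior summary: need ci_low <= mean <= ci_high")
  }
  structure(
    list(mean = mean, ci_low = ci_low, ci_high = ci_high,
         draws = draws, diagnostics = diagnostics),
    class = "posterior_summary"
  )
}

# summarize a vector of draws into a posterior_summary (equal-tailed 95%)
summarize_draws <- function(draws, diagnostics = list()) {
  q <- unname(quantile(draws, c(0.025, 0.975), names = FALSE, type = 7))
  posterior_summary(mean(draws), q[1], q[2], draws = draws,
                    diagnostics = diagnostics)
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior mean %.*f, 95%% CI [%.*f, %.*f]\n",
              digits, x$mean, digits, x$ci_low, digits, x$ci_high))
  if (length(x$diagnostics)) {
    d <- x$diagnostics
    if (!is.null(d$rhat)) {
      cat(sprintf("  split-Rhat %.3f, ESS %.0f%s\n", d$rhat, d$ess,
                  if (isTRUE(d$converged)) "" else "  [NOT CONVERGED]"))
    }
  }
  invisible(x)
}
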