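# Graded interpretation of a reliability correlation via labelled
# region-of-practical-equivalence (ROPE) bands.

#' Reliability interpretation bands
#'
#' Ordered, contiguous, non-overlapping correlation bands used to grade
#' reliability: poor below the first boundary, then moderate, good, and
#' excellent up to 1. The conventional two-decimal boundaries are 0.41,
#' 0.61, and 0.81, applied closed on the left (so 0.41 is already
#' "moderate"); the printed band labels (".41-.6", ".61-.8", ".81-1",
#' "<.4") leave the gaps between two-decimal endpoints unspecified, and the
#' contiguous closed-left convention is this package's resolution of those
#' gaps. Boundaries are configurable.
#'
#' @param boundaries increasing numeric vector of three inner boundaries
#'   (poor/moderate, moderate/good, good/excellent).
#' @param labels band labels, lowest to highest.
#' @return object of class `rope_bands`: data frame with `label`, `lower`,
#'   `upper`; bands are `[lower, upper)` except the last, which is
#'   `[lower, 1]`, and the first, which starts at -1 inclusive.
#' @export
rope_bands <- function(boundaries = c(0.41, 0.61, 0.81),
                       labels = c("poor", "moderate", "good", "excellent")) {
  if (length(boundaries) != length(labels) - 1) {
    stop("need one fewer boundary than labels")
  }
  if (is.unsorted(boundaries, strictly = TRUE) ||
        any(boundaries <= -1) || any(boundaries >= 1)) {
    stop("boundaries must be strictly increasing and inside (-1, 1)")
  }
  bands <- data.frame(
    label = labels,
    lower = c(-1, boundaries),
    upper = c(boundaries, 1),
    stringsAsFactors = FALSE
  )
  structure(bands, class = c("rope_bands", class(bands)))
}

#' Band containing a correlation value
#'
#' @param value correlation(s) in `[-1, 1]`.
#' @param bands a [rope_bands()] object.
#' @return character vector of band labels.
#' @examples
#' band_of(0.99)   # "excellent"
#' band_of(0.41)   # "moderate"
#' @export
band_of <- function(value, bands = rope_bands()) {
  stopifnot(inherits(bands, "rope_bands"))
  if (any(is.na(value)) || any(value < -1) || any(value > 1)) {
    stop("value must be in [-1, 1]")
  }
  idx <- findInterval(value, bands$lower, rightmost.closed = FALSE)
  # findInterval with the lower edges implements the closed-left convention;
  # values below the first inner boundary (including -1) land in band 1.
  bands$label[pmax(idx, 1L)]
}

#' Grade a reliability estimate against ROPE bands
#'
#' Implements the graded decision rule: if the entire 95% credible interval
#' of the correlation lies within one band, that band's interpretation is
#' accepted outright (`qualifier = "exactly"`); if the interval spans more
#' than one band, only the reliability of the lowest band the interval
#' touches is accepted (`qualifier = "at_least"`). A posterior mean of .82
#' with interval [.75, .89] is therefore graded "good" (at least), not
#' "excellent".
#'
#' @param summary a [posterior_summary()] object, or any list with `mean`,
#'   `ci_low`, `ci_high`.
#' @param bands a [rope_bands()] object.
#' @return list with `label`, `qualifier` (`"exactly"` or `"at_least"`),
#'   and `bands_used`.
#' @export
classify_reliability <- function(summary, bands = rope_bands()) {
  lo <- summary$ci_low; hi <- summary$ci_high
  if (is.null(lo) || is.null(hi) || is.na(lo) || is.na(hi)) {
    stop("summary must supply ci_low and ci_high")
  }
  if (lo > hi) stop("degenerate interval: ci_low > ci_high")
  if (lo < -1 || hi > 1) stop("interval bounds must be in [-1, 1]")
  band_lo <- band_of(lo, bands)
  band_hi <- band_of(hi, bands)
  list(
    label = band_lo,
    qualifier = if (identical(band_lo, band_hi)) "exactly" else "at_least",
    bands_used = bands
  )
}
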