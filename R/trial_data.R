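# Trial-level naming data: reading, validation, response classification,
# exclusion reporting, participant gating.

TRIAL_COLUMNS <- c(
  "participant_id", "session", "condition", "trial_index", "item_id",
  "target_word", "picture_onset_ms", "vocal_onset_ms", "response_word",
  "disfluent", "response_class"
)

RESPONSE_CLASSES <- c("correct", "wrong_word", "disfluency", "no_response")

#' Normalize a naming response for word-identity comparison
#'
#' Case-folds, trims surrounding whitespace, and strips a leading English
#' article (`the`, `a`, `an`). Responses are scored by word identity, so
#' "The dog" and "dog" count as the same response.
#'
#' @param x character vector of responses or target words.
#' @return normalized character vector.
#' @keywords internal
normalize_response <- function(x) {
  x <- tolower(trimws(x))
  sub("^(the|an|a)\\s+", "", x)
}

#' Classify a naming response
#'
#' Applies the fixed classification precedence used in preprocessing:
#' a trial with no vocal onset is a `no_response`; otherwise a trial flagged
#' as disfluent (false start, repair, filled pause) is a `disfluency`;
#' otherwise a response whose normalized form differs from the normalized
#' target is a `wrong_word`; everything else is `correct`.
#'
#' @param target_word character vector of target words (non-empty).
#' @param response_word character vector of produced words; `NA` if none.
#' @param disfluent logical vector; was the response disfluent?
#' @param vocal_onset_present logical vector; was a vocal onset detected
#'   within the response window?
#' @return character vector with values in
#'   `c("correct", "wrong_word", "disfluency", "no_response")`.
#' @examples
#' classify_response("dog", "dog", FALSE, TRUE)
#' classify_response("dog", NA, FALSE, FALSE)
#' classify_response("dog", "dog", TRUE, TRUE)
#' @export
classify_response <- function(target_word, response_word, disfluent,
                              vocal_onset_present) {
  n <- max(length(target_word), length(response_word), length(disfluent),
           length(vocal_onset_present))
  target_word <- rep_len(target_word, n)
  response_word <- rep_len(response_word, n)
  disfluent <- rep_len(as.logical(disfluent), n)
  vocal_onset_present <- rep_len(as.logical(vocal_onset_present), n)
  if (any(is.na(target_word) | !nzchar(target_word))) {
    stop("classify_response(): 'target_word' must be non-empty")
  }
  out <- rep("correct", n)
  wrong <- normalize_response(response_word) != normalize_response(target_word)
  wrong[is.na(wrong)] <- FALSE
  out[wrong] <- "wrong_word"
  out[disfluent] <- "disfluency"
  out[!vocal_onset_present] <- "no_response"
  out
}

#' Validate a trial table
#'
#' Checks the trial-record invariants: mandatory columns, positive latencies
#' equal to `vocal_onset_ms - picture_onset_ms`, `no_response` exactly on
#' trials without a vocal onset, and unique `trial_index` within each
#' participant-session. Malformed rows are reported by row number.
#'
#' @param trials data frame in the trial schema (see [read_trials()]).
#' @return the validated data frame, invisibly augmented with a `latency_ms`
#'   column if it was absent.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(trials)) stop("trial table is empty")
  bad_class <- which(!trials$response_class %in% RESPONSE_CLASSES)
  if (length(bad_class)) {
    stop("unknown response_class at row(s): ",
         paste(utils::head(bad_class, 5), collapse = ", "))
  }
  if (!"latency_ms" %in% names(trials)) {
    trials$latency_ms <- trials$vocal_onset_ms - trials$picture_onset_ms
  }
  has_onset <- !is.na(trials$vocal_onset_ms)
  bad_lat <- which(has_onset & (is.na(trials$latency_ms) |
                                  trials$latency_ms <= 0))
  if (length(bad_lat)) {
    stop("non-positive latency (vocal onset precedes picture onset) at row(s): ",
         paste(utils::head(bad_lat, 5), collapse = ", "))
  }
  bad_nr <- which((trials$response_class == "no_response") != !has_onset)
  if (length(bad_nr)) {
    stop("no_response must hold exactly when vocal onset is absent; row(s): ",
         paste(utils::head(bad_nr, 5), collapse = ", "))
  }
  if (any(is.na(trials$trial_index) | trials$trial_index < 1 |
            trials$trial_index != round(trials$trial_index))) {
    stop("trial_index must be a positive integer")
  }
  key <- paste(trials$participant_id, trials$session, trials$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate trial_index within participant-session at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  invisible(trials)
}

#' Read trial-level naming data from CSV
#'
#' Reads a comma-delimited, UTF-8 trial table with header columns
#' `participant_id, session, condition, trial_index, item_id, target_word,
#' picture_onset_ms, vocal_onset_ms, response_word, disfluent,
#' response_class`. Empty strings encode absent values (no vocal onset, no
#' response word). A `latency_ms` column is computed as
#' `vocal_onset_ms - picture_onset_ms` and all record invariants are
#' validated.
#'
#' @param path path to the CSV file.
#' @return data frame of validated trial records with `latency_ms`.
#' @seealso [write_trials()], [validate_trials()]
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("'", path, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  trials$session <- as.integer(trials$session)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$picture_onset_ms <- num(trials$picture_onset_ms)
  trials$vocal_onset_ms <- num(trials$vocal_onset_ms)
  trials$response_word[trials$response_word == ""] <- NA_character_
  trials$disfluent <- tolower(trials$disfluent) %in% c("true", "t", "1")
  trials$latency_ms <- trials$vocal_onset_ms - trials$picture_onset_ms
  validate_trials(trials)
  trials
}

#' Write trial-level naming data to CSV
#'
#' Inverse of [read_trials()]: writes the trial schema with empty strings for
#' absent values, so that a write-then-read round trip is the identity on the
#' schema columns.
#'
#' @param trials validated trial data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials[, TRIAL_COLUMNS]
  out$disfluent <- ifelse(out$disfluent, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Exclude error trials and report exclusions
#'
#' Keeps only trials with correct responses (the analysis set) and tabulates,
#' per session or condition, the number and percentage of trials in each
#' response class. Percentages use all trials of that session/condition as
#' the denominator and are rounded to two decimals, matching the convention
#' of reporting e.g. 232 wrong-word trials among 7,500 as 3.09%.
#'
#' @param trials validated trial data frame.
#' @param by grouping for the report: `"session"` (same task both sessions)
#'   or `"condition"` (e.g. speeded vs. non-speeded).
#' @return a list with elements `trials` (correct trials only) and `report`
#'   (a data frame of class `exclusion_report` with columns `group`,
#'   `response_class`, `count`, `percent`, `denominator`).
#' @examples
#' params <- generative_params(n_participants = 5, n_items = 20)
#' sim <- simulate_dataset(params)
#' filtered <- filter_trials(sim$trials)
#' filtered$report
#' @export
filter_trials <- function(trials, by = c("session", "condition")) {
  by <- match.arg(by)
  validate_trials(trials)
  if (!nrow(trials)) stop("filter_trials(): empty trial table")
  group <- as.character(trials[[by]])
  groups <- sort(unique(group))
  rows <- list()
  for (g in groups) {
    in_g <- group == g
    denom <- sum(in_g)
    for (cls in RESPONSE_CLASSES) {
      cnt <- sum(in_g & trials$response_class == cls)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, response_class = cls, count = cnt,
        percent = round(100 * cnt / denom, 2), denominator = denom,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("exclusion_report", class(report))
  list(trials = trials[trials$response_class == "correct", , drop = FALSE],
       report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report (percent of all trials per group)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Gate participants by naming accuracy
#'
#' Participants must reach a minimum naming accuracy in every completed
#' session to be retained; the gate is applied before any reliability
#' analysis. Accuracy is the proportion of correct responses among a
#' participant's trials in a session. A participant exactly at the threshold
#' is retained ("at least" the threshold).
#'
#' @param trials validated trial data frame.
#' @param threshold minimum accuracy, a proportion in (0, 1]. Default 0.60.
#' @return list with `retained` and `excluded` (character vectors of
#'   participant ids) and `accuracy` (data frame: participant_id, session,
#'   accuracy).
#' @export
gate_participants <- function(trials, threshold = 0.60) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
        threshold <= 0 || threshold > 1) {
    stop("gate_participants(): threshold must be in (0, 1]")
  }
  validate_trials(trials)
  key <- paste(trials$participant_id, trials$session, sep = "\r")
  acc <- tapply(trials$response_class == "correct", key, mean)
  parts <- do.call(rbind, strsplit(names(acc), "\r", fixed = TRUE))
  accuracy <- data.frame(participant_id = parts[, 1],
                         session = as.integer(parts[, 2]),
                         accuracy = as.numeric(acc),
                         stringsAsFactors = FALSE)
  low <- unique(accuracy$participant_id[accuracy$accuracy < threshold])
  all_ids <- unique(trials$participant_id)
  list(retained = setdiff(all_ids, low), excluded = low, accuracy = accuracy)
}
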