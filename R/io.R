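# Trial-log CSV dialects. Both are plain RFC-4180 CSV, UTF-8, header row,
# "." decimal separator; numbers serialised at full double precision by
# readr so written-then-reread logs reproduce metric and fit outputs.

prl_trial_cols <- c("subject_id", "day", "trial_index", "block_index",
                    "current_high_side", "chosen_side", "rewarded",
                    "reaction_time_s")

csrtt_trial_cols <- c("subject_id", "manipulation", "trial_index", "iti_s",
                      "stimulus_aperture", "stimulus_duration_s", "outcome",
                      "n_premature_pokes", "n_perseverative",
                      "correct_latency_s", "reward_latency_s")

#' Write reversal-learning sessions to a trial-log CSV
#'
#' One row per trial with columns subject_id, day, trial_index (0-based),
#' block_index, current_high_side, chosen_side, rewarded, reaction_time_s.
#'
#' @param sessions List of `prl_session` objects (or a single session).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prl_trials <- function(sessions, path) {
  if (inherits(sessions, "prl_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, function(s) {
    tibble::tibble(
      subject_id = attr(s, "subject_id") %||% NA_character_,
      day = attr(s, "day") %||% NA_integer_,
      trial_index = s$trial_index, block_index = s$block_index,
      current_high_side = s$current_high_side, chosen_side = s$chosen_side,
      rewarded = s$rewarded, reaction_time_s = s$reaction_time_s)
  }))
  readr::write_csv(df, path)
  invisible(path)
}

check_cols <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("parse error in '", path, "': missing column(s): ",
         paste(missing, collapse = ", "))
}

check_enum <- function(x, allowed, col, offset = 1L) {
  bad <- which(!is.na(x) & !x %in% allowed)
  if (length(bad))
    stop("parse error: bad value '", x[bad[1]], "' in column ", col,
         " at data row ", bad[1] + offset - 1L)
}

check_trial_index <- function(idx, rows) {
  if (idx[1] != 0L)
    stop("parse error: trial_index must start at 0 (data row ", rows[1], ")")
  if (length(idx) > 1L && any(diff(idx) <= 0L)) {
    bad <- which(diff(idx) <= 0L)[1] + 1L
    stop("parse error: trial_index not strictly increasing at data row ",
         rows[bad])
  }
}

#' Read a reversal-learning trial-log CSV back into sessions
#'
#' Validates the header, the side/choice enums, and that `trial_index`
#' starts at 0 and increases strictly within each (subject_id, day) session;
#' violations raise an error naming the offending data row. Row order within
#' a session is preserved.
#'
#' @param path CSV path, as written by [write_prl_trials()].
#' @return Named list of `prl_session` tibbles (names `subject.day`); a
#'   header-only file returns an empty list with a warning.
#' @export
read_prl_trials <- function(path) {
  hdr <- readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                         col_types = readr::cols())
  check_cols(hdr, prl_trial_cols, path)
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    subject_id = readr::col_character(), day = readr::col_integer(),
    trial_index = readr::col_integer(), block_index = readr::col_integer(),
    current_high_side = readr::col_character(),
    chosen_side = readr::col_character(), rewarded = readr::col_logical(),
    reaction_time_s = readr::col_double()))
  check_cols(df, prl_trial_cols, path)
  if (nrow(df) == 0L) {
    warning("'", path, "' has a header but no trial rows")
    return(list())
  }
  check_enum(df$current_high_side, c("left", "right"), "current_high_side")
  check_enum(df$chosen_side, c("left", "right"), "chosen_side")
  key <- paste(df$subject_id, df$day, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                function(rows) {
    s <- df[rows, setdiff(prl_trial_cols, c("subject_id", "day"))]
    check_trial_index(s$trial_index, rows)
    new_prl_session(tibble::as_tibble(s),
                    subject_id = df$subject_id[rows[1]],
                    day = df$day[rows[1]])
  })
  out
}

#' Write 5CSRTT sessions to an event-log CSV
#'
#' @param sessions List of `csrtt_session` objects (or a single session).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csrtt_trials <- function(sessions, path) {
  if (inherits(sessions, "csrtt_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, function(s) {
    cbind(tibble::tibble(
      subject_id = attr(s, "subject_id") %||% NA_character_,
      manipulation = attr(s, "manipulation") %||% NA_character_),
      s[, setdiff(csrtt_trial_cols, c("subject_id", "manipulation"))])
  }))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a 5CSRTT event-log CSV back into sessions
#'
#' Sessions are grouped by (subject_id, manipulation) with the same
#' validation discipline as [read_prl_trials()]: required columns, outcome
#' enum, and strictly increasing trial_index from 0 per session.
#'
#' @param path CSV path, as written by [write_csrtt_trials()].
#' @return Named list of `csrtt_session` tibbles.
#' @export
read_csrtt_trials <- function(path) {
  hdr <- readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                         col_types = readr::cols())
  check_cols(hdr, csrtt_trial_cols, path)
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    subject_id = readr::col_character(),
    manipulation = readr::col_character(),
    trial_index = readr::col_integer(), iti_s = readr::col_double(),
    stimulus_aperture = readr::col_integer(),
    stimulus_duration_s = readr::col_double(),
    outcome = readr::col_character(),
    n_premature_pokes = readr::col_integer(),
    n_perseverative = readr::col_integer(),
    correct_latency_s = readr::col_double(),
    reward_latency_s = readr::col_double()))
  check_cols(df, csrtt_trial_cols, path)
  if (nrow(df) == 0L) {
    warning("'", path, "' has a header but no trial rows")
    return(list())
  }
  check_enum(df$outcome, c("correct", "incorrect", "omission", "premature"),
             "outcome")
  key <- paste(df$subject_id, df$manipulation, sep = ".")
  lapply(split(seq_len(nrow(df)), factor(key, unique(key))), function(rows) {
    s <- df[rows, setdiff(csrtt_trial_cols, c("subject_id", "manipulation"))]
    check_trial_index(s$trial_index, rows)
    structure(tibble::as_tibble(s),
              class = unique(c("csrtt_session", class(tibble::as_tibble(s)))),
              subject_id = df$subject_id[rows[1]],
              manipulation = df$manipulation[rows[1]])
  })
}

#' Write the full cohort bundle to a directory
#'
#' Produces `subjects.csv`, `prl_trials.csv`, `csrtt_trials.csv`,
#' `prl_metrics.csv`, `csrtt_measures.csv`, `fits.csv` and `report.json`
#' (the recovery summary).
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param analysis A `cohort_analysis` from [cohort_analysis()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  write_prl_trials(cohort$prl_sessions, file.path(dir, "prl_trials.csv"))
  write_csrtt_trials(cohort$csrtt_sessions, file.path(dir, "csrtt_trials.csv"))
  readr::write_csv(analysis$prl_metrics, file.path(dir, "prl_metrics.csv"))
  readr::write_csv(analysis$csrtt_measures,
                   file.path(dir, "csrtt_measures.csv"))
  readr::write_csv(analysis$fits, file.path(dir, "fits.csv"))
  jsonlite::write_json(
    list(recovery = analysis$recovery,
         n_subjects = nrow(cohort$subjects),
         seed = cohort$config$seed),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
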