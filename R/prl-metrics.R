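#' Presses on the currently high-probability lever, per reversal block
#'
#' For each block between reversals, counts the trials on which the animal
#' pressed whichever lever was the high-probability lever *at that time*
#' (i.e. the count tracks the contingency through reversals). Under the
#' default schedule this is the familiar per-block triple for trials 0-40,
#' 41-80 and 81-120; an agent with no lever preference averages
#' `block_length / 2` (20) per block.
#'
#' @param session A `prl_session` (or data frame with `block_index`,
#'   `chosen_side`, `current_high_side`).
#' @return Named integer vector, one count per block (`block1`, `block2`, ...).
#' @export
high_lever_presses <- function(session) {
  if (nrow(session) == 0L) stop("input error: empty session")
  hit <- session$chosen_side == session$current_high_side
  counts <- tapply(hit, session$block_index, sum)
  out <- as.integer(counts)
  names(out) <- paste0("block", seq_along(out))
  out
}

#' Win-stay and lose-shift probabilities
#'
#' Over consecutive trial pairs: win-stay is the probability of repeating the
#' previous choice given it was rewarded; lose-shift the probability of
#' switching given it was not. A side with no qualifying transitions (e.g. a
#' session with no rewards) yields `NA`, not 0.
#'
#' @param session A session with at least 2 trials.
#' @return Named numeric `c(win_stay = , lose_shift = )`, entries in \[0, 1\]
#'   or `NA` when undefined.
#' @examples
#' s <- simulate_prl_session(random_policy(0.5), prl_config(), seed = 1)
#' win_stay_lose_shift(s)
#' @export
win_stay_lose_shift <- function(session) {
  n <- nrow(session)
  if (n < 2L) stop("input error: win-stay/lose-shift needs >= 2 trials")
  stay <- session$chosen_side[-1] == session$chosen_side[-n]
  won <- as.logical(session$rewarded[-n])
  c(win_stay = if (any(won)) mean(stay[won]) else NA_real_,
    lose_shift = if (any(!won)) mean(!stay[!won]) else NA_real_)
}

#' Sliding-window fraction of choices for the initially high lever
#'
#' For each trial t (0-based) the fraction of choices for the *initially*
#' high-probability lever among the 8 trials with indices in \[t-4, t+4)
#' (4 before, the current trial, and 3 after). Windows at the session edges
#' are truncated to the available trials, so the series has one value per
#' trial. Because the reference lever is the initial one, a well-adapting
#' animal's series sits near 1 in the first and third blocks and near 0 in
#' the middle block.
#'
#' @param session A `prl_session`.
#' @param window Even window width >= 2 (default 8).
#' @return Numeric vector in \[0, 1\], length `nrow(session)`.
#' @export
sliding_choice_fraction <- function(session, window = 8L) {
  if (window < 2L || window %% 2L != 0L)
    stop("window must be an even count >= 2")
  if (nrow(session) == 0L) stop("input error: empty session")
  half <- window %/% 2L
  initial_high <- session$current_high_side[session$block_index == 0L][1]
  hit <- session$chosen_side == initial_high
  n <- nrow(session)
  vapply(seq_len(n), function(t) {
    i0 <- max(1L, t - half)
    i1 <- min(n, t + half - 1L)
    mean(hit[i0:i1])
  }, numeric(1))
}

#' Percentage of pellets earned relative to the maximum obtainable
#'
#' The ceiling is one pellet per trial, so this is simply 100 times the
#' rewarded-trial fraction.
#'
#' @param session A `prl_session`.
#' @return Percentage in \[0, 100\].
#' @export
pellets_percent <- function(session) {
  if (nrow(session) == 0L) stop("input error: empty session")
  100 * mean(as.logical(session$rewarded))
}

#' All behavioural statistics of one session as a one-row table
#'
#' @param session A `prl_session`.
#' @param window Sliding-window width for [sliding_choice_fraction()] (kept
#'   out of the summary row; see `prl_sliding_table()` for the series).
#' @return One-row tibble: subject_id, day, block1_high..block3_high (or as
#'   many blocks as the schedule has), win_stay, lose_shift, pellets_pct,
#'   mean_rt_s.
#' @export
prl_session_metrics <- function(session, window = 8L) {
  blocks <- high_lever_presses(session)
  wsls <- win_stay_lose_shift(session)
  rt <- session$reaction_time_s
  row <- tibble::tibble(
    subject_id = attr(session, "subject_id") %||% NA_character_,
    day = attr(session, "day") %||% NA_integer_)
  for (b in seq_along(blocks)) row[[paste0("block", b, "_high")]] <- blocks[[b]]
  row$win_stay <- wsls[["win_stay"]]
  row$lose_shift <- wsls[["lose_shift"]]
  row$pellets_pct <- pellets_percent(session)
  row$mean_rt_s <- if (all(is.na(rt))) NA_real_ else mean(rt, na.rm = TRUE)
  row
}

#' Behavioural statistics for a list of sessions
#'
#' @param sessions List of `prl_session` objects.
#' @inheritParams prl_session_metrics
#' @return Tibble, one row per session.
#' @export
prl_metrics <- function(sessions, window = 8L) {
  do.call(rbind, lapply(sessions, prl_session_metrics, window = window))
}

#' Sliding-window series for a list of sessions in long format
#'
#' @inheritParams prl_metrics
#' @return Tibble: subject_id, day, trial_index, fraction.
#' @export
prl_sliding_table <- function(sessions, window = 8L) {
  do.call(rbind, lapply(sessions, function(s) {
    tibble::tibble(
      subject_id = attr(s, "subject_id") %||% NA_character_,
      day = attr(s, "day") %||% NA_integer_,
      trial_index = s$trial_index,
      fraction = sliding_choice_fraction(s, window = window))
  }))
}
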