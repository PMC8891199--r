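# Build a prl_session by hand from choice/reward vectors (for oracle tests
# the contingency table can be supplied too; defaults to the standard
# left-first 40-trial-block schedule truncated to the session length).
hand_session <- function(choices, rewards, high_sides = NULL,
                         block_length = 40L, subject_id = "hand", day = 1L) {
  n <- length(choices)
  stopifnot(length(rewards) == n)
  block <- (seq_len(n) - 1L) %/% block_length
  if (is.null(high_sides))
    high_sides <- ifelse(block %% 2L == 0L, "left", "right")
  df <- tibble::tibble(
    trial_index = seq_len(n) - 1L,
    block_index = block,
    current_high_side = high_sides,
    chosen_side = choices,
    rewarded = as.logical(rewards),
    reaction_time_s = NA_real_,
    p_choice = NA_real_)
  structure(df, class = unique(c("prl_session", class(df))),
            subject_id = subject_id, day = as.integer(day))
}

# Deterministic agent that presses a fixed side forever.
constant_policy <- function(side) {
  p <- c(left = 0, right = 0)
  p[[side]] <- 1
  cogflex:::new_prl_policy(paste0("constant_", side),
                           init = function() NULL,
                           choose = function(state, info) p,
                           update = function(state, choice, reward) state)
}

# Agent that always presses the side that was the high side in block 0
# (perseverates through reversals).
initial_side_policy <- function() {
  cogflex:::new_prl_policy("initial_side",
    init = function() NULL,
    choose = function(state, info) {
      side <- if (is.null(state)) info$high_side else state
      p <- c(left = 0, right = 0)
      p[[side]] <- 1
      p
    },
    update = function(state, choice, reward) choice)
}

# Hand-built 5CSRTT trial table with given outcomes.
hand_csrtt <- function(outcomes, n_premature_pokes = NULL,
                       n_perseverative = 0L,
                       correct_latency_s = 0.5, reward_latency_s = 1.2) {
  n <- length(outcomes)
  if (is.null(n_premature_pokes))
    n_premature_pokes <- ifelse(outcomes == "premature", 1L, 0L)
  tibble::tibble(
    trial_index = seq_len(n) - 1L,
    iti_s = 5, stimulus_aperture = 1L, stimulus_duration_s = 1,
    outcome = outcomes,
    n_premature_pokes = as.integer(n_premature_pokes),
    n_perseverative = as.integer(rep_len(n_perseverative, n)),
    correct_latency_s = ifelse(outcomes == "correct", correct_latency_s,
                               NA_real_),
    reward_latency_s = ifelse(outcomes == "correct", reward_latency_s,
                              NA_real_))
}
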