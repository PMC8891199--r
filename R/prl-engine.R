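#' Probabilistic reversal learning schedule configuration
#'
#' The task presents two levers; one is the high-probability lever (reward
#' with probability `p_high` when pressed), the other the low-probability
#' lever (`p_low`). Contingencies swap between the levers at the end of every
#' `block_length`-trial block, so the default 120-trial session has reversals
#' after trials 40 and 80 and three blocks overall.
#'
#' @param n_trials Trials per session (default 120).
#' @param block_length Trials between contingency reversals (default 40).
#' @param p_high,p_low Reward probabilities of the currently high and low
#'   lever (defaults 0.8 and 0.2); require `0 <= p_low < p_high <= 1`.
#' @param initial_high_side `"left"`, `"right"`, or `"random"` (a fair draw
#'   per session, consuming the seed).
#' @param n_sessions Number of daily sessions in the study design (default 5).
#' @param seed Optional integer seed used by [prl_schedule()] to resolve a
#'   `"random"` initial side.
#' @return An object of class `prl_config`.
#' @examples
#' prl_config()
#' @export
prl_config <- function(n_trials = 120L, block_length = 40L, p_high = 0.8,
                       p_low = 0.2, initial_high_side = "random",
                       n_sessions = 5L, seed = NULL) {
  n_trials <- as.integer(n_trials)
  block_length <- as.integer(block_length)
  if (is.na(n_trials) || n_trials <= 0L)
    stop("configuration error: n_trials must be a positive count")
  if (is.na(block_length) || block_length <= 0L)
    stop("configuration error: block_length must be a positive count")
  if (!is.numeric(p_high) || !is.numeric(p_low) ||
      p_low < 0 || p_low >= p_high || p_high > 1)
    stop("configuration error: need 0 <= p_low < p_high <= 1")
  initial_high_side <- match.arg(initial_high_side,
                                 c("random", "left", "right"))
  structure(
    list(n_trials = n_trials, block_length = block_length,
         p_high = p_high, p_low = p_low,
         initial_high_side = initial_high_side,
         n_sessions = as.integer(n_sessions),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "prl_config"
  )
}

#' @export
print.prl_config <- function(x, ...) {
  cat(sprintf(
    "PRL schedule: %d trials, reversal every %d, %.0f%%/%.0f%% contingencies, initial high side: %s\n",
    x$n_trials, x$block_length, 100 * x$p_high, 100 * x$p_low,
    x$initial_high_side))
  invisible(x)
}

other_side <- function(side) ifelse(side == "left", "right", "left")

#' Per-trial contingency table of a reversal schedule
#'
#' The high-probability side at trial t (0-based) is a pure function of the
#' parity of `floor(t / block_length)` and the initial side: even blocks keep
#' the initial assignment, odd blocks swap it. A `"random"` initial side is
#' resolved by a fair coin flip using `config$seed` when present (current RNG
#' stream otherwise).
#'
#' @param config A [prl_config()].
#' @return Tibble with one row per trial: `trial_index` (0-based),
#'   `block_index`, `high_side`, `p_left`, `p_right`.
#' @examples
#' sched <- prl_schedule(prl_config(initial_high_side = "left"))
#' table(sched$block_index, sched$high_side)
#' @export
prl_schedule <- function(config) {
  stopifnot(inherits(config, "prl_config"))
  side0 <- config$initial_high_side
  if (side0 == "random") {
    flip <- function() if (runif(1) < 0.5) "left" else "right"
    side0 <- if (!is.null(config$seed)) withr::with_seed(config$seed, flip())
             else flip()
  }
  trial <- seq_len(config$n_trials) - 1L
  block <- trial %/% config$block_length
  high <- ifelse(block %% 2L == 0L, side0, other_side(side0))
  tibble::tibble(
    trial_index = trial,
    block_index = block,
    high_side = high,
    p_left = ifelse(high == "left", config$p_high, config$p_low),
    p_right = ifelse(high == "right", config$p_high, config$p_low))
}

new_prl_policy <- function(name, init, choose, update) {
  structure(list(name = name, init = init, choose = choose, update = update),
            class = "prl_policy")
}

#' Agent policies for the reversal-learning simulator
#'
#' A policy bundles an initial internal state, a choice rule mapping
#' (state, trial info) to a probability over the two levers, and a state
#' update applied after each outcome.
#'
#' * `oracle_policy("high")` always presses the currently high-probability
#'   lever (it sees the schedule), so its long-run reward rate is `p_high`;
#'   `oracle_policy("low")` always presses the low lever (`p_low`).
#' * `random_policy(p_left)` presses left with fixed probability `p_left`
#'   regardless of history; `random_policy(0.5)` is the indifferent agent.
#' * `q_policy(params)` is the generative counterpart of the fitted model:
#'   choices from [choice_prob()], state updates via [q_update()], so the
#'   simulator and the likelihood share one definition of the model.
#'
#' @param target For `oracle_policy`: `"high"` or `"low"`, the contingency
#'   the agent tracks.
#' @param p_left For `random_policy`: probability of pressing the left lever.
#' @param params For `q_policy`: a [q_params()] object.
#' @return An object of class `prl_policy`.
#' @name prl_policies
NULL

#' @rdname prl_policies
#' @export
oracle_policy <- function(target = c("high", "low")) {
  target <- match.arg(target)
  new_prl_policy(
    name = paste0("oracle_", target),
    init = function() NULL,
    choose = function(state, info) {
      side <- if (target == "high") info$high_side else other_side(info$high_side)
      p <- c(left = 0, right = 0)
      p[[side]] <- 1
      p
    },
    update = function(state, choice, reward) state)
}

#' @rdname prl_policies
#' @export
random_policy <- function(p_left = 0.5) {
  if (!is.numeric(p_left) || p_left < 0 || p_left > 1)
    stop("p_left must be a probability")
  new_prl_policy(
    name = sprintf("random_%.3f", p_left),
    init = function() NULL,
    choose = function(state, info) c(left = p_left, right = 1 - p_left),
    update = function(state, choice, reward) state)
}

#' @rdname prl_policies
#' @export
q_policy <- function(params) {
  stopifnot(inherits(params, "q_params"))
  new_prl_policy(
    name = "q",
    init = function() q_state(params$q_init),
    choose = function(state, info) choice_prob(state, params),
    update = function(state, choice, reward) q_update(state, choice, reward, params))
}

#' Simulate one reversal-learning session
#'
#' Walks an agent through the schedule: at each trial the policy emits a
#' probability over the levers (checked to sum to 1 within 1e-9), a choice is
#' drawn, the reward is drawn Bernoulli with the chosen lever's current
#' contingency, and the policy state is updated with the outcome. Every trial
#' yields a choice (the task has no omission state). Reaction times, when
#' requested, are decorative log-normal draws independent of the choice
#' model.
#'
#' @param policy A `prl_policy` (see [oracle_policy()], [random_policy()],
#'   [q_policy()]).
#' @param config A [prl_config()]. A `"random"` initial high side is resolved
#'   from the session's RNG stream and recorded in the returned session's
#'   config attribute.
#' @param seed Optional integer; identical `(policy, config, seed)` give an
#'   identical session.
#' @param subject_id,day Identifiers recorded on the session.
#' @param rt_lognorm Optional `c(meanlog, sdlog)` for simulated reaction
#'   times; `NULL` leaves them `NA`.
#' @return A tibble of class `prl_session` with columns `trial_index`
#'   (0-based), `block_index`, `current_high_side`, `chosen_side`,
#'   `rewarded`, `reaction_time_s`, and `p_choice` (the probability the
#'   policy assigned to the choice it made, recorded for model-consistency
#'   checks). Attributes: `subject_id`, `day`, `config` (with the resolved
#'   initial side), `policy`, `seed`.
#' @examples
#' s <- simulate_prl_session(oracle_policy(), prl_config(), seed = 1)
#' mean(s$rewarded)  # near 0.8
#' @export
simulate_prl_session <- function(policy, config = prl_config(), seed = NULL,
                                 subject_id = "s1", day = 1L,
                                 rt_lognorm = NULL) {
  stopifnot(inherits(policy, "prl_policy"), inherits(config, "prl_config"))
  run <- function() {
    cfg <- config
    if (cfg$initial_high_side == "random")
      cfg$initial_high_side <- if (runif(1) < 0.5) "left" else "right"
    cfg$seed <- NULL
    sched <- prl_schedule(cfg)
    n <- cfg$n_trials
    chosen <- character(n)
    rewarded <- logical(n)
    p_choice <- numeric(n)
    rt <- rep(NA_real_, n)
    state <- policy$init()
    for (t in seq_len(n)) {
      info <- list(trial_index = t - 1L, high_side = sched$high_side[t])
      p <- policy$choose(state, info)
      if (abs(sum(p) - 1) > 1e-9 || any(p < -1e-12))
        stop("policy error: choice probabilities must be nonnegative and sum to 1")
      ch <- if (runif(1) < p[["left"]]) "left" else "right"
      p_rew <- if (ch == "left") sched$p_left[t] else sched$p_right[t]
      rw <- runif(1) < p_rew
      if (!is.null(rt_lognorm)) rt[t] <- rlnorm(1, rt_lognorm[1], rt_lognorm[2])
      chosen[t] <- ch
      rewarded[t] <- rw
      p_choice[t] <- p[[ch]]
      state <- policy$update(state, ch, as.integer(rw))
    }
    out <- tibble::tibble(
      trial_index = sched$trial_index,
      block_index = sched$block_index,
      current_high_side = sched$high_side,
      chosen_side = chosen,
      rewarded = rewarded,
      reaction_time_s = rt,
      p_choice = p_choice)
    new_prl_session(out, subject_id = subject_id, day = day, config = cfg,
                    policy = policy$name, seed = seed)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

new_prl_session <- function(df, subject_id, day, config = NULL,
                            policy = NA_character_, seed = NULL) {
  structure(df,
            class = unique(c("prl_session", class(df))),
            subject_id = subject_id, day = as.integer(day),
            config = config, policy = policy, seed = seed)
}

#' Simulate an ensemble of sessions
#'
#' Convenience wrapper deriving one child seed per session from `seed`, so
#' the whole ensemble is reproducible while sessions stay independent.
#'
#' @inheritParams simulate_prl_session
#' @param n Number of sessions; session i is labelled day i.
#' @return List of `prl_session` objects.
#' @export
simulate_prl_sessions <- function(policy, config = prl_config(), n = 5L,
                                  seed = NULL, subject_id = "s1",
                                  rt_lognorm = NULL) {
  seeds <- child_seeds(n, seed)
  lapply(seq_len(n), function(i)
    simulate_prl_session(policy, config, seed = seeds[i],
                         subject_id = subject_id, day = i,
                         rt_lognorm = rt_lognorm))
}
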