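#' Four-parameter Q-learning model parameters
#'
#' Bundles the parameters of the Rescorla-Wagner style choice model used for
#' the probabilistic reversal learning task: separate learning rates for
#' rewarded and unrewarded outcomes, a stickiness bonus for repeating the
#' previous choice, and a softmax inverse temperature.
#'
#' The model, written out, is
#' \deqn{Q_{t+1}(c_t) = Q_t(c_t) + \alpha_{eff} (r_t - Q_t(c_t)),}
#' with \eqn{\alpha_{eff} = \alpha^+} when \eqn{r_t = 1} and \eqn{\alpha^-}
#' when \eqn{r_t = 0} (the unchosen lever's value is not updated), and choice
#' probabilities
#' \deqn{P(a) \propto \exp(\beta Q(a) + \pi \, 1[a = c_{t-1}]).}
#' On the first trial of a session there is no previous choice and the
#' stickiness term contributes to neither lever.
#'
#' @param alpha_plus Reward learning rate in \[0, 1\]: how strongly a rewarded
#'   outcome pulls the chosen lever's value toward 1.
#' @param alpha_minus Punishment (reward-omission) learning rate in \[0, 1\].
#' @param pi Stickiness: additive bonus (in softmax units) for the lever
#'   chosen on the previous trial, independent of outcome. Positive values
#'   produce perseveration, negative values alternation.
#' @param beta Inverse temperature, >= 0: the extent to which choice follows
#'   the higher-valued lever (0 = random, large = greedy).
#' @param q_init Initial action value for both levers, in \[0, 1\];
#'   default 0.5, the uninformative midpoint for binary rewards.
#' @return An object of class `q_params`.
#' @examples
#' q_params(0.4, 0.3, 0, 3)
#' @export
q_params <- function(alpha_plus, alpha_minus, pi, beta, q_init = 0.5) {
  if (!is.numeric(alpha_plus) || alpha_plus < 0 || alpha_plus > 1)
    stop("alpha_plus must be in [0, 1]")
  if (!is.numeric(alpha_minus) || alpha_minus < 0 || alpha_minus > 1)
    stop("alpha_minus must be in [0, 1]")
  if (!is.numeric(beta) || beta < 0)
    stop("beta must be >= 0")
  if (!is.numeric(pi) || !is.finite(pi))
    stop("pi must be a finite number")
  if (!is.numeric(q_init) || q_init < 0 || q_init > 1)
    stop("q_init must be in [0, 1]")
  structure(
    list(alpha_plus = as.numeric(alpha_plus),
         alpha_minus = as.numeric(alpha_minus),
         pi = as.numeric(pi), beta = as.numeric(beta),
         q_init = as.numeric(q_init)),
    class = "q_params"
  )
}

#' @export
print.q_params <- function(x, ...) {
  cat(sprintf(
    "Q-learning parameters: alpha+ = %.3f, alpha- = %.3f, pi = %.3f, beta = %.3f (q_init = %.2f)\n",
    x$alpha_plus, x$alpha_minus, x$pi, x$beta, x$q_init))
  invisible(x)
}

#' Fresh learner state
#'
#' Both action values start at `q_init` and there is no previous choice, so
#' the stickiness term is inactive on the first trial.
#'
#' @param q_init Initial action value for both levers.
#' @return A list with elements `q` (named numeric, left/right) and `last`
#'   (the previously chosen side, `NA` at session start).
#' @export
q_state <- function(q_init = 0.5) {
  list(q = c(left = q_init, right = q_init), last = NA_character_)
}

#' Single-trial value update
#'
#' Applies the delta rule to the chosen lever only: the value moves toward
#' the obtained outcome by a fraction `alpha_plus` (rewarded) or
#' `alpha_minus` (not rewarded). With binary rewards and `q_init` in
#' \[0, 1\], values remain in \[0, 1\] indefinitely.
#'
#' @param state Learner state from [q_state()] or a previous update.
#' @param choice `"left"` or `"right"`.
#' @param reward 0 or 1.
#' @param params A [q_params()] object.
#' @return The updated state.
#' @examples
#' st <- q_update(q_state(), "left", 1, q_params(0.2, 0.5, 0, 3))
#' st$q  # left moved from 0.5 to 0.6
#' @export
q_update <- function(state, choice, reward, params) {
  if (!is.character(choice) || !choice %in% c("left", "right"))
    stop("input error: choice must be 'left' or 'right'")
  if (!is.numeric(reward) && !is.logical(reward))
    stop("input error: reward must be 0 or 1")
  reward <- as.numeric(reward)
  if (!reward %in% c(0, 1))
    stop("input error: reward must be 0 or 1")
  a <- if (reward == 1) params$alpha_plus else params$alpha_minus
  state$q[[choice]] <- state$q[[choice]] + a * (reward - state$q[[choice]])
  state$last <- choice
  state
}

#' Choice probabilities of the Q-learning model
#'
#' Softmax over `beta * Q(a) + pi * 1[a == last choice]`, computed with
#' log-sum-exp stabilisation so large `beta` cannot overflow.
#'
#' @inheritParams q_update
#' @return Named probability vector `c(left = , right = )` summing to 1.
#' @examples
#' choice_prob(q_state(), q_params(0.3, 0.3, 0, 0))  # beta 0: uniform
#' @export
choice_prob <- function(state, params) {
  x <- params$beta * state$q
  if (!is.na(state$last)) x[[state$last]] <- x[[state$last]] + params$pi
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

# choice/reward columns of a session as 0/1 integers for the C++ kernel
session_codes <- function(session) {
  list(choice = match(session$chosen_side, c("left", "right")) - 1L,
       reward = as.integer(session$rewarded))
}

#' Negative log-likelihood of a session under the Q-learning model
#'
#' The learner state is initialised fresh (values at `q_init`, no previous
#' choice) and the model is stepped through the session's recorded choices
#' and rewards; the returned value is \eqn{-\sum_t \ln P(c_t)} in nats.
#'
#' @param session A `prl_session` (or any data frame with `chosen_side` and
#'   `rewarded` columns in trial order).
#' @param params A [q_params()] object.
#' @return Negative log-likelihood in nats (single number, >= 0).
#' @examples
#' s <- simulate_prl_session(random_policy(0.5), prl_config(), seed = 1)
#' q_nll(s, q_params(0.3, 0.3, 0, 0))  # beta = pi = 0: 120 * log(2)
#' @export
q_nll <- function(session, params) {
  if (nrow(session) == 0L) stop("input error: empty session")
  cd <- session_codes(session)
  qnll_cpp(cd$choice, cd$reward, params$alpha_plus, params$alpha_minus,
           params$pi, params$beta, params$q_init)
}

#' Per-trial probabilities of the recorded choices
#'
#' Pure-R trace of the model through a session, returning the probability the
#' model assigned to the choice actually made at each trial. Useful for
#' diagnostics; `-sum(log(.))` equals [q_nll()].
#'
#' @inheritParams q_nll
#' @return Numeric vector, one probability per trial.
#' @export
q_trial_probs <- function(session, params) {
  if (nrow(session) == 0L) stop("input error: empty session")
  st <- q_state(params$q_init)
  n <- nrow(session)
  out <- numeric(n)
  for (t in seq_len(n)) {
    p <- choice_prob(st, params)
    ch <- session$chosen_side[t]
    out[t] <- p[[ch]]
    st <- q_update(st, ch, as.numeric(session$rewarded[t]), params)
  }
  out
}

#' Default box constraints for maximum-likelihood fitting
#'
#' Learning rates live in \[0, 1\] by construction; `beta` in \[0, 20\] and
#' `pi` in \[-5, 5\] cover the behaviourally plausible range while keeping
#' the likelihood well conditioned.
#'
#' @return List with named numeric vectors `lower` and `upper` in the order
#'   alpha_plus, alpha_minus, pi, beta.
#' @export
q_fit_bounds <- function() {
  list(lower = c(alpha_plus = 0, alpha_minus = 0, pi = -5, beta = 0),
       upper = c(alpha_plus = 1, alpha_minus = 1, pi = 5, beta = 20))
}

#' Fit the Q-learning model to one session by maximum likelihood
#'
#' Bounded L-BFGS-B optimisation of the negative log-likelihood from
#' `n_starts` Latin-hypercube starting points spread over the box
#' constraints. The best (lowest-NLL) solution is returned; exact NLL ties
#' are broken by lexicographic parameter order so the result is a pure
#' function of `(session, n_starts, bounds, seed)`.
#'
#' @inheritParams q_nll
#' @param n_starts Number of optimisation restarts (>= 1).
#' @param bounds Box constraints as from [q_fit_bounds()].
#' @param seed Integer seed controlling the start points.
#' @param q_init Initial action value used when evaluating the likelihood.
#' @return An object of class `q_fit`: list with `params` ([q_params()]),
#'   `nll`, `n_starts`, `converged` (logical, optimizer convergence at the
#'   returned solution), and `per_start_nll`.
#' @examples
#' s <- simulate_prl_session(q_policy(q_params(0.5, 0.4, 0, 4)),
#'                           prl_config(), seed = 7)
#' fit_q(s, n_starts = 4, seed = 1)
#' @export
fit_q <- function(session, n_starts = 10L, bounds = q_fit_bounds(),
                  seed = 1L, q_init = 0.5) {
  if (n_starts < 1L) stop("n_starts must be >= 1")
  if (nrow(session) == 0L) stop("input error: empty session")
  cd <- session_codes(session)
  fn <- function(p) qnll_cpp(cd$choice, cd$reward, p[1], p[2], p[3], p[4], q_init)
  lo <- bounds$lower
  hi <- bounds$upper
  u <- withr::with_seed(seed, lhs::randomLHS(as.integer(n_starts), 4L))
  starts <- sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)

  fits <- vector("list", n_starts)
  per_start_nll <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], fn, method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    if (!is.null(res)) {
      fits[[i]] <- res
      per_start_nll[i] <- res$value
    }
  }
  ok <- which(!is.na(per_start_nll))
  if (length(ok) == 0L)
    stop("convergence error: all ", n_starts, " optimisation starts failed")
  pars <- do.call(rbind, lapply(fits[ok], `[[`, "par"))
  ord <- order(per_start_nll[ok], pars[, 1], pars[, 2], pars[, 3], pars[, 4])
  best <- fits[ok][[ord[1]]]
  structure(
    list(params = q_params(best$par[1], best$par[2], best$par[3], best$par[4],
                           q_init = q_init),
         nll = best$value,
         n_starts = as.integer(n_starts),
         converged = best$convergence == 0L,
         per_start_nll = per_start_nll),
    class = "q_fit"
  )
}

#' @export
print.q_fit <- function(x, ...) {
  cat(sprintf("Q-model fit: nll = %.3f over %d starts (converged: %s)\n",
              x$nll, x$n_starts, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit many sessions into a tidy table
#'
#' @param sessions List of `prl_session` objects.
#' @param n_starts,bounds,seed Passed to [fit_q()]; per-session fit seeds are
#'   derived from `seed`.
#' @return A tibble with one row per session: subject_id, day, alpha_plus,
#'   alpha_minus, pi, beta, nll, n_trials, converged.
#' @export
fit_q_sessions <- function(sessions, n_starts = 10L, bounds = q_fit_bounds(),
                           seed = 1L) {
  seeds <- child_seeds(length(sessions), seed)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    f <- fit_q(s, n_starts = n_starts, bounds = bounds, seed = seeds[i])
    tibble::tibble(
      subject_id = attr(s, "subject_id") %||% NA_character_,
      day = attr(s, "day") %||% NA_integer_,
      alpha_plus = f$params$alpha_plus, alpha_minus = f$params$alpha_minus,
      pi = f$params$pi, beta = f$params$beta,
      nll = f$nll, n_trials = nrow(s), converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Parameter-recovery study
#'
#' Simulates agents with known parameters on the reversal-learning schedule,
#' refits each simulated session, and summarises how well each parameter is
#' retrieved (Pearson correlation and mean signed bias). This is the standard
#' validation that a cognitive model's fitting pipeline is informative at the
#' study's trial counts.
#'
#' @param true_params Either a single [q_params()] (recycled: a degenerate
#'   grid, flagged in the report), a list of [q_params()] of length
#'   `n_agents`, or a function `function(i)` returning the i-th agent's
#'   parameters (called under the recovery seed, so random draws are
#'   reproducible).
#' @param n_agents Number of simulated agents.
#' @param trials_per_agent Trials in each agent's single session (>= 120);
#'   must be a multiple of `block_length`.
#' @param seed Integer seed governing parameter draws, simulation and fits.
#' @param n_starts Optimisation restarts per fit.
#' @param block_length Reversal block length of the simulated schedule.
#' @return An object of class `recovery_report`: list with `draws` (tibble of
#'   true and recovered values per agent), `summary` (per-parameter
#'   correlation and bias), `n_trials_per_fit`, `seed`, and `degenerate`
#'   (TRUE when a parameter has zero variance in the truth, making its
#'   correlation undefined).
#' @export
recover_q <- function(true_params, n_agents = 100L, trials_per_agent = 600L,
                      seed = 1L, n_starts = 10L, block_length = 40L) {
  if (trials_per_agent < 120L)
    stop("trials_per_agent must be >= 120")
  config <- prl_config(n_trials = trials_per_agent,
                       block_length = block_length,
                       initial_high_side = "random")
  tp_list <- if (inherits(true_params, "q_params")) {
    rep(list(true_params), n_agents)
  } else if (is.function(true_params)) {
    withr::with_seed(seed, lapply(seq_len(n_agents), true_params))
  } else if (is.list(true_params)) {
    if (length(true_params) != n_agents)
      stop("true_params list must have length n_agents")
    true_params
  } else {
    stop("true_params must be q_params, a list of q_params, or a function")
  }
  seeds <- child_seeds(2L * n_agents, seed + 1L)
  rows <- lapply(seq_len(n_agents), function(i) {
    tp <- tp_list[[i]]
    sess <- simulate_prl_session(q_policy(tp), config, seed = seeds[i],
                                 subject_id = sprintf("agent%03d", i))
    f <- fit_q(sess, n_starts = n_starts, seed = seeds[n_agents + i])
    tibble::tibble(
      agent = i,
      true_alpha_plus = tp$alpha_plus, true_alpha_minus = tp$alpha_minus,
      true_pi = tp$pi, true_beta = tp$beta,
      fit_alpha_plus = f$params$alpha_plus,
      fit_alpha_minus = f$params$alpha_minus,
      fit_pi = f$params$pi, fit_beta = f$params$beta,
      nll = f$nll)
  })
  draws <- do.call(rbind, rows)
  pars <- c("alpha_plus", "alpha_minus", "pi", "beta")
  summ <- lapply(pars, function(p) {
    tv <- draws[[paste0("true_", p)]]
    fv <- draws[[paste0("fit_", p)]]
    degen <- sd(tv) == 0
    tibble::tibble(
      parameter = p,
      correlation = if (degen) NA_real_ else cor(tv, fv),
      bias = mean(fv - tv),
      degenerate = degen)
  })
  summ <- do.call(rbind, summ)
  structure(
    list(draws = draws, summary = summ,
         n_trials_per_fit = as.integer(trials_per_agent),
         seed = as.integer(seed),
         degenerate = any(summ$degenerate)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d agents, %d trials per fit\n",
              nrow(x$draws), x$n_trials_per_fit))
  if (x$degenerate)
    cat("note: degenerate truth grid; correlations undefined for flagged parameters\n")
  print(x$summary)
  invisible(x)
}
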