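#' Default subject-profile modulators for the non-timing manipulations
#'
#' Distractors penalise stimulus detection (and mildly slow responding, the
#' loose block also raising perseveration); free food access raises omissions
#' and slows both response and reward collection, reflecting reduced
#' motivation. Values are multiplicative on the corresponding profile fields
#' and apply only in the named manipulation.
#'
#' @return Named list of per-manipulation multiplier lists.
#' @export
default_modulators <- function() {
  list(
    distractor_fixed = list(attention_mult = 0.90, latency_mult = 1.15),
    distractor_loose = list(attention_mult = 0.85, persev_mult = 1.25,
                            latency_mult = 1.15),
    ad_lib_food = list(omission_mult = 3.0, latency_mult = 1.3,
                       reward_latency_mult = 1.3)
  )
}

#' Generative profile of a virtual 5CSRTT subject
#'
#' The per-trial generative model: a premature poke occurs during the ITI
#' with probability `1 - exp(-premature_hazard * ITI)` (exponential hazard);
#' otherwise the stimulus appears and is detected with probability
#' `1 - (1 - attention_p)^d` for a stimulus of d seconds (so `attention_p`
#' is the detection probability at the 1 s baseline stimulus). A detected
#' stimulus yields a correct poke with log-normal latency unless an omission
#' intervenes (`omission_p_given_detect`); an undetected stimulus yields an
#' incorrect poke at a random other aperture with probability
#' `guess_p_respond`, else an omission. Correct trials accrue
#' Poisson-distributed perseverative pokes and a log-normal reward-collection
#' latency.
#'
#' The defaults describe a well-trained animal: roughly 97% accuracy, ~9
#' omissions and ~6 premature trials per 100 baseline trials, inside the
#' usual stability criteria (accuracy > 80%, < 20 omissions).
#'
#' @param attention_p Probability of detecting a 1 s stimulus, in \[0, 1\].
#' @param premature_hazard Premature-poke hazard during the ITI, events/s.
#' @param omission_p_given_detect Probability a detected stimulus still ends
#'   in no response.
#' @param guess_p_respond Probability of poking (necessarily at a wrong
#'   aperture) when the stimulus went undetected.
#' @param persev_rate Mean perseverative pokes following a correct response.
#' @param latency_meanlog,latency_sdlog Log-normal parameters of the correct
#'   response latency (seconds); draws are truncated to the response window.
#' @param reward_latency_meanlog,reward_latency_sdlog Log-normal parameters
#'   of the reward-collection latency (seconds).
#' @param modulators Per-manipulation multiplier lists (see
#'   [default_modulators()]). Recognised keys: `attention_mult`,
#'   `premature_mult`, `omission_mult`, `guess_mult`, `persev_mult`,
#'   `latency_mult`, `reward_latency_mult`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(attention_p = 0.93, premature_hazard = 0.012,
                            omission_p_given_detect = 0.05,
                            guess_p_respond = 0.3, persev_rate = 1.5,
                            latency_meanlog = -0.7, latency_sdlog = 0.4,
                            reward_latency_meanlog = 0.1,
                            reward_latency_sdlog = 0.4,
                            modulators = default_modulators()) {
  probs <- c(attention_p, omission_p_given_detect, guess_p_respond)
  if (any(probs < 0) || any(probs > 1))
    stop("profile probabilities must be in [0, 1]")
  if (premature_hazard < 0 || persev_rate < 0)
    stop("rates must be >= 0")
  structure(
    list(attention_p = attention_p, premature_hazard = premature_hazard,
         omission_p_given_detect = omission_p_given_detect,
         guess_p_respond = guess_p_respond, persev_rate = persev_rate,
         latency_meanlog = latency_meanlog, latency_sdlog = latency_sdlog,
         reward_latency_meanlog = reward_latency_meanlog,
         reward_latency_sdlog = reward_latency_sdlog,
         modulators = modulators),
    class = "subject_profile"
  )
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# log-normal draw truncated to (0, upper] via the quantile transform,
# so truncation costs exactly one uniform draw (determinism-friendly)
rlnorm_trunc <- function(meanlog, sdlog, upper) {
  u <- runif(1) * plnorm(upper, meanlog, sdlog)
  qlnorm(u, meanlog, sdlog)
}

stim_duration_at <- function(stimulus, trial_index0) {
  if (stimulus$type == "fixed") return(stimulus$seconds)
  k <- (trial_index0 %/% stimulus$block_length) %% length(stimulus$seconds)
  stimulus$seconds[k + 1L]
}

draw_iti <- function(iti) {
  if (iti$type == "fixed") return(iti$seconds)
  # uniform over the whole seconds of the stated range
  sample(seq.int(iti$min, iti$max), 1L)
}

#' Simulate one 5CSRTT session
#'
#' Runs the trial state machine until `max_trials` trials are done or the
#' session clock passes `max_duration` (the trial in progress completes).
#' Each trial is one of four mutually exclusive outcomes — correct,
#' incorrect, omission, or premature (a poke during the ITI aborts the trial
#' before the stimulus but still counts toward the trial total) — so the
#' outcome counts always partition the completed trials. Incorrect,
#' omission and premature trials incur the timeout; correct trials add the
#' reward-collection latency plus a fixed 1 s consumption pause.
#'
#' @param profile A [subject_profile()].
#' @param config A [csrtt_config()] or manipulation name (string).
#' @param seed Optional integer; same (profile, config, seed) give an
#'   identical session.
#' @param subject_id Identifier recorded on the result.
#' @return Tibble of class `csrtt_session`, one row per trial: `trial_index`
#'   (0-based), `iti_s`, `stimulus_aperture`, `stimulus_duration_s`,
#'   `outcome`, `n_premature_pokes`, `n_perseverative`, `correct_latency_s`,
#'   `reward_latency_s`. Attributes: `subject_id`, `manipulation`, `config`,
#'   `seed`, `duration_s` (simulated clock at session end).
#' @examples
#' tr <- simulate_csrtt_session(subject_profile(), "baseline", seed = 1)
#' table(tr$outcome)
#' @export
simulate_csrtt_session <- function(profile, config = csrtt_manipulation("baseline"),
                                   seed = NULL, subject_id = "s1") {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.character(config)) config <- csrtt_manipulation(config)
  stopifnot(inherits(config, "csrtt_config"))

  mods <- profile$modulators[[config$manipulation]] %||% list()
  att_mult <- mods$attention_mult %||% 1
  prem_mult <- mods$premature_mult %||% 1
  om_mult <- mods$omission_mult %||% 1
  guess_mult <- mods$guess_mult %||% 1
  persev_mult <- mods$persev_mult %||% 1
  lat_shift <- log(mods$latency_mult %||% 1)
  rlat_shift <- log(mods$reward_latency_mult %||% 1)

  haz <- profile$premature_hazard * prem_mult
  p_att1s <- clamp01(profile$attention_p * att_mult)
  p_om <- clamp01(profile$omission_p_given_detect * om_mult)
  p_guess <- clamp01(profile$guess_p_respond * guess_mult)

  run <- function() {
    clock <- 0
    nmax <- config$max_trials
    iti_v <- numeric(nmax)
    aperture_v <- integer(nmax)
    stim_v <- numeric(nmax)
    outcome_v <- character(nmax)
    nprem_v <- integer(nmax)
    npersev_v <- integer(nmax)
    lat_v <- rep(NA_real_, nmax)
    rlat_v <- rep(NA_real_, nmax)
    t <- 0L
    while (t < nmax && clock < config$max_duration) {
      t <- t + 1L
      iti <- draw_iti(config$iti)
      stim_d <- stim_duration_at(config$stimulus, t - 1L)
      aperture <- sample.int(config$n_apertures, 1L)
      outcome <- NA_character_
      n_prem <- 0L
      n_persev <- 0L
      lat <- NA_real_
      rlat <- NA_real_
      p_prem <- 1 - exp(-haz * iti)
      if (runif(1) < p_prem) {
        outcome <- "premature"
        n_prem <- 1L + rgeom(1, 0.7)
        # arrival time of the first poke, exponential truncated to the ITI
        tpoke <- -log(1 - runif(1) * (1 - exp(-haz * iti))) / haz
        dur <- tpoke + config$timeout
      } else {
        p_det <- clamp01(1 - (1 - p_att1s)^stim_d)
        detected <- runif(1) < p_det
        if (detected && runif(1) >= p_om) {
          outcome <- "correct"
          lat <- rlnorm_trunc(profile$latency_meanlog + lat_shift,
                              profile$latency_sdlog, config$response_window)
          n_persev <- rpois(1, profile$persev_rate * persev_mult)
          rlat <- rlnorm(1, profile$reward_latency_meanlog + rlat_shift,
                         profile$reward_latency_sdlog)
          dur <- iti + lat + rlat + 1.0
        } else if (!detected && runif(1) < p_guess) {
          outcome <- "incorrect"
          dur <- iti + runif(1, 0, config$response_window) + config$timeout
        } else {
          outcome <- "omission"
          dur <- iti + config$response_window + config$timeout
        }
      }
      clock <- clock + dur
      iti_v[t] <- iti
      aperture_v[t] <- aperture
      stim_v[t] <- stim_d
      outcome_v[t] <- outcome
      nprem_v[t] <- n_prem
      npersev_v[t] <- n_persev
      lat_v[t] <- lat
      rlat_v[t] <- rlat
    }
    keep <- seq_len(t)
    out <- tibble::tibble(
      trial_index = keep - 1L, iti_s = iti_v[keep],
      stimulus_aperture = aperture_v[keep],
      stimulus_duration_s = stim_v[keep], outcome = outcome_v[keep],
      n_premature_pokes = nprem_v[keep], n_perseverative = npersev_v[keep],
      correct_latency_s = lat_v[keep], reward_latency_s = rlat_v[keep])
    structure(out,
              class = unique(c("csrtt_session", class(out))),
              subject_id = subject_id, manipulation = config$manipulation,
              config = config, seed = seed, duration_s = clock)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' The six per-session 5CSRTT measures
#'
#' Accuracy is the percentage of correct responses out of responded trials,
#' `100 * correct / (correct + incorrect)` — premature and omission trials do
#' not enter the denominator, and the measure is `NA` (not 0) when no trial
#' was responded. Premature responding is reported both as the number of
#' premature trials and the total poke count; latencies average over correct
#' trials only.
#'
#' @param trials A `csrtt_session` (or data frame with the same columns).
#' @return One-row tibble: `n_trials_completed`, `n_correct`, `n_incorrect`,
#'   `accuracy_pct`, `n_premature`, `n_premature_pokes`, `n_omissions`,
#'   `n_perseverative`, `mean_correct_latency_s`, `mean_reward_latency_s`.
#' @examples
#' tr <- simulate_csrtt_session(subject_profile(), "baseline", seed = 1)
#' csrtt_measures(tr)
#' @export
csrtt_measures <- function(trials) {
  if (nrow(trials) == 0L) stop("input error: empty trial list")
  nc <- sum(trials$outcome == "correct")
  ni <- sum(trials$outcome == "incorrect")
  lat <- trials$correct_latency_s[trials$outcome == "correct"]
  rlat <- trials$reward_latency_s[trials$outcome == "correct"]
  tibble::tibble(
    n_trials_completed = nrow(trials),
    n_correct = nc,
    n_incorrect = ni,
    accuracy_pct = if (nc + ni > 0) 100 * nc / (nc + ni) else NA_real_,
    n_premature = sum(trials$outcome == "premature"),
    n_premature_pokes = sum(trials$n_premature_pokes),
    n_omissions = sum(trials$outcome == "omission"),
    n_perseverative = sum(trials$n_perseverative),
    mean_correct_latency_s = if (nc > 0) mean(lat) else NA_real_,
    mean_reward_latency_s = if (nc > 0) mean(rlat) else NA_real_)
}
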