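#' Names of the supported 5CSRTT schedules
#'
#' Baseline plus the ten standard manipulations: three impulsivity probes
#' (lengthened or variable inter-trial intervals), four attention probes
#' (shortened/variable ITIs and stimulus durations), two distractor
#' conditions and the ad-libitum-food motivation probe. Distractor and
#' ad-lib conditions keep baseline timing and act through subject-profile
#' modulators.
#'
#' @return Character vector of schedule names accepted by
#'   [csrtt_manipulation()].
#' @export
csrtt_manipulations <- function() {
  c("baseline",
    "long_iti_7s", "long_var_iti_5_13", "mean_var_iti_3_7",
    "short_iti_2s", "short_var_iti_1_5",
    "short_stim_0.5", "var_stim_1.2_0.5",
    "distractor_fixed", "distractor_loose", "ad_lib_food")
}

#' 5CSRTT session configuration
#'
#' Baseline timing: 5 s inter-trial interval, 1 s stimulus, 2 s limited hold,
#' 5 s timeout after errors/omissions/premature pokes; a session runs to 100
#' trials or 30 minutes, whichever comes first. The response window (time
#' from stimulus onset within which a poke still counts) is 5 s — the
#' omission definition governs it; the shorter nominal limited hold is kept
#' as metadata.
#'
#' @param manipulation Schedule label (see [csrtt_manipulations()]).
#' @param iti Either `list(type = "fixed", seconds = x)` or
#'   `list(type = "uniform_int", min = a, max = b)` (ITI drawn uniformly over
#'   the whole seconds a..b, independently per trial).
#' @param stimulus Either `list(type = "fixed", seconds = x)` or
#'   `list(type = "alternating", seconds = c(x1, x2), block_length = k)`
#'   (duration constant within consecutive k-trial blocks, alternating).
#' @param limited_hold,response_window,timeout Durations in seconds.
#' @param max_trials Trial cap per session (default 100).
#' @param max_duration Session time cap in seconds (default 1800); the trial
#'   in progress when the cap is hit completes.
#' @param n_apertures Number of stimulus apertures (default 5).
#' @return An object of class `csrtt_config`.
#' @export
csrtt_config <- function(manipulation = "baseline",
                         iti = list(type = "fixed", seconds = 5),
                         stimulus = list(type = "fixed", seconds = 1),
                         limited_hold = 2, response_window = 5, timeout = 5,
                         max_trials = 100L, max_duration = 1800,
                         n_apertures = 5L) {
  durs <- c(limited_hold, response_window, timeout, max_duration)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("configuration error: all durations must be > 0")
  max_trials <- as.integer(max_trials)
  if (is.na(max_trials) || max_trials <= 0L)
    stop("configuration error: max_trials must be a positive count")
  if (!iti$type %in% c("fixed", "uniform_int"))
    stop("configuration error: unknown iti type '", iti$type, "'")
  if (identical(iti$type, "fixed") && iti$seconds <= 0)
    stop("configuration error: iti must be > 0")
  if (!stimulus$type %in% c("fixed", "alternating"))
    stop("configuration error: unknown stimulus type '", stimulus$type, "'")
  structure(
    list(manipulation = manipulation, iti = iti, stimulus = stimulus,
         limited_hold = limited_hold, response_window = response_window,
         timeout = timeout, max_trials = max_trials,
         max_duration = max_duration, n_apertures = as.integer(n_apertures)),
    class = "csrtt_config"
  )
}

#' @export
print.csrtt_config <- function(x, ...) {
  iti <- if (x$iti$type == "fixed") sprintf("%g s", x$iti$seconds)
         else sprintf("%g-%g s (uniform)", x$iti$min, x$iti$max)
  stim <- if (x$stimulus$type == "fixed") sprintf("%g s", x$stimulus$seconds)
          else sprintf("%s s alternating every %d trials",
                       paste(x$stimulus$seconds, collapse = "/"),
                       x$stimulus$block_length)
  cat(sprintf("5CSRTT schedule '%s': ITI %s, stimulus %s, cap %d trials / %g min\n",
              x$manipulation, iti, stim, x$max_trials, x$max_duration / 60))
  invisible(x)
}

#' Named 5CSRTT manipulation schedules
#'
#' Returns the configuration of any of the standard schedules: baseline
#' (5 s ITI, 1 s stimulus); impulsivity probes with a long 7 s ITI, a long
#' variable ITI of 5-13 s or a mean-variable ITI of 3-7 s; attention probes
#' with a short 2 s ITI, a short variable ITI of 1-5 s, a fixed 0.5 s
#' stimulus, or a stimulus alternating between 1.2 s and 0.5 s every 20
#' trials; and the distractor / ad-lib-food conditions, which reuse baseline
#' timing (their effect enters through subject-profile modulators keyed by
#' the manipulation name).
#'
#' @param name One of [csrtt_manipulations()].
#' @return A [csrtt_config()].
#' @examples
#' csrtt_manipulation("long_iti_7s")
#' @export
csrtt_manipulation <- function(name) {
  switch(name,
    baseline = csrtt_config("baseline"),
    long_iti_7s = csrtt_config(name, iti = list(type = "fixed", seconds = 7)),
    long_var_iti_5_13 =
      csrtt_config(name, iti = list(type = "uniform_int", min = 5, max = 13)),
    mean_var_iti_3_7 =
      csrtt_config(name, iti = list(type = "uniform_int", min = 3, max = 7)),
    short_iti_2s = csrtt_config(name, iti = list(type = "fixed", seconds = 2)),
    short_var_iti_1_5 =
      csrtt_config(name, iti = list(type = "uniform_int", min = 1, max = 5)),
    "short_stim_0.5" =
      csrtt_config(name, stimulus = list(type = "fixed", seconds = 0.5)),
    "var_stim_1.2_0.5" =
      csrtt_config(name, stimulus = list(type = "alternating",
                                         seconds = c(1.2, 0.5),
                                         block_length = 20L)),
    distractor_fixed = csrtt_config(name),
    distractor_loose = csrtt_config(name),
    ad_lib_food = csrtt_config(name),
    stop("configuration error: unknown manipulation '", name, "'")
  )
}
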