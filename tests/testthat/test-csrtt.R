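test_that("named manipulation schedules carry the right timing", {
  b <- csrtt_manipulation("baseline")
  expect_equal(b$iti, list(type = "fixed", seconds = 5))
  expect_equal(b$stimulus, list(type = "fixed", seconds = 1))
  expect_equal(b$limited_hold, 2)
  expect_equal(b$timeout, 5)
  expect_equal(b$max_trials, 100L)
  expect_equal(b$max_duration, 1800)

  expect_equal(csrtt_manipulation("long_iti_7s")$iti$seconds, 7)
  expect_equal(csrtt_manipulation("short_iti_2s")$iti$seconds, 2)
  lv <- csrtt_manipulation("long_var_iti_5_13")$iti
  expect_equal(c(lv$min, lv$max), c(5, 13))
  mv <- csrtt_manipulation("mean_var_iti_3_7")$iti
  expect_equal(c(mv$min, mv$max), c(3, 7))
  sv <- csrtt_manipulation("short_var_iti_1_5")$iti
  expect_equal(c(sv$min, sv$max), c(1, 5))
  expect_equal(csrtt_manipulation("short_stim_0.5")$stimulus$seconds, 0.5)
  vs <- csrtt_manipulation("var_stim_1.2_0.5")$stimulus
  expect_equal(vs$seconds, c(1.2, 0.5))
  expect_equal(vs$block_length, 20L)
  # distractor / ad-lib keep baseline timing
  expect_equal(csrtt_manipulation("distractor_loose")$iti$seconds, 5)
  expect_equal(csrtt_manipulation("ad_lib_food")$stimulus$seconds, 1)
  expect_error(csrtt_manipulation("nope"), "configuration error")
  expect_error(csrtt_config(timeout = 0), "configuration error")
})

test_that("deterministic profiles produce the forced outcomes", {
  all_correct <- subject_profile(attention_p = 1, premature_hazard = 0,
                                 omission_p_given_detect = 0)
  tr <- simulate_csrtt_session(all_correct, "baseline", seed = 1)
  expect_true(all(tr$outcome == "correct"))
  expect_equal(nrow(tr), 100L)
  all_omit <- subject_profile(attention_p = 0, premature_hazard = 0,
                              guess_p_respond = 0)
  tr2 <- simulate_csrtt_session(all_omit, "baseline", seed = 1)
  expect_true(all(tr2$outcome == "omission"))
})

test_that("sessions are reproducible under a fixed seed", {
  a <- simulate_csrtt_session(subject_profile(), "long_var_iti_5_13", seed = 5)
  b <- simulate_csrtt_session(subject_profile(), "long_var_iti_5_13", seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("outcome partition and session caps hold on every simulated session", {
  prof <- subject_profile()
  for (i in 1:20) {
    tr <- simulate_csrtt_session(prof, "baseline", seed = 400 + i)
    counts <- table(factor(tr$outcome, c("correct", "incorrect",
                                         "omission", "premature")))
    expect_equal(sum(counts), nrow(tr))
    expect_lte(nrow(tr), 100L)
  }
  # a very slow subject runs into the 30-minute cap before 100 trials
  slow <- subject_profile(attention_p = 0, premature_hazard = 0,
                          guess_p_respond = 0)
  cfg <- csrtt_config("baseline", iti = list(type = "fixed", seconds = 20),
                      response_window = 30, timeout = 30)
  tr <- simulate_csrtt_session(slow, cfg, seed = 2)
  expect_lt(nrow(tr), 100L)
  # the trial in progress at the cutoff completes: at most one trial of slack
  expect_lte(attr(tr, "duration_s"), cfg$max_duration + (20 + 30 + 30))
  expect_gte(attr(tr, "duration_s"), cfg$max_duration)
})

test_that("variable stimulus duration alternates in 20-trial blocks", {
  tr <- simulate_csrtt_session(subject_profile(), "var_stim_1.2_0.5", seed = 3)
  expect_equal(nrow(tr), 100L)
  per_block <- tapply(tr$stimulus_duration_s, tr$trial_index %/% 20L, unique)
  expect_equal(as.vector(unlist(per_block)), c(1.2, 0.5, 1.2, 0.5, 1.2))
})

test_that("variable ITIs are drawn from the stated whole-second range", {
  tr <- simulate_csrtt_session(subject_profile(), "long_var_iti_5_13", seed = 8)
  expect_true(all(tr$iti_s %in% 5:13))
  expect_gt(length(unique(tr$iti_s)), 4)
})

test_that("measures match hand-built enumerations and handle empty denominators", {
  m <- csrtt_measures(hand_csrtt(c(rep("correct", 3), "incorrect",
                                   rep("omission", 6))))
  expect_equal(m$accuracy_pct, 75)
  expect_equal(m$n_omissions, 6L)

  ten <- hand_csrtt(c(rep("premature", 2), rep("omission", 2),
                      rep("correct", 5), "incorrect"),
                    n_perseverative = c(rep(0, 4), rep(2, 5), 0))
  m2 <- csrtt_measures(ten)
  expect_equal(m2$accuracy_pct, 5 / 6 * 100)
  expect_equal(m2$n_premature, 2L)
  expect_equal(m2$n_omissions, 2L)
  expect_equal(m2$n_perseverative, 10L)
  expect_equal(m2$n_trials_completed, 10L)
  expect_equal(m2$mean_correct_latency_s, 0.5)

  none <- csrtt_measures(hand_csrtt(rep("omission", 4)))
  expect_true(is.na(none$accuracy_pct))
  expect_true(is.na(none$mean_correct_latency_s))
  expect_error(csrtt_measures(hand_csrtt(character(0))), "input error")
})

test_that("default baseline subject meets the stability criteria", {
  meas <- do.call(rbind, lapply(1:60, function(i)
    csrtt_measures(simulate_csrtt_session(subject_profile(), "baseline",
                                          seed = 6000 + i))))
  ok <- meas$accuracy_pct > 80 & meas$n_omissions < 20
  expect_gte(mean(ok), 0.95)
})

test_that("manipulations shift behaviour in the documented directions", {
  prof <- subject_profile()
  runs <- function(manip, n = 40, seed0 = 0)
    do.call(rbind, lapply(seq_len(n), function(i)
      csrtt_measures(simulate_csrtt_session(prof, manip,
                                            seed = seed0 + i))))
  base <- runs("baseline", seed0 = 100)
  long <- runs("long_iti_7s", seed0 = 200)
  short_iti <- runs("short_iti_2s", seed0 = 300)
  short_stim <- runs("short_stim_0.5", seed0 = 400)
  adlib <- runs("ad_lib_food", seed0 = 500)
  expect_gt(mean(long$n_premature), mean(base$n_premature))
  expect_lt(mean(short_iti$n_premature), mean(base$n_premature))
  expect_lt(mean(short_stim$accuracy_pct), mean(base$accuracy_pct))
  expect_gt(mean(short_stim$n_omissions), mean(base$n_omissions))
  expect_gt(mean(adlib$n_omissions), mean(base$n_omissions))
})
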