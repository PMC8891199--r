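small_cfg <- function(seed = 1, ...) {
  cohort_config(group_sizes = c(control.male = 2, control.female = 2,
                                wmi.male = 1, wmi.female = 1),
                csrtt_manipulations = c("baseline", "short_iti_2s"),
                seed = seed, ...)
}

test_that("default design sizes match the emulated study", {
  cfg <- cohort_config(seed = 5)
  expect_equal(sum(cfg$group_sizes), 48L)
  expect_equal(unname(cfg$group_sizes["control.male"]), 13L)
  expect_equal(unname(cfg$group_sizes["wmi.female"]), 8L)
  expect_equal(cfg$prl_days, 5L)
  expect_error(cohort_config(group_sizes = c(control.male = 0,
                                             control.female = 0,
                                             wmi.male = 0, wmi.female = 0)),
               "empty cohort")
  expect_error(cohort_config(effect_deltas = list(wmi = list(beta = -1))),
               "strictly positive")
})

test_that("a single-subject cohort yields 5 PRL sessions with 2 reversals each", {
  cfg <- cohort_config(group_sizes = c(control.male = 1, control.female = 0,
                                       wmi.male = 0, wmi.female = 0),
                       csrtt_manipulations = "baseline", seed = 9)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$subjects), 1L)
  expect_length(coh$prl_sessions, 5L)
  expect_length(coh$csrtt_sessions, 1L)
  for (s in coh$prl_sessions) {
    expect_equal(nrow(s), 120L)
    hs <- s$current_high_side
    expect_equal(sum(hs[-1] != hs[-120]), 2L)
  }
  expect_equal(vapply(coh$prl_sessions, function(s) attr(s, "day"),
                      integer(1)), 1:5)
})

test_that("cohort generation is reproducible and seed changes data, not shape", {
  a <- generate_cohort(small_cfg(seed = 3))
  b <- generate_cohort(small_cfg(seed = 3))
  expect_identical(as.data.frame(a$subjects), as.data.frame(b$subjects))
  expect_identical(as.data.frame(a$prl_sessions[[7]]),
                   as.data.frame(b$prl_sessions[[7]]))
  d <- generate_cohort(small_cfg(seed = 4))
  expect_equal(dim(d$subjects), dim(a$subjects))
  expect_length(d$prl_sessions, length(a$prl_sessions))
  expect_false(identical(d$subjects$alpha_plus, a$subjects$alpha_plus))
})

test_that("trial logs round-trip through CSV with identical metric and fit outputs", {
  coh <- generate_cohort(small_cfg(seed = 6))
  dir <- withr::local_tempdir()
  write_prl_trials(coh$prl_sessions, file.path(dir, "prl.csv"))
  back <- read_prl_trials(file.path(dir, "prl.csv"))
  expect_length(back, length(coh$prl_sessions))
  expect_equal(as.data.frame(prl_metrics(back)),
               as.data.frame(prl_metrics(coh$prl_sessions)))
  f1 <- fit_q_sessions(coh$prl_sessions[1:3], n_starts = 4, seed = 2)
  f2 <- fit_q_sessions(back[1:3], n_starts = 4, seed = 2)
  expect_equal(as.data.frame(f1), as.data.frame(f2))

  write_csrtt_trials(coh$csrtt_sessions, file.path(dir, "cs.csv"))
  cs <- read_csrtt_trials(file.path(dir, "cs.csv"))
  expect_length(cs, length(coh$csrtt_sessions))
  expect_equal(as.data.frame(csrtt_measures(cs[[1]])),
               as.data.frame(csrtt_measures(coh$csrtt_sessions[[1]])))
})

test_that("identity deltas make group labels exchangeable", {
  coh <- generate_cohort(cohort_config(
    group_sizes = c(control.male = 10, control.female = 10,
                    wmi.male = 10, wmi.female = 10),
    csrtt_manipulations = character(0), prl_days = 1, seed = 13))
  m <- prl_metrics(coh$prl_sessions)
  m$group <- coh$subjects$group[match(m$subject_id, coh$subjects$subject_id)]
  obs <- abs(mean(m$pellets_pct[m$group == "wmi"]) -
             mean(m$pellets_pct[m$group == "control"]))
  perm <- withr::with_seed(14, vapply(1:500, function(i) {
    g <- sample(m$group)
    abs(mean(m$pellets_pct[g == "wmi"]) - mean(m$pellets_pct[g == "control"]))
  }, numeric(1)))
  expect_gt(mean(perm >= obs), 0.05)
})

test_that("a positive reward-learning-rate drift is recovered across days", {
  cfg <- cohort_config(group_sizes = c(control.male = 12, control.female = 0,
                                       wmi.male = 0, wmi.female = 0),
                       csrtt_manipulations = character(0),
                       alpha_plus_day_drift = 0.08, seed = 19)
  coh <- generate_cohort(cfg)
  fits <- fit_q_sessions(coh$prl_sessions, n_starts = 5, seed = 20)
  day_means <- tapply(fits$alpha_plus, fits$day, mean)
  expect_gt(day_means[["5"]], day_means[["1"]])
})

test_that("the end-to-end pipeline emits the full bundle", {
  dir <- withr::local_tempdir()
  res <- run_cohort_pipeline(small_cfg(seed = 8), out_dir = dir, n_starts = 4)
  expect_s3_class(res$analysis$recovery, "tbl_df")
  expect_setequal(list.files(dir),
                  c("subjects.csv", "prl_trials.csv", "csrtt_trials.csv",
                    "prl_metrics.csv", "csrtt_measures.csv", "fits.csv",
                    "report.json"))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$n_subjects, 6L)
  expect_length(rep$recovery, 4L)
  # cohort-level generative control: pi is 0 for every synthetic subject
  expect_true(all(res$cohort$subjects$pi == 0))
})

test_that("YAML configuration round-trips into an equivalent cohort_config", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cohort.yaml")
  writeLines(c(
    "group_sizes:",
    "  control.male: 2",
    "  control.female: 1",
    "  wmi.male: 1",
    "  wmi.female: 1",
    "prl_days: 2",
    "csrtt_manipulations: [baseline]",
    "seed: 77"), yml)
  cfg <- cohort_config_from_yaml(yml)
  expect_equal(sum(cfg$group_sizes), 5L)
  expect_equal(cfg$prl_days, 2L)
  expect_equal(cfg$csrtt_manipulations, "baseline")
  expect_equal(cfg$seed, 77L)
})
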