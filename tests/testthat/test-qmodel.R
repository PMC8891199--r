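test_that("delta-rule update moves only the chosen value by the right amount", {
  p <- q_params(0.2, 0.5, 0, 3)
  st <- q_update(q_state(0.5), "left", 1, p)
  expect_equal(st$q[["left"]], 0.6)
  expect_equal(st$q[["right"]], 0.5)
  expect_equal(st$last, "left")
  st2 <- q_update(q_state(0.5), "left", 0, p)
  expect_equal(st2$q[["left"]], 0.25)
  frozen <- q_params(0, 0, 0, 3)
  st3 <- q_update(q_state(0.5), "right", 1, frozen)
  expect_equal(st3$q, c(left = 0.5, right = 0.5))
  expect_error(q_update(q_state(), "left", 2, p), "input error")
  expect_error(q_update(q_state(), "up", 1, p), "input error")
})

test_that("choice rule matches its closed forms", {
  expect_equal(choice_prob(q_state(), q_params(0.3, 0.3, 0, 0)),
               c(left = 0.5, right = 0.5))
  # equal values, sticky on left with pi = ln 3 -> 3:1 odds for left
  st <- q_state(0.5)
  st$last <- "left"
  pr <- choice_prob(st, q_params(0.3, 0.3, log(3), 7))
  expect_equal(pr[["left"]], 0.75, tolerance = 1e-12)
  # large beta on a clear value difference -> near-greedy
  st2 <- q_state()
  st2$q <- c(left = 0.8, right = 0.2)
  expect_gt(choice_prob(st2, q_params(0.3, 0.3, 0, 20))[["left"]], 0.999)
  # normalisation under extreme parameters
  st2$last <- "right"
  pr2 <- choice_prob(st2, q_params(1, 1, -5, 20))
  expect_equal(sum(pr2), 1, tolerance = 1e-12)
})

test_that("q-values stay in [0, 1] under arbitrary binary outcome sequences", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      p <- q_params(runif(1), runif(1), runif(1, -5, 5), runif(1, 0, 20),
                    q_init = runif(1))
      st <- q_state(p$q_init)
      for (t in 1:200) {
        st <- q_update(st, sample(c("left", "right"), 1),
                       sample(0:1, 1), p)
        expect_true(all(st$q >= 0 & st$q <= 1))
      }
    }
  })
})

test_that("chance-model likelihood is n * ln 2 and the C++ kernel matches the R trace", {
  s <- simulate_prl_session(random_policy(0.5), prl_config(), seed = 17)
  expect_equal(q_nll(s, q_params(0.4, 0.2, 0, 0)), 120 * log(2))
  one <- hand_session("left", 1)
  expect_equal(q_nll(one, q_params(0.5, 0.5, 2, 9)), log(2))
  p <- q_params(0.7, 0.1, -0.8, 6)
  expect_equal(q_nll(s, p), -sum(log(q_trial_probs(s, p))), tolerance = 1e-9)
  expect_error(q_nll(s[0, ], p), "input error")
})

test_that("fit is deterministic, respects bounds, and beats the generating parameters", {
  truth <- q_params(0.5, 0.35, 0.3, 4)
  s <- simulate_prl_session(q_policy(truth), prl_config(), seed = 23)
  f1 <- fit_q(s, n_starts = 8, seed = 4)
  f2 <- fit_q(s, n_starts = 8, seed = 4)
  expect_identical(f1$nll, f2$nll)
  expect_identical(unlist(f1$params), unlist(f2$params))
  b <- q_fit_bounds()
  par <- c(f1$params$alpha_plus, f1$params$alpha_minus, f1$params$pi,
           f1$params$beta)
  expect_true(all(par >= b$lower - 1e-12) && all(par <= b$upper + 1e-12))
  expect_lte(f1$nll, q_nll(s, truth) + 1e-6)
  expect_true(all(f1$per_start_nll >= f1$nll - 1e-8, na.rm = TRUE))
})

test_that("chance-level data fit collapses to the chance likelihood", {
  s <- simulate_prl_session(random_policy(0.5),
                            prl_config(n_trials = 400, block_length = 40),
                            seed = 8)
  f <- fit_q(s, n_starts = 8, seed = 2)
  expect_lt(abs(f$nll / 400 - log(2)), 0.05)
})

test_that("true model beats the chance model on informative self-generated data", {
  truth <- q_params(0.5, 0.4, 0, 5)
  sessions <- simulate_prl_sessions(q_policy(truth), prl_config(), n = 50,
                                    seed = 12)
  per_trial <- vapply(sessions, function(s) q_nll(s, truth) / nrow(s),
                      numeric(1))
  expect_lt(mean(per_trial), log(2))
})

test_that("shuffling trial order pushes fitted beta toward chance on average", {
  truth <- q_params(0.5, 0.4, 0, 5)
  sessions <- simulate_prl_sessions(q_policy(truth), prl_config(), n = 25,
                                    seed = 77)
  perm <- withr::with_seed(78, lapply(sessions, function(s) {
    idx <- sample.int(nrow(s))
    sh <- s[idx, ]
    sh$trial_index <- s$trial_index
    sh
  }))
  beta_of <- function(ss, seed0) mean(vapply(seq_along(ss), function(i)
    fit_q(ss[[i]], n_starts = 5, seed = seed0 + i)$params$beta, numeric(1)))
  expect_lte(beta_of(perm, 500), beta_of(sessions, 300))
})

test_that("beta groups are recovered in the right order", {
  # group medians, not means: at low true beta the likelihood is nearly flat
  # in beta, so the ML estimate has a heavy right tail that makes small-group
  # means unstable while the central tendency stays correctly ordered
  betas <- rep(c(0.5, 2, 8), each = 15)
  fits <- vapply(seq_along(betas), function(i) {
    truth <- q_params(0.5, 0.4, 0, betas[i])
    s <- simulate_prl_session(q_policy(truth),
                              prl_config(n_trials = 480, block_length = 40),
                              seed = 9100 + i)
    fit_q(s, n_starts = 6, seed = 9200 + i)$params$beta
  }, numeric(1))
  medians <- tapply(fits, betas, median)
  expect_true(all(diff(medians) > 0))
})

test_that("a degenerate truth grid is flagged and dispersion is still reported", {
  rep1 <- recover_q(q_params(0.5, 0.4, 0, 4), n_agents = 8,
                    trials_per_agent = 120, seed = 3, n_starts = 5)
  expect_true(rep1$degenerate)
  expect_true(all(is.na(rep1$summary$correlation)))
  expect_true(all(is.finite(rep1$summary$bias)))
  expect_equal(nrow(rep1$draws), 8L)
})

test_that("recovery correlation for the reward learning rate is positive and grows with trials", {
  gen <- function(i) q_params(runif(1, 0.1, 0.9), 0.35, 0, 4)
  r_short <- recover_q(gen, n_agents = 40, trials_per_agent = 120,
                       seed = 21, n_starts = 5)
  r_long <- recover_q(gen, n_agents = 40, trials_per_agent = 600,
                      seed = 21, n_starts = 5)
  c_short <- r_short$summary$correlation[r_short$summary$parameter == "alpha_plus"]
  c_long <- r_long$summary$correlation[r_long$summary$parameter == "alpha_plus"]
  expect_gt(c_short, 0)
  expect_gt(c_long, c_short)
})
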