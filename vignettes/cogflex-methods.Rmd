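---
title: "Modelling cognitive flexibility tasks with cogflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive flexibility tasks with cogflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogflex)
```

`cogflex` simulates and analyses two operant tasks used to probe executive
function in rodents — a two-lever probabilistic reversal learning (PRL) task
and the 5-choice serial reaction time task (5CSRTT) — together with the
reinforcement-learning model used to decompose PRL choice behaviour into
interpretable parameters. Because trial-by-trial animal data of this kind are
rarely shared, the package also ships a synthetic cohort generator that
emulates a full 2 (group) × 2 (sex) study design, so every stage of the
pipeline can be exercised and validated end to end on data with known ground
truth.

## The reversal learning task

A session presents two levers for 120 trials. One lever is the
high-probability lever — a press is rewarded with probability 0.8 — and the
other the low-probability lever (reward probability 0.2). Which physical side
starts high is a fair coin flip per session. After each block of 40 trials
the contingencies swap sides, so a session contains exactly two reversals
(after trials 40 and 80, with 0-based blocks `[0,40)`, `[40,80)`, `[80,120)`).
The schedule is a pure function of the block parity and the initial side;
rewards are independent Bernoulli draws per trial. Every trial yields a
choice — the task has no omission state — and animals run 5 daily sessions.

`prl_schedule()` exposes the contingency table, and `simulate_prl_session()`
plays any *policy* through it. Three policies ship with the package: an
oracle that always presses the currently high (or, for calibration checks,
low) lever, a fixed Bernoulli policy (`random_policy(0.5)` is the
indifferent agent), and `q_policy()`, the generative form of the fitted
model below. Sessions record, besides the choice and reward, the probability
the policy assigned to its own choice; this makes an exact
simulation-vs-likelihood consistency check possible and is dropped when logs
are written to CSV.

Reaction times are decorative in the simulator: they are log-normal draws
attached per trial from subject-level parameters and play no role in the
choice model, which matches how the behavioural reaction-time measure is an
independent outcome rather than a model input.

## The Q-learning model

Choice behaviour is modelled with a four-parameter Rescorla–Wagner learner.
Each lever carries a value $Q(a)$, initialised at 0.5 (the uninformative
midpoint for binary outcomes). After choosing lever $c_t$ and observing
reward $r_t \in \{0,1\}$:

$$Q_{t+1}(c_t) = Q_t(c_t) + \alpha_{\mathrm{eff}}\,(r_t - Q_t(c_t)),
\qquad
\alpha_{\mathrm{eff}} = \begin{cases}\alpha^{+} & r_t = 1\\
\alpha^{-} & r_t = 0\end{cases}$$

The unchosen lever's value is left untouched (no forgetting/decay term — the
simplest form consistent with four parameters). Choices follow a softmax
with a stickiness bonus:

$$P(a) \propto \exp\!\big(\beta\,Q(a) + \pi\,\mathbb{1}[a = c_{t-1}]\big),$$

computed with log-sum-exp stabilisation. The parameters and their meaning:

| parameter | range (fit bounds) | interpretation |
|---|---|---|
| $\alpha^{+}$ | $[0,1]$ | sensitivity to rewarding feedback |
| $\alpha^{-}$ | $[0,1]$ | sensitivity to reward omission |
| $\pi$ | $[-5,5]$ | outcome-independent preference for the last-chosen lever (perseveration when positive) |
| $\beta$ | $[0,20]$ | exploit/explore: consistency of choosing the higher-valued lever |

On the first trial of a session there is no previous choice, so the
stickiness term contributes to neither lever and the first-trial likelihood
is exactly $\tfrac12$; at $\beta = \pi = 0$ the session likelihood is exactly
$n\ln 2$, a useful analytic anchor used in the tests.

Fitting is per session — the learner state resets at each session start — by
maximum likelihood: `fit_q()` runs bounded L-BFGS-B from `n_starts = 10`
Latin-hypercube start points inside the box constraints, returns the lowest
negative log-likelihood, and breaks exact ties lexicographically so a fit is
a deterministic function of `(session, n_starts, seed)`. The likelihood
kernel is implemented in C++ for speed; the R-level `q_update()` /
`choice_prob()` pair remains the definitional source and the test suite
asserts that the two agree to floating-point accuracy. The bounds above are
wide relative to observed rodent estimates; a fitted parameter pinned at a
bound (most often $\beta$ for near-random sessions) flags a poorly
identified session rather than a substantive estimate.

### Parameter recovery

`recover_q()` simulates agents with known parameters, refits each session,
and reports per-parameter Pearson correlation and mean signed bias. Two
caveats discovered with this harness are worth knowing. First, 120-trial
sessions identify the parameters only weakly — correlations rise
substantially from 120 to 600 trials — so per-session estimates at the
study's session length should be analysed at the group level, not trusted
individually. Second, the ML estimate of $\beta$ is heavy-tailed when true
$\beta$ is small (near-random behaviour makes the likelihood almost flat in
$\beta$), so group *medians* order recovered $\beta$ reliably while small-group
means can be distorted by single outliers.

## PRL behavioural statistics

`prl_metrics()` computes the standard session statistics:

* **High-lever presses per block** count presses on the *currently*
  high-probability lever in each 40-trial block; an indifferent agent
  averages 20 per block, and that chance line is the natural reference for
  the statistic.
* **Win-stay / lose-shift**: probability of repeating a rewarded choice /
  leaving an unrewarded one, over consecutive trial pairs. Undefined
  denominators (e.g. a session without rewards) are reported as `NA`, never 0.
* **Sliding choice fraction** (window 8): for each trial, the fraction of
  choices for the *initially* high lever among the trials with 0-based
  indices in `[t-4, t+4)` — four before, the trial itself, three after, a
  half-open convention that keeps the window width exactly 8 with the centre
  trial in the leading half. Edge windows are truncated to the available
  trials so the series keeps one value per trial. Note the deliberate
  asymmetry with the block counts: the sliding series tracks the *initial*
  lever (so reversals appear as drops toward 0), while the block counts
  track the *current* one (so good performance is high in every block); the
  two conventions follow how each statistic is conventionally plotted.
* **Pellets earned** as a percentage of the maximum obtainable, with the
  ceiling taken as one pellet per trial (`n_trials`); the alternative
  ceiling — the expected maximum under the 80% contingency — would make
  100% unattainable and was rejected.

## The 5CSRTT engine

A 5CSRTT trial is a small state machine. Baseline timing: 5 s inter-trial
interval (ITI), then a 1 s stimulus in one of five apertures, a nominal 2 s
limited hold, a 5 s timeout after any failure, and a session cap of 100
trials or 30 minutes, whichever comes first (the trial in progress at the
time cap completes). One documented tension in the task description is that
the nominal limited hold is 2 s while an omission is defined as no response
within 5 s of stimulus onset; the engine lets the omission definition govern
(`response_window = 5`) and keeps the limited hold as metadata, both
configurable.

Each trial resolves to exactly one of four outcomes — premature (a poke
during the ITI, which aborts the trial before the stimulus but still counts
toward the trial total), correct, incorrect, or omission — so the outcome
counts always partition the completed trials. Premature responding follows
an exponential hazard through the ITI (probability $1-e^{-\lambda\,\mathrm{ITI}}$,
so longer ITIs mechanically raise premature rates, the signature impulsivity
effect); the poke count on a premature trial is 1 plus a geometric excess.
Stimulus detection scales with duration as $p_{\det}(d) = 1-(1-p_1)^{d}$
where $p_1$ is the profile's detection probability at the 1 s baseline —
shorter stimuli therefore lower accuracy and raise omissions. Detected
stimuli yield a correct poke with truncated log-normal latency unless an
omission intervenes; undetected stimuli yield an incorrect poke at a wrong
aperture with the profile's guessing probability, else an omission.
Perseverative pokes after a correct response are Poisson; the convention
that only correct trials accrue them follows the recorded measure
("perseverative responses after correct choice").

The ten standard manipulations are named schedules
(`csrtt_manipulation()`): impulsivity probes lengthen or vary the ITI
(fixed 7 s; uniform over whole seconds 5–13 s; 3–7 s), attention probes
shorten it (2 s; 1–5 s) or the stimulus (fixed 0.5 s; alternating
1.2 s/0.5 s in 20-trial blocks). Variable ITIs are drawn independently per
trial, uniformly over the stated whole-second values — the task description
gives only ranges. The two distractor conditions and the ad-libitum-food
motivation probe keep baseline timing and act through per-manipulation
profile modulators (an attention penalty for distractors; raised omission
probability and slowed latencies for free feeding), since that is how those
manipulations plausibly act on behaviour.

`csrtt_measures()` reports the six session measures; accuracy uses the
task's printed formula, correct/(correct+incorrect) × 100, with premature
and omission trials excluded from the denominator and `NA` (not 0) when no
trial was responded.

The default `subject_profile()` describes a *trained, stable* animal:
detection 0.93 at 1 s, omission-given-detection 0.05, guessing 0.3,
premature hazard 0.012/s, mean 1.5 perseverative pokes per correct. These
values were chosen from the training stability criteria (accuracy > 80%,
fewer than 20 omissions per session) and typical published baselines; they
put the simulated baseline near 97% accuracy, ~9 omissions and ~6 premature
trials per 100 — comfortably inside the criteria — and are deliberately not
tuned per manipulation.

## The synthetic cohort

`generate_cohort()` emulates the study design: 28 control (13 male,
15 female) and 20 injury-model (12 male, 8 female) subjects by default, each
with 5 daily PRL sessions of 120 trials and one 5CSRTT session per requested
schedule. Per-subject generative parameters are drawn once:
$\alpha^{+}\sim\mathrm{Beta}(8,12)$, $\alpha^{-}\sim\mathrm{Beta}(6,14)$,
$\beta\sim\mathrm{logNormal}(\ln 3, 0.25)$, and $\pi = 0$ — the stickiness
null mirrors the empirical finding that fitted stickiness in this task sits
near zero, and doubles as the generative control for the fitting pipeline.
An optional per-day increment on $\alpha^{+}$ emulates reward learning
strengthening across test days.

The default cohort is a **null cohort**: groups and sexes share identical
generative distributions, so group labels are exchangeable and any detected
difference is sampling noise — the right default for validating an analysis
pipeline. The study this design emulates reports effect *directions* but no
generative effect sizes, so the shipped `cohort_scenario("illustrative")`
preset (females slower and more perseverative, a small injury-model
perseveration shift) is clearly a package choice for demonstration, not an
empirical claim. What passing tests on this cohort show is that the
*pipeline* is correct and calibrated; they cannot show that real animals
conform to the generative model — real data bring omitted-variable
structure (satiation, circadian drift, estrous effects, apparatus quirks)
that the generator deliberately does not emulate.

`cohort_analysis()` then runs the analysis in the study's order — 5CSRTT
measures, PRL metrics, per-session Q-model fits — and compares fitted with
generating parameters. The emitted tables are tidy and ready for any
statistics tool; group inference (ANOVA and friends) is deliberately out of
scope.

## Numerical and design choices

* **Determinism.** Every simulation takes an explicit seed and uses an
  isolated RNG scope, so identical inputs give byte-identical outputs;
  ensembles derive independent child seeds from one master seed.
* **Truncation.** Correct-response latencies are truncated to the response
  window by the quantile transform (one uniform draw, no rejection loop), so
  determinism does not depend on a data-dependent number of draws.
* **Problem sizes.** The shipped validation uses ensembles of 100–700
  sessions, recovery studies of 40–100 agents at 120 and 600 trials, and an
  exhaustive 4-D likelihood grid (steps 0.05 on the learning rates, 0.25 on
  stickiness, 0.5 on inverse temperature) as a brute-force check on the
  optimiser; these sizes make the stochastic checks stable at the package's
  chosen tolerances while keeping a full run in minutes on one core.
* **CSV dialects.** Trial logs are plain UTF-8 CSV with a header; readers
  validate required columns, enum values and strict 0-based trial ordering,
  and name the offending row on failure. Written-then-reread logs reproduce
  metric and fit outputs exactly.

## Worked example

```{r example, eval = FALSE}
library(cogflex)

# a learner on the standard schedule
truth <- q_params(alpha_plus = 0.5, alpha_minus = 0.35, pi = 0, beta = 4)
s <- simulate_prl_session(q_policy(truth), prl_config(), seed = 1)
high_lever_presses(s)
fit_q(s, seed = 1)

# a small null cohort end to end
cfg <- cohort_config(group_sizes = c(control.male = 3, control.female = 3,
                                     wmi.male = 2, wmi.female = 2),
                     csrtt_manipulations = c("baseline", "long_iti_7s"),
                     seed = 42)
res <- run_cohort_pipeline(cfg)
res$analysis$recovery
```

## Known limitations

* Per-session fits at 120 trials are noisy by construction; pooled-over-day
  or hierarchical estimation would be the next step and is out of scope.
* The 5CSRTT generative model has no within-session dynamics (fatigue,
  satiation) and no trial-to-trial dependence; it reproduces ensemble-level
  effect directions, not published effect magnitudes.
* Only two response options and fixed session lengths are supported in the
  reversal task; reward-magnitude and delay manipulations are not modelled.
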