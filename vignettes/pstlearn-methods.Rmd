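---
title: "Models and methods behind pstlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pstlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstlearn)
```

# The task

The Probabilistic Selection Task (PST) presents pairs of stimuli with
complementary reward probabilities. `pstlearn` ships two variants:

* **modified**: two pairs, AB rewarded 80–20% and CD 65–35%, 240
  learning trials in three blocks of 80, a 40-trial feedback-free
  memory block repeated immediately, 30 minutes and (in the two-day
  design) 24 hours after learning, then a novel-pairs test in which all
  6 unordered stimulus combinations appear 15 times (90 trials);
* **original**: three pairs (80–20%, 70–30%, 60–40%), learning in
  blocks of 60 (20 per pair) gated by per-pair accuracy thresholds
  (strictly above 65%, 60% and 50% within one block; at most 7 blocks),
  no memory blocks, and all 15 combinations shown 6 times at test.

From the novel-pairs test, **choose-A** (how often the most-rewarded
stimulus is picked when shown) and **avoid-B** (how often the
least-rewarded one is avoided) separate the expression of positive and
negative reinforcement; the learning pairs themselves are excluded from
both denominators.

Schedule generation makes the design constraints explicit: equal pair
allocation per block, no more than three consecutive trials of the same
pair (the generator is silent-pathology insurance, not a claim about
the original software), the high stimulus on the left for exactly half
of each pair's slots per block (floor for odd counts), and feedback
pre-realised per slot. Feedback realisation is i.i.d. Bernoulli by
default, with an exact-proportion mode (a permuted fixed outcome
multiset) available; both are defensible readings of a probabilistic
reward schedule and the choice is a `pst_task_spec()` argument.
Practice trials use two dedicated stimuli with an 80–20% contingency.
Memory blocks split their 40 trials equally across the learning pairs.
A novel-pairs repetition count is configurable because the two natural
values (15 per combination for the modified task, 6 for the original)
both appear in descriptions of the design; the defaults follow the
procedural description of each variant.

# The agent

Choices come from a softmax on action values,
$p(a \succ b) = \operatorname{logit}^{-1}\!\big(\beta\,(Q_a - Q_b)\big)$,
and values are updated on feedback trials by the delta rule
$Q \leftarrow Q + \alpha\,(r - Q)$ with $r \in \{0, 1\}$, using
$\alpha_{gain}$ when the prediction error is positive and
$\alpha_{loss}$ when negative. Values start at $q_0 = 0.5$ — the
chance-level prior on a 0/1 reward scale — and remain in $[0,1]$.
Memory and novel-pairs trials are performed with frozen values.

Two extensions carry the study's hypotheses:

* **state-conditional parameters** — each of $\alpha_{gain}$,
  $\alpha_{loss}$, $\beta$ and $\rho$ may be a named pair
  `c(ON = , OFF = )`. The day-1 medication state selects the learning
  rates and the retention fraction; the state of the day a test phase
  falls on selects the test-phase inverse temperature (`beta_test`),
  so learning, consolidation and expression effects are independently
  switchable;
* **overnight retention** — between the 30-minute and 24-hour memory
  blocks the values are shrunk toward baseline,
  $Q' = q_0 + \rho\,(Q - q_0)$ with $\rho \in [0,1]$. This is a
  deliberately minimal operationalisation of consolidation as partial
  preservation of learned value deviations; it makes no claim about
  mechanism, only about the direction and size of the overnight change
  in expressed preferences.

# Likelihood and model fitting

`session_nll()` replays a session: values evolve from the *observed*
choices and feedback on practice and learning trials, stay frozen in
the feedback-free phases, and every responded choice trial contributes
$-\log p(\text{observed choice})$. Memory-phase and novel-phase choices
are included in the likelihood by default (they carry information about
$\beta$ and the learned values) but the phase sets are arguments, since
which phases the original analysis fit is not documented. Practice
trials update values but contribute no likelihood by default: their
stimuli are disjoint from the learning pairs, and treating them as
warm-up keeps the likelihood focused on the quantities of interest.
Unanswered trials are skipped. An independent brute-force
reimplementation of the likelihood is kept in the test suite and the
two agree to $10^{-10}$ on small sessions.

The fitted family is `single` ($\alpha, \beta$; $k=2$), `dual`
($\alpha_{gain}, \alpha_{loss}, \beta$; $k=3$) and `dual_by_state`
(gain/loss rates per day-1 state with shared $\beta$; $k=5$), each
nested in the next. `fit_mle()` runs bounded L-BFGS-B from multiple
starts with $\alpha \in [0,1]$ and $\beta \in [0, 50]$ — above ~50
choices are effectively greedy and the likelihood is flat in $\beta$.
Learning-rate starts are uniform; **inverse-temperature starts are
log-uniform** over $[0.5, 50]$ with one fixed mid-range start
$(0.3, \ldots, 4)$. We first used uniform $\beta$ starts and found that
they concentrate mass in the flat near-greedy region, where gradient
steps stall; on some subjects every restart then converged worse than
the generating parameters. Log-uniform starts fixed this, verified by
checking fitted likelihoods against the likelihood at the true
parameters on simulated subjects. When comparing nested variants,
`nested_start()` expands a simpler fit into a warm start for the richer
one, which guarantees the nested-likelihood inequality up to optimiser
tolerance. AIC ($2k + 2\,\mathrm{nll}$) is the primary comparison
criterion with BIC reported alongside, both shown because the original
selection criterion is not documented. $\rho$ is not fitted: with a
single overnight interval per session it is only weakly identified, and
the package treats it as a generative quantity for simulation studies.
A fit whose $\beta$ lands below 0.2 carries an identifiability warning,
since near-indifferent choice leaves the learning rates essentially
unconstrained.

# Behavioural metrics

All metrics exclude unanswered trials from denominators, and undefined
quantities propagate as `NA`, never as zeros — mirroring how missing
blocks have to be handled in real data. Win-stay/lose-shift transitions
are defined **within pair** (consecutive presentations of the same
pair), because staying is only meaningful with respect to the same two
options; a `scope = "global"` mode over consecutive trials regardless
of pair is available for comparison with analyses that pool pairs.
Memory-difference scores are later minus earlier, so an overnight
improvement is positive. The chance-level filter flags a condition when
A-vs-B accuracy in the novel-pairs test is at or below 50%, per
condition, and only novel-pairs analyses honour the flag.

# Statistical battery

Paired and independent t-tests, the one-way ANOVA and the Pearson
correlation wrap the standard `stats` machinery and attach effect
sizes. Two Cohen's d variants are attached to every paired test —
$d_z$ (mean difference over the SD of differences) and $d_{av}$ (mean
difference over the average condition SD) — because published d values
for paired designs are frequently computed either way and the two can
differ substantially. The 2×2 repeated-measures ANOVA computes each
one-degree-of-freedom effect as a one-sample t-test on the per-subject
contrast and reports $F = t^2$ with $\eta_p^2 = F\,df_1/(F\,df_1+df_2)$;
this is algebraically identical to the classical sums-of-squares
decomposition with effect-specific error terms, and the test suite
checks that identity against an independent implementation.

The Wilcoxon signed-rank test is implemented in-package: zero
differences are dropped, tied absolute differences get average ranks,
and for up to 25 retained pairs the two-tailed p-value comes from the
exact null distribution of $W^+$ computed by convolution over the
doubled ranks (doubling keeps tied average ranks on an integer
support). Beyond that, a normal approximation with tie-corrected
variance and continuity correction takes over. The exact branch exists
because the standard implementation refuses exact p-values under ties,
while cohort percentage data tie constantly; it is verified against
full $2^n$ enumeration in the tests.

# The synthetic cohort

No individual patient data are available for this design, so the
cohort generator is a first-class module, not a fixture. Defaults
mirror the study structure: 18 patients completing four counterbalanced
two-day conditions (ON-ON, ON-OFF, OFF-ON, OFF-OFF) with a distinct
stimulus version per condition, plus 18 once-tested controls
(`exp1`); 18 patients (ON, OFF) and 20 controls with immediate testing
(`exp2`); and 18 + 18 on the threshold-gated original task (`exp3`).
Condition orders follow a cyclic Latin square so every condition
occupies every position equally often.

Agent parameters are drawn per subject from truncated normals:
$\alpha_{gain} \sim N(0.35, 0.12)$, $\alpha_{loss} \sim N(0.30, 0.12)$
on $[0.02, 0.95]$, $\beta \sim N(4, 1.5)$ on $[0.5, 15]$, and retention
$\rho \sim N(0.85, 0.05)$ on $[0,1]$ for both states in the no-effect
baseline. No population values are published for this design, so these
were chosen once so that default modified-task cohorts land in the
reported learning regime (mean final-block accuracy near 78%) and were
then frozen. Three injections mirror the three hypotheses the design
separates: a learning-rate delta applied when learning happens ON
medication, a test-phase $\beta$ delta applied when testing happens ON,
and state-dependent retention. The documented consolidation injection
is $\rho_{ON} = 0.95$, $\rho_{OFF} = 0.60$, under which the day-1-ON
minus day-1-OFF ordering of the 24 hr − 30 min memory change is
recovered in essentially every simulated cohort, while the no-effect
baseline leaves the full paired battery at its nominal 5% rejection
rate.

Seeding is hierarchical — cohort root, subject children, session
grandchildren — so any subject is reproducible in isolation. Each seed
value spawns its children exactly once; an earlier revision reused a
subject's seed for both the parameter draw and the session streams,
which made session randomness a deterministic function of the drawn
parameters and visibly inflated likelihood-ratio statistics between
nested fits. The fix and the calibration check live in the test suite.

# What the generator does and does not emulate

It reproduces the design arithmetic, the feedback statistics, the
within-subject condition structure, counterbalancing, and behaviour
generated by the model family the package fits. It does **not** model
stimulus discriminability, age- or disease-related cognitive
covariates, reaction times, fatigue, or within-session forgetting.
Practically: cohorts on the threshold-gated original task learn it
about as well as the modified one (final accuracy near 77%, ~2–3
blocks), whereas elderly participants found the original task much
harder (final accuracy near 62%, ~5 blocks, novel-pairs performance
near chance). Reproducing that gap would require weaker agents —
plausibly lower $\beta$ — or mechanisms outside the Q-learning family.
Passing tests therefore certify the pipeline's internal correctness and
calibration, not that the generator is a faithful model of elderly
participants on the original task.

# Numerical choices and problem sizes

Optimiser tolerance is L-BFGS-B `factr = 1e7` with at most 500
iterations; restarts default to 20 (validation studies in the tests
use 4–8, which suffice with the log-uniform starts and warm starting).
Degenerate inputs return sentinels rather than errors where a real
dataset could produce them (zero-variance differences, all-zero
Wilcoxon differences, empty metric scopes). Simulation studies in the
tests and the acceptance script use 50 subjects for parameter
recovery, 2000 replicate null samples for type-I calibration, 500
(tests) or 200 (script) cohorts for the consolidation ordering, and
50/30 full-pipeline null cohorts; these sizes give Monte-Carlo error
comfortably below the margins being asserted.

# Known limitations

* $\rho$ is generative-only; estimating it would need designs with
  repeated overnight intervals.
* The likelihood assumes no lapses or response biases; a lapse-rate
  parameter is a natural extension.
* The "multivariate" comparison of choose-A and avoid-B is implemented
  as per-measure univariate tests; a true MANOVA is out of scope.
* The finite-sample likelihood-ratio between dual and state-conditional
  variants is mildly heavier-tailed than its asymptotic reference on
  some subjects; model-comparison conclusions should aggregate over
  subjects, as the pipeline does.
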