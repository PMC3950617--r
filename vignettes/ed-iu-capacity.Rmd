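---
title: "Modelling ED access with downstream inpatient blocking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ED access with downstream inpatient blocking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edqueue)
```

## The problem

Emergency departments (EDs) ration access by acuity: the CTAS ladder
assigns each patient one of five levels, each with a target time to first
physician assessment (3, 15, 30, 60 and 120 minutes in this package's
defaults). Two resources govern whether those targets are met. The obvious
one is the number of ED beds. The less obvious one sits downstream: when a
treated patient needs admission and every inpatient-unit (IU) bed is full,
the patient *boards* - physically occupying an ED bed while contributing
nothing to ED throughput. `edqueue` models this coupling and answers two
questions: what waits does a given (c1, c2) bed configuration produce per
acuity level, and what is the smallest configuration that meets the
targets?

## The model

Two connected queues:

* **ED**: an M/G/c1 queue with five preemptive-resume priority classes.
  Arrivals per class are Poisson with rates `lambda_k`; the treatment time
  is triangular (by default shared across classes; a per-class override
  exists). A fraction `x` of completed patients needs admission.
* **IU**: a G/GI/c2/c2 loss system fed by the ED transfer stream
  `x * R_d` (with `R_d = min(lambda, c1 mu)` the ED throughput) plus a
  direct Poisson stream `lambda_d`. Its triangular length of stay (LOS) is
  measured in days and converted to hours on load; hours are the single
  internal unit everywhere.

Boarding is folded into an *effective* ED service time,

$$ 1/\mu = 1/\mu_1 + P_b \cdot E[\min_i T_i], $$

where `mu_1` is the uncoupled ED service rate, `P_b` the IU blocking
probability and `E[min Ti]` the expected time until the first of the `c2`
concurrent stays ends (the wait of a blocked transfer for the next free IU
bed). `P_b` in turn depends on `mu` through the transfer rate, so `mu`
solves a fixed-point equation.

### The blocking probability

`blocking_probability()` evaluates a diffusion approximation,

$$ P_b = \frac{\alpha\beta e^{-k\beta/v}}
             {(1-e^{-k\beta/v})\,\rho_d\sqrt{c_2}},\qquad
   \beta=\sqrt{c_2}(1-\rho_d),\; k=\sqrt{c_2},\; v=\tfrac{1+C_a^2}{2}, $$

with `rho_d` the IU offered load per bed and `C_a^2` the SCV of the LOS
(0.09375 for the default 1-4-7-day triangle). Three numerical notes:

* At `beta = 0` the expression is 0/0; the analytic limit
  `alpha v / (c2 rho_d)` is used whenever `|beta| < 1e-6`.
* The raw value can leave [0, 1] at extreme loads; the reported `p_b` is
  clamped (the steady-state theory assumes a probability) and the raw
  value kept for diagnostics. Overloaded inputs (`rho_d > 1`) are legal -
  the feasibility search must evaluate them - and flagged.
* Against the exact Erlang-B loss probability (provided as `erlang_b()`
  for cross-checking), this formula is *not* a close approximation away
  from criticality: its exponential decays like `e^{-c(1-\rho)}` where the
  true large-deviations rate is much slower, so at moderate load it can
  sit orders of magnitude below Erlang-B. Near `rho_d = 1` the two agree
  within a small factor for desk-size units. The practical consequence is
  that the ED-IU coupling in this model only bites when the IU runs close
  to or beyond its critical load; the test suite asserts the true
  relationship (a bound plus near-critical comparability) rather than a
  false proximity claim.

### Per-priority waits

The waiting-time chain composes four classical results: the
Pollaczek-Khinchine M/G/1 delay, the Erlang-C delay probability, an M/G/c
FCFS value (exact for M/M/1 and M/M/2), and the single-server
preemptive-resume priority formulas. The c-server per-class estimate
scales the single-server priority solution by the ratio of c-server to
single-server FCFS values, with all reference arrival rates divided by `c`
so the reference system is stable whenever the real one is.

One design decision deserves emphasis. The three ingredients are printed
in two different metrics - the single-server FCFS term is a pure queueing
delay while the other two are time-in-system-like - and composing them
verbatim diverges as traffic vanishes (the denominator goes to zero while
the numerators tend to the mean service time; on the baseline flow at 20%
utilisation it yields an absurd 1.6-hour "delay"). `w_mgc_priority()`
therefore composes like with like:

* `queueing_delay` - time until first treatment, the quantity CTAS targets
  regulate - uses the exact single-server *first-access* delay
  `R_k/((1-\sigma_{k-1})(1-\sigma_k))` as the per-class numerator;
* `system_time` adds the interruption-inclusive single-server delay
  `W_1^k - S_k` to the (boarding-adjusted) mean service time.

Both compositions collapse *exactly* to the single-server formulas at
`c = 1` and to the FCFS delay for a single class, which the mixed-metric
form cannot do. The verbatim mixed-metric value is retained as the
diagnostic column `system_time_printed`. Accuracy against the
discrete-event simulator on the baseline flow at moderate load (6 beds,
68% utilisation): the two lowest-priority classes - the only ones with
delays above a few minutes - agree within about 2-7%, the aggregate within
about 15%; mid-priority delays are overestimated (they are under a minute
there, and the proportional scaling cannot know that an arriving urgent
patient preempts rather than queues behind minor cases).

### Feasibility and the fixed point

Since `0 <= P_b <= 1`, the effective rate is bracketed:
`mu_min = 1/(1/mu_1 + E[min Ti]) <= mu <= mu_1`. The residual
`1/\mu - P_b(\mu) E[\min T_i] - 1/\mu_1` is continuous, non-negative at
`mu_min` and non-positive at `mu_max`, so a root exists. Two independent
solvers are provided and cross-validated:

* `find_mu_roots()`: residual evaluation on a uniform grid (default 512
  points - cheap, and robust to multiple roots, which the theory does not
  exclude) followed by bisection of every sign-change bracket down to a
  `1e-10`-hour residual, plus direct acceptance of near-zero grid points
  (the uncoupled limit produces a root at the bracket end without a sign
  change). When several roots exist the conservative smallest one is used
  for reporting, giving the tightest sufficient stability condition.
* `solve_scenario()`: the moment iteration - start at `P_b = 0`, inflate
  the class service moments by the boarding shift, aggregate
  `1/\mu = \sum q_k \bar S_k`, recompute `R_d` and `P_b`, repeat until the
  largest change in a modified class mean is below `1e-8` hours (cap 1000
  iterations, with a 0.5-damped restart if the plain iteration
  oscillates). A scenario whose ED cannot keep up even unblocked
  (`lambda >= c1 mu_1`) is reported `unstable` without iterating;
  a non-converging iteration is reported `no_solution`, never silently
  patched.

For any scenario whose ED is stable, `R_d = lambda` and the blocking
probability does not actually depend on `mu`; the iteration then converges
in two passes and both solvers agree trivially. The genuinely implicit
regime is a capacity-limited ED, where the blocking feedback can be
extremely steep; there bisection is the reliable tool, which is why both
algorithms exist.

The boarding-shift applied to the second moment treats
`P_b E[min Ti]` as a deterministic increment. A mixture treatment (board
with probability `P_b` for a random duration) would add variance; the
deterministic form is what the effective-service-time definition above
states, and is implemented as such.

### The boarding-delay integral

`E[min Ti]` is the mean minimum of `c2` iid draws from the LOS law,
computed by adaptive quadrature of the survival form
`lower + \int (1-F)^{c_2} dz` to an absolute tolerance of `1e-8` hours
(the minimum of bounded draws has bounded support, so no tail truncation
arises). The test suite checks it against a million-draw Monte-Carlo
oracle - the minimum of `c2` iid uniforms is Beta(1, c2), so the oracle
draws Beta variates and maps them through the triangular quantile, an
entirely independent route.

Whether the `T_i` should instead be *residual* stays (the beds were
occupied before the transfer arrived) is a modelling question the
effective-service-time definition leaves open; taking the LOS law directly
is the default, and `mean_min(..., residual = TRUE)` exposes the
stationary-excess alternative. For the memoryless check, both coincide on
exponential stays.

## The fast track

`solve_fast_track()` splits the ED into an express line (CTAS IV-V, on
`round(fraction * c1)` beds) and a regular line (CTAS I-III), both coupled
to the *same* IU: one shared blocking probability whose transfer rate sums
both lines' throughput contributions. Three ambiguities had to be
resolved:

* The printed constraint that the two lines' uncoupled service *rates* sum
  to the base rate would make each line slower than the base system for no
  physical reason. Default: both lines keep the base service
  distribution; `literal_sum_constraint = TRUE` enforces the printed
  version (rates split proportionally to bed share).
* The admission fraction `x` applies equally to both lines; nothing in the
  model differentiates admission probability by acuity.
* Bed split: round-half-away-from-zero, each line keeping at least one
  bed.

A caution on experiment design: CTAS IV-V carry about 41% of the baseline
arrivals. If all classes share one service-time distribution, a 20% bed
share saturates the fast line whenever aggregate utilisation exceeds about
0.49 - and more fundamentally, with identical service laws a
work-conserving system cannot reduce the arrival-weighted average wait by
splitting a bed pool. The clinical premise of a fast track is precisely
that minor cases are *quick*. The congested fast-track experiments in the
test suite therefore give CTAS IV-V a short treatment triangle
(0.05-0.15-0.4 h versus 0.2-0.8-1.6 h for I-III) and a bed share (15%)
close to the express line's share of total work. Under those conditions
the two directional effects hold robustly across utilisations 0.85-0.93:
the overall average wait falls, and the CTAS III wait - the last class of
the regular line - rises.

## The discrete-event simulator

`simulate_scenario()` is an independent implementation of the *physical*
system (Rcpp event loop, all randomness from R's RNG so a seed fixes the
run bitwise): per-class Poisson arrivals, preemptive-resume service
(victim: lowest priority, then latest service start; preempted work
resumes), admission lottery at completion, boarding with bed retention,
FCFS boarder admission at IU departures, loss of direct admissions when
the IU is full. Deliberate divergences from the analytic abstraction,
documented rather than hidden:

* Boarders are not preemptible - their treatment is finished and the bed
  is physically occupied - whereas the analytic model folds boarding into
  preemptible service time.
* At an IU departure with a waiting boarder, the boarder takes the bed
  (ED decongestion priority) ahead of any simultaneous direct arrival;
  other ties break by event timestamp, then insertion order.

Default verification depth: 200 replications of a 2000-hour horizon with
a 200-hour warm-up. These sizes keep the full cross-validation suite
within a couple of minutes while giving confidence intervals a few percent
wide; the replication count is a precision dial, not a model feature.
Little's law per class and the exact M/M/c and preemptive M/M/1 formulas
are asserted within simulation confidence intervals.

## The synthetic-scenario generator

`make_fixture(seed, regime)` draws random valid scenarios for property
testing: ED offered load per bed targeted by regime (light < 0.3,
moderate 0.3-0.7, congested 0.7-0.95, unstable > 1), IU offered load drawn
analogously with the transfer fraction capped so the drawn IU load is
attainable, an acuity mix concentrated on levels III-IV as in the baseline
flow, and LOS means between 2 and 7 days. What passing tests on these
fixtures do *not* show about real EDs: arrival rates here are stationary
(no time-of-day or seasonal structure), the service laws are exactly
triangular, admission probability is acuity-independent, and every IU bed
accepts every patient. The model is a steady-state capacity-sizing tool,
not a forecast of any particular day.

## Known limitations

* The diffusion blocking formula materially underestimates loss away from
  critical IU load (see above); conclusions that depend on *small* absolute
  blocking probabilities should lean on the simulator.
* The Bondi-style proportional scaling overestimates mid-priority delays
  at multi-server stations; errors are small in absolute terms at the
  loads where targets bind.
* Wait metrics: the planner compares `queueing_delay` (time to first
  treatment) against the CTAS ladder by default; `system_time` is
  available by switch, and the verbatim mixed-metric composition only as a
  diagnostic.

## A worked baseline

```{r baseline}
scn <- load_scenario(system.file("extdata", "table2_baseline.yaml",
                                 package = "edqueue"))
rep <- solve_scenario(scn)
rep
min_ed_capacity(scn)$capacity
```

With 125 IU beds the IU runs at 57% of critical load, blocking is
negligible, and five ED beds already meet every CTAS target; shrinking the
IU toward its critical size (72 beds at this flow) pushes the requirement
up - the capacity-curve tests sweep exactly that frontier.
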