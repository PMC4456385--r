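---
title: "Modeling medication-induced impulsivity in Parkinson's disease with a basal ganglia network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling medication-induced impulsivity in Parkinson's disease with a basal ganglia network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgicd)
```

## The scientific problem

A subset of Parkinson's disease (PD) patients on dopaminergic medication
develops impulse control disorder (ICD): reward-driven, fast, risk-blind
behavior. `bgicd` implements a network model of the basal ganglia (BG)
that ties this clinical phenotype to two interacting neuromodulatory
systems: phasic dopamine (reward prediction error, altered in PD and by
medication) and tonic serotonin (risk sensitivity, modeled as
multiplicative coefficients on three striatal neuron pools). The model is
exercised on a probabilistic reward/punishment categorization task and
compared across four cohorts: healthy controls (HC), unmedicated patients
(PD-OFF), and medicated patients with and without ICD (PD-ON-ICD,
PD-ON-nonICD).

## The task

160 trials; each trial shows one of four stimuli. For the reward stimuli
(I1, I2) the optimal response pays +25 points with probability 0.8 and 0
otherwise, while the non-optimal response pays +25 with probability only
0.2. For the punishment stimuli (I3, I4) the optimal response avoids a
-25 loss with probability 0.8, while the non-optimal response loses -25
with probability 0.8. Stimuli are presented in a balanced pseudorandom
order (a seeded shuffle of 40 copies of each; no additional blocking
constraints are imposed, since equal testing of each stimulus is the only
structural property the task definition fixes). The model consumes
rewards on the unit scale, r in {-1, 0, +1}, mapped from {-25, 0, +25}.

## The model

**Striatum.** Three pools of medium spiny neurons (MSNs) hold
cortico-striatal weight matrices over (stimulus, action): D1-receptor
MSNs code action value Q, D2 MSNs code a punishment-linked signal, and
D1R-D2R co-expressing MSNs code outcome risk h. Cortical input is one-hot
on the current stimulus, so each pool's response equals its weight entry.
Subjective utility combines value and risk,

U = Q − α_D1D2 · sign(Q) · h,

where sign(Q) makes a positive risk penalize gains (risk aversion) and
deflate losses (risk seeking), and α_D1D2 is the serotonin coefficient on
the risk pool. Learning is driven by the TD error δ = r − Q through
receptor-specific sigmoid gain functions λ(δ): increasing for D1,
decreasing for D2, and U-shaped (sum of two half-sigmoids) for the
co-expressing pool, each with its own (c1, c2, c3) constants and learning
rate (η_D1 = 0.01, η_D2 = η_D1D2 = 0.1).

**Dopamine conditions.** Controls use the raw δ. PD-OFF clamps δ from
above at δ_Lim = 0.001 (cell loss: positive prediction errors cannot be
expressed). PD-ON adds a medication constant δ_Med = 0.06 after clamping.
The clamp is one-sided; no lower bound is applied because only the upper
bound is ever specified numerically.

**Action selection.** A second dopamine signal, the trial-to-trial
utility difference δ_U, gates the pathway drives through
selection-context gains: the direct pathway carries
x_DP = α_D1 λ_D1(δ_U) Q per action, the indirect pathway
x_IP = α_D2 λ_D2(δ_U) y_D2 + α_D1D2 sign(Q) λ_D1D2(δ_U) h. The
subthalamic nucleus (STN) and external pallidum (GPe) form a coupled
excitatory-inhibitory loop (one neuron per action; uniform lateral
connectivity ±0.12; integration coefficients 0.1 and 0.033; STN output
tanh with slope 3) whose oscillations implement exploration. GPi combines
the two routes, and each thalamic unit integrates the sign-inverted GPi
signal until the first crosses the decision threshold 1.815; the winner
is the chosen action and the iteration count is the reaction time (RT).
Ties are broken by the larger thalamic activity, then the lower index.

## Design choices in the open parts of the model

Several details are not pinned down by the published description; the
package fixes them as follows and exposes each as a configuration switch
where reasonable alternatives exist.

- **Risk enters utility linearly** (`risk_transform = "linear"`), as the
  utility equation is printed; a precursor lumped model used a
  square-root transform, available as `"sqrt"`.
- **The U-shaped gain** is implemented as λ_h-D1 + λ_h-D2 (an increasing
  plus a decreasing half-sigmoid). The printed equation line repeats the
  same half-sigmoid twice, which contradicts the surrounding text's
  requirement of a U-shape; the text wins.
- **δ_U** defaults to "the best available option now minus the utility
  realized at the previous selection" (`du_mode = "max"`,
  `u_prev_mode = "realized"`); alternatives (`"chosen"` for a lagged
  realized difference, `"state"` for re-evaluating the previous action in
  the current state) are provided. It is a scalar shared by all candidate
  actions, mirroring a diffuse dopamine signal. On the first trial it
  is 0.
- **Initial weights are zero**, so first choices are unbiased and all
  utilities start at 0.
- **Per-trial circuit initialization** draws STN/GPe states uniformly
  from ±0.01 (the loop needs symmetry breaking); thalamic integrators
  start at 0.
- **sign(0) = 0**: zero-value states carry no risk adjustment.
- **The clamp applies to the learning δ only**; δ_U is not conditioned,
  since the clamping rule redefines the TD error itself.

### Thalamic integration and the reaction-time rule

Two choices deserve a fuller account because the published description is
not self-consistent on them.

First, integrating the thalamic equation dy/dt = −y + x as a strictly
leaky discrete integrator can never produce a decision: the STN output is
bounded by 1 and the direct-pathway drive is bounded by the learned
weights (at most ~0.4 after a 160-trial session under η_D1 = 0.01), so
the leaky integrator's asymptote x_DP − y_STN stays below the printed
threshold 1.815 for every cohort — zero crossings in every simulated
session we ran. Published RTs, however, vary by trial and by group. The
package therefore treats the thalamic units as race accumulators
(`circuit_params(leak = 0)`, the default), in the tradition of the
accumulator models the RT rule is drawn from; `leak = 1` reproduces the
strictly leaky form, whose closed-form crossing times for constant
supra-threshold drive are verified in the test suite.

Second, with strong indirect-pathway drive the race can fail to cross
within the iteration cap (`max_iters = 1000`). These are precisely the
slow, suppressed decisions of the strong-α_D2 groups, so discarding them
from RT averages biases those groups fast — missing-not-at-random — and
inverts the group RT ordering. The default policy
(`rt_policy = "censor"`) records such trials at the cap, analogous to an
experimental response deadline; `"exclude"` drops them from RT averages.
Under censoring the simulation reproduces the published RT pattern
(PD-ON-nonICD slowest, PD-ON-ICD comparable to controls, PD-OFF
fastest).

The iteration-to-millisecond conversion is a single presentation-level
scale factor (`ms_per_iter`, default 1): simulated RTs are compared
between groups, never to empirical milliseconds.

## What the simulation reproduces, and what it does not

With the four fitted parameter sets, 100 instances per group, and the
defaults above, the simulation reproduces:

- reward optimality: PD-ON-ICD above PD-OFF;
- the full RT ordering: PD-ON-nonICD slower than both PD-ON-ICD and
  PD-OFF, PD-OFF fastest, PD-ON-ICD near controls;
- the dopamine-only ablation (α_D1 = α_D2 = 1, α_D1D2 = 0 for every
  group): the group orderings collapse, confirming that dopamine
  parameters alone do not explain the behavioral pattern.

It does **not** reproduce the punishment-optimality advantage of PD-OFF
over PD-ON-ICD: both sit near chance, and the contrast is not
significant at any seed we examined. The mechanism is traceable. The
printed D2 learning gain (c = (1, 50, −1)) is ≈ +1 for every TD error
below ~0.9, so the D2 weight of whichever action is taken grows by 0.1
on every visit — a visit counter. The printed selection gain evaluates to
λ_D2 ≈ −0.245 near δ_U = 0, so the indirect pathway transmits this
visit count with a negative sign, exciting GPe, suppressing STN, and
thereby *promoting* the most-visited action. For PD-OFF (α_D2 = 0.991)
this positive feedback locks each stimulus onto one response within a few
trials, an order of magnitude faster than value learning (η_D1 = 0.01)
can counteract, making punishment optimality a capture lottery
(per-instance sd ≈ 0.22, bimodal). We implement the printed constants
as printed and report the discrepancy rather than re-tuning them.

## Statistics pipeline

The same pipeline serves empirical and simulated records: per-subject
optimality proportions and mean RT; iterative two-sided Grubbs screening
(maximum studentized deviation against the α = 0.05 critical value,
repeated until no point is significant; applied to per-subject mean RTs
within each group, the unit at which outlier removal is described);
one-way fixed-effects ANOVA with every summary-table column (SS, df, MS,
F, p, F critical) computed explicitly so printed tables can be
reproduced cell by cell; and pairwise pooled-variance two-tailed t-tests
(Welch available via a flag; no multiple-comparison correction, since
none is reported). The ANOVA's unit of analysis is the per-subject
summary, which at the study's group sizes (20 + 26 + 16 + 14) gives the
reported df = (3, 72).

## Parameter fitting

The two-step procedure: step 1 seeds a real-coded genetic algorithm
(tournament selection size 3, BLX-0.5 crossover with probability 0.9,
per-gene Gaussian mutation with probability 0.1, single elite) from a
grid search over the free parameters and minimizes the squared error of
simulated versus target reward/punishment optimality; step 2 re-ranks
the step-1 survivors by squared error against the target mean RT. Cost
evaluations use common random numbers so candidate rankings are not
dominated by simulation noise. Two numerical safeguards matter. The
survivor band is relative (within 10% of the best step-1 cost) with an
absolute floor (`survivor_abs = 0.02`, roughly the squared sampling
error of a small-sample optimality mean): with a purely relative band, a
near-zero best cost admits no other candidates and step 2 has nothing to
rank. And step-2 RT costs are evaluated at three times the step-1
instance budget (`rt_instances`), affordable because the survivor set is
small. Bounds: α in [0, 1.2], δ_Lim in [1e-4, 1], δ_Med in [0, 0.5],
covering all fitted group values. The per-group free/fixed schedule
follows the study: controls fit the three α's; PD-OFF adds δ_Lim;
PD-ON-ICD fits the α's and δ_Med with δ_Lim carried over from PD-OFF;
PD-ON-nonICD fits only the α's with both δ constants carried over.

Exact numerical reproduction of the published parameter table is not a
goal (a GA on a stochastic cost with unpublished options will not return
identical reals); recovery is assessed as ordering recovery, and only
well-separated contrasts are decidable: adjacent fitted values such as
α_D1D2 = 0.001 versus 0.033 have no distinguishable behavioral
signature at any feasible simulation budget. The test suite and
acceptance script therefore run a scaled-down recovery on the most
separated contrast — fitting (α_D2, α_D1D2) by the full two-step
procedure against optimality and RT targets simulated from the
PD-ON-ICD and PD-OFF parameter sets (α_D2 0.046 versus 0.991, with a
large RT gap identifying the D2 pathway's strength) at 24 instances per
target, 6 per step-1 cost evaluation, grid 3², population 8, 3
generations — and check that the recovered α_D2 preserves the ICD < OFF
ordering. Full four-group, paper-budget fits are supported through the
same interface (`budget = "paper"` in the CLI).

## The synthetic cohort generator

`synthesize_cohort()` provides subject-level data with the study's group
structure when the deposited behavioral records are unavailable. Per
subject it draws latent reward/punishment optimality proportions
(truncated normal on [0, 1]) and a latent mean RT (lognormal; inflated
2.5× for a small fraction of outlier subjects, default 5%), then emits a
full balanced session with Bernoulli responses and lognormal trial RTs
(30% CV). The default group profile encodes the qualitative pattern of
the study at its group sizes: ICD reward-seeking (0.82 ± 0.10) and
punishment-poor (0.58), PD-OFF the reverse (0.55 / 0.78) and fastest
(520 ms), nonICD slowest (720 ms), controls balanced (0.75 / 0.74,
640 ms). These levels are the package's own choice of a realistic
cohort; they are recovered by the statistics pipeline in the tests.
The generator produces static per-subject response probabilities — it
does not emulate within-session learning curves, trial-order effects, or
RT autocorrelation, so passing tests certify the analysis pipeline, not
any learning dynamics of real subjects.

## Problem sizes and numerical notes

The shipped tests and the acceptance script use 100 instances per group
for the cohort simulations (the study's own instance count), 12/6
instances for fitting targets and cost evaluations, and 1000 random
datasets for the ANOVA equivalence property. The circuit inner loop is
compiled (Rcpp); a pure-R twin defines the semantics and the two are
asserted to agree exactly. Gain sigmoids saturate to machine ±1 beyond
|δ| ≈ 1 at c₂ = ∓50, so monotonicity is asserted non-strictly in the
tails. Degenerate cases are defined explicitly: sd = 0 vectors pass
Grubbs unchanged; identical constant groups compare with t = 0, p = 1;
empty sessions return empty record sets and untouched weights.

## Known limitations

- The punishment-optimality contrast (ii) is not reproduced; see above.
- Reward-optimality levels sit near 50–60%, below typical empirical
  control performance; the printed learning rates bound how far values
  can move in 160 trials.
- The STN-GPe loop is a rate model; spiking dynamics, synchrony
  phenomena, and norepinephrine modulation are out of scope.
- RT units are arbitrary (iterations); only orderings are meaningful.
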