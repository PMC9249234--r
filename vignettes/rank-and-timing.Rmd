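---
title: "Feedback rank and spike-timing tolerance in recurrent spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback rank and spike-timing tolerance in recurrent spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spikerank)
```

## The model

`spikerank` simulates and trains discrete-time recurrent networks of leaky
integrate-and-fire (LIF) neurons.  Each neuron $i$ carries a membrane
potential $v_i^t$, a binary spike $s_i^t$, and a low-pass synaptic trace
$\hat s_i^t$:

$$
\hat s_i^t = e^{-\Delta t/\tau_s}\,\hat s_i^{t-1}
  + \left(1 - e^{-\Delta t/\tau_s}\right) s_i^t,
$$
$$
v_i^t = e^{-\Delta t/\tau_m}\, v_i^{t-1}
  + \left(1 - e^{-\Delta t/\tau_m}\right)
    \Big(\textstyle\sum_j w_{ij}\,\hat s_j^{t-1} + I_i^t + v_\mathrm{rest}\Big)
  + w_\mathrm{res}\, s_i^t,
\qquad
s_i^t = \Theta\!\left[v_i^{t-1} - v_\mathrm{th}\right].
$$

A spike is registered one step after its threshold crossing, and the signed
reset increment $w_\mathrm{res} = -20$ is applied at the registration step,
so a single crossing produces a single spike followed by a deep
hyperpolarization.  (Applying the reset one step later, which a literal
reading of the update equations with the lagged spike would give, makes
every crossing fire twice under sustained drive; we regard that as an
indexing artifact and synchronize the reset with the registration.)
Threshold and rest are $v_\mathrm{th} = 0$ and $v_\mathrm{rest} = -4$.

Constants and their defaults (`network_params()`):

| parameter  | meaning                               | default |
|------------|---------------------------------------|---------|
| `dt`       | integration step                      | 1 ms    |
| `tau_m`    | membrane time constant                | 8 ms    |
| `tau_s`    | synaptic trace time constant          | 2 ms    |
| `tau_star` | spike-timing tolerance (error filter) | 2 ms    |
| `tau_ro`   | readout filter                        | 10 ms   |
| `dv`       | pseudo-derivative width               | 1       |

`tau_m`, `tau_s` and `dv` deserve a comment, because the qualitative
behavior of the whole framework depends on them.  Near threshold the
membrane moves by $(1 - e^{-\Delta t/\tau_m})$ times its drive surplus per
step, so the margin with which a spike is emitted — and hence the
robustness of a learned spike pattern to perturbations — scales inversely
with $\tau_m$.  With a slow membrane (tens of ms) at $\Delta t = 1$ ms we
found learned patterns too fragile to replay; $\tau_m = 8$ ms with
$\tau_s = 2$ ms supports millisecond-precise, replayable spike codes.
Similarly, the surrogate gradient
$p(v) = \operatorname{sech}^2\!\big(v/2\delta v\big)/4\delta v$ must reach
from rest to threshold: $v_\mathrm{rest}$ sits $4$ units below threshold,
so widths $\delta v \ll 1$ leave subthreshold neurons without any learning
signal.  We use $\delta v = 1$.  All of these are configurable.

## The learning rules

Training minimizes the squared error between a generalized target
$Y^{\star t}_k$ ($k = 1,\dots,R$) and the linearly decoded network activity
$Y^t_k = \sum_i B^+_{ki} \bar s_i^t$, where $\bar s$ is the spike train
filtered at the tolerance $\tau_\star$ ([filter_spikes()]).  Differentiating
through the threshold with the pseudo-derivative $p$ and the spike-response
(eligibility) recursion
$e_j^{t} = e^{-\Delta t/\tau_m} e_j^{t-1} + (1 - e^{-\Delta t/\tau_m})\hat
s_j^{t-1}$ gives the error-propagating form (`delta_w_error_form()`):

$$
\Delta w_{ij} \;=\; \eta \sum_t \Big[\sum_k B^+_{ki}
\big(Y^{\star t+1}_k - Y^{t+1}_k\big)\Big]\, p_i^t\, e_j^t .
$$

Substituting a spike-level target $s^\star$ with
$Y^\star = B^+ \bar s^\star$ turns the same update into the
target-propagating form (`delta_w_target_form()`) with feedback matrix
$D = B^{+\top}B^+$:

$$
\Delta w_{ij} \;=\; \eta \sum_t \Big[\sum_k D_{ik}
\big(\bar s^{\star t+1}_k - \bar s^{t+1}_k\big)\Big]\, p_i^t\, e_j^t ,
$$

and when $D$ is the identity this collapses to the purely local rule
(`delta_w_ltts()`), which needs only the postsynaptic neuron's own error.
The three forms are algebraically identical under these substitutions; the
test suite asserts the equivalence to $10^{-12}$ on random instances.

The two knobs the package is organized around:

* **Feedback rank $R$** — the number of independent rows of $B^+$ (or the
  rank of $D$).  At $R = O$ (the behavioral output dimension) only the
  task error is broadcast: an error-based rule of the e-prop family.  At
  $R = N$ every neuron receives its own target: a target-based rule
  (full-FORCE at large $\tau_\star$, spike-pattern learning at small
  $\tau_\star$).  Solutions compatible with a converged network span
  $\ker D$, of dimension $N - R$.
* **Spike-timing tolerance $\tau_\star$** — the filter applied to spikes
  before errors are formed.  $\tau_\star = 0$ (a dedicated limit, not a
  division by zero) compares raw spike trains: a precise timing code.
  Large $\tau_\star$ compares smoothed rates.

## Internal targets and the readout limit

For store-and-recall the internal spike target $s^\star$ is the response of
the *untrained* network ($w = 0$) to the task input plus a random Gaussian
projection of the desired output (`generate_target_spikes()`).  Two
generator details matter:

* the projection scale defaults to $|v_\mathrm{rest}|$ divided by the rms
  column norm of the target, which puts the projected drive on the scale
  of the rest-to-threshold gap and yields dense (tens of Hz), informative
  target patterns;
* the projected drive is faded in linearly over the first $3\tau_m$ steps.
  At the very start of an episode the synaptic traces are empty, so *no*
  recurrent weights can reproduce a drive there; without the fade-in the
  first target spikes are unreachable by construction and the spike error
  has an irreducible floor.

The readout $B$ is pre-trained (Adam, 2000 steps, learning rate $10^{-2}$
by default) to decode the desired output from the filtered target,
`train_readout()`.  Its residual is the **readout limit**: no trained
network can beat it through that readout, which makes it the natural floor
when judging convergence.

## The clamped variant and the robustness margin

At full rank the package offers a teacher-forced (clamped) variant: the
eligibility and pseudo-derivative factors — and the network's own spikes in
the error — are evaluated along the trajectory in which $s^\star$ replaces
the emitted spikes.  Per neuron this is a temporal perceptron on a *fixed*
input sequence, and if its one-step predictions reach zero error the free
run reproduces $s^\star$ exactly, by induction from the shared initial
state.  Because a prediction that is correct with zero margin flips under
the smallest perturbation and cascades, `learning_config(margin = )`
optionally requires target spikes to clear $v_\mathrm{th} + \kappa$ and
silent steps to stay below $v_\mathrm{th} - \kappa$ before they count as
correct.  A margin of $0.3$ turns near-convergence into a locked, replayable
pattern; the same margin trick is available along the free-running
trajectory for the unclamped rules.  Clamping is rejected below full rank,
where a per-neuron target is not defined.

## Benchmark tasks

**Store and recall** (`make_store_recall()`, `run_store_recall()`): three
output channels, each a superposition of 1, 2, 3 and 5 Hz sinusoids with
amplitudes uniform in $[0.5, 2]$ and phases uniform in $[0, 2\pi]$; the
input is a five-channel binary clock tiling the episode, projected through
a Gaussian matrix with scale `sigma_inp = 10`.  Output error (MSE through
the frozen readout, filtered at $\tau_\star$), spike error
$\Delta S = \sum_{it} |s^{\star t}_i - s_i^t|$ and the convergence time
(epochs to halve the initial MSE, `convergence_time()`) are tracked per
epoch; `sweep_rank_tau()` tabulates them over the $(R, \tau_\star)$ plane.

**Button and food** (`expert_trajectory()`, `train_behavioral_cloning()`,
`run_closed_loop()`): an agent starts at the arena center; a button sits at
polar $(0.2, -90^\circ)$ and food at $(0.7, \theta_\mathrm{food})$,
$\theta_\mathrm{food} \in [30^\circ, 150^\circ]$.  The food is locked until
the agent passes within $0.05$ of the button; the button state is *not* an
input.  The four agent-relative offsets (button and food, horizontal and
vertical) are each encoded by 20 Gaussian tuning curves with centers evenly
spaced on $[-1, 1]$ and width equal to the spacing.  The built-in expert
walks straight to the button and then to the food at constant speed
($T = 80$ steps, time split proportional to segment length).  Behavioral
cloning builds internal targets from the encoded expert states plus a
projection of the expert actions, pre-trains the readout
($\tau_\mathrm{RO} = 10$ ms), and refines readout and recurrent weights
concurrently (Adam, $\eta = \eta_\mathrm{RO} = 0.01$ for the unclamped
rule).  The final reward is $\mathbb{1}_\mathrm{btn}\, e^{-d/0.2}$ with $d$
the final agent–food distance — an explicit surrogate for a gated,
distance-decreasing reward; all conclusions drawn from it in the tests are
comparative (orderings), never absolute values.

The closed-loop input projection uses a larger scale (five times the
rest-gap heuristic) than the open-loop default: the readout trace starts
empty, and until the network spikes the agent cannot move, so a fast
activity onset shortens the dead time at the start of an episode that
otherwise leaves the agent short of the button.

## Dimensionality of the solution space

If learning halts, $\sum_i D_{hi}(\bar s_i^\star - \bar s_i) \approx 0$ for
every $h$, so the reachable solutions differ from $s^\star$ only inside
$\ker D$, of dimension $N - R$.  The package probes this two ways:

* **Replica estimator** (`replica_dimensionality()`): several trainings of
  the same episode from different weight initializations (the replica
  degree of freedom; scale `sigma_w`); the per-neuron spike errors
  $\Delta S_i$ of the converged replicas form a point cloud whose effective
  dimensionality is the participation ratio
  $d = 1/\sum_k \lambda_k^2$ over normalized principal-component variances
  (`participation_ratio()`, `cloud_dimensionality()`).  At full rank all
  replicas converge to $s^\star$ itself and the cloud degenerates
  ($d = 0$); lowering the rank frees directions for the replicas to spread
  along.  Replicas that fail to halve the attainable part of the initial
  output error (the excess over the readout limit) are flagged and
  excluded.
* **Single-trial estimator** (`single_trial_rank_sweep()`,
  `single_trial_dimensionality()`): one training with white synaptic noise
  of amplitude $\epsilon = 0.1$ added to every weight update
  (`noisy_train_step()`).  After a burn-in (default: the first half of the
  epochs) learning is equilibrated and the noise explores the solution
  space; the $\Delta S_i$ vectors of the recorded epochs *relative to the
  final dynamics* replace the replica cloud.  This estimator needs no
  knowledge of $s^\star$, which is what would make it applicable to
  recorded data.

Numerical choices: clouds are centered but not scaled before the principal
component analysis; components with normalized variance below $10^{-12}$
are discarded; a cloud with total variance below $10^{-9}$ is reported as
zero-dimensional.  The participation ratio is scale-invariant, so the
full-rank cloud only collapses when replicas converge *exactly* — this is
why the analyses below run the full-rank condition to complete spike
cloning, and why the episode length for the dimensionality experiments
($T = 70$ at $N = 60$) keeps the per-neuron constraint count near $N$,
where the unclamped rule can finish the job within a few thousand epochs.

## Study sizes used by the automated analyses

The package's acceptance analyses (under `tests/testthat/` and
`scripts/acceptance.R`) run at desk scale, chosen so the full suite
completes on one CPU core in tens of minutes: store-and-recall at
$N = 100$, $T = 200$ for the cloning and convergence-speed comparisons
($\leq 500$ and $300$ epochs); the $\tau_\star$ grid $\{1, 3, 6, 12\}$ ms
at $N = 60$, $T = 150$; dimensionality at $N = 60$, $T = 70$ over ranks
$\{60, 55, 50\}$ with ten replicas per rank (the cloud's participation
ratio is capped by the number of points, so the replica count must exceed
the largest kernel dimension probed); button-and-food at $N = 150$ with
experts at $\theta^\star \in \{50^\circ, 90^\circ, 130^\circ\}$.  These sizes are
scaled down from typical research settings (hundreds of neurons, thousands
of epochs); the qualitative contrasts they probe — low rank converges
faster, high rank clones spikes and scores lower error, the rank/timing
gap closes as $\tau_\star$ grows, solution-space dimensionality grows as
rank drops, high rank wins the memory-dependent navigation task — are the
ones that survive scaling.

## What the synthetic generators do and do not emulate

The generators produce clock-driven trajectory recall and a geometric
navigation task with an ideal expert: stationary episode structure, noise
only where the analysis injects it, spikes exactly reproducible.  They do
not emulate trial-to-trial variability of biological recordings,
conduction delays, Dale-constrained connectivity, or sensor noise in the
closed loop.  Passing tests therefore demonstrate the mechanics and the
comparative phenomenology of the learning framework, not performance on
physiological data; the single-trial dimensionality probe is the one
component designed with eventual application to recorded spike trains in
mind, and it only requires rasters plus an end-of-training reference.

## Known limitations

* Exact spike-pattern cloning depends on the realizability of the target:
  episodes much longer than $N$ steps, or targets generated without the
  fade-in, leave irreducible errors that no training schedule removes.
* The unclamped full-rank rule converges slowly when the free-running
  trajectory is far from the target; the clamped variant exists precisely
  for that regime and is restricted to $R = N$.
* Closed-loop behavioral cloning inherits the usual imitation-learning
  caveat: the policy is trained on expert states only, and compounding
  drift is visible as reduced reward away from the training conditions.
* The environment and reward of the navigation task are package
  constructions (the geometry is fixed; the reward shape is a documented
  surrogate), so only orderings across conditions are meaningful.
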