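---
title: "Planning with networks of spiking neurons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning with networks of spiking neurons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeplan)
```

## The problem

Goal-directed (model-based) decision making requires computing, online, the
*optimal value* of each situation: the expected cumulative reward obtainable
when the next action and all later actions are chosen optimally under an
internal model of the environment. For a Markov decision process (MDP) with
states $s$, per-state actions $a$, transition kernel $P(s'\mid s,a)$,
expected immediate rewards $\bar r(s,a)$ and discount $\gamma \in [0,1]$,
these values satisfy the Bellman optimality equation

$$V^*(s) \;=\; \max_a \Big[\bar r(s,a) + \gamma \sum_{s'} P(s'\mid s,a)\,V^*(s')\Big],$$

a strongly nonlinear fixed-point problem. `spikeplan` implements a recurrent
network of stochastic spike-response neurons whose *steady-state population
activity* encodes exactly these optimal values, together with the
surrounding machinery: exact dynamic-programming oracles, task generators,
mean-field and spiking simulators, local synaptic plasticity that learns the
weights from experience, a spike-count decision readout with psychometric
and chronometric analyses, and a spreading-activation baseline planner.

## Neuron and network model

Each neuron is a stochastic spike-response unit: its membrane potential
$u_i$ decays with time constant $\tau_m$, presynaptic spikes are filtered by
a causal exponential synaptic kernel
$\epsilon(t) = \tau_s^{-1} e^{-t/\tau_s}$ (unit time-integral), each of the
neuron's own spikes triggers an instantaneous afterhyperpolarizing current
pulse of magnitude $\eta$, and spikes are emitted as an inhomogeneous
Poisson process with the rectified-linear instantaneous rate
$\lambda_i = k\,[u_i - \theta_i]_+$. The mean-field (rate) reduction is

$$\tau_m\,\dot u = -u + W\lambda - \eta\,\lambda + I^{\text{ext}}(t),
\qquad \lambda = k\,[u - \theta]_+ .$$

Units: potentials in mV, rates in Hz, weights in mV/Hz (the synaptic kernel
is normalized to a 1 mV time-integral, so a weight multiplied by a
presynaptic rate is a potential), time in ms. $\eta$ enters the rate
equation as mV/Hz with the same numeric magnitude as its mV value.

### Value coding and weight compilation

In the tabular ("grandmother-cell") code, neuron $i$ codes for one
state-action pair $(s_i, a_i)$ and the network represents approximate
values as per-state rate sums,

$$\tilde V(s) = \frac{1}{\lambda_r} \sum_{i\,:\,s_i = s} \lambda_i \; - V_0,$$

where $\lambda_r$ is the rate of an external Poisson "reward unit" and
$V_0$ a baseline that lets non-negative rates represent negative values.
With the gain constant $c = 1/k + \eta$, `build_discrete_network()` sets

* excitatory weights, *reverse-directed*:
  $w^{\text{exc}}_{ij} = c\,\gamma\,P(s_j \mid s_i, a_i)$ from every neuron
  $j$ of the successor state onto $i$ — a transition $s_i \to s_j$ is stored
  as a connection $j \to i$, so value information flows backwards from
  outcomes to the actions that produce them;
* uniform lateral inhibition $w^{\text{inh}}_{ij} = -c$ between distinct
  neurons coding the same state (the substrate of the max operator);
* reward-input weights $w^r_i = c\,\bar r(s_i, a_i)$;
* thresholds $\theta = -\lambda_r\,c\,V_0\,(1-\gamma)$.

A short calculation shows why this works. At a steady state
$u = W\lambda - \eta\lambda + I^{\text{ext}}$, substituting the weights
gives, for every neuron,

$$u_i - \theta = \tfrac{1}{k}\lambda_i + c\,\lambda_r\,
  \big[\tilde Q(s_i,a_i) - \tilde V(s_i)\big],
\qquad \tilde Q(s,a) = \bar r(s,a) + \gamma {\textstyle\sum_{s'}} P(s'\mid s,a)\tilde V(s').$$

Rectification ($\lambda_i \ge k(u_i - \theta)$, with equality when
$\lambda_i > 0$) then forces $\tilde V(s) \ge \tilde Q(s,a)$ for every
action, with equality for every *active* neuron — i.e. the winner-take-all
competition driven by lateral inhibition implements the max, and the unique
steady-state value function is $V^*$. Two useful corollaries that the test
suite asserts directly: per state, rates sum to
$\lambda_r (V^*(s) + V_0)$; and asymptotically only neurons of optimal
actions stay active, except where several actions tie, in which case only
the sum of their rates (not its split, which depends on the initial
condition) is determined.

Absorbing zero-reward terminal states carry no neurons: their value is 0 by
construction, and a terminal unit would self-excite with weight
$c\,\gamma$ — at $\gamma = 1$ an exact integrator that freezes whatever
rate it starts with and shifts every upstream value. (When a nonzero
baseline $V_0$ is used with terminal states, the baseline contribution a
terminal successor would have carried is folded into the reward weight.)

This derivation is the package's binding contract: a property test compiles
batches of random MDPs (up to 20 states, 4 actions,
$\gamma \in \{0.7, 0.9, 0.98\}$) and requires the decoded rate-model steady
state to match value iteration to $10^{-6}$.

One structural subtlety matters numerically: within a state, the
*difference* between two active neurons is an exactly neutral direction of
the active linear dynamics (excitatory columns depend on the presynaptic
neuron only through its state, and the inhibition contributes exactly $+c$
along the difference), so the winner-take-all competition acts purely
through the rectification boundary. Genuine ties therefore keep an
initial-condition-dependent rate split (with the sum pinned), and
*near*-ties resolve on a time scale inversely proportional to the
action-value gap. `steady_state_rates(polish = TRUE)` complements the
integrator with an active-set solve of the piecewise-linear equilibrium
(one winner per state, swap pivoting), which lands on the exact fixed
point even when a near-tie would take the dynamics astronomically long to
settle.

### Distributed codes and continuous tasks

For continuous state spaces, each neuron carries a non-negative basis
function $\psi_i(s,a) = g_i(s)\,\mathbf 1[a = a_i]$ (Gaussian receptive
field $g_i$ on a grid, width $\sigma$ = half the grid spacing, one copy per
action) and the decoded values become
$\tilde V(s) = \lambda_r^{-1}\sum_i \lambda_i\,g_i(s) - V_0$. With
$T_{ij} = \iint \psi_i(s,a)\,P(s'\mid s,a)\,g_j(s')$ and overlaps
$G_{ij} = \int g_i g_j$, `build_fa_network()` sets the effective weights

$$w_{ij} = c\,\big(\gamma\,T_{ij} - G_{ij} + \delta_{ij}\big),\qquad
  w^r_i = c\,\langle \psi_i, \bar r\rangle,\qquad
  \theta_i = -\lambda_r\,c\,V_0\,(1-\gamma)\,m_i,$$

with basis mass $m_i = \int g_i$. Active neurons at a fixed point then
satisfy the basis-projected Bellman condition
$\langle \psi_i, \tilde V\rangle = \langle \psi_i, \tilde Q\rangle$; with
indicator bases every integral collapses to a sum, $G = I$, and the
discrete compiler is recovered exactly (a test asserts equality to
$10^{-10}$).

Two numerical points matter here. First, the transition integrals have no
closed form (the dynamics are nonlinear), so they are evaluated
numerically; plain Monte-Carlo at the default budget ($10^4$ samples) leaves
percent-level noise on each of the $\sim$280 000 weights of the pendulum
network, enough to push the recurrent operator across the stability margin.
The pendulum pipeline therefore uses the deterministic midpoint-lattice
quadrature (`method = "lattice"`, $2^{16}$ nodes), which is exact to
rounding for these smooth integrands; seeded Monte-Carlo remains available
and its $1/\sqrt{n}$ error scaling is property-tested. Second, the
projected fixed point is a *self-consistent* solution in the span of the
bases, not the projection of $V^*$: where the true value surface has
features below the basis resolution (the pendulum's separatrix ridge, the
clipped velocity boundary), the represented values deviate from the
tabular oracle even though the greedy policy read out from the same
activity is near-optimal. The acceptance checks therefore score *realized
return* (normalized performance), which is also what the original analyses
displayed; the value-surface agreement is asserted as a residual of the
projected Bellman condition (relative $\sim 10^{-5}$ at convergence) rather
than as pointwise equality with the grid oracle.

### Baseline $V_0$ and episodic tasks

$V_0$ is realized through the thresholds, which scale with $(1-\gamma)$;
at $\gamma = 1$ no nonzero baseline is representable, so episodic tasks use
$V_0 = 0$ (all in-scope episodic tasks have non-negative values). For
discounted tasks the default is $V_0 = 0$ when $\min V^* > 0$, else
$-\min V^* + 0.1\,\mathrm{range}(V^*)$, preserving the strict inequality
$\tilde V > -V_0$ that the steady-state argument needs.

## Simulation

`simulate_rate()` integrates the mean-field equation by forward Euler
(default $h = 0.05$ ms; the Euler fixed point coincides with the ODE fixed
point for any stable step, which `steady_state_rates()` exploits with a
coarser step and a geometric-tail stopping rule). `simulate_spiking()`
implements the full stochastic model: per-neuron synaptic trace with exact
exponential decay, Bernoulli spiking with probability $\lambda_i h$ (at
most one spike per step; $h = 0.1$ ms default, 0.02 ms for the
high-rate pendulum network so that $\lambda h \ll 1$), afterhyperpolarizing
jump $-1000\,\eta/\tau_m$ mV at own spikes, and a single shared reward-unit
Poisson train per trial. Trials are vectorized: all runs advance in one
matrix recursion per time step.

Convergence speed deserves a note: with $\eta k \gg 1$ the effective
membrane relaxation is $\tau_m/(1 + \eta k)$ ($\approx 1$ ms at the
planning settings $k = 1$ Hz/mV, $\eta = 20$ mV, $\tau_m = 20$ ms), which
is why the two-step example settles within 10 ms. The slowest modes are
(i) the value-backup mode, relaxing at roughly $(1-\gamma)(1+\eta k)/\tau_m$,
and (ii) winner-take-all competition between near-tied actions, whose
time scale is inversely proportional to the action-value gap. The
steady-state helper therefore runs with a generous time cap (tens of
simulated seconds) when $10^{-6}$ decoding accuracy is required.

## Reading out decisions

Values and policies are decoded linearly from rates or from cumulative
spike counts over $[0, t]$ with *no burn-in* — time serves simultaneously
to relax the dynamics and to average out spiking noise. Behavioral choices
use a race between population spike counts: accumulation starts at the
onset of the reward input (sensory delay $t_\Delta$), and the first moment
any two populations' counts differ by $\theta_{\text{dec}}$ triggers a
deterministic choice of the leading population. For sequential tasks the
threshold is discounted with the number of remaining movements (NRM),
$\theta_{\text{dec}} = \theta_0\,\gamma^{\text{NRM}}$. Trials that never
cross within the 1.5 s horizon are flagged and excluded from time
statistics (censoring is rare at the reference settings). Decision-time
distributions are normalized to a standard normal by quantile matching;
the chronometric analysis regresses per-ratio mean normalized times on the
offer-value ratio, with a seed-level bootstrap for the slope's standard
error.

### Reference parameter sets

| context | $k$ | $\eta$ | $\tau_m$ | $\tau_s$ | input |
|---|---|---|---|---|---|
| planning / benchmarks | 1 Hz/mV | 20 mV | 20 ms | 2 ms | constant $\lambda_r = 400$ Hz |
| binary choice | 1 Hz/mV | 0 mV | 25 ms | 2 ms | double-exponential, $t_r = 110$, $t_d = 300$, $t_\Delta = 60$ ms; $\lambda_{\max}$ 2.6–70 Hz by figure |
| sequential tasks | 1 Hz/mV | 3 mV | 50 ms | 2 ms | raised Gaussian, base 10 Hz, peak 75 Hz at 250 ms, width 60 ms ($\times 10$ for behavioral readout); $\gamma = 0.7$ |

Decision thresholds: $\theta_{\text{dec}} = 7$ spikes (binary choice,
calibrated in the source experiments to a 180 ms mean crossing);
$\theta_0 = 70$ (movement chains) or 7 (the short-horizon devaluation
maze).

## Learning

When the environment model is unknown, the environment-dependent weights
are learned by a postsynaptically gated delta rule: experiencing
$(s, a, r, s')$ updates only synapses onto the neuron coding $(s,a)$,
moving each excitatory weight toward $c\,\gamma\,\mathbf 1[s_j = s']$ (so
its expectation converges to $c\,\gamma\,P(s_j\mid s,a)$) and the reward
synapse toward $c\,r$; the external input fires at $\rho = r + r_0$ with an
offset $r_0$ (default $|\min r| + 1$) that keeps rates non-negative and
cancels from the learning target. Inhibitory weights are structural and
never plastic. The basis-function generalization gates by $\psi_i(s,a)$
and scales by the basis mass,
$\Delta w_{ij} = \alpha\,\psi_i(s,a)\,(c\gamma\,m_i\,g_j(s') - w_{ij})$;
its expected update vanishes exactly at the batch target weights under
uniform sampling, and it reduces bit-for-bit to the discrete rule under
indicator bases (both property-tested). Exploration is simplified to
parallel sampling: each trial draws one successor for every state-action
pair, then the free-running dynamics are scored. During learning,
activities are clamped by experience rather than by the recurrent
dynamics, so updates are applied directly per sampled transition.
Reference learning rates: $\alpha = 0.01$ (blackjack), 0.05 (maze,
pendulum); the RMS weight error floor scales as $O(\sqrt\alpha)$.

## Task zoo

* **Two-step door task** — four decision states, two actions; turning right
  at the root opens one of two doors with probability $\tfrac12$ each.
  Rewards are fixed so that the best open-loop sequence earns $\tfrac34$
  (starting L), any sequence starting R earns $\tfrac12$ on average, and
  closed-loop control earns 1 — the unique simple assignment reproducing
  all three printed returns, with both actions of the post-L state tied at
  $\tfrac34$.
* **Blackjack** — infinite deck (face cards 10, ace 1/11), dealer hits to
  17, player may (mistakenly) draw on 21; rewards 0/½/1 for
  loss/draw/win; $\gamma = 1$; start distribution from dealing until the
  hand total reaches 12.
* **Flag maze** — 9×6 grid (configurable ASCII layout), four moves, walls
  block, moves slip perpendicular with probability 0.1 (0.05 per side);
  state = (cell, flag bitmask); goal entry pays the number of flags
  collected; $\gamma = 0.98$. The default layout is a reconstruction: the
  published one is figure-only, so every claim on this task is
  property-based (reachability, slip structure, all-flags optimality).
* **Pendulum swing-up** — $\ddot\varphi = (-\mu\dot\varphi +
  mgl\sin\varphi + a)/(ml^2)$ with $\mu = 0.05$, $m = 1$, $l = 1$,
  $g = 9.81$, torques $\{-5, 0, 5\}$ N·m, reward
  $e^{-(\varphi^2 + 0.2\dot\varphi^2)}$, start $(\pi, 0)$. Control
  interval 0.1 s (inner Euler step 1 ms, accurate to $\sim 10^{-3}$ rad
  against a fine-step integrator), velocity clipped to $\pm 2\pi$ rad/s —
  matching the 33-point, $\pi/8$-spaced velocity grid of the
  16×33×3 = 1584-neuron basis code. A finer ($\pi/16$) tabular
  discretization serves as the dynamic-programming oracle.
* **Binary economic choice** — one state, two actions with rewards equal to
  the offered values in units of option B. The offer grid for behavioral
  analyses is configuration, not physiology: the default takes ratios
  0.1–1.0 with the larger offer at 2.5 B-units. The chronometric slope is
  sensitive to the (unpublished) offer magnitudes — a session-style
  reconstruction with quantity ratios from 1:3 to 10:1 roughly doubles it —
  so slope comparisons should be read with that caveat; the
  recurrent-vs-feedforward ordering and the fit quality ($R^2$) are robust
  to the choice.
* **Movement chains (NRM tasks)** — linear chains indexed by the number of
  remaining movements; wrong actions abort; final reward 1;
  $V^*(\text{NRM}=n) = \gamma^n$ in closed form. The multireward variant
  adds an intermediate reward whose re-collection is blocked by routing
  subsequent wrong actions to the state just after it; values, peak rates,
  and reaction times then become non-monotonic in NRM.
* **Devaluation maze** — three decision states; cheese 4 (devalued: 2)
  behind L-L, alternatives 1 (left branch) and 3, 2 (right branch). The
  right-branch rewards satisfy max = 3, sum = 5 > 4: linear
  spreading-activation planners follow the summed gradient to the right
  and collect 3, while the network's nonlinear competition keeps the
  optimal 4 and flips to R-L only when the cheese is actually devalued —
  without re-experiencing the maze, since only the reward-input synapse
  changes.

## Spreading-activation baseline

The comparison model assigns each corridor position the linear
superposition $\sum_g r_g e^{-d(p,g)/\gamma_{\text{spread}}}$ of
goal-generated activities ($d$ = corridor/ℓ₁ distance;
$\gamma_{\text{spread}} = 1.2$ corridor units, 1.2× the second segment of
the root-to-right path). The agent follows the activity gradient along
corridor centers. One discretization subtlety: with several distant goals
the superposition can dip slightly exactly at a junction; since an agent at
a junction chooses between corridors, the walk compares whole incident
corridors there (strict steepest ascent elsewhere). At the default
attenuation both semantics give the identical path; the chosen goal is
unchanged across half-to-double attenuation and under a retrodromic
restriction.

## Synthetic data and what the tests do (and do not) show

Every experiment runs on generated tasks; there are no external datasets.
The generators emulate the *structure* of the modeled experiments (offer
values, trial counts, input time courses, thresholds) but not
physiological variability across neurons or sessions, adaptation,
or correlated noise beyond the shared reward input — so green tests
demonstrate the model's computational claims (fixed-point correctness,
planning speed, plasticity targets, qualitative neural/behavioral
signatures), not quantitative agreement with any animal's data. Where a
published quantity depends on unprinted task details (offer magnitudes,
maze geometry, figure-level reward labels), the reconstruction satisfies
every printed constraint and the dependence is documented here and checked
by property-based tests.

## Problem sizes and defaults used by the shipped analyses

Acceptance-level analyses use: 50 random MDPs for the fixed-point
property; 5 spiking seeds (3 for the pendulum) over a 25–300 ms planning
grid for the benchmarks; 100 trials per offer pair over the 10-ratio
default grid for the chronometrics (1.2 s horizon); 100 trials per NRM
level for the movement chains; quadrature with $2^{16}$ lattice nodes for
the pendulum weights. The test suite scales some of these down (noted in
each test) while keeping every assertion at its stated tolerance.

## Known limitations

* The function-approximation value surface is self-consistent rather than
  the projection of $V^*$; its pointwise match to the tabular oracle is
  loose in rarely-visited, high-velocity regions (the policy is what is
  accurate).
* Episodic ($\gamma = 1$) tasks with negative optimal values cannot be
  represented (no baseline is realizable at zero threshold); none of the
  in-scope tasks needs this.
* The spiking simulator is a fixed-step Bernoulli thinning of the Poisson
  process; at the pendulum's population rates this requires the finer
  0.02 ms step, and counts (not instantaneous rates) should be trusted.
* In tasks rich in near-tied actions (the slip maze at $\gamma = 0.98$), a
  minority of spiking runs can drift, after a few hundred milliseconds,
  into a metastable wrong winner-take-all configuration in a few near-tie
  states — the rate-model fixed point is unique and correct, but spiking
  noise makes the wrong local winner long-lived, and a brittle route can
  lose most of its return from a couple of such states. Median performance
  across seeds, and the first-crossing planning times, are insensitive to
  this; single-run curves at long planning times are not.
* Interneurons are not modeled explicitly (effective inhibition violates
  Dale's principle by construction), and the continuous-time plasticity
  variant with a temporal eligibility kernel is out of scope.
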