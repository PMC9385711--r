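---
title: "Fitting key parameters of a thalamocortical relay neuron by chaotic-inertia PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting key parameters of a thalamocortical relay neuron by chaotic-inertia PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(tcrelay)
```

## The model and the problem

`tcrelay` fits the three parameters of a single-compartment, conductance-based
thalamocortical (TC) relay neuron that govern whether it relays a pulse-train
input faithfully (the "normal" regime) or fails to (the "Parkinsonian"
regime): the constant pallidal inhibitory current $I_{Gi}$, the maximal
T-type calcium conductance $g_T$ and the calcium reversal potential $E_T$.
The membrane equation is

$$C_m \dot V = -I_L - I_{Na} - I_K - I_T - I_{Gi} - I_{SM},$$

with $I_L = g_L(V - E_L)$, $I_{Na} = g_{Na} m_\infty^3(V)\, h\,(V - E_{Na})$,
$I_K = 0.75\, g_K (1-h)^4 (V - E_K)$ and
$I_T = g_T\, p_\infty^2(V)\, r\,(V - E_T)$. The two gates relax as
$\dot h = (h_\infty - h)/\tau_h$ and $\dot r = 2.5\,(r_\infty - r)/\tau_r$;
all four steady-state curves are sigmoids (midpoints $-37$, $-60$, $-41$ and
$-84$ mV), $\tau_h$ follows the two-rate form and
$\tau_r = 28 + e^{-(V+25)/10.5}$ ms.

The non-fitted background values (`c_m = 1`, `g_l = 0.05`, `e_l = -70`,
`g_na = 3`, `e_na = 50`, `g_k = 5`, `e_k = -75`) are literature-typical
constants for this reduced model; each is an argument of `tc_params()` and
can be overridden.

### Sign conventions

The membrane equation above subtracts both applied currents, but the
conventional parameter values are signed the other way: the sensorimotor
pulse amplitude is positive (5 pA/µm²) although the input is excitatory,
and the Parkinsonian reference drive is $I_{Gi} = -3.5$. Two flags in
`tc_params()` decide how each current enters:

* `flip_sign_sm = TRUE` (default) makes the square-wave pulses
  depolarizing, as an excitatory sensorimotor input must be;
* `flip_sign_gi = FALSE` (default) keeps the literal minus sign on
  $I_{Gi}$, under which the negative reference value raises the operating
  point of the cell and the reference triple produces dense spiking that
  drowns the input pulses — a relay failure through extra spikes.

The alternative (`flip_sign_gi = TRUE`, a hyperpolarizing drive of
3.5 pA/µm² against a leak conductance of 0.05) pins the membrane near
$-120$ mV, where the reference triple produces no spikes at all: the
"standard data" would then carry almost no information and the fitting
problem would be degenerate. We therefore ship the literal convention as
the default; both remain available, and the choice is recorded in every
exported metadata sidecar via the parameter object.

## Stimuli

Two pulse-train generators drive the model (`stimulus_square()`,
`stimulus_poisson()`), both rectangular pulses of amplitude
$A_{SM} = 5$ pA/µm² and width $\delta_{SM} = 5$ ms:

* the **square wave** is the Heaviside-gated sine form
  $I(t) = A\,H(\sin \tfrac{2\pi t}{\rho})\bigl(1 - H(\sin\tfrac{2\pi(t+\delta)}{\rho})\bigr)$
  with period $\rho_{SM} = 25$ ms — one ON window per period, analytic
  onsets;
* the **Poisson train** draws inter-onset gaps i.i.d. exponential
  (mean 25 ms, matching the square-wave period so the two regimes are
  comparable), redrawing any gap shorter than the pulse width so pulses
  never overlap. The realized mean gap is therefore
  $25 + 5 = 30$ ms by memorylessness. Each train is a pure function of its
  seed.

Pulse onsets are carried alongside the sampled trace rather than
re-detected from samples, so relay scoring never depends on an input-side
threshold.

These trains emulate the timing structure of sensorimotor drive, not its
biophysics: real inputs arrive through synaptic conductances with rise and
decay kinetics, amplitude jitter and background noise, none of which are
modelled. Passing tests therefore validate the machinery on clean,
noise-free traces; they do not establish robustness to recording noise or
synaptic variability.

## Relay scoring and spike features

`detect_spikes()` marks one spike per contiguous excursion at or above the
threshold (default $-25$ mV, configurable), at the excursion's voltage
maximum. `classify_relay()` opens a response window at each pulse onset
(nominal 25 ms, truncated at the next onset so windows never overlap):
no spike in the window is a *miss*, two or more are a *bad* relay, and each
input contributes at most one error. The reliability index is

$$RI = 1 - \frac{\text{missed} + \text{bad}}{\text{total inputs}},$$

with $RI > 0.9$ read as normal relay and $RI < 0.5$ as Parkinsonian.
Spikes falling between windows are ignored by default; `strict = TRUE`
charges them to the preceding input.

Four features summarize a trace for fitting: $RI$, the spike count $N$,
the mean spike peak $PK$ and the mean subthreshold voltage $ST$ (samples
strictly below the threshold, after a discarded initial transient). A
spikeless candidate takes $PK$ equal to the detection threshold so the
fitness stays defined during optimizer exploration. The fitness between a
candidate ("rec") and the reference ("ori") is

$$q_T = w_1 \textstyle\sum (RI_{rec}-RI_{ori})^2 + w_2 \sum (N_{rec}-N_{ori})^2
      + w_3 \sum (PK_{rec}-PK_{ori})^2 + w_4 \sum (ST_{rec}-ST_{ori})^2,$$

summed over evaluation trials. The default weights scale each term by the
reference feature's magnitude, $w_i = 1/\max(|f_i|, 1)^2$ — $RI$ lives in
$[0,1]$ while $N \sim 50$ and the voltages are tens of mV, and raw unit
weights would let a single term dominate. `fitness_weights()` accepts any
nonnegative weights for the raw-unit alternative.

### Why three trials

With a single square-wave trial the four aggregate features do **not**
identify the triple: increasing $g_T$ while lowering $E_T$ leaves the
T-current drive $g_T (V - E_T)$ nearly unchanged over the visited voltage
range, so a whole ridge of wrong triples matches $(RI, N, PK, ST)$ almost
exactly. The default protocol (`tc_default_trials()`) therefore sums the
fitness over three trials — the square wave plus two fixed-seed Poisson
realizations — which requires a candidate to reproduce the features of
three different input patterns simultaneously and sharpens the valley
around the true triple by roughly three orders of magnitude. The Poisson
seeds (101, 202) are constants of the protocol, so the reference data are
identical in every fit. The trial list is an argument of
`build_reference()`; single-trial fitting remains available.

## The optimizer

`run_pso()` is a classical global-best particle swarm with velocity rule
$v \leftarrow \omega v + c_1 r_1 (p - x) + c_2 r_2 (g - x)$, $c_1 = c_2 = 2$,
scalar $r_1, r_2 \sim U(0,1)$ fresh per particle and update, speeds clamped
componentwise to `v_max` (default one fifth of the box width) and positions
clamped to the box with the velocity zeroed on a clamped dimension. Five
inertia rules are implemented:

| scheme | $\omega(k)$ |
|---|---|
| `constant` | $0.7$ |
| `linear` | $\omega_{max} - (\omega_{max}-\omega_{min})\,k/k_{max}$ |
| `concave1` | $\omega_{min} (\omega_{max}/\omega_{min})^{1/(1 + 10 k/k_{max})}$ |
| `concave2` | $(\omega_{max}-\omega_{min})(k/k_{max})^2 + 2(\omega_{min}-\omega_{max})(k/k_{max}) + \omega_{max}$ |
| `improved` | per particle: `concave1` if $q_i \le \bar q$, else $\alpha + (1-\alpha) L$ |

with $\omega_{max}/\omega_{min} = 0.9/0.4$ and, for the improved rule,
$\alpha = \alpha_{max} - (\alpha_{max}-\alpha_{min}) k/k_{max}$ on
$[\alpha_{min}, \alpha_{max}] = [0.2, 0.8]$ and $L$ the state of a Logistic
map $L \leftarrow 4 L (1-L)$. The idea: particles already beating the swarm
mean get a decaying deterministic schedule (steep early for global search,
flat late for refinement), while lagging particles get a chaotic,
non-repeating weight in $[\alpha, 1]$ that kicks them out of local basins.

Choices the method statement leaves open, fixed here:

* the chaotic map is swarm-global and advances once per chaotic draw; its
  initial value is drawn per run seed from $(0,1)$ excluding the map's
  fixed and period-2 points $\{0, .25, .5, .75, 1\}$;
* a particle whose fitness ties the swarm mean takes the concave
  (exploitation) branch;
* the swarm mean uses the current iteration's fitnesses, not personal
  bests; non-finite objective values are replaced by $+\infty$ and counted;
* iteration stops at `k_max` or when the global best drops below `q_stop`.
  The default `q_stop = 1e-8`: on the scale-normalized fitness a random
  initial swarm already contains particles around $10^{-5}$, so a loose
  threshold would end runs at the first iteration; $10^{-8}$ is reached
  only by near-exact feature matches.

## The experiment pipeline

`build_reference()` simulates the model at the given truth
($[-3.5, 3, 120]$, the Parkinsonian operating point) under the trial
protocol and freezes its features as the standard data.
`fit_key_parameters()` searches $I_{Gi} \in [-10, 0]$, $g_T \in [0, 10]$,
$E_T \in [90, 140]$ — a box bracketing both relay regimes — and reports the
squared parameter error $e_T = \sum_i (\hat\theta_i - \theta_i)^2$ on the
natural-log scale. `run_comparison()` repeats the fit for all five inertia
schemes over replicate seeds; because a swarm outcome is a single draw, the
package reports per-scheme medians rather than single runs.
`reconstruct_and_compare()` re-simulates original and fitted models under
both input kinds and at a second, normally relaying operating point
(`tc_normal_key()`, $[-1, 0.6, 120]$: weaker pallidal drive and T
conductance, chosen so the square wave is relayed with $RI > 0.9$).

```{r quick-demo}
cfg <- sim_config(dt = 0.05, t_total = 500, t_discard = 100)
ref <- build_reference(tc_params(), config = cfg)
ref$features
```

```{r trace-plot}
autoplot(ref$sim)
```

```{r one-fit}
fit <- fit_key_parameters(ref, scheme = "improved", seed = 1,
                          n = 20, k_max = 50)
glance(fit)
tidy(fit)
```

## Numerical choices

* **Integrator**: fixed-step classical Runge–Kutta (compiled), the standard
  choice for non-stiff Hodgkin–Huxley-type systems when bit-reproducible
  fitness evaluations are required. The stimulus is sampled on the half
  grid so all four stages see exact pulse values. Step-halving tests
  confirm 4th-order convergence; a closed-form check integrates the gate
  subsystem at frozen voltage against its exponential solution.
* **Steps and horizons**: `dt = 0.01` ms and `t_total = 1000` ms for
  regime characterization; the fitting experiments in the test suite run
  at `dt = 0.05` ms and `t_total = 500` ms with swarms of 20 particles and
  50 iterations over 5 seeds, and the heavier property suites use a
  200-ms horizon — sizes chosen so the whole experiment reruns in minutes.
  The first 100 ms are always discarded from feature extraction.
* **Degenerate inputs**: candidate triples with $g_T < 0$ are clipped to
  0; a voltage excursion beyond $\pm 200$ mV aborts the simulation with an
  error naming the step, and such candidates are rejected by the
  objective; gates are monitored for numeric excursions beyond
  $[-10^{-6}, 1 + 10^{-6}]$ and flagged.
* **Ties and boundaries**: spike detection uses $\ge$ at the threshold;
  relay windows are half-open $[{\rm onset}, {\rm onset}+w)$; the square
  wave's analytic ON window is open on the left, closed on the right, as
  the Heaviside composition dictates.

## Known limitations

* The identifiability of $E_T$ from aggregate spike features is weak even
  under the three-trial protocol: the $(g_T, E_T)$ compensation ridge is
  shallow near the truth, so small fitness values do not guarantee small
  parameter error, and recovery of $E_T$ to a fraction of a millivolt is
  not generally achieved at the problem sizes above. The acceptance suite
  measures exactly this and reports the per-scheme medians; the ordering
  among inertia schemes on this landscape is correspondingly unstable.
* $I_{Gi}$ is a constant current, not a synaptic conductance: the
  pallidal drive has no kinetics and cannot saturate, which is what makes
  large drives run the membrane far from physiological voltages.
* The background parameters are literature-typical, not measured; the
  relay regimes reported here are properties of this parameterization.
* Windows, thresholds and weights are conventions. They are exposed as
  arguments and recorded with every result, but no sensitivity analysis
  over them is built in.
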