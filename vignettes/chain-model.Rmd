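---
title: "The chain molecular-communication model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chain molecular-communication model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcchain)
```

## The system

`mcchain` simulates a communication link in which a transmitter cell encodes
a binary message into hormone release, astrocytes relay the message as
Ca²⁺ oscillations, and a neuron converts the relayed signal into action
potentials that cross an axon and a chemical synapse before a receiver
decodes the message from the postsynaptic waveform. Every stage is a
standard piece of quantitative biology — free diffusion, the Li–Rinzel-type
IP₃ receptor model, inhomogeneous Poisson firing, passive cable theory,
vesicle-pool release, an M^x/G/1/K queue, alpha-function postsynaptic
potentials — and the package's contribution is wiring them into one
reproducible chain with an analytic capacity/delay layer on top.

All internal quantities use one unit system: seconds, micrometres,
micromolar, millivolts. Diffusion coefficients quoted in μm²/ms are
converted once at parameter construction (4.8 μm²/ms = 4800 μm²/s), which
avoids the silent unit errors that mixed ms/s formulations invite.

## Stage models

### On–off keying and the hormone channel

A bit string $b_1 b_2 \dots b_{N_b}$ is transmitted in slots of length $T$:
slot $i$ releases $Q_0$ hormone molecules as an impulse at $t = iT$ when
$b_i = 1$ and nothing otherwise (`encode_ook()`). Impulses are kept as
exact (time, quantity) events rather than grid spikes, so the diffusion
channel can superpose Green's functions without discretization error.

Passive diffusion from a point source in 3-D gives the per-molecule density

$$g(d, t) = (4\pi D_H t)^{-3/2} \exp\!\left(-\frac{d^2}{4 D_H t}\right),$$

and molecular degradation multiplies this by the survival factor
$e^{-\iota t}$, the complement of an exponential life expectancy with mean
$1/\iota$. The concentration at an astrocyte a distance $d$ from the
transmitter is the superposition over all past release events
(`concentration_at()`); because the channel is linear, inter-symbol
interference (the "memory effect" of earlier slots) appears automatically.

The probability that a molecule released at slot 0 is absorbed during slot
$n$ is the slot integral of $g\,e^{-\iota t}$ times a capture volume
$\kappa$ (μm³). The raw integral is a density, not a probability — the
source model never supplies a receptor cross-section — so $\kappa$ is a
package calibration: by default it is chosen so that a release of
$Q_0 = 5000$ molecules is detected (at least one molecule absorbed) in its
own slot with probability 0.5 at the reference geometry $d = 5$ μm,
$T = 10$ s. Putting the calibration at the *detection* level rather than
the per-molecule level is what makes the capacity layer respond to $Q_0$:
detection probabilities $1 - (1 - \kappa u_n^{raw})^{Q_0}$ rise with the
number of released molecules and saturate at 1.

The mean hormonal propagation delay $\Omega_H$ weights candidate delays
$\omega \in (0, T]$ by
$\mathrm{erf}\!\big(\sqrt{d^2/(4 D_H \omega)}\big)/\sqrt{8\pi D_H \omega}$.
As printed this weight is not a normalized density, so the package
normalizes it on $(0, T]$ and reports the weighted mean — the reading that
makes the published monotone behavior (delay growing with both $d$ and $T$)
come out.

### Astrocyte Ca²⁺ dynamics

Each astrocyte runs a three-variable IP₃-receptor model: cytoplasmic Ca²⁺
$C_{CY}$, ER Ca²⁺ $C_{ER}$, and the channel inactivation gate $h$, with
channel flux
$v_{chan}\, m_\infty^3\, n_\infty^3\, h^3\, (C_{ER} - C_{CY})$,
linear leak, a Hill-2 pump, and gate dynamics
$\dot h = (a_3 - h)/a_2$. The constants $b_1 \dots b_6$ are the classical
Li–Rinzel constants, which is how the package decides the ER sign question:
the equations as printed make $C_{ER}$ rise *with* $C_{CY}$ (their
$a_1$-weighted difference is conserved), which contradicts the
store-release picture and cannot oscillate in the usual way. The package
implements both conventions:

* `convention = "as_printed"` — literal equations; the invariant
  $C_{CY} - a_1 C_{ER} = const$ is asserted in the test suite;
* `convention = "li_rinzel"` (default) — $\dot C_{ER} = -\dot C_{CY}/a_1$,
  conserving total calcium $C_{CY} + a_1 C_{ER}$ (2 μM by default), the
  standard closed-cell Li–Rinzel reduction.

Under the default convention and the published constants, constant IP₃
between roughly 0.35 and 0.75 μM produces sustained oscillations with a
period near 11 s (`scan_oscillation_regime()` recomputes this bracket by
brute force); below the window Ca²⁺ settles low, above it Ca²⁺ stabilizes
at a high plateau — exactly the qualitative behavior the source describes
when hormone concentration is too high.

The hormone→IP₃ transduction (G-protein coupled receptor signalling) is not
specified quantitatively anywhere in the source, so the package uses the
minimal monotone saturating form, a Hill curve from `ip3_base` (0.1 μM,
below the oscillatory window) to `ip3_max` (0.9 μM, above it). Its
half-point $K_{1/2}$ is calibrated at configuration time to the mid-slot
concentration of a single "1" pulse at the median astrocyte distance, so a
typical pulse lands the oscillator mid-window regardless of the sampled
astrocyte geometry.

Ca²⁺ reaches the neuron boundary by diffusion from the ER treated as a
point source: the boundary flux is the cytoplasmic trace convolved with the
3-D Green's kernel at distance $d_{ER,B} = 10$ μm with $D_{Ca} = 20$
μm²/s. The flux gain defaults to `uptake_efficiency` (0.8) divided by the
kernel's time integral, i.e. the neuron eventually absorbs 80% of one
astrocyte's signal.

The Ca²⁺ relay delay $\Omega_{Ca}$ is the extra time the absorbed
neuron-side signal needs to accumulate one relayed signal's worth of
variation beyond the slot. The printed balance equation sums the
astrocyte-side variation over all $M_A$ astrocytes; with the absorbed flux
also summed over astrocytes both sides then scale linearly in $M_A$ and the
delay would be exactly independent of the astrocyte count — contradicting
the published finding that more astrocytes shorten the delay. The package
therefore targets the *mean per-astrocyte* variation by default (delivery
scales with $M_A$, the target does not, and the published trend emerges);
`target = "summed"` restores the literal reading.

### Firing and the axon

The neuron is an amplify-and-forward relay: the membrane potential is the
resting level plus the sum of astrocyte fluxes convolved with an
exponential response kernel (`membrane_potential()`), with no decoding at
the relay. The source simultaneously thresholds the potential at
$\theta_1$ and calls the spike train Poisson; the package bridges the two
with a logistic rate map
$\lambda(t) = \lambda_{max}/(1 + e^{-k(V - \theta_1)})$ — the hard
threshold is recovered as the slope $k \to \infty$ — and samples spikes by
thinning. Both statements survive in their limits, and the thinning output
is validated against the time-rescaling theorem in the test suite.

Axonal transmission uses the passive cable equation solved by separation of
variables. Two repairs were unavoidable:

* the printed leak prefactor $\exp(t - \gamma_m\gamma_c)$ grows without
  bound; it is read as $\exp(-t/(\gamma_m\gamma_c))$, the standard membrane
  leak factor;
* the printed cosine series starts at mode 1, but a cosine (sealed-end,
  Neumann) expansion of a general initial profile needs the mean mode
  $\zeta_0/2$; without it terminal potentials go negative and time-to-peak
  is degenerate. The package includes the mean mode (zero-mean profiles
  reduce to the printed sum exactly), and offers a sine-basis variant
  consistent with the printed grounded-end boundary condition.

The printed units (MΩ, mF/cm² with no geometry) do not form a consistent
time constant, so the two γ-products are treated as effective time
constants read in milliseconds: $\tau_m = \gamma_m\gamma_c$ ms ≈ 64 ms
(a realistic membrane constant) and
$\tau_{diff} = L_N^2\gamma_l\gamma_c$ ms. The axonal delay $\Omega_{Ax}$ is
the time-to-peak of the potential magnitude at the axon terminal for a
proximal initial bump, located by a dense scan plus golden-section
refinement; it grows with axon length as expected. Spike trains cross the
axon as a rigid shift by $\Omega_{Ax}$ — timing, not amplitude, is what the
decoder consumes.

### Synapse

Vesicles live in a readily releasable pool (RRP, 3–10 vesicles) refilled
from a reserve pool (RP, 60) at rate $1/\tau_f$. The printed release
probability $1 - \exp(\bar\lambda N_{RRP})$ exceeds 1 and grows with pool
size; the package implements
$P_{rele} = 1 - \exp(-p_v \bar\lambda T_{ref}/N_{RRP})$ with $p_v = 0.4$
and a 10 ms normalization window, which stays in $[0,1]$ and recovers the
linear small-argument approximation the source itself states. The
discrete-event simulator `simulate_release()` applies per-spike Bernoulli
release while the pool is nonempty, with exact integer bookkeeping.

The printed release-stage error probabilities
$P_{e1}(1) = 1 - P_{rele}^{k_i}$, $P_{e1}(0) = P_{rele}^{k_i}$ are
implemented verbatim (`release_error_probs()`). Note their structural
oddity: they sum to one, so as a stand-alone stage they carry no
information; information survives the composition only because the printed
neural-error expressions weight the two error paths asymmetrically by the
transmit probability.

Neurotransmitter absorption is an M^x/G/1/K queue: batch Poisson arrivals
(geometric batch sizes with parameter σ), one server with configurable
service distribution, capacity K, partial-batch acceptance by default. The
printed closed forms for blocking and waiting are internally inconsistent
(mixed K/N symbols, an undefined normalization), so the discrete-event
simulation is the normative implementation; it is validated against the
M/M/1/K closed form with unit batches and exponential service, and against
Little's law. Reported standard errors use batch means because blocking
events are strongly autocorrelated — naive binomial errors understate the
Monte-Carlo uncertainty severalfold.

Postsynaptic potentials are alpha functions
$F(t) = G_{max}(t/t_p)e^{1 - t/t_p}$ with i.i.d. Gamma amplitude jitter of
mean 1.

### Decoder

The receiver samples the waveform at interval $\tau_s$, declares a spike
wherever the windowed sample mean exceeds $\vartheta_2$ (the printed
criterion has the inequality inverted — a *low* mean would indicate a
spike — which contradicts the positive alpha-function amplitudes; the
literal reading survives behind `invert_threshold`), estimates the slot
rate by the Poisson MLE $\lambda' = n/T$, and tests Poissonness by a
one-sample KS of the inter-spike intervals against Exp($\lambda'$). The
printed acceptance rule scales the KS statistic by the slot index; the
package uses the conventional $\sqrt{m}$ scaling against the Kolmogorov
critical value (the literal form is available via `literal_ks`). A slot
decodes to "1" iff the test accepts and $\lambda' \ge \vartheta_3$.

Because $\lambda'$ is estimated from the same intervals, the KS test is
conservative (the Lilliefors effect): under a genuine homogeneous Poisson
null the measured rejection rate is well below the nominal α (about 0.006
at α = 0.05 in the calibration test), which the decoder's error model
accounts for by treating α as an upper bound on the false-rejection rate.

## Capacity and delay layer

The analytic layer treats each slot as a binary relay channel
$X \to Y \to Z$ (hormone → Ca²⁺ → decoded spikes) and computes
$I(X;Z)$ from the full joint distribution assembled from $P(Y|X)$ and
$P(Z|Y)$ under the Markov assumption; capacity is the maximum over the
transmit probability $p$, by grid search with golden-section refinement.
The relay transitions come from the slot detection probabilities,
$P(Y=1|X=1) = 1-(1-u_0)\prod_{i\ge1}(1-p u_i)$ with interference from
earlier slots, detection pooled across astrocytes
($1 - \prod_a(1 - u_{a,n})$, which is how the astrocyte count $M_A$ enters
the capacity). Two printed conditionals in the transition definitions are
duplicated; the joint is assembled from the four independently defined
conditionals, the only reading consistent with the chain decomposition the
source itself uses. Logs are base 2 throughout.

The vesicle stage feeds the printed error expressions with an *effective*
per-spike release probability derived from a steady-state RRP occupancy
fixed point (binomial release over the occupancy, per-vacancy refill
$(N_{RRP}-n)/\tau_f$), and a spike exponent $k_i = \bar\lambda T_k$ over a
release assessment window $T_k = 50$ ms — one inter-spike interval at the
reference 20 Hz. These two choices are the package's operationalization of
expressions the source leaves under-determined, and they were fixed by
requiring the five published qualitative trends to be simultaneously
realizable: capacity rising with $Q_0$, with $M_A$, with $N_{RRP}$ and with
shorter $\tau_f$, and falling with $\bar\lambda$. Under them the
capacity-maximizing $p^*$ lands near 0.7–0.8, matching the published
observation that the optimum is not 0.5. The decoder stage uses a Poisson
count model with the conservative KS pass probability.

Total delay is $\Omega = \Omega_H + \Omega_{Ca} + N_N(\omega + \Omega_{Ax})$
with $\omega$ the mean queueing wait.

## Operating points, defaults, and the high-SNR profile

`chain_config()` defaults are the published operating conditions: $T = 10$
s slots, $Q_0 = 5000$ molecules, $D_H = 4800$ μm²/s, $\iota = 0.2$ s⁻¹
(the source omits the unit; s⁻¹ is assumed), three astrocytes at uniform
random distances in 1–20 μm, the Li–Rinzel constants above, firing rates in
the 15–30 Hz range, pools of 8 + 60 vesicles with 10–40 ms refill.

The `high_snr` profile is a calibrated *receiver-side* operating point used
for the error-free end-to-end demonstrations; it touches only quantities
the source leaves open (release probability scale, membrane kernel
smoothing, coupling sharpness, postsynaptic kinetics, decoder thresholds),
never the physical channel conditions:

* `p_release = 0.5` — reliable vesicle release, so driven slots carry
  enough events for stable rate estimates;
* `kernel_tau = 2.5` s — the membrane integrates across Ca²⁺ wave troughs,
  so within-slot firing is near-homogeneous and the interval-KS accepts;
* Hill exponent 3 in the IP₃ coupling — the oscillator switches off
  quickly after a run of "1" slots, limiting inter-symbol memory;
* `t_p = tau_s = dt = 2.5` ms — postsynaptic events resolve individually,
  keeping detected inter-spike intervals exponential;
* decode window $[iT+5, (i+1)T)$, $\vartheta_3 = 5$ Hz, α = 10⁻⁴ —
  the window skips both the response build-up and the residual ring-down of
  the previous slot; the rate threshold sits centrally between the residual
  "0"-slot rates (≈ 2–4 Hz after long runs of ones) and the driven
  "1"-slot rates (≈ 7–11 Hz).

With this profile, 64-bit random frames decode with zero errors across all
seeds tried, while the *default* profile — the literal 10 ms release
normalization window — produces so few vesicle releases that frames do not
decode at all: the chain is honest about needing a receiver calibration.

## What the simulator does and does not emulate

The generator reproduces: superposed diffusion with degradation and slot
memory; stimulus-dependent Ca²⁺ oscillation frequency, onset, and
high-stimulus collapse to a plateau; Poisson firing statistics; pool
depletion and refill; queueing delay and blocking; amplitude-jittered
postsynaptic waveforms. It does not model: spatially resolved intracellular
Ca²⁺ or gap-junction coupling between astrocytes; conductance-based
(Hodgkin–Huxley gating) action potentials; active (drifted) hormone
transport; receptor subtype kinetics or reuptake in the cleft; extracellular
boundary effects or crowding. Passing tests therefore certify the chain
model's internal consistency and its agreement with the published
qualitative behaviors, not fidelity to any particular biological
preparation.

## Numerical choices

* ODE integration: `deSolve::lsoda`, rtol 10⁻⁸ / atol 10⁻¹⁰; oscillation
  tests are re-run at halved step for self-convergence, and both ER
  conventions carry exact linear invariants asserted to 10⁻⁶ μM.
* Convolutions (diffusion kernel, membrane kernel) use zero-padded FFTs at
  highly composite lengths; correctness is pinned against an O(n²) direct
  sum at 10⁻⁹ relative.
* Slot absorption integrals use adaptive quadrature
  (`stats::integrate`, rel.tol 10⁻¹⁰); tests compare against fixed-step
  trapezoid oracles, with a 5 μs step for the sharply peaked slot-0
  integrand.
* The cable series defaults to 64 modes; doubling changes nothing beyond
  10⁻⁶ for t ≥ 1 ms. The finite-difference comparison uses an explicit
  scheme at 20% of the stability limit.
* The calcium-delay crossing is found by bisection on the cumulative
  variation series (equivalent to, and tested against, a linear scan).
* Capacity maximization scans p on a 0.01 grid and refines with
  `stats::optimize`; tested against a 1001-point brute-force grid.
* Monte-Carlo components (queue, release, decoding errors) report batch
  means or binomial standard errors as appropriate; simulation sizes in the
  tests (10⁴ queue arrivals, 500 KS replicates, 100–200 decoding
  replicates, 10⁵ diffusion walkers) were chosen so every stochastic
  assertion sits at least 3σ from its boundary under the fixed seeds.
* Reproducibility: one root seed spawns labelled independent substreams per
  stage ("placement", "firing", "release", "queue", "amplitude"), so
  changing one stage's draws never perturbs another's.

## Known limitations

* The capacity layer's absolute numbers depend on the capture-volume and
  release-window calibrations; only the *trends* across parameters are
  anchored to published statements, and the published figure curves are not
  tabulated anywhere to compare against.
* The per-astrocyte reading of the Ca²⁺ delay balance is a repair; the
  literal summed reading is exactly $M_A$-invariant (see above) and remains
  available.
* The KS decoder is conservative with estimated rates; a Lilliefors-style
  corrected critical value would reject closer to the nominal α but is not
  what the source describes.
* At high release rates the waveform detector merges near-coincident
  events (an effective dead time of a few ms), biasing $\lambda'$ low; the
  high-SNR profile's fast postsynaptic kinetics keep this mild, but decoder
  thresholds should be recalibrated if `t_p` or `tau_s` are changed.
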