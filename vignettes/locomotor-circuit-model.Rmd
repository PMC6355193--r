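---
title: "A brainstem-spinal circuit model of locomotor frequency and gait"
author: "locomotoR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A brainstem-spinal circuit model of locomotor frequency and gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locomotoR)
```

## The model

Quadrupeds change gait with speed: walk and trot at low speeds (left and
right limbs alternate), gallop and bound at high speeds (left and right
limbs move in near-synchrony). `locomotoR` simulates a population-level
("activity-based") model of the circuits thought to control this: two
mesencephalic locomotor region nuclei — the cuneiform nucleus (CnF) and the
pedunculopontine nucleus (PPN) — converge on the lateral paragigantocellular
nucleus (LPGi) of the reticular formation, which drives the four spinal
rhythm generators (one per limb) and, through a separate pathway, the
commissural and long propriospinal interneurons that coordinate them.

Each population is a single rate unit. Its membrane potential $V$ obeys

$$C\,\dot V = -I_{NaP} - I_L - I_{SynE} - I_{SynI} - I_{Noise},$$

where the persistent-sodium current $I_{NaP} = \bar g_{NaP}\, m_\infty(V)\,
h\,(V - E_{Na})$ is present only in the flexor and extensor rhythm-generator
centers (RG-F, RG-E) and gives them intrinsic burst dynamics through the
slow inactivation gate $h$. All other populations are leaky rate units.
Population output is the piecewise-linear function

$$f(V) = \min\!\big(1, \max\big(0, (V - V_{thr})/(V_{max} - V_{thr})\big)\big),$$

with $V_{thr} = -50$ mV and $V_{max} = 0$ mV. Synapses are
conductance-based: weighted presynaptic output activity (and tonic drive)
enters an excitatory conductance reversing at $-10$ mV, inhibitory input a
conductance reversing at $-75$ mV. Stimulation of a population follows the
linear drive law $D(\alpha) = m\,\alpha + b$ with the normalized
stimulation strength $\alpha \in [0, 1.05]$; the slope and intercept values
for CnF, PPN and LPGi stimulation are part of the model definition. The
noise current is an Ornstein--Uhlenbeck process (relaxation time 10 ms,
stationary SD `sigmaNoise`, baseline 0.005 pA) advanced by one
Euler--Maruyama update per integration step.

The connectome — which populations exist, every signed connection weight,
and the constant vestibular (VN) drive of 2.15 that keeps the extensor
centers tonically active — is constructed by `buildDefaultNetwork()` and
validated structurally by `validateNetwork()` (exact left/right mirror
symmetry; weight signs matching each source's transmitter; no dangling
references). One transcription detail: the published weight table lists the
projections of the descending inhibitory relay (dIni) onto the V0
commissural neurons as positive magnitudes (4, 1.7, 7.5) under the name
"Ini"; the accompanying text is unambiguous that this relay inhibits its
targets, so the package realizes them as inhibitory weights and keeps the
printed magnitude alongside for table round-trips. The spinal "Ini"
interneuron (source of the $-0.075$ projection to RG-F) is a separate
population.

## Why the gaits change: the two-pathway logic

The model separates *speed* from *gait*:

* LPGi-Glu-1 receives both CnF and PPN input and excites the flexor centers
  of all four rhythm generators (via the Ine and CINe relays). More
  stimulation, more excitation, higher locomotor frequency.
* LPGi-Glu-2 receives only CnF input and excites the inhibitory dIni
  relays, which suppress the V0 commissural neurons and the descending
  V0$_D$ long propriospinal neurons. These commissural pathways are what
  hold the left and right limbs in alternation, so their progressive
  suppression converts walk into trot into gallop into bound.

Because the dIni weights differ (7.5 onto the fore V0$_D$-LPN, 4 onto
V0$_D$, 1.7 onto V0$_V$), the pathways are silenced in a fixed order as
dIni activity rises, which is what staggers the gait transitions. PPN
stimulation never engages LPGi-Glu-2, which is why it can only produce
walk and trot.

## Calibrated parameters

The source publication defines the network structure, all connection
weights, the drive laws and the analysis protocols, but defers the
intrinsic cell constants to a companion model. The package therefore
carries a calibrated parameter set, frozen once:

* Persistent sodium (`defaultNapParams()`): $\bar g_{NaP} = 14$ nS,
  $E_{Na} = 50$ mV, activation half-voltage $-32$ mV (slope $-6$),
  inactivation half-voltage $-44$ mV (slope 5), inactivation time-constant
  scale 250 ms. With the RG leak (4.5 nS, $E_L = -62.5$ mV, $C = 10$ pF)
  an isolated flexor center is quiescent below $\approx$0.15 nS of
  excitatory conductance, bursts between $\approx$3 and $\approx$10.5 Hz
  over 0.2--1.5 nS, and goes into sustained depolarization above
  $\approx$1.8 nS. `calibrateRGCenter()` reproduces this calibration by
  grid search and is the tool to re-derive it after any change.
* Synaptic scales (`defaultSynapseParams()`): 10 nS per unit weighted
  excitatory activity, 30 nS inhibitory, 0.18 nS per unit drive. The
  large inhibitory scale lets the numerically small commissural weights
  (0.03--0.07) act at the low output activities the brainstem cascade
  operates at.
* Tiered resting potentials. With conductance synapses reversing at
  $-10$ mV a multi-stage excitatory cascade attenuates unless each stage
  operates near its output threshold, so the brainstem and relay
  populations rest at $-52$ mV (just below threshold), the vestibular
  population at $-42$ mV (tonically active, as vestibulospinal neurons
  are), the gait relay dIni at $-54$ mV (recruited only at higher
  stimulation, which positions the gait transitions), and spinal
  interneurons at $-60$ mV.
* Per-population drive gains. The printed LPGi stimulation law
  ($m = 1.1$, $b = 2.45$) is numerically much weaker than the CnF law
  although the reported evoked behavior is similar, so the LPGi
  populations carry drive gains (2.4 for LPGi-Glu-1, 1.2 for LPGi-Glu-2,
  1.3 for the LPGi inhibitory population) while all other populations use
  gain 1.

These are package calibration choices, selected so that the isolated
rhythm generator spans the observed frequency range and the full network
expresses the qualitative study phenomena; they are not measured
quantities, and analyses that depend finely on them should say so.

## Numerical procedures

Integration is fixed-step classical RK4 (default $dt = 0.1$ ms; membrane
time constants are 2--4 ms, so this is far inside the stability and
accuracy region, and fixed-step keeps runs bitwise reproducible). For
stochastic runs the noise current is held constant within a step and
updated by Euler--Maruyama afterwards (default $dt = 0.2$ ms). A plain-R
`stateDerivative()` implements the same laws and is cross-checked against
the compiled core in the test suite.

The initial state is $V = E_L$, $h = h_\infty(V)$, zero noise, plus a
small graded voltage offset (0.01 mV times the population index) that
breaks the network's exact permutation symmetries — from a perfectly
symmetric state the dynamics would remain on the symmetric manifold even
where it is unstable, and no synchronous/alternating structure could
develop. Mirror-symmetry tests therefore mirror the initial state
explicitly.

Settling (`settleAtAlpha()`) follows the published protocol: integrate in
10-s chunks (5-s chunks in desk-scale runs) until the standard deviation
of each of the four inter-limb phase differences over the last five
locomotor cycles falls below $10^{-3}$, or a 200-s cap passes (20--30 s
desk scale). Phase differences are circular; the SD is computed after
re-centering, and reported phases are circular means. A step is quiescent
if the reference flexor output is flat (peak-to-trough < 0.05 over the
last 5 s) or produces no onset for 3 s. Burst onsets are upward crossings
of $f(V) = 0.1$ with linear interpolation and a 20-ms refractory gap;
frequency is the reciprocal of the cycle period.

Continuation sweeps (`bifurcationSweep()`) step $\alpha$ from 0 to 1.05
and back (published resolution 1000 steps; desk scale 30--100), each step
warm-starting from the previous step's final state; the down branch
continues from the up branch's final state, the standard hysteresis
protocol. Regions where the branches disagree expose bistability between
adjacent gaits.

Gait classification (`classifyGait()`) uses circular distances: bound if
both left--right phase differences are within 0.15 of synchrony; trot if
both are within 0.1 of alternation and the diagonal pair is within 0.15
of synchrony; walk if both alternate and the diagonal pair is not
synchronous; gallop for intermediate left--right phasing; otherwise
unclassified. The defining windows of the companion lineage are not
restated in the source, so these windows are package constants
(`gaitWindows()`), chosen to make the verbal definitions (0.5 =
alternation, 0/1 = synchronization, gallop in between) exhaustive and
mutually exclusive. Noisy histograms divide bin counts by the total
number of locomotor cycles (the source's two normalization statements
disagree; the per-cycle normalization is the one that yields a relative
frequency and is used here).

## What the default analyses show

With the frozen calibration, the desk-scale analyses reproduce the main
study phenomena:

* Unilateral CnF-Glu stimulation ($m = 1.35$, $b = 3.95$): frequency
  rises from $\approx$5.9 to $\approx$10.8 Hz along the up branch with
  the gait sequence walk, trot, gallop, bound and bistable transition
  regions between branches.
* Unilateral PPN-Glu stimulation ($m = 1.5$, $b = 4$): frequencies only
  up to $\approx$7.2 Hz and alternating gaits only.
* Unilateral LPGi-Glu stimulation ($m = 1.1$, $b = 2.45$): range and
  repertoire similar to CnF stimulation.
* Bilateral PPN inactivation during CnF stimulation ($m = 2.55$,
  $b = 4.2$): all frequencies reduced and the transition to synchronous
  gaits shifted to markedly lower frequency (first synchronous gait at
  $\approx$5.7 Hz versus $\approx$8.1 Hz intact).
* Inhibitory-drive grids: unilateral excitation of CnF or LPGi inhibitory
  populations slows and then stops locomotion at every tested excitatory
  level, whereas PPN inhibitory stimulation slows but never stops it.

## Known limitations

These are documented honestly because they bound what passing tests mean:

* The trot attractor is marginal. Under bilateral PPN inactivation the
  walk-to-synchrony transition skips trot entirely (verified at
  $\Delta\alpha = 0.0025$), and multiplicative weight perturbations of
  only 2% (`perturbWeights()`) collapse the trot window in roughly half
  of randomized models, so the robustness study retains all four gaits
  less often than the original report. Along the inhibitory-drive grid at
  high excitation the near-synchronous state sits just outside the 0.15
  bound window and trot is likewise absent. A future recalibration aiming
  specifically at a wide trot basin would need to revisit the fore--hind
  coupling balance, not just the scalar gains explored here.
* Up-branch frequency dips by a few tenths of a Hz just before the
  gallop-to-bound transition instead of being strictly non-decreasing.
* The robustness study's "unstable" classification (non-convergent,
  non-quiescent, drifting phases on more than 5% of steps) is sensitive
  to the settling cap; at desk-scale caps the unstable fraction at
  $\sigma_p = 0.2$ exceeds one half.
* The synthetic protocols emulate clean tonic stimulation of one
  population at a time with stationary noise. Real optogenetic drive is
  neither instantaneous nor population-pure; motoneurons, reflex circuits,
  biomechanics and sensory feedback are outside the model, so passing
  tests validate the circuit-level logic, not behavior of the limb.

## Reproducing the analyses

```{r, eval = FALSE}
net <- buildDefaultNetwork()

# continuation sweep of CnF stimulation, desk scale
bd <- bifurcationSweep(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                       nSteps = 100, chunk = 5000, cap = 20000)
head(upBranch(bd))

# noisy gait-probability map (published protocol: alphaStep = 0.01,
# 100 s per step, sigmaNoise = 1 pA)
rec <- noisySweep(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                  alphaStep = 0.05, durationPerStep = 20000,
                  sigmaNoise = 1, seed = 1)
gaitProbabilityMap(rec)

# inhibitory-drive grid and robustness study
g <- driveGrid(net, inTarget = "CnF-GABA/Gly")
r <- robustnessSuite(net, sigmaP = c(0.02, 0.2), nModels = 20, seed = 1)
```

The command-line interface (`inst/scripts/locomotor`) wraps the same
functions behind YAML configurations (`loadConfig()`), and
`scripts/acceptance.R` recomputes the headline frequency maxima from a
fresh build of the default network.
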