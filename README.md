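# locomotoR

Simulation of a bilateral brainstem–spinal circuit controlling locomotor
frequency and gait in quadrupeds, for computational neuroscientists
studying the supraspinal control of locomotion.

The model is a rate ("activity-based") network. Four spinal rhythm
generators — one per limb, each a flexor/extensor half-center whose flexor
center bursts through a persistent sodium current,

    C dV/dt = -I_NaP - I_L - I_SynE - I_SynI - I_Noise,
    I_NaP   = g_NaP m_inf(V) h (V - E_Na),

— are coordinated by commissural (V0_D, V0_V, V3, CINi) and long
propriospinal interneurons and driven from the brainstem: the cuneiform
(CnF) and pedunculopontine (PPN) nuclei project to the lateral
paragigantocellular nucleus (LPGi), whose two glutamatergic subpopulations
control locomotor frequency (via relays onto the rhythm generators) and
gait (via inhibitory relays onto the commissural pathways). Population
output is the piecewise-linear f(V) on [V_thr, V_max]; stimulation follows
the linear drive law D(alpha) = m*alpha + b with alpha in [0, 1.05].
Increasing CnF stimulation raises step frequency and switches the gait
from walk to trot to gallop to bound; PPN stimulation produces only slow
alternating gaits; inhibitory CnF/LPGi stimulation slows and stops
locomotion. See `vignettes/locomotor-circuit-model.Rmd` for the full
model account.

## Worked example

```r
library(locomotoR)

net <- buildDefaultNetwork()
validateNetwork(net)          # character(0): mirror-symmetric, signs OK
connectionWeight(net, "CnF-Glu:l", "PPN-Glu:l")
#> [1] 0.56

# Continuation sweep of left-CnF stimulation (desk scale: 40 alpha steps,
# 5-s settling chunks, 30-s caps)
bd <- bifurcationSweep(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                       nSteps = 40, chunk = 5000, cap = 30000)
up <- upBranch(bd)
range(up$freq[up$status == "converged"])
#> [1]  5.89109 10.80055
rle(up$gait)$values
#> [1] "walk"  "trot"  "gallop" "bound"
```

The frequencies are the converged locomotor frequencies (Hz) along the
rising branch of the stimulation sweep — walking at ~5.9 Hz at zero
stimulation strength up to bounding at ~10.8 Hz at alpha = 1.05 — and the
gait labels are classified per settled step from the four inter-limb
phase differences (hind left–right, fore left–right, homolateral,
diagonal). The same sweep on PPN-Glu (`m = 1.5, b = 4`) stays below
~7.2 Hz and produces only alternating gaits.

Stochastic runs pool per-cycle records for gait-probability maps:

```r
rec <- noisySweep(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                  alphaStep = 0.05, durationPerStep = 20000,
                  sigmaNoise = 1, seed = 1)
gaitProbabilityMap(rec)$prob[, 1:8]
```

A command-line front end wrapping the same functions ships in
`inst/scripts/locomotor`:

```sh
Rscript inst/scripts/locomotor sweep --stim CnF-Glu:l --reduced --out out/
```

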