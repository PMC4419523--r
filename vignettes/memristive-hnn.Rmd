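---
title: "Simulating a memristive hybrid neural network for imagined-speech EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a memristive hybrid neural network for imagined-speech EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memhnn)
```

## The system

`memhnn` is a behavioural simulator of a small hardware classifier for
imagined-speech EEG: a subject imagines speaking one of three vowels
(/a/, /i/, /u/), a software front-end turns each multi-channel EEG trial
into a 32-bit binary feature code, and a single-layer neural network built
on a 32 x 6 cross-point array of PCMO memristive synapses (192 devices)
recognizes the code. Six leaky integrate-and-fire (LIF) post-neurons are
paired into three groups, one per vowel pair (/a/ vs /i/, /a/ vs /u/,
/i/ vs /u/); decision logic takes the first-to-fire member of each group and
a majority over the three groups. Every class is represented by two neurons,
so a correctly recognized code fires exactly two of the six.

The package follows the classic R modelling idiom: `memhnn()` is the fitting
function (it trains the crossbar on labelled codes) and returns an object
with `print`, `summary`, `coef` (the 6 x 32 conductance matrix), `predict`
and `plot` methods. All the building blocks — the device model, bias
assignment, LIF dynamics, decision logic, the EEG front-end and the
synthetic-data generators — are exported functions.

## The synapse model

A device's state is its conductance $g$ (nA/V, i.e. read current per volt),
bounded in $[g_{\min}, g_{\max}] = [1.5, 5.5]$ nA/V. Reads are linear
($i = g v$) and non-destructive for $|v| \le V_R \approx 1$ V. A
supra-threshold pulse updates the state by an exponential-saturation rule:

$$\Delta g = \alpha_{pot} (g_{\max} - g) \quad\text{(potentiation)},\qquad
  \Delta g = -\alpha_{dep} (g - g_{\min}) \quad\text{(depression)}.$$

With the default $\alpha = 0.0875$ (i.e. `calibrate_rate(params, 0.35)`),
a pulse at $g_{\min}$ moves the state by 0.35 nA/V and a pulse at 90% of the
range by 0.035 nA/V, inside the device's measured per-pulse windows
(0.2–0.5 nA/V in the low state, 0.02–0.05 nA/V near saturation). This is the
simplest rule matching both endpoint windows, the saturating limits, and the
device's symmetric potentiation/depression response; the closed form
$g_{\max} - g_n = (1-\alpha)^n (g_{\max} - g_0)$ makes the train behaviour
exactly testable. Whether the printed rate windows reflect device-to-device
variation or cycle-to-cycle stochasticity is not known; an optional seeded
rate jitter (`jitter_sd`) supports either reading and is off by default so
unit tests are exact. A disturb model (`disturb_enabled`,
`disturb_fraction`) lets users study unintended switching of half-selected
cells quantitatively; the default (off) reproduces the ideal scheme.

## The modified half-bias learning scheme

Training uses two phases per code. Spike levels are $V_H = 5$ V and
$V_L = 3$ V; the common-mode level is set to $V_{CM} = 4$ V — their
midpoint, and the unique choice for which every non-targeted cell sees at
most $|V_H - V_{CM}| = 1\,\mathrm{V} = V_R$, so half-selected synapses are
never disturbed. In the potentiation phase the labelled rows' top electrodes
sit at $V_L$ and active-bit columns at $V_H$: targeted cells see +2 V and
potentiate.

Which cells the depression phase targets is not fully determined by the
hardware description, and the choice matters greatly. The package supports
three schemes (`learning_config(depress_scheme = ...)`):

* `"desired_inactive"` (default): the labelled rows themselves are depressed
  at the code's *inactive* bits. Each labelled row converges to a saturated
  template of its class — high conductance exactly at the class's active
  bits. Own-class read currents approach $15 \times 5.5 \approx 83$ nA,
  matching the hardware's reported per-neuron input current of about 90 nA,
  while cross-class currents stay near 45 nA. Training is monotone (no two
  classes ever write the same cell in opposite directions), margins are wide
  and stable.
* `"rival_active"`: the group rivals of the labelled rows are depressed at
  the code's *active* bits. Cells at bits shared between two classes are
  then potentiated by one class and depressed by the other on every epoch;
  because the update rate is large (the state effectively remembers only the
  last $1/\alpha \approx 11$ pulses) these contested cells follow whichever
  class was presented most recently, and all contested cells of a row move
  together. Winner and non-winner current distributions then overlap and no
  fixed firing threshold separates them reliably. We implemented and
  measured this scheme; the default was chosen because it is the one
  consistent with the reported ~90 nA own-class currents and with exactly
  two neurons firing per recognized code.
* `"both"`: both phases in sequence, for experimentation.

Training presents every code once per epoch (order reshuffled each epoch so
no class dominates the most recent updates), stopping as soon as every
training code is classified correctly **and** fires exactly its two
labelled neurons — the operational meaning of "fully trained" here. If the
epoch budget (default 20) runs out first, the state from the best epoch
under that criterion is kept, i.e. training is halted at the point it was
most completely trained.

## The LIF post-neuron

Each row's current accumulates on an inverting leaky integrator: from the
reset level $V_{reset} = 4$ V the output decays towards
$v_{sat} = V_{reset} - R\, i$ with time constant $\tau$,

$$v(t) = v_{sat} + (V_{reset} - v_{sat})\, e^{-t/\tau},$$

an almost linear early drop that saturates. The neuron fires when $v$ drops
strictly below $V_{TH} = 3$ V, which happens iff $R\, i > V_{reset} - V_{TH}
= 1$ V, at the closed-form time $t_f = \tau \ln\frac{V_{reset} -
v_{sat}}{V_{TH} - v_{sat}}$. After the integration window a refractory phase
discharges the capacitor back to 4 V.

The RC constant, transimpedance scale and window lengths of the hardware are
unpublished, so absolute fire times are not comparable to measurements —
only their order and the fire/no-fire pattern are. Defaults: $\tau = 10$ ms,
integration window 50 ms, refractory 10 ms, and gain $R = 1/58$ V/nA. The
gain places the 1 V firing margin at 58 nA of row current, chosen by
simulation (over seeds disjoint from any used in the tests) to sit between
the trained own-class current of a typical code (~83 nA) and the
cross-class (~45 nA) and untrained mid-conductance (~53 nA) currents; an
untrained uniform array therefore fires nothing, and a trained one fires
exactly the two labelled neurons. Exact threshold equality counts as not
fired, matching the closed-form boundary.

## Decision logic

Per group, the earlier-firing member wins; a firing member beats a
non-firing one; a tie or a silent group abstains (no tiebreak is described
for the hardware, and abstention is conservative and visible in the
reports). The output is the class winning at least two groups; cyclic
outcomes (one win each) abstain. All 27 group-outcome combinations are
enumerated in the tests.

## The EEG front-end

The feature-extraction chain is: zero-phase Butterworth band-pass (order 5,
8–30 Hz; forward–backward filtering is used because the analysis is
offline and phase distortion would shift oscillatory features), baseline
correction against the pre-stimulus window, multivariate empirical mode
decomposition (MEMD), selection of the dominant alpha-band (8–12 Hz) IMF,
pairwise common spatial patterns (CSP), log-variance features, and
median-threshold binarization to 32 bits. An `artifact_hook` slot is where
ICA-based artifact removal would sit; the criteria used in the original
recordings are unpublished, so the hook defaults to the identity.

**MEMD.** No published parameter set exists for this pipeline, so reference
settings are used: 64 Hammersley-sequence directions on the channel-space
hypersphere, natural-spline envelopes of the multivariate signal at each
projection's extrema (two extrema mirrored at each boundary), a
Rilling-style stop (sift until the fraction of samples with mean-envelope to
envelope-amplitude ratio above 0.05 falls below 0.05 and none exceeds 0.5;
at most 15 sifts), and at most 8–10 IMFs. Because a single mean envelope is
shared by all channels, IMFs are aligned across channels, and the
decomposition reconstructs the input to machine precision by construction.
The envelope kernel is compiled (C++) with a pure-R reference implementation
kept for verification. The alpha IMF is the one maximizing the mean
channel-wise fraction of periodogram power in 8–12 Hz; ties go to the
lowest (fastest) index. A Morlet time–frequency map (7 cycles, 1–40 Hz) is
provided for inspection plots.

**CSP.** For each of the three class pairs, class covariances are
trace-normalized and averaged, and the generalized eigenproblem
$C_1 w = \lambda (C_1 + C_2) w$ is solved by whitening the composite
covariance (a $10^{-6}$ trace-scaled ridge is added only if the composite is
near-singular). The 5 largest- and 5 smallest-$\lambda$ filters are kept
(10 per pair). Features are $\log(v_i / \sum_j v_j)$ of the filtered
variances. Each feature binarizes to 1 iff it strictly exceeds its
training-set median, giving ~50% ones per feature on the training split;
the three 10-bit blocks are concatenated and padded with 2 zero bits to
32. The exact filter count, binarization rule and bit layout of the
original system are unknown; this is one consistent realization, recorded
in the pipeline's provenance log. CSP filters and thresholds are fitted on
the training split only — the tests verify that removing or changing test
trials leaves them bit-identical.

## Synthetic data

Two seeded generators make every stage testable without recordings.

`gen_codes()` emulates the binarized feature codes: one prototype per class
with independent per-bit flips at rate $p = 0.05$, 65 distinct training and
15 distinct testing codes (the counts of the original data set), class
counts balanced to within one. Prototypes are laid out in pairwise blocks
(3 blocks of 10 bits + 2 pad), mirroring what pairwise-CSP median
binarization produces: within block $(x, y)$, class $x$ sets one half of
the bits, class $y$ the complementary half, and the third class a random
half. This gives balanced codes (~15 of 32 ones) with small cross-class
active-bit overlap (~5 bits), the geometry on which the absolute firing
threshold of the hardware scheme is well-conditioned. Unstructured random
prototypes are available (`structure = "random"`); with them, cross-class
overlaps grow until a several-bit-flipped own-class code carries the same
row current as a close other-class code, and no threshold can then satisfy
both perfect training accuracy and the two-fire signature — a useful
illustration of why the block structure matters.

`gen_eeg()` emulates the recording protocol: 250 samples/s, 3.5 s trials
partitioned into cue (0–1 s), baseline (1–2 s) and imagery (2–3.5 s)
windows, $1/f$ background noise on all channels, and during the imagery
window a 10 Hz oscillation mixed through one of three fixed orthogonal
spatial patterns (a DCT basis over channels), scaled by `effect_size = 2`
(planted alpha amplitude twice the noise SD at the pattern's peak channel —
enough that imagery-window alpha power exceeds the baseline window by at
least 2x on pattern channels). Defaults are desk-scale: 16 channels and 20
trials per class, so the full front-end runs in about three minutes; 64
channels and 100 trials per class (the original protocol) are a config
change. The generator plants only band-limited, class-dependent spatial
structure: no eye-blink or muscle artifacts, no non-stationarity, no
volume-conduction realism. Passing tests therefore show that the pipeline
recovers the class-dependent alpha-band structure it assumes — not that it
would perform comparably on real recordings.

## What the simulation reproduces, and what it does not

On generated codes at the defaults, training reaches 100% accuracy within
the epoch budget, at least 14 of 15 test codes are recognized, and every
correctly recognized code fires exactly its two labelled neurons. On the
EEG path the front-end recovers the planted effect essentially perfectly (a
nearest-prototype read-out of the binarized codes exceeds 90% test
accuracy), but the crossbar back-end is more conservative: EEG-derived
codes carry 20–30% within-class bit noise on the interior CSP filters
(whose eigenvalues are near 0.5), their row currents straddle the fixed
58 nA firing level, and weak trials abstain rather than misclassify —
at the desk-scale defaults roughly a third of EEG trials abstain while
essentially none are assigned to a wrong class. This absolute-threshold
sensitivity is a genuine property of the hardware scheme, not of the
simulation; the first-to-fire ordering itself is almost always correct.

Hardware aspects deliberately not modelled: wire resistance and sneak
paths, op-amp non-idealities (offset, hysteresis, rail clipping), device
retention and endurance, analog noise, power, and the FPGA/switch timing.
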