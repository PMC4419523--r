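# memhnn

Behavioural simulation of a memristive hybrid neural network (HNN) for
imagined-speech EEG recognition, together with the EEG feature-extraction
front-end that feeds it and seeded synthetic-data generators that make the
whole system testable end to end.

## The problem and the system

Imagined speech — thinking a vowel (/a/, /i/, /u/) without vocalizing — has
a measurable EEG signature, strongest in the alpha band (8–12 Hz). A compact
hardware classifier for it can be built from a cross-point array of PCMO
memristive synapses: 32 pre-neurons drive a 32 × 6 array (192 two-terminal
devices) whose conductances are the learned weights, six leaky
integrate-and-fire (LIF) post-neurons integrate the column currents, and
simple decision logic reads out the first neuron to fire. The six neurons
are paired into three groups, one per vowel pair (/a/ vs /i/, /a/ vs /u/,
/i/ vs /u/); the predicted vowel is the class that wins at least two groups,
so a correctly recognized code fires exactly two of the six neurons.

`memhnn` simulates this system for people studying memristive learning
schemes and EEG feature pipelines:

* **Device:** conductance g ∈ [1.5, 5.5] nA/V, linear non-destructive reads
  below the switching threshold V_R ≈ 1 V, and threshold-gated saturating
  updates Δg = α(g_max − g) per potentiating pulse (−α(g − g_min) for
  depression), calibrated so one pulse moves a low-conductance device by
  0.2–0.5 nA/V and a nearly saturated one by 0.02–0.05 nA/V.
* **Learning:** a modified half-bias scheme with V_H = 5 V, V_L = 3 V and
  V_CM = 4 V. Targeted cells see 2 V and switch; every half-selected cell
  sees at most 1 V = V_R and is untouched. A potentiation phase raises the
  labelled rows' conductance at the code's active bits; a depression phase
  sculpts each labelled row into a template of its class (scheme selectable).
* **Neuron:** inverting leaky integrator, v(t) = v_sat + (4 − v_sat)e^(−t/τ)
  with v_sat = 4 − R·i; the neuron fires when v drops below V_TH = 3 V,
  i.e. iff R·i exceeds the 1 V margin; refractory reset to 4 V.
* **Decision:** first-to-fire per group, majority over three groups,
  abstention on ties and silent groups.
* **EEG front-end:** zero-phase Butterworth band-pass (order 5, 8–30 Hz),
  baseline correction, multivariate empirical mode decomposition (MEMD,
  compiled envelope kernel), dominant alpha-IMF selection, pairwise common
  spatial patterns (CSP), log-variance features, median-threshold
  binarization to 32-bit codes (65 train / 15 test at the defaults).
* **Generators:** `gen_codes()` (prototype feature codes with bit flips) and
  `gen_eeg()` (1/f noise with class-specific alpha-band spatial patterns),
  both fully seeded.

## Worked example

```r
library(memhnn)
set.seed(42)
d <- gen_codes(code_gen_config(seed = 42))   # 65 train / 15 test codes
fit <- memhnn(d$train)                       # train the 32 x 6 crossbar
fit
#> Memristive hybrid neural network (half-bias trained crossbar)
#>   array: 32 x 6 (192 synapses), classes: a, i, u
#>   trained on 65 codes, 3 epoch(s); training accuracy 100.0%

res <- predict(fit, d$test)
head(res[, 1:6], 5)
#>   true predicted n_fired group1 group2 group3
#> 1    a         a       2      a      a   <NA>
#> 2    a         a       2      a      a   <NA>
#> 3    a         a       2      a      a   <NA>
#> 4    i         i       2      i   <NA>      i
#> 5    a         a       2      a      a   <NA>
mean(res$predicted == res$true)
#> [1] 1
```

Training saturated in 3 epochs; every test code is recognized, and each
correct trial fires exactly its class's two neurons (`n_fired = 2`) — the
two groups containing that class decide it, the third group stays silent.
`coef(fit)` returns the trained 6 × 32 conductance matrix (nA/V);
`plot(fit, type = "traces", code = d$test[[1]])` draws the six integrator
outputs falling from the 4 V reset toward the 3 V threshold.

The device model itself can be characterized directly:

```r
simulate_device_response(500)$summary
#> $first_pulse_rate_pot: 0.35   # nA/V per pulse at g_min
#> $first_pulse_rate_dep: 0.35
#> $saturation_pot: 5.5          # nA/V after a long pulse train
#> $saturation_dep: 1.5
```

The full chain from synthetic EEG through feature extraction to the trained
network is one call: `run_all(source = "eeg", seed = 42)` (about three
minutes; see the vignette for what the EEG path does and does not reproduce).
A thin command-line wrapper with subcommands `gen-data`, `extract-features`,
`train`, `test`, `simulate-device` and `run-all` is in
`inst/cli/memhnn-cli.R`.

## Layout

* `R/` — device, crossbar, neuron, decision logic, EEG features, generators,
  the `memhnn` model interface, I/O.
* `src/` — compiled MEMD envelope kernel (a pure-R reference implementation
  is kept alongside and the tests verify their agreement).
* `vignettes/memristive-hnn.Rmd` — the methods vignette: model equations,
  parameter choices and their rationale, numerical details, limitations.
* `inst/extdata/codes_synthetic_seed1.txt` — a small synthetic feature-code
  fixture (generated by `gen_codes`, seed 1).
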