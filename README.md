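# respirodecon

Input estimation (deconvolution) for flow-through respirometry and other
linear time-invariant measurement systems.

## The problem

In flow-through respirometry an animal sits in a chamber flushed at a known
flow rate; a downstream gas analyzer records CO2 concentration. Any short
burst of CO2 the animal releases is smeared over seconds to minutes by
chamber washout, so the recorded trace *y* is not the animal's instantaneous
emission *u* but a causal convolution with the system's impulse response *h*:

    y(k) = Σ_j h(j) u(k − j),      or in matrix form   y = H u,

where **H** is the lower-triangular Toeplitz matrix built from *h* (measured
once per setup by injecting a short calibration pulse). Recovering *u* from
*y* is an ill-conditioned inverse problem: naive inversion amplifies
measurement noise catastrophically, and for long recordings (hours at 10 Hz)
**H** is too large to handle directly. This matters whenever respiratory
timing must be resolved at sub-second scale — e.g. synchronizing CO2 bursts
with abdominal pumping or spiracle opening in insects.

`respirodecon` implements two estimators that scale to recordings of any
length:

1. **Sequential Tikhonov regularization** — minimizes
   `||H u − y||² + γ ||Q u||²` (with **Q** an identity, first-difference or
   second-difference penalty), applied block-by-block: solve a block of
   `n + n₀` samples, accept the first `n` estimated inputs, subtract their
   forward contribution from the data ahead, advance. The block system is
   factorized once and reused, so each cycle costs only triangular solves.

2. **Dimension reduction** — assumes the input is constant over windows of
   `m` samples (`u = L v`, with **L** a block indicator whose columns are
   orthogonal), solves the `m`-fold smaller and much better-conditioned
   least-squares problem `min ||H L v − y||`, then slides the window grid
   one sample at a time and averages the `m` aligned solutions to restore
   temporal resolution. Two remedies handle the singularity caused by a
   transport delay (leading zeros in *h*): trimming the delay, or a ridge
   term `γ Q'Q` at the projected dimension.

Each method has a single tuning parameter (γ or m) trading noise resistance
against temporal resolution; grid-sweep helpers tune it on a calibration
pair. A simulator generates synthetic validation experiments (chamber
washout kernels, rectangular pulse-train inputs, calibrated Gaussian
noise), and plain-text readers/writers plus a CLI connect the package to
recorded data.

## Worked example

Simulate a 10-minute experiment at 10 Hz in a 28 ml chamber flushed at
500 ml/min (washout time constant 3.36 s, transport delay 1.5 s), with an
animal emitting three 1-second CO2 pulses and 1 % measurement noise, then
recover the emission pattern:

```r
library(respirodecon)

h <- synth_impulse_response(chamber_config(volume = 28, flow = 500, delay = 1.5))
h
#> Impulse response: support 284 samples (28.4 s) at dt = 0.1 s
#>   delay: 15 samples (1.5 s); sum(h) = 1

u <- synth_pulse_train(pulse_train_config(frequency = 0.5), N = 6000, dt = 0.1)
y <- add_noise(forward_convolve(u, h), level = 1, seed = 42)

fit <- deconvolve(y, h, method = "dr", m = 8, trim_delay = TRUE)
fit
#> Input estimation (deconvolution) fit
#>   method: dimension reduction (sliding-average projection)
#>   data: 5985 samples at dt = 0.1 s; kernel support 269 samples (delay 0)
#>   m = 8, averaging = TRUE
#>   sequential: 7 blocks (accept 780, look-ahead 720)
#>   residual ||H u - y|| = 0.355902; 720 low-confidence trailing estimates

pearson_correlation(coef(fit), u$values[seq_along(coef(fit))], mask = fit$flagged)
#> [1] 0.9290707
pearson_correlation(y$values, u$values)   # the raw trace, for comparison
#> [1] 0.362689
```

The raw washout-smeared trace correlates with the true emission at only
r = 0.36; the recovered input reaches r = 0.93. `coef()` returns the
estimated input, `fitted()`/`residuals()` the implied output and misfit,
`plot(fit, truth = u)` draws both panels, and `summary(fit)` adds per-block
diagnostics. `deconvolve(..., method = "tikhonov", gamma = ...)` runs the
Tikhonov estimator through the same interface; `sweep_gamma()` / `sweep_m()`
tune the parameters on a calibration pair.

## Command line

A thin wrapper in `inst/cli/respirodecon` exposes the same pipeline on
two-column (time, value) text files:

```sh
respirodecon simulate --out-dir data --duration 600 --frequency 0.5 --noise 1 --seed 7
respirodecon recover  --impulse-response data/ImpulseResponse.txt \
                      --data data/Data.txt --method dr --m 8 --trim-delay on
respirodecon tune     --param m --impulse-response data/ImpulseResponse.txt \
                      --data data/Data.txt --truth data/TrueInput.txt
respirodecon benchmark --preset reduced --seed 1 --out scores.tsv
```

`recover` writes `Recovered_Tikhonov.txt` or
`Recovered_DimentionReduction.txt` (three columns: time, original signal,
corrected signal).

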