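---
title: "Input estimation for washout-smeared physiological signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input estimation for washout-smeared physiological signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respirodecon)
```

## The forward model and its assumptions

The package models the measurement chain — respirometry chamber, tubing, gas
analyzer — as a causal linear time-invariant system. If $u(t)$ is the true
instantaneous gas-exchange signal and $h(t)$ the system's impulse response,
the analyzer records the convolution $y = h * u$. Working with uniformly
sampled signals (sample $k$ representing the average over
$[k\,\delta t, (k+1)\,\delta t)$), the discrete model is

$$ y(k) = \sum_j h(j)\, u(k-j), \qquad \mathbf{y} = H\mathbf{u}, $$

where $h(k)$ is the integral of the continuous kernel over one sampling bin
and $H$ is lower-triangular Toeplitz with first column $h$. The model
assumes: linearity and time-invariance of the washout (valid while flow rate
and chamber geometry are fixed), a finite kernel support (the calibration
recording continues until the signal vanishes; no extrapolated tail), and
zero inputs and outputs before time zero. `discretize_impulse_response()`
uses the rectangle rule `sample * dt` (with a trapezoid variant), which is
how a sampled analyzer recording is actually available; after unit-sum
normalization the rule is exact for exponentials up to tail truncation.

Direct inversion $H^{-1}\mathbf{y}$ is useless in practice: $H$ is badly
conditioned (and exactly singular when a transport delay puts leading zeros
in $h$), so inverted noise swamps the estimate. Both estimators below
regularize, each with a single tuning parameter.

## Tikhonov regularization and the sequential scheme

`tikhonov_solve_full()` minimizes
$\lVert H u - y\rVert^2 + \gamma\lVert Q u\rVert^2$ with closed form
$\hat u = (H^{\top}H + \gamma Q^{\top}Q)^{-1}H^{\top}y$. Numerically we never
form that inverse: the estimate is computed from a QR factorization of the
stacked system $[H;\ \sqrt\gamma\,Q]$, which is mathematically equivalent
and avoids squaring the condition number. $Q$ is identity, first difference
(first column $(1,-1,0,\dots)$) or second difference ($(1,-2,1,0,\dots)$),
all lower-triangular Toeplitz; the default is the second difference, which
penalizes curvature and gives the smoothest estimates — switch to the first
difference when sharp input transitions must survive. With $\gamma = 0$ the
solver refuses to proceed unless a condition estimate of $H$ is below
$10^{10}$, naming the remedy (set $\gamma > 0$).

For long recordings the full system is too large, so
`tikhonov_solve_sequential()` partitions the data: each cycle solves a block
of $n + n_0$ samples, accepts only the first $n$ estimated inputs (the
trailing $n_0$ also influence outputs beyond the block and are unreliable),
subtracts the accepted inputs' forward contribution from the data ahead,
drops $n$ samples, and repeats. The block matrix is factorized once and
reused, so each cycle costs two triangular solves. The defaults
(`partition_plan(780, 720)`, i.e. blocks of 1500 samples with a 720-sample
look-ahead at 10 Hz, scaled proportionally at other rates) follow
established practice for hour-long respirometry recordings; the look-ahead
should cover the kernel's contribution window (`support_len - 1`), and the
solver warns when it does not.

Two design points were genuinely open:

* **Penalty coupling across blocks.** The penalty $Q$ is built per block,
  not across block boundaries — the literal reading of the cycle. The
  consequence is a small boundary artifact that grows with $\gamma$; at the
  small $\gamma$ values appropriate for low-noise data it is negligible
  (interior agreement with the full solve is well under 2 % in the tests),
  and the effect saturates rather than vanishes as the overlap grows, since
  it is a property of the per-block penalty, not of data truncation.
* **The final partial block.** When fewer than $n + n_0$ samples remain, the
  smaller block is solved at its natural size and *all* its inputs are
  returned, with the trailing `n_overlap` estimates flagged as
  low-confidence rather than silently discarded. Flagging preserves
  length alignment with the measured series; consumers can trim via the
  `flagged` mask.

## Dimension reduction with sliding-average reconstruction

`dr_solve_single()` constrains the input to be constant on windows of $m$
samples: $u = Lv$ with $L$ the $N\times n$ block indicator ($n = N/m$; when
$m \nmid N$ the data are zero-padded to the next multiple and the padded
estimates trimmed on return — the padding choice is recorded in the
projection object). The columns of $L$ are orthogonal with squared norm $m$,
and the projected operator $HL$ — whose columns are $m$-sample running sums
of the kernel — is both $m$ times smaller and much better conditioned than
$H$; the package assembles it directly from its band structure rather than
by a dense product. The projected least-squares problem is solved by QR, and
the lifted estimate is piecewise constant.

Because a piecewise-constant estimate cannot track changes within a window,
`dr_solve_averaged()` slides the window grid $m$ times in one-sample
increments: for shift $k$ the data vector is shifted down $k-1$ slots
(zero-filled — outputs before time zero are zero), solved, and the estimate
shifted back up; the final estimate is the mean of the $m$ aligned
solutions. Structurally this equals applying the average of shifted copies
of the single-window reconstruction map, and the implementation reuses one
QR factorization for all $m$ shifts instead of materializing any $N \times
N$ matrix. The trailing kernel-support estimates lack look-ahead data and
are flagged (not deleted), again to preserve alignment.

A transport delay of $d$ samples zeroes the first $d$ rows and last $d$
columns of $H$, so $L^{\top}H^{\top}HL$ can be singular. Two remedies are
implemented and cross-validated against each other:

* `eliminate_delay()` drops the $d$ leading kernel zeros and the first $d$
  output samples. The trimmed system estimates the same input timeline
  (minus the final $d$ samples, which no observed output constrains); the
  tests confirm the trimmed solution equals the vanishing-ridge limit of the
  untrimmed solve to $10^{-6}$.
* `dr_solve_regularized()` adds $\gamma Q^{\top}Q$ to the projected normal
  matrix. $Q$ is built at the projected dimension $n$ — the only
  dimensionally consistent reading — with identity as the default penalty.

`dr_solve_sequential()` plugs the averaged projected solver into the same
partition-subtract-advance loop as the Tikhonov scheme.

Numerical rank of $HL$ is decided by singular values above
$10^{-10} \sigma_{\max}$; a rank-deficient unregularized solve fails with an
error naming both remedies rather than returning a garbage minimum-norm
solution silently.

## Tuning parameters

| parameter | method | meaning | default | guidance |
|---|---|---|---|---|
| `gamma` | Tikhonov | penalty weight, dimensionless | 0.01 (`deconvolve`) | no universal value; tune per setup with `sweep_gamma()` on a calibration pair. Clean data favor small values; noise pushes the optimum up. |
| `reg_kind` | both | penalty operator | 2nd difference (Tikhonov), identity (ridge DR) | 1st difference preserves sharper transitions |
| `m` | DR | window width, samples | 8 | useful values typically fall between 4 and 30; tune with `sweep_m()`. `m = 1` is plain least squares. |
| `n`, `n_overlap` | both | block partition, samples | 780 / 720 at 10 Hz | `n_overlap` ≥ kernel support − 1 |

Both sweeps score candidates by Pearson correlation against the known
calibration input and return the full score table, not just the argmax, so
the flatness of the optimum is visible.

## The simulator: what it emulates and what it does not

`make_benchmark_suite()` reproduces the synthetic validation design: a 28 ml
chamber at inlet flows of 250 and 500 ml/min, three-pulse rectangular inputs
(duty 0.5) at 0.1–2 Hz, 10 Hz sampling, and zero-mean Gaussian noise at
0.01–10 % of the clean output's peak amplitude (an `rms` reference is
available; the percentage's reference amplitude is a package choice, as
analyzer noise specifications vary). The `"full"` preset spans one hour
(36,000 samples); the `"reduced"` preset spans 10 minutes (6,000 samples)
and is what the test suite and acceptance script use, keeping every solve
desk-scale while exercising the multi-block path (6,000 samples is four
blocks of 1500).

The kernel is a *synthetic* stand-in: a well-mixed chamber washes out as a
first-order exponential with time constant $\tau_w = V/F$ (3.36 s at
500 ml/min, 8.06 s at 250 ml/min) after a transport delay (default 1.5 s, a
typical tubing lag at these flows); each discrete weight is the exact bin
integral of that density, normalized to unit sum. Measured kernels of real
rigs have the same gross shape but heavier tails and analyzer smoothing, and
measured recordings add baseline drift and non-Gaussian disturbances none of
which the simulator emulates. Passing the synthetic benchmark therefore
demonstrates correct and stable inversion of a realistic washout operator,
not field performance on any particular rig; for real setups the kernel must
be measured and the parameters re-tuned. Per-instance noise seeds are fanned
out deterministically from one master seed, so every instance is
individually reproducible.

## Numerical choices, degenerate inputs, and problem sizes

* Stacked-QR solves everywhere; explicit normal-equations inversion appears
  only as an independent oracle in the tests (agreement $10^{-8}$ on random
  instances, observed at machine precision).
* Delay detection when discretizing measured kernels: leading samples with
  magnitude $\le 10^{-3}\max|h|$ are treated as baseline noise, forced to
  zero, and counted as delay (configurable via `zero_tol`).
* Dense realizations of $H$ are allowed up to $N = 20{,}000$ by default;
  beyond that only the matrix-free convolution path (`stats::filter`) is
  available — both schemes exist precisely to avoid huge dense matrices.
* Degenerate inputs fail loudly: all-zero kernels, non-uniform or
  non-monotone time columns (line numbers reported), constant series in
  correlations, empty tuning grids, mismatched sampling intervals.
* Test problem sizes were chosen so the whole suite runs in about two
  minutes on one core: oracle comparisons at $N \le 100$ (Tikhonov) and
  $N \le 60$ (averaged map), block-consistency at $N = 1000$–$3000$, and
  recovery/noise-monotonicity studies on the reduced 6,000-sample preset
  with 20 noise replicates.

## Known limitations

Single-channel only (no simultaneous O2/H2O deconvolution); time-invariant
kernels (a flow change mid-recording invalidates $h$); no automatic
selection of $\gamma$ or $m$ (discrepancy principle, L-curve, GCV are out of
scope — only calibration-based grid sweeps are provided); per-block penalties
introduce the boundary effect described above; and the piecewise-constant
assumption limits the dimension-reduction method's resolution to features a
few samples wide unless $m$ is small.
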