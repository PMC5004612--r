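Package: respirodecon
Title: Input Estimation for Flow-Through Respirometry and Other Linear Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers instantaneous input signals (such as an animal's true CO2
    emission pattern) from indirectly measured, washout-smeared recordings in
    linear time-invariant measurement systems. Implements two large-dataset
    deconvolution methods: a sequential, partitioned Tikhonov regularization
    that processes arbitrarily long recordings in overlapping blocks, and a
    sliding-average dimension-reduction method that projects the input onto
    piecewise-constant windows, solves a well-conditioned least-squares
    problem, and averages shifted solutions to restore temporal resolution.
    Includes a flow-through respirometry simulator (chamber washout kernels,
    rectangular pulse-train inputs, calibrated Gaussian noise), plain-text
    signal file readers and writers, tuning sweeps for the regularization
    parameters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
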