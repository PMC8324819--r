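Package: fpinverse
Title: Inverse Estimation of One-Dimensional Fokker-Planck Dynamics from
    Noisy Density Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Joint recovery of the drift and diffusion terms of a
    one-dimensional, time-independent Fokker-Planck equation together with
    denoised probability densities, from sequences of noisy discretized
    densities.  Estimation alternates between an exact least-squares update
    of the per-bin drift and diffusion vectors and per-frame quadratic
    updates of the densities, both built on multi-offset Euler predictions
    through high-order finite-difference derivative operators.  Includes
    explicit Runge-Kutta forward solvers, three reference stochastic systems
    (Ornstein-Uhlenbeck heat flux, DNA-bubble Bessel dynamics, agent-wealth
    dynamics), multiplicative-noise simulation with calibrated noise level,
    Savitzky-Golay initialization, forecasting of future distributions, and
    normalized error metrics with a t-test boundary mask.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
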