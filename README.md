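# fpinverse

Inverse estimation of one-dimensional Fokker–Planck dynamics from noisy
probability-density sequences.

Stochastic systems are often observed not as trajectories but as evolving
probability densities — sea-surface heat-flux histograms, DNA
bubble-length distributions, wealth distributions of economic agents.
When the density $P(x,t)$ follows a one-dimensional, time-independent
Fokker–Planck equation

$$\partial_t P = \partial_x\big(g(x)P\big) + \partial_{xx}\big(h(x)P\big),$$

the scientific question is usually the inverse one: given noisy,
discretized snapshots $P(x, t_k)$ at a fixed time gap, what are the drift
term $g(x)$ and the diffusion term $h(x)$?  `fpinverse` answers it with a
self-supervised alternating estimator: multi-offset Euler predictions
through fixed finite-difference derivative matrices tie each density frame
to its $2n+1$ temporal neighbors; one step estimates the per-bin vectors
$(\hat g, \hat h)$ by penalized least squares with the densities held
fixed, the next refines the densities (denoising them) with the terms
held fixed.  The package is aimed at anyone who works with evolving
distributions and wants data-driven drift/diffusion laws without assuming
a parametric form: each of $\hat g$ and $\hat h$ is a free value per grid
bin.

The package also contains everything needed to validate the method from
scratch: forward Runge–Kutta solvers, three fully parameterized reference
systems (Ornstein–Uhlenbeck heat flux, DNA-bubble Bessel dynamics,
agent-wealth dynamics), calibrated multiplicative observation noise,
Savitzky–Golay initialization, normalized error metrics with a t-test
boundary mask, and forecasting of future distributions from held-out
sequences.

## A worked example

Simulate the heat-flux study — 120 Ornstein–Uhlenbeck density sequences
($g = 2.86\,x$, $h = 0.0013$) of 50 frames on a 110-bin grid, corrupted by
1% multiplicative noise — and recover the dynamics from the 100 training
sequences:

```r
library(fpinverse)

ds <- fp_simulate(fp_example("flux"), seed = 1)
ds
#> Simulated 'flux' dataset: 100 train + 20 test sequences, 50 frames each
#> noise amplitude W = 0.010009 (target ratio 0.01)

fit <- fpe_fit(ds, n = 2)
fit
#> Fokker-Planck inverse fit ('flux'): 100 sequences, 110 bins, n = 2
#> 29 iterations (best at 9, stopped by patience); L_gh = 1966, L_P = 1.211e+04
#> final E_P = 0.002125, E_g = 0.3959, E_h = 0.08849
```

The denoised densities end up five times closer to the truth than the
observations (`E_P` 0.0021 against a noise level of 0.01), and the
recovered drift and diffusion are within a few percent of $2.86x$ and
$0.0013$ over the well-sampled interior of the grid:

```r
fp_metrics(fit, ds)
#> E_P = 0.002125 (noisy 0.01005, smoothed 0.005071)
#> E_g = 0.3959 (interior 0.1094)   E_h = 0.08849 (interior 0.06677)
#> first-iteration interior errors: g 1.63, h 0.8358
#> boundary bins: 26 of 110
```

`interior` errors exclude the boundary area — bins whose densities are
statistically below 1% of the observed maximum — where no method can
pin the terms down; the `first-iteration` line shows how far estimates
obtained from smoothing alone are from the truth before the alternating
training runs.  `coef(fit)` returns the per-bin estimates for plotting
(`plot(fit)` overlays the true curves), and forecasts of the held-out
sequences stay at a relative error of a few 0.001 over five future
frames:

```r
forecast_error(fit, ds)
#>   horizon        mean           sd
#> 1       1 0.002914189 0.0009573991
#> 2       2 0.002796484 0.0008420513
#> 3       3 0.003190565 0.0006975199
#> 4       4 0.003979055 0.0006817691
#> 5       5 0.005035306 0.0008302162
```

`fp_example("bubble")` and `fp_example("wealth")` run the same pipeline
on the other two reference systems; `vignettes/fokker-planck-inverse.Rmd`
explains the estimator, its tunable parameters and its limitations in
detail.

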