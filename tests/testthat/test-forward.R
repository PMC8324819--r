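test_that("reference systems evaluate their drift and diffusion vectors", {
  flux <- fp_terms(fp_example("flux"))
  i <- which.min(abs(flux$grid$x - 0.1))
  # g = theta x, h = D constant
  expect_equal(flux$g, 2.86 * flux$grid$x)
  expect_equal(flux$h, rep(0.0013, 110))
  bubble <- fp_terms(fp_example("bubble"))
  expect_equal(bubble$h, rep(0.5, 100))
  expect_equal(bubble$g, 1 / bubble$grid$x - 0.2)
  wealth <- fp_terms(fp_example("wealth"))
  j <- which.min(abs(wealth$grid$x - 1))
  expect_equal(wealth$g[j], wealth$grid$x[j] - 1)
  expect_equal(wealth$h, 0.2 * wealth$grid$x^2)
})

test_that("the bubble system rejects grids crossing the drift pole", {
  expect_error(fp_example("bubble", grid = fp_grid(-0.1, 1, 50)),
               class = "fpinverse_invalid")
})

test_that("the analytic OU density has the right moments and limits", {
  g <- fp_grid(-0.1, 0.1, 400)
  # long-time limit: mean 0, variance D / theta
  p <- ou_density(g, t = 50, D = 0.0013, theta = 2.86, x0 = 0.06)
  m1 <- sum(g$x * p) * g$dx
  m2 <- sum(g$x^2 * p) * g$dx - m1^2
  expect_lt(abs(m1), 1e-6)
  expect_equal(m2, 0.0013 / 2.86, tolerance = 1e-3)
  # short-time limit: mean -> x0
  p0 <- ou_density(g, t = 1e-3, D = 0.0013, theta = 2.86, x0 = 0.06)
  expect_lt(abs(sum(g$x * p0) * g$dx - 0.06), 1e-3)
  expect_error(ou_density(g, t = 0), class = "fpinverse_invalid")
  expect_error(ou_density(g, t = 1, D = -1), class = "fpinverse_invalid")
})

test_that("the discrete generator is linear and annihilates trivial input", {
  ex <- fp_example("flux")
  ops <- fd_operators(ex$grid)
  tr <- fp_terms(ex)
  B <- ex$grid$n_bins
  expect_equal(fpe_rhs(rep(0, B), tr, ops), rep(0, B))
  zero <- list(g = rep(0, B), h = rep(0, B))
  expect_equal(fpe_rhs(runif(B), zero, ops), rep(0, B))
  P1 <- ou_density(ex$grid, 0.05)
  P2 <- ou_density(ex$grid, 0.08)
  expect_equal(fpe_rhs(2 * P1 - 3 * P2, tr, ops),
               2 * fpe_rhs(P1, tr, ops) - 3 * fpe_rhs(P2, tr, ops))
  expect_error(fpe_rhs(rep(0, B - 1), tr, ops), class = "fpinverse_invalid")
})

test_that("the stationary OU density is an equilibrium of the generator", {
  ex <- fp_example("flux")
  ops <- fd_operators(ex$grid)
  tr <- fp_terms(ex)
  p_inf <- ou_density(ex$grid, t = 100)   # relaxed Gaussian
  rate <- fpe_rhs(p_inf, tr, ops)
  # interior rates vanish relative to the dynamic scale theta * max(P)
  expect_lt(max(abs(rate[10:100])), 1e-3 * 2.86 * max(p_inf))
})

test_that("RK4 reproduces the analytic OU path and conserves mass", {
  ex <- fp_example("flux")
  ops <- fd_operators(ex$grid)
  tr <- fp_terms(ex)
  P0 <- ou_density(ex$grid, 0.04, x0 = 0.06)
  expect_equal(rk4_solve(P0, tr, ops, ex$dt, 0), matrix(P0, 1))
  frames <- rk4_solve(P0, tr, ops, ex$dt, 20)
  errs <- vapply(0:20, function(k)
    fpinverse:::rel_l2(frames[k + 1, ],
                       ou_density(ex$grid, 0.04 + k * ex$dt, x0 = 0.06)),
    numeric(1))
  expect_lt(max(errs), 1e-3)
  # interior-supported density: discrete mass drift below 1e-6
  Pmid <- ou_density(ex$grid, 0.03, x0 = 0.05)
  fr <- rk4_solve(Pmid, tr, ops, ex$dt, 10)
  masses <- rowSums(fr) * ex$grid$dx
  expect_lt(max(abs(masses - masses[1])), 1e-6)
})

test_that("RK4 signals numeric failure instead of returning rubbish", {
  ex <- fp_example("bubble")
  ops <- fd_operators(ex$grid)
  tr <- fp_terms(ex)
  P0 <- dnorm(ex$grid$x, 0.5, 0.07)
  expect_error(rk4_solve(P0, tr, ops, dt = 100, n_steps = 25, substeps = 1),
               class = "fpinverse_numeric")
})
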