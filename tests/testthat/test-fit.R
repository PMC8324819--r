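test_that("exact-backend steps weakly decrease their own losses", {
  ds <- small_dataset("flux")
  ex <- ds$example
  ops <- fd_operators(ex$grid)
  P0 <- sg_smooth(ds$train)
  gh1 <- fpinverse:::gh_step(P0, ops, ex$dt, 2)
  P1 <- fpinverse:::p_step(P0, gh1, ops, ex$dt, 2)
  # gh-step: global (penalized) minimizer given P1 beats the old terms
  gh2 <- fpinverse:::gh_step(P1, ops, ex$dt, 2)
  l_old <- loss_gh(P1, gh1, ops, ex$dt, 2)
  l_new <- loss_gh(P1, gh2, ops, ex$dt, 2)
  expect_lte(l_new, l_old * (1 + 1e-8))
  # P-step: per-frame global minimizer beats the previous densities
  P2 <- fpinverse:::p_step(P0, gh2, ops, ex$dt, 2)
  lp_old <- fpinverse:::loss_p_total(P1, P0, gh2, ops, ex$dt, 2)
  lp_new <- fpinverse:::loss_p_total(P2, P0, gh2, ops, ex$dt, 2)
  expect_lte(lp_new, lp_old * (1 + 1e-8))
  # gradient P-step also moves downhill from its starting point
  P2g <- fpinverse:::p_step(P0, gh2, ops, ex$dt, 2, P_prev = P1, epochs = 10)
  lp_g <- fpinverse:::loss_p_total(P2g, P0, gh2, ops, ex$dt, 2)
  expect_lte(lp_g, lp_old * (1 + 1e-8))
})

test_that("with zero terms the P-step returns windowed target means", {
  g <- fp_grid(0, 1, 15)
  ops <- fd_operators(g)
  zero <- list(g = rep(0, 15), h = rep(0, 15))
  set.seed(41)
  P0 <- list(matrix(runif(7 * 15), 7, 15))
  out <- fpinverse:::p_step(P0, zero, ops, 0.01, 1)
  expect_equal(out[[1]][3, ], colMeans(P0[[1]][2:4, ]), tolerance = 1e-10)
  # edge frame uses its truncated window
  expect_equal(out[[1]][1, ], colMeans(P0[[1]][1:2, ]), tolerance = 1e-10)
})

test_that("training obeys the stopping contract and returns the best state", {
  fit <- small_fit("flux")
  h <- fit$history
  expect_identical(nrow(h), fit$iterations)
  expect_identical(fit$best_iter, which.min(h$total))
  if (fit$converged) {
    # the final `patience` iterations brought no appreciable improvement
    tail_tot <- h$total[(fit$best_iter + 1):fit$iterations]
    expect_true(all(tail_tot >= min(h$total) * (1 - 1e-4)))
    expect_gte(fit$iterations - fit$best_iter, 1L)
  }
  fit1 <- fpe_fit(small_dataset("flux"), n = 2, patience = 1, max_iter = 50)
  # patience 1: stops one iteration after the best total
  expect_identical(fit1$iterations, fit1$best_iter + 1L)
})

test_that("fitting is deterministic given the dataset and configuration", {
  ds <- small_dataset("wealth")
  f1 <- fpe_fit(ds, n = 2, max_iter = 6)
  f2 <- fpe_fit(ds, n = 2, max_iter = 6)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$P_hat, f2$P_hat)
  expect_identical(f1$history, f2$history)
})

test_that("training improves on the initialization and denoises", {
  fit <- small_fit("flux")
  ds <- small_dataset("flux")
  m <- fp_metrics(fit, ds)
  expect_lt(m$Et_g, m$initial$Et_g)
  expect_lt(m$Et_h, m$initial$Et_h)
  expect_lt(m$E_P, m$E_P_noisy)
})

test_that("input validation rejects malformed training requests", {
  ds <- small_dataset("flux")
  expect_error(fpe_fit(ds, n = 0), class = "fpinverse_invalid")
  expect_error(fpe_fit(ds, n = 12), class = "fpinverse_invalid")
  expect_error(fpe_fit(ds$train), class = "fpinverse_invalid") # no grid/dt
  expect_error(fpe_fit(ds, n = 2, patience = 0), class = "fpinverse_invalid")
})

test_that("the fitted-model methods are coherent", {
  fit <- small_fit("flux")
  ds <- small_dataset("flux")
  co <- coef(fit)
  expect_s3_class(co, "data.frame")
  expect_identical(nrow(co), 110L)
  expect_identical(names(co), c("x", "g", "h"))
  expect_identical(fitted(fit), fit$P_hat)
  res <- residuals(fit)
  expect_equal(res[[1]], fit$P0[[1]] - fit$P_hat[[1]])
  expect_output(print(fit), "Fokker-Planck inverse fit")
  expect_output(print(summary(fit)), "loss trace")
  # simulate draws fresh sequences under the fitted terms
  sims <- simulate(fit, nsim = 2, seed = 99, n_times = 4)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), c(4L, 110L))
  sims2 <- simulate(fit, nsim = 2, seed = 99, n_times = 4)
  expect_identical(sims, sims2)
  # predict returns horizon-by-bins forecasts
  pred <- predict(fit, ds$test[[1]], horizon = 3)
  expect_identical(dim(pred), c(3L, 110L))
})
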