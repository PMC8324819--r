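test_that("multi-offset Euler predictions are linear in the offset", {
  ex <- fp_example("flux")
  ops <- fd_operators(ex$grid)
  tr <- fp_terms(ex)
  P <- ou_density(ex$grid, 0.05)
  pred <- predict_offsets(P, tr, ops, ex$dt, c(-3, 0, 3))
  expect_equal(pred[2, ], P)
  expect_equal(pred[1, ] + pred[3, ], 2 * P)
  # mass is preserved up to edge terms for an interior-supported density
  Pmid <- ou_density(ex$grid, 0.03, x0 = 0.05)
  pm <- predict_offsets(Pmid, tr, ops, ex$dt, -2:2)
  expect_lt(max(abs(rowSums(pm) - sum(Pmid)) * ex$grid$dx), 1e-6)
})

test_that("the drift/diffusion loss is zero, quadratic and truncation-small", {
  ds <- small_dataset("flux")
  ex <- ds$example
  ops <- fd_operators(ex$grid)
  tr <- fp_terms(ex)
  # n = 0: every prediction equals its own target
  expect_equal(loss_gh(ds$clean_train, tr, ops, ex$dt, 0), 0)
  # doubling the densities quadruples the quadratic loss
  l1 <- loss_gh(ds$clean_train, tr, ops, ex$dt, 2)
  l2 <- loss_gh(lapply(ds$clean_train, `*`, 2), tr, ops, ex$dt, 2)
  expect_equal(l2, 4 * l1, tolerance = 1e-10)
  # with the true terms on clean data only Euler truncation remains:
  # far below the loss of a detuned model
  detuned <- list(g = 2 * tr$g, h = 2 * tr$h)
  expect_lt(l1, 0.01 * loss_gh(ds$clean_train, detuned, ops, ex$dt, 2))
})

test_that("the density loss is minimized in closed form (oracle match)", {
  # small grid so a generic numerical optimizer is a practical oracle
  g <- fp_grid(0, 1, 12)
  ops <- fd_operators(g)
  set.seed(31)
  terms <- list(g = runif(12, -1, 1), h = runif(12, 0.1, 0.3))
  dt <- 0.01
  targets <- matrix(abs(rnorm(5 * 12, 1, 0.3)), 5, 12)
  offsets <- -2:2
  L <- fpinverse:::build_L(terms, ops)
  exact <- fpinverse:::solve_state(targets, offsets, L, dt)
  num <- optim(targets[3, ],
               function(P) loss_p(P, targets, offsets, terms, ops, dt),
               method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
  expect_lt(fpinverse:::rel_l2(num, exact), 1e-5)
  expect_lt(loss_p(exact, targets, offsets, terms, ops, dt),
            loss_p(targets[3, ], targets, offsets, terms, ops, dt) + 1e-12)
})

test_that("with no dynamics the optimal frame is the target mean", {
  g <- fp_grid(0, 1, 15)
  ops <- fd_operators(g)
  zero <- list(g = rep(0, 15), h = rep(0, 15))
  set.seed(32)
  targets <- matrix(runif(3 * 15), 3, 15)
  L <- fpinverse:::build_L(zero, ops)
  out <- fpinverse:::solve_state(targets, -1:1, L, 0.01)
  expect_equal(as.vector(out), colMeans(targets), tolerance = 1e-10)
})

test_that("the backward-window loss reduces to a plain distance at r = 0", {
  g <- fp_grid(0, 1, 10)
  ops <- fd_operators(g)
  set.seed(33)
  terms <- list(g = runif(10), h = runif(10, 0.1, 0.2))
  target <- runif(10)
  P <- runif(10)
  expect_equal(loss_app(P, rbind(target), terms, ops, 0.01),
               sum((P - target)^2))
  # and the r = 0 state fit returns the target itself
  out <- estimate_state(rbind(target), terms, ops, 0.01, smooth = FALSE)
  expect_equal(out, target, tolerance = 1e-9)
})

test_that("wider offset windows suppress noise in derivative responses", {
  # Monte-Carlo: the multi-offset response sum_i i P(t+i) / (S2 dt)
  # estimates dP/dt; with i.i.d. multiplicative target noise its variance
  # shrinks as the window widens
  ex <- fp_example("flux")
  dt <- ex$dt
  clean <- t(vapply(0:16, function(k) ou_density(ex$grid, 0.04 + k * dt),
                    numeric(110)))
  truth <- (clean[10, ] - clean[8, ]) / (2 * dt)   # reference slope at t = 9
  mse <- sapply(c(1, 4), function(n) {
    S2 <- 2 * sum(seq_len(n)^2)
    set.seed(34)
    errs <- replicate(40, {
      noisy <- clean * (1 + 0.01 * matrix(rnorm(length(clean)), nrow(clean)))
      est <- colSums(noisy[9 + (-n:n), ] * (-n:n)) / (S2 * dt)
      sum((est - truth)^2)
    })
    mean(errs)
  })
  expect_lt(mse[2], mse[1])
})
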