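#' Fit Fokker-Planck drift/diffusion terms and denoised densities
#'
#' Solves the inverse problem of the one-dimensional, time-independent
#' Fokker-Planck equation from noisy density sequences.  The observations
#' are first Savitzky-Golay smoothed (`P0`, the fixed fitting target) and
#' an initial `(g, h)` obtained by stacked linear least squares
#' ([lls_init()]).  Each subsequent iteration alternates two steps on the
#' quadratic training objectives:
#'
#' * **gh-step**: with the current density estimate fixed, minimize
#'   [loss_gh()] over `(g, h)` -- one curvature-penalized least-squares
#'   solve in the `2 B` per-bin unknowns, pooled over all eligible frames
#'   of all training sequences.
#' * **P-step**: with `(g, h)` fixed, update every frame against the
#'   density-fitting loss (targets are always the smoothed observations
#'   `P0`, never re-updated); frames near a sequence edge use their
#'   truncated offset window.
#'
#' With the default `backend = "gradient"` the P-step performs `p_epochs`
#' plain gradient-descent passes per frame from the frame's previous
#' value, evaluated in closed form (the subproblem is quadratic, so the
#' gradient trajectory has an exact spectral expression and the update is
#' deterministic).  This incremental schedule denoises the fast,
#' strongly-determined components of each frame first while leaving the
#' slow components near the data, which is how iterative network-style
#' training behaves; it is essential for stiff systems, where the exact
#' per-frame minimizer visibly over-smooths genuine structure.
#' `backend = "exact"` instead jumps to the exact per-frame minimizer
#' (one SPD solve); both losses then decrease monotonically per step.
#'
#' Training stops when the summed loss fails to improve its running best
#' by a relative `improvement` for `patience` consecutive iterations, or
#' after `max_iter` iterations; the state of the best recorded total is
#' returned.
#'
#' @param data an [fp_simulate()] dataset (its training split is used), or
#'   a list of frames-by-bins matrices of noisy densities.
#' @param n offset half-width: predictions are compared at the `2 n + 1`
#'   neighboring frames `-n, ..., n`.  Larger `n` averages away more target
#'   noise at the price of Euler truncation error.
#' @param grid,dt required when `data` is a plain list; taken from the
#'   dataset otherwise.
#' @param accuracy finite-difference stencil accuracy (default 4).
#' @param backend `"gradient"` (incremental P-step, default) or `"exact"`
#'   (per-frame exact minimizer); see Details.
#' @param p_epochs gradient passes per P-step and frame (gradient backend).
#' @param sg_window,sg_degree Savitzky-Golay window (bins) and degree.
#' @param patience stopping patience in iterations (default 20).
#' @param max_iter iteration cap (default 100).
#' @param improvement relative improvement threshold of the summed loss;
#'   an iteration improving by less counts toward the patience.
#' @param smooth curvature-penalty strength of the gh-step solve, relative
#'   to the top eigenvalue of the block-scaled normal matrix.  The penalty
#'   (squared second differences of `g` and of `h` across bins) regularizes
#'   the locally collinear drift-vs-diffusion split where densities are
#'   small and extends both vectors linearly into bins without data.
#' @param ridge tiny spectral jitter for numerical definiteness.
#' @param truth optional list with elements `clean` (list of clean series)
#'   and `terms` (an [fp_terms()]); filled in automatically from a
#'   simulated dataset.  When available, normalized errors are recorded
#'   per iteration.
#' @param alpha significance level of the boundary-area t-test used for
#'   the interior error trace.
#' @param verbose print a line every 10 iterations.
#' @return An object of class `fpe_fit`: `coefficients` (list `g`, `h`),
#'   denoised series `P_hat`, smoothed targets `P0`, `init` (the LLS
#'   estimates `g0`, `h0` and the first-iteration weights `g1`, `h1`),
#'   per-iteration `history`, `best_iter`, `converged`, and the
#'   configuration.  Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `plot`, `predict`, `simulate`.
#' @seealso [fp_metrics()], [forecast_error()], [predict.fpe_fit()]
#' @examples
#' ds <- fp_simulate(fp_example("flux"), n_sequences = 6, n_times = 12,
#'                   n_train = 4, seed = 1)
#' fit <- fpe_fit(ds, n = 2, max_iter = 5)
#' head(coef(fit))
#' @export
fpe_fit <- function(data, n = 2L, grid = NULL, dt = NULL, accuracy = 4L,
                    backend = c("gradient", "exact"), p_epochs = 30L,
                    sg_window = 9L, sg_degree = 3L,
                    patience = 20L, max_iter = 100L,
                    improvement = 1e-4, smooth = 3e-3, ridge = 1e-12,
                    truth = NULL, alpha = 0.05, verbose = FALSE) {
  backend <- match.arg(backend)
  cl <- match.call()
  example <- NULL
  if (inherits(data, "fp_dataset")) {
    series <- data$train
    grid <- data$example$grid
    dt <- data$example$dt
    example <- data$example
    if (is.null(truth))
      truth <- list(clean = data$clean_train, terms = fp_terms(data$example))
  } else {
    series <- if (is.list(data)) data else list(data)
    if (is.null(grid) || is.null(dt))
      stop(fp_condition("grid and dt are required for plain series input",
                        "fpinverse_invalid"))
  }
  n <- as.integer(n)
  if (n < 1L) stop(fp_condition("n must be >= 1", "fpinverse_invalid"))
  if (patience < 1L) stop(fp_condition("patience must be >= 1",
                                       "fpinverse_invalid"))
  if (any(vapply(series, nrow, 1L) < 2L * n + 1L))
    stop(fp_condition("sequences shorter than 2n + 1 frames",
                      "fpinverse_invalid"))
  ops <- fd_operators(grid, accuracy)

  P0 <- sg_smooth(series, sg_window, sg_degree)
  init <- lls_init(P0, ops, dt, smooth, ridge)
  have_truth <- !is.null(truth)
  mask <- if (have_truth) boundary_mask(series, alpha = alpha) else NULL

  P_cur <- P0
  hist <- vector("list", max_iter)
  best <- list(total = Inf, iter = 0L)
  g1h1 <- NULL
  stall <- 0L
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    gh <- gh_step(P_cur, ops, dt, n, smooth, ridge)
    l_gh <- loss_gh(P_cur, gh, ops, dt, n)
    if (k == 1L) g1h1 <- gh
    P_cur <- p_step(P0, gh, ops, dt, n, P_prev = P_cur,
                    epochs = if (backend == "gradient") p_epochs else NULL)
    l_p <- loss_p_total(P_cur, P0, gh, ops, dt, n)
    total <- l_gh + l_p
    rec <- data.frame(iter = k, L_gh = l_gh, L_P = l_p, total = total)
    if (have_truth) {
      rec$E_P <- rel_l2(P_cur, truth$clean)
      rec$E_g <- rel_l2(gh$g, truth$terms$g)
      rec$E_h <- rel_l2(gh$h, truth$terms$h)
      rec$Et_g <- rel_l2(gh$g[!mask], truth$terms$g[!mask])
      rec$Et_h <- rel_l2(gh$h[!mask], truth$terms$h[!mask])
    }
    hist[[k]] <- rec
    if (total < best$total * (1 - improvement)) {
      best <- list(total = total, iter = k, gh = gh, P_hat = P_cur)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (verbose && k %% 10L == 0L)
      message(sprintf("iter %3d: L_gh %.4g  L_P %.4g", k, l_gh, l_p))
    if (stall >= patience) break
  }
  history <- do.call(rbind, hist[seq_len(k)])
  structure(
    list(coefficients = best$gh, P_hat = best$P_hat, P0 = P0,
         init = list(g0 = init$g, h0 = init$h, g1 = g1h1$g, h1 = g1h1$h),
         history = history, best_iter = best$iter, iterations = k,
         converged = stall >= patience,
         grid = grid, dt = dt, n = n, accuracy = as.integer(accuracy),
         backend = backend, p_epochs = as.integer(p_epochs),
         sg = list(window = sg_window, degree = sg_degree),
         smooth = smooth, ridge = ridge, patience = patience, boundary = mask,
         example = example, call = cl),
    class = "fpe_fit")
}

# Exact gh-step: global minimizer of loss_gh given the current densities.
# The normal equations reduce to the lls_init system with the response
# sum_i i * P(t + i) / (S2 * dt), a multi-offset time-derivative estimate.
gh_step <- function(P_list, ops, dt, n, smooth = 1e-2, ridge = 1e-12) {
  B <- nrow(ops$D1)
  S2 <- 2 * sum(seq_len(n)^2)
  C <- matrix(0, B, B)
  rg <- rh <- numeric(B)
  any_center <- FALSE
  for (Pm in P_list) {
    Tn <- nrow(Pm)
    if (Tn < 2L * n + 1L) next
    any_center <- TRUE
    tt <- (n + 1L):(Tn - n)
    Cm <- matrix(0, length(tt), B)
    for (i in c(-(n:1), 1:n))
      Cm <- Cm + i * Pm[tt + i, , drop = FALSE]
    Pc <- Pm[tt, , drop = FALSE]
    C <- C + crossprod(Pc)
    rg <- rg + colSums(Pc * (Cm %*% ops$D1))
    rh <- rh + colSums(Pc * (Cm %*% ops$D2))
  }
  if (!any_center)
    stop(fp_condition("no eligible center frames for the gh-step",
                      "fpinverse_degenerate"))
  solve_gh_normal(C, rg / (S2 * dt), rh / (S2 * dt), ops, smooth, ridge)
}

# P-step with fixed (g, h); targets are always the smoothed observations
# P0.  With epochs = NULL every frame jumps to the exact per-frame
# minimizer of the density-fitting loss (one SPD solve per offset
# pattern).  With a finite epoch count each frame instead takes that many
# plain gradient-descent steps from its previous value P_prev (step size
# 1/lambda_max), evaluated in closed form through the eigendecomposition
# of the quadratic's normal matrix:
#   x_K = x0 + V phi(lambda) V' (rhs - H x0),
#   phi(lambda) = (1 - (1 - eta lambda)^K) / lambda.
p_step <- function(P0_list, terms, ops, dt, n, P_prev = NULL,
                   epochs = NULL) {
  L <- build_L(terms, ops)
  B <- nrow(L)
  gradient <- !is.null(epochs)
  if (gradient && is.null(P_prev))
    stop(fp_condition("gradient P-step needs the previous densities",
                      "fpinverse_invalid"))
  cache <- new.env(parent = emptyenv())
  fact_for <- function(io) {
    key <- paste(range(io), collapse = ":")
    if (is.null(cache[[key]])) {
      H <- state_normal_matrix(io, L, dt)
      cache[[key]] <- if (!gradient) {
        chol(H)
      } else {
        ed <- eigen((H + t(H)) / 2, symmetric = TRUE)
        lam <- pmax(ed$values, 0)
        eta <- 1 / max(lam)
        x <- pmin(eta * lam, 1)
        phi <- ifelse(lam > 1e-300 * max(lam),
                      (1 - (1 - x)^epochs) / lam, epochs * eta)
        list(V = ed$vectors, lam = lam, phi = phi)
      }
    }
    cache[[key]]
  }
  advance <- function(fac, RHS, X0) {
    if (!gradient) return(backsolve_chol(fac, RHS))
    HX0 <- fac$V %*% (fac$lam * crossprod(fac$V, X0))
    X0 + fac$V %*% (fac$phi * crossprod(fac$V, RHS - HX0))
  }
  lapply(seq_along(P0_list), function(s) {
    P0m <- P0_list[[s]]
    Pm <- if (gradient) P_prev[[s]] else NULL
    Tn <- nrow(P0m)
    new <- matrix(NA_real_, Tn, B)
    tt <- if (Tn >= 2L * n + 1L) (n + 1L):(Tn - n) else integer(0)
    if (length(tt)) {
      S0 <- matrix(0, length(tt), B)
      S1 <- matrix(0, length(tt), B)
      for (i in (-n):n) {
        S0 <- S0 + P0m[tt + i, , drop = FALSE]
        if (i != 0L) S1 <- S1 + i * P0m[tt + i, , drop = FALSE]
      }
      RHS <- t(S0 + dt * (S1 %*% L))
      X0 <- if (gradient) t(Pm[tt, , drop = FALSE]) else NULL
      new[tt, ] <- t(advance(fact_for((-n):n), RHS, X0))
    }
    for (t in setdiff(seq_len(Tn), tt)) {
      io <- offset_window(t, Tn, n)
      q <- P0m[t + io, , drop = FALSE]
      rhs <- colSums(q) + dt * as.vector(crossprod(L, colSums(q * io)))
      x0 <- if (gradient) matrix(Pm[t, ]) else NULL
      new[t, ] <- advance(fact_for(io), matrix(rhs), x0)
    }
    new
  })
}

# total P-loss over all frames, each with its (possibly truncated) window
loss_p_total <- function(P_list, P0_list, terms, ops, dt, n) {
  L <- build_L(terms, ops)
  tot <- 0
  for (s in seq_along(P_list)) {
    Pm <- P_list[[s]]
    P0m <- P0_list[[s]]
    Tn <- nrow(Pm)
    Q <- Pm %*% t(L)
    for (i in (-n):n) {
      tt <- max(1L, 1L - i):min(Tn, Tn - i)
      R <- Pm[tt, , drop = FALSE] + (i * dt) * Q[tt, , drop = FALSE] -
        P0m[tt + i, , drop = FALSE]
      tot <- tot + sum(R^2)
    }
  }
  tot
}

#' @export
print.fpe_fit <- function(x, ...) {
  cat(sprintf(
    "Fokker-Planck inverse fit%s: %d sequences, %d bins, n = %d\n",
    if (!is.null(x$example)) sprintf(" ('%s')", x$example$name) else "",
    length(x$P_hat), x$grid$n_bins, x$n))
  cat(sprintf("%d iterations (best at %d, %s); L_gh = %.4g, L_P = %.4g\n",
              x$iterations, x$best_iter,
              if (x$converged) "stopped by patience" else "hit max_iter",
              x$history$L_gh[x$best_iter], x$history$L_P[x$best_iter]))
  if (!is.null(x$history$E_P))
    cat(sprintf("final E_P = %.4g, E_g = %.4g, E_h = %.4g\n",
                x$history$E_P[x$best_iter], x$history$E_g[x$best_iter],
                x$history$E_h[x$best_iter]))
  invisible(x)
}

#' @export
summary.fpe_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fpe_fit")
}

#' @export
print.summary.fpe_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  h <- f$history
  cat(sprintf("loss trace: L_gh %.4g -> %.4g, L_P %.4g -> %.4g\n",
              h$L_gh[1], h$L_gh[f$best_iter], h$L_P[1], h$L_P[f$best_iter]))
  if (!is.null(h$E_P)) {
    cat(sprintf("error trace: E_P %.4g -> %.4g, E_g %.4g -> %.4g, E_h %.4g -> %.4g\n",
                h$E_P[1], h$E_P[f$best_iter], h$E_g[1], h$E_g[f$best_iter],
                h$E_h[1], h$E_h[f$best_iter]))
    cat(sprintf("interior (non-boundary) errors: Et_g = %.4g, Et_h = %.4g over %d bins\n",
                h$Et_g[f$best_iter], h$Et_h[f$best_iter], sum(!f$boundary)))
  }
  invisible(x)
}

#' @export
coef.fpe_fit <- function(object, ...) {
  data.frame(x = object$grid$x, g = object$coefficients$g,
             h = object$coefficients$h)
}

#' @export
fitted.fpe_fit <- function(object, ...) object$P_hat

#' Residuals of a Fokker-Planck inverse fit
#'
#' Differences between the smoothed observations and the denoised
#' densities, one matrix per training sequence.
#'
#' @param object an [fpe_fit()] result.
#' @param ... unused.
#' @export
residuals.fpe_fit <- function(object, ...) {
  mapply(function(a, b) a - b, object$P0, object$P_hat, SIMPLIFY = FALSE)
}

#' Plot a Fokker-Planck inverse fit
#'
#' `which = "terms"` draws the recovered drift and diffusion vectors
#' against the bin centers (with the true curves overlaid when known);
#' `which = "loss"` draws the loss trace.
#'
#' @param x an [fpe_fit()] result.
#' @param which `"terms"` or `"loss"`.
#' @param truth optional [fp_terms()] to overlay (defaults to the true
#'   terms of the simulated example when available).
#' @param ... passed to the underlying plot calls.
#' @export
plot.fpe_fit <- function(x, which = c("terms", "loss"), truth = NULL, ...) {
  which <- match.arg(which)
  if (which == "loss") {
    graphics::matplot(x$history$iter, cbind(x$history$L_gh, x$history$L_P),
                      type = "l", lty = 1, col = c(2, 4), log = "y",
                      xlab = "iteration", ylab = "loss", ...)
    graphics::legend("topright", c("L_gh", "L_P"), lty = 1, col = c(2, 4))
    return(invisible(x))
  }
  if (is.null(truth) && !is.null(x$example)) truth <- fp_terms(x$example)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (term in c("g", "h")) {
    graphics::plot(x$grid$x, x$coefficients[[term]], pch = 5, cex = 0.6,
                   xlab = "x", ylab = term, ...)
    if (!is.null(truth)) graphics::lines(x$grid$x, truth[[term]])
  }
  invisible(x)
}

#' Simulate new density sequences from a fitted model
#'
#' Advances the fitted drift/diffusion terms with [rk4_solve()] from fresh
#' initial conditions, producing sequences distributed like the training
#' data under the fitted dynamics.
#'
#' @param object an [fpe_fit()] result.
#' @param nsim number of sequences.
#' @param seed optional integer seed.
#' @param n_times frames per sequence.
#' @param init optional matrix of initial densities (bins x nsim) or a
#'   function returning one density vector per call; defaults to the
#'   initial-condition sampler of the fitted example.
#' @param ... unused.
#' @return A list of `n_times x n_bins` matrices.
#' @export
simulate.fpe_fit <- function(object, nsim = 1, seed = NULL, n_times = 50L,
                             init = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  B <- object$grid$n_bins
  draw <- if (is.function(init)) {
    init
  } else if (is.matrix(init)) {
    k <- 0L
    function() { k <<- k + 1L; init[, k] }
  } else if (!is.null(object$example)) {
    function() sample_initial_state(object$example)$P
  } else {
    stop(fp_condition("no initial-condition sampler available; supply init",
                      "fpinverse_invalid"))
  }
  ops <- fd_operators(object$grid, object$accuracy)
  lapply(seq_len(nsim), function(s)
    rk4_solve(draw(), object$coefficients, ops, object$dt, n_times - 1L))
}
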