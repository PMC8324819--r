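#' Fit the latest state of an observed sequence
#'
#' Given the last `r + 1` observed (noisy) frames of a sequence and trained
#' drift/diffusion terms, recovers the density at the final observed time
#' by fitting the backward-window loss [loss_app()]: Euler predictions
#' from the candidate state at offsets `-r, ..., 0` are matched against
#' the Savitzky-Golay-smoothed observations.  With `epochs = NULL` the
#' exact minimizer is returned (one SPD solve); with a finite epoch count
#' the state takes that many closed-form gradient passes from the smoothed
#' frame at the latest time, mirroring the incremental P-step of the
#' gradient backend.
#'
#' @param observed matrix with `r + 1` rows, the frames at offsets
#'   `-r, ..., 0` (last row = latest time).
#' @param terms trained drift/diffusion vectors.
#' @param ops an [fd_operators()].
#' @param dt frame time gap.
#' @param smooth smooth the observed frames first (default `TRUE`).
#' @param sg_window,sg_degree Savitzky-Golay parameters.
#' @param epochs `NULL` for the exact solve, or the number of gradient
#'   passes.
#' @return The fitted density vector at the latest observed time.
#' @export
estimate_state <- function(observed, terms, ops, dt, smooth = TRUE,
                           sg_window = 9L, sg_degree = 3L,
                           epochs = NULL) {
  observed <- rbind(observed)
  if (smooth && nrow(observed) > 0L)
    observed <- sg_smooth(observed, sg_window, sg_degree)
  r <- nrow(observed) - 1L
  L <- build_L(terms, ops)
  io <- (-r):0L
  out <- tryCatch({
    if (is.null(epochs)) {
      solve_state(observed, io, L, dt)
    } else {
      H <- state_normal_matrix(io, L, dt)
      ed <- eigen((H + t(H)) / 2, symmetric = TRUE)
      lam <- pmax(ed$values, 0)
      eta <- 1 / max(lam)
      phi <- ifelse(lam > 1e-300 * max(lam),
                    (1 - (1 - pmin(eta * lam, 1))^epochs) / lam, epochs * eta)
      q0 <- colSums(observed)
      rhs <- q0 + dt * as.vector(crossprod(L, colSums(observed * io)))
      x0 <- observed[r + 1L, ]
      Hx0 <- ed$vectors %*% (lam * crossprod(ed$vectors, x0))
      x0 + ed$vectors %*% (phi * crossprod(ed$vectors, rhs - Hx0))
    }
  }, error = function(e)
    stop(fp_condition(paste0("state system could not be solved: ",
                             conditionMessage(e)), "fpinverse_numeric")))
  as.vector(out)
}

#' Forecast future density frames
#'
#' Single-step Euler extrapolations of a fitted state: the frame at
#' horizon `i` is `P + i * dt * (D1 (g P) + D2 (h P))`, each computed from
#' the same fitted state (not iterated).
#'
#' @param P fitted density at the last observed time.
#' @param terms trained drift/diffusion vectors.
#' @param ops an [fd_operators()].
#' @param dt frame time gap.
#' @param horizon number of future frames (default 5).
#' @return A `horizon x n_bins` matrix, row `i` at time `t + i * dt`.
#' @export
forecast_density <- function(P, terms, ops, dt, horizon = 5L) {
  if (horizon < 1L) stop(fp_condition("horizon must be >= 1",
                                      "fpinverse_invalid"))
  predict_offsets(P, terms, ops, dt, seq_len(horizon))
}

#' Predict future distributions from a fitted model
#'
#' For each supplied sequence of noisy frames, fits the latest state from
#' its last `r + 1` frames ([estimate_state()]) and extrapolates `horizon`
#' frames ahead ([forecast_density()]).
#'
#' @param object an [fpe_fit()] result.
#' @param newdata a frames-by-bins matrix or a list of them.
#' @param horizon forecast horizon in frames (default 5).
#' @param r backward window half-width; defaults to the training `n`.
#' @param smooth smooth the observed frames first.
#' @param ... unused.
#' @return A `horizon x n_bins` matrix, or a list of them for list input.
#' @export
predict.fpe_fit <- function(object, newdata, horizon = 5L, r = object$n,
                            smooth = TRUE, ...) {
  ops <- fd_operators(object$grid, object$accuracy)
  one <- function(Pm) {
    Tn <- nrow(Pm)
    if (Tn < r + 1L)
      stop(fp_condition("sequence shorter than r + 1 frames",
                        "fpinverse_invalid"))
    Pfit <- estimate_state(Pm[(Tn - r):Tn, , drop = FALSE],
                           object$coefficients, ops, object$dt,
                           smooth = smooth, sg_window = object$sg$window,
                           sg_degree = object$sg$degree,
                           epochs = fit_epochs(object))
    forecast_density(Pfit, object$coefficients, ops, object$dt, horizon)
  }
  if (is.list(newdata)) lapply(newdata, one) else one(newdata)
}

#' Forecasting error on the held-out sequences
#'
#' For every test sequence the state at the frame `horizon` steps before
#' the sequence end is fitted from the preceding `r + 1` noisy frames, the
#' remaining frames are forecast, and each horizon's relative L2 error
#' against the clean simulated frame is recorded.  Reported as mean and
#' standard deviation over the test sequences.
#'
#' @param fit an [fpe_fit()] result.
#' @param dataset the [fp_simulate()] dataset providing the test split.
#' @param horizon forecast horizon (default 5).
#' @param r backward window; defaults to the training `n`.
#' @return A data frame with columns `horizon`, `mean`, `sd`.
#' @export
forecast_error <- function(fit, dataset, horizon = 5L, r = fit$n) {
  stopifnot(inherits(dataset, "fp_dataset"))
  ops <- fd_operators(fit$grid, fit$accuracy)
  errs <- vapply(seq_along(dataset$test), function(s) {
    Pm <- dataset$test[[s]]
    Cm <- dataset$clean_test[[s]]
    Tn <- nrow(Pm)
    t0 <- Tn - horizon
    if (t0 < r + 1L)
      stop(fp_condition("test sequence too short for this r and horizon",
                        "fpinverse_invalid"))
    Pfit <- estimate_state(Pm[(t0 - r):t0, , drop = FALSE],
                           fit$coefficients, ops, fit$dt,
                           sg_window = fit$sg$window,
                           sg_degree = fit$sg$degree,
                           epochs = fit_epochs(fit))
    pred <- forecast_density(Pfit, fit$coefficients, ops, fit$dt, horizon)
    vapply(seq_len(horizon), function(i)
      rel_l2(pred[i, ], Cm[t0 + i, ]), numeric(1))
  }, numeric(horizon))
  errs <- matrix(errs, nrow = horizon)
  data.frame(horizon = seq_len(horizon),
             mean = rowMeans(errs),
             sd = apply(errs, 1L, stats::sd))
}

# epochs to use for state fitting, matching the training backend
fit_epochs <- function(fit) {
  if (identical(fit$backend, "gradient")) fit$p_epochs else NULL
}
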