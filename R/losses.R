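#' Multi-offset Euler predictions
#'
#' From a single density frame, predicts the frames `i * dt` away for each
#' offset `i` by one explicit Euler step of the discrete Fokker-Planck
#' equation: `P + i * dt * (D1 (g P) + D2 (h P))`.  No renormalization is
#' applied; the generator preserves mass up to edge terms, so predictions
#' of an interior-supported density keep unit mass automatically.
#'
#' @param P density vector.
#' @param terms drift/diffusion vectors.
#' @param ops an [fd_operators()].
#' @param dt frame time gap.
#' @param offsets integer vector of time-gap multiples (may include 0 and
#'   negative values).
#' @return A matrix with one row per offset.
#' @export
predict_offsets <- function(P, terms, ops, dt, offsets) {
  rhs <- fpe_rhs(P, terms, ops)
  t(vapply(offsets, function(i) P + (i * dt) * rhs, numeric(length(P))))
}

# offsets eligible as prediction targets for center frame t (1-based)
# within a sequence of Tn frames, clipped to the half-width n
offset_window <- function(t, Tn, n) max(1L - t, -n):min(Tn - t, n)

#' Drift/diffusion training loss
#'
#' Sum over all eligible center frames (those with a full offset window)
#' and offsets `i in -n:n` of the squared L2 distance between the Euler
#' prediction from frame `t` and the stored frame at `t + i`.  This is the
#' objective minimized by the gh-step of [fpe_fit()]; both predictions and
#' targets are taken from `series` (the current density estimate).
#'
#' @param series frames-by-bins matrix or list of them.
#' @param terms drift/diffusion vectors.
#' @param ops an [fd_operators()].
#' @param dt frame time gap.
#' @param n offset half-width (`n >= 0`).
#' @return Nonnegative scalar.
#' @export
loss_gh <- function(series, terms, ops, dt, n) {
  if (!is.list(series)) series <- list(series)
  n <- as.integer(n)
  L <- build_L(terms, ops)
  tot <- 0
  for (Pm in series) {
    Tn <- nrow(Pm)
    if (Tn < 2L * n + 1L) next
    tt <- (n + 1L):(Tn - n)
    Q <- Pm %*% t(L)
    for (i in (-n):n) {
      R <- Pm[tt, , drop = FALSE] + (i * dt) * Q[tt, , drop = FALSE] -
        Pm[tt + i, , drop = FALSE]
      tot <- tot + sum(R^2)
    }
  }
  tot
}

#' Density-fitting loss for one frame
#'
#' Squared-error objective of the P-step: Euler predictions from the
#' candidate frame `P` at the given offsets, compared with fixed target
#' frames (the smoothed observations).  Quadratic and convex in `P`.
#'
#' @param P candidate density frame.
#' @param targets matrix of target frames, one row per entry of `offsets`.
#' @param offsets integer offsets.
#' @inheritParams loss_gh
#' @return Nonnegative scalar.
#' @export
loss_p <- function(P, targets, offsets, terms, ops, dt) {
  targets <- rbind(targets)
  if (nrow(targets) != length(offsets))
    stop(fp_condition("one target row per offset required",
                      "fpinverse_invalid"))
  pred <- predict_offsets(P, terms, ops, dt, offsets)
  sum((pred - targets)^2)
}

#' Latest-state fitting loss
#'
#' [loss_p()] with the backward offset window `{-r, ..., 0}` used when
#' fitting the latest state of a held-out sequence before forecasting.
#'
#' @param P candidate density frame at the final observed time.
#' @param targets matrix with `r + 1` rows: the (smoothed) observed frames
#'   at offsets `-r, ..., 0`.
#' @inheritParams loss_gh
#' @return Nonnegative scalar.
#' @export
loss_app <- function(P, targets, terms, ops, dt) {
  targets <- rbind(targets)
  r <- nrow(targets) - 1L
  loss_p(P, targets, (-r):0L, terms, ops, dt)
}

# Exact minimizer of sum_i || (I + i dt L) P - q_i ||^2 over P.
# targets: one row per offset.  Shared by the P-step and state fitting.
solve_state <- function(targets, offsets, L, dt, ch = NULL) {
  targets <- rbind(targets)
  m <- length(offsets)
  if (is.null(ch)) ch <- chol(state_normal_matrix(offsets, L, dt))
  q0 <- colSums(targets)
  q1 <- colSums(targets * offsets) # recycles down columns (rows = offsets)
  rhs <- q0 + dt * as.vector(crossprod(L, q1))
  backsolve_chol(ch, rhs)
}

state_normal_matrix <- function(offsets, L, dt) {
  m <- length(offsets)
  s1 <- sum(offsets)
  s2 <- sum(offsets^2)
  H <- diag(m, nrow(L)) + (s2 * dt^2) * crossprod(L)
  if (s1 != 0) H <- H + (s1 * dt) * (L + t(L))
  H
}
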