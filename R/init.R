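#' Savitzky-Golay smoothing of density frames
#'
#' Smooths each frame independently along the spatial axis with a local
#' polynomial (Savitzky-Golay) filter; the time axis is untouched.  The
#' filter reproduces polynomials up to `degree` exactly, so it does not
#' bias features wider than the window.
#'
#' @param series a frames-by-bins matrix or a list of them.
#' @param window odd window length in bins (default 7).
#' @param degree polynomial degree, `1 <= degree < window` (default 3).
#' @return The smoothed series, same shape.
#' @export
sg_smooth <- function(series, window = 7L, degree = 3L) {
  if (is.list(series))
    return(lapply(series, sg_smooth, window = window, degree = degree))
  window <- as.integer(window); degree <- as.integer(degree)
  if (window %% 2L == 0L || degree < 1L || degree >= window)
    stop(fp_condition("need odd window and 1 <= degree < window",
                      "fpinverse_invalid"))
  if (window > ncol(series))
    stop(fp_condition("smoothing window exceeds the number of bins",
                      "fpinverse_invalid"))
  t(apply(series, 1L, signal::sgolayfilt, p = degree, n = window))
}

# Solve the stacked normal equations of  dP/dt ~ D1 diag(P) g + D2 diag(P) h
# given the accumulated moments
#   C  = sum_t P_t P_t'          (B x B)
#   rg = sum_t P_t o (D1' r_t),  rh = sum_t P_t o (D2' r_t)
# with a curvature (second-difference) penalty on g and h plus a tiny
# spectral ridge.  The penalty regularizes the locally collinear
# drift-vs-diffusion decomposition where the densities are small and
# extrapolates both vectors linearly into bins the data never visit;
# its strength is relative to the top eigenvalue of the block-scaled
# normal matrix.  Returns list(g, h).
solve_gh_normal <- function(C, rg, rh, ops, smooth = 1e-2, ridge = 1e-12) {
  B <- nrow(C)
  G12 <- crossprod(ops$D1, ops$D2) * C
  G <- rbind(cbind(crossprod(ops$D1) * C, G12),
             cbind(t(G12), crossprod(ops$D2) * C))
  r <- c(rg, rh)
  # one scale per block (g, h have different units); scaling per block
  # keeps the curvature penalty meaningful across bins
  dg <- diag(G)
  sg <- sqrt(max(dg[seq_len(B)], 2.2e-308))
  sh <- sqrt(max(dg[B + seq_len(B)], 2.2e-308))
  sinv <- c(rep(1 / sg, B), rep(1 / sh, B))
  Gs <- G * tcrossprod(sinv)
  K <- diff(diag(B), differences = 2L)
  KK <- crossprod(K)
  KK <- KK / norm(KK, "2")
  lam_top <- norm(Gs, "2")
  M <- Gs + (ridge * lam_top) * diag(2L * B)
  M[seq_len(B), seq_len(B)] <- M[seq_len(B), seq_len(B)] +
    (smooth * lam_top) * KK
  M[B + seq_len(B), B + seq_len(B)] <- M[B + seq_len(B), B + seq_len(B)] +
    (smooth * lam_top) * KK
  w <- tryCatch(
    sinv * backsolve_chol(chol(M), sinv * r),
    error = function(e)
      stop(fp_condition(paste0("drift/diffusion system could not be solved: ",
                               conditionMessage(e)),
                        "fpinverse_degenerate")))
  list(g = w[seq_len(B)], h = w[B + seq_len(B)])
}

backsolve_chol <- function(ch, b) {
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

#' Linear least-squares initialization of the drift and diffusion vectors
#'
#' Estimates the time derivative of each smoothed sequence by central
#' differences at interior frames (one-sided first-order differences at the
#' first and last frame, so every frame contributes), stacks the linear
#' system `dP/dt = D1 diag(P) g + D2 diag(P) h` over all frames and
#' sequences, and solves for the `2 B` unknowns `(g, h)` in the
#' penalized least-squares sense (curvature penalty, see [fpe_fit()]).
#'
#' @param series list of frames-by-bins matrices (at least 3 frames each),
#'   typically the [sg_smooth()]ed observations.
#' @param ops an [fd_operators()].
#' @param dt time gap between frames.
#' @param smooth curvature-penalty strength (see Details of [fpe_fit()]).
#' @param ridge tiny spectral jitter for numerical definiteness.
#' @return A list with initial estimates `g` and `h`.
#' @export
lls_init <- function(series, ops, dt, smooth = 1e-2, ridge = 1e-12) {
  if (!is.list(series)) series <- list(series)
  B <- nrow(ops$D1)
  C <- matrix(0, B, B)
  rg <- rh <- numeric(B)
  ss_dp <- ss_p <- 0
  for (Pm in series) {
    Tn <- nrow(Pm)
    if (Tn < 3L || ncol(Pm) != B)
      stop(fp_condition("each series needs >= 3 frames matching the grid",
                        "fpinverse_invalid"))
    dPm <- rbind((Pm[2L, ] - Pm[1L, ]) / dt,
                 (Pm[3:Tn, , drop = FALSE] -
                    Pm[1:(Tn - 2L), , drop = FALSE]) / (2 * dt),
                 (Pm[Tn, ] - Pm[Tn - 1L, ]) / dt)
    C <- C + crossprod(Pm)
    rg <- rg + colSums(Pm * (dPm %*% ops$D1))
    rh <- rh + colSums(Pm * (dPm %*% ops$D2))
    ss_dp <- ss_dp + sum(dPm^2)
    ss_p <- ss_p + sum(Pm^2)
  }
  if (ss_dp <= 1e-24 * ss_p)
    stop(fp_condition(
      "stationary data: time derivatives vanish, drift/diffusion unidentifiable",
      "fpinverse_degenerate"))
  solve_gh_normal(C, rg, rh, ops, smooth, ridge)
}
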