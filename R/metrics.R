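#' Boundary-area mask from noisy training densities
#'
#' Flags the grid bins whose density values, pooled over all training
#' sequences and frames, are statistically below `threshold_frac` times the
#' maximum noisy density (one-sided one-sample t-test at level `alpha`).
#' Drift and diffusion values at such bins are weakly identified because
#' the densities there are tiny; the mask is used only when reporting the
#' interior error metrics, never during fitting.  A zero-variance bin is
#' boundary if its constant value lies below the threshold.
#'
#' @param series list of noisy frames-by-bins matrices (training split).
#' @param alpha significance level (default 0.05).
#' @param threshold_frac threshold as a fraction of the maximum noisy
#'   density (default 0.01).
#' @return Logical vector, `TRUE` for boundary bins.
#' @export
boundary_mask <- function(series, alpha = 0.05, threshold_frac = 0.01) {
  if (!is.list(series)) series <- list(series)
  big <- do.call(rbind, series)
  if (nrow(big) < 2L)
    stop(fp_condition("need at least 2 frames for the boundary t-test",
                      "fpinverse_invalid"))
  thr <- threshold_frac * max(big)
  mask <- vapply(seq_len(ncol(big)), function(j) {
    v <- big[, j]
    if (stats::sd(v) == 0) return(v[1L] < thr)
    stats::t.test(v, mu = thr, alternative = "less")$p.value < alpha
  }, logical(1))
  if (all(mask))
    stop(fp_condition("boundary mask covers every bin", "fpinverse_invalid"))
  mask
}

#' Normalized error metrics of a fit against simulation truth
#'
#' Computes the relative L2 errors of the denoised densities (`E_P`, all
#' training sequences and frames flattened) and of the recovered drift and
#' diffusion vectors (`E_g`, `E_h` over all bins; `Et_g`, `Et_h`
#' restricted to the interior, i.e. non-boundary, bins).  The same interior
#' errors of the first-iteration weights (fit on the merely smoothed
#' observations) are reported alongside, quantifying how much the
#' alternating density training improves on smoothing alone.
#'
#' @param fit an [fpe_fit()] result.
#' @param dataset the [fp_simulate()] dataset the fit was trained on.
#' @param alpha significance level of the boundary t-test.
#' @return An object of class `fp_metrics`.
#' @export
fp_metrics <- function(fit, dataset, alpha = 0.05) {
  stopifnot(inherits(fit, "fpe_fit"), inherits(dataset, "fp_dataset"))
  truth <- fp_terms(dataset$example, fit$grid)
  mask <- boundary_mask(dataset$train, alpha = alpha)
  int <- !mask
  gh <- fit$coefficients
  res <- list(
    E_P = rel_l2(fit$P_hat, dataset$clean_train),
    E_g = rel_l2(gh$g, truth$g),
    E_h = rel_l2(gh$h, truth$h),
    Et_g = rel_l2(gh$g[int], truth$g[int]),
    Et_h = rel_l2(gh$h[int], truth$h[int]),
    E_P_noisy = rel_l2(dataset$train, dataset$clean_train),
    E_P_smoothed = rel_l2(fit$P0, dataset$clean_train),
    initial = list(
      Et_g = rel_l2(fit$init$g1[int], truth$g[int]),
      Et_h = rel_l2(fit$init$h1[int], truth$h[int])),
    boundary = mask)
  structure(res, class = "fp_metrics")
}

#' @export
print.fp_metrics <- function(x, ...) {
  cat(sprintf("E_P = %.4g (noisy %.4g, smoothed %.4g)\n",
              x$E_P, x$E_P_noisy, x$E_P_smoothed))
  cat(sprintf("E_g = %.4g (interior %.4g)   E_h = %.4g (interior %.4g)\n",
              x$E_g, x$Et_g, x$E_h, x$Et_h))
  cat(sprintf("first-iteration interior errors: g %.4g, h %.4g\n",
              x$initial$Et_g, x$initial$Et_h))
  cat(sprintf("boundary bins: %d of %d\n", sum(x$boundary),
              length(x$boundary)))
  invisible(x)
}
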