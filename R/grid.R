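#' Uniform spatial grid
#'
#' Discretizes the support of the observable into `n_bins` equal bins.
#' Densities, drift and diffusion vectors are all evaluated at the bin
#' centers `x_min + (j - 1/2) * dx`, `j = 1, ..., n_bins`.
#'
#' @param x_min,x_max support of the observable, `x_max > x_min`.
#' @param n_bins number of bins, at least 7 (the widest derivative stencil
#'   and the default smoothing window need 7 points).
#' @return An object of class `fp_grid` with fields `x_min`, `x_max`,
#'   `n_bins`, `dx` and the bin-center vector `x`.
#' @examples
#' g <- fp_grid(-0.01, 0.1, 110)
#' g$dx # 0.001
#' @export
fp_grid <- function(x_min, x_max, n_bins) {
  stop_invalid <- function(msg) stop(fp_condition(msg, "fpinverse_invalid"))
  if (!is.numeric(x_min) || !is.numeric(x_max) || x_max <= x_min)
    stop_invalid("degenerate support: need x_max > x_min")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 7L)
    stop_invalid("n_bins must be an integer >= 7")
  dx <- (x_max - x_min) / n_bins
  structure(
    list(x_min = x_min, x_max = x_max, n_bins = n_bins, dx = dx,
         x = x_min + (seq_len(n_bins) - 0.5) * dx),
    class = "fp_grid")
}

#' @export
print.fp_grid <- function(x, ...) {
  cat(sprintf("Uniform grid: %d bins on [%g, %g], dx = %g\n",
              x$n_bins, x$x_min, x$x_max, x$dx))
  invisible(x)
}

# Fornberg's recursion: weights of the m-th derivative at point z from
# function values at (distinct) nodes xs.  Exact for polynomials up to
# degree length(xs) - 1.
fd_weights <- function(z, xs, m) {
  n <- length(xs)
  if (n < m + 1L) stop(fp_condition("too few nodes for derivative order",
                                    "fpinverse_invalid"))
  C <- matrix(0, n, m + 1L)
  C[1L, 1L] <- 1
  c1 <- 1
  c4 <- xs[1L] - z
  for (i in 2:n) {
    mn <- min(i - 1L, m)
    c2 <- 1
    c5 <- c4
    c4 <- xs[i] - z
    for (j in 1:(i - 1L)) {
      c3 <- xs[i] - xs[j]
      c2 <- c2 * c3
      if (j == i - 1L) {
        if (mn >= 1L)
          for (k in mn:1L)
            C[i, k + 1L] <- c1 * (k * C[i - 1L, k] - c5 * C[i - 1L, k + 1L]) / c2
        C[i, 1L] <- -c1 * c5 * C[i - 1L, 1L] / c2
      }
      if (mn >= 1L)
        for (k in mn:1L)
          C[j, k + 1L] <- (c4 * C[j, k + 1L] - k * C[j, k]) / c3
      C[j, 1L] <- c4 * C[j, 1L] / c3
    }
    c1 <- c2
  }
  C[, m + 1L]
}

#' Finite-difference derivative matrix
#'
#' Builds the dense banded matrix that maps a vector of bin values to its
#' first or second spatial derivative.  Interior rows carry a central
#' stencil of the requested accuracy; the rows too close to an edge use
#' low-order one-sided stencils (no boundary condition is imposed).  The
#' default `edge_accuracy = 1` keeps the edge rows minimal: their numerical
#' dissipation keeps the open-boundary operator stable under explicit time
#' stepping, whereas matched-order extrapolative edge rows support growing
#' edge modes that visibly corrupt long forward solves.  See `graded` for
#' the rank/stability trade-off at the edge rows.  Row sums are forced to
#' exactly zero so constants are annihilated to the last bit.
#'
#' @param grid an [fp_grid()].
#' @param deriv derivative order, 1 or 2.
#' @param accuracy even interior stencil accuracy order (default 4).
#' @param edge_accuracy accuracy of the outermost one-sided row (default 1).
#' @param graded if `TRUE`, the one-sided stencil widens by one node per
#'   row toward the interior (default for the second derivative); if
#'   `FALSE` all edge rows use the minimal stencil (default for the first
#'   derivative -- the minimal rows are the most dissipative choice and
#'   keep the advective part stable).  At the default interior accuracy
#'   the two policies give nearly identical matrices; estimation at edge
#'   bins is regularized by the curvature penalty of the inverse solver,
#'   not by the stencil choice.
#' @return an `n_bins x n_bins` matrix.
#' @export
fd_matrix <- function(grid, deriv = 1L, accuracy = 4L, edge_accuracy = 1L,
                      graded = (deriv == 2L)) {
  stopifnot(inherits(grid, "fp_grid"))
  deriv <- as.integer(deriv)
  accuracy <- as.integer(accuracy)
  if (!deriv %in% c(1L, 2L))
    stop(fp_condition("deriv must be 1 or 2", "fpinverse_invalid"))
  if (accuracy < 2L || accuracy %% 2L != 0L)
    stop(fp_condition("accuracy must be a positive even integer",
                      "fpinverse_invalid"))
  edge_accuracy <- as.integer(edge_accuracy)
  if (edge_accuracy < 1L)
    stop(fp_condition("edge_accuracy must be >= 1", "fpinverse_invalid"))
  B <- grid$n_bins
  w_central <- accuracy + 2L * ((deriv + 1L) %/% 2L) - 1L # odd width
  h <- (w_central - 1L) %/% 2L
  # widest graded edge stencil: distance h - 1 from the edge
  w_edge_max <- deriv + edge_accuracy + h - 1L
  if (B < max(w_central, w_edge_max))
    stop(fp_condition("n_bins smaller than the stencil width",
                      "fpinverse_invalid"))
  D <- matrix(0, B, B)
  for (j in seq_len(B)) {
    idx <- if (j - h >= 1L && j + h <= B) {
      (j - h):(j + h)
    } else {
      e <- min(j, B + 1L - j) - 1L          # distance from the edge
      w <- deriv + edge_accuracy + if (graded) e else 0L
      if (j <= h) 1L:w else (B - w + 1L):B
    }
    # unit-spaced nodes for conditioning, then rescale by dx^deriv
    w <- fd_weights(0, idx - j, deriv) / grid$dx^deriv
    w[idx == j] <- w[idx == j] - sum(w) # exact annihilation of constants
    D[j, idx] <- w
  }
  D
}

#' First- and second-derivative operators
#'
#' Convenience wrapper bundling the two derivative matrices used by every
#' other function in the package.
#'
#' @inheritParams fd_matrix
#' @return A list of class `fd_operators` with elements `D1`, `D2`,
#'   `accuracy`, `edge_accuracy` and `grid`.
#' @examples
#' ops <- fd_operators(fp_grid(0, 1, 20))
#' range(ops$D1 %*% rep(1, 20)) # zero: constants are annihilated
#' @export
fd_operators <- function(grid, accuracy = 4L, edge_accuracy = 1L) {
  structure(
    list(D1 = fd_matrix(grid, 1L, accuracy, edge_accuracy),
         D2 = fd_matrix(grid, 2L, accuracy, edge_accuracy),
         accuracy = as.integer(accuracy),
         edge_accuracy = as.integer(edge_accuracy),
         grid = grid),
    class = "fd_operators")
}

# classed conditions used across the package
fp_condition <- function(msg, class) {
  structure(class = c(class, "fpinverse_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# scale columns of M by v: M %*% diag(v) without the diag
colscale <- function(M, v) M * rep(v, each = nrow(M))

# relative L2 deviation of a from b, flattening any shape
rel_l2 <- function(a, b) {
  a <- as.numeric(unlist(a, use.names = FALSE))
  b <- as.numeric(unlist(b, use.names = FALSE))
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop(fp_condition("zero-norm reference", "fpinverse_invalid"))
  sqrt(sum((a - b)^2)) / nb
}
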