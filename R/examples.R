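#' Reference stochastic systems
#'
#' Three parameterized Fokker-Planck systems used throughout the package as
#' ground truth for simulation studies, each written in the convention
#' \deqn{\partial_t P = \partial_x(g(x) P) + \partial_{xx}(h(x) P).}
#'
#' * `"flux"`: sea-surface heat-flux deviations, an Ornstein-Uhlenbeck
#'   process with `g(x) = theta * x` and constant `h(x) = D`.  Defaults
#'   `D = 0.0013`, `theta = 2.86` (empirical sea-measurement values),
#'   110 bins on `[-0.01, 0.1]`, `dt = 0.001`.
#' * `"bubble"`: thermally driven DNA bubble-length dynamics, a generalized
#'   Bessel process with `g(x) = mu / x - epsilon` and `h(x) = 1/2`.
#'   Defaults `mu = 1`, `epsilon = 0.2`, 100 bins on `[0.1, 1.1]`,
#'   `dt = 0.001`.
#' * `"wealth"`: agent-wealth dynamics with `g(x) = x - m` and
#'   `h(x) = (lambda / 2) * x^2`.  Defaults `lambda = 0.4`, `m = 1`,
#'   100 bins on `[0, 1]`, `dt = 5e-4`.
#'
#' @param name which system.
#' @param D,theta OU diffusion and drift coefficients (`"flux"`).
#' @param mu,epsilon Bessel drift parameters (`"bubble"`).
#' @param lambda,m wealth-dynamics parameters (`"wealth"`).
#' @param grid an [fp_grid()]; defaults to the grid above for each system.
#' @param dt time gap between saved frames; defaults as above.
#' @return An object of class `fp_example`.
#' @examples
#' ex <- fp_example("flux")
#' tr <- fp_terms(ex)
#' tr$g[1:3] # theta * x at the first bin centers
#' @export
fp_example <- function(name = c("flux", "bubble", "wealth"),
                       D = 0.0013, theta = 2.86,
                       mu = 1, epsilon = 0.2,
                       lambda = 0.4, m = 1,
                       grid = NULL, dt = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    flux   = list(grid = fp_grid(-0.01, 0.1, 110), dt = 0.001,
                  params = list(D = D, theta = theta)),
    bubble = list(grid = fp_grid(0.1, 1.1, 100), dt = 0.001,
                  params = list(mu = mu, epsilon = epsilon)),
    wealth = list(grid = fp_grid(0, 1, 100), dt = 5e-4,
                  params = list(lambda = lambda, m = m)))
  if (is.null(grid)) grid <- defaults$grid
  if (is.null(dt)) dt <- defaults$dt
  stopifnot(inherits(grid, "fp_grid"))
  if (!is.numeric(dt) || dt <= 0)
    stop(fp_condition("dt must be positive", "fpinverse_invalid"))
  p <- defaults$params
  if (name == "flux" && (D <= 0 || theta <= 0))
    stop(fp_condition("flux requires D > 0 and theta > 0",
                      "fpinverse_invalid"))
  if (name == "wealth" && lambda <= 0)
    stop(fp_condition("wealth requires lambda > 0", "fpinverse_invalid"))
  if (name == "bubble" && any(grid$x <= 0))
    stop(fp_condition("bubble grid must exclude x <= 0 (drift has a 1/x pole)",
                      "fpinverse_invalid"))
  structure(list(name = name, params = p, grid = grid, dt = dt),
            class = "fp_example")
}

#' @export
print.fp_example <- function(x, ...) {
  cat(sprintf("Fokker-Planck example '%s': %s; dt = %g\n", x$name,
              paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), x$dt))
  print(x$grid)
  invisible(x)
}

#' True drift and diffusion vectors of a reference system
#'
#' Evaluates the drift `g(x)` and diffusion `h(x)` of an [fp_example()] at
#' the bin centers of its grid.
#'
#' @param example an [fp_example()].
#' @param grid optional alternative [fp_grid()].
#' @return A list of class `fp_terms` with vectors `g` and `h`.
#' @export
fp_terms <- function(example, grid = example$grid) {
  stopifnot(inherits(example, "fp_example"), inherits(grid, "fp_grid"))
  x <- grid$x
  p <- example$params
  gh <- switch(example$name,
    flux   = list(g = p$theta * x, h = rep(p$D, length(x))),
    bubble = {
      if (any(x <= 0))
        stop(fp_condition("bubble grid must exclude x <= 0",
                          "fpinverse_invalid"))
      list(g = p$mu / x - p$epsilon, h = rep(0.5, length(x)))
    },
    wealth = list(g = x - p$m, h = (p$lambda / 2) * x^2))
  structure(c(gh, list(grid = grid)), class = "fp_terms")
}

#' Analytic Ornstein-Uhlenbeck density
#'
#' Transition density of the OU process with drift `theta * x` and constant
#' diffusion `D` (convention `dP/dt = theta d/dx(x P) + D d2P/dx2`),
#' started from a point mass at `x0`: a Gaussian with mean
#' `x0 * exp(-theta * t)` and variance `D * (1 - exp(-2 theta t)) / theta`.
#' This is the unique Gaussian family solving the equation
#' (`d var/dt = 2 D - 2 theta var`); as `t -> Inf` the variance relaxes to
#' the stationary value `D / theta`.
#'
#' @param x numeric vector of evaluation points, or an [fp_grid()] (bin
#'   centers are used).
#' @param t time since the point-mass initial condition, `t > 0`.
#' @param D,theta positive OU coefficients.
#' @param x0 initial state.
#' @return Density values at `x` (not renormalized to the grid).
#' @export
ou_density <- function(x, t, D = 0.0013, theta = 2.86, x0 = 0.06) {
  if (inherits(x, "fp_grid")) x <- x$x
  if (!is.numeric(t) || t <= 0 || D <= 0 || theta <= 0)
    stop(fp_condition("ou_density requires t > 0, D > 0, theta > 0",
                      "fpinverse_invalid"))
  v <- D * (1 - exp(-2 * theta * t)) / theta
  stats::dnorm(x, mean = x0 * exp(-theta * t), sd = sqrt(v))
}
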