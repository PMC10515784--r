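# Composite-Simpson weights on an odd-length uniform grid.
simpson_weights <- function(n, h) {
  if (n %% 2L == 0L) stop("Simpson grid needs an odd number of points", call. = FALSE)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  w * h / 3
}

odd_grid <- function(n) {
  n <- as.integer(n)
  if (n < 1001L) stop("grid resolution must be at least 1001 points per dimension",
                      call. = FALSE)
  if (n %% 2L == 0L) n + 1L else n
}

#' Boltzmann average for a single base pair (quadrature oracle)
#'
#' Exact (to quadrature accuracy) canonical average of an observable for one
#' isolated base pair in the Morse potential on the bounded displacement
#' domain: `<f> = int f(y) exp(-V(y)/kB T) dy / int exp(-V(y)/kB T) dy`,
#' computed by composite Simpson quadrature over exactly the sampler's
#' bounds. Serves as the independent reference for MCMC estimates of mean
#' opening and flipping probability; also usable to validate custom
#' parameter files.
#'
#' @param D,a Morse depth (eV) and inverse width (1/Å).
#' @param temperature Temperature (K).
#' @param observable Function of `y` (vectorised), e.g. `identity` for the
#'   mean opening or `function(y) y > 1.5` for a flipping probability.
#' @param bounds Length-2 integration bounds (Å); must equal the sampling
#'   bounds for apples-to-apples comparisons.
#' @param kB Boltzmann constant (eV/K).
#' @param n_grid Grid resolution (>= 1001; forced odd).
#' @return The expectation value.
#' @export
boltzmann_average_1bp <- function(D, a, temperature, observable = identity,
                                  bounds = c(-2, 20), kB = 8.617333262e-5,
                                  n_grid = 8001L) {
  n <- odd_grid(n_grid)
  y <- seq(bounds[1L], bounds[2L], length.out = n)
  w <- simpson_weights(n, y[2L] - y[1L])
  boltz <- exp(-morse_potential(y, D, a) / (kB * temperature))
  f <- as.numeric(observable(y))
  num <- sum(w * f * boltz)
  den <- sum(w * boltz)
  if (!is.finite(num) || !is.finite(den) || den <= 0)
    stop("non-finite Boltzmann integrand; check parameters and bounds", call. = FALSE)
  num / den
}

#' Boltzmann average for a two-base-pair system (quadrature oracle)
#'
#' Two-dimensional Simpson quadrature of
#' `<f> = int f(y1,y2) exp(-(V1+V2+W)/kB T) / Z` over the bounded square,
#' with `V1`, `V2` the two Morse terms and `W` the single stacking term.
#' Reference for 2-bp MCMC means and for the joint-opening probability
#' `P(1, 2, thr)` via `observable = function(y1, y2) (y1 > thr) & (y2 > thr)`.
#'
#' @param sp An `epbd_site_params` object with `n = 2` (see
#'   [epbd_site_params()] / [resolve_site_parameters()]).
#' @param temperature Temperature (K).
#' @param observable Vectorised function of `(y1, y2)`.
#' @param n_grid Points per dimension (>= 1001; forced odd).
#' @return The expectation value.
#' @export
boltzmann_average_2bp <- function(sp, temperature,
                                  observable = function(y1, y2) y1,
                                  n_grid = 1501L) {
  stopifnot(inherits(sp, "epbd_site_params"), sp$n == 2L)
  n <- odd_grid(n_grid)
  y <- seq(sp$y_min_bound, sp$y_max_bound, length.out = n)
  w <- simpson_weights(n, y[2L] - y[1L])
  beta <- 1 / (sp$kB * temperature)
  v1 <- morse_potential(y, sp$D[1L], sp$a[1L])   # along y1
  v2 <- morse_potential(y, sp$D[2L], sp$a[2L])   # along y2
  # energy matrix E[i, j] for y1 = y[i], y2 = y[j]
  Y1 <- matrix(y, n, n)
  Y2 <- matrix(y, n, n, byrow = TRUE)
  W <- stacking_potential(Y2, Y1, sp$k_step[1L], sp$rho, sp$b)
  boltz <- exp(-(outer(v1, v2, `+`) + W) * beta)
  f <- observable(Y1, Y2)
  storage.mode(f) <- "double"
  wmat <- outer(w, w)
  num <- sum(wmat * f * boltz)
  den <- sum(wmat * boltz)
  if (!is.finite(num) || !is.finite(den) || den <= 0)
    stop("non-finite Boltzmann integrand; check parameters and bounds", call. = FALSE)
  num / den
}
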