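#' Morse on-site potential
#'
#' Hydrogen-bond stretching energy of one base pair,
#' `V(y) = D * (exp(-a*y) - 1)^2`: zero at equilibrium (`y = 0`), a
#' dissociation plateau `V -> D` as `y -> Inf`, and a steep repulsive wall
#' for `y < 0`. Vectorised over `y`, `D` and `a`.
#'
#' @param y Displacement(s) in Å.
#' @param D Well depth(s) in eV (> 0).
#' @param a Inverse width(s) in 1/Å (> 0).
#' @return Energy in eV.
#' @export
morse_potential <- function(y, D, a) {
  stopifnot(all(D > 0), all(a > 0))
  e <- expm1(-a * y)
  D * e * e
}

#' Anharmonic stacking potential
#'
#' Stacking interaction between neighbouring base pairs,
#' `W(y, y_prev) = (k/2) * (1 + rho * exp(-b*(y + y_prev))) * (y - y_prev)^2`.
#' The exponential factor stiffens the coupling while both pairs are closed
#' and relaxes it once either opens, which sharpens denaturation. Symmetric
#' in its two displacement arguments; vectorised.
#'
#' @param y,y_prev Displacements of the two coupled base pairs (Å).
#' @param k Harmonic stacking constant, eV/Å² (> 0).
#' @param rho Anharmonicity amplitude (dimensionless, >= 0).
#' @param b Anharmonicity range, 1/Å (>= 0).
#' @return Energy in eV.
#' @export
stacking_potential <- function(y, y_prev, k, rho, b) {
  stopifnot(all(k > 0), all(rho >= 0), all(b >= 0))
  d <- y - y_prev
  0.5 * k * (1 + rho * exp(-b * (y + y_prev))) * d * d
}

check_config <- function(y, sp) {
  if (length(y) != sp$n)
    stop(sprintf("configuration length %d does not match the %d-site parameter set",
                 length(y), sp$n), call. = FALSE)
  invisible(y)
}

#' Total EPBD energy of a configuration
#'
#' Open-chain energy `E(y) = sum_n V(y_n) + sum_{n=2..N} W(y_n, y_{n-1})`:
#' exactly N Morse terms and N-1 stacking terms. The all-zero configuration
#' has energy exactly 0.
#'
#' @param y Numeric displacement vector (Å), length N.
#' @param sp An `epbd_site_params` object (see [resolve_site_parameters()]).
#' @return Total energy in eV.
#' @export
total_energy <- function(y, sp) {
  check_config(y, sp)
  e <- sum(morse_potential(y, sp$D, sp$a))
  if (sp$n > 1L) {
    e <- e + sum(stacking_potential(y[-1L], y[-sp$n], sp$k_step, sp$rho, sp$b))
  }
  e
}

#' Local energy difference of a single-coordinate move
#'
#' Energy change of replacing `y[site]` by `new_y`, computed from the Morse
#' term at `site` and the (at most two) adjacent stacking terms only. Equals
#' `total_energy(after) - total_energy(before)` up to floating point.
#'
#' @param y Current displacement vector (Å).
#' @param site 1-based site index.
#' @param new_y Proposed displacement (Å); must lie inside the bounds of
#'   `sp`, otherwise an error of class `epbd_bounds_error` is signalled
#'   (bounds violations are move rejections, not energy evaluations).
#' @param sp An `epbd_site_params` object.
#' @return Energy difference in eV.
#' @export
delta_energy <- function(y, site, new_y, sp) {
  check_config(y, sp)
  if (site < 1L || site > sp$n) stop("site out of range", call. = FALSE)
  if (new_y < sp$y_min_bound || new_y > sp$y_max_bound) {
    stop(structure(class = c("epbd_bounds_error", "error", "condition"),
                   list(message = sprintf(
                     "proposed displacement %.4g A outside bounds [%g, %g]",
                     new_y, sp$y_min_bound, sp$y_max_bound),
                     call = sys.call(-1L))))
  }
  yo <- y[site]
  dE <- morse_potential(new_y, sp$D[site], sp$a[site]) -
    morse_potential(yo, sp$D[site], sp$a[site])
  if (site > 1L) {
    k <- sp$k_step[site - 1L]
    dE <- dE + stacking_potential(new_y, y[site - 1L], k, sp$rho, sp$b) -
      stacking_potential(yo, y[site - 1L], k, sp$rho, sp$b)
  }
  if (site < sp$n) {
    k <- sp$k_step[site]
    dE <- dE + stacking_potential(y[site + 1L], new_y, k, sp$rho, sp$b) -
      stacking_potential(y[site + 1L], yo, k, sp$rho, sp$b)
  }
  dE
}

#' Transverse displacement from per-strand coordinates
#'
#' The potential energy depends only on the H-bond stretching coordinate
#' `y_n = (u_n - v_n) / sqrt(2)`; the common mode carries no energy. This
#' helper maps per-strand coordinates to `y`.
#'
#' @param u,v Per-strand coordinate vectors (Å), equal length.
#' @return The displacement vector `y` (Å).
#' @export
strand_to_y <- function(u, v) {
  stopifnot(length(u) == length(v))
  (u - v) / sqrt(2)
}
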