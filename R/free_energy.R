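#' Local free energy of the active/inactive monomer mixture
#'
#' Evaluates the regular-solution (lattice-gas) local free-energy density
#'
#' \deqn{f(n, n_0) = n\ln n + n_0\ln n_0 + s\ln s + \chi\, n\, s + X\, n\, n_0,
#'   \qquad s = 1 - n - n_0,}
#'
#' together with its partial derivatives with respect to `n` and `n0`.
#' The entropic terms are those of a three-component lattice mixture
#' (active monomer, inactive monomer, solvent); `chi` is the active-monomer
#' self-interaction (demixing for `chi > 2` in the one-species symmetric
#' mixture) and `X` the active-inactive cross-interaction. Logarithms are
#' floored at `params$eps_log` to avoid singularities on the simplex boundary;
#' the stability module uses the unfloored analytic forms, which agree with
#' the floored ones everywhere in the interior.
#'
#' The free-energy form is pluggable: if `params$free_energy_fn` is a function
#' `(n, n0, params) -> list(f, df_dn, df_dn0)`, it replaces the built-in
#' regular-solution form throughout the package.
#'
#' @param n_val,n0_val Numeric vectors/arrays of active and inactive monomer
#'   volume fractions, with `0 <= n, n0` and `n + n0 <= 1`.
#' @param params A [model_params()] object (supplies `chi`, `X`, `eps_log`).
#' @return A list with components `f`, `df_dn`, `df_dn0`, each the same shape
#'   as the inputs.
#' @examples
#' p <- model_params(chi = 2.5, X = 0)
#' local_free_energy(0.5, 0, p)$f
#' @export
local_free_energy <- function(n_val, n0_val, params) {
  if (length(n0_val) == 1 && length(n_val) > 1)
    n0_val <- array(n0_val, dim = dim(as.array(n_val)))
  tol <- 1e-12
  if (any(n_val < -tol) || any(n0_val < -tol) || any(n_val + n0_val > 1 + tol))
    stop("local_free_energy: (n, n0) outside the [0,1] simplex", call. = FALSE)
  fe_derivs(n_val, n0_val, params)
}

# Unvalidated evaluation used in the inner integration loop, where transient
# overshoots slightly outside the simplex are handled by the log flooring.
fe_derivs <- function(n_val, n0_val, params) {
  fn <- params$free_energy_fn
  if (is.function(fn)) return(fn(n_val, n0_val, params))
  eps <- params$eps_log
  s <- 1 - n_val - n0_val
  ln <- function(x) log(pmax(x, eps))
  f <- n_val * ln(n_val) + n0_val * ln(n0_val) + s * ln(s) +
    params$chi * n_val * s + params$X * n_val * n0_val
  df_dn <- ln(n_val) - ln(s) + params$chi * (s - n_val) + params$X * n0_val
  df_dn0 <- ln(n0_val) - ln(s) - params$chi * n_val + params$X * n_val
  list(f = f, df_dn = df_dn, df_dn0 = df_dn0)
}

# Unfloored analytic Hessian of the local free energy (interior compositions).
free_energy_hessian <- function(n_val, n0_val, params) {
  s <- 1 - n_val - n0_val
  f_nn <- 1 / n_val + 1 / s - 2 * params$chi
  f_nn0 <- 1 / s - params$chi + params$X
  f_n0n0 <- if (n0_val > 0) 1 / n0_val + 1 / s else Inf
  matrix(c(f_nn, f_nn0, f_nn0, f_n0n0), 2, 2)
}

# One-species (n0 = 0) curvature f''(n); roots are the spinodal compositions.
one_species_fpp <- function(n, chi) 1 / n + 1 / (1 - n) - 2 * chi

#' One-species spinodal and binodal compositions
#'
#' For the symmetric one-species regular solution (`n0 = 0`) the spinodal is
#' the root pair of \eqn{f''(n) = 1/n + 1/(1-n) - 2\chi = 0}, i.e.
#' \eqn{n = (1 \pm \sqrt{1 - 2/\chi})/2}, and the binodal (coexistence)
#' compositions solve the equal chemical potential/common-tangent condition
#' \eqn{\ln(n/(1-n)) = \chi (2n - 1)}; both exist only above the critical
#' interaction `chi = 2`.
#'
#' @param chi Self-interaction strength (> 2 for a miscibility gap).
#' @return Numeric vector `c(low, high)` of compositions.
#' @export
one_species_spinodal <- function(chi) {
  if (chi <= 2) stop("one_species_spinodal: no spinodal for chi <= 2",
                     call. = FALSE)
  d <- sqrt(1 - 2 / chi)
  c((1 - d) / 2, (1 + d) / 2)
}

#' @rdname one_species_spinodal
#' @export
one_species_binodal <- function(chi) {
  if (chi <= 2) stop("one_species_binodal: no coexistence for chi <= 2",
                     call. = FALSE)
  g <- function(n) log(n / (1 - n)) - chi * (2 * n - 1)
  hi <- uniroot(g, c(0.5 + 1e-8, 1 - 1e-12), tol = 1e-14)$root
  c(1 - hi, hi)
}

#' Chemical potentials of the monomer species on the grid
#'
#' The active monomer carries interfacial energy, so its chemical potential is
#' the Cahn-Hilliard functional derivative
#' \eqn{\mu_n = \partial f/\partial n - \kappa \nabla^2 n} (periodic spectral
#' Laplacian); the inactive monomer has no gradient penalty, so
#' \eqn{\mu_{n_0} = \partial f/\partial n_0}.
#'
#' @param state A [field_state()].
#' @param params A [model_params()].
#' @return A list with grids `mu_n` and `mu_n0`.
#' @export
chemical_potential <- function(state, params) {
  validate_field_state(state, params)
  d <- local_free_energy(state$n, state$n0, params)
  lap_n <- spectral_laplacian(state$n, params)
  list(mu_n = d$df_dn - params$kappa * lap_n, mu_n0 = d$df_dn0)
}

# --- spectral helpers (periodic grids) --------------------------------------

# Squared-wavenumber array k^2 for an N^d periodic grid of edge length L.
wavenumber_sq <- function(params) {
  N <- params$N
  L <- params$L
  k1 <- (2 * pi / L) * c(0:(N %/% 2), -((N - (N %/% 2 + 1)):1))
  k1sq <- k1^2
  if (params$dimension == 2) {
    outer(k1sq, k1sq, `+`)
  } else {
    o2 <- outer(k1sq, k1sq, `+`)
    outer(o2, k1sq, `+`)
  }
}

spectral_laplacian <- function(field, params) {
  k2 <- wavenumber_sq(params)
  Re(fft(-k2 * fft(field), inverse = TRUE)) / length(field)
}

#' Total discrete free energy of a field state
#'
#' Sum of the local free-energy density and the gradient (interfacial) energy
#' \eqn{\kappa/2\,|\nabla n|^2}, the latter evaluated spectrally via
#' Parseval's identity. Without reactions the Cahn-Hilliard dynamics is a
#' gradient flow of this functional, so it must not increase between steps.
#'
#' @inheritParams chemical_potential
#' @return Scalar free energy (per grid-cell volume).
#' @export
free_energy_total <- function(state, params) {
  d <- fe_derivs(state$n, state$n0, params)
  h <- params$L / params$N
  k2 <- wavenumber_sq(params)
  nh <- fft(state$n)
  grad2 <- sum(k2 * Mod(nh)^2) / length(state$n)
  (sum(d$f) + params$kappa / 2 * grad2) * h^params$dimension
}
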