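#' Model parameters for the reactive Cahn-Hilliard condensate model
#'
#' Bundles the rate constants of the inhibition and activation reactions, the
#' transport coefficients, the local free-energy parameters and the numerical
#' discretization into a validated parameter object. All quantities are
#' dimensionless; time is measured in units of the forward inhibition rate
#' times the monomer concentration scale, and length in grid units (the
#' default grid has unit spacing, `L = N`).
#'
#' @param k_f,k_b Forward/backward rate constants of the inhibition reaction
#'   `n + I <-> n0` (per concentration per time / per time). Must be >= 0.
#' @param h_f,h_b Forward/backward rate constants of the activation reaction
#'   `n0 + A <-> n + W`. Must be >= 0.
#' @param D_I,D_A,D_W,D_n0 Diffusivities of inhibitor, activator, waste and
#'   inactive monomer (length^2/time). Must be >= 0.
#' @param M Mobility of the active (phase-separating) monomer. Must be > 0.
#' @param kappa Gradient-energy coefficient penalizing interfaces of `n`.
#'   Must be > 0.
#' @param chi Active-monomer self-interaction strength of the regular-solution
#'   free energy (`chi > 2` puts a symmetric one-species mixture inside the
#'   two-phase region).
#' @param X Active-inactive cross-interaction strength. `X < 0` attracts
#'   inactive monomers into droplets; `X > 2` excludes them.
#' @param eps_log Small positive floor applied inside logarithms to avoid
#'   singularities at the simplex boundary. Must lie in (0, 1e-4).
#' @param dimension Spatial dimension, 2 or 3.
#' @param L Domain edge length.
#' @param N Grid points per edge (>= 16).
#' @param dt Time step of the semi-implicit integrator.
#' @param stab Splitting (stabilization) constant of the semi-implicit update;
#'   part of the local free-energy curvature is treated implicitly to keep the
#'   scheme stable at the default `dt`. Defaults to `2 * chi`.
#' @param seed Integer RNG seed used by stochastic helpers.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(chi = 2.5, X = 1)
#' p$chi
#' @export
model_params <- function(k_f = 1, k_b = 1, h_f = 1, h_b = 1,
                         D_I = 1, D_A = 1, D_W = 1, D_n0 = 1,
                         M = 1, kappa = 1, chi = 2.5, X = 1,
                         eps_log = 1e-9, dimension = 2,
                         L = 128, N = 128, dt = 0.01,
                         stab = 2 * chi, seed = 1L) {
  p <- list(k_f = k_f, k_b = k_b, h_f = h_f, h_b = h_b,
            D_I = D_I, D_A = D_A, D_W = D_W, D_n0 = D_n0,
            M = M, kappa = kappa, chi = chi, X = X,
            eps_log = eps_log, dimension = as.integer(dimension),
            L = L, N = as.integer(N), dt = dt, stab = stab,
            seed = as.integer(seed))
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) stop(sprintf("invalid model_params: '%s' %s", key, what),
                          call. = FALSE)
  }
  for (key in c("k_f", "k_b", "h_f", "h_b"))
    chk(is.numeric(p[[key]]) && length(p[[key]]) == 1 && p[[key]] >= 0,
        key, "must be a non-negative scalar rate constant")
  for (key in c("D_I", "D_A", "D_W", "D_n0"))
    chk(is.numeric(p[[key]]) && p[[key]] >= 0, key, "must be >= 0")
  chk(p$M > 0, "M", "must be > 0")
  chk(p$kappa > 0, "kappa", "must be > 0")
  chk(is.numeric(p$chi) && is.finite(p$chi), "chi", "must be finite")
  chk(is.numeric(p$X) && is.finite(p$X), "X", "must be finite")
  chk(p$eps_log > 0 && p$eps_log < 1e-4, "eps_log", "must lie in (0, 1e-4)")
  chk(p$dimension %in% c(2L, 3L), "dimension", "must be 2 or 3")
  chk(p$N >= 16, "N", "must be >= 16")
  chk(p$L > 0, "L", "must be > 0")
  chk(p$dt > 0, "dt", "must be > 0")
  chk(p$stab >= 0, "stab", "must be >= 0")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  reactions : k_f=%g k_b=%g h_f=%g h_b=%g\n",
              x$k_f, x$k_b, x$h_f, x$h_b))
  cat(sprintf("  transport : M=%g D_n0=%g D_I=%g D_A=%g D_W=%g\n",
              x$M, x$D_n0, x$D_I, x$D_A, x$D_W))
  cat(sprintf("  energy    : chi=%g X=%g kappa=%g\n", x$chi, x$X, x$kappa))
  cat(sprintf("  grid      : %dD, N=%d, L=%g, dt=%g\n",
              x$dimension, x$N, x$L, x$dt))
  invisible(x)
}

#' Serialize / deserialize model parameters as YAML
#'
#' The YAML form is written into the header of every output file produced by
#' the command-line tools so that each result carries its provenance.
#'
#' @param params A `model_params` object.
#' @param path File to write to, or `NULL` to return the YAML string.
#' @return `params_to_yaml` returns the path (or the YAML string);
#'   `params_from_yaml` returns a `model_params` object.
#' @export
params_to_yaml <- function(params, path = NULL) {
  stopifnot(inherits(params, "model_params"))
  txt <- yaml::as.yaml(unclass(params))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname params_to_yaml
#' @export
params_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(model_params, vals)
}

grid_shape <- function(params) rep(params$N, params$dimension)

#' Gridded concentration fields of the five chemical species
#'
#' A `field_state` holds concentration grids (volume-fraction-like,
#' dimensionless, all the same shape) for the active monomer `n`, inactive
#' monomer `n0`, inhibitor `I`, activator `A` and waste `W`, plus the elapsed
#' simulation time.
#'
#' @param n,n0,I,A,W Numeric arrays of identical shape with non-negative,
#'   finite entries; `n + n0` must not exceed 1 anywhere (volume-fraction
#'   interpretation). Species other than `n` default to zero grids.
#' @param t Elapsed simulation time.
#' @param params Optional `model_params` used to check the grid shape.
#' @return An object of class `field_state`.
#' @export
field_state <- function(n, n0 = NULL, I = NULL, A = NULL, W = NULL, t = 0,
                        params = NULL) {
  zeros <- array(0, dim = dim(as.array(n)))
  if (is.null(n0)) n0 <- zeros
  if (is.null(I)) I <- zeros
  if (is.null(A)) A <- zeros
  if (is.null(W)) W <- zeros
  s <- list(n = as.array(n), n0 = as.array(n0), I = as.array(I),
            A = as.array(A), W = as.array(W), t = t)
  class(s) <- "field_state"
  validate_field_state(s, params)
  s
}

validate_field_state <- function(state, params = NULL, tol = 1e-9) {
  dims <- dim(state$n)
  for (sp in c("n0", "I", "A", "W")) {
    if (!identical(dim(state[[sp]]), dims))
      stop("invalid field_state: species grids have inconsistent shapes",
           call. = FALSE)
  }
  for (sp in c("n", "n0", "I", "A", "W")) {
    if (!all(is.finite(state[[sp]])))
      stop(sprintf("invalid field_state: non-finite values in '%s'", sp),
           call. = FALSE)
  }
  if (max(state$n + state$n0) > 1 + tol)
    stop("invalid field_state: n + n0 exceeds 1 (volume fractions)",
         call. = FALSE)
  if (min(state$n) < -tol || min(state$n0) < -tol)
    stop("invalid field_state: negative concentrations", call. = FALSE)
  if (!is.null(params) && !identical(as.integer(dims), grid_shape(params)))
    stop("invalid field_state: grid shape does not match model_params",
         call. = FALSE)
  invisible(state)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> %s grid, t=%g\n",
              paste(dim(x$n), collapse = "x"), x$t))
  for (sp in c("n", "n0", "I", "A", "W"))
    cat(sprintf("  %-2s: mean=%.4g range=[%.4g, %.4g]\n",
                sp, mean(x[[sp]]), min(x[[sp]]), max(x[[sp]])))
  invisible(x)
}

# Evaluate a function with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
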