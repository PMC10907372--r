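#' Well-mixed chemical equilibrium of the inhibition/activation network
#'
#' Solves the mass-action steady state `k_f n I = k_b n0` and
#' `h_f n0 A = h_b n W` subject to the three conservation laws
#' `n + n0 = n_tot`, `I + n0 + W = I_tot`, `A + W = A_tot`. With no activator
#' the problem reduces to a quadratic in `n0` solved in closed form; the
#' general case adds an outer bisection over the waste concentration.
#'
#' @param n_tot,I_tot,A_tot Total monomer, inhibitor and activator amounts
#'   (all >= 0).
#' @param params A [model_params()] supplying the rate constants.
#' @return Named numeric vector `c(n, n0, I, A, W)` with residuals of both
#'   equilibrium conditions below 1e-10 (attached as attribute `residuals`).
#' @examples
#' p <- model_params(k_f = 1, k_b = 1)
#' well_mixed_equilibrium(1, 1, 0, p)[["n0"]]  # (3 - sqrt(5)) / 2
#' @export
well_mixed_equilibrium <- function(n_tot, I_tot, A_tot = 0, params) {
  if (any(c(n_tot, I_tot, A_tot) < 0))
    stop("well_mixed_equilibrium: totals must be >= 0", call. = FALSE)

  # Inner problem: inhibition equilibrium at fixed waste W.
  # Free inhibitor pool is I_tot - W - n0; k_f n I = k_b n0.
  solve_n0 <- function(W) {
    I_pool <- I_tot - W
    if (params$k_f == 0 || I_pool <= 0 || n_tot == 0) return(0)
    if (params$k_b == 0) return(min(n_tot, I_pool))
    a <- params$k_f
    b <- -(params$k_f * (n_tot + I_pool) + params$k_b)
    cc <- params$k_f * n_tot * I_pool
    disc <- sqrt(max(b^2 - 4 * a * cc, 0))
    min(2 * cc / (-b + disc), n_tot, I_pool)  # smaller root, stable form
  }

  W <- 0
  if (A_tot > 0 && I_tot > 0 && params$h_f > 0) {
    g <- function(W) {
      n0 <- solve_n0(W)
      n <- n_tot - n0
      params$h_f * n0 * (A_tot - W) - params$h_b * n * W
    }
    W_max <- min(A_tot, I_tot)
    if (g(0) > 0) {
      if (params$h_b == 0) {
        # irreversible activation: waste grows until activator or the
        # inhibited pool is exhausted
        W <- uniroot(function(W) solve_n0(W) * (A_tot - W),
                     c(0, W_max), tol = 1e-15)$root
      } else {
        W <- uniroot(g, c(0, W_max), tol = 1e-15)$root
      }
    }
  }
  n0 <- solve_n0(W)
  n <- n_tot - n0
  I <- I_tot - W - n0
  A <- A_tot - W
  res <- c(inhibition = params$k_f * n * I - params$k_b * n0,
           activation = params$h_f * n0 * A - params$h_b * n * W)
  if (any(abs(res) > 1e-8))
    stop("well_mixed_equilibrium: residuals exceed tolerance", call. = FALSE)
  structure(c(n = n, n0 = n0, I = I, A = A, W = W), residuals = res)
}

#' Is a homogeneous composition inside the spinodal (two-phase) region?
#'
#' A composition `(n, n0)` is linearly unstable to long-wavelength conserved
#' perturbations when the Hessian of the local free energy in `(n, n0)` has a
#' negative eigenvalue. For the regular-solution form the `n0`-diagonal entry
#' `1/n0 + 1/s` is always positive, so instability is equivalent to a
#' negative Hessian determinant (or, on the `n0 = 0` boundary, to a negative
#' one-species curvature `f''(n)`).
#'
#' @param composition Numeric vector `c(n, n0)` (remaining entries ignored)
#'   on the interior of the simplex.
#' @param params A [model_params()].
#' @return `TRUE` if the composition is inside the two-phase (unstable)
#'   region.
#' @export
spinodal_region <- function(composition, params) {
  n <- composition[[1]]
  n0 <- if (length(composition) >= 2) composition[[2]] else 0
  if (n < 0 || n0 < 0 || n + n0 > 1)
    stop("spinodal_region: composition outside the simplex", call. = FALSE)
  if (n == 0) return(FALSE)
  if (n0 < 1e-12) return(one_species_fpp(n, params$chi) < 0)
  H <- free_energy_hessian(n, n0, params)
  det(H) < 0
}

#' Phase diagram in total inhibitor vs interaction strength
#'
#' For each point of an `(I_tot, chi)` grid, computes the well-mixed chemical
#' equilibrium composition at the given inhibition rate ratio and classifies
#' it with the spinodal criterion, reproducing the diagrams in which adding
#' inhibitor acts on the condensing species like raising temperature.
#'
#' @param I_grid Strictly increasing grid of total inhibitor amounts.
#' @param chi_grid Strictly increasing grid of self-interaction strengths.
#' @param ratio Ratio `k_f / k_b` of the inhibition rate constants (with
#'   `k_b` fixed at 1; `ratio = 0` means the inhibitor never binds).
#' @param params A [model_params()] (supplies `X` and the other constants).
#' @param n_tot Total monomer amount used for every grid point.
#' @return An object of class `phase_diagram`: axis grids plus a boolean
#'   region matrix (`TRUE` = two coexisting phases) of shape
#'   `length(I_grid) x length(chi_grid)`.
#' @export
phase_diagram_inhibitor <- function(I_grid, chi_grid, ratio = 1, params,
                                    n_tot = 0.5) {
  if (is.unsorted(I_grid, strictly = TRUE) ||
      is.unsorted(chi_grid, strictly = TRUE))
    stop("phase_diagram_inhibitor: axis grids must be strictly increasing",
         call. = FALSE)
  region <- matrix(FALSE, length(I_grid), length(chi_grid))
  p <- params
  p$k_b <- 1
  p$k_f <- ratio
  for (j in seq_along(chi_grid)) {
    p$chi <- chi_grid[j]
    for (i in seq_along(I_grid)) {
      eq <- tryCatch(well_mixed_equilibrium(n_tot, I_grid[i], 0, p),
                     error = function(e)
                       stop(sprintf("phase diagram failed at I=%g, chi=%g: %s",
                                    I_grid[i], chi_grid[j],
                                    conditionMessage(e)), call. = FALSE))
      region[i, j] <- spinodal_region(c(eq[["n"]], eq[["n0"]]), p)
    }
  }
  structure(list(axis1 = list(name = "I_tot", grid = I_grid),
                 axis2 = list(name = "chi", grid = chi_grid),
                 region = region, params = params, ratio = ratio,
                 n_tot = n_tot),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %s (%d) x %s (%d); two-phase fraction %.2f\n",
              x$axis1$name, length(x$axis1$grid),
              x$axis2$name, length(x$axis2$grid), mean(x$region)))
  invisible(x)
}

#' Export a phase diagram as a long-format data frame / CSV
#'
#' @param pd A `phase_diagram`.
#' @param path Optional CSV path; when given, the file is written with a YAML
#'   provenance header (commented lines) followed by the table.
#' @return A data frame with columns `axis1`, `axis2`, `two_phase`.
#' @export
phase_diagram_to_csv <- function(pd, path = NULL) {
  df <- expand.grid(axis1 = pd$axis1$grid, axis2 = pd$axis2$grid)
  df$two_phase <- as.vector(pd$region)
  names(df)[1:2] <- c(pd$axis1$name, pd$axis2$name)
  if (!is.null(path)) {
    hdr <- paste0("# ", strsplit(params_to_yaml(pd$params), "\n")[[1]])
    writeLines(hdr, path)
    suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                                 row.names = FALSE, quote = FALSE))
  }
  df
}

#' Plot a phase diagram
#'
#' Renders the two-phase region of a [phase_diagram_inhibitor()] result as a
#' filled image (orange = two coexisting phases).
#'
#' @param x A `phase_diagram`.
#' @param ... Passed on to [graphics::image()].
#' @return The diagram, invisibly.
#' @export
plot.phase_diagram <- function(x, ...) {
  graphics::image(x$axis1$grid, x$axis2$grid, x$region * 1,
                  col = c("grey85", "darkorange"),
                  xlab = x$axis1$name, ylab = x$axis2$name,
                  main = "two-phase region", ...)
  invisible(x)
}

#' Inactive/active ratio at which phase separation is suppressed
#'
#' Starting from an active-monomer concentration inside the one-species
#' two-phase region, inactive monomer is added at increasing ratio
#' `n0/n` (active amount held fixed) until the homogeneous mixed state
#' becomes linearly stable; the smallest such ratio is located by scan plus
#' bisection. For intermediate cross-interactions (0 < X < 2) the inactive
#' species enters droplets without co-condensing, lowering the effective
#' binding energy, so a finite ratio of order 0.6 suppresses condensation.
#' For `X <= 0` the inactive monomers co-condense and no finite threshold
#' exists (returns `NA` with attribute `status = "none"`).
#'
#' @param X Cross-interaction strength.
#' @param n_active Active monomer volume fraction; must lie inside the
#'   one-species spinodal at `params$chi`.
#' @param params A [model_params()].
#' @param tol Bisection tolerance on the ratio (default 1e-3).
#' @return The threshold ratio, or `NA` (status `"none"`) if the mixture
#'   stays two-phase up to the solvent-exhaustion limit.
#' @export
inactive_ratio_threshold <- function(X, n_active, params, tol = 1e-3) {
  p <- params
  p$X <- X
  if (!spinodal_region(c(n_active, 0), p))
    stop("inactive_ratio_threshold: already suppressed at ratio 0 ",
         "(n_active is outside the one-species two-phase region)",
         call. = FALSE)
  # Co-condensing inactive monomers (partition coefficient > 1, i.e. X < 0)
  # rejoin the droplets instead of diluting their binding: the homogeneous
  # state only restabilizes when the solvent is exhausted, which is not
  # suppression. Report "none" directly.
  if (p$chi > 2 && dense_phase_partition(X, p)$curve$partition_coeff[1] > 1)
    return(structure(NA_real_, status = "none"))
  # scan stops before solvent exhaustion (s >= 0.05): a "stable" state found
  # beyond that is the fully condensed branch, not a suppressed mixture
  r_max <- (1 - n_active - 0.05) / n_active
  if (r_max <= 0)
    return(structure(NA_real_, status = "none"))
  unstable <- function(r) spinodal_region(c(n_active, r * n_active), p)
  # coarse upward scan for the first stable ratio
  grid <- seq(0, r_max, length.out = 257L)[-1]
  first_stable <- which(!vapply(grid, unstable, logical(1)))[1]
  if (is.na(first_stable))
    return(structure(NA_real_, status = "none"))
  lo <- if (first_stable == 1L) 0 else grid[first_stable - 1L]
  hi <- grid[first_stable]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unstable(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Partitioning and exclusion of inactive monomers in the dense phase
#'
#' Uses the common-tangent (equal chemical potential) construction on the
#' two-species free energy, in the dilute-tracer limit for the inactive
#' species, to compute how inactive monomers partition between the dense
#' droplet phase and the dilute phase as a function of the cross-interaction
#' `X`. Also locates two critical interaction strengths by bisection:
#'
#' * `X_cocondensation`: the `X` at which the dense/dilute partition
#'   coefficient of the inactive species crosses 1. Below it the inactive
#'   monomers are net-attracted into droplets (co-condensation); for the
#'   symmetric regular solution the crossing sits at `X = 0`.
#' * `X_exclusion`: the `X` above which the active/inactive sub-mixture of
#'   the dense phase itself demixes, i.e. inactive monomers are expelled from
#'   the droplet interior. Found as the root in `X` of the minimum curvature
#'   of the solvent-free binary mixing free energy
#'   `x ln x + (1-x) ln(1-x) + X x(1-x)`; for the symmetric regular solution
#'   this is the critical interaction `X = 2`.
#'
#' @param X_values Grid of cross-interaction strengths for the partition
#'   curve.
#' @param params A [model_params()] with `chi > 2` (a dense phase must
#'   exist).
#' @param n0_dilute Reference inactive concentration in the dilute phase for
#'   reporting a dense-phase concentration (tracer limit).
#' @return A list with `curve` (data frame `X`, `partition_coeff`,
#'   `n0_dense`), `X_cocondensation`, `X_exclusion`, and the coexisting
#'   one-species compositions `n_dilute`, `n_dense`.
#' @export
dense_phase_partition <- function(X_values = seq(-1, 3, by = 0.1), params,
                                  n0_dilute = 1e-3) {
  chi <- params$chi
  if (chi <= 2)
    stop("dense_phase_partition: no dense phase below the critical point",
         call. = FALSE)
  bin <- one_species_binodal(chi)
  n_dil <- bin[1]
  n_den <- bin[2]
  # Tracer chemical potential of n0 equal across the coexisting phases:
  # mu_n0 = ln n0 - ln s + (X - chi) n  =>  partition coefficient
  # K(X) = n0_dense / n0_dilute = (s_den/s_dil) * exp(-(X - chi)(n_den - n_dil))
  K <- function(X) {
    (1 - n_den) / (1 - n_dil) * exp(-(X - chi) * (n_den - n_dil))
  }
  curve <- data.frame(X = X_values, partition_coeff = K(X_values))
  curve$n0_dense <- n0_dilute * curve$partition_coeff
  X_co <- uniroot(function(X) K(X) - 1, c(-10, 10), tol = 1e-9)$root

  # Demixing of the dense-phase active/inactive sub-mixture (solvent-free):
  # the mixture is stable while min_x f_bin''(x) >= 0.
  min_curv <- function(X) {
    optimize(function(x) 1 / x + 1 / (1 - x) - 2 * X,
             interval = c(1e-6, 1 - 1e-6))$objective
  }
  X_ex <- tryCatch(
    uniroot(min_curv, c(0.5, 10), tol = 1e-9)$root,
    error = function(e)
      stop("dense_phase_partition: common-tangent/demixing construction ",
           "failed: ", conditionMessage(e), call. = FALSE))
  list(curve = curve[, c("X", "partition_coeff", "n0_dense")],
       X_cocondensation = X_co, X_exclusion = X_ex,
       n_dilute = n_dil, n_dense = n_den)
}
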