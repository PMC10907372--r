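#' Initialize a field state for spinodal decomposition
#'
#' Starts from a uniform active-monomer field at `n_total` with small,
#' mean-preserving uniform noise (the standard spinodal-decomposition initial
#' condition); all other species start at zero.
#'
#' @param params A [model_params()].
#' @param n_total Initial monomer volume fraction, in (0, 1).
#' @param seed Integer seed; equal seeds give bit-identical states.
#' @param noise_amplitude Amplitude of the uniform perturbation (default 1e-3).
#' @return A [field_state()] with spatial mean of `n` exactly `n_total`.
#' @export
initialize_state <- function(params, n_total, seed = params$seed,
                             noise_amplitude = 1e-3) {
  if (!is.numeric(n_total) || n_total <= 0 || n_total >= 1)
    stop("initialize_state: n_total must lie in (0, 1)", call. = FALSE)
  shape <- grid_shape(params)
  noise <- with_seed(seed, array(runif(prod(shape), -1, 1), dim = shape))
  noise <- noise - mean(noise)  # mean-preserving
  n <- n_total + noise_amplitude * noise
  field_state(n, t = 0, params = params)
}

# Precomputed spectral operators reused across steps.
step_operators <- function(params) {
  k2 <- wavenumber_sq(params)
  list(k2 = k2,
       denom_n = 1 + params$dt * params$M *
         (params$stab * k2 + params$kappa * k2^2),
       denom = lapply(c(n0 = "D_n0", I = "D_I", A = "D_A", W = "D_W"),
                      function(D) 1 + params$dt * params[[D]] * k2))
}

#' Advance the coupled Cahn-Hilliard / reaction-diffusion system one time step
#'
#' Semi-implicit (IMEX) spectral update on a periodic grid. The active monomer
#' follows conserved Cahn-Hilliard dynamics
#' \eqn{\partial n/\partial t = M \nabla^2 \mu_n + R_n} with the stiff
#' \eqn{\kappa\nabla^4} term and a linear splitting term (`params$stab`)
#' treated implicitly and the nonlinear local chemical potential and the
#' chemistry treated explicitly. The inactive monomer, inhibitor, activator
#' and waste are simple Fickian diffusers
#' \eqn{\partial c/\partial t = D_c \nabla^2 c + R_c} with their diffusion
#' treated implicitly. Spectral transport conserves each field's spatial mean
#' exactly, so the reaction invariants `n + n0`, `I + n0 + W` and `A + W` are
#' conserved up to the explicit-chemistry truncation error.
#'
#' @param state A [field_state()].
#' @param params A [model_params()].
#' @param ops Optional precomputed operators from an earlier call (internal
#'   speed-up for long runs); leave `NULL` for single steps.
#' @return The advanced [field_state()].
#' @export
ch_step <- function(state, params, ops = NULL) {
  if (is.null(ops)) ops <- step_operators(params)
  dt <- params$dt
  # inline mass-action rates: transient spectral undershoots (slightly
  # negative concentrations after sharp injections) are tolerated here and
  # relax under diffusion, so the strict state validator is not applied
  r1 <- params$k_f * state$n * state$I - params$k_b * state$n0
  r2 <- params$h_f * state$n0 * state$A - params$h_b * state$n * state$W
  R <- list(dn = -r1 + r2, dn0 = r1 - r2, dI = -r1, dA = -r2, dW = r2)
  d <- fe_derivs(state$n, state$n0, params)

  nl <- d$df_dn - params$stab * state$n
  n_hat <- (fft(state$n) +
              dt * (-params$M * ops$k2 * fft(nl) + fft(R$dn))) / ops$denom_n
  new <- list(n = Re(fft(n_hat, inverse = TRUE)) / length(state$n))
  for (sp in c("n0", "I", "A", "W")) {
    c_hat <- (fft(state[[sp]]) + dt * fft(R[[paste0("d", sp)]])) /
      ops$denom[[sp]]
    new[[sp]] <- Re(fft(c_hat, inverse = TRUE)) / length(state$n)
  }
  if (!all(vapply(new, function(x) all(is.finite(x)), logical(1))))
    stop(sprintf(
      "integration failure: non-finite field after step at t=%g (dt=%g)",
      state$t, dt), call. = FALSE)
  out <- list(n = new$n, n0 = new$n0, I = new$I, A = new$A, W = new$W,
              t = state$t + dt)
  class(out) <- "field_state"
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Inject inhibitor or activator into a running simulation
#'
#' Adds the requested species either uniformly over the whole domain or only
#' in the dilute phase (where `n` is below the droplet threshold, the midpoint
#' of the one-species binodal); the latter mimics an inhibitor that must enter
#' droplets by diffusion. The total added mass equals `amount` times the
#' domain volume in either placement.
#'
#' @param state A [field_state()].
#' @param species `"I"` or `"A"`.
#' @param amount Mean concentration added (>= 0).
#' @param placement `"uniform"` or `"dilute-phase-only"`.
#' @param params A [model_params()] (needed to locate the dilute phase).
#' @return The updated [field_state()].
#' @export
inject_species <- function(state, species, amount,
                           placement = c("uniform", "dilute-phase-only"),
                           params = NULL) {
  if (!species %in% c("I", "A"))
    stop("inject_species: species must be 'I' or 'A'", call. = FALSE)
  placement <- match.arg(placement)
  if (!is.numeric(amount) || amount < 0)
    stop("inject_species: amount must be >= 0", call. = FALSE)
  if (amount == 0) return(state)
  if (placement == "uniform") {
    state[[species]] <- state[[species]] + amount
  } else {
    if (is.null(params))
      stop("inject_species: params required for dilute-phase-only placement",
           call. = FALSE)
    thr <- droplet_threshold(params)
    mask <- state$n < thr
    if (!any(mask))
      stop("inject_species: no dilute phase below the droplet threshold",
           call. = FALSE)
    add <- amount * length(mask) / sum(mask)  # rescale to conserve total mass
    increment <- array(0, dim = dim(state$n))
    increment[mask] <- add
    # soften the mask edge with a narrow Gaussian (positive, mean-preserving)
    # so the spectral transport of the injected profile does not ring
    k2 <- wavenumber_sq(params)
    inc_hat <- fft(increment) * exp(-k2 / 2)
    increment <- pmax(Re(fft(inc_hat, inverse = TRUE)) / length(increment), 0)
    increment <- increment * (amount * length(increment) / sum(increment))
    state[[species]] <- state[[species]] + increment
  }
  state
}

#' Dense/dilute classification threshold
#'
#' Midpoint of the one-species binodal compositions at the run's `chi`
#' (0.5 for the symmetric regular solution), falling back to 0.5 below the
#' critical point. This is the parameter-free droplet threshold used by the
#' morphometry functions and by dilute-phase-only injection.
#'
#' @param params A [model_params()].
#' @return Scalar threshold composition.
#' @export
droplet_threshold <- function(params) {
  if (params$chi > 2) mean(one_species_binodal(params$chi)) else 0.5
}

#' Define a dissolution/regrowth scenario
#'
#' A scenario equilibrates droplets from a noisy uniform start, then applies
#' scheduled injections of inhibitor and/or activator, each expressed as a
#' ratio of the total monomer amount (e.g. 0.25x, 0.5x, 1x).
#'
#' @param n_total Initial monomer amount (volume fraction).
#' @param equilibration_time Time integrated before the first injection.
#' @param injections A data frame with columns `time`, `species` ("I"/"A"),
#'   `ratio` (>= 0, relative to `n_total`) and optionally `placement`;
#'   times must be non-decreasing.
#' @param total_time Total simulated time.
#' @param snapshot_interval Time between stored snapshots (> 0).
#' @return An object of class `ch_scenario`.
#' @export
scenario <- function(n_total, equilibration_time = 0, injections = NULL,
                     total_time, snapshot_interval) {
  if (is.null(injections))
    injections <- data.frame(time = numeric(), species = character(),
                             ratio = numeric(), placement = character())
  if (is.null(injections$placement)) injections$placement <- "uniform"
  if (is.unsorted(injections$time))
    stop("scenario: injection times must be non-decreasing", call. = FALSE)
  if (any(injections$ratio < 0))
    stop("scenario: injection ratios must be >= 0", call. = FALSE)
  if (snapshot_interval <= 0)
    stop("scenario: snapshot_interval must be > 0", call. = FALSE)
  structure(list(n_total = n_total, equilibration_time = equilibration_time,
                 injections = injections, total_time = total_time,
                 snapshot_interval = snapshot_interval),
            class = "ch_scenario")
}

#' Run a scenario and collect a trajectory of snapshots
#'
#' Integrates the coupled system, applying the scenario's injections at their
#' scheduled times, and stores snapshots at the requested cadence together
#' with a conserved-quantity audit (total monomer, inhibitor and activator,
#' which chemistry and spectral transport must preserve).
#'
#' @param scn A [scenario()].
#' @param params A [model_params()].
#' @param seed Seed for the initial condition (default `params$seed`).
#' @param initial_state Optional [field_state()] to continue from (e.g. a
#'   snapshot of an earlier equilibration run); its clock is reset to 0 and
#'   the scenario's injection times are relative to it. When given, the
#'   scenario's `n_total` and `seed` only affect injection amounts.
#' @param verbose Print progress lines.
#' @return An object of class `ch_trajectory`: a list with `snapshots` (list
#'   of [field_state()]), `times`, `audit` (data frame), `scenario`, `params`.
#' @export
run_scenario <- function(scn, params, seed = params$seed,
                         initial_state = NULL, verbose = FALSE) {
  stopifnot(inherits(scn, "ch_scenario"))
  state <- if (is.null(initial_state)) {
    initialize_state(params, scn$n_total, seed = seed)
  } else {
    initial_state$t <- 0
    initial_state
  }
  ops <- step_operators(params)
  n_steps <- ceiling(scn$total_time / params$dt)
  snap_every <- max(1L, round(scn$snapshot_interval / params$dt))
  inj <- scn$injections
  inj_step <- if (nrow(inj)) pmax(0L, round(inj$time / params$dt)) else integer()

  snapshots <- list(state)
  times <- state$t
  audits <- list(conserved_totals(state))
  for (k in seq_len(n_steps)) {
    if (nrow(inj)) {
      due <- which(inj_step == k - 1L)
      for (j in due) {
        state <- inject_species(state, inj$species[j],
                                inj$ratio[j] * scn$n_total,
                                inj$placement[j], params)
      }
    }
    state <- tryCatch(ch_step(state, params, ops), error = function(e)
      stop(sprintf("run_scenario: %s (step %d of %d)",
                   conditionMessage(e), k, n_steps), call. = FALSE))
    if (k %% snap_every == 0L || k == n_steps) {
      snapshots[[length(snapshots) + 1L]] <- state
      times <- c(times, state$t)
      audits[[length(audits) + 1L]] <- conserved_totals(state)
      if (verbose)
        message(sprintf("t=%8.2f  monomer=%.6f  inhibitor=%.6f  activator=%.6f",
                        state$t, audits[[length(audits)]][1],
                        audits[[length(audits)]][2],
                        audits[[length(audits)]][3]))
    }
  }
  audit <- cbind(data.frame(time = times), do.call(rbind, audits))
  structure(list(snapshots = snapshots, times = times, audit = audit,
                 scenario = scn, params = params, seed = seed),
            class = "ch_trajectory")
}

#' @export
print.ch_trajectory <- function(x, ...) {
  cat(sprintf("<ch_trajectory> %d snapshots, t in [%g, %g], %s grid\n",
              length(x$snapshots), min(x$times), max(x$times),
              paste(dim(x$snapshots[[1]]$n), collapse = "x")))
  invisible(x)
}

#' Save or load a trajectory
#'
#' Trajectories are stored as an RDS file (full state) together with a YAML
#' provenance header of the parameters; `trajectory_to_csv` exports the
#' snapshot audit table and per-frame droplet metrics to plain CSV.
#'
#' @param traj A `ch_trajectory`.
#' @param path Output path.
#' @return `save_trajectory` invisibly returns `path`; `load_trajectory`
#'   returns the trajectory.
#' @export
save_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  params_to_yaml(traj$params, paste0(path, ".params.yaml"))
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) readRDS(path)
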