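#' Reference parameters and canonical scenarios for invasion/anti-invasion runs
#'
#' `reference_params()` returns the parameter set used throughout the
#' package's worked examples and validation runs. Time is nondimensionalized
#' so the forward inhibition rate times the monomer scale is 1 (`k_f = 1`);
#' inhibition is strongly forward-biased (`k_b = 0.1`), as toehold-mediated
#' strand invasion is, and activation even more so (`h_b = 0.01`), so that
#' activator addition restores enough active monomer to re-enter the unstable
#' region. The quench `chi = 2.5` sits moderately above the critical
#' interaction 2, giving coexisting compositions near 0.145/0.855 and a
#' spinodal at 0.276/0.724; the cross-interaction `X = 1` is in the
#' intermediate range where inactive monomers enter droplets without
#' co-condensing and thereby suppress phase separation. The 64 x 64 grid
#' with unit spacing resolves tens of droplets at the default monomer
#' loading 0.35.
#'
#' @param D_I Inhibitor diffusivity (vary to contrast surface- vs
#'   volume-driven dissolution).
#' @param dt Time step (0.2 with the default stabilization; use smaller
#'   values when fine temporal resolution of fast dissolution is needed).
#' @param N,L Grid points and domain length per edge.
#' @param ... Further overrides passed to [model_params()].
#' @return A [model_params()] object.
#' @export
reference_params <- function(D_I = 1, dt = 0.2, N = 64, L = 64, ...) {
  model_params(chi = 2.5, X = 1, k_f = 1, k_b = 0.1, h_f = 1, h_b = 0.01,
               D_I = D_I, D_A = 1, D_W = 1, D_n0 = 1, M = 1, kappa = 1,
               N = N, L = L, dt = dt, stab = 5, ...)
}

#' @rdname reference_params
#' @param n_total Initial monomer volume fraction.
#' @param time Equilibration time (droplets nucleate and coarsen from the
#'   noisy uniform start; 400 time units suffices at the reference quench).
#' @param snapshot_interval Snapshot cadence.
#' @export
equilibration_scenario <- function(n_total = 0.35, time = 400,
                                   snapshot_interval = 50) {
  scenario(n_total = n_total, equilibration_time = time,
           total_time = time, snapshot_interval = snapshot_interval)
}

#' @rdname reference_params
#' @param ratio Inhibitor amount relative to total monomer (the
#'   0.25x / 0.5x / 1x dose series).
#' @param at Injection time.
#' @param total_time Total simulated time.
#' @param placement `"uniform"` or `"dilute-phase-only"`.
#' @export
invasion_scenario <- function(ratio, n_total = 0.35, at = 400,
                              total_time = 1000, snapshot_interval = 10,
                              placement = "uniform") {
  scenario(n_total = n_total, equilibration_time = at,
           injections = data.frame(time = at, species = "I", ratio = ratio,
                                   placement = placement),
           total_time = total_time, snapshot_interval = snapshot_interval)
}

#' @rdname reference_params
#' @param activator_at Activator injection time (100 time units after the
#'   inhibitor, while partial dissolution is still under way at 0.5x but
#'   dissolution is already complete at 1x).
#' @export
anti_invasion_scenario <- function(ratio, n_total = 0.35, at = 400,
                                   activator_at = at + 100,
                                   total_time = 1400,
                                   snapshot_interval = 25) {
  scenario(n_total = n_total, equilibration_time = at,
           injections = data.frame(time = c(at, activator_at),
                                   species = c("I", "A"),
                                   ratio = c(ratio, ratio),
                                   placement = "uniform"),
           total_time = total_time, snapshot_interval = snapshot_interval)
}

#' Time for the total dense area to halve after an injection
#'
#' Convenience metric for dissolution kinetics: the first time (relative to
#' `after`) at which the total thresholded dense area falls below half its
#' value at the injection, linearly interpolated; `Inf` if it never does
#' (e.g. a 0.25x inhibitor dose, whose effect saturates before halving).
#'
#' @param metrics Frame metrics from [trajectory_metrics()].
#' @param after Injection time.
#' @return Scalar half-time (possibly `Inf`).
#' @export
dense_area_halftime <- function(metrics, after) {
  i0 <- which.min(abs(metrics$frame_time - after))
  A0 <- metrics$total_area[i0]
  if (A0 <= 0) stop("dense_area_halftime: no dense area at the injection",
                    call. = FALSE)
  post <- metrics[metrics$frame_time >= metrics$frame_time[i0], ]
  ht <- dissolution_halftime(post$frame_time, post$total_area)
  if (is.na(ht)) Inf else ht - metrics$frame_time[i0]
}
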