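#' Ground truth for a synthetic fluorescence micrograph
#'
#' Describes a scene of near-circular bright droplets on a dark background:
#' per-droplet center, true diameter, peak intensity and focus flag, plus the
#' optics (per-focus blur sigmas), noise model (background level, Poisson
#' shot noise, Gaussian read noise) and geometry. Droplets are rendered with
#' a spherical-cap (chord-length) intensity profile, as epifluorescence of a
#' spherical condensate integrates fluorophores along the optical axis.
#' Out-of-focus objects get a larger blur and reduced contrast, emulating
#' objects outside the focal plane with softer edges.
#'
#' @param droplets Data frame with columns `cx`, `cy` (pixels), `diameter_um`,
#'   `intensity` (counts above background) and logical `in_focus`. May be
#'   generated with [sample_droplets()].
#' @param width,height Image size in pixels.
#' @param pixel_size Micrometers per pixel (default 0.11, a typical 60x oil
#'   objective sampling).
#' @param blur_sigma_in,blur_sigma_out Gaussian blur sigma (px) for in-focus
#'   and out-of-focus droplets; out-of-focus objects default to 4x the
#'   in-focus blur (with halved contrast), soft enough that the edge-based
#'   pipeline rejects them.
#' @param defocus_contrast Intensity factor applied to out-of-focus droplets
#'   (default 0.5).
#' @param background Background level in counts.
#' @param read_noise_sd Gaussian read noise standard deviation in counts.
#' @param poisson_noise Apply Poisson shot noise to the expected signal.
#' @param seed Integer seed fixed per scene.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(droplets, width = 512, height = 512,
                        pixel_size = 0.11, blur_sigma_in = 1.5,
                        blur_sigma_out = 4 * blur_sigma_in,
                        defocus_contrast = 0.5,
                        background = 200, read_noise_sd = 20,
                        poisson_noise = TRUE, seed = 1L) {
  need <- c("cx", "cy", "diameter_um", "intensity", "in_focus")
  if (!all(need %in% names(droplets)))
    stop("scene_truth: droplets must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(droplets$diameter_um <= 0))
    stop("scene_truth: diameters must be positive", call. = FALSE)
  r_px <- droplets$diameter_um / (2 * pixel_size)
  if (any(droplets$cx < 1 | droplets$cx > width |
            droplets$cy < 1 | droplets$cy > height))
    stop("scene_truth: droplet centers must lie inside the frame",
         call. = FALSE)
  if (any(2 * r_px > pmin(width, height)))
    stop("scene_truth: droplet larger than the frame", call. = FALSE)
  structure(list(droplets = droplets, width = width, height = height,
                 pixel_size = pixel_size, blur_sigma_in = blur_sigma_in,
                 blur_sigma_out = blur_sigma_out,
                 defocus_contrast = defocus_contrast,
                 background = background, read_noise_sd = read_noise_sd,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "scene_truth")
}

#' Sample a random droplet population for a scene
#'
#' Diameters are log-normal (default median 3 um, sigma_log 0.4, spanning the
#' 0.5-20 um range of typical DNA-nanostar condensates); positions are
#' uniform with a margin keeping droplets inside the frame; a fraction of
#' droplets is flagged out of focus.
#'
#' @param n_droplets Number of droplets.
#' @param width,height,pixel_size Scene geometry (as in [scene_truth()]).
#' @param median_diameter_um,sdlog Log-normal diameter distribution
#'   parameters.
#' @param intensity Mean peak intensity (counts above background); per-droplet
#'   intensities vary by +/- 20%.
#' @param frac_out_of_focus Fraction of droplets rendered out of focus.
#' @param seed Integer seed.
#' @return A droplet data frame suitable for [scene_truth()].
#' @export
sample_droplets <- function(n_droplets, width = 512, height = 512,
                            pixel_size = 0.11, median_diameter_um = 3,
                            sdlog = 0.4, intensity = 2000,
                            frac_out_of_focus = 0.25, seed = 1L) {
  with_seed(seed, {
    d <- pmin(stats::rlnorm(n_droplets, log(median_diameter_um), sdlog), 20)
    r_px <- d / (2 * pixel_size)
    margin <- pmin(r_px + 8, (pmin(width, height) - 2) / 2)
    data.frame(
      cx = runif(n_droplets, 1 + margin, width - margin),
      cy = runif(n_droplets, 1 + margin, height - margin),
      diameter_um = d,
      intensity = intensity * runif(n_droplets, 0.8, 1.2),
      in_focus = runif(n_droplets) >= frac_out_of_focus)
  })
}

#' Render a synthetic micrograph with its ground-truth mask
#'
#' Draws each droplet with the spherical-cap profile
#' \eqn{I(\rho) = I_0 \sqrt{1 - (\rho/r)^2}}, blurs in-focus and out-of-focus
#' layers with their respective sigmas, adds background, optional Poisson
#' shot noise and Gaussian read noise, and clips to the 16-bit range. The
#' returned truth mask covers in-focus droplets only (the objects the
#' edge-based pipeline is meant to measure). Deterministic per scene seed.
#'
#' @param truth A [scene_truth()].
#' @return A list with `image` (numeric matrix, counts in \[0, 65535\]) and
#'   `mask` (logical matrix of in-focus droplet interiors).
#' @export
render_scene <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  W <- truth$width; H <- truth$height
  layer_in <- matrix(0, W, H)
  layer_out <- matrix(0, W, H)
  mask <- matrix(FALSE, W, H)
  dr <- truth$droplets
  for (i in seq_len(nrow(dr))) {
    r <- dr$diameter_um[i] / (2 * truth$pixel_size)
    x0 <- dr$cx[i]; y0 <- dr$cy[i]
    xs <- max(1, floor(x0 - r - 2)):min(W, ceiling(x0 + r + 2))
    ys <- max(1, floor(y0 - r - 2)):min(H, ceiling(y0 + r + 2))
    rho2 <- outer((xs - x0)^2, (ys - y0)^2, `+`)
    prof <- sqrt(pmax(0, 1 - rho2 / r^2))
    if (dr$in_focus[i]) {
      layer_in[xs, ys] <- layer_in[xs, ys] + dr$intensity[i] * prof
      mask[xs, ys] <- mask[xs, ys] | (rho2 <= r^2)
    } else {
      layer_out[xs, ys] <- layer_out[xs, ys] +
        truth$defocus_contrast * dr$intensity[i] * prof
    }
  }
  blur <- function(m, sigma) {
    if (sigma > 0 && max(m) > 0) EBImage::imageData(EBImage::gblur(m, sigma))
    else m
  }
  expected <- truth$background +
    blur(layer_in, truth$blur_sigma_in) +
    blur(layer_out, truth$blur_sigma_out)
  img <- with_seed(truth$seed, {
    out <- if (truth$poisson_noise) {
      matrix(stats::rpois(length(expected), pmax(expected, 0)),
             nrow(expected), ncol(expected))
    } else expected
    if (truth$read_noise_sd > 0)
      out <- out + rnorm(length(out), 0, truth$read_noise_sd)
    out
  })
  list(image = pmin(pmax(img, 0), 65535), mask = mask)
}

#' Generate a synthetic time-course experiment with ground truth
#'
#' Produces, for each time point, a set of images (8 per time point by
#' default, emulating one imaging condition) whose droplet populations evolve
#' by a declared law:
#'
#' * `"dissolution"`: every droplet radius shrinks linearly to zero over
#'   `dissolve_time`; the final time point is droplet-free.
#' * `"coarsening"`: droplet number decreases while total truth area is
#'   conserved (the smallest droplet is merged into a surviving one at each
#'   coarsening event).
#' * `"regrowth"`: new droplets nucleate over time and existing ones grow,
#'   emulating reactivation after anti-invader addition.
#'
#' @param scenario_name One of `"coarsening"`, `"dissolution"`, `"regrowth"`.
#' @param time_points Numeric vector of time stamps.
#' @param n_droplets Initial droplet count (final for `"regrowth"`).
#' @param images_per_condition Images rendered per time point.
#' @param dissolve_time Time at which linear dissolution reaches zero
#'   (defaults to the last time point).
#' @param seed Integer seed controlling all randomness.
#' @param width,height,pixel_size,... Scene parameters forwarded to
#'   [scene_truth()] / [sample_droplets()].
#' @return A list of time points, each a list with `time`, `scenes` (list of
#'   rendered scenes with their `scene_truth`), and `truth_table` (per-image
#'   droplet truth records).
#' @export
generate_experiment <- function(scenario_name = c("coarsening", "dissolution",
                                                  "regrowth"),
                                time_points = c(0, 10, 20, 30),
                                n_droplets = 25, images_per_condition = 8,
                                dissolve_time = NULL, seed = 1L,
                                width = 384, height = 384,
                                pixel_size = 0.11, ...) {
  scenario_name <- match.arg(scenario_name)
  if (is.null(dissolve_time)) dissolve_time <- max(time_points)
  lapply(seq_along(time_points), function(ti) {
    tp <- time_points[ti]
    scenes <- lapply(seq_len(images_per_condition), function(im) {
      # one base droplet population per image series, evolved through time;
      # the noise realization still differs per frame
      series_seed <- as.integer(seed) * 10000L + im
      base <- sample_droplets(n_droplets, width, height, pixel_size,
                              seed = series_seed, ...)
      dr <- evolve_droplets(base, scenario_name, tp, max(time_points),
                            dissolve_time, series_seed)
      truth <- scene_truth(dr, width, height, pixel_size,
                           seed = series_seed + 101L * ti)
      c(render_scene(truth), list(truth = truth))
    })
    truth_table <- do.call(rbind, lapply(seq_along(scenes), function(im) {
      dr <- scenes[[im]]$truth$droplets
      if (nrow(dr)) cbind(data.frame(time = tp, image = im), dr)
      else data.frame(time = numeric(), image = integer(), cx = numeric(),
                      cy = numeric(), diameter_um = numeric(),
                      intensity = numeric(), in_focus = logical())
    }))
    list(time = tp, scenes = scenes, truth_table = truth_table)
  })
}

# Apply the scenario's deterministic evolution law to a base droplet set.
evolve_droplets <- function(base, scenario_name, tp, t_max, dissolve_time,
                            seed) {
  if (scenario_name == "dissolution") {
    shrink <- pmax(0, 1 - tp / dissolve_time)
    base$diameter_um <- base$diameter_um * shrink
    base[base$diameter_um > 0, , drop = FALSE]
  } else if (scenario_name == "coarsening") {
    # one merge event per unit of normalized time: count strictly decreasing,
    # total truth area conserved exactly
    n_events <- if (t_max > 0) floor((nrow(base) - 1) * tp / t_max) else 0
    areas <- base$diameter_um^2
    keep <- base
    for (e in seq_len(n_events)) {
      if (nrow(keep) <= 1) break
      j_small <- which.min(keep$diameter_um)
      j_big <- which.max(keep$diameter_um)
      keep$diameter_um[j_big] <- sqrt(keep$diameter_um[j_big]^2 +
                                        keep$diameter_um[j_small]^2)
      keep <- keep[-j_small, , drop = FALSE]
    }
    keep
  } else {  # regrowth: nucleate progressively, grow linearly after birth
    frac <- if (t_max > 0) tp / t_max else 1
    n_now <- ceiling(nrow(base) * frac)
    if (n_now == 0) return(base[0, , drop = FALSE])
    birth <- with_seed(seed + 7L,
                       sort(runif(nrow(base), 0, 0.8 * max(t_max, 1e-9))))
    alive <- birth <= tp
    out <- base[alive, , drop = FALSE]
    age <- (tp - birth[alive]) / max(t_max, 1e-9)
    out$diameter_um <- pmax(0.5, out$diameter_um * (0.3 + 0.7 * age))
    out
  }
}

#' Write a rendered experiment to 16-bit TIFFs plus truth CSVs
#'
#' @param experiment Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_experiment: the 'tiff' package is required", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tp in experiment) {
    for (im in seq_along(tp$scenes)) {
      f <- file.path(dir, sprintf("t%03d_img%02d.tif", round(tp$time), im))
      tiff::writeTIFF(tp$scenes[[im]]$image / 65535, f, bits.per.sample = 16)
      paths <- c(paths, f)
    }
    fcsv <- file.path(dir, sprintf("t%03d_truth.csv", round(tp$time)))
    write.csv(tp$truth_table, fcsv, row.names = FALSE)
    paths <- c(paths, fcsv)
  }
  invisible(paths)
}

#' Paint a field state with dense-phase disks for unit fixtures
#'
#' Produces a [field_state()] whose active-monomer field consists of disks at
#' the dense binodal composition on a dilute-binodal background, with an
#' optional tanh-smoothed interface. Droplets must not overlap (fixtures must
#' be unambiguous) and truth areas are recorded in the `truth` attribute.
#'
#' @param droplets Data frame with columns `cx`, `cy`, `r` (grid units).
#' @param params A [model_params()] with `chi > 2`.
#' @param interface_width Width of the tanh interface smoothing (0 = sharp).
#' @return A [field_state()] with attribute `truth` (the droplet table with
#'   exact disk areas `pi r^2`).
#' @export
generate_field_fixture <- function(droplets, params, interface_width = 0) {
  N <- params$N
  bin <- one_species_binodal(params$chi)
  if (nrow(droplets)) {
    if (any(droplets$cx - droplets$r < 0.5 | droplets$cx + droplets$r > N + 0.5 |
              droplets$cy - droplets$r < 0.5 |
              droplets$cy + droplets$r > N + 0.5))
      stop("generate_field_fixture: droplet outside the domain",
           call. = FALSE)
    if (nrow(droplets) > 1) {
      dmat <- as.matrix(stats::dist(droplets[, c("cx", "cy")]))
      rsum <- outer(droplets$r, droplets$r, `+`)
      if (any(dmat[upper.tri(dmat)] <
                (rsum + 2 * interface_width + 1)[upper.tri(rsum)]))
        stop("generate_field_fixture: droplets overlap", call. = FALSE)
    }
  }
  xs <- seq_len(N)
  n <- matrix(bin[1], N, N)
  for (i in seq_len(nrow(droplets))) {
    rho <- sqrt(outer((xs - droplets$cx[i])^2, (xs - droplets$cy[i])^2, `+`))
    if (interface_width > 0) {
      prof <- (1 - tanh((rho - droplets$r[i]) / interface_width)) / 2
      n <- n + (bin[2] - bin[1]) * prof
    } else {
      n[rho <= droplets$r[i]] <- bin[2]
    }
  }
  n <- pmin(n, bin[2])
  st <- field_state(n, params = params)
  truth <- droplets
  if (nrow(truth)) truth$area <- pi * truth$r^2
  attr(st, "truth") <- truth
  st
}
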