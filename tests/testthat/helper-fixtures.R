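# Shared fixtures: small grids keep the suite fast.

tiny_params <- function(...) {
  args <- modifyList(list(chi = 2.5, X = 1, N = 32, L = 32, dt = 0.1,
                          stab = 5, k_f = 1, k_b = 0.1, h_f = 1,
                          h_b = 0.01),
                     list(...))
  do.call(model_params, args)
}

uniform_state <- function(params, n = 0.3, n0 = 0, I = 0, A = 0, W = 0) {
  shape <- rep(params$N, params$dimension)
  field_state(array(n, shape), array(n0, shape), array(I, shape),
              array(A, shape), array(W, shape))
}

# A rendered scene with known in-focus disks on a fixed grid.
disk_scene <- function(diameters_um, intensity = 2000, width = 512,
                       height = 512, pixel_size = 0.11, seed = 3,
                       in_focus = TRUE, ...) {
  k <- length(diameters_um)
  slots <- expand.grid(cx = seq(70, width - 70, length.out = ceiling(sqrt(k))),
                       cy = seq(70, height - 70, length.out = ceiling(sqrt(k))))
  dr <- data.frame(cx = slots$cx[seq_len(k)], cy = slots$cy[seq_len(k)],
                   diameter_um = diameters_um, intensity = intensity,
                   in_focus = in_focus)
  truth <- scene_truth(dr, width, height, pixel_size, blur_sigma_in = 1.5,
                       seed = seed, ...)
  c(render_scene(truth), list(droplets = dr, truth = truth))
}

blank_scene <- function(seed, width = 256, height = 256) {
  empty <- data.frame(cx = numeric(), cy = numeric(),
                      diameter_um = numeric(), intensity = numeric(),
                      in_focus = logical())
  render_scene(scene_truth(empty, width, height, 0.11, seed = seed))
}

# Match detected records to true droplets by centroid distance (pixels).
match_detection <- function(records, droplets, pixel_size = 0.11) {
  vapply(seq_len(nrow(droplets)), function(i) {
    r_px <- droplets$diameter_um[i] / (2 * pixel_size)
    d <- sqrt((records$cx - droplets$cx[i])^2 +
                (records$cy - droplets$cy[i])^2)
    j <- which(d < r_px + 10)
    if (length(j)) j[which.min(d[j])] else NA_integer_
  }, integer(1))
}
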