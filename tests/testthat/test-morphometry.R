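test_that("droplet labeling handles empty, painted and saturated fields", {
  p <- tiny_params()
  # uniform dilute field: nothing above threshold
  expect_identical(nrow(label_droplets(matrix(0.1, 32, 32), 0.5)), 0L)

  # painted disks: areas within 5% of pi r^2, centroids recovered
  fix <- generate_field_fixture(
    data.frame(cx = c(9, 22), cy = c(9, 24), r = c(4, 6)), p)
  recs <- label_droplets(fix$n, params = p)
  recs <- recs[order(recs$area), ]
  expect_identical(nrow(recs), 2L)
  expect_equal(recs$area, pi * c(16, 36), tolerance = 0.05)
  expect_equal(recs$equivalent_diameter, 2 * sqrt(recs$area / pi))
  expect_lt(max(abs(recs$cx - c(9, 22))), 1)
  expect_lt(max(abs(recs$cy - c(9, 24))), 1)
  expect_lt(max(recs$eccentricity), 0.3)

  # entirely dense field: one record spanning the domain
  dense <- label_droplets(matrix(0.9, 32, 32), 0.5)
  expect_identical(nrow(dense), 1L)
  expect_equal(dense$area, 32^2)

  expect_error(label_droplets(matrix(NA_real_, 4, 4), 0.5), "non-finite")
})

test_that("labeling is 8-connected and respects periodic wrap", {
  m <- matrix(0, 16, 16)
  m[3, 3] <- 1; m[4, 4] <- 1; m[5, 5] <- 1; m[5, 6] <- 1  # diagonal chain
  recs <- label_droplets(m, 0.5, min_size = 1, periodic = FALSE)
  expect_identical(nrow(recs), 1L)

  # a disk crossing the periodic boundary is one droplet with an
  # unwrapped centroid on the seam
  mw <- matrix(0, 32, 32)
  xs <- seq_len(32)
  rho <- sqrt(outer(pmin(abs(xs - 1), 32 - abs(xs - 1))^2,
                    (xs - 16)^2, `+`))
  mw[rho <= 5] <- 1
  wrapped <- label_droplets(mw, 0.5, periodic = TRUE)
  expect_identical(nrow(wrapped), 1L)
  expect_equal(wrapped$area, sum(mw))
  expect_lt(min(abs(wrapped$cx - c(1, 33))), 0.7)
  split <- label_droplets(mw, 0.5, periodic = FALSE)
  expect_identical(nrow(split), 2L)

  # no double counting: per-droplet areas sum to the thresholded mask area
  p <- tiny_params()
  fix <- generate_field_fixture(
    data.frame(cx = c(8, 24), cy = c(8, 24), r = c(4, 5)), p)
  recs <- label_droplets(fix$n, params = p, min_size = 1)
  expect_identical(sum(recs$area), sum(fix$n > droplet_threshold(p)))
})

test_that("trajectory metrics equal an independent per-frame recomputation", {
  p <- tiny_params(dt = 0.2)
  traj <- run_scenario(scenario(n_total = 0.35, total_time = 60,
                                snapshot_interval = 20), p, seed = 2)
  m <- trajectory_metrics(traj)
  expect_identical(nrow(m), length(traj$snapshots))
  thr <- droplet_threshold(p)
  for (k in seq_along(traj$snapshots)) {
    again <- label_droplets(traj$snapshots[[k]]$n, thr)
    expect_identical(m$count[k], nrow(again))
    expect_equal(m$total_area[k], sum(again$area))
    if (nrow(again)) expect_equal(m$mean_area[k], mean(again$area))
  }

  # a static trajectory has constant metrics
  static <- traj
  static$snapshots <- rep(traj$snapshots[length(traj$snapshots)], 3)
  static$times <- 1:3
  ms <- trajectory_metrics(static)
  expect_identical(length(unique(ms$count)), 1L)
  expect_identical(length(unique(ms$total_area)), 1L)
})

test_that("dissolution half-time interpolates the crossing exactly", {
  # linear decay A(t) = A0 (1 - t/T): half-time T/2 exactly
  tt <- seq(0, 10, by = 0.5)
  A <- 100 * (1 - tt / 10)
  expect_equal(dissolution_halftime(tt, A), 5)

  # piecewise series crossing between frames: hand-computed interpolation
  expect_equal(dissolution_halftime(c(0, 1, 2), c(80, 60, 20)),
               1 + 20 / 40)
  # non-shrinking droplet: undissolved sentinel
  ht <- dissolution_halftime(1:5, rep(7, 5))
  expect_true(is.na(ht))
  expect_identical(attr(ht, "status"), "undissolved")
  expect_error(dissolution_halftime(numeric(), numeric()), "positive area")
})

test_that("power-law exponents are exact, shift-invariant and match search", {
  x <- c(1, 2, 4, 8, 16)
  fit <- scaling_exponent(x, 2.5 * x^3)
  expect_equal(fit$exponent, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # invariance under rescaling either axis
  fit2 <- scaling_exponent(7.3 * x, 0.01 * (2.5 * x^3))
  expect_equal(fit2$exponent, 3, tolerance = 1e-10)

  # matches an independent brute-force grid search on noisy points
  set.seed(13)
  xs <- exp(runif(20, 0, 3))
  ys <- 1.7 * xs^(-1.4) * exp(rnorm(20, 0, 0.05))
  fit3 <- scaling_exponent(xs, ys)
  grid <- expand.grid(lc = seq(-1, 2, by = 0.005),
                      e = seq(-3, 1, by = 0.005))
  sse <- (outer(grid$lc, rep(1, 20)) +
            outer(grid$e, log(xs)) -
            matrix(log(ys), nrow(grid), 20, byrow = TRUE))^2
  best <- grid[which.min(rowSums(sse)), ]
  expect_equal(fit3$exponent, best$e, tolerance = 0.01)

  expect_error(scaling_exponent(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(scaling_exponent(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("tracked half-times increase with painted initial radius", {
  p <- tiny_params(N = 48, L = 48, dt = 0.1)
  fix <- generate_field_fixture(
    data.frame(cx = c(12, 33), cy = c(12, 33), r = c(4, 8)), p,
    interface_width = 1)
  st <- inject_species(fix, "I", 0.5, "uniform")
  scn <- scenario(n_total = 0.3, total_time = 60, snapshot_interval = 2)
  traj <- run_scenario(scn, p, initial_state = st)
  tracks <- track_droplets(traj)
  expect_gte(length(unique(tracks$track)), 2)
  areas0 <- vapply(split(tracks, tracks$track),
                   function(d) d$area[1], numeric(1))
  small_tr <- as.integer(names(which.min(areas0)))
  big_tr <- as.integer(names(which.max(areas0)))
  ht <- function(tr) {
    d <- tracks[tracks$track == tr, ]
    # pad with a zero frame if the droplet disappears before the end
    t_end <- max(traj$times)
    if (max(d$frame_time) < t_end) {
      d <- rbind(d, data.frame(track = tr,
                               frame_time = min(d$frame_time[length(d$frame_time)] + 2,
                                                t_end),
                               area = 0))
    }
    dissolution_halftime(d$frame_time, d$area)
  }
  expect_gt(ht(big_tr), ht(small_tr))
})

test_that("interface sharpness distinguishes sharp from blurred droplets", {
  p <- tiny_params()
  sharp <- generate_field_fixture(data.frame(cx = 16, cy = 16, r = 7), p)
  blurred <- generate_field_fixture(data.frame(cx = 16, cy = 16, r = 7), p,
                                    interface_width = 3)
  thr <- droplet_threshold(p)
  expect_gt(interface_sharpness(sharp$n, thr),
            interface_sharpness(blurred$n, thr))
  expect_identical(interface_sharpness(matrix(0.1, 16, 16), 0.5), 0)
})
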