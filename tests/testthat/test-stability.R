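test_that("well-mixed equilibrium matches closed forms and edge cases", {
  p <- model_params(k_f = 1, k_b = 1)
  # no inhibitor: nothing is deactivated
  eq0 <- well_mixed_equilibrium(0.4, 0, 0, p)
  expect_equal(eq0[["n"]], 0.4)
  expect_equal(eq0[["n0"]], 0)

  # symmetric totals: quadratic closed form (3 - sqrt(5))/2
  eq <- well_mixed_equilibrium(1, 1, 0, p)
  expect_equal(eq[["n0"]], (3 - sqrt(5)) / 2, tolerance = 1e-10)
  expect_equal(eq[["n"]], eq[["I"]], tolerance = 1e-12)

  # irreversible limit with excess inhibitor: complete deactivation
  p_irr <- model_params(k_f = 1, k_b = 0)
  eq_irr <- well_mixed_equilibrium(0.3, 0.5, 0, p_irr)
  expect_equal(eq_irr[["n"]], 0)
  expect_equal(eq_irr[["n0"]], 0.3)

  expect_error(well_mixed_equilibrium(-0.1, 0, 0, p), "totals")
})

test_that("well-mixed equilibrium satisfies both balances on random totals", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    p <- model_params(k_f = runif(1, 0, 2), k_b = runif(1, 0, 2),
                      h_f = runif(1, 0, 2), h_b = runif(1, 0, 2))
    eq <- well_mixed_equilibrium(runif(1), runif(1), runif(1), p)
    worst <- max(worst, abs(attr(eq, "residuals")), -min(eq))
  }
  expect_lt(worst, 1e-10)
})

test_that("spinodal classification agrees with closed form and brute force", {
  p <- model_params(chi = 2.5, X = 1)
  # ideal mixture is stable everywhere
  p0 <- model_params(chi = 0, X = 0)
  for (n in c(0.1, 0.4, 0.7))
    expect_false(spinodal_region(c(n, 0.1), p0))

  # one-species boundary crossings at (1 +/- sqrt(1 - 2/chi))/2
  roots <- one_species_spinodal(2.5)
  expect_true(spinodal_region(c(mean(roots), 0), p))
  expect_false(spinodal_region(c(roots[1] - 1e-3, 0), p))
  expect_false(spinodal_region(c(roots[2] + 1e-3, 0), p))
  expect_true(spinodal_region(c(roots[1] + 1e-3, 0), p))

  # Hessian test equals brute-force minimization of the quadratic form
  # over 360 directions, on a grid of interior compositions
  thetas <- seq(0, pi, length.out = 360)
  for (n in seq(0.1, 0.7, by = 0.15)) {
    for (n0 in seq(0.05, 0.85 - n, by = 0.2)) {
      H <- condensr:::free_energy_hessian(n, n0, p)
      qmin <- min(vapply(thetas, function(th) {
        v <- c(cos(th), sin(th))
        drop(t(v) %*% H %*% v)
      }, numeric(1)))
      expect_equal(spinodal_region(c(n, n0), p), qmin < 0)
    }
  }
  expect_error(spinodal_region(c(0.7, 0.5), p), "simplex")
})

test_that("spinodal region is symmetric under n <-> solvent relabeling", {
  p <- model_params(chi = 2.7, X = 0)
  for (n in seq(0.05, 0.85, by = 0.1)) {
    n0 <- 0.05
    expect_identical(spinodal_region(c(n, n0), p),
                     spinodal_region(c(1 - n - n0, n0), p))
  }
})

test_that("inhibitor phase diagram reduces correctly in its limits", {
  p <- model_params(chi = 2.5, X = 1)
  I_grid <- seq(0, 0.6, length.out = 13)
  chi_grid <- seq(1.6, 4, length.out = 13)
  pd <- phase_diagram_inhibitor(I_grid, chi_grid, ratio = 1, p, n_tot = 0.5)
  expect_identical(dim(pd$region), c(13L, 13L))

  # the I = 0 column is the one-species spinodal classification in chi
  expected0 <- vapply(chi_grid, function(chi)
    spinodal_region(c(0.5, 0), model_params(chi = chi)), logical(1))
  expect_identical(pd$region[1, ], expected0)

  # inhibitor that never binds leaves the diagram independent of I
  pd0 <- phase_diagram_inhibitor(I_grid, chi_grid, ratio = 0, p, n_tot = 0.5)
  expect_true(all(apply(pd0$region, 2,
                        function(col) length(unique(col)) == 1)))

  expect_error(phase_diagram_inhibitor(c(0.2, 0.1), chi_grid, 1, p),
               "increasing")
})

test_that("phase boundary is stable under grid refinement", {
  p <- model_params(chi = 2.5, X = 1)
  chi_grid <- c(2.6, 3.0)
  coarse_I <- seq(0, 0.6, length.out = 16)
  fine_I <- seq(0, 0.6, length.out = 31)    # halved spacing
  pdc <- phase_diagram_inhibitor(coarse_I, chi_grid, 1, p, n_tot = 0.5)
  pdf_ <- phase_diagram_inhibitor(fine_I, chi_grid, 1, p, n_tot = 0.5)
  for (j in seq_along(chi_grid)) {
    bc <- coarse_I[sum(pdc$region[, j])]        # last two-phase I, coarse
    bf <- fine_I[sum(pdf_$region[, j])]
    expect_lt(abs(bc - bf), diff(coarse_I)[1] + 1e-12)
  }
})

test_that("inactive-monomer suppression threshold behaves as designed", {
  p <- model_params(chi = 2.5, X = 1)
  n_act <- 1.5 * one_species_spinodal(2.5)[1]

  thr <- inactive_ratio_threshold(1, n_act, p)
  expect_true(is.finite(thr))
  # bisection tolerance 1e-3: the threshold separates the two classifications
  expect_true(spinodal_region(c(n_act, (thr - 2e-3) * n_act), p))
  expect_false(spinodal_region(c(n_act, (thr + 2e-3) * n_act), p))

  # co-condensing inactive species (X < 0): no finite threshold
  none <- inactive_ratio_threshold(-0.5, n_act, p)
  expect_true(is.na(none))
  expect_identical(attr(none, "status"), "none")

  # starting composition outside the two-phase region is rejected
  expect_error(inactive_ratio_threshold(1, 0.1, p), "already suppressed")
})

test_that("dense-phase partitioning: ideal point, monotonicity, thresholds", {
  p <- model_params(chi = 2.5, X = 1)
  dp <- dense_phase_partition(seq(-1, 3, by = 0.25), p)

  # X = 0: the inactive tracer partitions ideally (coefficient exactly 1)
  expect_equal(dp$curve$partition_coeff[dp$curve$X == 0], 1,
               tolerance = 1e-9)
  # curve monotone non-increasing in X
  expect_true(all(diff(dp$curve$partition_coeff) <= 0))
  # attraction into droplets exactly below X = 0, exclusion beyond X = 2
  expect_equal(dp$X_cocondensation, 0, tolerance = 1e-8)
  expect_equal(dp$X_exclusion, 2, tolerance = 1e-8)
  expect_error(dense_phase_partition(params = model_params(chi = 1.5)),
               "critical")
})

test_that("tracer partition matches brute-force free-energy minimization", {
  p <- model_params(chi = 2.5)
  bin <- one_species_binodal(p$chi)
  n0_tot <- 1e-3
  for (X in c(-0.5, 0.5, 1.5)) {
    pX <- model_params(chi = 2.5, X = X)
    # split a tracer amount between the coexisting phases (volume 1/2 each)
    # and minimize the total free energy over the split
    obj <- function(x) {
      n0_d <- 2 * n0_tot * x
      n0_dil <- 2 * n0_tot * (1 - x)
      0.5 * local_free_energy(bin[2], n0_d, pX)$f +
        0.5 * local_free_energy(bin[1], n0_dil, pX)$f
    }
    x_best <- optimize(obj, c(1e-6, 1 - 1e-6), tol = 1e-10)$minimum
    K_brute <- x_best / (1 - x_best)
    K_ct <- dense_phase_partition(X, pX)$curve$partition_coeff[1]
    expect_equal(K_brute, K_ct, tolerance = 0.02)
  }
})
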