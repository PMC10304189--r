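# Mass weighting, rigid-body projection, frequency conversion, scaling.

diatomic_modes <- function(k = 1.0, r0 = 0.92, els = c("F", "H"),
                           step = 2e-4) {
  ff <- toy_ff_params(bonds = data.frame(el1 = els[1], el2 = els[2],
                                         k = k, r0 = r0))
  g <- finite_geometry(els, rbind(c(0, 0, 0), c(r0, 0, 0)))
  b <- toyff_backend(g, ff)
  list(g = g, nm = vibrational_analysis(finite_difference_hessian(b, g, step),
                                        g))
}

test_that("the diatomic frequency matches the closed form to 1e-6 relative", {
  for (k in c(0.3, 1.0)) {
    d <- diatomic_modes(k = k)
    m <- element_mass(c("F", "H"))
    mu <- m[1] * m[2] / sum(m)
    closed <- sqrt(2 * k / mu) * vibrafrag:::.freq_conv
    expect_length(d$nm$frequencies, 1)
    expect_lt(abs(d$nm$frequencies - closed) / closed, 1e-6)
    expect_equal(d$nm$n_projected, 5)  # linear molecule: 3 + 2
  }
})

test_that("mode counting is 3N-6 (3N-5 linear) with small rigid residues", {
  # nonlinear triatomic: 3 modes
  fx <- make_toy_crystal("water_sheet", reps = c(1, 1, 1))
  mols <- extract_molecules(fx$structure)
  g <- finite_geometry(mols[[1]]$elements, mols[[1]]$coords)
  b <- toyff_backend(g, fx$truth$ff)
  nm <- vibrational_analysis(finite_difference_hessian(b, g, 2e-4), g)
  expect_length(nm$frequencies, 3)
  expect_equal(nm$n_projected, 6)
  expect_lt(max(nm$rigid_frequencies), 1)
  expect_true(all(nm$frequencies > 0))

  # formamide molecule: 3 * 6 - 6 = 12 modes
  fx2 <- make_toy_crystal("formamide_sheet", reps = c(1, 1, 1))
  mols2 <- extract_molecules(fx2$structure)
  g2 <- finite_geometry(mols2[[1]]$elements, mols2[[1]]$coords)
  b2 <- toyff_backend(g2, fx2$truth$ff)
  nm2 <- vibrational_analysis(finite_difference_hessian(b2, g2, 2e-4), g2)
  expect_length(nm2$frequencies, 12)
  expect_lt(max(nm2$rigid_frequencies), 1)
})

test_that("negative eigenvalues are encoded as negative wavenumbers", {
  d <- diatomic_modes()
  H <- matrix(0, 6, 6)
  H[1, 1] <- H[4, 4] <- 1; H[1, 4] <- H[4, 1] <- -1  # bound pair
  H <- H * -0.5                                       # flip: maximum, not min
  nm <- vibrational_analysis(H, d$g, project = FALSE)
  expect_true(nm$has_imaginary)
  expect_lt(nm$frequencies[1], 0)
})

test_that("modes are orthonormal and projection is idempotent", {
  fx <- make_toy_crystal("formamide_sheet", reps = c(1, 1, 1))
  mols <- extract_molecules(fx$structure)
  g <- finite_geometry(mols[[1]]$elements, mols[[1]]$coords)
  b <- toyff_backend(g, fx$truth$ff)
  nm <- vibrational_analysis(finite_difference_hessian(b, g), g)
  gram <- t(nm$modes) %*% nm$modes
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  P <- vibrafrag:::.rigid_projector(g)
  expect_lt(max(abs(P %*% P - P)), 1e-10)
})

test_that("frequencies are invariant under rigid rotation of the system", {
  fx <- make_toy_crystal("water_sheet", reps = c(1, 1, 1))
  mols <- extract_molecules(fx$structure)
  g <- finite_geometry(mols[[1]]$elements, mols[[1]]$coords)
  b <- toyff_backend(g, fx$truth$ff)
  H <- finite_difference_hessian(b, g)
  nm <- vibrational_analysis(H, g)
  R <- vibrafrag:::.rotation_between(c(1, 0, 0), c(0.3, -1, 0.7))
  g2 <- g; g2$coords <- g$coords %*% t(R)
  B <- kronecker(diag(nrow(g$coords)), R)
  H2 <- B %*% H %*% t(B)
  H2 <- (H2 + t(H2)) / 2
  nm2 <- vibrational_analysis(H2, g2)
  expect_equal(nm2$frequencies, nm$frequencies, tolerance = 1e-6)
})

test_that("increasing any atomic mass never increases any frequency", {
  fx <- make_toy_crystal("water_sheet", reps = c(1, 1, 1))
  mols <- extract_molecules(fx$structure)
  g <- finite_geometry(mols[[1]]$elements, mols[[1]]$coords)
  b <- toyff_backend(g, fx$truth$ff)
  H <- finite_difference_hessian(b, g)
  base <- vibrational_analysis(H, g)$frequencies
  for (i in seq_along(g$masses)) {
    g2 <- g
    g2$masses[i] <- g2$masses[i] * 1.5
    heavier <- vibrational_analysis(H, g2)$frequencies
    expect_true(all(heavier <= base + 1e-6),
                label = paste("isotope monotonicity, atom", i))
  }
})

test_that("invalid Hessians and masses are rejected", {
  d <- diatomic_modes()
  H <- matrix(rnorm(36), 6)
  expect_error(vibrational_analysis(H, d$g), "symmetr")
  g0 <- d$g; g0$masses[1] <- 0
  expect_error(vibrational_analysis(diag(6), g0), "> 0|masses")
  expect_error(vibrational_analysis(diag(5), d$g), "3N")
})

test_that("scaling reproduces the published 0.99-scaled entries", {
  nm <- structure(list(frequencies = c(3517.12, 3656.99)),
                  class = "normal_modes")
  scaled <- apply_scale_factor(nm, scale_factor(0.99))
  expect_equal(round_half_up(scaled$frequencies, 2), c(3481.95, 3620.42))
  # identity and composition
  expect_equal(apply_scale_factor(nm, 1.0)$frequencies, nm$frequencies)
  a <- apply_scale_factor(apply_scale_factor(nm, 0.98), 0.95)$frequencies
  b <- apply_scale_factor(nm, 0.98 * 0.95)$frequencies
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(scale_factor(1.5), "0, 1.2")
  expect_error(scale_factor(0), "0, 1.2")
})

test_that("reported tables round half-up to two decimals", {
  # 0.125 is exactly representable: half-up gives .13 where banker's gives .12
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  nm <- structure(list(frequencies = c(100.125, 200.004)),
                  class = "normal_modes")
  tab <- frequency_table(nm, 0.99)
  expect_equal(tab$freq_cm1, c(100.13, 200.00))
  expect_equal(tab$scaled_cm1, round_half_up(c(100.125, 200.004) * 0.99, 2))
})
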