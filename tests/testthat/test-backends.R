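# Toy force field, geometry optimizer, finite-difference Hessians.

hf_ff <- function() {
  toy_ff_params(bonds = data.frame(el1 = "F", el2 = "H", k = 1.0, r0 = 0.92))
}
hf_geom <- function(r = 0.92) {
  finite_geometry(c("F", "H"), rbind(c(0, 0, 0), c(r, 0, 0)))
}

test_that("a diatomic at its reference length has zero energy and gradient", {
  g <- hf_geom()
  b <- toyff_backend(g, hf_ff())
  expect_equal(b$energy(g), 0)
  expect_equal(max(abs(b$gradient(g))), 0)
})

test_that("analytic gradients match central differences on all fixtures", {
  for (kind in c("water_sheet", "formamide_sheet", "ethanol_dimer_cell")) {
    fx <- make_toy_crystal(kind, noise = 0.03, seed = 11)
    mols <- extract_molecules(fx$structure)
    g <- finite_geometry(unlist(lapply(mols, `[[`, "elements")),
                         do.call(rbind, lapply(mols, `[[`, "coords")))
    b <- toyff_backend(g, fx$truth$ff, fx$truth$criteria)
    expect_lt(max(abs(b$gradient(g) - oracle_numeric_gradient(b, g))), 1e-6,
              label = paste("gradient mismatch for", kind))
  }
})

test_that("LJ and Coulomb terms also differentiate correctly", {
  ff <- toy_ff_params(
    bonds = data.frame(el1 = "O", el2 = "H", k = 0.85, r0 = 0.96),
    angles = data.frame(el1 = "H", center = "O", el2 = "H", k = 0.15,
                        theta0 = 104.5 * pi / 180),
    lj = data.frame(el = c("O", "H"), eps = c(1e-4, 2e-5),
                    sigma = c(3.1, 1.5)),
    charges = c(O = -0.8, H = 0.4))
  th <- 104.5 * pi / 180
  w <- function(o) rbind(o, o + c(0.96, 0, 0), o + 0.96 * c(cos(th), sin(th), 0))
  g <- finite_geometry(rep(c("O", "H", "H"), 2),
                       rbind(w(c(0, 0, 0)), w(c(3.2, 0.4, 0.2))))
  b <- toyff_backend(g, ff)
  expect_lt(max(abs(b$gradient(g) - oracle_numeric_gradient(b, g))), 1e-6)
})

test_that("energy is invariant under rigid translation and rotation", {
  fx <- make_toy_crystal("ethanol_dimer_cell", noise = 0.02, seed = 3)
  mols <- extract_molecules(fx$structure)
  g <- finite_geometry(unlist(lapply(mols, `[[`, "elements")),
                       do.call(rbind, lapply(mols, `[[`, "coords")))
  b <- toyff_backend(g, fx$truth$ff, fx$truth$criteria)
  e0 <- b$energy(g)
  g_t <- g; g_t$coords <- sweep(g$coords, 2, c(1, 2, 3), "+")
  expect_equal(b$energy(g_t), e0, tolerance = 1e-12)
  R <- vibrafrag:::.rotation_between(c(0, 0, 1), c(1, 1, 0.5))
  g_r <- g; g_r$coords <- g$coords %*% t(R)
  expect_equal(b$energy(g_r), e0, tolerance = 1e-10)
})

test_that("missing parameters and overlapping atoms raise named errors", {
  g <- finite_geometry(c("C", "N"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  b <- toyff_backend(g, hf_ff())
  expect_error(b$energy(g), "C:N")
  g2 <- finite_geometry(c("F", "H"), rbind(c(0, 0, 0), c(0.05, 0, 0)))
  expect_error(toy_ff_energy_gradient(g2, hf_ff(),
                                      perceive_bonds(hf_geom())),
               "overlapping")
})

test_that("the optimizer converges at a minimum in zero steps", {
  g <- hf_geom()
  r <- optimize_geometry(g, toyff_backend(g, hf_ff()))
  expect_true(r$converged)
  expect_lte(r$steps, 1)
  expect_equal(r$model$coords, g$coords)
})

test_that("a displaced diatomic relaxes back to its reference length", {
  g <- hf_geom(0.92 + 0.2)
  r <- optimize_geometry(g, toyff_backend(g, hf_ff()))
  expect_true(r$converged)
  bond <- sqrt(sum((r$model$coords[2, ] - r$model$coords[1, ])^2))
  expect_lt(abs(bond - 0.92), 0.005)
  expect_true(all(diff(r$energy_trace) <= 0))
})

test_that("non-convergence raises a condition carrying the last geometry", {
  # two LJ-only atoms inside the repulsive wall with a one-step budget
  ff <- toy_ff_params(lj = data.frame(el = "C", eps = 1e-3, sigma = 3.4))
  g <- finite_geometry(c("C", "C"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  b <- toyff_backend(g, ff)
  err <- tryCatch(
    optimize_geometry(g, b, convergence_criteria(max_energy_change = 1e-12,
                                                 max_force = 1e-12,
                                                 max_displacement = 1e-12,
                                                 max_steps = 1)),
    vibrafrag_not_converged = function(e) e)
  expect_s3_class(err, "vibrafrag_not_converged")
  expect_false(is.null(err$model))
  expect_equal(dim(err$model$coords), c(2L, 3L))
})

test_that("energy never increases along an optimization of a jittered cluster", {
  fx <- make_toy_crystal("water_sheet", reps = c(1, 1, 1), noise = 0.05,
                         seed = 5)
  mols <- extract_molecules(fx$structure)
  g <- finite_geometry(mols[[1]]$elements, mols[[1]]$coords)
  r <- optimize_geometry(g, toyff_backend(g, fx$truth$ff))
  expect_true(r$converged)
  expect_true(all(diff(r$energy_trace) <= 0))
})

test_that("finite-difference Hessians recover closed-form force constants", {
  g <- hf_geom()
  b <- toyff_backend(g, hf_ff())
  H <- finite_difference_hessian(b, g)
  expect_equal(max(abs(H - t(H))), 0)  # symmetrized exactly
  # d2E/dx1dx1 along the bond axis equals 2k
  expect_equal(H[1, 1], 2 * 1.0, tolerance = 1e-6)
  expect_equal(H[1, 4], -2 * 1.0, tolerance = 1e-6)
})

test_that("central differences are exact for a quadratic potential", {
  set.seed(9)
  A <- crossprod(matrix(rnorm(36), 6))
  g <- finite_geometry(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  quad_backend <- list(
    name = "quadratic",
    energy = function(gg) {
      x <- as.vector(t(gg$coords)); 0.5 * sum(x * (A %*% x))
    },
    gradient = function(gg) {
      x <- as.vector(t(gg$coords)); matrix(A %*% x, 2, 3, byrow = TRUE)
    })
  H1 <- finite_difference_hessian(quad_backend, g, 0.01)
  H2 <- finite_difference_hessian(quad_backend, g, 0.001)
  expect_lt(max(abs(H1 - H2)), 1e-8)
  expect_lt(max(abs(H1 - (A + t(A)) / 2)), 1e-8)
})

test_that("Hessians obey the acoustic sum rule (translation invariance)", {
  for (kind in c("hf_chain", "water_sheet")) {
    fx <- make_toy_crystal(kind, reps = c(2, 1, 1))
    mols <- extract_molecules(fx$structure)
    g <- finite_geometry(unlist(lapply(mols, `[[`, "elements")),
                         do.call(rbind, lapply(mols, `[[`, "coords")))
    b <- toyff_backend(g, fx$truth$ff, fx$truth$criteria)
    # a 2e-4 A step keeps the O(step^2) truncation below the 1e-6 budget
    H <- finite_difference_hessian(b, g, 2e-4)
    n <- nrow(g$coords)
    for (ax in 1:3) {
      cols <- seq(ax, 3 * n, by = 3)
      expect_lt(max(abs(rowSums(H[, cols, drop = FALSE]))), 1e-6)
    }
  }
})

test_that("force field parameters survive a JSON round trip", {
  fx <- make_toy_crystal("formamide_sheet")
  f <- tempfile(fileext = ".json")
  write_ff_params(fx$truth$ff, f)
  p2 <- read_ff_params(f)
  expect_equal(p2$bonds, fx$truth$ff$bonds)
  expect_equal(p2$angles, fx$truth$ff$angles)
  expect_equal(p2$hbond, fx$truth$ff$hbond)
})
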