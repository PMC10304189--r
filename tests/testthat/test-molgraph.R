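# Bond perception, molecule extraction/unwrapping, dihedrals, conjugation.

test_that("bond perception follows the covalent-radius rule", {
  box <- diag(3) * 20
  s <- crystal_structure(box, c("O", "H"),
                         cart_to_frac(rbind(c(5, 5, 5), c(5.97, 5, 5)), box))
  g <- perceive_bonds(s)
  expect_equal(nrow(g), 1)  # 0.97 <= 0.66 + 0.31 + 0.40
  s2 <- crystal_structure(box, c("O", "O"),
                          cart_to_frac(rbind(c(5, 5, 5), c(7.80, 5, 5)), box))
  expect_equal(nrow(perceive_bonds(s2)), 0)  # 2.80 > 0.66 + 0.66 + 0.40
  expect_error(perceive_bonds(crystal_structure(box, "Xx", matrix(.5, 1, 3))),
               "Xx")
})

test_that("bonds realized only through an image carry the shift", {
  box <- diag(c(10, 10, 10))
  # direct separation 9.05 A; via image shift along a it is 0.95 A
  s <- crystal_structure(box, c("O", "H"),
                         rbind(c(0.02, 0.5, 0.5), c(0.925, 0.5, 0.5)))
  g <- perceive_bonds(s)
  expect_equal(nrow(g), 1)
  expect_equal(abs(g$sa), 1)
  expect_equal(g$length, 0.95, tolerance = 1e-9)
})

test_that("molecule extraction partitions sites and unwraps across faces", {
  box <- diag(3) * 12
  # two separated water-like units
  w <- function(origin) rbind(origin, origin + c(0.96, 0, 0),
                              origin + c(-0.24, 0.93, 0))
  cart <- rbind(w(c(2, 2, 2)), w(c(8, 8, 8)))
  s <- crystal_structure(box, rep(c("O", "H", "H"), 2),
                         cart_to_frac(cart, box))
  mols <- extract_molecules(s)
  expect_length(mols, 2)
  expect_equal(vapply(mols, function(m) length(m$elements), 0L), c(3L, 3L))
  expect_equal(sum(vapply(mols, function(m) length(m$elements), 0L)),
               length(s$elements))

  # molecule straddling a cell face: O just inside, H's wrapped around
  cart2 <- w(c(11.8, 6, 6))
  s2 <- crystal_structure(box, c("O", "H", "H"), cart_to_frac(cart2, box))
  m <- extract_molecules(s2)[[1]]
  d <- as.matrix(dist(m$coords))
  expect_lt(max(d[1, 2], d[1, 3]), 2)  # unwrapped: bonded pairs stay short

  expect_length(extract_molecules(
    crystal_structure(box, character(0), matrix(numeric(0), 0, 3))), 0)
})

test_that("extraction is invariant under rigid fractional translation", {
  fx <- make_toy_crystal("formamide_sheet", reps = c(2, 1, 1))
  s <- fx$structure
  s2 <- crystal_structure(s$lattice, s$elements,
                          (s$frac_coords + matrix(c(.31, .47, .23),
                                                  nrow(s$frac_coords), 3,
                                                  byrow = TRUE)))
  m1 <- extract_molecules(s)
  m2 <- extract_molecules(s2)
  expect_equal(length(m1), length(m2))
  expect_equal(sort(vapply(m1, function(m) m$formula, "")),
               sort(vapply(m2, function(m) m$formula, "")))
  # intramolecular geometry is preserved exactly (compare sorted distance sets)
  d1 <- sort(as.vector(dist(m1[[1]]$coords)))
  d2 <- sort(as.vector(dist(m2[[1]]$coords)))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("an infinite polymer is detected and rejected", {
  # carbon chain bonded to its own periodic continuation
  s <- crystal_structure(rbind(c(3, 0, 0), c(0, 12, 0), c(0, 0, 12)),
                         c("C", "C"),
                         rbind(c(0, 0.5, 0.5), c(0.5, 0.5, 0.5)))
  expect_error(extract_molecules(s), "polymer")
})

test_that("bond perception matches the 27-image brute-force oracle", {
  for (kind in c("water_sheet", "formamide_sheet")) {
    fx <- make_toy_crystal(kind)
    got <- perceive_bonds(fx$structure)
    want <- oracle_bonds(fx$structure)
    expect_equal(nrow(got), nrow(want))
    key <- function(m) paste(m[, 1], m[, 2])
    expect_setequal(key(cbind(got$i, got$j)), key(want))
  }
})

test_that("dihedral differences fold correctly and flag collinearity", {
  mk <- function(phi) {
    p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1.5, 0, 0)
    p4 <- zmat_place(p1, p2, p3, 1.5, 109.5, phi)
    structure(list(coords = rbind(p1, p2, p3, p4)), class = "molecule")
  }
  expect_equal(dihedral_difference(mk(60), mk(60), 1:4), 0)
  expect_equal(dihedral_difference(mk(180), mk(60), 1:4), 120,
               tolerance = 1e-8)
  expect_equal(dihedral_difference(mk(10), mk(350), 1:4), 20,
               tolerance = 1e-8)
  lin <- structure(list(coords = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                       c(3, 1, 0))), class = "molecule")
  expect_error(dihedral_difference(lin, lin, 1:4), "collinear")
  expect_error(dihedral_difference(mk(0), mk(0), c(1, 2, 3, 9)),
               "out of range")
})

test_that("conjugated groups follow the geometric bond-length flag", {
  # benzene-like ring: C-C 1.39 A, C-H 1.09 A
  ring <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    1.39 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  hs <- ring * (1 + 1.09 / 1.39)
  benz <- finite_geometry(c(rep("C", 6), rep("H", 6)), rbind(ring, hs))
  grp <- detect_conjugated_groups(benz)
  expect_length(grp, 1)
  expect_setequal(grp[[1]], 1:6)

  # ethane-like C-C at 1.54 A: no conjugation
  eth <- finite_geometry(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))
  expect_length(detect_conjugated_groups(eth), 0)

  # amide O=C-N fragment
  am <- finite_geometry(c("O", "C", "N"),
                        rbind(c(0, 0, 0), c(1.23, 0, 0), c(1.9, 1.16, 0)))
  grp <- detect_conjugated_groups(am)
  expect_length(grp, 1)
  expect_setequal(grp[[1]], 1:3)
})
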