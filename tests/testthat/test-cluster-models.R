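# Construction of the three cluster models and fragment interception.

test_that("the single-molecule model holds exactly one whole molecule", {
  fx <- make_toy_crystal("water_sheet")
  sc <- fx$structure
  mols <- extract_molecules(sc)
  cm <- build_single_molecule(sc, 3)
  expect_equal(cm$model_kind, "single")
  expect_true(all(cm$atom_roles == "central"))
  expect_equal(cm$geometry$coords, mols[[3]]$coords, ignore_attr = TRUE)
  expect_equal(cm$global_indices, mols[[3]]$site_indices)
  expect_error(build_single_molecule(sc, 99), "out of range")
})

test_that("the repeating unit collects the full hydrogen-bond shell", {
  fx <- make_toy_crystal("hf_chain")
  unit <- build_repeating_unit(fx$structure, NULL, fx$truth$criteria)
  expect_equal(unit$model_kind, "repeating_unit")
  # interior molecule of the chain: left and right partners
  expect_length(unit$source_molecules, 3)
  expect_equal(sum(unit$atom_roles == "central"), 2)
  expect_equal(sum(unit$atom_roles == "neighbor"), 4)
})

test_that("an isolated molecule yields a one-molecule unit with a warning", {
  box <- diag(3) * 20
  th <- 104.5 * pi / 180
  cart <- rbind(c(10, 10, 10), c(10.96, 10, 10),
                c(10, 10, 10) + 0.96 * c(cos(th), sin(th), 0))
  s <- crystal_structure(box, c("O", "H", "H"), cart_to_frac(cart, box))
  expect_warning(unit <- build_repeating_unit(s), "no hydrogen-bond partners")
  expect_equal(length(unit$geometry$elements), 3)
  expect_true(all(unit$atom_roles == "central"))
})

test_that("an incomplete hydrogen-bond shell near the boundary is an error", {
  fx <- make_toy_crystal("hf_chain", reps = c(1, 1, 1))
  expect_error(build_repeating_unit(fx$structure, NULL, fx$truth$criteria),
               "larger supercell")
})

test_that("central extraction returns the central atoms verbatim and
           commutes with rigid rotation", {
  fx <- make_toy_crystal("formamide_sheet")
  unit <- build_repeating_unit(fx$structure, NULL, fx$truth$criteria)
  central <- extract_central_molecule(unit)
  keep <- which(unit$atom_roles == "central")
  expect_identical(central$geometry$coords,
                   unit$geometry$coords[keep, , drop = FALSE])
  expect_equal(central$model_kind, "central")
  # one-molecule cluster extracts to itself
  single_like <- extract_central_molecule(central)
  expect_identical(single_like$geometry$coords, central$geometry$coords)
  # rotate whole cluster, then extract == extract, then rotate
  R <- vibrafrag:::.rotation_between(c(1, 0, 0), c(1, 2, 2))
  rotated <- unit
  rotated$geometry$coords <- unit$geometry$coords %*% t(R)
  a <- extract_central_molecule(rotated)$geometry$coords
  b <- central$geometry$coords %*% t(R)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("interception at the radius limits reproduces the spec endpoints", {
  fx <- make_toy_crystal("ethanol_dimer_cell")
  unit <- build_repeating_unit(fx$structure, NULL, fx$truth$criteria)
  # infinite radius: fragment == repeating unit, zero caps
  frag_inf <- intercept_fragment(unit, interception_rule(radius = Inf),
                                 fx$truth$criteria)
  expect_equal(sum(frag_inf$atom_roles == "cap"), 0)
  expect_equal(frag_inf$geometry$coords, unit$geometry$coords)
  # zero radius, both keep flags off: central molecule only, zero caps
  frag0 <- intercept_fragment(
    unit, interception_rule(radius = 0, keep_hbond_groups = FALSE,
                            keep_conjugated_extensions = FALSE),
    fx$truth$criteria)
  expect_equal(sum(frag0$atom_roles == "central"),
               length(frag0$geometry$elements))
  expect_equal(length(frag0$geometry$elements),
               sum(unit$atom_roles == "central"))
})

test_that("the hydrogen-bond functional group of an ethanol neighbor is
           retained with one cap on the severed C-C bond", {
  fx <- make_toy_crystal("ethanol_dimer_cell")
  unit <- build_repeating_unit(fx$structure, NULL, fx$truth$criteria)
  frag <- intercept_fragment(
    unit, interception_rule(radius = 0, keep_conjugated_extensions = FALSE),
    fx$truth$criteria)
  nb <- frag$geometry$elements[frag$atom_roles == "neighbor"]
  # hydroxyl O, its H, the adjacent C and that carbon's two H's
  expect_equal(sort(nb), c("C", "H", "H", "H", "O"))
  expect_equal(sum(frag$atom_roles == "cap"), 1)
  # cap is H, placed along the severed C->C direction at 1.09 A
  cap <- which(frag$atom_roles == "cap")
  expect_equal(frag$geometry$elements[cap], "H")
  g <- perceive_bonds(frag$geometry)
  cap_edges <- g[g$i == cap | g$j == cap, ]
  expect_equal(nrow(cap_edges), 1)
  expect_equal(cap_edges$length, 1.09, tolerance = 1e-6)
  anchor <- setdiff(c(cap_edges$i, cap_edges$j), cap)
  expect_equal(frag$geometry$elements[anchor], "C")

  # brute-force evaluation of the retention predicate, atom by atom:
  # central molecule + {O, H(O), C_adjacent} + H closure on that C
  hb <- detect_hbonds(extract_molecules(fx$structure), fx$truth$criteria)
  expect_equal(length(frag$geometry$elements),
               sum(unit$atom_roles == "central") + 5 + 1)
})

test_that("fragment size is monotone in radius and interception idempotent", {
  fx <- make_toy_crystal("ethanol_dimer_cell")
  unit <- build_repeating_unit(fx$structure, NULL, fx$truth$criteria)
  sizes <- vapply(c(0, 2, 4, 6, Inf), function(r) {
    length(intercept_fragment(unit, interception_rule(radius = r),
                              fx$truth$criteria)$geometry$elements)
  }, 0L)
  expect_true(all(diff(sizes) >= 0))

  rule <- interception_rule(radius = 0, keep_conjugated_extensions = FALSE)
  f1 <- intercept_fragment(unit, rule, fx$truth$criteria)
  f2 <- intercept_fragment(f1, rule, fx$truth$criteria)
  expect_equal(f2$geometry$elements, f1$geometry$elements)
  expect_equal(f2$geometry$coords, f1$geometry$coords, tolerance = 1e-12)
  expect_equal(f2$atom_roles, f1$atom_roles)
})

test_that("central atoms are preserved intact in every model", {
  fx <- make_toy_crystal("formamide_sheet")
  sc <- fx$structure
  unit <- build_repeating_unit(sc, NULL, fx$truth$criteria)
  central_sites <- sort(unit$global_indices[unit$atom_roles == "central"])
  single <- build_single_molecule(
    sc, unit$source_molecules[1])
  expect_equal(sort(single$global_indices), central_sites)
  for (r in c(0, 3, Inf)) {
    frag <- intercept_fragment(unit, interception_rule(radius = r),
                               fx$truth$criteria)
    expect_equal(sort(frag$global_indices[frag$atom_roles == "central"]),
                 central_sites)
  }
})

test_that("cutting through a conjugated system is refused", {
  fx <- make_toy_crystal("formamide_sheet")
  unit <- build_repeating_unit(fx$structure, NULL, fx$truth$criteria)
  # hbond functional group pulls in the amide O and C; with conjugated
  # extensions disabled the C-N bond inside the O=C-N group would be severed
  expect_error(
    intercept_fragment(unit,
                       interception_rule(radius = 0,
                                         keep_conjugated_extensions = FALSE),
                       fx$truth$criteria),
    "conjugated")
  # with extensions on, the whole amide group (and its hydrogens) survives
  frag <- intercept_fragment(unit, interception_rule(radius = 0),
                             fx$truth$criteria)
  expect_equal(sum(frag$atom_roles == "cap"), 0)
})
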