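# Synthetic toy crystals with ground truth, and the vendored experimental /
# calculated frequency tables.
#
# Fixture geometries use idealized bond lengths and angles (O-H 0.96, F-H
# 0.92, N-H 1.01, C-H 1.09, C-C 1.54, C-O 1.43, C=O 1.23, C-N(amide) 1.34 A;
# tetrahedral/trigonal angles; H-bond H...A separation 1.8 A) chosen to sit
# inside all default detection windows. At noise 0 every fixture is an exact
# stationary point of its accompanying toy force field.

.tetra_dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                      4, 3, byrow = TRUE) / sqrt(3)

# rotation matrix mapping unit(a) onto unit(b) (Rodrigues)
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

# ---- per-kind unit-cell blueprints --------------------------------------
# Each returns: lattice, elements, cart (in-cell Cartesian), bonds (local
# pairs), hbond templates (donor, h, acceptor local indices + cell offset of
# the acceptor), ff params, hbond criteria, default reps.

.blueprint_hf_chain <- function() {
  lattice <- rbind(c(2.72, 0, 0), c(0, 10, 0), c(0, 0, 10))
  cart <- rbind(c(0.4, 5, 5), c(1.32, 5, 5))  # F, H; next F at 0.4 + 2.72
  list(lattice = lattice, elements = c("F", "H"), cart = cart,
       bonds = rbind(c(1, 2)),
       hb = data.frame(d = 1, h = 2, a = 1, da = 1, db = 0, dc = 0),
       ff = toy_ff_params(
         bonds = data.frame(el1 = "F", el2 = "H", k = 1.0, r0 = 0.92),
         hbond = data.frame(donor_el = "F", acceptor_el = "F",
                            eps = 0.005, r0 = 1.8)),
       criteria = hbond_criteria(donor_elements = c("N", "O", "F"),
                                 acceptor_elements = c("N", "O", "F", "S")),
       reps = c(5L, 1L, 1L))
}

.blueprint_water_sheet <- function() {
  th <- 104.5 * pi / 180
  a <- c(2.76, 0, 0)
  b <- 2.76 * c(cos(th), sin(th), 0)
  lattice <- rbind(a, b, c(0, 0, 8))
  # keep the molecule strictly interior so no site sits on a cell face
  O <- 0.25 * a + 0.25 * b + c(0, 0, 4)
  H1 <- O + c(0.96, 0, 0)
  H2 <- O + 0.96 * c(cos(th), sin(th), 0)
  list(lattice = lattice, elements = c("O", "H", "H"),
       cart = rbind(O, H1, H2),
       bonds = rbind(c(1, 2), c(1, 3)),
       hb = data.frame(d = c(1, 1), h = c(2, 3), a = c(1, 1),
                       da = c(1, 0), db = c(0, 1), dc = c(0, 0)),
       ff = toy_ff_params(
         bonds = data.frame(el1 = "O", el2 = "H", k = 0.85, r0 = 0.96),
         angles = data.frame(el1 = "H", center = "O", el2 = "H",
                             k = 0.15, theta0 = th),
         hbond = data.frame(donor_el = "O", acceptor_el = "O",
                            eps = 0.005, r0 = 1.8)),
       criteria = hbond_criteria(),
       reps = c(3L, 3L, 1L))
}

.blueprint_formamide_sheet <- function() {
  s60 <- sin(pi / 3); c60 <- 0.5
  off <- c(0.5, 6, 4)
  O <- c(0, 0, 0)
  C <- c(1.23, 0, 0)
  N <- C + 1.34 * c(c60, s60, 0)
  HC <- C + 1.09 * c(c60, -s60, 0)
  HA <- N + c(1.01, 0, 0)
  HB <- N + 1.01 * c(-c60, s60, 0)
  cart <- sweep(rbind(O, C, N, HC, HA, HB), 2, off, "+")
  ax <- HA[1] + 1.8  # next molecule's O sits 1.8 A beyond the amide H
  lattice <- rbind(c(ax, N[2], 0), c(0, 12, 0), c(0, 0, 8))
  list(lattice = lattice, elements = c("O", "C", "N", "H", "H", "H"),
       cart = cart,
       bonds = rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5), c(3, 6)),
       hb = data.frame(d = 3, h = 5, a = 1, da = 1, db = 0, dc = 0),
       ff = toy_ff_params(
         bonds = data.frame(el1 = c("C", "C", "C", "N"),
                            el2 = c("O", "N", "H", "H"),
                            k = c(1.4, 0.9, 0.75, 0.8),
                            r0 = c(1.23, 1.34, 1.09, 1.01)),
         angles = data.frame(el1 = c("O", "O", "N", "C", "H"),
                             center = c("C", "C", "C", "N", "N"),
                             el2 = c("N", "H", "H", "H", "H"),
                             k = 0.15, theta0 = 2 * pi / 3),
         hbond = data.frame(donor_el = "N", acceptor_el = "O",
                            eps = 0.005, r0 = 1.8)),
       criteria = hbond_criteria(),
       reps = c(5L, 1L, 1L))
}

.blueprint_ethanol_dimer <- function() {
  v <- .tetra_dirs
  C2 <- c(0, 0, 0)
  C1 <- 1.54 * v[1, ]
  O <- 1.43 * v[2, ]
  H11 <- C1 - 1.09 * v[2, ]; H12 <- C1 - 1.09 * v[3, ]
  H13 <- C1 - 1.09 * v[4, ]
  H21 <- 1.09 * v[3, ]; H22 <- 1.09 * v[4, ]
  HO <- O - 0.96 * v[1, ]
  base <- rbind(C1, C2, O, H11, H12, H13, H21, H22, HO)
  R <- .rotation_between(v[2, ], v[1, ])
  A <- O - 2.76 * v[1, ]  # acceptor oxygen: collinear O-H...O at 1.8 A
  acceptor <- sweep(sweep(base, 2, O) %*% t(R), 2, A, "+")
  cart <- rbind(base, acceptor)
  cart <- sweep(cart, 2, colMeans(cart))           # center the dimer
  cart <- sweep(cart, 2, c(7, 7, 7), "+")
  lattice <- diag(c(14, 14, 14))
  el1 <- c("C", "C", "O", "H", "H", "H", "H", "H", "H")
  list(lattice = lattice, elements = c(el1, el1), cart = cart,
       bonds = {
         b <- rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                    c(2, 7), c(2, 8), c(3, 9))
         rbind(b, b + 9L)
       },
       # donor molecule 1: O(3)-HO(9) ... acceptor O(12), same cell
       hb = data.frame(d = 3, h = 9, a = 12, da = 0, db = 0, dc = 0),
       ff = toy_ff_params(
         bonds = data.frame(el1 = c("C", "C", "C", "O"),
                            el2 = c("C", "O", "H", "H"),
                            k = c(0.55, 0.65, 0.75, 0.85),
                            r0 = c(1.54, 1.43, 1.09, 0.96)),
         angles = data.frame(el1 = c("C", "C", "H", "H", "C"),
                             center = c("C", "C", "C", "C", "O"),
                             el2 = c("O", "H", "O", "H", "H"),
                             k = 0.12, theta0 = acos(-1 / 3)),
         hbond = data.frame(donor_el = "O", acceptor_el = "O",
                            eps = 0.005, r0 = 1.8)),
       criteria = hbond_criteria(),
       reps = c(1L, 1L, 1L))
}

#' Generate a toy molecular crystal with ground truth
#'
#' Deterministic synthetic crystals of small hydrogen-bond donor/acceptor
#' molecules, used throughout the test suite. At \code{noise = 0} the
#' geometry is an exact stationary point of the accompanying toy force field
#' (all bonds, angles and hydrogen-bond contacts at their reference values).
#' The returned ground truth carries the expected covalent bonds, hydrogen
#' bonds and molecule count of the supercell (as a finite cluster: bonds
#' across the outer boundary are not expected), the force field parameters,
#' and the hydrogen-bond criteria appropriate to the fixture's chemistry.
#'
#' @param kind one of \code{"hf_chain"}, \code{"water_sheet"},
#'   \code{"formamide_sheet"}, \code{"ethanol_dimer_cell"}
#' @param reps supercell repetitions (default depends on kind)
#' @param noise Cartesian jitter standard deviation in Angstrom (default 0)
#' @param seed RNG seed for the jitter
#' @return list with \code{structure} (the supercell, a
#'   \code{crystal_structure}), \code{cell} (the unit cell before
#'   replication and jitter) and \code{truth} (list: \code{bonds},
#'   \code{hbonds}, \code{n_molecules}, \code{ff}, \code{criteria},
#'   \code{kind}, \code{reps})
#' @export
make_toy_crystal <- function(kind, reps = NULL, noise = 0, seed = 1L) {
  bp <- switch(kind,
               hf_chain = .blueprint_hf_chain(),
               water_sheet = .blueprint_water_sheet(),
               formamide_sheet = .blueprint_formamide_sheet(),
               ethanol_dimer_cell = .blueprint_ethanol_dimer(),
               stop("unknown toy crystal kind: '", kind, "' (valid: hf_chain, ",
                    "water_sheet, formamide_sheet, ethanol_dimer_cell)"))
  if (noise < 0) stop("noise must be >= 0")
  if (is.null(reps)) reps <- bp$reps
  reps <- as.integer(round(reps))
  if (length(reps) != 3 || any(reps < 1)) stop("reps must be three integers >= 1")

  nsite <- length(bp$elements)
  frac <- cart_to_frac(bp$cart, bp$lattice)
  cell <- crystal_structure(bp$lattice, bp$elements, frac,
                            space_group_applied = TRUE)
  sc <- build_supercell(cell, reps)
  if (noise > 0) {
    set.seed(as.integer(seed))
    cart <- frac_to_cart(sc$frac_coords, sc$lattice)
    cart <- cart + matrix(stats::rnorm(length(cart), sd = noise),
                          nrow(cart), 3)
    sc <- crystal_structure(sc$lattice, sc$elements,
                            cart_to_frac(cart, sc$lattice), sc$site_labels,
                            space_group_applied = TRUE)
  }

  cell_index <- function(ia, ib, ic) ((ia * reps[2]) + ib) * reps[3] + ic
  gidx <- function(ia, ib, ic, k) cell_index(ia, ib, ic) * nsite + k

  bonds <- NULL
  hbonds <- NULL
  for (ia in 0:(reps[1] - 1L)) for (ib in 0:(reps[2] - 1L)) {
    for (ic in 0:(reps[3] - 1L)) {
      for (r in seq_len(nrow(bp$bonds))) {
        bonds <- rbind(bonds, c(gidx(ia, ib, ic, bp$bonds[r, 1]),
                                gidx(ia, ib, ic, bp$bonds[r, 2])))
      }
      for (r in seq_len(nrow(bp$hb))) {
        ja <- ia + bp$hb$da[r]; jb <- ib + bp$hb$db[r]; jc <- ic + bp$hb$dc[r]
        if (ja < reps[1] && jb < reps[2] && jc < reps[3]) {
          hbonds <- rbind(hbonds, c(
            donor = gidx(ia, ib, ic, bp$hb$d[r]),
            h = gidx(ia, ib, ic, bp$hb$h[r]),
            acceptor = gidx(ja, jb, jc, bp$hb$a[r])))
        }
      }
    }
  }
  hbonds <- if (is.null(hbonds)) {
    data.frame(donor = integer(0), h = integer(0), acceptor = integer(0))
  } else {
    as.data.frame(hbonds)
  }
  n_mol_per_cell <- length(unique(.component_ids(
    perceive_bonds(finite_geometry(bp$elements, bp$cart)), nsite)))
  truth <- list(bonds = bonds, hbonds = hbonds,
                n_molecules = prod(reps) * n_mol_per_cell,
                ff = bp$ff, criteria = bp$criteria,
                kind = kind, reps = reps)
  list(structure = sc, cell = cell, truth = truth)
}

#' Load a vendored experimental/calculated frequency table
#'
#' Row-for-row copies (cm^-1) of the published comparison tables for
#' Finasteride (FIN), Lamivudine (LAM) and Repaglinide (REP): \code{*_t1}
#' single-molecule calculation with the 0.99-scaled column, \code{*_t2}
#' central-molecule calculation, \code{*_t3} intercepted-fragment
#' calculation. Note that the REP scaled column (and one LAM row) as printed
#' are not consistent with the stated 0.99 factor; they are vendored as
#' printed.
#'
#' @param name one of FIN_t1, LAM_t1, REP_t1, FIN_t2, LAM_t2, REP_t2,
#'   FIN_t3, LAM_t3, REP_t3
#' @return an \code{assignment_table} with columns label, exp, calc, group
#'   and, depending on the table, scaled or central
#' @export
load_paper_table <- function(name) {
  valid <- c("FIN_t1", "LAM_t1", "REP_t1", "FIN_t2", "LAM_t2", "REP_t2",
             "FIN_t3", "LAM_t3", "REP_t3")
  if (!name %in% valid) {
    stop("unknown table '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  path <- system.file("extdata", "paper_tables",
                      paste0(tolower(name), ".csv"), package = "vibrafrag")
  if (!nzchar(path)) stop("packaged table not found for ", name)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- assignment_table(df$label, df$exp, df$calc, df$group)
  if (!is.null(df$scaled)) out$scaled <- df$scaled
  if (!is.null(df$central)) out$central <- df$central
  out
}
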