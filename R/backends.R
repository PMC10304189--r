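# Energy/gradient backend contract, the built-in harmonic toy force field,
# quasi-Newton geometry optimization, and finite-difference Hessians.
#
# A backend is a list with fields `name`, `energy(geometry) -> Hartree` and
# `gradient(geometry) -> n x 3 matrix in Hartree/Angstrom`. Any object
# honouring that contract (e.g. an adapter around an external quantum code)
# can drive the optimizer and the Hessian builder.

#' Toy force field parameters
#'
#' A transparent harmonic force field used as the testing backend:
#' E = sum k_b (r - r0)^2 + sum k_theta (theta - theta0)^2 + nonbonded,
#' with optional per-element Lennard-Jones and fixed point charges
#' (1-2 and 1-3 pairs excluded) and an optional 12-10 hydrogen-bond term
#' applied to an explicit H...acceptor pair list.
#'
#' @param bonds data.frame with columns el1, el2, k (Hartree/A^2), r0 (A)
#' @param angles data.frame with columns el1, center, el2, k (Hartree/rad^2),
#'   theta0 (radians); ends are order-insensitive
#' @param lj optional data.frame with columns el, eps (Hartree), sigma (A)
#' @param charges optional named numeric vector of per-element charges (e)
#' @param hbond optional data.frame with columns donor_el, acceptor_el,
#'   eps (Hartree), r0 (A) for the 12-10 term
#' @return an object of class \code{toy_ff_params}
#' @export
toy_ff_params <- function(bonds = NULL, angles = NULL, lj = NULL,
                          charges = NULL, hbond = NULL) {
  if (!is.null(bonds) && (any(bonds$k < 0) || any(bonds$r0 <= 0))) {
    stop("bond k must be >= 0 and r0 > 0")
  }
  if (!is.null(angles) && any(angles$k < 0)) stop("angle k must be >= 0")
  if (!is.null(lj) && any(lj$sigma <= 0)) stop("LJ sigma must be > 0")
  structure(list(bonds = bonds, angles = angles, lj = lj, charges = charges,
                 hbond = hbond),
            class = "toy_ff_params")
}

#' Optimization convergence criteria
#'
#' Defaults follow common practice for molecular cluster optimization:
#' 1e-5 Hartree energy change, 0.002 Hartree/A force, 0.005 A displacement,
#' all three required simultaneously on an accepted step. Force and
#' displacement are measured as the maximum over atoms of the per-atom
#' Euclidean norm.
#'
#' @param max_energy_change Hartree
#' @param max_force Hartree/Angstrom
#' @param max_displacement Angstrom
#' @param max_steps maximum optimizer steps
#' @return an object of class \code{convergence_criteria}
#' @export
convergence_criteria <- function(max_energy_change = 1e-5, max_force = 0.002,
                                 max_displacement = 0.005, max_steps = 500L) {
  vals <- c(max_energy_change, max_force, max_displacement, max_steps)
  if (any(vals <= 0)) stop("all convergence criteria must be positive")
  structure(list(max_energy_change = max_energy_change,
                 max_force = max_force,
                 max_displacement = max_displacement,
                 max_steps = as.integer(max_steps)),
            class = "convergence_criteria")
}

.bond_lookup <- function(params, e1, e2) {
  b <- params$bonds
  if (!is.null(b)) {
    hit <- which((b$el1 == e1 & b$el2 == e2) | (b$el1 == e2 & b$el2 == e1))
    if (length(hit)) return(b[hit[1], ])
  }
  stop("missing toy-FF bond term for pair ", .pair_key(e1, e2))
}

.angle_lookup <- function(params, e1, ec, e2) {
  a <- params$angles
  if (!is.null(a)) {
    hit <- which(a$center == ec &
                   ((a$el1 == e1 & a$el2 == e2) | (a$el1 == e2 & a$el2 == e1)))
    if (length(hit)) return(a[hit[1], ])
  }
  stop("missing toy-FF angle term for ", e1, "-", ec, "-", e2)
}

# angle triples (i, j, k) with j the center, from a finite bond graph
.angle_list <- function(bonds, n) {
  bonded <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    bonded[[bonds$i[r]]] <- c(bonded[[bonds$i[r]]], bonds$j[r])
    bonded[[bonds$j[r]]] <- c(bonded[[bonds$j[r]]], bonds$i[r])
  }
  out <- NULL
  for (j in seq_len(n)) {
    nb <- sort(bonded[[j]])
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      out <- rbind(out, cbind(pr[1, ], j, pr[2, ]))
    }
  }
  out
}

#' Toy force field energy and analytic gradient
#'
#' @param g a \code{finite_geometry}
#' @param params a \code{toy_ff_params}
#' @param topology a finite \code{bond_graph} over the atoms of \code{g}
#' @param hbond_pairs optional 2-column matrix of (H atom, acceptor atom)
#'   indices receiving the 12-10 hydrogen-bond term
#' @return list with \code{energy} (Hartree) and \code{gradient}
#'   (n x 3, Hartree/Angstrom)
#' @export
toy_ff_energy_gradient <- function(g, params, topology, hbond_pairs = NULL) {
  x <- g$coords
  n <- nrow(x)
  E <- 0
  grad <- matrix(0, n, 3)

  # overlap guard
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sum((x[j, ] - x[i, ])^2) < 0.01) {
        stop("overlapping atoms ", i, " and ", j, " (r < 0.1 A)")
      }
    }
  }

  # bonds
  for (r in seq_len(nrow(topology))) {
    i <- topology$i[r]; j <- topology$j[r]
    term <- .bond_lookup(params, g$elements[i], g$elements[j])
    d <- x[j, ] - x[i, ]
    rij <- sqrt(sum(d^2))
    E <- E + term$k * (rij - term$r0)^2
    f <- 2 * term$k * (rij - term$r0) * d / rij
    grad[i, ] <- grad[i, ] - f
    grad[j, ] <- grad[j, ] + f
  }

  # angles
  ang <- .angle_list(topology, n)
  for (r in seq_len(NROW(ang))) {
    i <- ang[r, 1]; j <- ang[r, 2]; k <- ang[r, 3]
    term <- .angle_lookup(params, g$elements[i], g$elements[j], g$elements[k])
    u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    ct <- max(-1, min(1, sum(u * v) / (lu * lv)))
    th <- acos(ct)
    st <- sqrt(max(1e-12, 1 - ct^2))
    E <- E + term$k * (th - term$theta0)^2
    pref <- 2 * term$k * (th - term$theta0)
    dth_di <- (ct * u / lu - v / lv) / (lu * st)
    dth_dk <- (ct * v / lv - u / lu) / (lv * st)
    grad[i, ] <- grad[i, ] + pref * dth_di
    grad[k, ] <- grad[k, ] + pref * dth_dk
    grad[j, ] <- grad[j, ] - pref * (dth_di + dth_dk)
  }

  # nonbonded LJ + Coulomb with 1-2/1-3 exclusions
  if (!is.null(params$lj) || !is.null(params$charges)) {
    excl <- matrix(FALSE, n, n)
    for (r in seq_len(nrow(topology))) {
      excl[topology$i[r], topology$j[r]] <- TRUE
      excl[topology$j[r], topology$i[r]] <- TRUE
    }
    ang2 <- .angle_list(topology, n)
    for (r in seq_len(NROW(ang2))) {
      excl[ang2[r, 1], ang2[r, 3]] <- TRUE
      excl[ang2[r, 3], ang2[r, 1]] <- TRUE
    }
    if (!is.null(hbond_pairs)) {
      for (r in seq_len(NROW(hbond_pairs))) {
        excl[hbond_pairs[r, 1], hbond_pairs[r, 2]] <- TRUE
        excl[hbond_pairs[r, 2], hbond_pairs[r, 1]] <- TRUE
      }
    }
    lj <- params$lj
    q <- params$charges
    coulomb_k <- 0.529177210903  # Hartree * A per e^2 (1/(4 pi eps0) in a.u.)
    for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
      if (n < 2 || excl[i, j]) next
      d <- x[j, ] - x[i, ]
      rij <- sqrt(sum(d^2))
      dEdr <- 0
      if (!is.null(lj)) {
        pi_ <- match(g$elements[i], lj$el); pj_ <- match(g$elements[j], lj$el)
        if (!is.na(pi_) && !is.na(pj_)) {
          eps <- sqrt(lj$eps[pi_] * lj$eps[pj_])
          sig <- (lj$sigma[pi_] + lj$sigma[pj_]) / 2
          sr6 <- (sig / rij)^6
          E <- E + 4 * eps * (sr6^2 - sr6)
          dEdr <- dEdr + 4 * eps * (-12 * sr6^2 + 6 * sr6) / rij
        }
      }
      if (!is.null(q)) {
        qi <- q[g$elements[i]]; qj <- q[g$elements[j]]
        if (!is.na(qi) && !is.na(qj) && qi * qj != 0) {
          E <- E + coulomb_k * qi * qj / rij
          dEdr <- dEdr - coulomb_k * qi * qj / rij^2
        }
      }
      if (dEdr != 0) {
        f <- dEdr * d / rij
        grad[i, ] <- grad[i, ] - f
        grad[j, ] <- grad[j, ] + f
      }
    }
  }

  # 12-10 hydrogen-bond term on explicit pairs
  if (!is.null(hbond_pairs) && NROW(hbond_pairs) && !is.null(params$hbond)) {
    hb <- params$hbond
    for (r in seq_len(NROW(hbond_pairs))) {
      h <- hbond_pairs[r, 1]; a <- hbond_pairs[r, 2]
      d_el <- attr(hbond_pairs, "donor_el")
      del <- if (!is.null(d_el)) d_el[r] else NA
      hit <- which(hb$acceptor_el == g$elements[a] &
                     (is.na(del) | hb$donor_el == del))
      if (!length(hit)) {
        stop("missing toy-FF hbond term for acceptor ", g$elements[a])
      }
      eps <- hb$eps[hit[1]]; r0 <- hb$r0[hit[1]]
      d <- x[a, ] - x[h, ]
      rij <- sqrt(sum(d^2))
      sr <- r0 / rij
      E <- E + eps * (5 * sr^12 - 6 * sr^10)
      dEdr <- eps * (-60 * sr^12 + 60 * sr^10) / rij
      f <- dEdr * d / rij
      grad[h, ] <- grad[h, ] - f
      grad[a, ] <- grad[a, ] + f
    }
  }

  list(energy = E, gradient = grad)
}

#' Construct a toy force field backend for a geometry
#'
#' Perceives the covalent topology once at construction and, when hydrogen-bond
#' parameters and criteria are supplied, detects the H...acceptor pairs that
#' receive the 12-10 term. The topology is then frozen, consistent with the
#' harmonic treatment around a reference structure.
#'
#' @param geometry a \code{finite_geometry} defining the topology
#' @param params a \code{toy_ff_params}
#' @param criteria optional \code{hbond_criteria} enabling the 12-10 term
#' @param tolerance covalent bond tolerance in Angstrom
#' @return a backend list with \code{name}, \code{energy}, \code{gradient},
#'   plus the frozen \code{topology} and \code{hbond_pairs}
#' @export
toyff_backend <- function(geometry, params, criteria = NULL,
                          tolerance = 0.40) {
  topology <- perceive_bonds(geometry, tolerance)
  hbond_pairs <- NULL
  if (!is.null(criteria) && !is.null(params$hbond)) {
    mol_id <- .component_ids(topology, length(geometry$elements))
    hb <- .detect_hbonds_flat(geometry$elements, geometry$coords, mol_id,
                              seq_along(geometry$elements), criteria, topology)
    if (nrow(hb)) {
      hbond_pairs <- cbind(hb$h, hb$acceptor)
      attr(hbond_pairs, "donor_el") <- geometry$elements[hb$donor]
    }
  }
  list(
    name = "toyff",
    topology = topology,
    hbond_pairs = hbond_pairs,
    energy = function(g) {
      toy_ff_energy_gradient(g, params, topology, hbond_pairs)$energy
    },
    gradient = function(g) {
      toy_ff_energy_gradient(g, params, topology, hbond_pairs)$gradient
    }
  )
}

# connected-component labels from a finite bond graph
.component_ids <- function(bonds, n) {
  id <- integer(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (id[s]) next
    cur <- cur + 1L
    queue <- s; id[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!id[w]) { id[w] <- cur; queue <- c(queue, w) }
    }
  }
  id
}

#' Quasi-Newton geometry optimization
#'
#' BFGS with backtracking line search. Converged when, on one accepted step,
#' the energy change, the maximum per-atom force and the maximum per-atom
#' displacement are all within the criteria simultaneously. Atom roles and
#' bookkeeping of cluster models are preserved. Energy never increases
#' between accepted steps. Failure to converge raises a condition of class
#' \code{vibrafrag_not_converged} carrying the last geometry.
#'
#' @param c a \code{cluster_model} or \code{finite_geometry}
#' @param b an energy backend (see \code{\link{toyff_backend}})
#' @param crit a \code{convergence_criteria}
#' @return list with the optimized \code{model} (same class as the input),
#'   \code{converged}, \code{steps}, \code{energy}, \code{energy_trace},
#'   \code{max_force}, \code{energy_change}, \code{max_displacement}
#' @export
optimize_geometry <- function(c, b, crit = convergence_criteria()) {
  is_cluster <- inherits(c, "cluster_model")
  geom <- if (is_cluster) c$geometry else c
  n <- nrow(geom$coords)
  as_geom <- function(x) {
    finite_geometry(geom$elements, matrix(x, n, 3, byrow = TRUE), geom$masses)
  }
  pack <- function(m) as.vector(t(m))
  max_atom_norm <- function(v) {
    m <- matrix(v, n, 3, byrow = TRUE)
    sqrt(max(rowSums(m^2)))
  }
  wrap <- function(gfin) {
    if (!is_cluster) return(gfin)
    out <- c
    out$geometry <- gfin
    out
  }

  x <- pack(geom$coords)
  E <- b$energy(as_geom(x))
  gr <- pack(b$gradient(as_geom(x)))
  trace <- E
  H <- diag(3 * n)  # inverse Hessian approximation
  steps <- 0L
  dE <- 0; dx <- 0

  fail <- function(msg, xlast, Elast, grlast) {
    cond <- structure(
      class = c("vibrafrag_not_converged", "error", "condition"),
      list(message = msg, call = NULL, model = wrap(as_geom(xlast)),
           energy = Elast, max_force = max_atom_norm(grlast), steps = steps))
    stop(cond)
  }

  if (max_atom_norm(gr) <= crit$max_force) {
    return(list(model = wrap(as_geom(x)), converged = TRUE, steps = 0L,
                energy = E, energy_trace = trace,
                max_force = max_atom_norm(gr), energy_change = 0,
                max_displacement = 0))
  }

  while (steps < crit$max_steps) {
    steps <- steps + 1L
    p <- -as.vector(H %*% gr)
    if (sum(p * gr) >= 0) { H <- diag(3 * n); p <- -gr }
    # keep the first trial step physically small
    pn <- max_atom_norm(p)
    t0 <- min(1, 0.3 / pn)
    t <- t0
    accepted <- FALSE
    while (t > 1e-14) {
      x1 <- x + t * p
      E1 <- b$energy(as_geom(x1))
      if (E1 <= E + 1e-4 * t * sum(gr * p)) { accepted <- TRUE; break }
      t <- t / 2
    }
    if (!accepted) {
      if (max_atom_norm(gr) <= crit$max_force) break
      fail(sprintf("line search failed at step %d (flat or non-descent region)",
                   steps), x, E, gr)
    }
    gr1 <- pack(b$gradient(as_geom(x1)))
    s <- x1 - x
    y <- gr1 - gr
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(3 * n)
      V <- I - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    dE <- abs(E - E1)
    dx <- max_atom_norm(s)
    x <- x1; E <- E1; gr <- gr1
    trace <- c(trace, E)
    if (dE <= crit$max_energy_change &&
        max_atom_norm(gr) <= crit$max_force &&
        dx <= crit$max_displacement) {
      return(list(model = wrap(as_geom(x)), converged = TRUE, steps = steps,
                  energy = E, energy_trace = trace,
                  max_force = max_atom_norm(gr), energy_change = dE,
                  max_displacement = dx))
    }
  }
  if (max_atom_norm(gr) <= crit$max_force &&
      dE <= crit$max_energy_change && dx <= crit$max_displacement) {
    return(list(model = wrap(as_geom(x)), converged = TRUE, steps = steps,
                energy = E, energy_trace = trace,
                max_force = max_atom_norm(gr), energy_change = dE,
                max_displacement = dx))
  }
  fail(sprintf("not converged in %d steps (|dE|=%.2e, max force=%.2e, max dx=%.2e)",
               steps, dE, max_atom_norm(gr), dx), x, E, gr)
}

#' Finite-difference Hessian from backend gradients
#'
#' Central differences of the gradient with symmetrization
#' H <- (H + t(H)) / 2.
#'
#' @param b an energy backend
#' @param g a \code{finite_geometry}
#' @param step displacement step in Angstrom (default 0.005)
#' @return 3N x 3N symmetric matrix in Hartree/Angstrom^2
#' @export
finite_difference_hessian <- function(b, g, step = 0.005) {
  if (step <= 0) stop("step must be > 0")
  n <- nrow(g$coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    for (ax in 1:3) {
      col <- 3 * (a - 1) + ax
      gp <- g; gp$coords[a, ax] <- gp$coords[a, ax] + step
      gm <- g; gm$coords[a, ax] <- gm$coords[a, ax] - step
      dp <- tryCatch(b$gradient(gp), error = function(e) {
        stop("backend gradient failed at atom ", a, " axis ", ax,
             " (+", step, " A): ", conditionMessage(e))
      })
      dm <- tryCatch(b$gradient(gm), error = function(e) {
        stop("backend gradient failed at atom ", a, " axis ", ax,
             " (-", step, " A): ", conditionMessage(e))
      })
      H[, col] <- as.vector(t(dp - dm)) / (2 * step)
    }
  }
  (H + t(H)) / 2
}

#' Write toy force field parameters to a JSON file
#' @param params a \code{toy_ff_params}
#' @param path output file path
#' @return invisibly, the path
#' @export
write_ff_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read toy force field parameters from a JSON file
#' @param path path to a JSON file written by \code{\link{write_ff_params}}
#' @return a \code{toy_ff_params}
#' @export
read_ff_params <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ch <- if (is.null(x$charges)) NULL else unlist(x$charges)
  toy_ff_params(bonds = x$bonds, angles = x$angles, lj = x$lj,
                charges = ch, hbond = x$hbond)
}
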