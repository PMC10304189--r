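# Covalent bond perception under periodic boundary conditions, molecule
# extraction with unwrapping, conformational comparison.

#' Hill-notation molecular formula
#' @param elements character vector of element symbols
#' @return formula string (C first, H second, others alphabetical)
#' @export
hill_formula <- function(elements) {
  tab <- table(elements)
  syms <- names(tab)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    if (tab[[s]] == 1) s else paste0(s, tab[[s]])
  }, ""), collapse = "")
}

#' Perceive covalent bonds
#'
#' Two sites are bonded iff their minimum-image distance does not exceed the
#' sum of their covalent radii plus \code{tolerance}; H-H bonds are excluded.
#' For periodic structures the realizing lattice image shift is recorded per
#' edge: the bond is realized between site i and the image of site j displaced
#' by \code{shift} cells.
#'
#' @param s a \code{crystal_structure} or \code{finite_geometry}
#' @param tolerance bond-perception tolerance in Angstrom (default 0.40)
#' @return a \code{bond_graph}: data.frame with columns i, j, sa, sb, sc
#'   (image shift of j) and length (Angstrom), with attribute \code{n_sites}
#' @export
perceive_bonds <- function(s, tolerance = 0.40) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (inherits(s, "finite_geometry")) {
    el <- s$elements
    cart <- s$coords
    periodic <- FALSE
  } else {
    el <- s$elements
    periodic <- TRUE
  }
  n <- length(el)
  rc <- if (n) covalent_radius(el) else numeric(0)
  edges <- data.frame(i = integer(0), j = integer(0), sa = integer(0),
                      sb = integer(0), sc = integer(0), length = numeric(0))
  if (n >= 2) {
    shifts <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (el[i] == "H" && el[j] == "H") next
        cutoff <- rc[i] + rc[j] + tolerance
        if (periodic) {
          # record every image within the cutoff: a pair bonded through two
          # different images signals a periodic polymer, caught downstream
          d <- s$frac_coords[j, ] - s$frac_coords[i, ]
          for (k in seq_len(nrow(shifts))) {
            r <- sqrt(sum(((d + shifts[k, ]) %*% s$lattice)^2))
            if (r <= cutoff) {
              edges <- rbind(edges, data.frame(
                i = i, j = j, sa = shifts[k, 1], sb = shifts[k, 2],
                sc = shifts[k, 3], length = r))
            }
          }
        } else {
          r <- sqrt(sum((cart[j, ] - cart[i, ])^2))
          if (r <= cutoff) {
            edges <- rbind(edges, data.frame(i = i, j = j, sa = 0L, sb = 0L,
                                             sc = 0L, length = r))
          }
        }
      }
    }
  }
  attr(edges, "n_sites") <- n
  class(edges) <- c("bond_graph", "data.frame")
  edges
}

# adjacency list from a bond_graph: for each site, a matrix of
# (neighbor, sa, sb, sc) rows; shift is the image of the neighbor.
.adjacency <- function(g, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(g))) {
    i <- g$i[k]; j <- g$j[k]; s <- c(g$sa[k], g$sb[k], g$sc[k])
    adj[[i]] <- rbind(adj[[i]], c(j, s))
    adj[[j]] <- rbind(adj[[j]], c(i, -s))
  }
  adj
}

#' Extract whole molecules from a periodic structure
#'
#' Molecules are the connected components of the covalent bond graph. Each
#' component is unwrapped by breadth-first traversal accumulating image
#' shifts, so every bond is realized without minimum-image wrapping; the
#' component's lowest site index is anchored at shift (0,0,0). A component
#' that revisits a site at a different net shift is an infinite polymer and
#' raises an error. Molecules are ordered by (formula, centroid).
#'
#' @param s a \code{crystal_structure}
#' @param g a \code{bond_graph} built from \code{s} (default: perceived here)
#' @param tolerance bond tolerance used when \code{g} is not supplied
#' @return list of \code{molecule} objects, each with fields
#'   \code{site_indices}, \code{elements}, \code{coords} (unwrapped Cartesian),
#'   \code{formula}, \code{centroid}
#' @export
extract_molecules <- function(s, g = NULL, tolerance = 0.40) {
  n <- length(s$elements)
  if (!n) return(list())
  if (is.null(g)) g <- perceive_bonds(s, tolerance)
  adj <- .adjacency(g, n)
  visited <- logical(n)
  net_shift <- matrix(NA_real_, n, 3)
  mols <- list()
  for (start in seq_len(n)) {
    if (visited[start]) next
    comp <- integer(0)
    visited[start] <- TRUE
    net_shift[start, ] <- c(0, 0, 0)
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          w <- nb[r, 1]
          sh <- net_shift[v, ] + nb[r, 2:4]
          if (!visited[w]) {
            visited[w] <- TRUE
            net_shift[w, ] <- sh
            queue <- c(queue, w)
          } else if (any(abs(net_shift[w, ] - sh) > 1e-9)) {
            stop("periodic polymer, not a molecular crystal: site ", w,
                 " is reachable at two different lattice shifts")
          }
        }
      }
    }
    comp <- sort(comp)
    cart <- (s$frac_coords[comp, , drop = FALSE] +
               net_shift[comp, , drop = FALSE]) %*% s$lattice
    mols[[length(mols) + 1L]] <- structure(list(
      site_indices = comp,
      elements = s$elements[comp],
      coords = cart,
      formula = hill_formula(s$elements[comp]),
      centroid = colMeans(cart)
    ), class = "molecule")
  }
  cen <- t(vapply(mols, function(m) m$centroid, numeric(3)))
  ord <- order(vapply(mols, function(m) m$formula, ""),
               round(cen[, 1], 6), round(cen[, 2], 6), round(cen[, 3], 6))
  mols[ord]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule %s: %d atoms, centroid (%.3f, %.3f, %.3f) A\n",
              x$formula, length(x$elements),
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Signed dihedral angle (IUPAC convention)
#' @param p 4 x 3 matrix of Cartesian positions
#' @return signed dihedral in degrees, in (-180, 180]
#' @export
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-8 || sqrt(sum(n2^2)) < 1e-8) {
    stop("undefined dihedral: three consecutive atoms are collinear")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2n)
  atan2(y, x) * 180 / pi
}

#' Dihedral twist between two conformations
#'
#' Absolute difference of the signed dihedrals of the same four atoms in two
#' molecules with identical atom ordering, folded into [0, 180] degrees.
#'
#' @param a,b \code{molecule} objects (or anything with a \code{coords} matrix)
#' @param quad integer vector of four atom indices
#' @return twist angle in degrees
#' @export
dihedral_difference <- function(a, b, quad) {
  if (length(quad) != 4) stop("quad must contain four atom indices")
  if (any(quad < 1) || any(quad > nrow(a$coords)) || any(quad > nrow(b$coords))) {
    stop("quad indices out of range")
  }
  da <- dihedral_angle(a$coords[quad, , drop = FALSE])
  db <- dihedral_angle(b$coords[quad, , drop = FALSE])
  d <- abs(da - db) %% 360
  if (d > 180) d <- 360 - d
  d
}

#' Detect conjugated groups by bond-length criteria
#'
#' An atom is flagged unsaturated if it participates in a bond shorter than
#' the multiple-bond threshold for its element pair, or if it is O/N
#' covalently bonded to such an atom. Returns the maximal connected sets of
#' flagged atoms (connected through covalent bonds between flagged atoms).
#'
#' @param m a \code{molecule} or \code{finite_geometry}
#' @param bonds optional \code{bond_graph} over the atoms of \code{m}
#' @param tolerance bond tolerance used when \code{bonds} is not supplied
#' @return list of integer vectors of atom indices (possibly empty)
#' @export
detect_conjugated_groups <- function(m, bonds = NULL, tolerance = 0.40) {
  g <- if (inherits(m, "finite_geometry")) m else
    finite_geometry(m$elements, m$coords)
  n <- length(g$elements)
  if (is.null(bonds)) bonds <- perceive_bonds(g, tolerance)
  flagged <- logical(n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    key <- .pair_key(g$elements[i], g$elements[j])
    thr <- .unsat_threshold[key]
    if (!is.na(thr) && bonds$length[k] < thr) flagged[i] <- flagged[j] <- TRUE
  }
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (flagged[i] && !flagged[j] && g$elements[j] %in% c("N", "O")) {
      flagged[j] <- TRUE
    }
    if (flagged[j] && !flagged[i] && g$elements[i] %in% c("N", "O")) {
      flagged[i] <- TRUE
    }
  }
  if (!any(flagged)) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (flagged[i] && flagged[j]) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  groups <- list()
  for (start in which(flagged)) {
    if (seen[start]) next
    comp <- integer(0); queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    groups[[length(groups) + 1L]] <- sort(comp)
  }
  groups
}
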