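# Periodic crystal structures, CIF subset I/O, supercells, XYZ I/O.

#' Periodic crystal structure
#'
#' A minimal container for a periodic cell: row-wise lattice vectors (Angstrom),
#' per-site element symbols and fractional coordinates. Fractional coordinates
#' are wrapped into [0, 1) on construction; Cartesian coordinates are used
#' everywhere outside this container.
#'
#' @param lattice 3x3 numeric matrix, rows are the a, b, c lattice vectors (Angstrom)
#' @param elements character vector of element symbols, one per site
#' @param frac_coords n x 3 numeric matrix of fractional coordinates
#' @param site_labels optional character vector of site labels
#' @param space_group_applied logical, whether symmetry expansion has been performed
#' @return an object of class \code{crystal_structure}
#' @export
crystal_structure <- function(lattice, elements, frac_coords,
                              site_labels = NULL, space_group_applied = FALSE) {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  if (nrow(frac_coords) == 0) {
    frac_coords <- matrix(numeric(0), 0, 3)
  } else {
    frac_coords <- matrix(as.numeric(frac_coords), ncol = 3)
  }
  if (length(elements) != nrow(frac_coords)) {
    stop("length(elements) must equal nrow(frac_coords)")
  }
  vol <- abs(det(lattice))
  if (!is.finite(vol) || vol <= 0) stop("cell volume must be > 0")
  if (is.null(site_labels)) {
    site_labels <- if (length(elements)) {
      paste0(elements, seq_along(elements))
    } else character(0)
  }
  frac_coords <- frac_coords %% 1
  structure(list(
    lattice = lattice,
    elements = as.character(elements),
    frac_coords = frac_coords,
    site_labels = as.character(site_labels),
    space_group_applied = isTRUE(space_group_applied)
  ), class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  p <- cell_params(x)
  cat(sprintf("crystal_structure: %d sites, a=%.4f b=%.4f c=%.4f A, ",
              length(x$elements), p[1], p[2], p[3]))
  cat(sprintf("alpha=%.2f beta=%.2f gamma=%.2f deg, V=%.2f A^3\n",
              p[4], p[5], p[6], cell_volume(x)))
  invisible(x)
}

#' Cell volume in cubic Angstrom
#' @param s a \code{crystal_structure}
#' @return numeric scalar
#' @export
cell_volume <- function(s) abs(det(s$lattice))

#' Cell parameters (a, b, c, alpha, beta, gamma) from a structure
#' @param s a \code{crystal_structure}
#' @return numeric vector of lengths (Angstrom) and angles (degrees)
#' @export
cell_params <- function(s) {
  L <- s$lattice
  a <- sqrt(sum(L[1, ]^2)); b <- sqrt(sum(L[2, ]^2)); c <- sqrt(sum(L[3, ]^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = a, b = b, c = c,
    alpha = ang(L[2, ], L[3, ]), beta = ang(L[1, ], L[3, ]),
    gamma = ang(L[1, ], L[2, ]))
}

#' Lattice vectors from cell parameters (canonical orientation)
#'
#' a along x, b in the xy plane, c completing a right-handed cell.
#' @param a,b,c cell lengths in Angstrom
#' @param alpha,beta,gamma cell angles in degrees
#' @return 3x3 matrix of row-wise lattice vectors
#' @export
lattice_from_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell parameters")
  rbind(c(a, 0, 0),
        c(b * cg, b * sg, 0),
        c(cx, cy, sqrt(cz2)))
}

#' Fractional to Cartesian coordinates
#' @param frac n x 3 matrix of fractional coordinates
#' @param lattice 3x3 row-wise lattice matrix
#' @return n x 3 matrix of Cartesian coordinates (Angstrom)
#' @export
frac_to_cart <- function(frac, lattice) {
  matrix(as.numeric(frac), ncol = 3) %*% lattice
}

#' Cartesian to fractional coordinates
#' @param cart n x 3 matrix of Cartesian coordinates (Angstrom)
#' @param lattice 3x3 row-wise lattice matrix
#' @return n x 3 matrix of fractional coordinates
#' @export
cart_to_frac <- function(cart, lattice) {
  matrix(as.numeric(cart), ncol = 3) %*% solve(lattice)
}

# minimum-image Cartesian distance between two fractional coordinates
.min_image_dist <- function(f1, f2, lattice) {
  d <- f2 - f1
  d <- d - round(d)
  sqrt(sum((d %*% lattice)^2))
}

# ---------------------------------------------------------------------------
# CIF subset parser: P1 cells and explicit symmetry operator lists.

.strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

.tokenize_cif_line <- function(line) {
  out <- character(0)
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

#' Parse a symmetry operator string
#'
#' Accepts the usual xyz notation ("x, -y+1/2, z"); returns the rotation
#' matrix and translation vector acting on fractional coordinates.
#' @param text operator string, e.g. \code{"-x, y+1/2, -z"}
#' @return list with 3x3 matrix \code{R} and length-3 vector \code{t}
#' @export
parse_symop <- function(text) {
  comps <- strsplit(gsub("[[:space:]]", "", tolower(text)), ",")[[1]]
  if (length(comps) != 3) stop("unparseable symmetry operator: '", text, "'")
  R <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (k in 1:3) {
    toks <- regmatches(comps[k],
                       gregexpr("[+-]?[^+-]+", comps[k], perl = TRUE))[[1]]
    if (!length(toks)) stop("unparseable symmetry operator: '", text, "'")
    for (tok in toks) {
      sgn <- 1
      body <- tok
      if (startsWith(body, "+")) body <- substring(body, 2)
      if (startsWith(body, "-")) { sgn <- -1; body <- substring(body, 2) }
      if (body %in% c("x", "y", "z")) {
        R[k, match(body, c("x", "y", "z"))] <-
          R[k, match(body, c("x", "y", "z"))] + sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        f <- as.numeric(strsplit(body, "/")[[1]])
        tr[k] <- tr[k] + sgn * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tr[k] <- tr[k] + sgn * as.numeric(body)
      } else {
        stop("unparseable symmetry operator: '", text, "'")
      }
    }
  }
  list(R = R, t = tr)
}

#' Apply symmetry operators and merge duplicate sites
#'
#' Expands each site by every operator, wraps fractional coordinates into
#' [0, 1) and merges sites closer than \code{merge_tol} (Cartesian,
#' minimum image). Expansion is idempotent: re-expanding an expanded
#' structure with the same operators changes nothing.
#'
#' @param s a \code{crystal_structure}
#' @param ops list of operators as returned by \code{parse_symop}
#' @param merge_tol duplicate-site merge tolerance in Angstrom
#' @return expanded \code{crystal_structure} with \code{space_group_applied = TRUE}
#' @export
expand_symmetry <- function(s, ops, merge_tol = 0.3) {
  if (!length(ops)) ops <- list(list(R = diag(3), t = numeric(3)))
  frac <- NULL; el <- character(0); lab <- character(0)
  for (i in seq_along(s$elements)) {
    for (op in ops) {
      f <- (op$R %*% s$frac_coords[i, ] + op$t) %% 1
      frac <- rbind(frac, as.numeric(f))
      el <- c(el, s$elements[i])
      lab <- c(lab, s$site_labels[i])
    }
  }
  keep <- logical(nrow(frac))
  for (i in seq_len(nrow(frac))) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (keep[j] &&
          .min_image_dist(frac[i, ], frac[j, ], s$lattice) < merge_tol) {
        dup <- TRUE; break
      }
    }
    keep[i] <- !dup
  }
  crystal_structure(s$lattice, el[keep], frac[keep, , drop = FALSE],
                    lab[keep], space_group_applied = TRUE)
}

#' Read a crystal structure from a CIF file
#'
#' Supports a practical subset: one data block with cell parameters, an atom
#' site loop with fractional coordinates, and either no symmetry (P1) or an
#' explicit operator loop (\code{_symmetry_equiv_pos_as_xyz} /
#' \code{_space_group_symop_operation_xyz}). Symmetry is applied and duplicate
#' sites are merged. Sites with occupancy < 1 are rejected: partial occupancy
#' is undefined for cluster building.
#'
#' @param path path to a CIF file
#' @param merge_tol duplicate-site merge tolerance in Angstrom
#' @return a \code{crystal_structure} with symmetry applied
#' @export
read_cif <- function(path, merge_tol = 0.3) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[[:space:]]*#.*$", "", lines)
  lines <- trimws(lines)

  first_data <- which(grepl("^data_", lines))
  if (length(first_data)) {
    stop_at <- if (length(first_data) > 1) first_data[2] - 1L else length(lines)
    lines <- lines[(first_data[1] + 1L):stop_at]
  }
  lines <- lines[nzchar(lines)]

  tags <- list()
  loops <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (tolower(ln) == "loop_") {
      cols <- character(0)
      i <- i + 1L
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        cols <- c(cols, tolower(.tokenize_cif_line(lines[i])[1]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines) && !startsWith(lines[i], "_") &&
             tolower(lines[i]) != "loop_" && !startsWith(lines[i], "data_")) {
        toks <- .tokenize_cif_line(lines[i])
        if (length(toks)) rows[[length(rows) + 1L]] <- toks
        i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(cols = cols, rows = rows)
    } else if (startsWith(ln, "_")) {
      toks <- .tokenize_cif_line(ln)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        tags[[tag]] <- paste(toks[-1], collapse = " ")
      } else if (i < length(lines) && !startsWith(lines[i + 1L], "_")) {
        tags[[tag]] <- lines[i + 1L]
        i <- i + 1L
      }
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  for (tag in need) {
    if (is.null(tags[[tag]])) stop("malformed CIF: missing tag ", tag)
  }
  L <- lattice_from_cell(
    .strip_su(tags[["_cell_length_a"]]), .strip_su(tags[["_cell_length_b"]]),
    .strip_su(tags[["_cell_length_c"]]), .strip_su(tags[["_cell_angle_alpha"]]),
    .strip_su(tags[["_cell_angle_beta"]]), .strip_su(tags[["_cell_angle_gamma"]]))

  op_cols <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  ops <- list()
  for (lp in loops) {
    hit <- which(lp$cols %in% op_cols)
    if (length(hit)) {
      for (row in lp$rows) ops[[length(ops) + 1L]] <- parse_symop(row[hit[1]])
    }
  }

  site_loop <- NULL
  for (lp in loops) {
    if (any(grepl("^_atom_site_fract_x$", lp$cols))) { site_loop <- lp; break }
  }
  if (is.null(site_loop)) stop("malformed CIF: missing tag _atom_site_fract_x")
  cols <- site_loop$cols
  idx <- function(tag) match(tag, cols)
  ix <- idx("_atom_site_fract_x"); iy <- idx("_atom_site_fract_y")
  iz <- idx("_atom_site_fract_z")
  if (is.na(iy)) stop("malformed CIF: missing tag _atom_site_fract_y")
  if (is.na(iz)) stop("malformed CIF: missing tag _atom_site_fract_z")
  ilab <- idx("_atom_site_label"); ityp <- idx("_atom_site_type_symbol")
  iocc <- idx("_atom_site_occupancy")

  el <- character(0); lab <- character(0); frac <- NULL
  for (row in site_loop$rows) {
    raw <- if (!is.na(ityp)) row[ityp] else row[ilab]
    sym <- sub("^([A-Za-z]{1,2}).*$", "\\1", raw)
    sym <- paste0(toupper(substr(sym, 1, 1)), tolower(substring(sym, 2)))
    if (!is.na(iocc)) {
      occ <- .strip_su(row[iocc])
      if (is.finite(occ) && occ < 1 - 1e-6) {
        stop("site ", row[if (!is.na(ilab)) ilab else 1],
             " has occupancy ", occ,
             ": partially occupied sites are not supported")
      }
    }
    el <- c(el, sym)
    lab <- c(lab, if (!is.na(ilab)) row[ilab] else sym)
    frac <- rbind(frac, c(.strip_su(row[ix]), .strip_su(row[iy]),
                          .strip_su(row[iz])))
  }

  s <- crystal_structure(L, el, frac, lab)
  expand_symmetry(s, ops, merge_tol = merge_tol)
}

#' Write a crystal structure as a P1 CIF file
#'
#' @param s a \code{crystal_structure}
#' @param path output file path
#' @return invisibly, the path
#' @export
write_cif <- function(s, path) {
  p <- cell_params(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_vibrafrag",
    sprintf("_cell_length_a    %.6f", p["a"]),
    sprintf("_cell_length_b    %.6f", p["b"]),
    sprintf("_cell_length_c    %.6f", p["c"]),
    sprintf("_cell_angle_alpha %.6f", p["alpha"]),
    sprintf("_cell_angle_beta  %.6f", p["beta"]),
    sprintf("_cell_angle_gamma %.6f", p["gamma"]),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy"
  ), con)
  for (i in seq_along(s$elements)) {
    writeLines(sprintf("%s %s %.8f %.8f %.8f 1.0",
                       s$site_labels[i], s$elements[i],
                       s$frac_coords[i, 1], s$frac_coords[i, 2],
                       s$frac_coords[i, 3]), con)
  }
  invisible(path)
}

#' Build a supercell
#'
#' Replicates the cell \code{reps[1] x reps[2] x reps[3]} times. Image cells
#' are visited in lexicographic (ia, ib, ic) order with the original sites
#' kept in order inside each image, so site \code{k} of image \code{m}
#' (0-based) lands at row \code{m * n_sites + k}.
#'
#' @param s a \code{crystal_structure}
#' @param reps integer triple of repetitions, all >= 1
#' @return a \code{crystal_structure} with \code{prod(reps)} times the sites
#' @export
build_supercell <- function(s, reps) {
  reps <- as.integer(round(reps))
  if (length(reps) != 3 || any(reps < 1)) {
    stop("reps must be three integers >= 1")
  }
  L2 <- diag(reps) %*% s$lattice
  n <- length(s$elements)
  el <- character(0); lab <- character(0); frac <- NULL
  for (ia in 0:(reps[1] - 1L)) for (ib in 0:(reps[2] - 1L)) {
    for (ic in 0:(reps[3] - 1L)) {
      shift <- c(ia, ib, ic)
      if (n) {
        f <- sweep(s$frac_coords, 2, shift, "+")
        f <- sweep(f, 2, reps, "/")
        frac <- rbind(frac, f)
        el <- c(el, s$elements)
        lab <- c(lab, paste0(s$site_labels, "_", ia, ib, ic))
      }
    }
  }
  if (is.null(frac)) frac <- matrix(numeric(0), 0, 3)
  crystal_structure(L2, el, frac, lab,
                    space_group_applied = s$space_group_applied)
}

# ---------------------------------------------------------------------------
# Finite geometries and XYZ I/O.

#' Finite (non-periodic) molecular geometry
#'
#' @param elements character vector of element symbols
#' @param coords n x 3 matrix of Cartesian coordinates in Angstrom
#' @param masses optional per-atom masses in amu (defaults from element table)
#' @return an object of class \code{finite_geometry}
#' @export
finite_geometry <- function(elements, coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords)) {
    stop("length(elements) must equal nrow(coords)")
  }
  if (is.null(masses)) masses <- element_mass(elements)
  if (length(masses) != length(elements) || any(masses <= 0)) {
    stop("all masses must be > 0 and match the atom count")
  }
  structure(list(elements = as.character(elements), coords = coords,
                 masses = as.numeric(masses)),
            class = "finite_geometry")
}

#' @export
print.finite_geometry <- function(x, ...) {
  cat(sprintf("finite_geometry: %d atoms (%s)\n", length(x$elements),
              hill_formula(x$elements)))
  invisible(x)
}

#' Write a finite geometry as an XYZ file
#'
#' Standard dialect: atom count line, comment line, then one
#' \code{element x y z} row per atom (Angstrom). An optional per-atom tag
#' (e.g. cluster roles) is written as a fifth column.
#'
#' @param g a \code{finite_geometry}
#' @param path output file path
#' @param comment comment line content
#' @param tags optional character vector, one tag per atom
#' @return invisibly, the path
#' @export
write_xyz <- function(g, path, comment = "", tags = NULL) {
  if (!length(g$elements)) stop("refusing to write an empty geometry")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(g$elements)), comment), con)
  for (i in seq_along(g$elements)) {
    ln <- sprintf("%-2s %16.8f %16.8f %16.8f", g$elements[i],
                  g$coords[i, 1], g$coords[i, 2], g$coords[i, 3])
    if (!is.null(tags)) ln <- paste(ln, tags[i])
    writeLines(ln, con)
  }
  invisible(path)
}

#' Read a finite geometry from an XYZ file
#'
#' @param path path to an XYZ file
#' @return a \code{finite_geometry}; a fifth column, if present, is attached
#'   as attribute \code{"tags"}
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: count line is not an integer")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("malformed XYZ: count line says ", n, " atoms but found ",
         length(body), " atom lines")
  }
  el <- character(n); xyz <- matrix(0, n, 3); tags <- character(n)
  has_tags <- FALSE
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(toks) < 4) stop("malformed XYZ: bad atom line: ", body[i])
    el[i] <- toks[1]
    xyz[i, ] <- as.numeric(toks[2:4])
    if (length(toks) >= 5) { tags[i] <- toks[5]; has_tags <- TRUE }
  }
  g <- finite_geometry(el, xyz)
  if (has_tags) attr(g, "tags") <- tags
  g
}
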