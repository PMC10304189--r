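# Independent brute-force oracles used to cross-check the implementation.

# all-pairs x 27-image bond perception, written naively
oracle_bonds <- function(s, tolerance = 0.40) {
  n <- length(s$elements)
  rc <- covalent_radius(s$elements)
  out <- NULL
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (s$elements[i] == "H" && s$elements[j] == "H") next
    best <- Inf
    for (sa in -1:1) for (sb in -1:1) for (sc in -1:1) {
      d <- s$frac_coords[j, ] + c(sa, sb, sc) - s$frac_coords[i, ]
      r <- sqrt(sum((d %*% s$lattice)^2))
      if (r < best) best <- r
    }
    if (best <= rc[i] + rc[j] + tolerance) out <- rbind(out, c(i, j))
  }
  out
}

# exhaustive (D, H, A) triplet enumeration over a molecule list
oracle_hbonds <- function(mols, crit, tolerance = 0.40) {
  el <- unlist(lapply(mols, function(m) m$elements))
  xyz <- do.call(rbind, lapply(mols, function(m) m$coords))
  gid <- unlist(lapply(mols, function(m) m$site_indices))
  rc <- covalent_radius(el)
  n <- length(el)
  covalent <- function(i, j) {
    if (el[i] == "H" && el[j] == "H") return(FALSE)
    sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= rc[i] + rc[j] + tolerance
  }
  out <- NULL
  for (h in which(el == "H")) for (d in seq_len(n)) {
    if (d == h || !el[d] %in% crit$donor_elements || !covalent(d, h)) next
    for (a in seq_len(n)) {
      if (a == h || a == d || !el[a] %in% crit$acceptor_elements) next
      if (covalent(h, a)) next
      d_ha <- sqrt(sum((xyz[a, ] - xyz[h, ])^2))
      d_da <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (d_ha <= crit$max_h_acceptor && d_da <= crit$max_donor_acceptor &&
          ang >= crit$min_angle) {
        out <- rbind(out, c(gid[d], gid[h], gid[a]))
      }
    }
  }
  out
}

# central-difference numeric gradient of a backend energy
oracle_numeric_gradient <- function(b, g, step = 1e-4) {
  n <- nrow(g$coords)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) for (ax in 1:3) {
    gp <- g; gp$coords[i, ax] <- gp$coords[i, ax] + step
    gm <- g; gm$coords[i, ax] <- gm$coords[i, ax] - step
    out[i, ax] <- (b$energy(gp) - b$energy(gm)) / (2 * step)
  }
  out
}

# exhaustive minimum total |exp - calc| over all one-to-one pairings
# within the window (maximizing the matched count first)
oracle_min_assignment <- function(calc, exp, window) {
  ne <- length(exp); nc <- length(calc)
  best <- list(n = -1L, total = Inf)
  recurse <- function(i, used, n, total) {
    if (i > ne) {
      if (n > best$n || (n == best$n && total < best$total)) {
        best <<- list(n = n, total = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used, n, total)  # leave exp[i] unmatched
    for (j in seq_len(nc)) {
      if (!used[j] && abs(exp[i] - calc[j]) <= window) {
        used[j] <- TRUE
        recurse(i + 1L, used, n + 1L, total + abs(exp[i] - calc[j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nc), 0L, 0)
  best
}

# place a fourth atom at given bond length, angle (deg) and dihedral (deg)
# relative to three existing positions (classic z-matrix construction)
zmat_place <- function(p1, p2, p3, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  b1 <- p2 - p1; b2 <- p3 - p2
  b2n <- b2 / sqrt(sum(b2^2))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  nv <- cross(b1, b2); nv <- nv / sqrt(sum(nv^2))
  mv <- cross(nv, b2n)
  d <- r * (-b2n * cos(th) + mv * sin(th) * cos(ph) + nv * sin(th) * sin(ph))
  p3 + d
}

# write a minimal CIF text fixture
write_test_cif <- function(path, cell = c(10, 10, 10, 90, 90, 90),
                           sites = list(), symops = NULL, occupancy = NULL,
                           drop_tag = NULL) {
  lines <- c("data_test",
             sprintf("_cell_length_a %.4f", cell[1]),
             sprintf("_cell_length_b %.4f", cell[2]),
             sprintf("_cell_length_c %.4f", cell[3]),
             sprintf("_cell_angle_alpha %.4f", cell[4]),
             sprintf("_cell_angle_beta %.4f", cell[5]),
             sprintf("_cell_angle_gamma %.4f", cell[6]))
  if (!is.null(drop_tag)) lines <- lines[!grepl(drop_tag, lines, fixed = TRUE)]
  if (!is.null(symops)) {
    lines <- c(lines, "loop_", "_symmetry_equiv_pos_as_xyz",
               sprintf("'%s'", symops))
  }
  cols <- c("_atom_site_label", "_atom_site_type_symbol",
            "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  if (!is.null(occupancy)) cols <- c(cols, "_atom_site_occupancy")
  lines <- c(lines, "loop_", cols)
  for (k in seq_along(sites)) {
    st <- sites[[k]]
    row <- sprintf("%s%d %s %.6f %.6f %.6f", st$el, k, st$el,
                   st$xyz[1], st$xyz[2], st$xyz[3])
    if (!is.null(occupancy)) row <- paste(row, occupancy[k])
    lines <- c(lines, row)
  }
  writeLines(lines, path)
  path
}
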