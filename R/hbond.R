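# Geometric hydrogen-bond detection and the molecule-level network.

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow common crystallographic practice: H...A <= 2.5 A,
#' D...A <= 3.5 A, D-H...A angle >= 120 deg, donors N/O, acceptors N/O/S
#' (S included because thio-containing drugs such as Lamivudine accept
#' through sulfur). All values are user-overridable.
#'
#' @param max_h_acceptor maximum H...A distance in Angstrom
#' @param max_donor_acceptor maximum D...A distance in Angstrom
#' @param min_angle minimum D-H...A angle at H, in degrees
#' @param donor_elements element symbols allowed as donors
#' @param acceptor_elements element symbols allowed as acceptors
#' @return an object of class \code{hbond_criteria}
#' @export
hbond_criteria <- function(max_h_acceptor = 2.5, max_donor_acceptor = 3.5,
                           min_angle = 120,
                           donor_elements = c("N", "O"),
                           acceptor_elements = c("N", "O", "S")) {
  if (max_h_acceptor <= 0 || max_donor_acceptor <= 0) {
    stop("distance cutoffs must be > 0")
  }
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_h_acceptor = max_h_acceptor,
                 max_donor_acceptor = max_donor_acceptor,
                 min_angle = min_angle,
                 donor_elements = donor_elements,
                 acceptor_elements = acceptor_elements),
            class = "hbond_criteria")
}

# core detector on flat per-atom arrays; mol_id maps atoms to molecules,
# global_id carries caller-facing indices. bonds is a finite bond_graph
# over the same atoms.
.detect_hbonds_flat <- function(elements, coords, mol_id, global_id,
                                crit, bonds) {
  n <- length(elements)
  bonded <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    bonded[[i]] <- c(bonded[[i]], j)
    bonded[[j]] <- c(bonded[[j]], i)
  }
  out <- data.frame(donor = integer(0), h = integer(0), acceptor = integer(0),
                    donor_molecule = integer(0), acceptor_molecule = integer(0),
                    d_ha = numeric(0), d_da = numeric(0), angle = numeric(0))
  hs <- which(elements == "H")
  acc <- which(elements %in% crit$acceptor_elements)
  for (h in hs) {
    for (d in bonded[[h]]) {
      if (!elements[d] %in% crit$donor_elements) next
      for (a in acc) {
        if (a == d || a == h) next
        if (a %in% bonded[[h]]) next  # same covalent bond
        d_ha <- sqrt(sum((coords[a, ] - coords[h, ])^2))
        if (d_ha > crit$max_h_acceptor) next
        d_da <- sqrt(sum((coords[a, ] - coords[d, ])^2))
        if (d_da > crit$max_donor_acceptor) next
        v1 <- coords[d, ] - coords[h, ]; v2 <- coords[a, ] - coords[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < crit$min_angle) next
        out <- rbind(out, data.frame(
          donor = global_id[d], h = global_id[h], acceptor = global_id[a],
          donor_molecule = mol_id[d], acceptor_molecule = mol_id[a],
          d_ha = d_ha, d_da = d_da, angle = ang))
      }
    }
  }
  out <- out[order(out$donor_molecule, out$d_ha), , drop = FALSE]
  rownames(out) <- NULL
  out$intramolecular <- out$donor_molecule == out$acceptor_molecule
  class(out) <- c("hbond_list", "data.frame")
  out
}

#' Detect hydrogen bonds among molecules
#'
#' Every covalent D-H pair with D in the donor set is tested against every
#' acceptor atom (excluding atoms of the same covalent bond); all and only
#' triplets passing the distance and angle tests are returned, sorted by
#' (donor molecule, H...A distance). Bifurcated contacts are all reported.
#' Molecules must share one Cartesian frame (e.g. unwrapped supercell
#' coordinates); detection is not periodic.
#'
#' @param mols list of \code{molecule} objects
#' @param crit an \code{hbond_criteria}
#' @param tolerance covalent bond tolerance for identifying D-H pairs
#' @return an \code{hbond_list} data.frame with columns donor, h, acceptor
#'   (site indices of the parent structure), donor_molecule,
#'   acceptor_molecule, d_ha, d_da, angle, intramolecular
#' @export
detect_hbonds <- function(mols, crit = hbond_criteria(), tolerance = 0.40) {
  elements <- unlist(lapply(mols, function(m) m$elements))
  coords <- do.call(rbind, lapply(mols, function(m) m$coords))
  mol_id <- rep(seq_along(mols),
                vapply(mols, function(m) length(m$elements), 0L))
  global_id <- unlist(lapply(mols, function(m) m$site_indices))
  if (!length(elements)) {
    return(.detect_hbonds_flat(character(0), matrix(0, 0, 3), integer(0),
                               integer(0), crit,
                               perceive_bonds(finite_geometry(character(0),
                                                              matrix(0, 0, 3)))))
  }
  g <- finite_geometry(elements, coords)
  bonds <- perceive_bonds(g, tolerance)
  .detect_hbonds_flat(elements, coords, mol_id, global_id, crit, bonds)
}

#' Molecule-level hydrogen-bond adjacency
#'
#' Undirected graph on molecule indices: an edge exists iff at least one
#' intermolecular hydrogen bond links the two molecules; edge weights count
#' the hydrogen bonds. Intramolecular hydrogen bonds induce no edges.
#'
#' @param mols list of \code{molecule} objects
#' @param hbonds an \code{hbond_list} detected from \code{mols}
#' @return symmetric integer matrix of hydrogen-bond counts
#' @export
hbond_adjacency <- function(mols, hbonds) {
  n <- length(mols)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(hbonds))) {
    i <- hbonds$donor_molecule[k]; j <- hbonds$acceptor_molecule[k]
    if (i != j) {
      A[i, j] <- A[i, j] + 1L
      A[j, i] <- A[j, i] + 1L
    }
  }
  A
}
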