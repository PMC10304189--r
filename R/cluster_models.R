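# The three cluster models: single molecule, hydrogen-bonded repeating unit
# (whence the central molecule), and the intercepted fragment with hydrogen
# link-atom capping.

.new_cluster_model <- function(geometry, atom_roles, source_molecules,
                               atom_molecule, model_kind, provenance,
                               global_indices) {
  if (!any(atom_roles == "central")) stop("cluster has no central atoms")
  if (any(atom_roles == "cap" & geometry$elements != "H")) {
    stop("cap atoms must be hydrogen")
  }
  structure(list(geometry = geometry, atom_roles = atom_roles,
                 source_molecules = source_molecules,
                 atom_molecule = atom_molecule,
                 model_kind = model_kind, provenance = provenance,
                 global_indices = global_indices),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model [%s]: %d atoms (%d central, %d neighbor, %d cap)\n",
              x$model_kind, length(x$geometry$elements),
              sum(x$atom_roles == "central"), sum(x$atom_roles == "neighbor"),
              sum(x$atom_roles == "cap")))
  invisible(x)
}

#' Fragment interception rule
#'
#' Governs which neighbor atoms the fragment model retains around the central
#' molecule, and how severed covalent bonds are capped.
#'
#' @param radius distance cutoff in Angstrom from any central-molecule atom
#'   (default 4.0; use \code{Inf} to keep the whole repeating unit)
#' @param keep_hbond_groups retain the covalent functional group of every
#'   hydrogen bond to the central molecule (heavy atom plus direct covalent
#'   neighbors; attached hydrogens follow by closure)
#' @param keep_conjugated_extensions retain whole conjugated groups that touch
#'   any retained atom
#' @param cap_bond_lengths named numeric map from the retained atom's element
#'   to the cap X-H bond length in Angstrom
#' @return an object of class \code{interception_rule}
#' @export
interception_rule <- function(radius = 4.0, keep_hbond_groups = TRUE,
                              keep_conjugated_extensions = TRUE,
                              cap_bond_lengths = .default_cap_lengths) {
  if (radius < 0) stop("radius must be >= 0")
  if (any(cap_bond_lengths <= 0)) stop("cap bond lengths must be > 0")
  structure(list(radius = radius,
                 keep_hbond_groups = isTRUE(keep_hbond_groups),
                 keep_conjugated_extensions = isTRUE(keep_conjugated_extensions),
                 cap_bond_lengths = cap_bond_lengths),
            class = "interception_rule")
}

#' Build the single-molecule model
#'
#' Extracts one whole molecule from the crystal; all atoms are tagged central.
#'
#' @param s a \code{crystal_structure}
#' @param mol_index index into the molecule list of \code{extract_molecules}
#' @param tolerance covalent bond tolerance in Angstrom
#' @return a \code{cluster_model} with \code{model_kind = "single"}
#' @export
build_single_molecule <- function(s, mol_index, tolerance = 0.40) {
  mols <- extract_molecules(s, tolerance = tolerance)
  if (mol_index < 1 || mol_index > length(mols)) {
    stop("mol_index ", mol_index, " out of range: structure has ",
         length(mols), " molecules")
  }
  m <- mols[[mol_index]]
  .new_cluster_model(
    geometry = finite_geometry(m$elements, m$coords),
    atom_roles = rep("central", length(m$elements)),
    source_molecules = mol_index,
    atom_molecule = rep(mol_index, length(m$elements)),
    model_kind = "single",
    provenance = sprintf("single molecule %d (%s) extracted from crystal",
                         mol_index, m$formula),
    global_indices = m$site_indices)
}

# distance from every atom of a molecule to the nearest cell boundary plane
.boundary_clearance <- function(s, mol) {
  frac <- cart_to_frac(mol$coords, s$lattice)
  L <- s$lattice
  vol <- abs(det(L))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  heights <- c(vol / sqrt(sum(cross(L[2, ], L[3, ])^2)),
               vol / sqrt(sum(cross(L[1, ], L[3, ])^2)),
               vol / sqrt(sum(cross(L[1, ], L[2, ])^2)))
  min(vapply(seq_len(nrow(frac)), function(i) {
    min(pmin(frac[i, ] %% 1, 1 - (frac[i, ] %% 1)) * heights)
  }, 0))
}

#' Build the minimal hydrogen-bonded repeating unit
#'
#' A chosen central molecule plus every molecule sharing at least one
#' intermolecular hydrogen bond with it, whole molecules only. The supercell
#' must be large enough that the central molecule's hydrogen-bond shell is
#' complete: every central atom must be farther than
#' \code{crit$max_donor_acceptor} from the cell boundary, else an error
#' advises larger repetitions.
#'
#' @param s a \code{crystal_structure} (typically a supercell)
#' @param central_index molecule index, or \code{NULL} to pick the molecule
#'   whose centroid is nearest the supercell centroid
#' @param crit an \code{hbond_criteria}
#' @param tolerance covalent bond tolerance in Angstrom
#' @return a \code{cluster_model} with \code{model_kind = "repeating_unit"};
#'   if the central molecule has no hydrogen-bond partners a warning is issued
#'   and a single-molecule cluster (kind \code{repeating_unit}) is returned
#' @export
build_repeating_unit <- function(s, central_index = NULL,
                                 crit = hbond_criteria(), tolerance = 0.40) {
  mols <- extract_molecules(s, tolerance = tolerance)
  if (!length(mols)) stop("structure contains no molecules")
  if (is.null(central_index)) {
    center <- as.numeric(frac_to_cart(matrix(c(.5, .5, .5), 1), s$lattice))
    d2 <- vapply(mols, function(m) sum((m$centroid - center)^2), 0)
    central_index <- which.min(d2)
  }
  if (central_index < 1 || central_index > length(mols)) {
    stop("central_index ", central_index, " out of range: structure has ",
         length(mols), " molecules")
  }
  clearance <- .boundary_clearance(s, mols[[central_index]])
  if (clearance <= crit$max_donor_acceptor) {
    stop(sprintf(paste0("central molecule is only %.2f A from the supercell ",
                        "boundary (need > %.2f A for a complete hydrogen-bond ",
                        "shell); build a larger supercell"),
                 clearance, crit$max_donor_acceptor))
  }
  hb <- detect_hbonds(mols, crit, tolerance)
  inter <- hb[!hb$intramolecular & (hb$donor_molecule == central_index |
                                      hb$acceptor_molecule == central_index), ,
              drop = FALSE]
  partners <- sort(setdiff(unique(c(inter$donor_molecule,
                                    inter$acceptor_molecule)), central_index))
  if (!length(partners)) {
    warning("central molecule has no hydrogen-bond partners under the given ",
            "criteria; returning a single-molecule cluster")
  }
  members <- c(central_index, partners)
  el <- unlist(lapply(mols[members], function(m) m$elements))
  xyz <- do.call(rbind, lapply(mols[members], function(m) m$coords))
  roles <- rep(c("central", rep("neighbor", length(partners))),
               vapply(mols[members], function(m) length(m$elements), 0L))
  mol_id <- rep(members, vapply(mols[members],
                                function(m) length(m$elements), 0L))
  gidx <- unlist(lapply(mols[members], function(m) m$site_indices))
  .new_cluster_model(
    geometry = finite_geometry(el, xyz),
    atom_roles = roles,
    source_molecules = members,
    atom_molecule = mol_id,
    model_kind = "repeating_unit",
    provenance = sprintf("repeating unit: central molecule %d + %d H-bonded partner(s) [%s]",
                         central_index, length(partners),
                         paste(partners, collapse = ",")),
    global_indices = gidx)
}

#' Extract the central molecule from a cluster
#'
#' Returns exactly the atoms tagged central, with the coordinates they
#' currently hold (i.e. the geometry acquired when the whole cluster was
#' optimized).
#'
#' @param c a \code{cluster_model}
#' @return a \code{cluster_model} with \code{model_kind = "central"}
#' @export
extract_central_molecule <- function(c) {
  keep <- which(c$atom_roles == "central")
  if (!length(keep)) stop("cluster has no atoms tagged central")
  .new_cluster_model(
    geometry = finite_geometry(c$geometry$elements[keep],
                               c$geometry$coords[keep, , drop = FALSE],
                               c$geometry$masses[keep]),
    atom_roles = rep("central", length(keep)),
    source_molecules = unique(c$atom_molecule[keep]),
    atom_molecule = c$atom_molecule[keep],
    model_kind = "central",
    provenance = paste0(c$provenance, " -> central molecule extracted"),
    global_indices = c$global_indices[keep])
}

#' Intercept the multi-molecular fragment
#'
#' Trims the (typically optimized) repeating unit to the parts connected to
#' the central molecule, capping severed covalent bonds with hydrogen link
#' atoms. A neighbor atom is retained iff it is (i) within \code{rule$radius}
#' of any central atom, or (ii) \code{keep_hbond_groups} and it belongs to the
#' covalent functional group (donor/acceptor heavy atom plus its direct
#' covalent neighbors) of a hydrogen bond to the central molecule, or (iii)
#' \code{keep_conjugated_extensions} and it lies in a conjugated group
#' containing an already-retained atom. Hydrogens bonded to a retained heavy
#' atom are always retained. Every severed single covalent bond R-X is
#' replaced by a cap H placed along R->X at the configured cap length;
#' severing a bond inside a conjugated group is an error.
#'
#' @param c a \code{cluster_model} of kind \code{repeating_unit} (or
#'   \code{fragment}; interception is idempotent)
#' @param rule an \code{interception_rule}
#' @param crit \code{hbond_criteria} used to locate hydrogen bonds to the
#'   central molecule
#' @param tolerance covalent bond tolerance in Angstrom
#' @return a \code{cluster_model} with \code{model_kind = "fragment"}
#' @export
intercept_fragment <- function(c, rule = interception_rule(),
                               crit = hbond_criteria(), tolerance = 0.40) {
  if (!c$model_kind %in% c("repeating_unit", "fragment")) {
    stop("intercept_fragment expects a repeating_unit (or fragment) cluster")
  }
  g <- c$geometry
  n <- length(g$elements)
  bonds <- perceive_bonds(g, tolerance)
  bonded <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    bonded[[bonds$i[k]]] <- c(bonded[[bonds$i[k]]], bonds$j[k])
    bonded[[bonds$j[k]]] <- c(bonded[[bonds$j[k]]], bonds$i[k])
  }
  central <- which(c$atom_roles == "central")
  retained <- c$atom_roles == "central"

  # (i) radius clause
  if (is.finite(rule$radius)) {
    if (rule$radius > 0) {
      for (i in which(!retained)) {
        d2 <- min(colSums((t(g$coords[central, , drop = FALSE]) -
                             g$coords[i, ])^2))
        if (d2 <= rule$radius^2) retained[i] <- TRUE
      }
    }
  } else {
    retained[] <- TRUE
  }

  # (ii) hydrogen-bond functional groups
  if (rule$keep_hbond_groups) {
    hb <- .detect_hbonds_flat(g$elements, g$coords, c$atom_molecule,
                              seq_len(n), crit, bonds)
    central_mol <- unique(c$atom_molecule[central])
    for (k in seq_len(nrow(hb))) {
      dm <- hb$donor_molecule[k]; am <- hb$acceptor_molecule[k]
      touches <- (dm %in% central_mol) != (am %in% central_mol)
      if (!touches) next
      anchor <- if (dm %in% central_mol) hb$acceptor[k] else hb$donor[k]
      retained[anchor] <- TRUE
      retained[bonded[[anchor]]] <- TRUE
      if (!(dm %in% central_mol)) retained[hb$h[k]] <- TRUE
    }
  }

  # (iii) conjugated extensions, to a fixed point
  groups <- detect_conjugated_groups(g, bonds)
  if (rule$keep_conjugated_extensions && length(groups)) {
    repeat {
      grew <- FALSE
      for (grp in groups) {
        if (any(retained[grp]) && !all(retained[grp])) {
          retained[grp] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  }

  # closure: hydrogens on retained heavy atoms
  repeat {
    grew <- FALSE
    for (i in which(!retained)) {
      if (g$elements[i] == "H" &&
          any(retained[bonded[[i]]] &
                g$elements[bonded[[i]]] != "H")) {
        retained[i] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }

  # caps for severed covalent bonds
  cap_xyz <- NULL; cap_anchor_mol <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (retained[i] == retained[j]) next
    r <- if (retained[i]) i else j
    x <- if (retained[i]) j else i
    grp_hit <- any(vapply(groups, function(grp) r %in% grp && x %in% grp,
                          TRUE))
    if (grp_hit) {
      stop("interception would cut through a conjugated system (atoms ", r,
           "-", x, "); enlarge the radius")
    }
    len <- rule$cap_bond_lengths[g$elements[r]]
    if (is.na(len)) len <- 1.0
    dir <- g$coords[x, ] - g$coords[r, ]
    dir <- dir / sqrt(sum(dir^2))
    cap_xyz <- rbind(cap_xyz, g$coords[r, ] + len * dir)
    cap_anchor_mol <- c(cap_anchor_mol, c$atom_molecule[r])
  }

  keep <- which(retained)
  el <- c(g$elements[keep], rep("H", length(cap_anchor_mol)))
  xyz <- rbind(g$coords[keep, , drop = FALSE], cap_xyz)
  roles <- c(c$atom_roles[keep], rep("cap", length(cap_anchor_mol)))
  mol_id <- c(c$atom_molecule[keep], cap_anchor_mol)
  gidx <- c(c$global_indices[keep], rep(NA_integer_, length(cap_anchor_mol)))
  .new_cluster_model(
    geometry = finite_geometry(el, xyz),
    atom_roles = roles,
    source_molecules = unique(mol_id),
    atom_molecule = mol_id,
    model_kind = "fragment",
    provenance = sprintf("%s -> fragment (radius %.2f A, %d atoms kept, %d caps)",
                         c$provenance, rule$radius, length(keep),
                         length(cap_anchor_mol)),
    global_indices = gidx)
}
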