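# Harmonic vibrational analysis: mass weighting, rigid-body (Eckart)
# projection, eigenfrequencies in cm^-1, imaginary-mode flagging, and
# empirical scale factors.

# TRUE when the geometry is collinear to within tol (Angstrom)
.is_linear <- function(coords, tol = 1e-6) {
  n <- nrow(coords)
  if (n <= 2) return(TRUE)
  d <- sweep(coords, 2, colMeans(coords))
  v1 <- svd(d)$v[, 1]
  resid <- d - (d %*% v1) %*% t(v1)
  max(sqrt(rowSums(resid^2))) < tol
}

# Orthonormal rigid-body basis (mass-weighted coordinates): 3 translations
# plus 3 rotations (2 if the geometry is collinear within tol, 0 rotations
# for a single atom). Modified Gram-Schmidt with rank dropping, so degenerate
# rotation vectors vanish instead of polluting the basis.
.rigid_body_basis <- function(g, tol = 1e-6) {
  n <- nrow(g$coords)
  m <- g$masses
  com <- colSums(g$coords * m) / sum(m)
  r <- sweep(g$coords, 2, com)
  sq <- sqrt(m)
  V <- matrix(0, 3 * n, 6)
  for (ax in 1:3) {
    v <- matrix(0, n, 3); v[, ax] <- sq
    V[, ax] <- as.vector(t(v))
  }
  e <- diag(3)
  for (ax in 1:3) {
    v <- t(vapply(seq_len(n), function(i) {
      sq[i] * c(r[i, 2] * e[3, ax] - r[i, 3] * e[2, ax],
                r[i, 3] * e[1, ax] - r[i, 1] * e[3, ax],
                r[i, 1] * e[2, ax] - r[i, 2] * e[1, ax])
    }, numeric(3)))
    V[, 3 + ax] <- as.vector(t(v))
  }
  Q <- NULL
  for (k in 1:6) {
    v <- V[, k]
    if (!is.null(Q)) v <- v - Q %*% (t(Q) %*% v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) Q <- cbind(Q, as.vector(v) / nv)
  }
  Q
}

# projector onto the complement of the rigid-body space
.rigid_projector <- function(g, tol = 1e-6) {
  Q <- .rigid_body_basis(g, tol)
  diag(3 * nrow(g$coords)) - Q %*% t(Q)
}

#' Harmonic vibrational analysis
#'
#' Mass-weights the Cartesian Hessian, optionally projects out the rigid-body
#' translations and rotations at the center of mass (3 + 3, or 3 + 2 for a
#' collinear geometry), diagonalizes, and converts eigenvalues to wavenumbers.
#' Imaginary modes (negative eigenvalues) are encoded as negative cm^-1.
#'
#' @param h symmetric 3N x 3N Hessian in Hartree/Angstrom^2
#' @param g a \code{finite_geometry} supplying masses and coordinates
#' @param project project out rigid-body modes (default TRUE)
#' @return an object of class \code{normal_modes} with fields
#'   \code{frequencies} (cm^-1, ascending, imaginary negative), \code{modes}
#'   (3N x n_modes orthonormal mass-weighted displacement columns),
#'   \code{n_projected}, \code{has_imaginary}, \code{rigid_frequencies}
#'   (magnitudes of the removed modes, cm^-1), and the input geometry
#' @export
vibrational_analysis <- function(h, g, project = TRUE) {
  n <- nrow(g$coords)
  if (!is.matrix(h) || nrow(h) != 3 * n || ncol(h) != 3 * n) {
    stop("Hessian must be 3N x 3N for the given geometry")
  }
  if (max(abs(h - t(h))) > 1e-8) {
    stop("Hessian is not symmetric (max asymmetry ",
         format(max(abs(h - t(h)))), "); symmetrize with (H + t(H))/2 first")
  }
  if (any(g$masses <= 0)) stop("all masses must be > 0")
  invsq <- 1 / sqrt(rep(g$masses, each = 3))
  Hw <- h * outer(invsq, invsq)
  n_projected <- 0L
  rigid <- numeric(0)
  if (project) {
    Q <- .rigid_body_basis(g)
    n_projected <- ncol(Q)
    P <- diag(3 * n) - Q %*% t(Q)
    # magnitudes of the rigid-body block before removal (diagnostic)
    rb <- t(Q) %*% Hw %*% Q
    rl <- eigen(( rb + t(rb)) / 2, symmetric = TRUE, only.values = TRUE)$values
    rigid <- sqrt(abs(rl)) * .freq_conv
    Hw <- P %*% Hw %*% P
    Hw <- (Hw + t(Hw)) / 2
  }
  eig <- eigen(Hw, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  if (n_projected > 0) {
    drop_idx <- order(abs(vals))[seq_len(n_projected)]
    keep <- setdiff(seq_along(vals), drop_idx)
    vals <- vals[keep]; vecs <- vecs[, keep, drop = FALSE]
  }
  freqs <- sign(vals) * sqrt(abs(vals)) * .freq_conv
  ord <- order(freqs)
  structure(list(frequencies = freqs[ord],
                 modes = vecs[, ord, drop = FALSE],
                 n_projected = n_projected,
                 has_imaginary = any(freqs < -1e-6),
                 rigid_frequencies = rigid,
                 geometry = g),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("normal_modes: %d modes (%d rigid-body removed)%s\n",
              length(x$frequencies), x$n_projected,
              if (x$has_imaginary) ", imaginary modes present" else ""))
  cat("frequencies (cm^-1):",
      paste(sprintf("%.2f", round_half_up(x$frequencies, 2)), collapse = " "),
      "\n")
  invisible(x)
}

#' Empirical frequency scale factor
#'
#' @param value dimensionless multiplier in (0, 1.2]
#' @param provenance free-text note on where the factor comes from
#' @return an object of class \code{scale_factor}
#' @export
scale_factor <- function(value = 0.99, provenance = "empirical") {
  if (value <= 0 || value > 1.2) stop("scale factor must be in (0, 1.2]")
  structure(list(value = value, provenance = provenance),
            class = "scale_factor")
}

#' Apply a frequency scale factor
#'
#' Multiplies every frequency; ordering and modes are preserved. Reported
#' tables round half-up to 2 decimals (see \code{\link{frequency_table}});
#' the stored values keep full precision.
#'
#' @param r a \code{normal_modes} result
#' @param f a \code{scale_factor} or a bare numeric value
#' @return a scaled \code{normal_modes}
#' @export
apply_scale_factor <- function(r, f) {
  if (is.numeric(f)) f <- scale_factor(f)
  r$frequencies <- r$frequencies * f$value
  r$scale <- if (is.null(r$scale)) f$value else r$scale * f$value
  r
}

#' Frequency table for reporting
#'
#' @param r a \code{normal_modes} result
#' @param scale optional scale factor applied in an extra column
#' @return data.frame with mode index, frequency, scaled frequency and unit
#'   intensity, all frequencies rounded half-up to 2 decimals
#' @export
frequency_table <- function(r, scale = NULL) {
  sc <- if (is.null(scale)) 1 else if (is.numeric(scale)) scale else scale$value
  data.frame(mode = seq_along(r$frequencies),
             freq_cm1 = round_half_up(r$frequencies, 2),
             scaled_cm1 = round_half_up(r$frequencies * sc, 2),
             intensity = 1)
}

#' Fraction of mode amplitude on a subset of atoms
#'
#' Mass-weighted modes are orthonormal, so the squared components on the
#' selected atoms give the locality fraction directly.
#'
#' @param r a \code{normal_modes} result
#' @param atoms integer vector of atom indices
#' @return numeric vector, one fraction in [0, 1] per mode
#' @export
mode_locality <- function(r, atoms) {
  rows <- as.vector(t(outer(atoms, 1:3, function(a, ax) 3 * (a - 1) + ax)))
  colSums(r$modes[rows, , drop = FALSE]^2)
}
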