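# IR spectrum synthesis, exp/calc peak assignment, MAE/RMSE scoring.

#' Synthesize a broadened IR spectrum
#'
#' Sum of area-normalized line shapes, one per mode, with peak area
#' proportional to intensity; modes outside the grid still contribute their
#' tails.
#'
#' @param freqs mode positions in cm^-1
#' @param intensities non-negative intensities (default: unit)
#' @param shape "lorentzian" or "gaussian"
#' @param fwhm full width at half maximum in cm^-1
#' @param grid wavenumber grid, strictly increasing (default 400-4000 step 1)
#' @return a \code{spectrum_ir}: data.frame with columns \code{wavenumber}
#'   and \code{absorbance}
#' @export
synthesize_spectrum <- function(freqs, intensities = NULL,
                                shape = c("lorentzian", "gaussian"),
                                fwhm = 8, grid = seq(400, 4000, by = 1)) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  if (is.null(intensities)) intensities <- rep(1, length(freqs))
  if (length(intensities) != length(freqs)) {
    stop("freqs and intensities must have the same length")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  y <- numeric(length(grid))
  for (k in seq_along(freqs)) {
    if (shape == "lorentzian") {
      gam <- fwhm / 2
      y <- y + intensities[k] * (gam / pi) / ((grid - freqs[k])^2 + gam^2)
    } else {
      sd <- fwhm / (2 * sqrt(2 * log(2)))
      y <- y + intensities[k] * stats::dnorm(grid, freqs[k], sd)
    }
  }
  out <- data.frame(wavenumber = grid, absorbance = y)
  class(out) <- c("spectrum_ir", "data.frame")
  out
}

# Jonker-Volgenant style shortest-augmenting-path solver for the square
# assignment problem; returns the column assigned to each row (minimization).
.solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square")
  # 1-based port of the classic potentials algorithm; index 1 = virtual column
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_row <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign_row[p[j]] <- j - 1L
  assign_row
}

#' Assignment table of experimental vs calculated peaks
#'
#' @param label per-row mode description
#' @param exp experimental wavenumbers (cm^-1), > 0
#' @param calc calculated wavenumbers (cm^-1), > 0
#' @param group optional "FG"/"NFG" classification per row
#' @return an \code{assignment_table} data.frame
#' @export
assignment_table <- function(label, exp, calc, group = NULL) {
  if (any(exp <= 0) || any(calc <= 0)) {
    stop("exp and calc wavenumbers must be > 0")
  }
  if (any(!nzchar(label))) stop("labels must be nonempty")
  out <- data.frame(label = as.character(label), exp = exp, calc = calc,
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- as.character(group)
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Match calculated frequencies to experimental peaks
#'
#' One-to-one pairing within a wavenumber window. \code{nearest_greedy}
#' visits experimental peaks in descending order and takes the nearest unused
#' calculated value within the window. \code{optimal} minimizes the total
#' absolute deviation over all one-to-one pairings (maximizing the number of
#' matched pairs first); ties between equal-total pairings are broken toward
#' the rank-preserving (descending-order) pairing, which is how published
#' assignment tables are laid out.
#'
#' @param calc calculated wavenumbers (cm^-1)
#' @param exp experimental wavenumbers (cm^-1)
#' @param window maximum |exp - calc| for a pair (cm^-1, default 100)
#' @param strategy "optimal" (default) or "nearest_greedy"
#' @param labels optional per-experimental-peak labels
#' @param groups optional per-experimental-peak "FG"/"NFG" classification
#' @return an \code{assignment_table} of matched pairs, sorted by descending
#'   exp; unmatched peaks are in attributes \code{unmatched_exp} and
#'   \code{unmatched_calc}
#' @export
match_assignments <- function(calc, exp, window = 100,
                              strategy = c("optimal", "nearest_greedy"),
                              labels = NULL, groups = NULL) {
  strategy <- match.arg(strategy)
  if (window <= 0) stop("window must be > 0")
  ne <- length(exp); nc <- length(calc)
  if (is.null(labels)) labels <- sprintf("exp_%g", exp)
  pair_e <- integer(0); pair_c <- integer(0)
  if (ne && nc) {
    if (strategy == "nearest_greedy") {
      used <- logical(nc)
      for (i in order(exp, decreasing = TRUE)) {
        d <- abs(calc - exp[i])
        d[used] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] <= window) {
          used[j] <- TRUE
          pair_e <- c(pair_e, i); pair_c <- c(pair_c, j)
        }
      }
    } else {
      FORBID <- 1e12; UNMATCH <- 1e6
      n <- ne + nc
      cost <- matrix(0, n, n)
      re <- rank(-exp, ties.method = "first")
      rc <- rank(-calc, ties.method = "first")
      for (i in seq_len(ne)) for (j in seq_len(nc)) {
        d <- abs(exp[i] - calc[j])
        cost[i, j] <- if (d <= window) {
          # infinitesimal rank penalty: deterministic, order-preserving ties
          d + 1e-7 * abs(re[i] - rc[j])
        } else FORBID
      }
      # dummy columns/rows let peaks stay unmatched at cost UNMATCH; the
      # bottom-right zero block absorbs the leftover dummies
      cost[seq_len(ne), nc + seq_len(ne)] <- FORBID
      cost[cbind(seq_len(ne), nc + seq_len(ne))] <- UNMATCH
      cost[ne + seq_len(nc), seq_len(nc)] <- FORBID
      cost[cbind(ne + seq_len(nc), seq_len(nc))] <- UNMATCH
      sol <- .solve_assignment(cost)
      for (i in seq_len(ne)) {
        j <- sol[i]
        if (j <= nc && cost[i, j] < UNMATCH) {
          pair_e <- c(pair_e, i); pair_c <- c(pair_c, j)
        }
      }
    }
  }
  ord <- order(exp[pair_e], decreasing = TRUE)
  pair_e <- pair_e[ord]; pair_c <- pair_c[ord]
  out <- data.frame(label = labels[pair_e], exp = exp[pair_e],
                    calc = calc[pair_c], stringsAsFactors = FALSE)
  if (!is.null(groups)) out$group <- as.character(groups)[pair_e]
  class(out) <- c("assignment_table", "data.frame")
  attr(out, "unmatched_exp") <- exp[setdiff(seq_len(ne), pair_e)]
  attr(out, "unmatched_calc") <- calc[setdiff(seq_len(nc), pair_c)]
  out
}

#' MAE and RMSE of an assignment table
#'
#' mae = mean |exp - calc|, rmse = sqrt(mean (exp - calc)^2); when a
#' \code{group} column is present, the same statistics are reported per
#' functional-group class.
#'
#' @param t an \code{assignment_table}
#' @return an \code{error_summary}: list with \code{mae}, \code{rmse},
#'   \code{n} and optional \code{per_group}
#' @export
error_summary <- function(t) {
  if (!nrow(t)) stop("assignment table is empty")
  dev <- t$exp - t$calc
  out <- list(mae = mean(abs(dev)), rmse = sqrt(mean(dev^2)), n = nrow(t))
  if (!is.null(t$group)) {
    per <- lapply(split(dev, t$group), function(d) {
      list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), n = length(d))
    })
    out$per_group <- per
  }
  class(out) <- "error_summary"
  out
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("MAE %.2f cm^-1, RMSE %.2f cm^-1 (n = %d)\n",
              round_half_up(x$mae, 2), round_half_up(x$rmse, 2), x$n))
  if (!is.null(x$per_group)) {
    for (gname in names(x$per_group)) {
      gx <- x$per_group[[gname]]
      cat(sprintf("  %s: MAE %.2f, RMSE %.2f (n = %d)\n", gname,
                  round_half_up(gx$mae, 2), round_half_up(gx$rmse, 2), gx$n))
    }
  }
  invisible(x)
}

#' Classify assignment labels as functional-group or skeletal vibrations
#'
#' A row is FG when its mode label involves an N-H, O-H, S-H or C=O (CO)
#' stretch or bend -- the hydrogen-bond donor/acceptor moieties; everything
#' else (C-H, ring and skeletal modes) is NFG. User labels can override.
#'
#' @param labels character vector of mode descriptions
#' @return character vector of "FG"/"NFG"
#' @export
classify_fg <- function(labels) {
  fg <- grepl("N[0-9_,-]*H|O[0-9_,-]*H|S[0-9_,-]*H|C[0-9_,-]*[=]?O",
              labels, ignore.case = FALSE)
  ifelse(fg, "FG", "NFG")
}
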