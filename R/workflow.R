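# End-to-end pipeline: structure -> three models -> optimize -> frequencies
# -> scaled/compared spectra -> comparison report.

#' Pipeline configuration
#'
#' @param reps supercell repetitions
#' @param hbond an \code{hbond_criteria}
#' @param interception an \code{interception_rule}
#' @param convergence a \code{convergence_criteria}
#' @param ff_params \code{toy_ff_params} for the built-in backend
#' @param backend backend name; \code{"toyff"} is built in
#' @param scale frequency scale factor applied to the single-molecule model
#' @param match_window assignment window in cm^-1
#' @param match_strategy \code{"optimal"} or \code{"nearest_greedy"}
#' @param central central molecule index, or \code{"auto"} for the molecule
#'   nearest the supercell centroid
#' @param exp_range wavenumber range (cm^-1) kept when generating
#'   pseudo-experimental peaks; the default drops lattice/librational modes
#'   below 400 cm^-1, which mid-IR acquisition does not record
#' @param modes \code{"central_localized"} reports only fragment/unit modes
#'   with >= \code{locality_threshold} of their mass-weighted amplitude on the
#'   central molecule; \code{"all"} reports every mode
#' @param locality_threshold central-amplitude fraction for mode filtering
#' @param models which model branches to run
#' @param bond_tolerance covalent bond perception tolerance in Angstrom
#' @param outdir optional output directory for intermediates and the manifest
#' @return an object of class \code{pipeline_config}
#' @export
pipeline_config <- function(reps = c(1, 1, 1), hbond = hbond_criteria(),
                            interception = interception_rule(),
                            convergence = convergence_criteria(),
                            ff_params = NULL, backend = "toyff",
                            scale = 0.99, match_window = 100,
                            match_strategy = "optimal", central = "auto",
                            exp_range = c(400, Inf),
                            modes = c("central_localized", "all"),
                            locality_threshold = 0.5,
                            models = c("single", "single_scaled", "central",
                                       "fragment"),
                            bond_tolerance = 0.40, outdir = NULL) {
  modes <- match.arg(modes)
  if (backend != "toyff") stop("unknown backend '", backend, "'")
  if (is.null(ff_params)) stop("ff_params are required for the toyff backend")
  bad <- setdiff(models, c("single", "single_scaled", "central", "fragment"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  structure(list(reps = as.integer(round(reps)), hbond = hbond,
                 interception = interception, convergence = convergence,
                 ff_params = ff_params, backend = backend, scale = scale,
                 match_window = match_window,
                 match_strategy = match_strategy, central = central,
                 exp_range = exp_range,
                 modes = modes, locality_threshold = locality_threshold,
                 models = models, bond_tolerance = bond_tolerance,
                 outdir = outdir),
            class = "pipeline_config")
}

# strip environments/closures for provenance serialization
.config_json <- function(cfg) {
  flat <- lapply(unclass(cfg), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null",
                   force = TRUE)
}

#' Run the full model-comparison pipeline
#'
#' Executes, for the requested models: single-molecule build + optimize +
#' frequencies (plus the scaled variant); repeating-unit build + optimize +
#' frequencies; central-molecule extraction + frequencies at the in-cluster
#' geometry; fragment interception + frequencies. Calculated frequencies are
#' matched against the experimental peak list and summarized as MAE/RMSE per
#' model. When no experimental peaks are given, pseudo-experimental peaks are
#' taken from the optimized repeating unit's central-localized modes (a
#' stand-in for a measured spectrum, useful for end-to-end testing).
#'
#' The pipeline is deterministic: identical config and inputs give an
#' identical report payload.
#'
#' @param cfg a \code{pipeline_config}
#' @param structure a \code{crystal_structure} (unit cell; the supercell is
#'   built here from \code{cfg$reps})
#' @param exp_peaks numeric vector of experimental wavenumbers, or NULL
#' @return a \code{comparison_report}: list with per-model \code{summaries}
#'   (\code{error_summary}), \code{frequencies}, assignment \code{tables},
#'   \code{models} (the cluster geometries), \code{exp_peaks} and
#'   \code{provenance}
#' @export
run_pipeline <- function(cfg, structure, exp_peaks = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  done <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed (completed stages: ",
           if (length(done)) paste(done, collapse = ", ") else "none",
           "): ", conditionMessage(e), call. = FALSE)
    })
  }
  mark <- function(name) done <<- c(done, name)

  sc <- stage("supercell", build_supercell(structure, cfg$reps))
  mark("supercell")
  central_index <- if (identical(cfg$central, "auto")) NULL else
    as.integer(cfg$central)

  backend_for <- function(geom) {
    toyff_backend(geom, cfg$ff_params, cfg$hbond, cfg$bond_tolerance)
  }
  freqs_of <- function(model) {
    b <- backend_for(model$geometry)
    h <- finite_difference_hessian(b, model$geometry)
    vibrational_analysis(h, model$geometry)
  }

  need_unit <- any(c("central", "fragment") %in% cfg$models)
  models <- list(); freqs <- list()

  if (any(c("single", "single_scaled") %in% cfg$models)) {
    single <- stage("single_build", {
      idx <- central_index
      if (is.null(idx)) {
        mols <- extract_molecules(sc, tolerance = cfg$bond_tolerance)
        center <- as.numeric(frac_to_cart(matrix(c(.5, .5, .5), 1),
                                          sc$lattice))
        idx <- which.min(vapply(mols,
                                function(m) sum((m$centroid - center)^2), 0))
      }
      build_single_molecule(sc, idx, cfg$bond_tolerance)
    })
    mark("single_build")
    single_opt <- stage("single_optimize",
                        optimize_geometry(single, backend_for(single$geometry),
                                          cfg$convergence)$model)
    mark("single_optimize")
    nm_single <- stage("single_frequencies", freqs_of(single_opt))
    mark("single_frequencies")
    if ("single" %in% cfg$models) {
      models$single <- single_opt; freqs$single <- nm_single
    }
    if ("single_scaled" %in% cfg$models) {
      models$single_scaled <- single_opt
      freqs$single_scaled <- apply_scale_factor(nm_single, cfg$scale)
    }
  }

  unit_opt <- NULL; nm_unit <- NULL
  if (need_unit || is.null(exp_peaks)) {
    unit <- stage("unit_build",
                  build_repeating_unit(sc, central_index, cfg$hbond,
                                       cfg$bond_tolerance))
    mark("unit_build")
    unit_opt <- stage("unit_optimize",
                      optimize_geometry(unit, backend_for(unit$geometry),
                                        cfg$convergence)$model)
    mark("unit_optimize")
    nm_unit <- stage("unit_frequencies", freqs_of(unit_opt))
    mark("unit_frequencies")
  }

  central_atoms_of <- function(model) which(model$atom_roles == "central")
  filtered_freqs <- function(nm, model) {
    if (cfg$modes == "all" || all(model$atom_roles == "central")) {
      return(nm$frequencies)
    }
    loc <- mode_locality(nm, central_atoms_of(model))
    nm$frequencies[loc >= cfg$locality_threshold]
  }

  if ("central" %in% cfg$models) {
    central <- stage("central_extract", extract_central_molecule(unit_opt))
    mark("central_extract")
    models$central <- central
    freqs$central <- stage("central_frequencies", freqs_of(central))
    mark("central_frequencies")
  }
  if ("fragment" %in% cfg$models) {
    fragment <- stage("fragment_intercept",
                      intercept_fragment(unit_opt, cfg$interception,
                                         cfg$hbond, cfg$bond_tolerance))
    mark("fragment_intercept")
    models$fragment <- fragment
    freqs$fragment <- stage("fragment_frequencies", freqs_of(fragment))
    mark("fragment_frequencies")
  }

  if (is.null(exp_peaks)) {
    exp_peaks <- filtered_freqs(nm_unit, unit_opt)
    exp_peaks <- exp_peaks[exp_peaks >= cfg$exp_range[1] &
                             exp_peaks <= cfg$exp_range[2]]
    exp_source <- "pseudo-experimental (optimized repeating unit)"
  } else {
    exp_source <- "user-supplied"
  }

  tables <- list(); summaries <- list()
  for (mn in names(freqs)) {
    fr <- filtered_freqs(freqs[[mn]], models[[mn]])
    tab <- match_assignments(fr, exp_peaks, cfg$match_window,
                             cfg$match_strategy)
    tables[[mn]] <- tab
    summaries[mn] <- list(if (nrow(tab)) error_summary(tab) else NULL)
  }

  report <- structure(list(
    summaries = summaries,
    tables = tables,
    frequencies = lapply(freqs, function(f) f$frequencies),
    models = models,
    unit = unit_opt,
    exp_peaks = exp_peaks,
    exp_source = exp_source,
    provenance = list(
      config = jsonlite::fromJSON(.config_json(cfg), simplifyVector = TRUE),
      config_hash = {
        tmp <- tempfile()
        writeLines(.config_json(cfg), tmp)
        h <- unname(tools::md5sum(tmp))
        unlink(tmp)
        h
      },
      package_version = as.character(utils::packageVersion("vibrafrag"))
    )
  ), class = "comparison_report")

  if (!is.null(cfg$outdir)) .write_report(report, cfg$outdir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (", x$exp_source, ", ",
      length(x$exp_peaks), " reference peaks)\n", sep = "")
  for (mn in names(x$summaries)) {
    s <- x$summaries[[mn]]
    if (is.null(s)) {
      cat(sprintf("  %-13s no matched peaks\n", mn))
    } else {
      cat(sprintf("  %-13s MAE %8.2f  RMSE %8.2f  (n = %d)\n", mn,
                  round_half_up(s$mae, 2), round_half_up(s$rmse, 2), s$n))
    }
  }
  invisible(x)
}

# serializable payload: everything except raw geometries (written as XYZ)
.report_payload <- function(report) {
  list(
    exp_source = report$exp_source,
    exp_peaks = round_half_up(report$exp_peaks, 6),
    frequencies = lapply(report$frequencies,
                         function(f) round_half_up(f, 6)),
    summaries = lapply(report$summaries, function(s) {
      if (is.null(s)) NULL else unclass(s)
    }),
    tables = lapply(report$tables, function(t) as.data.frame(unclass(t))),
    provenance = report$provenance
  )
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (mn in names(report$models)) {
    f <- file.path(outdir, paste0(mn, ".xyz"))
    write_xyz(report$models[[mn]]$geometry, f,
              comment = report$models[[mn]]$provenance,
              tags = report$models[[mn]]$atom_roles)
    files <- c(files, basename(f))
    ft <- frequency_table(list(frequencies = report$frequencies[[mn]]))
    fcsv <- file.path(outdir, paste0(mn, "_freq.csv"))
    utils::write.csv(ft, fcsv, row.names = FALSE)
    files <- c(files, basename(fcsv))
  }
  if (!is.null(report$unit)) {
    f <- file.path(outdir, "repeating_unit.xyz")
    write_xyz(report$unit$geometry, f, comment = report$unit$provenance,
              tags = report$unit$atom_roles)
    files <- c(files, basename(f))
  }
  jsonlite::write_json(.report_payload(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  files <- c(files, "report.json")
  jsonlite::write_json(list(files = files,
                            config_hash = report$provenance$config_hash),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
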