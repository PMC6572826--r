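# Run configuration and the three-tier pipeline driver.

#' Pipeline run configuration
#'
#' Defaults mirror the printed settings of typical top-down validation
#' software for this kind of experiment: 25 ppm fragmentation tolerance,
#' S/N cutoff 3, deconvolution mass range 15,000-300,000 Da, isotope
#' pruning limit 1e-4, and a 1.5 Da intact-mass tolerance.
#'
#' @param tol_intact Intact-mass tolerance in Da for delta explanations.
#' @param tol_ppm Fragment matching tolerance in ppm.
#' @param z_range_ms1,z_range_ms2 Charge windows for MS1/MS2 deconvolution.
#' @param mass_range Deconvolution mass window in Da.
#' @param max_species Maximum deconvolved species per spectrum.
#' @param snr_cutoff Peak-picking signal-to-noise cutoff.
#' @param apply_snr_filter Apply [pick_peaks()] before deconvolution. The
#'   default `TRUE` mirrors a raw-data workflow; supply `FALSE` for peak
#'   lists that are already noise-filtered.
#' @param prune Isotope-distribution pruning limit.
#' @param fit_threshold Envelope-fit threshold for metal calls.
#' @param assign_tol Tolerance (Da) for assigning deconvolved species to
#'   proteoform hypotheses.
#' @param k_max Maximum entries per delta explanation.
#' @param seed Seed recorded in reports and used by any simulation step.
#' @param catalog_path Optional path to a catalog TSV (`NULL` = packaged).
#' @return A list of class `run_config`.
#' @export
run_config <- function(tol_intact = 1.5, tol_ppm = 25,
                       z_range_ms1 = c(10, 25), z_range_ms2 = c(5, 20),
                       mass_range = c(15000, 300000), max_species = 15,
                       snr_cutoff = 3, apply_snr_filter = TRUE, prune = 1e-4,
                       fit_threshold = 0.8, assign_tol = 5, k_max = 3,
                       seed = 1L, catalog_path = NULL) {
  structure(list(tol_intact = tol_intact, tol_ppm = tol_ppm,
                 z_range_ms1 = z_range_ms1, z_range_ms2 = z_range_ms2,
                 mass_range = mass_range, max_species = max_species,
                 snr_cutoff = snr_cutoff, apply_snr_filter = apply_snr_filter,
                 prune = prune,
                 fit_threshold = fit_threshold, assign_tol = assign_tol,
                 k_max = k_max, seed = as.integer(seed),
                 catalog_path = catalog_path),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key/value YAML; keys not present fall back to [run_config()]
#' defaults, unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file (e.g. CLI flags).
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

# assign deconvolved species to subunit/apo-or-bound hypotheses
assign_species <- function(species, subunits, catalog, assign_tol) {
  expected <- list()
  for (id in names(subunits)) {
    su <- subunits[[id]]
    m0 <- if (!is.null(su$theoretical_mass)) su$theoretical_mass else {
      p_apo <- su$proteoform; p_apo$adducts <- list()
      proteoform_mass(p_apo)
    }
    expected[[length(expected) + 1]] <- data.frame(subunit = id, bound = "apo",
                                                   expected_mass = m0)
    if (!is.null(su$metal)) {
      expected[[length(expected) + 1]] <-
        data.frame(subunit = id, bound = su$metal$name,
                   expected_mass = m0 + adduct_shift(su$metal, "average"))
    }
  }
  exp_df <- do.call(rbind, expected)
  sp <- as.data.frame(species)
  sp$subunit <- NA_character_; sp$bound <- NA_character_
  sp$expected_mass <- NA_real_; sp$delta <- NA_real_
  for (i in seq_len(nrow(sp))) {
    d <- abs(exp_df$expected_mass - sp$neutral_mass[i])
    j <- which.min(d)
    if (d[j] <= assign_tol) {
      sp$subunit[i] <- exp_df$subunit[j]
      sp$bound[i] <- exp_df$bound[j]
      sp$expected_mass[i] <- exp_df$expected_mass[j]
      sp$delta[i] <- sp$neutral_mass[i] - exp_df$expected_mass[j]
    }
  }
  sp
}

#' Run the three-tier interpretation pipeline
#'
#' Executes, on whatever measurement tiers are supplied: MS1 deconvolution
#' and intact-mass delta explanation; MS2 deconvolution, species-to-subunit
#' assignment, delta explanation and metal occupancy; MS1-MS2 mass-balance
#' accounting; and per-subunit MS3 fragment matching, Poisson p-score,
#' metal-bound fragment detection and interval localization. Missing inputs
#' skip their stage with a logged reason; only hard errors raise.
#'
#' @param config A [run_config()].
#' @param ms1 Optional MS1 [ms_spectrum()].
#' @param ms2 Optional MS2 [ms_spectrum()] or list of replicate spectra.
#' @param ms3 Optional named list (by subunit id) of MS3 inputs, each a list
#'   with `masses` (neutral monoisotopic Da) and optional `envelopes`.
#' @param subunits Optional named list of subunit hypotheses, each a list
#'   with `proteoform` (or `theoretical_mass`) and optional `metal`
#'   (a [metal_adduct()]).
#' @param protomer_mass Optional theoretical intact-complex mass (Da) for
#'   the MS1 delta table.
#' @return A list of class `ntdms_report` with elements `config`, `ms1`,
#'   `ms2`, `balance`, `ms3`, `skipped`.
#' @export
run_pipeline <- function(config = run_config(), ms1 = NULL, ms2 = NULL,
                         ms3 = NULL, subunits = NULL, protomer_mass = NULL) {
  catalog <- read_catalog(config$catalog_path)
  skipped <- character(0)
  report <- list(config = unclass(config))

  # --- MS1: intact complex ---
  if (!is.null(ms1)) {
    in1 <- if (config$apply_snr_filter) pick_peaks(ms1, config$snr_cutoff) else ms1
    sp1 <- deconvolute(in1, config$z_range_ms1, config$mass_range,
                       config$max_species)
    deltas <- NULL
    if (!is.null(protomer_mass) && nrow(sp1)) {
      deltas <- lapply(seq_len(nrow(sp1)), function(i) {
        d <- sp1$neutral_mass[i] - protomer_mass
        list(neutral_mass = sp1$neutral_mass[i], delta = d,
             explanations = as.data.frame(
               explain_delta(d, catalog, config$k_max, config$tol_intact)))
      })
    }
    report$ms1 <- list(species = as.data.frame(sp1), protomer_mass = protomer_mass,
                       deltas = deltas)
  } else skipped <- c(skipped, "MS1: no spectrum supplied")

  # --- MS2: ejected subunits ---
  ms2_assigned <- NULL
  if (!is.null(ms2)) {
    reps <- if (inherits(ms2, "ntdms_spectrum")) list(ms2) else ms2
    sp2 <- lapply(reps, function(s) {
      s <- if (config$apply_snr_filter) pick_peaks(s, config$snr_cutoff) else s
      deconvolute(s, config$z_range_ms2, config$mass_range, config$max_species)
    })
    if (!is.null(subunits)) {
      asg <- lapply(sp2, assign_species, subunits = subunits,
                    catalog = catalog, assign_tol = config$assign_tol)
      ms2_assigned <- asg
      occ <- tryCatch({
        known <- lapply(asg, function(a) a[!is.na(a$subunit), ])
        metal_subs <- names(subunits)[!vapply(subunits, function(s)
          is.null(s$metal), logical(1))]
        occ_in <- lapply(known, function(a) a[a$subunit %in% metal_subs, ])
        if (all(vapply(occ_in, nrow, integer(1)) > 0)) {
          as.data.frame(occupancy_fractions(occ_in, group = "bound",
                                            within = "subunit"))
        } else NULL
      }, error = function(e) NULL)
      deltas <- lapply(asg[[1]][!is.na(asg[[1]]$subunit), "delta"],
                       function(d) as.data.frame(
                         explain_delta(d, catalog, config$k_max,
                                       config$tol_intact)))
      report$ms2 <- list(species = lapply(asg, as.data.frame),
                         occupancy = occ, delta_explanations = deltas)
    } else {
      report$ms2 <- list(species = lapply(sp2, as.data.frame))
      skipped <- c(skipped, "MS2 assignment: no subunit hypotheses supplied")
    }
  } else skipped <- c(skipped, "MS2: no spectrum supplied")

  # --- MS1-MS2 mass balance ---
  if (!is.null(report$ms1) && nrow(report$ms1$species) &&
      !is.null(ms2_assigned)) {
    a1 <- ms2_assigned[[1]]
    comp <- vapply(split(a1[!is.na(a1$subunit), ],
                         a1$subunit[!is.na(a1$subunit)]),
                   function(d) d$neutral_mass[which.max(d$total_intensity)],
                   numeric(1))
    bal <- mass_balance(report$ms1$species$neutral_mass[1], comp,
                        catalog = catalog, tol = config$tol_intact,
                        k_max = config$k_max)
    report$balance <- list(complex_mass = report$ms1$species$neutral_mass[1],
                           component_masses = as.list(comp),
                           residual = bal$residual,
                           explanations = as.data.frame(bal$explanations))
  } else skipped <- c(skipped, "mass balance: needs both MS1 and assigned MS2 species")

  # --- MS3: backbone fragments per subunit ---
  if (!is.null(ms3)) {
    if (is.null(subunits)) {
      skipped <- c(skipped, "MS3: no subunit hypotheses supplied")
    } else {
      report$ms3 <- list()
      for (id in names(ms3)) {
        su <- subunits[[id]]
        if (is.null(su) || is.null(su$proteoform)) {
          skipped <- c(skipped, paste0("MS3 ", id, ": no proteoform sequence"))
          next
        }
        p <- su$proteoform
        hyp <- if (!is.null(su$metal)) list(list(spec = su$metal, count = 1)) else list()
        theo <- generate_fragments(p, c("b", "y"), adducts = hyp)
        obs <- ms3[[id]]$masses
        mres <- match_fragments(theo, obs, config$tol_ppm)
        span <- diff(range(obs))
        ps <- if (span > 0) {
          fragment_pscore(nrow(mres$matches), length(obs), nrow(theo),
                          config$tol_ppm, mean(theo$neutral_mass), span)
        } else NA_real_
        entry <- list(n_observed = length(obs),
                      n_matched = nrow(mres$matches),
                      coverage = mres$coverage, p_score = ps,
                      map = as.data.frame(mres$map))
        if (!is.null(su$metal)) {
          calls <- detect_metal_fragments(mres$matches, su$metal,
                                          proteoform = p,
                                          envelopes = ms3[[id]]$envelopes,
                                          metal_spec = su$metal,
                                          fit_threshold = config$fit_threshold,
                                          prune = config$prune)
          loc <- localize_adduct(calls, nchar(p$sequence),
                                 offset = p$n_term_start - 1L)
          entry$metal_calls <- as.data.frame(calls)
          entry$localization <- unclass(loc)
        }
        report$ms3[[id]] <- entry
      }
    }
  } else skipped <- c(skipped, "MS3: no fragment masses supplied")

  report$skipped <- skipped
  class(report) <- "ntdms_report"
  report
}

#' @export
print.ntdms_report <- function(x, ...) {
  cat("nTDMS pipeline report\n")
  if (!is.null(x$ms1)) {
    cat(sprintf("  MS1: %d species; top mass %.1f Da\n", nrow(x$ms1$species),
                if (nrow(x$ms1$species)) x$ms1$species$neutral_mass[1] else NA))
  }
  if (!is.null(x$ms2)) {
    cat(sprintf("  MS2: %d replicate spectrum/spectra\n", length(x$ms2$species)))
  }
  if (!is.null(x$balance)) {
    cat(sprintf("  MS1-MS2 residual: %.1f Da\n", x$balance$residual))
  }
  for (id in names(x$ms3)) {
    e <- x$ms3[[id]]
    cat(sprintf("  MS3 %s: %d/%d matched, coverage %.2f\n", id,
                e$n_matched, e$n_observed, e$coverage))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine-readable, includes the full effective
#' configuration and seed) and `report.txt` (human-readable summary) into
#' `dir`.
#'
#' @param report An [run_pipeline()] report.
#' @param dir Output directory (created if needed).
#' @return Path of the JSON file, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  writeLines(utils::capture.output(print(report)), file.path(dir, "report.txt"))
  invisible(json_path)
}
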