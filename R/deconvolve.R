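# Charge-state deconvolution of native ESI spectra.
#
# Positive mode only. m/z charging uses the proton mass (1.00728 Da):
# implied neutral mass for a peak at m/z with charge z is z * (mz - 1.00728).
# The clustering tolerance scales with mass (default 1.5 Da + 20 ppm), a
# scale set by the ~0.3-1.1 Da standard deviations typical of native
# deconvolution at 28-99 kDa.

cluster_tol <- function(mass, tol_da = 1.5, tol_ppm = 20) {
  tol_da + tol_ppm * 1e-6 * mass
}

#' S/N-based peak picking
#'
#' Retains peaks whose intensity is at least `snr_cutoff` times the noise
#' estimate, taken as the median absolute intensity of the spectrum. The
#' noise estimate is recorded in the spectrum metadata and reused when the
#' operation is re-applied to its own output, making picking idempotent.
#'
#' @param spec An [ms_spectrum()] object.
#' @param snr_cutoff Signal-to-noise cutoff (`> 0`; default 3).
#' @return The picked [ms_spectrum()].
#' @export
pick_peaks <- function(spec, snr_cutoff = 3) {
  if (snr_cutoff <= 0) stop("snr_cutoff must be positive", call. = FALSE)
  if (!nrow(spec$peaks)) return(spec)
  noise <- spec$metadata$noise_level
  if (is.null(noise)) noise <- stats::median(abs(spec$peaks$intensity))
  keep <- spec$peaks$intensity >= snr_cutoff * noise
  meta <- spec$metadata
  meta$noise_level <- noise
  ms_spectrum(spec$peaks$mz[keep], spec$peaks$intensity[keep],
           level = spec$level, metadata = meta)
}

# all (peak, z) candidates with implied neutral masses
charge_candidates <- function(spec, z_range) {
  z <- seq(min(z_range), max(z_range))
  if (any(z < 1 | z > 50)) stop("z_range must lie within [1, 50]", call. = FALSE)
  pk <- spec$peaks
  data.frame(peak = rep(seq_len(nrow(pk)), each = length(z)),
             mz = rep(pk$mz, each = length(z)),
             intensity = rep(pk$intensity, each = length(z)),
             z = rep(z, nrow(pk)),
             mass = rep(z, nrow(pk)) * (rep(pk$mz, each = length(z)) - PROTON_MASS))
}

#' Assign charges to peaks of a charge-state envelope
#'
#' For each peak and each candidate charge the implied neutral mass is
#' `z * (mz - 1.00728)`. Implied masses are clustered with a mass-scaled
#' tolerance; a cluster is accepted when at least two distinct peaks imply
#' the same mass (or unconditionally when `z_range` contains a single
#' charge, where no envelope ambiguity exists). A peak consistent with more
#' than one accepted cluster is assigned to the nearest implied mass, ties
#' to the higher-intensity cluster.
#'
#' @param spec An [ms_spectrum()] object.
#' @param z_range Integer charge interval, e.g. `c(15, 18)`, within `[1, 50]`.
#' @param tol_da,tol_ppm Clustering tolerance: `tol_da + tol_ppm * 1e-6 * M`.
#' @return A list with `assigned` (data.frame: peak index, `mz`, `intensity`,
#'   `z`, `mass`, `species` cluster id) and `unassigned` (peak indices).
#' @export
assign_charges <- function(spec, z_range, tol_da = 1.5, tol_ppm = 20) {
  cand <- charge_candidates(spec, z_range)
  single_z <- length(unique(cand$z)) == 1L
  cand <- cand[order(cand$mass), ]
  gap_tol <- cluster_tol(cand$mass[-1], tol_da, tol_ppm)
  cl <- cumsum(c(TRUE, diff(cand$mass) > gap_tol))
  cand$cluster <- cl

  info <- do.call(rbind, lapply(split(cand, cand$cluster), function(d) {
    zu <- sort(unique(d$z[!duplicated(d$peak)]))
    data.frame(cluster = d$cluster[1], n_peaks = length(unique(d$peak)),
               consec = length(zu) > 1 && any(diff(zu) == 1L),
               mass = stats::weighted.mean(d$mass, d$intensity),
               intensity = sum(d$intensity[!duplicated(d$peak)]))
  }))
  # a real charge-state envelope shows >= 2 peaks at consecutive charges;
  # this rejects harmonic artifacts (e.g. a 2M ghost at sparse charges)
  ok <- (info$n_peaks >= 2 & info$consec) | single_z
  accepted <- info$cluster[ok]
  cand <- cand[cand$cluster %in% accepted, ]
  if (!nrow(cand)) {
    return(list(assigned = cand[, c("peak", "mz", "intensity", "z", "mass")],
                unassigned = seq_len(nrow(spec$peaks))))
  }
  m <- match(cand$cluster, info$cluster)
  cand$cluster_mass <- info$mass[m]
  cand$cluster_int <- info$intensity[m]
  cand$cluster_n <- info$n_peaks[m]
  # per-peak resolution: richest envelope first, then nearest implied mass,
  # then higher-intensity species
  cand <- cand[order(cand$peak, -cand$cluster_n,
                     abs(cand$mass - cand$cluster_mass), -cand$cluster_int), ]
  cand <- cand[!duplicated(cand$peak), ]
  # re-validate clusters after exclusive assignment
  n_by_cluster <- table(cand$cluster)
  keep_cl <- as.integer(names(n_by_cluster)[n_by_cluster >= 2 | single_z])
  cand <- cand[cand$cluster %in% keep_cl, ]
  assigned <- cand[order(cand$cluster, cand$z),
                   c("peak", "mz", "intensity", "z", "mass", "cluster")]
  names(assigned)[names(assigned) == "cluster"] <- "species"
  rownames(assigned) <- NULL
  list(assigned = assigned,
       unassigned = setdiff(seq_len(nrow(spec$peaks)), assigned$peak))
}

#' Deconvolute a native spectrum into neutral species
#'
#' Clusters charge-assigned peaks into neutral species. For each species the
#' neutral mass is the intensity-weighted mean of the implied masses, and
#' the reported standard deviation is the unweighted SD of the per-charge-
#' state implied masses (the convention used when a deconvoluted neutral
#' average mass is reported as M +/- SD from sampling multiple charge
#' states). Species outside `mass_range` are discarded and at most
#' `max_species` are returned, ranked by total intensity.
#'
#' @inheritParams assign_charges
#' @param mass_range Neutral mass window in Da (default 15,000-300,000).
#' @param max_species Maximum number of species returned (default 15).
#' @return A data.frame of class `deconv_species` with columns
#'   `neutral_mass`, `mass_sd`, `n_charges`, `charges` (comma-separated),
#'   `total_intensity`. Empty when no envelope is assignable.
#' @export
deconvolute <- function(spec, z_range, mass_range = c(15000, 300000),
                        max_species = 15, tol_da = 1.5, tol_ppm = 20) {
  if (length(mass_range) != 2 || diff(mass_range) <= 0 || any(mass_range <= 0)) {
    stop("mass_range must be a positive ordered interval", call. = FALSE)
  }
  asg <- assign_charges(spec, z_range, tol_da, tol_ppm)$assigned
  empty <- data.frame(neutral_mass = numeric(0), mass_sd = numeric(0),
                      n_charges = integer(0), charges = character(0),
                      total_intensity = numeric(0))
  class(empty) <- c("deconv_species", "data.frame")
  if (!nrow(asg)) return(empty)
  out <- do.call(rbind, lapply(split(asg, asg$species), function(d) {
    # implied mass per charge state (intensity-weighted within a charge)
    per_z <- vapply(split(d, d$z),
                    function(g) stats::weighted.mean(g$mass, g$intensity),
                    numeric(1))
    data.frame(neutral_mass = stats::weighted.mean(d$mass, d$intensity),
               mass_sd = if (length(per_z) > 1) stats::sd(per_z) else 0,
               n_charges = length(per_z),
               charges = paste(sort(unique(d$z)), collapse = ","),
               total_intensity = sum(d$intensity))
  }))
  out <- out[out$neutral_mass >= mass_range[1] & out$neutral_mass <= mass_range[2], ]
  out <- out[order(-out$total_intensity), ]
  out <- utils::head(out, max_species)
  rownames(out) <- NULL
  class(out) <- c("deconv_species", "data.frame")
  out
}
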