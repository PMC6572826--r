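# Seeded synthetic MS1/MS2/MS3 generator.
#
# Emulates the statistical structure of native top-down experiments on a
# ~100 kDa membrane-protein complex: charge-state envelopes at 15-18+,
# ejected subunits at 28-42 kDa, HCD b/y ladders with ppm-scale mass error
# and enhanced cleavage C-terminal to Asp, metal adducts retained with
# configurable probability, ammonium-style adducts and periodic
# lipid-cluster background. Identical config + seed gives identical output.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles the generator's noise and envelope parameters. Defaults model
#' the study conditions the pipeline is designed for: a discretized
#' Gaussian charge envelope centered at 16.5 with SD 1 (a 15-18+ window for
#' a ~100 kDa complex), additive m/z jitter of 0.05 Th (propagating to
#' ~0.3-1.1 Da deconvolution SDs at 28-99 kDa), multiplicative log-normal
#' intensity noise of 10%, 5 ppm fragment mass jitter (well inside a 25 ppm
#' matching tolerance), half the backbone sampled as fragments, a 3x
#' cleavage enhancement C-terminal to Asp, and deterministic metal
#' retention unless a scenario sets otherwise.
#'
#' @param z_center,z_sd Center and SD of the discretized Gaussian over
#'   integer charge states.
#' @param mz_jitter_sd Additive m/z jitter SD in Th.
#' @param intensity_noise_sd SD of multiplicative log-normal intensity noise.
#' @param lipid_mass,lipid_count,lipid_intensity Periodic background peak
#'   series (singly charged clusters of a lipid of `lipid_mass` Da);
#'   `lipid_count = 0` (default) disables it.
#' @param noise_peaks,noise_intensity Dense chemical-noise baseline:
#'   `noise_peaks` peaks at uniform random m/z over the signal range with
#'   exponentially distributed intensities of mean `noise_intensity`;
#'   `noise_peaks = 0` (default) disables it. A baseline is what an S/N
#'   peak-picking cutoff is measured against.
#' @param metal_retention_prob Probability a metal adduct is retained on a
#'   fragment covering its site.
#' @param fragment_coverage Fraction of backbone cleavage sites sampled.
#' @param fragment_ppm_sd Fragment mass jitter SD in ppm.
#' @param asp_cleavage_bias Sampling-weight multiplier (`>= 1`) for cleavage
#'   sites C-terminal to an Asp residue.
#' @param envelope_noise_sd Multiplicative noise on rendered isotope
#'   envelope intensities.
#' @param seed Integer seed; every stochastic generator draws from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(z_center = 16.5, z_sd = 1.0, mz_jitter_sd = 0.05,
                       intensity_noise_sd = 0.1, lipid_mass = 760.08,
                       lipid_count = 0, lipid_intensity = 0,
                       noise_peaks = 0, noise_intensity = 0,
                       metal_retention_prob = 1.0, fragment_coverage = 0.5,
                       fragment_ppm_sd = 5, asp_cleavage_bias = 3,
                       envelope_noise_sd = 0.05, seed = 1L) {
  stopifnot(z_sd > 0, mz_jitter_sd >= 0, intensity_noise_sd >= 0,
            metal_retention_prob >= 0, metal_retention_prob <= 1,
            fragment_coverage > 0, fragment_coverage <= 1,
            asp_cleavage_bias >= 1)
  structure(list(z_center = z_center, z_sd = z_sd, mz_jitter_sd = mz_jitter_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 lipid_mass = lipid_mass, lipid_count = lipid_count,
                 lipid_intensity = lipid_intensity,
                 noise_peaks = as.integer(noise_peaks),
                 noise_intensity = noise_intensity,
                 metal_retention_prob = metal_retention_prob,
                 fragment_coverage = fragment_coverage,
                 fragment_ppm_sd = fragment_ppm_sd,
                 asp_cleavage_bias = asp_cleavage_bias,
                 envelope_noise_sd = envelope_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# integer charge support of a discretized Gaussian envelope
charge_weights <- function(z_center, z_sd, rel_min = 1e-3) {
  z <- seq.int(max(1, floor(z_center - 5 * z_sd)), ceiling(z_center + 5 * z_sd))
  w <- stats::dnorm(z, z_center, z_sd)
  keep <- w >= rel_min * max(w)
  list(z = z[keep], w = w[keep] / sum(w[keep]))
}

#' Simulate an intact-species native spectrum (MS1 or MS2)
#'
#' For every species, peaks are placed at `mz = (M + z * 1.00728) / z` over
#' the charge envelope with intensities proportional to abundance times
#' envelope weight, then perturbed by additive m/z jitter and multiplicative
#' log-normal intensity noise. Optionally adds a periodic singly-charged
#' lipid-cluster background series.
#'
#' @param species List of species, each a list with `id`, `mass` (neutral
#'   average Da) or `proteoform` (a [proteoform()], whose average mass is
#'   used), `abundance` (`> 0`), and optional per-species `z_center`/`z_sd`
#'   overrides.
#' @param config A [sim_config()].
#' @param level `"MS1"` or `"MS2"`.
#' @return An [ms_spectrum()] whose metadata records the config seed and the
#'   per-species true masses (ground truth for tests).
#' @export
simulate_intact_spectrum <- function(species, config = sim_config(),
                                     level = c("MS1", "MS2")) {
  level <- match.arg(level)
  with_seed(config$seed, {
    mzs <- numeric(0); ints <- numeric(0); truth <- list()
    for (sp in species) {
      M <- if (!is.null(sp$mass)) sp$mass else proteoform_mass(sp$proteoform)
      ab <- sp$abundance
      if (is.null(ab) || ab <= 0) stop("species abundance must be > 0", call. = FALSE)
      zc <- if (!is.null(sp$z_center)) sp$z_center else config$z_center
      zs <- if (!is.null(sp$z_sd)) sp$z_sd else config$z_sd
      env <- charge_weights(zc, zs)
      mz <- (M + env$z * PROTON_MASS) / env$z
      if (config$mz_jitter_sd > 0) {
        mz <- mz + stats::rnorm(length(mz), 0, config$mz_jitter_sd)
      }
      intensity <- ab * env$w
      if (config$intensity_noise_sd > 0) {
        intensity <- intensity *
          exp(stats::rnorm(length(intensity), 0, config$intensity_noise_sd))
      }
      mzs <- c(mzs, mz); ints <- c(ints, intensity)
      truth[[sp$id]] <- M
    }
    if (config$lipid_count > 0) {
      n <- seq_len(config$lipid_count)
      lip_mz <- n * config$lipid_mass + PROTON_MASS
      lip_int <- config$lipid_intensity * exp(-0.15 * (n - 1))
      mzs <- c(mzs, lip_mz); ints <- c(ints, lip_int)
    }
    if (config$noise_peaks > 0) {
      rng <- if (length(mzs)) range(mzs) else c(500, 8000)
      mzs <- c(mzs, stats::runif(config$noise_peaks, rng[1] - 50, rng[2] + 50))
      ints <- c(ints, config$noise_intensity * stats::rexp(config$noise_peaks))
    }
    ms_spectrum(mzs, ints, level = level,
             metadata = list(simulated = TRUE, seed = config$seed,
                             true_masses = truth))
  })
}

#' Simulate ejection of subunits from a complex (MS2)
#'
#' Each subunit inherits the complex's abundance; a subunit carrying a
#' metal adduct retains it with probability `1 - metal_loss_prob` per
#' complex ion, splitting the subunit signal into apo and metal-bound
#' species with binomially sampled abundances (`n_draws` complex ions).
#'
#' @param subunits List of subunit definitions: `id`, `mass` (apo neutral
#'   average mass, Da), optional `metal` (a [metal_adduct()] or adduct
#'   catalog row), optional `z_center`/`z_sd`, and optional per-subunit
#'   `metal_loss_prob` overriding the global value (a fully retained
#'   structural metal and a labile one can then coexist in one complex).
#' @param metal_loss_prob Probability a bound metal is lost on ejection.
#' @param config A [sim_config()].
#' @param n_draws Number of complex ions sampled.
#' @return A list: `spectrum` (MS2 [ms_spectrum()]), `species` (the species
#'   list passed to the intact simulator, with `subunit` and `bound`
#'   fields), and `truth` (true masses and bound fractions).
#' @export
simulate_ejection <- function(subunits, metal_loss_prob, config = sim_config(),
                              n_draws = 1000) {
  stopifnot(metal_loss_prob >= 0, metal_loss_prob <= 1)
  species <- list(); truth <- list()
  draws <- with_seed(config$seed + 1L, {
    lapply(subunits, function(su) {
      if (is.null(su$metal)) return(NULL)
      loss <- if (!is.null(su$metal_loss_prob)) su$metal_loss_prob else metal_loss_prob
      stats::rbinom(1, n_draws, 1 - loss) / n_draws
    })
  })
  for (k in seq_along(subunits)) {
    su <- subunits[[k]]
    if (is.null(su$metal)) {
      species[[length(species) + 1]] <- list(id = su$id, mass = su$mass,
                                             abundance = 1, subunit = su$id,
                                             bound = "apo",
                                             z_center = su$z_center, z_sd = su$z_sd)
      truth[[su$id]] <- list(mass = su$mass, bound_fraction = 0)
    } else {
      f <- draws[[k]]
      shift <- adduct_shift(su$metal, "average")
      if (f < 1) {
        species[[length(species) + 1]] <-
          list(id = paste0(su$id, ":apo"), mass = su$mass, abundance = 1 - f,
               subunit = su$id, bound = "apo",
               z_center = su$z_center, z_sd = su$z_sd)
      }
      if (f > 0) {
        species[[length(species) + 1]] <-
          list(id = paste0(su$id, ":", su$metal$name), mass = su$mass + shift,
               abundance = f, subunit = su$id, bound = su$metal$name,
               z_center = su$z_center, z_sd = su$z_sd)
      }
      truth[[su$id]] <- list(mass = su$mass, bound_fraction = f,
                             metal = su$metal$name, metal_shift = shift)
    }
  }
  spec <- simulate_intact_spectrum(species, config, level = "MS2")
  list(spectrum = spec, species = species, truth = truth)
}

#' Simulate deisotoped fragment masses of a proteoform (MS3)
#'
#' Samples backbone cleavage sites without replacement (sampling weight
#' multiplied by `asp_cleavage_bias` at sites C-terminal to Asp), emits the
#' b and y neutral monoisotopic masses at each sampled site with ppm-scale
#' jitter, and, when a metal site is given, shifts each fragment covering
#' the site by the metal's monoisotopic net mass with probability
#' `metal_retention_prob`. Optionally renders noisy observed isotope
#' envelopes for selected fragments.
#'
#' @param p A [proteoform()].
#' @param config A [sim_config()].
#' @param metal Optional [metal_adduct()] (or adduct catalog row) bound to
#'   the proteoform.
#' @param metal_site Optional 1-based residue index of the metal site.
#' @param render_envelopes `"none"` (default), `"all"`, or an integer vector
#'   of site indices whose b fragments get rendered envelopes.
#' @return A list: `masses` (data.frame `series`, `index`, `neutral_mass`,
#'   `metal_bound`), `envelopes` (named list keyed `"b165"` style, possibly
#'   empty), and `truth` (`metal_site`, sampled sites).
#' @export
simulate_fragment_masses <- function(p, config = sim_config(), metal = NULL,
                                     metal_site = NULL,
                                     render_envelopes = "none") {
  L <- nchar(p$sequence)
  aa <- strsplit(p$sequence, "")[[1]]
  theo <- generate_fragments(p, c("b", "y"))
  bm <- theo$neutral_mass[theo$series == "b"]
  ym <- theo$neutral_mass[theo$series == "y"]
  metal_mono <- if (!is.null(metal)) entry_shift(metal, "monoisotopic") else 0

  with_seed(config$seed + 2L, {
    sites <- seq_len(L - 1)
    w <- rep(1, L - 1)
    w[aa[sites] == "D"] <- config$asp_cleavage_bias
    n <- max(1L, round(config$fragment_coverage * (L - 1)))
    picked <- sort(sample(sites, n, prob = w))

    rows <- list(); envs <- list()
    for (s in picked) {
      for (ser in c("b", "y")) {
        idx <- if (ser == "b") s else L - s
        base <- if (ser == "b") bm[idx] else ym[idx]
        covers <- !is.null(metal_site) &&
          (if (ser == "b") idx >= metal_site else idx >= L - metal_site + 1)
        bound <- covers && !is.null(metal) &&
          stats::runif(1) <= config$metal_retention_prob
        m <- base + if (bound) metal_mono else 0
        if (config$fragment_ppm_sd > 0) {
          m <- m * (1 + stats::rnorm(1, 0, config$fragment_ppm_sd * 1e-6))
        }
        rows[[length(rows) + 1]] <- data.frame(series = ser, index = idx,
                                               neutral_mass = m,
                                               metal_bound = bound)
        want_env <- identical(render_envelopes, "all") ||
          (is.numeric(render_envelopes) && ser == "b" && idx %in% render_envelopes)
        if (want_env) {
          f <- fragment_formula(p, ser, idx,
                                adduct = if (bound) list(spec = metal, count = 1))
          env <- render_envelope(f, total_intensity = 100)
          if (config$envelope_noise_sd > 0) {
            env$intensity <- env$intensity *
              exp(stats::rnorm(nrow(env), 0, config$envelope_noise_sd))
          }
          envs[[paste0(ser, idx)]] <- env
        }
      }
    }
    masses <- do.call(rbind, rows)
    rownames(masses) <- NULL
    list(masses = masses, envelopes = envs,
         truth = list(metal_site = metal_site, sites = picked))
  })
}

#' Random protein-like test sequence
#'
#' Draws residues from typical protein composition frequencies, then places
#' a His-x-His motif at `his_pair_at` (a plausible metal-coordination
#' signature) and ensures Asp content for cleavage-bias modeling. Sequences
#' made this way are synthetic stand-ins with realistic length and
#' composition, not any organism's true sequence.
#'
#' @param n_res Number of residues.
#' @param seed Integer seed.
#' @param his_pair_at Optional residue index i placing H at i and i+2.
#' @return A residue string.
#' @export
make_test_sequence <- function(n_res, seed, his_pair_at = NULL) {
  aa <- c(A = 8.3, R = 5.6, N = 4.1, D = 5.5, C = 1.4, E = 6.6, Q = 4.0,
          G = 7.2, H = 2.2, I = 5.6, L = 9.7, K = 5.9, M = 2.4, F = 3.9,
          P = 4.6, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  with_seed(seed, {
    s <- sample(names(aa), n_res, replace = TRUE, prob = aa)
    if (!is.null(his_pair_at)) {
      stopifnot(his_pair_at >= 1, his_pair_at + 2 <= n_res)
      s[his_pair_at] <- "H"; s[his_pair_at + 2] <- "H"
      s[his_pair_at - 1] <- "W"  # aromatic anchor just upstream of the motif
    }
    paste(s, collapse = "")
  })
}

#' Packaged pMMO-like three-subunit scenario
#'
#' The default end-to-end test scenario: a three-subunit ~100 kDa complex
#' with two ~28 kDa subunits (A and C) and one ~42 kDa subunit (B). Subunit
#' B carries one fully occupied Cu(II) site at a His-x-His motif; subunit C
#' carries a partially occupied Cu(II) site (16% bound). Sequences are
#' synthetic (see [make_test_sequence()]). The returned ground truth plays
#' the role of a sidecar the pipeline report is checked against.
#'
#' @param seed Integer seed controlling the synthetic sequences.
#' @return A list with `subunits` (named list of [proteoform()]s), `metal`
#'   (the Cu(II) [metal_adduct()]), and `truth` (subunit average masses,
#'   metal counts, metal sites, bound fractions).
#' @export
pmmo_like_scenario <- function(seed = 20L) {
  cu2 <- metal_adduct("Cu(II)", "Cu1", 2)
  seqA <- make_test_sequence(255, seed + 1L)
  seqB <- make_test_sequence(380, seed + 2L, his_pair_at = 137)
  seqC <- make_test_sequence(256, seed + 3L, his_pair_at = 130)
  subA <- proteoform("subA", seqA)
  subB <- proteoform("subB", seqB, adducts = list(list(spec = cu2, count = 1)))
  subC <- proteoform("subC", seqC)
  truth <- list(
    masses = c(subA = proteoform_mass(subA),
               subB_apo = proteoform_mass(proteoform("subB", seqB)),
               subB = proteoform_mass(subB),
               subC = proteoform_mass(subC)),
    metal_count = c(subA = 0L, subB = 1L, subC = 1L),
    metal_site = c(subB = 137L, subC = 130L),
    bound_fraction = c(subA = 0, subB = 1, subC = 0.16))
  list(subunits = list(subA = subA, subB = subB, subC = subC),
       metal = cu2, truth = truth)
}
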