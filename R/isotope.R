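# Aggregated (nucleon-count) isotope distributions and envelope-fit scoring.
#
# Distributions are computed by iterated convolution of per-element isotope
# patterns with binary exponentiation over atom counts. Aggregation is by
# nucleon count, which is sufficient for envelope fitting at the resolving
# powers of intact-protein and large-fragment work; isotopic fine structure
# is out of scope.

# one-element distribution as list(n0 = first nucleon count, ab, m)
iso_element <- function(element) {
  iso <- mass_tables()$isotopes
  d <- iso[iso$element == element, ]
  if (!nrow(d)) {
    stop("no isotope data for element '", element, "'", call. = FALSE)
  }
  d <- d[order(d$nucleons), ]
  n <- d$nucleons[1]:d$nucleons[nrow(d)]
  ab <- numeric(length(n)); m <- numeric(length(n))
  idx <- d$nucleons - d$nucleons[1] + 1L
  ab[idx] <- d$abundance / sum(d$abundance)
  m[idx] <- d$mass
  list(n0 = d$nucleons[1], ab = ab, m = m)
}

# convolution of two aggregated distributions; bins with negligible
# abundance are dropped to keep widths bounded during exponentiation
iso_conv <- function(a, b, work_prune = 1e-12) {
  la <- length(a$ab); lb <- length(b$ab)
  ab <- numeric(la + lb - 1L)
  mw <- numeric(la + lb - 1L)
  for (j in seq_len(lb)) {
    if (b$ab[j] == 0) next
    rng <- j:(j + la - 1L)
    w <- a$ab * b$ab[j]
    ab[rng] <- ab[rng] + w
    mw[rng] <- mw[rng] + w * (a$m + b$m[j])
  }
  m <- ifelse(ab > 0, mw / ab, 0)
  keep <- ab > work_prune * max(ab)
  first <- which(keep)[1]; last <- max(which(keep))
  list(n0 = a$n0 + b$n0 + first - 1L,
       ab = ab[first:last], m = m[first:last])
}

iso_power <- function(base, n) {
  out <- NULL
  sq <- base
  while (n > 0) {
    if (n %% 2 == 1) out <- if (is.null(out)) sq else iso_conv(out, sq)
    n <- n %/% 2
    if (n > 0) sq <- iso_conv(sq, sq)
  }
  out
}

#' Aggregated isotope distribution of a formula
#'
#' Computes the isotopologue distribution of a chemical formula aggregated
#' by nucleon count. Peaks below `prune` times the most abundant peak are
#' removed and the distribution renormalized (the default 1e-4 mirrors the
#' pruning limit commonly used by Mercury-style calculators in top-down
#' validation software).
#'
#' @param formula Formula-like object with non-negative counts.
#' @param prune Relative-abundance pruning threshold in `[0, 0.01]`.
#' @return A data.frame of class `isotope_distribution` with columns `mass`
#'   (Da, strictly increasing) and `abundance` (fractions summing to 1).
#' @examples
#' isotope_distribution("C100")
#' @export
isotope_distribution <- function(formula, prune = 1e-4) {
  if (prune < 0 || prune > 0.01) stop("prune must be in [0, 0.01]", call. = FALSE)
  f <- as_formula(formula)
  if (any(unclass(f) < 0)) {
    stop("isotope distributions require non-negative counts", call. = FALSE)
  }
  if (!length(f)) {
    out <- data.frame(mass = 0, abundance = 1)
    class(out) <- c("isotope_distribution", "data.frame")
    return(out)
  }
  dist <- NULL
  for (el in names(f)) {
    p <- iso_power(iso_element(el), unclass(f)[[el]])
    dist <- if (is.null(dist)) p else iso_conv(dist, p)
  }
  keep <- dist$ab >= prune * max(dist$ab)
  ab <- dist$ab[keep] / sum(dist$ab[keep])
  out <- data.frame(mass = dist$m[keep], abundance = ab)
  out <- out[order(out$mass), ]
  rownames(out) <- NULL
  class(out) <- c("isotope_distribution", "data.frame")
  out
}

#' Averagine composition for a target average mass
#'
#' Scales the standard averagine residue composition
#' (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417, 111.1254 Da) to a target
#' average mass, rounding C/N/O/S counts and choosing the hydrogen count
#' that brings the formula mass closest to the target. Used to model the
#' isotope envelope of a species known only by mass.
#'
#' @param average_mass Target average mass in Da (`>= 0`).
#' @return A [chem_formula] (empty for mass 0).
#' @export
averagine_formula <- function(average_mass) {
  if (average_mass < 0) stop("average_mass must be >= 0", call. = FALSE)
  if (average_mass == 0) return(chem_formula())
  unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
  k <- average_mass / 111.1254
  counts <- round(unit[c("C", "N", "O", "S")] * k)
  heavy <- formula_mass(chem_formula(stats::setNames(as.integer(counts),
                                                     names(counts))), "average")
  h <- max(0L, round((average_mass - heavy) / hydrogen_mass("average")))
  chem_formula(c(counts, H = h))
}

#' Envelope fit score between a theoretical distribution and observed peaks
#'
#' Aligns each theoretical isotope peak to the nearest observed peak within
#' `tol` and scores the agreement of the intensity pattern as a centered
#' cosine (Pearson correlation clamped to `[0, 1]`; plain cosine when fewer
#' than three peaks align). The score is invariant to overall intensity
#' scaling, 1 for an exactly rendered envelope, and low for flat noise.
#'
#' @param theoretical An [isotope_distribution()].
#' @param observed A data.frame with columns `mass` (or `mz`) and `intensity`,
#'   e.g. a spectrum slice around the candidate fragment.
#' @param tol Alignment window in Da (default 0.35, a typical cluster
#'   tolerance for isotopically resolved top-down data).
#' @return Score in `[0, 1]`, or `NA` when no observed peak falls within
#'   `tol` of any theoretical peak (no-fit sentinel).
#' @export
envelope_fit_score <- function(theoretical, observed, tol = 0.35) {
  mcol <- if ("mass" %in% names(observed)) "mass" else "mz"
  if (!nrow(observed)) return(NA_real_)
  obs_int <- vapply(theoretical$mass, function(m) {
    d <- abs(observed[[mcol]] - m)
    i <- which.min(d)
    if (length(i) && d[i] <= tol) observed$intensity[i] else 0
  }, numeric(1))
  if (all(obs_int == 0)) return(NA_real_)
  t <- theoretical$abundance
  if (length(t) < 3) {
    s <- sum(t * obs_int) / sqrt(sum(t^2) * sum(obs_int^2))
  } else {
    s <- suppressWarnings(stats::cor(t, obs_int))
    if (is.na(s)) s <- 0
  }
  max(0, min(1, s))
}

#' Render a theoretical isotope envelope as a peak list
#'
#' Convenience wrapper used by the synthetic-data generator and tests:
#' computes the isotope distribution of a formula and returns it as
#' mass/intensity peaks scaled to a total intensity.
#'
#' @param formula Formula-like object.
#' @param total_intensity Total intensity over the envelope.
#' @param prune Pruning threshold passed to [isotope_distribution()].
#' @return data.frame with columns `mass`, `intensity`.
#' @export
render_envelope <- function(formula, total_intensity = 100, prune = 1e-4) {
  d <- isotope_distribution(formula, prune)
  data.frame(mass = d$mass, intensity = d$abundance * total_intensity)
}
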