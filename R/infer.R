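# Metal-site interval localization, proteoform occupancy, and MS1/MS2
# mass-balance accounting.

#' Localize a metal adduct from apo/metal-bound fragment calls
#'
#' Each called fragment constrains the metal site s (fragment-map
#' coordinates, 1-based): a metal-bound b_i implies s in \[1, i\]; an apo
#' b_j implies s in \[j+1, L\]; a metal-bound y_k implies s in \[L-k+1, L\];
#' an apo y_m implies s in \[1, L-m\]. The returned interval is the
#' intersection of all constraints; when the constraints conflict the
#' interval is empty and `consistent` is `FALSE`. Ambiguous calls carry no
#' constraint.
#'
#' By default apo fragments are hard exclusion constraints, mirroring how an
#' apo prefix fragment bounds a binding region from the left. An apo
#' fragment that strictly contains a shorter metal-bound fragment of the
#' same series contradicts direct evidence and is attributed to gas-phase
#' metal loss instead of excluding the region. Because such loss can in
#' principle make any apo observation a false exclusion,
#' `apo_constraints = "soft"` downgrades all apo fragments to
#' recorded-but-unused evidence.
#'
#' @param calls A [detect_metal_fragments()] table (or any data.frame with
#'   `series`, `index`, `call`).
#' @param L Sequence length in fragment-map numbering.
#' @param apo_constraints `"hard"` (default) or `"soft"`.
#' @param offset Offset mapping fragment-map residue 1 back to the
#'   unprocessed translation (a proteoform's `n_term_start - 1`).
#' @return A list of class `localization_interval`: `start`, `end`
#'   (inclusive, map numbering), `consistent`, `localized`, `n_metal`,
#'   `n_apo`, `offset`, and `start_unprocessed`/`end_unprocessed`. When no
#'   metal-bound fragment exists, `localized` is `FALSE` and the bounds are
#'   `NA` (no-localization sentinel, not an error).
#' @export
localize_adduct <- function(calls, L, apo_constraints = c("hard", "soft"),
                            offset = 0L) {
  apo_constraints <- match.arg(apo_constraints)
  metal <- calls[calls$call == "metal-bound", ]
  apo <- calls[calls$call == "apo", ]
  out <- list(start = NA_integer_, end = NA_integer_, consistent = NA,
              localized = FALSE, n_metal = nrow(metal), n_apo = nrow(apo),
              offset = as.integer(offset),
              start_unprocessed = NA_integer_, end_unprocessed = NA_integer_)
  class(out) <- "localization_interval"
  if (!nrow(metal)) return(out)
  lo <- 1L; hi <- as.integer(L)
  for (k in seq_len(nrow(metal))) {
    if (metal$series[k] == "b") hi <- min(hi, metal$index[k])
    else lo <- max(lo, L - metal$index[k] + 1L)
  }
  if (apo_constraints == "hard") {
    # an apo fragment strictly containing a shorter metal-bound fragment of
    # the same series is evidence of gas-phase metal loss, not exclusion
    min_metal_b <- suppressWarnings(min(metal$index[metal$series == "b"]))
    min_metal_y <- suppressWarnings(min(metal$index[metal$series == "y"]))
    for (k in seq_len(nrow(apo))) {
      if (apo$series[k] == "b") {
        if (apo$index[k] > min_metal_b) next
        lo <- max(lo, apo$index[k] + 1L)
      } else {
        if (apo$index[k] > min_metal_y) next
        hi <- min(hi, L - apo$index[k])
      }
    }
  }
  out$localized <- TRUE
  out$consistent <- lo <= hi
  if (out$consistent) {
    out$start <- as.integer(lo); out$end <- as.integer(hi)
    out$start_unprocessed <- out$start + out$offset
    out$end_unprocessed <- out$end + out$offset
  }
  out
}

#' @export
print.localization_interval <- function(x, ...) {
  if (!x$localized) {
    cat("<no metal-bound fragments: site not localized>\n")
  } else if (!x$consistent) {
    cat("<conflicting fragment constraints: empty interval>\n")
  } else {
    cat(sprintf("<metal site within [%d, %d] (%d metal-bound, %d apo fragments)>\n",
                x$start, x$end, x$n_metal, x$n_apo))
  }
  invisible(x)
}

#' Proteoform occupancy fractions from deconvolved species intensities
#'
#' Fractions of summed species intensity per group (e.g. apo vs one metal),
#' optionally computed within levels of a second key (e.g. per subunit).
#' With two or more replicate species tables, the reported fraction is the
#' mean across replicates and `sd` its standard deviation. Assumes equal
#' ionization response across proteoforms of one subunit.
#'
#' @param species A [deconvolute()] table (needs `total_intensity`), or a
#'   list of such tables (replicates). Must carry the grouping columns.
#' @param group Name of the grouping column (e.g. `"bound"`).
#' @param within Optional name of an outer grouping column (e.g.
#'   `"subunit"`); fractions then sum to 1 within each level.
#' @return data.frame of class `occupancy_result`: optional `within` column,
#'   `group`, `fraction`, `sd` (`NA` without replicates), `n_replicates`.
#' @export
occupancy_fractions <- function(species, group = "group", within = NULL) {
  reps <- if (is.data.frame(species)) list(species) else species
  one <- function(df) {
    if (!nrow(df) || sum(df$total_intensity) <= 0) {
      stop("species table has zero total intensity", call. = FALSE)
    }
    key <- if (is.null(within)) df[[group]] else
      interaction(df[[within]], df[[group]], drop = TRUE, sep = "\r")
    tot <- tapply(df$total_intensity, key, sum)
    denom <- if (is.null(within)) sum(df$total_intensity) else {
      wtot <- tapply(df$total_intensity, df[[within]], sum)
      wtot[vapply(strsplit(names(tot), "\r"), `[`, character(1), 1)]
    }
    stats::setNames(as.numeric(tot / denom), names(tot))
  }
  fr <- lapply(reps, one)
  keys <- unique(unlist(lapply(fr, names)))
  mat <- vapply(fr, function(f) {
    v <- f[keys]; v[is.na(v)] <- 0; v
  }, numeric(length(keys)))
  mat <- matrix(mat, nrow = length(keys), dimnames = list(keys, NULL))
  out <- data.frame(group = keys,
                    fraction = rowMeans(mat),
                    sd = if (ncol(mat) > 1) apply(mat, 1, stats::sd) else NA_real_,
                    n_replicates = ncol(mat))
  if (!is.null(within)) {
    parts <- strsplit(out$group, "\r")
    out <- data.frame(within = vapply(parts, `[`, character(1), 1),
                      group = vapply(parts, `[`, character(1), 2),
                      fraction = out$fraction, sd = out$sd,
                      n_replicates = out$n_replicates)
    names(out)[1] <- within
  }
  rownames(out) <- NULL
  class(out) <- c("occupancy_result", "data.frame")
  out
}

#' MS1/MS2 mass balance with ranked explanations of the residual
#'
#' The residual is the intact-complex mass minus the sum of the component
#' masses; a positive residual indicates mass lost upon subunit ejection
#' (for example a metal ion shed in the gas phase). The residual is handed
#' to [explain_delta()] for ranked catalog explanations.
#'
#' @param complex_mass Intact-complex neutral average mass (Da).
#' @param component_masses Non-empty numeric vector of component masses (Da).
#' @param catalog,tol,k_max Passed to [explain_delta()].
#' @return A list of class `mass_balance`: `residual` (Da) and
#'   `explanations` (a [explain_delta()] table).
#' @export
mass_balance <- function(complex_mass, component_masses,
                         catalog = read_catalog(), tol = 1.5, k_max = 2) {
  if (!length(component_masses)) {
    stop("component_masses must be non-empty", call. = FALSE)
  }
  residual <- complex_mass - sum(component_masses)
  out <- list(residual = residual,
              explanations = explain_delta(residual, catalog = catalog,
                                           k_max = k_max, tol = tol))
  class(out) <- "mass_balance"
  out
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("<mass balance: residual %.1f Da, %d explanation(s)>\n",
              x$residual, nrow(x$explanations)))
  if (nrow(x$explanations)) {
    print(utils::head(as.data.frame(x$explanations), 5))
  }
  invisible(x)
}
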