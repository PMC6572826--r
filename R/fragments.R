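# Theoretical b/y fragments, ppm matching, fragment maps, Poisson p-score
# and isotopic-fit detection of metal-bound fragments.
#
# All fragment work is monoisotopic (MS3 spectra are isotopically resolved);
# observed fragment masses are assumed already deisotoped to neutral
# monoisotopic values.

# monoisotopic shift of a positioned/terminal modification entry
mod_mono_shift <- function(spec) entry_shift(spec, "monoisotopic")

# does a modification placement apply to fragment (series, index) of length-L?
mod_in_fragment <- function(m, series, index, L) {
  pos <- m$position
  term <- if (!is.null(m$spec$terminal_specificity)) m$spec$terminal_specificity else "none"
  if (is.null(pos) || all(is.na(pos))) {
    # unpositioned: apply by terminal specificity; strict mode drops
    # unpositioned, non-terminal ("floating") modifications entirely
    if (identical(term, "N-term")) return(series == "b")
    if (identical(term, "C-term")) return(series == "y")
    return(FALSE)
  }
  if (length(pos) == 2) {  # region-ambiguous: only fragments spanning the region
    if (series == "b") return(pos[2] <= index)
    return(pos[1] >= L - index + 1)
  }
  if (series == "b") pos <= index else pos >= L - index + 1
}

#' Generate theoretical b/y fragment ions
#'
#' Generates all b and/or y fragments of a proteoform at indices
#' `1..L-1`, each without adduct and, for every adduct hypothesis supplied,
#' with that adduct. Positioned modifications are included only in fragments
#' spanning their site; region-ambiguous modifications only in fragments
#' fully containing their region (a floating modification with no region is
#' excluded from all fragments rather than silently mislocalized). The
#' proteoform's own intact-level adducts are not baked into fragment masses;
#' metal retention on fragments is exactly what the adduct hypotheses probe.
#'
#' @param p A [proteoform()] with at least 2 residues.
#' @param series Character subset of `c("b", "y")`.
#' @param adducts List of adduct hypotheses, each a list with `spec` (a
#'   [metal_adduct()] or adduct catalog row) and `count >= 1`.
#' @return data.frame of class `fragment_ions`: `series`, `index`, `adduct`
#'   (`""` for apo), `neutral_mass` (monoisotopic Da).
#' @export
generate_fragments <- function(p, series = c("b", "y"), adducts = list()) {
  L <- nchar(p$sequence)
  if (L < 2) stop("proteoform must have at least 2 residues", call. = FALSE)
  for (a in adducts) {
    if (is.null(a$count) || a$count < 0) {
      stop("adduct hypothesis count must be non-negative", call. = FALSE)
    }
  }
  residues <- mass_tables()$residues
  aa <- strsplit(p$sequence, "")[[1]]
  res_mono <- vapply(residues, formula_mass, numeric(1), scale = "monoisotopic")
  masses <- res_mono[aa]
  prefix <- cumsum(masses)           # b backbone: residues 1..i
  water <- formula_mass(WATER, "monoisotopic")
  suffix <- rev(cumsum(rev(masses))) # residues i..L

  rows <- list()
  for (s in intersect(c("b", "y"), series)) {
    idx <- seq_len(L - 1)
    base <- if (s == "b") prefix[idx] else suffix[L - idx + 1] + water
    modshift <- vapply(idx, function(i) {
      sh <- 0
      for (m in p$modifications) {
        if (mod_in_fragment(m, s, i, L)) sh <- sh + mod_mono_shift(m$spec)
      }
      sh
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(series = s, index = idx, adduct = "",
                                           neutral_mass = base + modshift)
    for (a in adducts) {
      sh <- a$count * entry_shift(a$spec, "monoisotopic")
      nm <- if (is.data.frame(a$spec)) a$spec$name else a$spec$name
      rows[[length(rows) + 1]] <- data.frame(series = s, index = idx,
                                             adduct = nm,
                                             neutral_mass = base + modshift + sh)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fragment_ions", "data.frame")
  out
}

#' Elemental composition of one fragment
#'
#' Composition of a b or y fragment including modifications it spans
#' (see [generate_fragments()]); used to compute theoretical isotope
#' envelopes for metal-call validation.
#'
#' @inheritParams generate_fragments
#' @param series `"b"` or `"y"`.
#' @param index Fragment index (residues from the terminus).
#' @param adduct Optional adduct placement (`list(spec=, count=)`) whose net
#'   composition (cation minus displaced protons) is added.
#' @return A [chem_formula].
#' @export
fragment_formula <- function(p, series, index, adduct = NULL) {
  L <- nchar(p$sequence)
  stopifnot(index >= 1, index <= L - 1)
  residues <- mass_tables()$residues
  aa <- strsplit(p$sequence, "")[[1]]
  span <- if (series == "b") seq_len(index) else (L - index + 1):L
  f <- chem_formula()
  counts <- table(aa[span])
  for (r in names(counts)) f <- formula_add(f, formula_scale(residues[[r]], counts[[r]]))
  if (series == "y") f <- formula_add(f, WATER)
  for (m in p$modifications) {
    if (mod_in_fragment(m, series, index, L)) {
      net <- formula_subtract(as_formula(m$spec$delta_formula),
                              chem_formula(c(H = as.integer(
                                if (is.null(m$spec$protons_displaced) ||
                                    is.na(m$spec$protons_displaced)) 0
                                else m$spec$protons_displaced))))
      f <- formula_add(f, net)
    }
  }
  if (!is.null(adduct)) {
    net <- formula_subtract(as_formula(adduct$spec$delta_formula),
                            chem_formula(c(H = adduct$spec$protons_displaced)))
    f <- formula_add(f, formula_scale(net, adduct$count))
  }
  f
}

#' Match observed fragment masses to theoretical fragments
#'
#' One-to-one greedy matching by smallest absolute ppm error: each observed
#' neutral monoisotopic mass matches at most one theoretical fragment and
#' vice versa, within `tol_ppm`. Unmatched masses are reported separately,
#' never an error.
#'
#' @param theoretical A [generate_fragments()] table.
#' @param observed Numeric vector of neutral monoisotopic masses (Da).
#' @param tol_ppm Fragmentation tolerance in ppm (`> 0`; default 25).
#' @param L Sequence length used for the fragment map; defaults to
#'   `max(index) + 1` of the theoretical table.
#' @return A list: `matches` (data.frame `series`, `index`, `adduct`,
#'   `theoretical_mass`, `observed_mass`, `ppm_error`, and `ppm_margin`,
#'   the ppm distance from the observed mass to the nearest competing
#'   theoretical fragment), `unmatched` (observed masses), `map` (see
#'   [fragment_map()]) and `coverage`.
#' @export
match_fragments <- function(theoretical, observed, tol_ppm = 25, L = NULL) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive", call. = FALSE)
  if (is.null(L)) L <- max(theoretical$index) + 1L
  nt <- nrow(theoretical); no <- length(observed)
  matches <- data.frame(series = character(0), index = integer(0),
                        adduct = character(0), theoretical_mass = numeric(0),
                        observed_mass = numeric(0), ppm_error = numeric(0),
                        ppm_margin = numeric(0))
  if (nt && no) {
    ppm <- outer(observed, theoretical$neutral_mass,
                 function(o, t) (o - t) / t * 1e6)
    cand <- which(abs(ppm) <= tol_ppm, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(abs(ppm[cand])), , drop = FALSE]
      used_o <- logical(no); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_o[i] && !used_t[j]) {
          used_o[i] <- TRUE; used_t[j] <- TRUE; keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      # margin to the nearest competing theoretical fragment: a small margin
      # means the observed mass cannot discriminate between two hypotheses
      margin <- vapply(seq_len(nrow(cand)), function(k) {
        d <- abs(ppm[cand[k, 1], ])
        d[cand[k, 2]] <- Inf
        min(d)
      }, numeric(1))
      matches <- data.frame(series = theoretical$series[cand[, 2]],
                            index = theoretical$index[cand[, 2]],
                            adduct = theoretical$adduct[cand[, 2]],
                            theoretical_mass = theoretical$neutral_mass[cand[, 2]],
                            observed_mass = observed[cand[, 1]],
                            ppm_error = ppm[cand],
                            ppm_margin = margin)
      matches <- matches[order(matches$series, matches$index), ]
      rownames(matches) <- NULL
    }
  }
  map <- fragment_map(matches, L)
  list(matches = matches,
       unmatched = setdiff(observed, matches$observed_mass),
       map = map, coverage = attr(map, "coverage"))
}

#' Per-cleavage-site fragment map
#'
#' Flags each backbone cleavage site `1..L-1` as b-supported and/or
#' y-supported by the matched fragments (b_i supports site i; y_j supports
#' site L-j). Coverage is the fraction of the `L-1` sites supported by
#' either series.
#'
#' @param matches The `matches` table from [match_fragments()].
#' @param L Sequence length.
#' @return data.frame of class `fragment_map` (`site`, `b_supported`,
#'   `y_supported`) with attribute `coverage`.
#' @export
fragment_map <- function(matches, L) {
  site <- seq_len(L - 1)
  b_sites <- matches$index[matches$series == "b"]
  y_sites <- L - matches$index[matches$series == "y"]
  out <- data.frame(site = site,
                    b_supported = site %in% b_sites,
                    y_supported = site %in% y_sites)
  attr(out, "coverage") <- mean(out$b_supported | out$y_supported)
  class(out) <- c("fragment_map", "data.frame")
  out
}

#' Write a fragment map as per-site TSV
#'
#' @param map A [fragment_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plain-text flag diagram of a fragment map
#'
#' One character per cleavage site: `|` both series, `b`/`y` one series,
#' `.` unsupported; wrapped at `width` sites per line.
#'
#' @param map A [fragment_map()].
#' @param width Sites per line.
#' @return Character vector of lines.
#' @export
fragment_map_text <- function(map, width = 60) {
  ch <- ifelse(map$b_supported & map$y_supported, "|",
               ifelse(map$b_supported, "b", ifelse(map$y_supported, "y", ".")))
  starts <- seq(1, length(ch), by = width)
  vapply(starts, function(s) {
    e <- min(s + width - 1, length(ch))
    sprintf("%5d %s", s, paste(ch[s:e], collapse = ""))
  }, character(1))
}

#' Poisson p-score for a fragment-matching result
#'
#' Significance of observing `n_matched` of `n_observed` masses within
#' tolerance of `n_theoretical` fragments by chance. The expected number of
#' random hits is
#' `lambda = n_observed * (n_theoretical * 2 * tol_da) / mass_span`, where
#' `tol_da = tol_ppm * 1e-6 * mean_fragment_mass` is the mean absolute
#' tolerance half-window in Da, and the p-score is the Poisson tail
#' `P(X >= n_matched)`. Strictly decreasing in `n_matched`; 1 when nothing
#' matched.
#'
#' @param n_matched,n_observed,n_theoretical Counts
#'   (`0 <= n_matched <= n_observed`).
#' @param tol_ppm Matching tolerance in ppm.
#' @param mean_fragment_mass Mean theoretical fragment mass in Da.
#' @param mass_span Span of the observed masses in Da (`> 0`).
#' @return Tail probability in `(0, 1]`.
#' @export
fragment_pscore <- function(n_matched, n_observed, n_theoretical, tol_ppm,
                            mean_fragment_mass, mass_span) {
  if (mass_span <= 0) stop("mass_span must be positive", call. = FALSE)
  if (n_matched < 0 || n_matched > n_observed) {
    stop("need 0 <= n_matched <= n_observed", call. = FALSE)
  }
  tol_da <- tol_ppm * 1e-6 * mean_fragment_mass
  lambda <- n_observed * (n_theoretical * 2 * tol_da) / mass_span
  if (n_matched == 0) return(1)
  stats::ppois(n_matched - 1, lambda, lower.tail = FALSE)
}

#' Classify matched fragments as apo or metal-bound
#'
#' A fragment is called metal-bound when its metal-adduct hypothesis matched
#' within tolerance and (when an observed envelope is available) the
#' envelope fit against the metal-containing theoretical isotope
#' distribution reaches `fit_threshold`; apo analogously. Fragments whose
#' mass supports both hypotheses, or whose mass matched but whose envelope
#' failed validation, are flagged ambiguous rather than called.
#'
#' @param matches `matches` table from [match_fragments()] computed against
#'   both apo and metal-adduct hypotheses.
#' @param metal Name of the metal adduct as it appears in the `adduct`
#'   column, or a [metal_adduct()] (its `name` is used).
#' @param proteoform The [proteoform()] the fragments derive from; required
#'   for envelope validation.
#' @param envelopes Optional named list of observed envelope slices
#'   (data.frames with `mass`, `intensity`), keyed `"b165"` style. When
#'   `NULL`, calls rest on mass alone and `envelope_score` is `NA`.
#' @param metal_spec The [metal_adduct()] used to build metal-bound
#'   theoretical envelopes (defaults to Cu(II)-style lookup in the packaged
#'   catalog by `metal` name).
#' @param fit_threshold Minimum envelope fit score (default 0.8).
#' @param tol Envelope alignment window in Da.
#' @param prune Isotope-distribution pruning threshold.
#' @param margin_ppm Matches whose ppm margin to the nearest competing
#'   theoretical fragment (see [match_fragments()]) is below this are
#'   flagged ambiguous: their observed mass cannot discriminate between two
#'   fragment hypotheses, so they must not drive a metal call.
#' @return data.frame of class `metal_calls`: `series`, `index`, `call`
#'   (`"apo"`, `"metal-bound"`, `"ambiguous"`), `envelope_score`.
#' @export
detect_metal_fragments <- function(matches, metal, proteoform = NULL,
                                   envelopes = NULL, metal_spec = NULL,
                                   fit_threshold = 0.8, tol = 0.35,
                                   prune = 1e-4, margin_ppm = 5) {
  metal_name <- if (is.list(metal) && !is.null(metal$name)) metal$name else metal
  if (is.null(metal_spec)) {
    metal_spec <- tryCatch(catalog_entry(read_catalog(), metal_name),
                           error = function(e) NULL)
  }
  keys <- unique(matches[, c("series", "index")])
  if (!nrow(keys)) {
    out <- data.frame(series = character(0), index = integer(0),
                      call = character(0), envelope_score = numeric(0))
    class(out) <- c("metal_calls", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    s <- keys$series[k]; i <- keys$index[k]
    sub <- matches[matches$series == s & matches$index == i, ]
    apo_mass <- any(sub$adduct == "")
    metal_mass <- any(sub$adduct == metal_name)
    poor_margin <- !is.null(sub$ppm_margin) && any(sub$ppm_margin < margin_ppm)
    score <- NA_real_
    env <- envelopes[[paste0(s, i)]]
    if (!is.null(env) && !is.null(proteoform) && !is.null(metal_spec)) {
      hyp_adduct <- if (metal_mass) list(spec = metal_spec, count = 1) else NULL
      theo <- isotope_distribution(
        fragment_formula(proteoform, s, i, adduct = hyp_adduct), prune)
      score <- envelope_fit_score(theo, env, tol)
    }
    env_checked <- !is.na(score)
    call <- if (poor_margin && !(env_checked && score >= fit_threshold)) {
      "ambiguous"
    } else if (metal_mass && apo_mass) {
      "ambiguous"
    } else if (metal_mass) {
      if (env_checked && score < fit_threshold) "ambiguous" else "metal-bound"
    } else {
      if (env_checked && score < fit_threshold) "ambiguous" else "apo"
    }
    data.frame(series = s, index = i, call = call, envelope_score = score)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$series, out$index), ]
  rownames(out) <- NULL
  class(out) <- c("metal_calls", "data.frame")
  out
}
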