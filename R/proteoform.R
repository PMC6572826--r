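# Modification/adduct catalog and proteoform mass bookkeeping.

#' Read a modification/adduct catalog
#'
#' Reads a UNIMOD-style catalog as tab-separated text with columns
#' `name`, `delta_formula` (Hill notation, signed counts), `terminal_specificity`
#' (`none`, `N-term`, `C-term`), `residue_specificity` (single residue letter
#' or `.`), `category` (`PTM`, `truncation`, `processing`, `adduct`) and
#' `protons_displaced`. For adducts `delta_formula` is the bare cation
#' composition and the net neutral shift is
#' `mass(delta_formula) - protons_displaced * mass(H)`.
#'
#' @param path Path to a catalog TSV; `NULL` (default) loads the packaged
#'   catalog (N-terminal acetylation, initiator-Met removal, methylation,
#'   Cu(II), Zn(II), ammonium and sodium adducts).
#' @return A data.frame of class `ntdms_catalog` with an extra numeric column
#'   `net_average` (net neutral average-mass shift per entry).
#' @export
read_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modification_catalog.tsv",
                        package = "ntdms", mustWork = TRUE)
  }
  cat <- utils::read.delim(path, comment.char = "#")
  need <- c("name", "delta_formula", "terminal_specificity",
            "residue_specificity", "category", "protons_displaced")
  miss <- setdiff(need, names(cat))
  if (length(miss)) {
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(cat$protons_displaced < 0)) {
    stop("protons_displaced must be non-negative", call. = FALSE)
  }
  # validates every formula against the packaged element table
  cat$net_average <- vapply(seq_len(nrow(cat)), function(i)
    entry_shift(cat[i, ], "average"), numeric(1))
  class(cat) <- c("ntdms_catalog", "data.frame")
  cat
}

#' Net mass shift of a catalog entry
#'
#' The neutral-mass shift contributed by one catalog entry:
#' `mass(delta_formula) - protons_displaced * mass(H)` on the requested scale.
#' Charge-neutral metal binding displaces as many protons as the cation
#' charge, e.g. Cu(II) replaces two protons for a net average shift of
#' +61.5 Da.
#'
#' @param entry One catalog row (data.frame with one row) or a list with
#'   fields `delta_formula` and `protons_displaced`.
#' @param scale `"average"` or `"monoisotopic"`.
#' @return Signed mass shift in Da.
#' @export
entry_shift <- function(entry, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  pd <- entry$protons_displaced
  if (is.null(pd) || is.na(pd)) pd <- 0
  formula_mass(as_formula(entry$delta_formula), scale) - pd * hydrogen_mass(scale)
}

#' Construct a metal/cation adduct specification
#'
#' @param name Display name, e.g. `"Cu(II)"`.
#' @param cation_formula Composition of the bare cation, e.g. `"Cu1"`.
#' @param protons_displaced Number of protons the cation replaces (equal to
#'   the cation charge for charge-neutral binding). Must be `>= 0`.
#' @return A list of class `metal_adduct` usable wherever a catalog entry is.
#' @examples
#' cu2 <- metal_adduct("Cu(II)", "Cu1", 2)
#' adduct_shift(cu2)  # +61.53 Da
#' @export
metal_adduct <- function(name, cation_formula, protons_displaced) {
  if (protons_displaced < 0) {
    stop("protons_displaced must be non-negative", call. = FALSE)
  }
  structure(list(name = name,
                 delta_formula = as_formula(cation_formula),
                 category = "adduct",
                 protons_displaced = as.integer(protons_displaced)),
            class = "metal_adduct")
}

#' Net neutral-mass shift of a metal/cation adduct
#'
#' @param adduct A [metal_adduct()] or catalog row.
#' @inheritParams entry_shift
#' @return Signed shift in Da: `mass(cation) - protons_displaced * mass(H)`.
#' @export
adduct_shift <- function(adduct, scale = c("average", "monoisotopic")) {
  entry_shift(adduct, scale)
}

#' Look up a catalog entry by name
#'
#' @param catalog An [read_catalog()] data.frame.
#' @param name Entry name.
#' @return The matching one-row data.frame.
#' @export
catalog_entry <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("no catalog entry named '", name, "'", call. = FALSE)
  catalog[i, ]
}

#' Sequence-aware N-terminal truncation entries
#'
#' Generates catalog rows for the loss of the first `1..max_len` residues of
#' a specific sequence, so that intact-mass differences can be explained by
#' truncations of the actual protein rather than generic averages. The delta
#' formula of each entry is minus the summed composition of the removed
#' residues (no water change: interior peptide-bond residues are removed).
#'
#' @param sequence Residue string (one-letter codes).
#' @param max_len Longest truncation to generate (default 10).
#' @return A catalog-shaped data.frame (category `"truncation"`).
#' @export
truncation_entries <- function(sequence, max_len = 10) {
  residues <- mass_tables()$residues
  aa <- strsplit(sequence, "")[[1]]
  max_len <- min(max_len, length(aa) - 1L)
  if (max_len < 1L) {
    return(data.frame(name = character(0), delta_formula = character(0),
                      terminal_specificity = character(0),
                      residue_specificity = character(0),
                      category = character(0), protons_displaced = numeric(0),
                      net_average = numeric(0)))
  }
  f <- chem_formula()
  rows <- lapply(seq_len(max_len), function(k) {
    f <<- formula_add(f, residues[[aa[k]]])
    loss <- formula_scale(f, -1L)
    data.frame(name = sprintf("Trunc_N%d(%s)", k, substr(sequence, 1, k)),
               delta_formula = deparse_formula(loss),
               terminal_specificity = "N-term", residue_specificity = ".",
               category = "truncation", protons_displaced = 0,
               net_average = formula_mass(loss, "average"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ntdms_catalog", "data.frame")
  out
}

deparse_formula <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return("0")
  paste0(names(f), unclass(f), collapse = "")
}

#' Construct a proteoform
#'
#' A proteoform is a (possibly processed) sequence together with positioned
#' modifications and metal/cation adducts; its neutral mass is a pure
#' function of these fields.
#'
#' @param id Identifier.
#' @param sequence Residue string over the 20 standard one-letter codes.
#' @param modifications List of modification placements. Each element is a
#'   list with `spec` (catalog row or [metal_adduct()]-style list) and
#'   `position`: a single 1-based index, a length-2 range `c(start, end)` for
#'   a region-ambiguous ("floating") modification, or `NA` for a terminal
#'   modification placed by its `terminal_specificity`.
#' @param adducts List of adduct placements: each a list with `spec` (a
#'   [metal_adduct()] or adduct catalog row) and `count`.
#' @param n_term_start Offset of residue 1 relative to the unprocessed
#'   translation (1 for an unprocessed chain; 7 for a chain whose first six
#'   residues were removed).
#' @return An object of class `proteoform`.
#' @examples
#' p <- proteoform("pep", "MAATTE")
#' proteoform_mass(p)  # 622.69 Da
#' @export
proteoform <- function(id, sequence, modifications = list(), adducts = list(),
                       n_term_start = 1L) {
  residues <- mass_tables()$residues
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), names(residues))
  if (length(bad)) {
    stop("sequence contains non-standard residue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  L <- length(aa)
  for (m in modifications) {
    pos <- m$position
    if (!is.null(pos) && !all(is.na(pos))) {
      if (any(pos < 1 | pos > L)) {
        stop("modification position out of range [1, ", L, "]", call. = FALSE)
      }
    }
  }
  for (a in adducts) {
    if (is.null(a$count) || a$count < 0) {
      stop("adduct count must be a non-negative integer", call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, modifications = modifications,
                 adducts = adducts, n_term_start = as.integer(n_term_start)),
            class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat(sprintf("<proteoform %s: %d residues, %d modification(s), %d adduct(s)>\n",
              x$id, nchar(x$sequence), length(x$modifications), length(x$adducts)))
  invisible(x)
}

#' Total elemental composition of a proteoform
#'
#' Residue compositions plus one water, plus all modification delta formulas,
#' plus adduct cations with their displaced protons subtracted as hydrogen
#' atoms. Because adduct proton displacement is expressed in the formula, the
#' same composition drives both mass scales and isotope distributions.
#'
#' @param p A [proteoform()].
#' @return A [chem_formula].
#' @export
proteoform_formula <- function(p) {
  residues <- mass_tables()$residues
  aa <- strsplit(p$sequence, "")[[1]]
  f <- as_formula(WATER)
  counts <- table(aa)
  for (r in names(counts)) {
    f <- formula_add(f, formula_scale(residues[[r]], counts[[r]]))
  }
  for (m in p$modifications) f <- formula_add(f, as_formula(m$spec$delta_formula))
  for (a in p$adducts) {
    net <- formula_subtract(as_formula(a$spec$delta_formula),
                            chem_formula(c(H = a$spec$protons_displaced)))
    f <- formula_add(f, formula_scale(net, a$count))
  }
  f
}

#' Neutral mass of a proteoform
#'
#' Sum of residue masses plus water, modification shifts and adduct net
#' shifts, all derived from elemental composition. Additivity is exact:
#' adding a modification changes the mass by exactly that modification's
#' shift.
#'
#' @param p A [proteoform()].
#' @param scale `"average"` (intact MS1/MS2 bookkeeping) or `"monoisotopic"`
#'   (isotopically resolved MS3 fragment work).
#' @return Neutral mass in Da.
#' @export
proteoform_mass <- function(p, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  formula_mass(proteoform_formula(p), scale)
}

#' Remove an N-terminal run of residues from a proteoform
#'
#' Truncation is modeled as processing: the returned proteoform has the
#' shortened sequence, an updated `n_term_start`, and a mass lower by exactly
#' the summed residue masses of the removed run.
#'
#' @param p A [proteoform()].
#' @param n Number of N-terminal residues to remove.
#' @return A [proteoform()].
#' @export
truncate_nterm <- function(p, n) {
  L <- nchar(p$sequence)
  if (n < 1 || n >= L) stop("truncation length out of range", call. = FALSE)
  shift_pos <- function(pos) pos - n
  mods <- lapply(p$modifications, function(m) {
    if (!is.null(m$position) && !all(is.na(m$position))) {
      if (any(m$position <= n)) return(NULL)  # modification removed with run
      m$position <- shift_pos(m$position)
    }
    m
  })
  mods <- Filter(Negate(is.null), mods)
  proteoform(p$id, substr(p$sequence, n + 1L, L), mods, p$adducts,
             n_term_start = p$n_term_start + as.integer(n))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names are record ids).
#'   Sequences containing the ambiguity codes U, B, Z or X are rejected.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  bad <- grepl("[UBZX]", out)
  if (any(bad)) {
    stop("sequence(s) contain unsupported residue codes (U/B/Z/X): ",
         paste(names(out)[bad], collapse = ", "), call. = FALSE)
  }
  out
}
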