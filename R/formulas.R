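# Elemental mass tables and chemical-formula arithmetic.
#
# All theoretical masses in the package are derived from these tables; no
# mass shift is ever stored independently of a formula.

.ntdms_tables <- new.env(parent = emptyenv())

#' Packaged mass tables
#'
#' Returns the packaged elemental mass tables: IUPAC conventional standard
#' atomic weights, stable-isotope masses/abundances, and amino-acid residue
#' compositions. Loaded once per session from `inst/extdata`.
#'
#' @return A list with elements `average` (named numeric, Da per element),
#'   `monoisotopic` (named numeric, mass of the most abundant isotope),
#'   `isotopes` (data.frame: element, nucleons, mass, abundance) and
#'   `residues` (named list of [chem_formula] objects keyed by one-letter
#'   residue code).
#' @export
mass_tables <- function() {
  if (is.null(.ntdms_tables$average)) {
    ext <- function(f) system.file("extdata", f, package = "ntdms", mustWork = TRUE)
    aw <- utils::read.delim(ext("atomic_weights.tsv"), comment.char = "#")
    iso <- utils::read.delim(ext("isotopes.tsv"), comment.char = "#")
    res <- utils::read.delim(ext("residues.tsv"), comment.char = "#")

    avg <- stats::setNames(aw$average_mass, aw$element)
    # monoisotopic convention: mass of the most abundant stable isotope
    mono <- vapply(split(iso, iso$element),
                   function(d) d$mass[which.max(d$abundance)], numeric(1))
    residues <- stats::setNames(lapply(res$formula, parse_formula_raw), res$residue)

    .ntdms_tables$average <- avg
    .ntdms_tables$monoisotopic <- mono[names(avg)]
    .ntdms_tables$isotopes <- iso
    .ntdms_tables$residues <- residues
  }
  as.list(.ntdms_tables)
}

# formula parser that does not validate symbols (used while tables load)
parse_formula_raw <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  if (x == "" || x == "0") return(chem_formula())
  m <- gregexpr("[A-Z][a-z]?(-?[0-9]+)?", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse chemical formula: '", x, "'", call. = FALSE)
  }
  el <- sub("(-?[0-9]+)?$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  chem_formula(stats::setNames(as.integer(counts), names(counts)), validate = FALSE)
}

#' Chemical formula with signed element counts
#'
#' A chemical formula is a named integer vector of element counts. Counts may
#' be negative so that losses (for example removal of the initiator
#' methionine) are ordinary formulas and formula arithmetic stays closed.
#'
#' @param counts Named integer vector (names are element symbols) or a
#'   character scalar in Hill-style notation with optional signed counts,
#'   for example `"C2H3N1O1"` or `"C-5H-9N-1O-1S-1"`.
#' @param validate Check element symbols against the packaged table.
#' @return An object of class `chem_formula` (named integer vector, zero
#'   counts dropped, elements sorted).
#' @examples
#' chem_formula("H2O1")
#' chem_formula(c(C = 2, H = 2, O = 1))
#' @export
chem_formula <- function(counts = integer(0), validate = TRUE) {
  if (is.character(counts)) return(as_formula(counts))
  if (length(counts) && is.null(names(counts))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  counts <- counts[counts != 0]
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[counts != 0]
  }
  f <- stats::setNames(as.integer(counts), names(counts))
  if (length(f)) f <- f[order(names(f))]
  if (validate && length(f)) {
    known <- names(mass_tables()$average)
    bad <- setdiff(names(f), known)
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(f, class = "chem_formula")
}

#' @rdname chem_formula
#' @param x Formula-like object (string, named vector, or `chem_formula`).
#' @export
as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    f <- parse_formula_raw(x)
    return(chem_formula(unclass(f)))
  }
  chem_formula(x)
}

#' @export
print.chem_formula <- function(x, ...) {
  if (!length(x)) {
    cat("<empty formula>\n")
  } else {
    cat(paste0(names(x), unclass(x), collapse = " "), "\n")
  }
  invisible(x)
}

#' Formula arithmetic
#'
#' Element-wise sum, difference and integer scaling of chemical formulas.
#' The operations are closed and associative; negative counts represent
#' losses.
#'
#' @param a,b Formula-like objects (see [as_formula()]).
#' @param f Formula-like object.
#' @param k Integer multiplier (may be negative).
#' @return A [chem_formula].
#' @export
formula_add <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  all_el <- union(names(a), names(b))
  out <- stats::setNames(integer(length(all_el)), all_el)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  chem_formula(out, validate = FALSE)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) formula_add(a, formula_scale(b, -1L))

#' @rdname formula_add
#' @export
formula_scale <- function(f, k) {
  f <- as_formula(f)
  chem_formula(stats::setNames(unclass(f) * as.integer(k), names(f)), validate = FALSE)
}

#' Mass of a chemical formula
#'
#' Computes the mass of a formula on the average (standard atomic weights)
#' or monoisotopic (most abundant isotope) scale. Linear in the counts;
#' negative counts subtract.
#'
#' @param formula Formula-like object.
#' @param scale `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' formula_mass("H2O1")                      # 18.015
#' formula_mass("C1", "monoisotopic")        # 12
#' @export
formula_mass <- function(formula, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  f <- as_formula(formula)
  if (!length(f)) return(0)
  tab <- mass_tables()[[scale]]
  bad <- setdiff(names(f), names(tab))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(tab[names(f)] * unclass(f))
}

# mass of one hydrogen atom on the requested scale (used for proton
# displacement bookkeeping; m/z charging uses the proton mass instead)
hydrogen_mass <- function(scale = "average") mass_tables()[[scale]][["H"]]

#' Proton mass used for m/z charging
#'
#' Mass of the proton (1.00728 Da) used to convert between m/z and neutral
#' mass in positive-mode electrospray. Distinct from the average-hydrogen
#' mass (1.008 Da) used in proton-displacement bookkeeping for metal adducts,
#' so that both reproduce the values conventionally printed on each scale.
#' @export
PROTON_MASS <- 1.00728

WATER <- c(H = 2L, O = 1L)
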