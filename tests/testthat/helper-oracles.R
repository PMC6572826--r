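# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: enumeration instead of convolution,
# direct tail sums instead of ppois, residue-table sums instead of
# proteoform_mass internals.

# exhaustive isotopologue enumeration for small formulas (<= ~6 atoms):
# every atom picks an isotope; aggregate abundance and mean mass by
# total nucleon count
enumerate_isotopologues <- function(counts) {
  iso <- mass_tables()$isotopes
  atoms <- rep(names(counts), counts)
  if (!length(atoms)) return(data.frame(mass = 0, abundance = 1))
  choices <- lapply(atoms, function(el) which(iso$element == el))
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  ab <- apply(grid, 1, function(ix) prod(iso$abundance[ix]))
  ms <- apply(grid, 1, function(ix) sum(iso$mass[ix]))
  nn <- apply(grid, 1, function(ix) sum(iso$nucleons[ix]))
  ab <- ab / sum(ab)
  agg_ab <- tapply(ab, nn, sum)
  agg_m <- tapply(ab * ms, nn, sum) / agg_ab
  out <- data.frame(mass = as.numeric(agg_m), abundance = as.numeric(agg_ab))
  out[order(out$mass), ]
}

# brute-force Poisson upper tail P(X >= n) by direct pmf summation
poisson_tail_bruteforce <- function(n, lambda) {
  if (n <= 0) return(1)
  kmax <- max(ceiling(lambda + 60 * sqrt(lambda + 1)), n + 200)
  sum(stats::dpois(n:kmax, lambda))
}

# residue-table sum oracle for peptide average mass (independent of
# proteoform_mass: works from the residue TSV and atomic weights directly)
peptide_average_mass_oracle <- function(sequence) {
  tabs <- mass_tables()
  aa <- strsplit(sequence, "")[[1]]
  res_mass <- vapply(tabs$residues, function(f)
    sum(tabs$average[names(f)] * unclass(f)), numeric(1))
  sum(res_mass[aa]) + 2 * tabs$average[["H"]] + tabs$average[["O"]]
}

# random small chemical formula over CHNOS(+Cu), at most `max_atoms` atoms
random_small_formula <- function(max_atoms = 6, elements = c("C", "H", "N", "O", "S", "Cu")) {
  n <- sample(max_atoms, 1)
  atoms <- sample(elements, n, replace = TRUE)
  counts <- table(atoms)
  stats::setNames(as.integer(counts), names(counts))
}

# deterministic full-ladder metal calls for a known site: bound b_i iff
# i >= s, bound y_j iff j >= L - s + 1 (fragment covers the site)
ladder_calls <- function(L, s, b_idx = seq_len(L - 1), y_idx = seq_len(L - 1)) {
  rbind(
    data.frame(series = "b", index = b_idx,
               call = ifelse(b_idx >= s, "metal-bound", "apo")),
    data.frame(series = "y", index = y_idx,
               call = ifelse(y_idx >= L - s + 1, "metal-bound", "apo")))
}

# minimal centroided mzML writer (64-bit little-endian, no compression),
# used only to exercise the mzML reading path against the TSV path
write_minimal_mzml <- function(mz, intensity, path) {
  enc <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                   endian = "little"))
  bda <- function(accession, name, data) sprintf(paste0(
    "<binaryDataArray encodedLength=\"%d\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"%s\" name=\"%s\" value=\"\"/>",
    "<binary>%s</binary></binaryDataArray>"),
    nchar(enc(data)), accession, name, enc(data))
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>\n",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">",
    "<cvList count=\"1\"><cv id=\"MS\" fullName=\"PSI-MS\" URI=\"psi-ms.obo\"/></cvList>",
    "<fileDescription><fileContent>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000579\" name=\"MS1 spectrum\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\" value=\"\"/>",
    "</fileContent></fileDescription>",
    "<run id=\"r1\"><spectrumList count=\"1\" defaultDataProcessingRef=\"dp1\">",
    sprintf("<spectrum index=\"0\" id=\"scan=1\" defaultArrayLength=\"%d\">",
            length(mz)),
    "<cvParam cvRef=\"MS\" accession=\"MS:1000511\" name=\"ms level\" value=\"1\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\" value=\"\"/>",
    "<binaryDataArrayList count=\"2\">",
    bda("MS:1000514", "m/z array", mz),
    bda("MS:1000515", "intensity array", intensity),
    "</binaryDataArrayList></spectrum></spectrumList></run></mzML>")
  writeLines(xml, path)
  path
}
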