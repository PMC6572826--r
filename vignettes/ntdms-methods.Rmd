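---
title: "Interpreting native top-down MS of metalloprotein complexes with ntdms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting native top-down MS of metalloprotein complexes with ntdms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdms)
```

## The measurement this package models

Native top-down mass spectrometry (nTDMS) interrogates an intact protein
complex in three tiers. The complex is electrosprayed from a non-denaturing
buffer and its intact mass measured from the charge-state envelope (MS1);
collisional activation then ejects individual subunits whose masses are
measured the same way (MS2); further activation fragments each subunit's
backbone into b/y ions recorded at isotopic resolution (MS3). For a
metalloenzyme such as particulate methane monooxygenase (pMMO) — a
three-subunit, ~100 kDa membrane complex with mononuclear copper sites —
this one experiment can report, per subunit, the proteoform inventory
(truncations, acetylation, methylation), the metal stoichiometry, and a
sequence interval confining each metal site.

`ntdms` implements the interpretation layer of that experiment: everything
between a centroided peak list and the biological statement "one Cu(II) per
subunit B, confined to residues i–j, at f% occupancy on subunit C".

## Mass bookkeeping

All theoretical masses derive from packaged tables of IUPAC standard atomic
weights and stable-isotope masses; nothing is stored as a bare number.
Two scales coexist deliberately:

* **average** masses for MS1/MS2 work, where intact species are reported as
  deconvoluted neutral average masses;
* **monoisotopic** masses for MS3 fragments, which are isotopically
  resolved.

A metal cation that binds without changing the net charge displaces as many
protons as its charge, so its net shift is `mass(cation) − n·mass(H)`:
Cu(II) gives +61.53 Da on the average scale, ammonium +17.03 Da. Proton
displacement is expressed in the elemental formula itself (remove `n`
hydrogens, add the cation), so isotope distributions of metal-bound species
need no special casing. Note the deliberate distinction between the average
hydrogen mass (1.008 Da) used in this bookkeeping and the proton mass
(1.00728 Da) used to convert m/z to neutral mass when charging.

```{r}
cu2 <- metal_adduct("Cu(II)", "Cu1", 2)
adduct_shift(cu2)
```

A `proteoform` couples a sequence with positioned modifications, terminal
processing and metal adducts; its mass is a pure function of those fields,
and additivity is exact by construction. Truncations are modelled as the
loss of the actual removed residues, so that an intact-mass difference on a
specific protein is explained by its own sequence rather than by a generic
average residue.

## Explaining intact-mass differences

`explain_delta()` enumerates all multisets of catalog entries up to a small
cardinality (guarded at 4) and keeps those whose net shift matches the
observed difference within tolerance, ranked parsimony-first (fewer
entries), then by absolute residual, then lexicographically. This mirrors
how unexplained shifts are assigned by hand against a modification database:
the smallest story that fits wins, and near-ties stay visible in the ranked
table instead of being silently resolved.

The packaged catalog carries the entries this kind of experiment needs:
N-terminal acetylation, initiator-methionine removal, methylation, Cu(II),
Zn(II), ammonium and sodium. Copper is catalogued in its +2 oxidation
state: under native, non-reducing electrospray the bound copper of a
resting metalloenzyme is predominantly Cu(II) (EPR-established for the
enzymes this workflow targets), and a Cu(I)/Cu(II) pair differing by one
proton (1.008 Da) cannot be distinguished at intact-mass accuracy anyway —
listing both would only convert every copper assignment into a coin toss.
Users who work with reduced samples can add a Cu(I) row (`metal_adduct
("Cu(I)", "Cu1", 1)`) or supply their own catalog TSV. The default
intact-mass tolerance is 1.5 Da, the scale tolerated by assignments at
28–99 kDa.

## Charge-state deconvolution

For each peak and candidate charge `z` the implied neutral mass is
`z·(mz − 1.00728)`. Implied masses are clustered with a mass-scaled
tolerance (1.5 Da + 20 ppm, matching the ~0.3–1.1 Da standard deviations
typical of native deconvolution at 28–99 kDa). A cluster is accepted as a
species only when at least two distinct peaks agree *and* at least two of
their charges are consecutive — the signature of a genuine electrospray
envelope. The consecutive-charge requirement is what suppresses harmonic
artifacts (a peak set consistent with mass M is also consistent with 2M at
doubled charges, but only at non-consecutive ones). Peaks consistent with
several species go to the richest envelope first, then the nearest mass,
then the more intense species.

The reported species mass is the intensity-weighted mean of implied masses;
the reported standard deviation is the unweighted SD across the
per-charge-state masses — the convention behind "M ± SD from sampling
multiple charge states". S/N peak picking (cutoff 3 against the median
absolute intensity) assumes a dense noise baseline; the picked spectrum
records its noise estimate so that re-picking is idempotent, and the
pipeline's `apply_snr_filter` switch exists for peak lists that are already
noise-filtered.

## Isotope engine and envelope fitting

Isotope distributions are aggregated by nucleon count and computed by
binary-exponentiation convolution of per-element patterns, pruned at 1e-4
relative abundance (the limit conventionally used by Mercury-style
calculators in top-down validation). Aggregate resolution is sufficient at
the ~120,000 resolving power of isotopically resolved fragment data; fine
structure is out of scope. Species known only by mass get an averagine
composition scaled to the target and hydrogen-adjusted to within 0.5 Da.

The envelope fit score aligns theoretical peaks to the nearest observed
peak within 0.35 Da and computes a centered cosine (Pearson correlation
clamped to [0, 1]). Centering matters: a plain cosine between two
non-negative envelope shapes is high (~0.7) even for flat noise, whereas
the centered score is ~0 for noise, 1 for an exact rendering, and
scale-invariant. The metal-call threshold defaults to 0.8; the underlying
experimental literature reports isotopic fits without a numeric criterion,
so the threshold is an explicit, configurable package decision.

## Fragments, matching, and metal calls

b/y fragments are generated for every backbone position, with and without
each metal-adduct hypothesis; positioned modifications enter only fragments
spanning their site, and a floating modification with a candidate region
enters only fragments containing the whole region (with no region it is
excluded — strict mode — to avoid silent mislocalization). Matching is
one-to-one greedy by smallest |ppm| at a 25 ppm tolerance, which is
deterministic and mirrors validator-style tools.

Each match also records its **ppm margin**: the distance to the nearest
competing theoretical fragment. At 25 ppm on multi-kDa fragments,
occasional sub-ppm coincidences between unrelated fragments are
statistically inevitable; a match whose margin is below 5 ppm cannot
discriminate between hypotheses by mass and is therefore flagged ambiguous
unless an isotopic fit rescues it. Ambiguous fragments carry no metal call
and no localization constraint.

The match-level significance is a Poisson p-score: with `n_observed`
masses, `n_theoretical` fragments and a mean tolerance half-window of
`tol_ppm × mean fragment mass`, the expected number of chance hits is
`λ = n_observed · n_theoretical · 2·tol_Da / span`, and the p-score is the
upper tail `P(X ≥ n_matched)`. The experimental literature names such a
score without defining it; this form is the package's documented,
test-locked choice.

## Localizing a metal site

Fragment-map coordinates are 1-based over the processed proteoform, with an
offset back to the unprocessed translation. Calls constrain the site `s`:

* metal-bound b_i ⇒ s ∈ [1, i]; apo b_j ⇒ s ∈ [j+1, L]
* metal-bound y_k ⇒ s ∈ [L−k+1, L]; apo y_m ⇒ s ∈ [1, L−m]

The interval is the intersection. Apo fragments are hard exclusions by
default — that is exactly the reasoning that turns "no copper on b135,
copper on b165" into "site within [136, 165]" — with two refinements. An
apo fragment that strictly contains a shorter metal-bound fragment of the
same series contradicts direct evidence and is read as gas-phase metal loss
rather than exclusion. And `apo_constraints = "soft"` downgrades all apo
evidence for labile sites. Note that strict intersection of apo-b135 with
metal-b165 yields [136, 165]; a published account may quote a slightly
different right edge when it anchors the region to a residue of interest,
and this package always returns the strict intersection.

## Occupancy

Occupancy is the summed deconvolved intensity of the metal-bound species
over the subunit total, assuming equal ionization response across
proteoforms of one subunit (stated assumption, not established fact; it is
the standard reading of relative abundances within one subunit's envelope).
With replicate spectra the fraction is the replicate mean ± SD.

## The synthetic-data generator

No desk-scale raw data exist for this kind of experiment, so the package
carries a seeded generator that emulates the statistical structure of the
real measurement and serves as the test bed for every stage:

* discretized Gaussian charge envelopes over integer z (default center
  16.5, SD 1.0 — a 15–18+ window for a ~100 kDa complex);
* additive m/z jitter (default SD 0.05 Th, chosen so deconvolution SDs land
  at the ~0.3–1.1 Da scale seen at 28–99 kDa) and multiplicative log-normal
  intensity noise (default SD 0.1);
* subunit ejection with per-subunit binomial metal retention;
* b/y ladders sampled without replacement at a configurable coverage
  (default 0.5), with a 3x sampling-weight enhancement at sites C-terminal
  to Asp (enhanced acidic-residue cleavage is well documented for native
  collisional activation; the multiplier itself is a package choice),
  5 ppm fragment mass jitter, and metal retention on covering fragments;
* optional periodic lipid-cluster background and a dense exponential noise
  baseline against which S/N picking is meaningful.

Identical config + seed gives byte-identical peak lists. The packaged
`pmmo_like_scenario()` builds a three-subunit complex (two ~28 kDa
subunits, one ~42 kDa) with a fully occupied Cu(II) site on subunit B at a
His-x-His motif and a partially occupied (16%) site on subunit C. Its
sequences are random with placed His/Asp motifs — synthetic stand-ins with
realistic length and composition, not any organism's sequence — so the
repository stays self-contained; real sequences enter via FASTA.

What the generator does *not* emulate: profile-mode peak shapes, detector
physics, charge-reduction chemistry, overlapping isotopic envelopes at the
raw MS3 level (fragment masses arrive deisotoped), and ionization-response
differences between proteoforms. Passing tests therefore demonstrate the
correctness of the interpretation logic under the stated noise model, not
instrument-level robustness.

## Numerical choices and degenerate inputs

* Charge assignment requires two peaks per envelope except when the charge
  window is a single value (no ambiguity exists).
* A spectrum with no assignable envelope deconvolutes to an empty table,
  not an error; an empty peak-list file reads as an empty spectrum with a
  warning; a malformed line errors with its line number.
* `explain_delta` refuses cardinality > 4 without an explicit override
  (combinatorial guard) and includes the empty explanation for |Δm| ≤ tol.
* Envelope fitting returns an NA sentinel when no observed peak lies within
  tolerance of any theoretical peak.
* Localization without any metal-bound fragment returns a no-localization
  sentinel; conflicting constraints return an explicitly inconsistent,
  empty interval.
* Matching ties are broken by smallest |ppm|, then first-seen order over a
  deterministic sort — results are independent of input order.

## Problem sizes used in the tests

The shipped test-suite exercises the pipeline at sizes chosen to be
representative yet quick: 100-seed Monte-Carlo round trips for the 98.7 kDa
deconvolution and for each occupancy level, 1,000 random proteoforms for
the fragment identities, exhaustive site localization for chains up to 50
residues, and one full three-subunit end-to-end scenario with ~380-residue
subunits. These sizes reproduce the regimes of the motivating experiment
(15–18+ envelopes at ~99 kDa, 28–42 kDa subunits, hundreds of observed
fragments) without requiring instrument-scale data volumes.

## Known limitations

* Mass-only metal calls on large fragments are limited by accidental
  near-coincidences; the ppm-margin rule removes them from inference but a
  real analysis should confirm calls isotopically where signal permits.
* Occupancy assumes equal response factors within a subunit.
* The deconvolution model is a clustering heuristic, not a Bayesian
  mixture; heavily overlapping envelopes at low signal may merge or drop.
* Aggregate isotope distributions ignore fine structure, which becomes
  visible above ~500,000 resolving power.
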