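# b/y fragment generation, ppm matching, Poisson p-score, metal detection.

cu2 <- metal_adduct("Cu(II)", "Cu1", 2)

test_that("dipeptide fragments match the residue-table values", {
  fr <- generate_fragments(proteoform("gg", "GG"))
  b1 <- fr$neutral_mass[fr$series == "b" & fr$index == 1]
  y1 <- fr$neutral_mass[fr$series == "y" & fr$index == 1]
  expect_equal(b1, 57.0215, tolerance = 1e-4)
  expect_equal(y1, 75.0320, tolerance = 1e-4)
})

test_that("b/y complementarity holds across random proteoforms", {
  water <- formula_mass("H2O1", "monoisotopic")
  for (seed in 1:100) {
    sq <- make_test_sequence(sample(5:40, 1), seed = seed)
    p <- proteoform("p", sq)
    fr <- generate_fragments(p)
    L <- nchar(sq)
    prec <- proteoform_mass(p, "monoisotopic")
    b <- fr$neutral_mass[fr$series == "b"][seq_len(L - 1)]
    y <- fr$neutral_mass[fr$series == "y"][seq_len(L - 1)]
    expect_equal(b + rev(y), rep(prec, L - 1), tolerance = 1e-6)
  }
})

test_that("adduct hypotheses double the ladder and count correctly", {
  p <- proteoform("p", make_test_sequence(200, seed = 8))
  fr <- generate_fragments(p, c("b", "y"),
                           adducts = list(list(spec = cu2, count = 1)))
  expect_equal(nrow(fr), 2 * 2 * 199)
  shift <- fr$neutral_mass[fr$series == "b" & fr$adduct == "Cu(II)"] -
    fr$neutral_mass[fr$series == "b" & fr$adduct == ""]
  expect_equal(shift, rep(entry_shift(cu2, "monoisotopic"), 199),
               tolerance = 1e-9)
  expect_error(generate_fragments(p, adducts = list(list(spec = cu2, count = -1))),
               "non-negative")
  expect_error(generate_fragments(proteoform("x", "G")), "at least 2")
})

test_that("positioned and region modifications enter only spanning fragments", {
  catalog <- read_catalog()
  methyl <- catalog_entry(catalog, "Methyl")
  sq <- make_test_sequence(30, seed = 2)
  p <- proteoform("p", sq, modifications = list(list(spec = methyl, position = 10)))
  fr0 <- generate_fragments(proteoform("p", sq))
  fr1 <- generate_fragments(p)
  dm <- entry_shift(methyl, "monoisotopic")
  db <- fr1$neutral_mass[fr1$series == "b"] - fr0$neutral_mass[fr0$series == "b"]
  expect_equal(db, ifelse(1:29 >= 10, dm, 0), tolerance = 1e-9)
  dy <- fr1$neutral_mass[fr1$series == "y"] - fr0$neutral_mass[fr0$series == "y"]
  expect_equal(dy, ifelse(1:29 >= 30 - 10 + 1, dm, 0), tolerance = 1e-9)

  # floating modification with a candidate region: only fully containing
  # fragments; with no region at all: no fragment carries it (strict mode)
  pr <- proteoform("p", sq, modifications = list(
    list(spec = methyl, position = c(8, 12))))
  frr <- generate_fragments(pr)
  dbr <- frr$neutral_mass[frr$series == "b"] - fr0$neutral_mass[fr0$series == "b"]
  expect_equal(dbr, ifelse(1:29 >= 12, dm, 0), tolerance = 1e-9)
  pf <- proteoform("p", sq, modifications = list(
    list(spec = methyl, position = NA)))
  frf <- generate_fragments(pf)
  expect_equal(frf$neutral_mass, fr0$neutral_mass, tolerance = 1e-9)
})

test_that("matching is one-to-one, tolerance-bounded and order-invariant", {
  p <- proteoform("p", make_test_sequence(120, seed = 5))
  theo <- generate_fragments(p)
  b10 <- theo$neutral_mass[theo$series == "b" & theo$index == 10]

  res <- match_fragments(theo, b10, tol_ppm = 25)
  expect_equal(nrow(res$matches), 1)
  expect_equal(res$matches$ppm_error, 0)

  res_out <- match_fragments(theo, b10 * (1 + 30e-6), tol_ppm = 25)
  expect_equal(nrow(res_out$matches), 0)
  expect_equal(res_out$unmatched, b10 * (1 + 30e-6))

  # 50 forward-generated masses with <= 10 ppm jitter all match back
  set.seed(31)
  pick <- sample(nrow(theo), 50)
  obs <- theo$neutral_mass[pick] * (1 + stats::runif(50, -1e-5, 1e-5))
  res50 <- match_fragments(theo, obs, tol_ppm = 25)
  expect_equal(nrow(res50$matches), 50)
  gen_sites <- unique(ifelse(theo$series[pick] == "b", theo$index[pick],
                             nchar(p$sequence) - theo$index[pick]))
  expect_equal(res50$coverage, length(gen_sites) / (nchar(p$sequence) - 1))
  # order of observed masses is irrelevant
  res_rev <- match_fragments(theo, rev(obs), tol_ppm = 25)
  o1 <- res50$matches[order(res50$matches$observed_mass), ]
  o2 <- res_rev$matches[order(res_rev$matches$observed_mass), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("fragment map flags sites by series and exports cleanly", {
  m <- data.frame(series = c("b", "y"), index = c(3, 2))
  map <- fragment_map(m, L = 10)
  expect_true(map$b_supported[3])
  expect_true(map$y_supported[8])
  expect_equal(attr(map, "coverage"), 2 / 9)
  txt <- fragment_map_text(map, width = 5)
  expect_length(txt, 2)
  path <- tempfile(fileext = ".tsv")
  write_fragment_map(map, path)
  back <- utils::read.delim(path)
  expect_equal(back$site, 1:9)
})

test_that("the Poisson p-score equals the brute-force tail sum", {
  # frozen worked case: 25 of 30 observed vs 400 theoretical at 25 ppm,
  # mean fragment mass 5 kDa, span 20 kDa
  lambda <- 30 * (400 * 2 * 25e-6 * 5000) / 20000
  want <- poisson_tail_bruteforce(25, lambda)
  got <- fragment_pscore(25, 30, 400, 25, 5000, 20000)
  expect_equal(got, want, tolerance = 1e-12)

  expect_equal(fragment_pscore(0, 30, 400, 25, 5000, 20000), 1)
  p_seq <- vapply(1:30, fragment_pscore, numeric(1), n_observed = 30,
                  n_theoretical = 400, tol_ppm = 25,
                  mean_fragment_mass = 5000, mass_span = 20000)
  expect_true(all(diff(p_seq) < 0))
  expect_error(fragment_pscore(5, 10, 100, 25, 5000, 0), "positive")
  expect_error(fragment_pscore(11, 10, 100, 25, 5000, 100), "n_matched")

  # property over a lambda grid
  for (lam in c(0.1, 1, 7, 30)) {
    span <- 400 * 2 * 25e-6 * 5000 * 20 / lam
    expect_equal(fragment_pscore(8, 20, 400, 25, 5000, span),
                 poisson_tail_bruteforce(8, 20 * (400 * 2 * 25e-6 * 5000) / span),
                 tolerance = 1e-12)
  }
})

test_that("metal detection separates bound and apo at a retention boundary", {
  p <- proteoform("p", make_test_sequence(220, seed = 14, his_pair_at = 140))
  theo <- generate_fragments(p, c("b", "y"),
                             adducts = list(list(spec = cu2, count = 1)))
  # deterministic ladder, exact masses: Cu retained on b >= 140
  apo_b <- theo[theo$series == "b" & theo$adduct == "" & theo$index < 140, ]
  cu_b <- theo[theo$series == "b" & theo$adduct == "Cu(II)" & theo$index >= 140, ]
  obs <- c(apo_b$neutral_mass, cu_b$neutral_mass)
  m <- match_fragments(theo, obs, 25)
  calls <- detect_metal_fragments(m$matches, cu2, proteoform = p,
                                  metal_spec = cu2)
  called <- calls[calls$call != "ambiguous", ]
  expect_true(all(called$call[called$index >= 140] == "metal-bound"))
  expect_true(all(called$call[called$index < 140] == "apo"))
  # no incorrect calls on exact data
  expect_equal(sum(called$call == "metal-bound" & called$index < 140), 0)

  # apo-only data yields zero metal-bound calls
  m0 <- match_fragments(theo, apo_b$neutral_mass, 25)
  calls0 <- detect_metal_fragments(m0$matches, cu2, proteoform = p,
                                   metal_spec = cu2)
  expect_equal(sum(calls0$call == "metal-bound"), 0)
})

test_that("mass-matched but envelope-failing fragments become ambiguous", {
  p <- proteoform("p", make_test_sequence(120, seed = 9))
  theo <- generate_fragments(p, "b", adducts = list(list(spec = cu2, count = 1)))
  cu_b80 <- theo[theo$series == "b" & theo$adduct == "Cu(II)" & theo$index == 80, ]
  m <- match_fragments(theo, cu_b80$neutral_mass, 25)

  # a clean rendered envelope confirms the metal call
  good_env <- render_envelope(fragment_formula(p, "b", 80,
                                               adduct = list(spec = cu2, count = 1)))
  names(good_env)[1] <- "mass"
  calls_good <- detect_metal_fragments(m$matches, cu2, proteoform = p,
                                       envelopes = list(b80 = good_env),
                                       metal_spec = cu2)
  expect_equal(calls_good$call, "metal-bound")
  expect_gte(calls_good$envelope_score, 0.8)

  # noise-corrupted envelope below threshold: ambiguous, not metal-bound
  set.seed(21)
  bad_env <- good_env
  bad_env$intensity <- stats::runif(nrow(bad_env))
  calls_bad <- detect_metal_fragments(m$matches, cu2, proteoform = p,
                                      envelopes = list(b80 = bad_env),
                                      metal_spec = cu2)
  expect_equal(calls_bad$call, "ambiguous")
})
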