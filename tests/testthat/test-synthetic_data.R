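# The seeded generator: determinism, noise-free forward models, metal
# retention bookkeeping, and Asp cleavage bias.

cu2 <- metal_adduct("Cu(II)", "Cu1", 2)

test_that("identical config and seed give byte-identical peak lists", {
  cfg <- sim_config(seed = 123, lipid_count = 5, lipid_intensity = 3,
                    noise_peaks = 50, noise_intensity = 0.1)
  species <- list(list(id = "p", mass = 98696.0, abundance = 100))
  f1 <- tempfile(); f2 <- tempfile()
  write_peaklist(simulate_intact_spectrum(species, cfg), f1)
  write_peaklist(simulate_intact_spectrum(species, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the output
  cfg2 <- sim_config(seed = 124, lipid_count = 5, lipid_intensity = 3,
                     noise_peaks = 50, noise_intensity = 0.1)
  f3 <- tempfile()
  write_peaklist(simulate_intact_spectrum(species, cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("the noise-free forward model is analytic", {
  cfg <- sim_config(z_center = 16.5, z_sd = 0.55, mz_jitter_sd = 0,
                    intensity_noise_sd = 0, seed = 1)
  sp <- simulate_intact_spectrum(list(list(id = "p", mass = 98696.0,
                                           abundance = 100)), cfg)
  # envelope support 15..18 at this width; exact m/z values
  env <- sp$peaks
  expect_equal(nrow(env), 4)
  z <- 18:15  # increasing m/z = decreasing charge
  expect_equal(env$mz, (98696.0 + z * PROTON_MASS) / z, tolerance = 1e-9)

  # two proteoforms at 84:16 keep exactly that summed-intensity ratio
  ma <- 98696.0; mb <- 98757.5
  sp2 <- simulate_intact_spectrum(
    list(list(id = "a", mass = ma, abundance = 84),
         list(id = "b", mass = mb, abundance = 16)), cfg)
  grid_a <- (ma + (15:18) * PROTON_MASS) / (15:18)
  is_a <- vapply(sp2$peaks$mz, function(x) min(abs(grid_a - x)) < 1e-6,
                 logical(1))
  ia <- sum(sp2$peaks$intensity[is_a])
  ib <- sum(sp2$peaks$intensity[!is_a])
  expect_equal(ia / ib, 84 / 16, tolerance = 1e-9)
})

test_that("generated masses agree exactly with proteoform bookkeeping", {
  p <- proteoform("p", make_test_sequence(60, seed = 5))
  cfg <- sim_config(mz_jitter_sd = 0, intensity_noise_sd = 0,
                    fragment_ppm_sd = 0, fragment_coverage = 1, seed = 2)
  sp <- simulate_intact_spectrum(list(list(id = "p", proteoform = p,
                                           abundance = 1)), cfg)
  z <- round(proteoform_mass(p) / (sp$peaks$mz[1] - PROTON_MASS) / 1) # top charge
  expect_equal(min(abs(sp$metadata$true_masses$p - proteoform_mass(p))), 0)

  frg <- simulate_fragment_masses(p, cfg)
  theo <- generate_fragments(p)
  key <- paste(theo$series, theo$index)
  expect_equal(frg$masses$neutral_mass,
               theo$neutral_mass[match(paste(frg$masses$series, frg$masses$index),
                                       key)], tolerance = 1e-9)
})

test_that("metal loss on ejection follows the binomial bookkeeping", {
  subs <- list(list(id = "B", mass = 40000, metal = cu2))
  cfg <- sim_config(seed = 9, mz_jitter_sd = 0, intensity_noise_sd = 0,
                    z_center = 12, z_sd = 1)
  # loss 0: everything bound
  ej0 <- simulate_ejection(subs, 0, cfg)
  expect_equal(ej0$truth$B$bound_fraction, 1)
  expect_equal(length(ej0$species), 1)
  expect_equal(ej0$species[[1]]$mass, 40000 + adduct_shift(cu2))
  # loss 1: all apo; the complex-minus-components gap is the metal shift
  ej1 <- simulate_ejection(subs, 1, cfg)
  expect_equal(ej1$truth$B$bound_fraction, 0)
  expect_equal(ej1$species[[1]]$mass, 40000)
  expect_equal((40000 + adduct_shift(cu2)) - ej1$species[[1]]$mass,
               adduct_shift(cu2))
  # loss 0.84 over 1000 draws: bound fraction near 0.16
  ej <- simulate_ejection(subs, 0.84, cfg, n_draws = 1000)
  expect_lt(abs(ej$truth$B$bound_fraction - 0.16), 0.04)
  # per-subunit override beats the global loss probability
  ej_mix <- simulate_ejection(
    list(list(id = "B", mass = 40000, metal = cu2, metal_loss_prob = 0),
         list(id = "C", mass = 28000, metal = cu2)), 0.84, cfg)
  expect_equal(ej_mix$truth$B$bound_fraction, 1)
  expect_lt(ej_mix$truth$C$bound_fraction, 0.5)
})

test_that("a full-coverage jitter-free ladder round-trips through matching", {
  p <- proteoform("p", make_test_sequence(80, seed = 6))
  cfg <- sim_config(fragment_coverage = 1, fragment_ppm_sd = 0, seed = 3)
  frg <- simulate_fragment_masses(p, cfg)
  res <- match_fragments(generate_fragments(p), frg$masses$neutral_mass, 25)
  expect_equal(res$coverage, 1)
  expect_equal(nrow(res$matches), nrow(frg$masses))
})

test_that("a retained metal splits the ladder at the site", {
  p <- proteoform("p", make_test_sequence(120, seed = 7, his_pair_at = 40))
  cfg <- sim_config(fragment_coverage = 1, fragment_ppm_sd = 0,
                    metal_retention_prob = 1, seed = 4)
  frg <- simulate_fragment_masses(p, cfg, metal = cu2, metal_site = 40)
  b <- frg$masses[frg$masses$series == "b", ]
  expect_true(all(b$metal_bound[b$index >= 40]))
  expect_true(all(!b$metal_bound[b$index < 40]))
  theo <- generate_fragments(p, c("b", "y"),
                             adducts = list(list(spec = cu2, count = 1)))
  m <- match_fragments(theo, frg$masses$neutral_mass, 25)
  calls <- detect_metal_fragments(m$matches, cu2, proteoform = p,
                                  metal_spec = cu2)
  loc <- localize_adduct(calls, 120)
  expect_true(loc$consistent)
  expect_true(loc$start <= 40 && 40 <= loc$end)
})

test_that("Asp-biased cleavage sampling enriches post-Asp sites", {
  sq <- make_test_sequence(200, seed = 44)
  p <- proteoform("p", sq)
  aa <- strsplit(sq, "")[[1]]
  asp_sites <- which(aa[seq_len(199)] == "D")
  expect_gt(length(asp_sites), 3)
  hits <- integer(199)
  for (s in 1:300) {
    cfg <- sim_config(fragment_coverage = 0.2, asp_cleavage_bias = 5, seed = s)
    frg <- simulate_fragment_masses(p, cfg)
    hits[frg$truth$sites] <- hits[frg$truth$sites] + 1L
  }
  rate_asp <- mean(hits[asp_sites]) / 300
  rate_other <- mean(hits[-asp_sites]) / 300
  # sampling without replacement damps the nominal 5x weight ratio, but the
  # enrichment must be strong and in the right direction
  expect_gt(rate_asp / rate_other, 2)
})
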