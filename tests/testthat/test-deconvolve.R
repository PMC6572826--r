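# Peak picking, charge assignment and deconvolution round trips.

test_that("peak picking filters on S/N against the median and is idempotent", {
  flat <- ms_spectrum(seq(1000, 1999), rep(5, 1000))
  expect_equal(nrow(pick_peaks(flat, 3)$peaks), 0)

  # one spike at 100x a flat baseline survives alone
  spike <- ms_spectrum(seq(1000, 1999), c(rep(1, 999), 100))
  picked <- pick_peaks(spike, 3)
  expect_equal(nrow(picked$peaks), 1)
  expect_equal(picked$peaks$intensity, 100)

  # idempotence: re-picking the picked spectrum changes nothing
  again <- pick_peaks(picked, 3)
  expect_equal(again$peaks, picked$peaks)

  # empty input is an empty output, not an error
  expect_equal(nrow(pick_peaks(ms_spectrum(), 3)$peaks), 0)
  expect_error(pick_peaks(flat, 0), "positive")
})

test_that("single-charge assignment inverts m/z exactly", {
  sp <- ms_spectrum(1001.00728, 100)
  asg <- assign_charges(sp, c(1, 1))$assigned
  expect_equal(nrow(asg), 1)
  expect_equal(asg$mass, 1000, tolerance = 1e-9)
})

test_that("a forward-generated envelope is assigned to one common mass", {
  M <- 98696.0
  z <- 15:18
  sp <- ms_spectrum((M + z * PROTON_MASS) / z, rep(25, 4))
  asg <- assign_charges(sp, c(10, 25))$assigned
  expect_equal(nrow(asg), 4)
  expect_equal(sort(asg$z), z)
  expect_equal(asg$mass, rep(M, 4), tolerance = 1e-6)
  # charge consistency: implied masses within the clustering tolerance
  expect_lt(diff(range(asg$mass)), 1.5 + 20e-6 * M)
})

test_that("two interleaved envelopes separate into two mass clusters", {
  m1 <- 28166.8; m2 <- 28245.2
  z <- 8:13
  mz <- c((m1 + z * PROTON_MASS) / z, (m2 + z * PROTON_MASS) / z)
  sp <- ms_spectrum(mz, rep(10, length(mz)))
  asg <- assign_charges(sp, c(5, 20))$assigned
  expect_equal(nrow(asg), length(mz))
  centers <- sort(vapply(split(asg$mass, asg$species), mean, numeric(1)))
  expect_equal(as.numeric(centers), c(m1, m2), tolerance = 1e-3)
  # every peak sits in exactly one cluster
  expect_equal(anyDuplicated(asg$peak), 0)
})

test_that("noise-free deconvolution recovers the mass almost exactly", {
  cfg <- sim_config(mz_jitter_sd = 0, intensity_noise_sd = 0, seed = 1)
  sp <- simulate_intact_spectrum(list(list(id = "p", mass = 98696.0,
                                           abundance = 100)), cfg)
  d <- deconvolute(sp, c(10, 25))
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$neutral_mass - 98696.0), 0.1)
  expect_lt(d$mass_sd, 0.1)
  # intensity conservation: species intensity equals its member peaks
  expect_equal(d$total_intensity, sum(sp$peaks$intensity), tolerance = 1e-9)
})

test_that("jittered deconvolution stays within the propagated uncertainty", {
  ok <- 0; sds <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(mz_jitter_sd = 0.05, intensity_noise_sd = 0.1, seed = s)
    sp <- simulate_intact_spectrum(list(list(id = "p", mass = 98696.0,
                                             abundance = 100)), cfg)
    d <- deconvolute(sp, c(10, 25))
    if (nrow(d) && abs(d$neutral_mass[1] - 98696.0) <= 1.5) ok <- ok + 1
    sds[s] <- d$mass_sd[1]
  }
  expect_gte(ok, 19)
  # reported SD on the order of 1 Da (0.05 Th jitter at z ~ 13-20)
  expect_gt(stats::median(sds), 0.2)
  expect_lt(stats::median(sds), 3)
})

test_that("an MS2-like three-species mixture is fully resolved", {
  cfg <- sim_config(z_center = 10.5, z_sd = 1, mz_jitter_sd = 0.02, seed = 3)
  sp <- simulate_intact_spectrum(
    list(list(id = "A", mass = 28166.8, abundance = 50),
         list(id = "B", mass = 42221.6, abundance = 80, z_center = 12),
         list(id = "C", mass = 28245.2, abundance = 40)), cfg, "MS2")
  d <- deconvolute(sp, c(5, 20))
  expect_gte(nrow(d), 3)
  found <- vapply(c(28166.8, 42221.6, 28245.2), function(m)
    min(abs(d$neutral_mass - m)), numeric(1))
  expect_true(all(found < 1.5))
})

test_that("round trip over random masses and charge windows", {
  set.seed(99)
  for (k in 1:8) {
    M <- stats::runif(1, 20000, 200000)
    zc <- stats::runif(1, 10, 22)
    cfg <- sim_config(z_center = zc, z_sd = 1, mz_jitter_sd = 0.01,
                      intensity_noise_sd = 0.05, seed = k)
    sp <- simulate_intact_spectrum(list(list(id = "p", mass = M,
                                             abundance = 10)), cfg)
    d <- deconvolute(sp, c(5, 30))
    expect_gte(nrow(d), 1)
    expect_lt(abs(d$neutral_mass[1] - M), 3 * 0.01 * zc + 0.5)
  }
})

test_that("mass_range filtering and ranking honour their contracts", {
  cfg <- sim_config(mz_jitter_sd = 0, intensity_noise_sd = 0, seed = 2,
                    z_center = 12, z_sd = 1)
  sp <- simulate_intact_spectrum(
    list(list(id = "small", mass = 20000, abundance = 10),
         list(id = "big", mass = 90000, abundance = 90)), cfg)
  d <- deconvolute(sp, c(5, 25), mass_range = c(50000, 300000))
  expect_true(all(d$neutral_mass >= 50000))
  expect_equal(d$neutral_mass[1], 90000, tolerance = 0.1)
  expect_error(deconvolute(sp, c(5, 25), mass_range = c(10, -5)), "ordered")
  # no assignable envelope: empty result, not an error
  empty <- deconvolute(ms_spectrum(c(1000, 3000), c(1, 1)), c(5, 10))
  expect_equal(nrow(empty), 0)
})

test_that("periodic lipid-cluster series can be stripped before deconvolution", {
  cfg <- sim_config(mz_jitter_sd = 0, intensity_noise_sd = 0, seed = 6,
                    lipid_count = 12, lipid_intensity = 40)
  sp <- simulate_intact_spectrum(list(list(id = "p", mass = 98696.0,
                                           abundance = 100)), cfg)
  cleaned <- remove_periodic_series(sp, 760.08)
  expect_lt(nrow(cleaned$peaks), nrow(sp$peaks))
  d <- deconvolute(cleaned, c(10, 25))
  expect_lt(abs(d$neutral_mass[1] - 98696.0), 0.1)
})
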