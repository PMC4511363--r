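# A dense synthetic trace: Gaussian peak of known closed-form area.
gaussian_trace <- function(A = 1e5, mu = 10, sd = 0.1, offset = 0,
                           from = 8, to = 12, by = 0.01) {
  rt <- seq(from, to, by = by)
  data.frame(rt = rt, intensity = A * dnorm(rt, mu, sd) + offset)
}

test_that("XIC extraction windows in m/z and RT behave as configured", {
  scans <- lapply(seq(9, 11, by = 0.1), function(rt)
    list(rt = rt, mz = c(500.0, 500.5, 501.2),
         intensity = c(10, 20, 40) * rt))
  run <- spectrum_run(scans)
  tr <- extract_xic(run, xic_request(500.0, rt = 10, mz_width = 0.3,
                                     rt_width = 1))
  expect_true(all(tr$rt >= 9.5 & tr$rt <= 10.5))
  expect_equal(tr$intensity, 10 * tr$rt)       # only the 500.0 centroid
  # co-eluting species 0.5 Th away is excluded by the 0.3 Th window
  tr2 <- extract_xic(run, xic_request(500.5, rt = 10, rt_width = 1))
  expect_equal(tr2$intensity, 20 * tr2$rt)
  # a target 1 Th from all signal gives an all-zero trace
  tr3 <- extract_xic(run, xic_request(502.2, rt = 10, rt_width = 1))
  expect_true(all(tr3$intensity == 0))
})

test_that("XIC extraction is linear in scan intensities", {
  scans <- lapply(seq(9, 11, by = 0.05), function(rt)
    list(rt = rt, mz = 500, intensity = 100 * dnorm(rt, 10, 0.2)))
  run1 <- spectrum_run(scans)
  run2 <- spectrum_run(lapply(scans, function(s) {
    s$intensity <- 2 * s$intensity; s
  }))
  req <- xic_request(500, 10)
  t1 <- extract_xic(run1, req); t2 <- extract_xic(run2, req)
  expect_equal(t2$intensity, 2 * t1$intensity)
  expect_equal(integrate_peak(t2)$area, 2 * integrate_peak(t1)$area,
               tolerance = 1e-9)
})

test_that("peak integration recovers the closed-form Gaussian area", {
  A <- 5e4
  pk <- integrate_peak(gaussian_trace(A = A, sd = 0.1))
  expect_equal(pk$area, A, tolerance = 0.01)    # A*sd*sqrt(2*pi)/... = A here
  expect_equal(pk$apex_rt, 10, tolerance = 0.01)
  expect_true(pk$flag %in% c("ok", "edge-clipped"))
})

test_that("a constant offset is removed by the linear baseline", {
  A <- 5e4
  flat <- integrate_peak(gaussian_trace(A = A, sd = 0.1, offset = 0))
  raised <- integrate_peak(gaussian_trace(A = A, sd = 0.1, offset = 300))
  expect_equal(raised$area, flat$area, tolerance = 0.02)
})

test_that("flat and empty traces are flagged no-peak with zero area", {
  rt <- seq(8, 12, by = 0.01)
  zero <- integrate_peak(data.frame(rt = rt, intensity = rep(0, length(rt))))
  expect_equal(zero$flag, "no-peak")
  expect_equal(zero$area, 0)
  tiny <- integrate_peak(data.frame(rt = 1:2, intensity = c(0, 0)))
  expect_equal(tiny$flag, "no-peak")
})

test_that("ratio quantification scales with spike and is gain-invariant", {
  expect_equal(quantify_ratio(100, 100, 50), 50)
  expect_equal(quantify_ratio(200, 100, 50), 100)
  for (gain in c(0.1, 3, 1e4))
    expect_equal(quantify_ratio(200 * gain, 100 * gain, 50),
                 quantify_ratio(200, 100, 50), tolerance = 1e-12)
  expect_warning(out <- quantify_ratio(100, 0, 50), "no peak")
  expect_true(is.na(out))
  expect_error(quantify_ratio(1, 1, 0), "positive")
})

test_that("serum concentration follows the volume ledger", {
  expect_equal(serum_concentration(2.723, volume_ledger(0.1)), 27.23)
  base <- serum_concentration(5, volume_ledger(0.1, fractions = 1))
  half <- serum_concentration(5, volume_ledger(0.1, fractions = 0.5))
  expect_equal(half, 2 * base)
  expect_error(volume_ledger(0.1, fractions = 0), "fractions")
})

test_that("mass/molar concentration conversion matches the reference pair", {
  molar_mass <- 0.56 / 16.97 * 1e6      # fixed by the 0.56 <-> 16.97 pair
  expect_equal(mass_to_molar(0.56, molar_mass), 16.97, tolerance = 1e-6)
  expect_equal(mass_to_molar(2.3, molar_mass), 69.70, tolerance = 0.01)
  x <- 7.89
  expect_equal(molar_to_mass(mass_to_molar(x, 33000), 33000), x,
               tolerance = 1e-9)
})

test_that("noiseless simulated runs are quantified within 1%", {
  for (amt in c(10, 100)) {
    sp <- data.frame(sequence = "LLQALR", label = c("light", "heavy"),
                     charge = 2, amount_fmol = c(amt, 50), rt = 10)
    run <- simulate_run(run_spec(sp, seed = 1))
    q <- quantify_species(run, "LLQALR", 2, expected_rt = 10)
    expect_equal(q$analyte_fmol, amt, tolerance = 0.01)
  }
})

test_that("an absent endogenous analyte propagates as zero via no-peak", {
  sp <- data.frame(sequence = "LLQALR", label = "heavy", charge = 2,
                   amount_fmol = 50, rt = 10)
  run <- simulate_run(run_spec(sp, seed = 4))
  q <- quantify_species(run, "LLQALR", 2, expected_rt = 10)
  expect_equal(q$light_flag, "no-peak")
  expect_equal(q$analyte_fmol, 0)
})
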