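test_that("illuminance follows the 683 V(lambda) integral", {
  expect_equal(illuminance(spectrum(rep(0, 401))), 0)
  mono555 <- rep(0, 401); mono555[555 - 379] <- 1
  expect_equal(illuminance(spectrum(mono555)), 683)
  s <- mixed_led_spectrum("6ch", e_v = 250)
  expect_equal(illuminance(s), oracle_illuminance(as.numeric(s)),
               tolerance = 0.002)
  expect_error(spectrum(rep(1, 100)), "401")
  expect_error(spectrum(rep(1, 401), wavelengths = 400:800), "grid")
})

test_that("melanopic EDI matches the independent integration oracle", {
  expect_equal(melanopic_edi(spectrum(rep(0, 401))), 0)
  expect_equal(melanopic_edi(d65_spd(100)), 100, tolerance = 0.5 / 100)
  for (preset in c("6ch", "8ch", "11ch")) {
    s <- mixed_led_spectrum(preset)
    expect_equal(melanopic_edi(s), oracle_melanopic_edi(as.numeric(s)),
                 tolerance = 0.002)
  }
})

test_that("the derived melanopic D65 constant reproduces the published value", {
  expect_equal(ref_tables()$k_mel_d65, 1.3262e-3, tolerance = 0.01)
})

test_that("melanopic DER is 1 for D65 and scale invariant", {
  expect_equal(melanopic_der(d65_spd()), 1, tolerance = 0.002)
  expect_equal(melanopic_der(d65_spd(17)), 1, tolerance = 0.002)
  s <- mixed_led_spectrum("8ch")
  expect_identical(melanopic_der(spectrum(as.numeric(s) * 7.3)),
                   melanopic_der(s))
  # E_mel = E_v * gamma, the defining rearrangement
  expect_equal(melanopic_edi(s), illuminance(s) * melanopic_der(s))
  expect_error(melanopic_der(spectrum(rep(0, 401))), "illuminance")
})

test_that("melanopic EDI is linear in the spectrum", {
  set.seed(4)
  s1 <- abs(stats::rnorm(401)); s2 <- abs(stats::rnorm(401))
  lhs <- melanopic_edi(spectrum(2.5 * s1 + 0.3 * s2))
  rhs <- 2.5 * melanopic_edi(spectrum(s1)) + 0.3 * melanopic_edi(spectrum(s2))
  expect_equal(lhs, rhs)
})

test_that("chromaticity reproduces the standard anchors", {
  ee <- chromaticity(spectrum(rep(0.01, 401)))
  expect_equal(ee$x, 1 / 3, tolerance = 1e-3)
  expect_equal(ee$y, 1 / 3, tolerance = 1e-3)
  d <- chromaticity(d65_spd())
  expect_equal(d$x, 0.3127, tolerance = 0.001 / 0.3127)
  expect_equal(d$y, 0.3290, tolerance = 0.001 / 0.3290)
  s <- mixed_led_spectrum("11ch")
  expect_identical(chromaticity(s),
                   chromaticity(spectrum(as.numeric(s) * 4)))
  expect_error(chromaticity(spectrum(rep(0, 401))), "degenerate")
})

test_that("rescaling hits the target illuminance and preserves DER", {
  s <- mixed_led_spectrum("6ch", e_v = 100)
  r <- rescale_to_illuminance(s, 250)
  expect_equal(illuminance(r), 250)
  expect_equal(melanopic_der(r), melanopic_der(s))
  expect_equal(as.numeric(rescale_to_illuminance(s, illuminance(s))),
               as.numeric(s))
  ch1 <- chromaticity(s); ch2 <- chromaticity(r)
  expect_equal(ch1$u_prime, ch2$u_prime)
  expect_error(rescale_to_illuminance(spectrum(rep(0, 401)), 250), "zero")
})

test_that("spectra round-trip through the wide CSV format", {
  sp <- list(a = mixed_led_spectrum("6ch"), b = d65_spd(250))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path)
  expect_named(back, c("a", "b"))
  expect_equal(as.numeric(back$a), as.numeric(sp$a), tolerance = 1e-8)
})
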