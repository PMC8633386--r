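test_that("gaussian primaries peak where stated and carry unit power", {
  ch <- gaussian_primary(521, 20)
  v <- as.numeric(ch$spd)
  expect_equal(wl_grid()[which.max(v)], 521)
  expect_equal(sum(v), 1)           # unit radiometric power at full drive
  expect_lt(max(v[c(1, 401)]), 1e-6)  # negligible truncation for mid-grid peaks
  expect_error(gaussian_primary(379, 20), "grid")
  expect_error(gaussian_primary(800, 20), "grid")
  # narrowband limit: a 555 nm primary lands close to the spectrum locus
  ch555 <- chromaticity(gaussian_primary(555, 20)$spd)
  mono <- rep(0, 401); mono[555 - 379] <- 1
  chm <- chromaticity(spectrum(mono))
  expect_lt(abs(ch555$u_prime - chm$u_prime), 0.01)
  expect_lt(abs(ch555$v_prime - chm$v_prime), 0.01)
})

test_that("phosphor whites hit their target CCT close to the locus", {
  for (cct in c(2740, 4655)) {
    w <- phosphor_white(cct)
    expect_lt(abs(w$cct - cct), 50)
    expect_lt(abs(w$duv), 0.005)
    w2 <- phosphor_white(cct)
    expect_identical(as.numeric(w$spd), as.numeric(w2$spd))  # deterministic
  }
})

test_that("presets contain the stated channel rosters", {
  l6 <- build_luminaire("6ch"); l8 <- build_luminaire("8ch")
  l11 <- build_luminaire("11ch")
  expect_length(l6$channels, 6)
  expect_length(l8$channels, 8)
  expect_length(l11$channels, 11)
  peaks <- function(l) vapply(Filter(function(c) c$kind == "narrowband",
                                     l$channels), `[[`, 0, "peak_nm")
  expect_equal(peaks(l6), c(475, 504, 521, 662))
  expect_equal(peaks(l8), c(450, 465, 504, 521, 638, 662))
  expect_equal(peaks(l11), c(419, 450, 457, 504, 521, 597, 638, 662))
  expect_equal(sum(vapply(l11$channels, `[[`, "", "kind") == "phosphor_lime"), 1)
  # the two whites are the same objects across presets
  expect_identical(l6$primaries[, "white2740"], l11$primaries[, "white2740"])
  expect_identical(l6$primaries[, "white4655"], l8$primaries[, "white4655"])
})

test_that("mixing is additive and validated", {
  lum <- build_luminaire("8ch")
  n <- length(lum$channels)
  expect_equal(as.numeric(mix(lum, rep(0, n))), rep(0, 401))
  onehot <- replace(rep(0, n), 3, 1)
  expect_equal(as.numeric(mix(lum, onehot)),
               as.numeric(lum$channels[[3]]$spd))
  w1 <- rep(0.2, n); w2 <- rep(0.3, n)
  expect_equal(as.numeric(mix(lum, w1)) + as.numeric(mix(lum, w2)),
               as.numeric(mix(lum, w1 + w2)))
  expect_error(mix(lum, rep(0.5, n - 1)), "weights")
  expect_error(mix(lum, replace(rep(0.5, n), 1, 1.2)), "0, 1")
  # channel-level photometric linearity
  ev_ch <- vapply(seq_len(n), function(i)
    illuminance(mix(lum, replace(rep(0, n), i, 1))), 0)
  w <- seq(0.1, 0.8, length.out = n)
  expect_equal(illuminance(mix(lum, w)), sum(w * ev_ch))
})

test_that("random feasible targets are deterministic and in-gamut", {
  lum <- build_luminaire("6ch")
  a <- random_feasible_target(lum, 123)
  b <- random_feasible_target(lum, 123)
  expect_identical(a, b)
  expect_equal(illuminance(mix(lum, a$weights)), 220)
  duvs <- vapply(1:25, function(i)
    random_feasible_target(lum, i)$target$duv, 0)
  expect_true(all(is.na(duvs) | abs(duvs) <= 0.05))
})
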