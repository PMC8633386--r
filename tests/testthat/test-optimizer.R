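# shared fixtures: keep the search sizes modest, the contracts don't
# depend on them
small_settings <- optimizer_settings(generations = 120, max_archive = 300)

test_that("the harvest is reproducible and grows with repetitions", {
  lum <- build_luminaire("8ch")
  tg <- build_grid(n_cct = 1, cct_range = c(4200, 4200), duv_max = 0)
  r1 <- optimize_target(lum, tg[1, ], seed = 5, repetitions = 2,
                        settings = small_settings)
  r2 <- optimize_target(lum, tg[1, ], seed = 5, repetitions = 2,
                        settings = small_settings)
  expect_identical(r1$weights, r2$weights)
  r4 <- optimize_target(lum, tg[1, ], seed = 5, repetitions = 4,
                        settings = small_settings)
  expect_gte(r4$n_feasible, r1$n_feasible)
  # the first repetitions of the longer run are the same searches
  expect_identical(r4$weights[seq_len(r1$n_feasible), ], r1$weights)
})

test_that("every archived solution satisfies the working constraints", {
  lum <- build_luminaire("11ch")
  tg <- build_grid(n_cct = 1, cct_range = c(5000, 5000), duv_max = 0.003)
  run <- optimize_target(lum, tg[2, ], seed = 3, repetitions = 2,
                         settings = small_settings)
  expect_gt(run$n_feasible, 0)
  for (i in seq_len(min(run$n_feasible, 50))) {
    s <- mix(lum, run$weights[i, ])
    ch <- chromaticity(s)
    expect_lte(abs(ch$u_prime - tg$u_prime[2]), 0.001)
    expect_lte(abs(ch$v_prime - tg$v_prime[2]), 0.001)
    expect_lte(abs(illuminance(s) - 220), 2)
  }
})

test_that("a mid-gamut 11-channel target yields a rich metamer set", {
  lum <- build_luminaire("11ch")
  tg <- build_grid(n_cct = 1, cct_range = c(4500, 4500), duv_max = 0)
  run <- optimize_target(lum, tg[1, ], seed = 1, repetitions = 8)
  ms <- filter_metamers(run)
  expect_gte(ms$n, 50)
})

test_that("targets outside the additive gamut come back infeasible", {
  lum <- build_luminaire("6ch")
  mono <- rep(0, 401); mono[520 - 379] <- 1    # spectrum-locus point
  ch <- chromaticity(spectrum(mono))
  tg <- data.frame(cct_K = NA, duv = NA, u_prime = ch$u_prime,
                   v_prime = ch$v_prime, x = ch$x, y = ch$y,
                   cct_level = 1L, duv_level = 0L)
  run <- optimize_target(lum, tg, seed = 2, repetitions = 2,
                         settings = small_settings)
  expect_true(run$infeasible)
  expect_equal(filter_metamers(run)$n, 0L)
})

test_that("feasible-by-construction targets are recovered", {
  lum <- build_luminaire("11ch")
  for (i in 1:5) {
    rt <- random_feasible_target(lum, seed = 100 + i)
    run <- optimize_target(lum, rt$target, seed = 200 + i, repetitions = 2,
                           settings = small_settings)
    expect_gte(run$n_feasible, 1)
  }
})

test_that("enforce_channel_limit zeroes the smallest weights, idempotently", {
  w <- c(0.9, 0.05, 0.4, 0.02, 0.6, 0.3, 0.08, 0.7, 0.1, 0.2, 0.5)
  expect_identical(enforce_channel_limit(w, 11), w)
  w9 <- enforce_channel_limit(w, 9)
  expect_equal(sum(w9 > 0), 9)
  expect_equal(which(w9 == 0), c(2, 4))       # the two smallest dropped
  expect_identical(enforce_channel_limit(w9, 9), w9)
  lum <- build_luminaire("11ch", max_active = 7)
  tg <- build_grid(n_cct = 1, cct_range = c(4500, 4500), duv_max = 0)
  run <- optimize_target(lum, tg[1, ], seed = 9, repetitions = 2,
                         settings = small_settings)
  if (run$n_feasible > 0)
    expect_true(all(rowSums(run$weights > 0) <= 7))
})

test_that("filter_metamers matches a brute-force filter and rescales exactly", {
  lum <- build_luminaire("6ch")
  tg <- build_grid(n_cct = 1, cct_range = c(4000, 4000), duv_max = 0)[1, ]
  # synthetic archive: perturb a feasible solution by random weight noise so
  # some members drift out of tolerance
  base <- optimize_target(lum, tg, seed = 8, repetitions = 2,
                          settings = small_settings)
  expect_gt(base$n_feasible, 10)
  set.seed(42)
  W <- base$weights[sample(base$n_feasible, 50, replace = TRUE), ] +
    matrix(stats::rnorm(50 * 6, sd = 0.01), 50, 6)
  W[W < 0] <- 0; W[W > 1] <- 1
  run <- base; run$weights <- W; run$n_feasible <- nrow(W)
  run$infeasible <- FALSE
  ms <- filter_metamers(run)
  # oracle: per-member scalar recheck
  keep <- logical(50)
  for (i in 1:50) {
    ch <- chromaticity(mix(lum, W[i, ]))
    keep[i] <- abs(ch$u_prime - tg$u_prime) <= 0.001 &
      abs(ch$v_prime - tg$v_prime) <= 0.001
  }
  expect_equal(ms$n, sum(keep))
  if (ms$n > 0) {
    ev <- 683 * colSums(ms$spectra * ref_tables()$vlambda)
    expect_equal(ev, rep(250, ms$n), tolerance = 1e-12)
    expect_true(all(abs(ms$metrics$du_prime) <= 0.001))
    expect_true(all(abs(ms$metrics$dv_prime) <= 0.001))
  }
})
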