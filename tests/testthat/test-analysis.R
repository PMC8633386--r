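test_that("Michelson contrast reproduces the worked pairs", {
  expect_equal(michelson_contrast(181, 271), 90 / 452)
  expect_equal(round(michelson_contrast(181, 271), 2), 0.20)
  expect_equal(michelson_contrast(135, 185), 0.15625)
  expect_equal(round(michelson_contrast(135, 185), 2), 0.16)
  expect_equal(round(michelson_contrast(115, 165), 2), 0.18)
  expect_equal(michelson_contrast(120, 120), 0)
  expect_error(michelson_contrast(0, 0), "undefined")
  expect_error(michelson_contrast(200, 100))
  # invariance under common scaling, monotone in the maximum
  expect_equal(michelson_contrast(181 * 3, 271 * 3),
               michelson_contrast(181, 271))
  expect_gt(michelson_contrast(181, 280), michelson_contrast(181, 271))
})

test_that("DER tuning ranges convert to lx at a given illuminance", {
  expect_equal(delta_e_at_lux(0.236, 250), 59)
  expect_equal(delta_e_at_lux(0.25, 250), 62.5)
  expect_equal(delta_e_at_lux(0.4, 0), 0)
  expect_equal((185 - 135) / 250, 0.2)  # the worked pair as a DER range
  expect_equal(0.8 * 500, 400)          # DER to EDI at 500 lx
})

make_fake_set <- function(e_mel, target = NULL) {
  if (is.null(target))
    target <- data.frame(cct_K = 4000, duv = 0, u_prime = 0.22,
                         v_prime = 0.49, x = 0.38, y = 0.38,
                         cct_level = 1L, duv_level = 0L)
  n <- length(e_mel)
  structure(list(target = target, luminaire = "8ch", n = n,
                 weights = matrix(0.5, n, 8),
                 spectra = matrix(1, 401, n),
                 metrics = data.frame(e_v = rep(250, n), e_mel = e_mel,
                                      gamma_mel = e_mel / 250,
                                      u_prime = target$u_prime,
                                      v_prime = target$v_prime,
                                      du_prime = 0, dv_prime = 0)),
            class = "metamer_set")
}

test_that("target summaries match an exhaustive scan", {
  set.seed(31)
  em <- stats::runif(100, 100, 300)
  s <- summarize_target(make_fake_set(em))
  expect_equal(s$e_mel_min, min(em))
  expect_equal(s$e_mel_max, max(em))
  expect_equal(s$delta_e_mel, abs(max(em) - min(em)))
  expect_equal(s$delta_gamma, s$delta_e_mel / 250)
  expect_equal(s$delta_e_mel, 250 * s$delta_gamma)
  expect_equal(s$c_m, (max(em) - min(em)) / (max(em) + min(em)))
  # worked pair: extremes 181 and 271 lx give a 90 lx tuning range
  s2 <- summarize_target(make_fake_set(c(181, 220, 271)))
  expect_equal(s2$delta_e_mel, 90)
  single <- summarize_target(make_fake_set(200))
  expect_equal(single$delta_gamma, 0)
  expect_equal(single$c_m, 0)
  empty <- make_fake_set(1); empty$n <- 0L
  expect_null(summarize_target(empty))
})

test_that("per-CCT aggregates pick extremes and argmax Duv independently", {
  tgt <- function(lvl, duv, dlvl) data.frame(
    cct_K = 2901, duv = duv, u_prime = 0.25, v_prime = 0.51,
    x = 0.44, y = 0.4, cct_level = lvl, duv_level = dlvl)
  rows <- rbind(
    summarize_target(make_fake_set(c(126, 185), tgt(1, -0.039, -13))),
    summarize_target(make_fake_set(c(120, 179), tgt(1, -0.018, -6))),
    summarize_target(make_fake_set(c(130, 160), tgt(1, 0, 0))))
  # plant the example structure: gamma_hat_max at one Duv, largest tuning
  # range at another
  rows$gamma_max[1] <- 0.74; rows$delta_gamma[1] <- 0.236
  rows$gamma_max[2] <- 0.71; rows$delta_gamma[2] <- 0.29
  cs <- summarize_cct(rows)
  expect_equal(cs$gamma_hat_max, 0.74)
  expect_equal(cs$duv_at_gamma_max, -0.039)
  expect_equal(cs$delta_gamma_tilde, 0.29)
  expect_equal(cs$duv_at_delta_gamma, -0.018)
  expect_equal(cs$gamma_hat_min, min(rows$gamma_min))
  # random grouped summaries match a brute-force group scan
  set.seed(7)
  big <- do.call(rbind, lapply(1:4, function(lvl)
    do.call(rbind, lapply(-3:3, function(d)
      summarize_target(make_fake_set(stats::runif(5, 100, 280),
                                     tgt(lvl, d * 0.003, d)))))))
  cs2 <- summarize_cct(big)
  for (lvl in 1:4) {
    g <- big[big$cct_level == lvl, ]
    expect_equal(cs2$gamma_hat_max[cs2$cct_level == lvl], max(g$gamma_max))
    expect_equal(cs2$delta_gamma_tilde[cs2$cct_level == lvl],
                 max(g$delta_gamma))
  }
})

test_that("atlas interpolation is node-exact and bounded by the data", {
  # synthetic 4 x 5 structured layout with irregular xy positions
  set.seed(12)
  rows <- list()
  for (ci in 1:4) for (di in 1:5) {
    t <- data.frame(cct_K = 3000 + 500 * ci, duv = 0.003 * (di - 3),
                    u_prime = 0.2, v_prime = 0.48,
                    x = 0.30 + 0.02 * ci + 0.002 * di,
                    y = 0.32 + 0.015 * di + 0.001 * ci,
                    cct_level = ci, duv_level = di - 3L)
    rows[[length(rows) + 1]] <-
      summarize_target(make_fake_set(stats::runif(4, 120, 260), t))
  }
  summaries <- do.call(rbind, rows)
  vals <- metamel:::.atlas_interp(summaries, summaries$x, summaries$y,
                                  c("delta_gamma", "c_m"))
  expect_equal(vals$delta_gamma, summaries$delta_gamma, tolerance = 1e-9)
  expect_equal(vals$c_m, summaries$c_m, tolerance = 1e-9)
  atlas <- build_atlas(summaries, raster_n = 60)
  expect_lte(max(atlas$raster$delta_gamma, na.rm = TRUE),
             max(summaries$delta_gamma) + 1e-12)
  expect_equal(atlas$maxima$value[atlas$maxima$metric == "delta_gamma"],
               max(summaries$delta_gamma))
  expect_equal(atlas$maxima$value[atlas$maxima$metric == "c_m"],
               max(summaries$c_m))
  # constant field interpolates to the constant
  summaries$delta_gamma <- 0.2
  flat <- build_atlas(summaries, raster_n = 40)
  vv <- flat$raster$delta_gamma[!is.na(flat$raster$delta_gamma)]
  expect_equal(vv, rep(0.2, length(vv)), tolerance = 1e-12)
})
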