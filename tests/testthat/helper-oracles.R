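# Independent oracles used across the suite.  They deliberately avoid the
# package's integration/search code paths: trapezoid instead of rectangle
# integration, exhaustive table search instead of parabolic refinement,
# plain scalar loops instead of the vectorised colour-appearance pipeline.

trapz <- function(y, dx = 1) dx * (sum(y) - (y[1] + y[length(y)]) / 2)

# illuminance / melanopic EDI by trapezoid integration (the conversion
# constant is itself re-derived with the trapezoid rule)
oracle_illuminance <- function(values) {
  tab <- ref_tables()
  683 * trapz(tab$vlambda * values)
}

oracle_melanopic_edi <- function(values) {
  tab <- ref_tables()
  k <- trapz(tab$smel * tab$d65) / (683 * trapz(tab$ybar * tab$d65))
  trapz(tab$smel * values) / k
}

# brute-force CCT/Duv: nearest point on a 1 K resolution Planckian table
# in the CIE 1960 uv space
oracle_cct_duv <- function(u_prime, v_prime) {
  tab <- ref_tables()
  if (is.null(.oracle_env$planck_1k)) {
    temps <- seq(1500, 12000, by = 1)
    lam <- wl_grid() * 1e-9
    M <- outer(lam^-5, rep(1, length(temps))) /
      (exp(outer(1.4388e-2 / lam, 1 / temps)) - 1)
    X <- colSums(M * tab$xbar); Y <- colSums(M * tab$ybar)
    Z <- colSums(M * tab$zbar)
    den <- X + 15 * Y + 3 * Z
    .oracle_env$planck_1k <- list(t = temps, u = 4 * X / den, v = 6 * Y / den)
  }
  loc <- .oracle_env$planck_1k
  u <- u_prime; v <- 2 / 3 * v_prime
  d <- sqrt((loc$u - u)^2 + (loc$v - v)^2)
  i <- which.min(d)
  list(cct = loc$t[i], duv = sign(v - loc$v[i]) * d[i])
}
.oracle_env <- new.env()

# scalar re-implementation of the fidelity score: per-sample loops, its own
# CAM02 constants and its own tristimulus sums; shares only the bundled
# tables, the evaluation samples and the reference-illuminant definition
oracle_fidelity_rf <- function(spd_values, cct) {
  tab <- ref_tables()
  R <- fidelity_samples()
  ref_values <- as.numeric(fidelity_reference(cct))
  Mcat <- matrix(c(0.7328, 0.4296, -0.1624,
                   -0.7036, 1.6975, 0.0061,
                   0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
  Mhpe <- matrix(c(0.38971, 0.68898, -0.07868,
                   -0.22981, 1.18340, 0.04641,
                   0, 0, 1), 3, 3, byrow = TRUE)
  M2 <- Mhpe %*% solve(Mcat)
  FL <- 0.2 * (1 / 501)^4 * 500 + 0.1 * (1 - (1 / 501)^4)^2 * 500^(1 / 3)
  n <- 0.2; Nbb <- 0.725 * 5^0.2; z <- 1.48 + sqrt(n)
  D <- 1 - (1 / 3.6) * exp(-142 / 92)
  cam <- function(illum) {
    kN <- 100 / sum(tab$ybar * illum)
    xyz_w <- kN * c(sum(tab$xbar * illum), sum(tab$ybar * illum),
                    sum(tab$zbar * illum))
    rgb_w <- as.numeric(Mcat %*% xyz_w)
    dfac <- 100 * D / rgb_w + 1 - D
    press <- function(q) {
      qq <- (abs(q) * FL / 100)^0.42
      sign(q) * 400 * qq / (27.13 + qq) + 0.1
    }
    rw <- press(as.numeric(M2 %*% (dfac * rgb_w)))
    Aw <- (2 * rw[1] + rw[2] + rw[3] / 20 - 0.305) * Nbb
    res <- matrix(0, ncol(R), 3)
    for (j in seq_len(ncol(R))) {
      xyz <- kN * c(sum(tab$xbar * illum * R[, j]),
                    sum(tab$ybar * illum * R[, j]),
                    sum(tab$zbar * illum * R[, j]))
      rgb <- press(as.numeric(M2 %*% (dfac * as.numeric(Mcat %*% xyz))))
      a <- rgb[1] - 12 * rgb[2] / 11 + rgb[3] / 11
      b <- (rgb[1] + rgb[2] - 2 * rgb[3]) / 9
      h <- atan2(b, a)
      A <- (2 * rgb[1] + rgb[2] + rgb[3] / 20 - 0.305) * Nbb
      J <- 100 * max(A / Aw, 0)^(0.69 * z)
      et <- 0.25 * (cos(h + 2) + 3.8)
      tt <- (50000 / 13 * Nbb * et * sqrt(a^2 + b^2)) /
        (rgb[1] + rgb[2] + 21 * rgb[3] / 20)
      C <- max(tt, 0)^0.9 * sqrt(J / 100) * (1.64 - 0.29^n)^0.73
      M <- C * FL^0.25
      Jp <- 1.7 * J / (1 + 0.007 * J)
      Mp <- log(1 + 0.0228 * M) / 0.0228
      res[j, ] <- c(Jp, Mp * cos(h), Mp * sin(h))
    }
    res
  }
  ct <- cam(spd_values); cr <- cam(ref_values)
  dE <- sqrt(rowSums((ct - cr)^2))
  10 * log(exp((100 - 6.73 * mean(dE)) / 10) + 1)
}

# a reproducible polychromatic LED test spectrum
mixed_led_spectrum <- function(preset = "6ch", weights = NULL, e_v = 250) {
  lum <- build_luminaire(preset)
  if (is.null(weights))
    weights <- seq(0.2, 0.7, length.out = length(lum$channels))
  rescale_to_illuminance(mix(lum, weights), e_v)
}
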