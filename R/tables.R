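# Bundled reference tables and physical spectra.
#
# All tables are resampled to the fixed 380..780 nm, 1 nm working grid
# (401 samples).  The 5 nm source tabulations are expanded by linear
# interpolation, the conventional practice for the CIE 1931 data.

.metamel <- new.env(parent = emptyenv())

#' The fixed wavelength grid
#'
#' Every spectrum handled by the package lives on the same 380--780 nm grid
#' with 1 nm spacing (401 samples).
#'
#' @return Integer vector of wavelengths in nm.
#' @export
#' @examples
#' length(wl_grid())
wl_grid <- function() 380:780

.grid_n <- 401L

#' Bundled reference tables
#'
#' Returns the colourimetric and melanopic reference tables used throughout
#' the package, resampled to [wl_grid()]:
#'
#' * `xbar`, `ybar`, `zbar`: CIE 1931 2-degree colour-matching functions;
#' * `vlambda`: photopic luminous efficiency V(lambda) (identical to `ybar`,
#'   with V(555 nm) = 1);
#' * `smel`: melanopic action spectrum, peak-normalised to 1 (see
#'   [melanopic_sensitivity()]);
#' * `d65`: relative spectral power distribution of CIE standard illuminant
#'   D65 (100 at 560 nm);
#' * `k_mel_d65`: the melanopic D65 conversion constant in W m-2 lx-1,
#'   derived from the bundled tables so that the melanopic daylight efficacy
#'   ratio of D65 is exactly 1 (the published value is 1.3262e-3);
#' * `version`: provenance string recorded in output metadata.
#'
#' @return A list with the components described above.
#' @export
ref_tables <- function() {
  if (!is.null(.metamel$tables)) return(.metamel$tables)
  wl <- wl_grid()
  cmf_path <- system.file("extdata", "cie1931_cmf_2deg_5nm.csv",
                          package = "metamel", mustWork = TRUE)
  d65_path <- system.file("extdata", "cie_d65_5nm.csv",
                          package = "metamel", mustWork = TRUE)
  cmf <- utils::read.csv(cmf_path)
  d65 <- utils::read.csv(d65_path)
  xbar <- stats::approx(cmf$wavelength_nm, cmf$xbar, wl)$y
  ybar <- stats::approx(cmf$wavelength_nm, cmf$ybar, wl)$y
  zbar <- stats::approx(cmf$wavelength_nm, cmf$zbar, wl)$y
  d65v <- stats::approx(d65$wavelength_nm, d65$spd, wl)$y
  smel <- melanopic_sensitivity(wl)
  # Melanopic irradiance of D65 per lx of D65: the defining calibration of
  # the melanopic equivalent daylight illuminance (DER of D65 == 1).
  k_mel <- sum(smel * d65v) / (683 * sum(ybar * d65v))
  .metamel$tables <- list(
    wl = wl, xbar = xbar, ybar = ybar, zbar = zbar,
    vlambda = ybar, smel = smel, d65 = d65v, k_mel_d65 = k_mel,
    version = "CIE1931-2deg-5nm/CIE15-D65-5nm/melanopic-nomogram-480nm-age32"
  )
  .metamel$tables
}

#' Melanopic action spectrum
#'
#' Constructs the melanopic spectral sensitivity on an arbitrary wavelength
#' grid from first principles: the Govardovskii et al. (2000) vitamin-A1
#' opsin nomogram with peak absorbance at 480 nm (quantal sensitivity),
#' converted to an energy basis and filtered by the ocular-media spectral
#' transmittance of a 32-year-old standard observer (van de Kraats & van
#' Norren 2007 lens/media model).  The result is peak-normalised to 1 and
#' peaks near 490 nm, matching the tabulated melanopic action spectrum of
#' CIE S 026 to within a fraction of a percent in the D65 closure (see
#' `ref_tables()$k_mel_d65`).
#'
#' @param wl Wavelength vector in nm (default the package grid).
#' @return Numeric vector of dimensionless sensitivities, max 1.
#' @export
melanopic_sensitivity <- function(wl = wl_grid()) {
  lmax <- 480
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  beta <- 0.26 * exp(-((wl - (189 + 0.315 * lmax)) / (-40.5 + 0.195 * lmax))^2)
  quantal <- alpha + beta
  tau <- 10^(-.ocular_media_density(wl, age = 32))
  s <- quantal * tau * wl   # quantal -> energy basis
  s / max(s)
}

# Optical density of the ocular media (lens + other pre-retinal media) for a
# standard observer of the given age; van de Kraats & van Norren (2007).
.ocular_media_density <- function(wl, age = 32) {
  d_rl   <- (0.446 + 0.000031 * age^2) * (400 / wl)^4
  d_tp   <- 14.19 * 10.68 * exp(-(0.057 * (wl - 273))^2)
  d_ly   <- (0.998 - 0.000063 * age^2) * 2.13 * exp(-(0.029 * (wl - 370))^2)
  d_louv <- (0.059 + 0.000186 * age^2) * 11.95 * exp(-(0.021 * (wl - 325))^2)
  d_lo   <- (0.016 + 0.000132 * age^2) * 1.43 * exp(-(0.008 * (wl - 325))^2) + 0.111
  d_rl + d_tp + d_ly + d_louv + d_lo
}

#' Blackbody (Planckian) radiator spectrum
#'
#' Spectral radiant exitance of a blackbody at temperature `temp_K` on the
#' working grid, by Planck's law with c2 = 1.4388e-2 m K.  The absolute
#' scale is arbitrary for colourimetric use; values are normalised so the
#' maximum over the grid is 1.
#'
#' @param temp_K Temperature in kelvin (scalar, > 0).
#' @return A [spectrum()] object.
#' @export
#' @examples
#' cct_duv_of(planck_spd(3000))
planck_spd <- function(temp_K) {
  stopifnot(is.numeric(temp_K), length(temp_K) == 1L, temp_K > 0)
  lam <- wl_grid() * 1e-9
  c1 <- 3.741771e-16   # W m^2
  c2 <- 1.4388e-2      # m K
  m <- c1 / (lam^5 * (exp(c2 / (lam * temp_K)) - 1))
  spectrum(m / max(m))
}

#' D65 reference spectrum
#'
#' The bundled CIE standard illuminant D65, optionally rescaled to a given
#' photopic illuminance.
#'
#' @param illuminance_lx If not `NULL`, rescale so that [illuminance()]
#'   equals this value (lx).
#' @return A [spectrum()] object.
#' @export
#' @examples
#' melanopic_der(d65_spd())  # 1 by calibration
d65_spd <- function(illuminance_lx = NULL) {
  s <- spectrum(ref_tables()$d65)
  if (!is.null(illuminance_lx)) s <- rescale_to_illuminance(s, illuminance_lx)
  s
}

#' CIE daylight-series spectrum
#'
#' Reconstructs the relative spectral power distribution of a CIE daylight
#' phase at correlated colour temperature `cct` from the daylight
#' chromaticity locus (closed form) and the characteristic vectors S1/S2.
#' The mean vector S0 is anchored to the bundled D65 table (S0 = D65 -
#' M1(D65) S1 - M2(D65) S2), so `daylight_spd(6504)` reproduces D65 itself.
#'
#' @param cct Correlated colour temperature in kelvin, 4000--25000.
#' @return A [spectrum()] object (relative SPD).
#' @export
daylight_spd <- function(cct) {
  stopifnot(is.numeric(cct), length(cct) == 1L, cct >= 4000, cct <= 25000)
  tab <- .daylight_vectors()
  m <- .daylight_m(cct)
  spectrum(pmax(tab$s0 + m[1] * tab$s1 + m[2] * tab$s2, 0))
}

# Daylight-locus chromaticity and the M1/M2 weights (CIE 15 closed forms).
.daylight_xy <- function(cct) {
  t3 <- 1e9 / cct^3; t2 <- 1e6 / cct^2; t1 <- 1e3 / cct
  x <- if (cct <= 7000) {
    -4.6070 * t3 + 2.9678 * t2 + 0.09911 * t1 + 0.244063
  } else {
    -2.0064 * t3 + 1.9018 * t2 + 0.24748 * t1 + 0.237040
  }
  y <- -3.000 * x^2 + 2.870 * x - 0.275
  c(x = x, y = y)
}

.daylight_m <- function(cct) {
  xy <- .daylight_xy(cct)
  den <- 0.0241 + 0.2562 * xy[1] - 0.7341 * xy[2]
  c((-1.3515 - 1.7703 * xy[1] + 5.9114 * xy[2]) / den,
    (0.0300 - 31.4424 * xy[1] + 30.0717 * xy[2]) / den)
}

.daylight_vectors <- function() {
  if (!is.null(.metamel$dayvec)) return(.metamel$dayvec)
  wl <- wl_grid()
  p <- system.file("extdata", "cie_daylight_s1s2_10nm.csv",
                   package = "metamel", mustWork = TRUE)
  tab <- utils::read.csv(p)
  s1 <- stats::approx(tab$wavelength_nm, tab$s1, wl)$y
  s2 <- stats::approx(tab$wavelength_nm, tab$s2, wl)$y
  m65 <- .daylight_m(6504)
  s0 <- ref_tables()$d65 - m65[1] * s1 - m65[2] * s2
  .metamel$dayvec <- list(s0 = s0, s1 = s1, s2 = s2)
  .metamel$dayvec
}
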