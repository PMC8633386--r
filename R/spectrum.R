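# The spectrum container and the scalar metrics attached to it.

#' Create a spectrum
#'
#' A spectrum is a spectral irradiance distribution on the fixed package
#' grid ([wl_grid()], 380--780 nm, 1 nm, 401 samples), in W m-2 nm-1.
#' Values must be non-negative and finite.
#'
#' @param values Numeric vector of length 401 (or a `spectrum` object,
#'   returned unchanged).
#' @param wavelengths Wavelength vector; must equal `wl_grid()`.  Present so
#'   that callers holding external data fail loudly on a grid mismatch
#'   rather than silently misaligning.
#' @return An object of class `spectrum`: the numeric vector with the grid
#'   attached as an attribute.
#' @export
#' @examples
#' s <- spectrum(rep(0.01, 401))
#' illuminance(s)
spectrum <- function(values, wavelengths = wl_grid()) {
  if (inherits(values, "spectrum")) return(values)
  if (!identical(as.integer(wavelengths), as.integer(wl_grid())))
    stop("spectrum grid mismatch: expected the fixed 380..780 nm, 1 nm grid",
         call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != .grid_n)
    stop("spectrum must have 401 samples (380..780 nm at 1 nm)", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(values < 0)) {
    if (min(values) < -1e-12) stop("spectrum values must be >= 0", call. = FALSE)
    values[values < 0] <- 0
  }
  structure(values, class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> 380-780 nm, 1 nm;",
      sprintf("E_v = %.4g lx, melanopic EDI = %.4g lx\n",
              illuminance(x), melanopic_edi(x)))
  invisible(x)
}

.spd_values <- function(spd) as.numeric(spectrum(spd))

#' Photopic illuminance
#'
#' Illuminance in lx by the rectangle rule on the 1 nm grid:
#' 683 lm/W x sum V(lambda) X(lambda) d(lambda).
#'
#' @param spd A [spectrum()].
#' @return Illuminance in lx (>= 0).
#' @export
illuminance <- function(spd) {
  683 * sum(ref_tables()$vlambda * .spd_values(spd))
}

#' Melanopic equivalent daylight illuminance (melanopic EDI)
#'
#' The illuminance of standard daylight D65 that produces the same melanopic
#' irradiance as the test spectrum: the melanopic irradiance
#' sum s_mel(lambda) X(lambda) d(lambda) divided by the melanopic irradiance
#' of D65 per lx of D65.  That conversion constant is derived from the
#' bundled tables (`ref_tables()$k_mel_d65`; published value 1.3262e-3
#' W m-2 lx-1), which makes the melanopic DER of D65 exactly 1.
#'
#' @param spd A [spectrum()].
#' @return Melanopic EDI in lx (>= 0).
#' @export
melanopic_edi <- function(spd) {
  tab <- ref_tables()
  sum(tab$smel * .spd_values(spd)) / tab$k_mel_d65
}

#' Melanopic daylight efficacy ratio (melanopic DER)
#'
#' The ratio of melanopic EDI to photopic illuminance.  Dimensionless,
#' invariant under positive scaling of the spectrum, and 1 for D65.
#'
#' @param spd A [spectrum()].
#' @return Melanopic DER.
#' @export
melanopic_der <- function(spd) {
  ev <- illuminance(spd)
  if (ev <= 0)
    stop("melanopic DER undefined: photopic illuminance is zero", call. = FALSE)
  melanopic_edi(spd) / ev
}

#' Chromaticity coordinates of a spectrum
#'
#' CIE 1931 (x, y) and CIE 1976 (u', v') chromaticity from the 2-degree
#' tristimulus values.
#'
#' @param spd A [spectrum()].
#' @return Named list `x`, `y`, `u_prime`, `v_prime`.
#' @export
chromaticity <- function(spd) {
  v <- .spd_values(spd)
  tab <- ref_tables()
  X <- sum(tab$xbar * v); Y <- sum(tab$ybar * v); Z <- sum(tab$zbar * v)
  if (X + Y + Z <= 0)
    stop("degenerate spectrum: zero tristimulus, chromaticity undefined",
         call. = FALSE)
  .xyz_to_chroma(X, Y, Z)
}

.xyz_to_chroma <- function(X, Y, Z) {
  s <- X + Y + Z
  den <- X + 15 * Y + 3 * Z
  list(x = X / s, y = Y / s, u_prime = 4 * X / den, v_prime = 9 * Y / den)
}

# u'v' <-> CIE 1960 uv (the Duv working space) and u'v' -> xy
.upvp_to_uv <- function(up, vp) c(u = up, v = 2 / 3 * vp)
.uv_to_upvp <- function(u, v) c(u_prime = u, v_prime = 1.5 * v)
.upvp_to_xy <- function(up, vp) {
  den <- 6 * up - 16 * vp + 12
  c(x = 9 * up / den, y = 4 * vp / den)
}

#' Rescale a spectrum to a target illuminance
#'
#' Linear rescaling; chromaticity and melanopic DER are unchanged.
#'
#' @param spd A [spectrum()] with positive illuminance.
#' @param target Target photopic illuminance in lx (> 0).
#' @return A [spectrum()] with `illuminance()` equal to `target`.
#' @export
rescale_to_illuminance <- function(spd, target) {
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  ev <- illuminance(spd)
  if (ev <= 0)
    stop("cannot rescale a zero-illuminance spectrum", call. = FALSE)
  spectrum(.spd_values(spd) * (target / ev))
}

#' All scalar metrics of a spectrum
#'
#' @param spd A [spectrum()].
#' @return One-row data frame with `e_v`, `e_mel`, `gamma_mel`, `x`, `y`,
#'   `u_prime`, `v_prime`, `cct`, `duv`.  `cct`/`duv` are `NA` when the
#'   chromaticity is too far from the Planckian locus.
#' @export
spectrum_metrics <- function(spd) {
  ch <- chromaticity(spd)
  cd <- tryCatch(cct_duv(ch$u_prime, ch$v_prime),
                 error = function(e) list(cct = NA_real_, duv = NA_real_))
  data.frame(e_v = illuminance(spd), e_mel = melanopic_edi(spd),
             gamma_mel = melanopic_der(spd),
             x = ch$x, y = ch$y, u_prime = ch$u_prime, v_prime = ch$v_prime,
             cct = cd$cct, duv = cd$duv)
}

#' Read / write spectra in wide CSV form
#'
#' The on-disk format is a wide CSV whose first column is `wavelength_nm`
#' (380..780) with one column per spectrum.
#'
#' @param path File path.
#' @return `read_spectra_csv()`: a named list of [spectrum()] objects.
#' @export
read_spectra_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] != "wavelength_nm")
    stop("first column must be wavelength_nm", call. = FALSE)
  if (!identical(as.integer(tab[[1]]), as.integer(wl_grid())))
    stop("spectra file is not on the 380..780 nm, 1 nm grid", call. = FALSE)
  out <- lapply(tab[-1], spectrum)
  names(out) <- names(tab)[-1]
  out
}

#' @rdname read_spectra_csv
#' @param spectra A named list of [spectrum()] objects or a 401-row matrix.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (is.matrix(spectra)) {
    m <- spectra
  } else {
    if (is.null(names(spectra)))
      names(spectra) <- paste0("spd_", seq_along(spectra))
    m <- vapply(spectra, .spd_values, numeric(.grid_n))
  }
  tab <- data.frame(wavelength_nm = wl_grid(), m, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
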