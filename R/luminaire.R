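# Synthetic multi-channel LED luminaires.
#
# Emulates the three simulated luminaire configurations: a 6-channel
# (narrowband 475/504/521/662 nm plus phosphor whites at 4655 K and
# 2740 K), an 8-channel (450/465/504/521/638/662 nm plus the two whites)
# and an 11-channel (419/450/457/504/521/597/638/662 nm plus a lime
# phosphor channel and the two whites).  The true measured primaries of
# the physical luminaire are not published; Gaussian lineshapes and a
# two-Gaussian blue-pump/phosphor white model stand in, so absolute
# tuning-range numbers are indicative rather than exact.

#' Gaussian narrowband LED primary
#'
#' A Gaussian lineshape on the working grid, truncated at the grid edges
#' and normalised to unit radiometric power (sum x 1 nm = 1 W m-2).
#'
#' @param peak_nm Peak wavelength, strictly inside (380, 780).
#' @param fwhm_nm Full width at half maximum in nm (> 0); 20 nm is a
#'   typical single-colour LED linewidth and the package default.
#' @param name Channel label.
#' @param kind Channel kind tag.
#' @return An `led_channel`: list with `name`, `kind`, `peak_nm`, `spd`.
#' @export
gaussian_primary <- function(peak_nm, fwhm_nm = 20,
                             name = paste0("nb", peak_nm),
                             kind = "narrowband") {
  stopifnot(fwhm_nm > 0)
  if (peak_nm <= 380 || peak_nm >= 780)
    stop("peak wavelength must lie strictly inside the 380-780 nm grid",
         call. = FALSE)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  v <- exp(-0.5 * ((wl_grid() - peak_nm) / sigma)^2)
  v <- v / sum(v)
  structure(list(name = name, kind = kind, peak_nm = peak_nm,
                 spd = spectrum(v)),
            class = "led_channel")
}

#' Phosphor-converted white LED primary
#'
#' Models a white LED as a blue pump Gaussian (450 nm, FWHM 20 nm) plus a
#' broad phosphor Gaussian (FWHM 110 nm) whose centre and power ratio are
#' solved numerically so that the mixed chromaticity lands on the Planckian
#' locus at the requested CCT (|CCT error| <= 50 K, |Duv| <= 0.005).
#'
#' @param target_cct Target correlated colour temperature, 2000--8000 K.
#' @param name Channel label.
#' @return An `led_channel` (unit radiometric power), with the achieved
#'   `cct` and `duv` attached.
#' @export
#' @examples
#' ch <- phosphor_white(2740)
#' ch$cct
phosphor_white <- function(target_cct, name = paste0("white", target_cct)) {
  stopifnot(target_cct >= 2000, target_cct <= 8000)
  wl <- wl_grid()
  pump <- exp(-0.5 * ((wl - 450) / (20 / 2.3548200450309493))^2)
  pump <- pump / sum(pump)
  sig_ph <- 110 / 2.3548200450309493
  uv_t <- .planck_uv(target_cct)
  obj <- function(par) {
    centre <- par[1]; ratio <- exp(par[2])
    ph <- exp(-0.5 * ((wl - centre) / sig_ph)^2)
    mixv <- pump + ratio * ph / sum(ph)
    ch <- chromaticity(spectrum(mixv))
    uv <- .upvp_to_uv(ch$u_prime, ch$v_prime)
    sum((uv - uv_t)^2)
  }
  # deterministic coarse scan over phosphor centres (ratio refined per
  # centre), then a Nelder-Mead polish from the best cell
  best <- NULL
  for (centre in seq(540, 680, by = 5)) {
    f1 <- stats::optimize(function(lr) obj(c(centre, lr)), c(-5, 5), tol = 1e-10)
    if (is.null(best) || f1$objective < best$val)
      best <- list(centre = centre, lr = f1$minimum, val = f1$objective)
  }
  fit <- stats::optim(c(best$centre, best$lr), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  if (fit$value > 1e-8)
    stop(sprintf("phosphor white model did not converge for %.0f K", target_cct),
         call. = FALSE)
  centre <- fit$par[1]; ratio <- exp(fit$par[2])
  ph <- exp(-0.5 * ((wl - centre) / sig_ph)^2)
  v <- pump + ratio * ph / sum(ph)
  v <- v / sum(v)
  ch <- chromaticity(spectrum(v))
  cd <- cct_duv(ch$u_prime, ch$v_prime)
  if (abs(cd$cct - target_cct) > 50 || abs(cd$duv) > 0.005)
    stop("phosphor white model outside tolerance", call. = FALSE)
  structure(list(name = name, kind = "phosphor_white", peak_nm = target_cct,
                 spd = spectrum(v), cct = cd$cct, duv = cd$duv),
            class = "led_channel")
}

# broad lime phosphor channel (centre 550 nm, FWHM 100 nm)
.lime_phosphor <- function() {
  gaussian_primary(550, 100, name = "lime", kind = "phosphor_lime")
}

#' Build a preset luminaire configuration
#'
#' @param preset One of `"6ch"`, `"8ch"`, `"11ch"`.
#' @param fwhm_nm FWHM used for all narrowband channels (nm).
#' @param max_active Optional limit on the number of simultaneously active
#'   channels (default: no limit).
#' @return A `luminaire`: list with `name`, `channels` (list of
#'   `led_channel`), `max_active`, and the mixing matrix `primaries`
#'   (401 x n, one column per channel at full drive).
#' @export
#' @examples
#' lum <- build_luminaire("6ch")
#' length(lum$channels)
build_luminaire <- function(preset = c("6ch", "8ch", "11ch"),
                            fwhm_nm = 20, max_active = NULL) {
  preset <- match.arg(preset)
  peaks <- switch(preset,
    "6ch"  = c(475, 504, 521, 662),
    "8ch"  = c(450, 465, 504, 521, 638, 662),
    "11ch" = c(419, 450, 457, 504, 521, 597, 638, 662))
  channels <- lapply(peaks, gaussian_primary, fwhm_nm = fwhm_nm)
  if (preset == "11ch") channels <- c(channels, list(.lime_phosphor()))
  channels <- c(channels, list(.white_cached(4655), .white_cached(2740)))
  n <- length(channels)
  primaries <- vapply(channels, function(ch) as.numeric(ch$spd),
                      numeric(.grid_n))
  colnames(primaries) <- vapply(channels, `[[`, "", "name")
  structure(list(name = preset, channels = channels,
                 max_active = if (is.null(max_active)) n else max_active,
                 primaries = primaries),
            class = "luminaire")
}

# the two white channels are shared across presets; solve them once
.white_cached <- function(cct) {
  key <- paste0("white", cct)
  if (is.null(.metamel[[key]])) .metamel[[key]] <- phosphor_white(cct)
  .metamel[[key]]
}

#' @export
print.luminaire <- function(x, ...) {
  cat("<luminaire>", x$name, "with", length(x$channels), "channels:\n")
  for (ch in x$channels)
    cat(sprintf("  %-10s %-14s %s\n", ch$name, ch$kind,
                if (ch$kind == "phosphor_white") paste0(ch$peak_nm, " K")
                else paste0(ch$peak_nm, " nm")))
  invisible(x)
}

#' Additively mix luminaire channels
#'
#' The spectrum of the luminaire with each channel driven at the given
#' fractional weight.  Mixing is exactly linear (the duty-cycle
#' nonlinearity of a physical driver is not modelled).
#'
#' @param config A [build_luminaire()] object.
#' @param weights Numeric vector, one weight per channel, each in `[0, 1]`.
#' @return A [spectrum()].
#' @export
mix <- function(config, weights) {
  stopifnot(inherits(config, "luminaire"))
  n <- ncol(config$primaries)
  if (length(weights) != n)
    stop(sprintf("expected %d weights, got %d", n, length(weights)),
         call. = FALSE)
  if (anyNA(weights) || any(weights < 0) || any(weights > 1))
    stop("channel weights must be in [0, 1]", call. = FALSE)
  spectrum(as.numeric(config$primaries %*% weights))
}

#' Draw a feasible chromaticity target from a luminaire's gamut
#'
#' Samples random channel weights, scales them so the mixture reaches the
#' optimiser's working illuminance (220 lx), and returns the mixture's
#' chromaticity as a target that is achievable by construction, together
#' with the generating weights.  Used to benchmark the optimiser's recovery
#' rate.
#'
#' @param config A [build_luminaire()] object.
#' @param seed Integer seed (deterministic output for a given seed).
#' @param working_lx Illuminance the generating weights are scaled to.
#' @return List with `target` (a one-row data frame like a grid row) and
#'   `weights`.
#' @export
random_feasible_target <- function(config, seed, working_lx = 220) {
  stopifnot(inherits(config, "luminaire"))
  n <- ncol(config$primaries)
  lm_per_ch <- 683 * colSums(config$primaries * ref_tables()$vlambda)
  set.seed(seed)
  for (i in 1:100) {
    w <- stats::runif(n, 0.05, 1)
    scl <- working_lx / sum(lm_per_ch * w)
    if (scl * max(w) <= 1) { w <- w * scl; break }
    if (i == 100) stop("could not scale random weights into [0,1]", call. = FALSE)
  }
  ch <- chromaticity(mix(config, w))
  cd <- tryCatch(cct_duv(ch$u_prime, ch$v_prime),
                 error = function(e) list(cct = NA_real_, duv = NA_real_))
  target <- data.frame(cct_K = cd$cct, duv = cd$duv,
                       u_prime = ch$u_prime, v_prime = ch$v_prime,
                       x = ch$x, y = ch$y, cct_level = NA_integer_,
                       duv_level = NA_integer_)
  list(target = target, weights = w)
}
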