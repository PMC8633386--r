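# Correlated colour temperature and Duv.
#
# CCT/Duv follow Ohno's (2013) table-search method: the Planckian locus is
# tabulated densely in the CIE 1960 (u, v) uniform chromaticity space (the
# conventional working space for Duv), the nearest locus point is found, and
# both CCT and Duv are refined with a parabolic fit through the three
# nearest table entries.  Duv is signed: positive above the locus.

.planck_locus <- function() {
  if (!is.null(.metamel$locus)) return(.metamel$locus)
  tab <- ref_tables()
  # geometric temperature ladder, ~0.05 % steps: parabolic refinement then
  # resolves CCT far below 0.1 % and Duv below 1e-5
  temps <- exp(seq(log(1000), log(25000), length.out = 6500))
  lam <- wl_grid() * 1e-9
  c2 <- 1.4388e-2
  # Planck SPD matrix (401 x n), each column max-normalised
  M <- outer(lam^-5, rep(1, length(temps))) /
    (exp(outer(c2 / lam, 1 / temps)) - 1)
  X <- colSums(M * tab$xbar); Y <- colSums(M * tab$ybar); Z <- colSums(M * tab$zbar)
  den <- X + 15 * Y + 3 * Z
  u <- 4 * X / den
  v <- 6 * Y / den           # CIE 1960 v = (2/3) v' = 6Y/(X + 15Y + 3Z)
  .metamel$locus <- list(t = temps, u = u, v = v)
  .metamel$locus
}

# uv of the Planckian radiator at temperature T (same computation as the
# locus table, so round trips through cct_duv() close tightly)
.planck_uv <- function(temp_K) {
  tab <- ref_tables()
  lam <- wl_grid() * 1e-9
  c2 <- 1.4388e-2
  m <- lam^-5 / (exp(c2 / (lam * temp_K)) - 1)
  X <- sum(m * tab$xbar); Y <- sum(m * tab$ybar); Z <- sum(m * tab$zbar)
  den <- X + 15 * Y + 3 * Z
  c(u = 4 * X / den, v = 6 * Y / den)
}

#' Correlated colour temperature and Duv of a chromaticity
#'
#' @param u_prime,v_prime CIE 1976 chromaticity of the point.
#' @param max_duv Reject points farther than this from the Planckian locus
#'   (the CCT is conventionally undefined there).
#' @return List with `cct` (K) and signed `duv` (positive above the locus,
#'   measured in the CIE 1960 uv space).
#' @export
#' @examples
#' ch <- chromaticity(planck_spd(3000))
#' cct_duv(ch$u_prime, ch$v_prime)
cct_duv <- function(u_prime, v_prime, max_duv = 0.05) {
  uv <- .upvp_to_uv(u_prime, v_prime)
  loc <- .planck_locus()
  d2 <- (loc$u - uv[1])^2 + (loc$v - uv[2])^2
  m <- which.min(d2)
  if (m == 1L || m == length(loc$t))
    stop("chromaticity outside the CCT-definable range (1000-25000 K)",
         call. = FALSE)
  d <- sqrt(d2[(m - 1):(m + 1)])
  tt <- loc$t[(m - 1):(m + 1)]
  # parabola through (T, d); vertex refines both CCT and |Duv|
  x1 <- tt[1]; x2 <- tt[2]; x3 <- tt[3]
  den <- (x3 - x2) * (x2 - x1) * (x3 - x1)
  a <- ((x3 - x2) * d[1] - (x3 - x1) * d[2] + (x2 - x1) * d[3]) / den
  b <- -((x3 - x2) * (x3 + x2) * d[1] - (x3 - x1) * (x3 + x1) * d[2] +
           (x2 - x1) * (x2 + x1) * d[3]) / den
  cc <- d[2] - (a * x2^2 + b * x2)
  cct <- -b / (2 * a)
  dmin <- a * cct^2 + b * cct + cc
  if (!is.finite(cct) || cct < min(tt) - 1 || cct > max(tt) + 1) {
    cct <- x2; dmin <- d[2]   # degenerate parabola: fall back to the node
  }
  sgn <- sign(uv[2] - stats::approx(loc$t, loc$v, cct)$y)
  if (sgn == 0) sgn <- 1
  duv <- unname(sgn * abs(dmin))
  if (abs(duv) > max_duv)
    stop(sprintf("point too far from the Planckian locus (|Duv| = %.4f > %.3f)",
                 abs(duv), max_duv), call. = FALSE)
  list(cct = cct, duv = duv)
}

#' @rdname cct_duv
#' @param spd A [spectrum()]; convenience wrapper taking the spectrum's
#'   chromaticity.
#' @export
cct_duv_of <- function(spd, max_duv = 0.05) {
  ch <- chromaticity(spd)
  cct_duv(ch$u_prime, ch$v_prime, max_duv = max_duv)
}

#' Chromaticity of the Planckian radiator
#'
#' @param cct Correlated colour temperature in K (1000--20000).
#' @return Named list `x`, `y`, `u_prime`, `v_prime`.
#' @export
planck_point <- function(cct) {
  stopifnot(is.numeric(cct), length(cct) == 1L)
  if (cct < 1000 || cct > 20000)
    stop("cct out of range (1000-20000 K)", call. = FALSE)
  uv <- .planck_uv(cct)
  upvp <- .uv_to_upvp(uv[1], uv[2])
  xy <- .upvp_to_xy(upvp[1], upvp[2])
  list(x = unname(xy[1]), y = unname(xy[2]),
       u_prime = unname(upvp[1]), v_prime = unname(upvp[2]))
}

#' Displace a chromaticity perpendicular to the Planckian locus
#'
#' Moves the chromaticity `base` (typically a locus point from
#' [planck_point()]) by the signed distance `duv` along the normal to the
#' locus at the base point's CCT, in the CIE 1960 uv working space.
#' Positive offsets go above the locus.
#'
#' @param base Chromaticity as returned by [planck_point()] (a list with
#'   `u_prime`, `v_prime`).
#' @param duv Signed offset, |duv| <= 0.05.
#' @return Named list `x`, `y`, `u_prime`, `v_prime`.
#' @export
#' @examples
#' p <- duv_offset(planck_point(5000), 0.021)
#' cct_duv(p$u_prime, p$v_prime)
duv_offset <- function(base, duv) {
  stopifnot(abs(duv) <= 0.05)
  if (duv == 0) {
    xy <- .upvp_to_xy(base$u_prime, base$v_prime)
    return(list(x = unname(xy[1]), y = unname(xy[2]),
                u_prime = base$u_prime, v_prime = base$v_prime))
  }
  cd <- cct_duv(base$u_prime, base$v_prime)
  t0 <- cd$cct
  uv0 <- .upvp_to_uv(base$u_prime, base$v_prime)
  # locus tangent by symmetric difference, then the upward-pointing normal
  h <- t0 * 1e-3
  p1 <- .planck_uv(t0 - h); p2 <- .planck_uv(t0 + h)
  tg <- c(p2[1] - p1[1], p2[2] - p1[2])
  tg <- tg / sqrt(sum(tg^2))
  n <- c(-tg[2], tg[1])
  if (n[2] < 0) n <- -n
  uv <- uv0 + duv * n
  upvp <- .uv_to_upvp(uv[1], uv[2])
  xy <- .upvp_to_xy(upvp[1], upvp[2])
  list(x = unname(xy[1]), y = unname(xy[2]),
       u_prime = unname(upvp[1]), v_prime = unname(upvp[2]))
}
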