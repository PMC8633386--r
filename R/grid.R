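# Chromaticity-target grid along the Planckian locus.

#' Build the chromaticity target grid
#'
#' Constructs the grid of optimisation targets along the Planckian locus:
#' `n_cct` CCT levels between `cct_range[1]` and `cct_range[2]`, each with a
#' ladder of signed Duv offsets `{0, +/-duv_step, ..., +/-duv_max}`.  With
#' the defaults this yields 17 x 33 = 561 targets.
#'
#' CCT levels are placed uniformly in arc position along the locus in the
#' CIE 1976 u'v' diagram (`spacing = "uv_arc"`), which is what a "uniform
#' grid in u'v'" means geometrically; `spacing = "recip_cct"` places them
#' uniformly in reciprocal CCT (mired) instead.
#'
#' @param n_cct Number of CCT levels (default 17).
#' @param cct_range Endpoints of the CCT ladder in K.
#' @param duv_max Largest |Duv| offset (multiple of `duv_step`).
#' @param duv_step Duv ladder step.
#' @param spacing CCT-level spacing rule (see above).
#' @return A `target_grid` data frame with columns `cct_K`, `duv`,
#'   `u_prime`, `v_prime`, `x`, `y`, `cct_level`, `duv_level`.
#' @export
#' @examples
#' g <- build_grid()
#' nrow(g)  # 561
build_grid <- function(n_cct = 17, cct_range = c(2700, 7443),
                       duv_max = 0.048, duv_step = 0.003,
                       spacing = c("uv_arc", "recip_cct")) {
  spacing <- match.arg(spacing)
  stopifnot(n_cct >= 1, duv_step > 0, duv_max >= 0)
  k <- duv_max / duv_step
  if (abs(k - round(k)) > 1e-9)
    stop("duv_max must be an integer multiple of duv_step", call. = FALSE)
  k <- as.integer(round(k))
  ccts <- .cct_ladder(n_cct, cct_range, spacing)
  duvs <- duv_step * seq.int(-k, k)
  rows <- vector("list", n_cct * length(duvs))
  idx <- 0L
  for (i in seq_len(n_cct)) {
    base <- planck_point(ccts[i])
    for (j in seq_along(duvs)) {
      p <- duv_offset(base, duvs[j])
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        cct_K = ccts[i], duv = duvs[j],
        u_prime = p$u_prime, v_prime = p$v_prime, x = p$x, y = p$y,
        cct_level = i, duv_level = j - k - 1L)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("target_grid", "data.frame")
  out
}

.cct_ladder <- function(n_cct, cct_range, spacing) {
  if (n_cct == 1) return(cct_range[1])
  if (spacing == "recip_cct") {
    return(1e6 / seq(1e6 / cct_range[1], 1e6 / cct_range[2],
                     length.out = n_cct))
  }
  # uniform in u'v' arc length along the locus
  tt <- exp(seq(log(cct_range[1]), log(cct_range[2]), length.out = 400))
  pts <- t(vapply(tt, .planck_uv, numeric(2))) * c(1, 1.5)  # to u'v'
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arc <- c(0, cumsum(seg))
  want <- seq(0, arc[length(arc)], length.out = n_cct)
  ccts <- stats::approx(arc, tt, want)$y
  ccts[1] <- cct_range[1]; ccts[n_cct] <- cct_range[2]
  ccts
}

#' Write / read a target grid as CSV
#'
#' @param grid A [build_grid()] data frame.
#' @param path File path.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  out <- utils::read.csv(path)
  need <- c("cct_K", "duv", "u_prime", "v_prime", "x", "y",
            "cct_level", "duv_level")
  if (!all(need %in% names(out)))
    stop("not a target grid CSV", call. = FALSE)
  class(out) <- c("target_grid", "data.frame")
  out
}
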