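# Reduction of metamer sets into tuning-range metrics and the CIExy atlas.

#' Michelson contrast of a melanopic EDI pair
#'
#' `(e_max - e_min) / (e_max + e_min)`, the relative modulation depth of
#' the melanopic stimulus achievable by a metameric pair.
#'
#' @param e_min,e_max Melanopic EDI extremes in lx, `e_max >= e_min >= 0`,
#'   `e_max > 0`.
#' @return Contrast in `[0, 1)`.
#' @export
#' @examples
#' michelson_contrast(181, 271)  # ~0.20
michelson_contrast <- function(e_min, e_max) {
  stopifnot(all(e_min >= 0), all(e_max >= e_min))
  if (any(e_max <= 0))
    stop("Michelson contrast undefined for an all-zero pair", call. = FALSE)
  (e_max - e_min) / (e_max + e_min)
}

#' Melanopic EDI tuning range at a given illuminance
#'
#' Converts a melanopic DER tuning range into lx at a photopic illuminance:
#' `delta_E_mel = E_v * delta_gamma`.
#'
#' @param delta_gamma Melanopic DER tuning range (>= 0).
#' @param e_v Photopic illuminance in lx (>= 0).
#' @return Tuning range in lx.
#' @export
#' @examples
#' delta_e_at_lux(0.236, 250)  # ~59 lx
delta_e_at_lux <- function(delta_gamma, e_v) {
  stopifnot(all(delta_gamma >= 0), all(e_v >= 0))
  delta_gamma * e_v
}

#' Summarise one metamer set
#'
#' Extracts the melanopic extremes of the set: minimum and maximum
#' melanopic EDI (and DER), their differences, and the melanopic Michelson
#' contrast.  Ties are broken by first occurrence.
#'
#' @param ms A [filter_metamers()] (optionally fidelity-gated) metamer set.
#' @return One-row data frame with the target columns plus `n_metamers`,
#'   `e_mel_min`, `e_mel_max`, `delta_e_mel`, `gamma_min`, `gamma_max`,
#'   `delta_gamma`, `c_m` — or `NULL` for an empty set.
#' @export
summarize_target <- function(ms) {
  stopifnot(inherits(ms, "metamer_set"))
  if (ms$n == 0L) return(NULL)
  em <- ms$metrics$e_mel
  gm <- ms$metrics$gamma_mel
  i_min <- which.min(em); i_max <- which.max(em)
  out <- cbind(
    as.data.frame(ms$target),
    data.frame(luminaire = ms$luminaire,
               criterion = if (is.null(ms$criterion)) "none" else ms$criterion,
               n_metamers = ms$n,
               e_mel_min = em[i_min], e_mel_max = em[i_max],
               delta_e_mel = abs(em[i_max] - em[i_min]),
               gamma_min = gm[i_min], gamma_max = gm[i_max],
               delta_gamma = abs(gm[i_max] - gm[i_min]),
               c_m = if (em[i_max] > 0)
                 michelson_contrast(em[i_min], em[i_max]) else 0))
  rownames(out) <- NULL
  out
}

#' Per-CCT aggregates across the Duv ladder
#'
#' For each CCT level, reduces the per-target summaries across all Duv
#' offsets: the per-CCT extremes of the melanopic DER (`gamma_hat_min`,
#' `gamma_hat_max`), the largest per-target tuning range
#' (`delta_gamma_tilde`), and the Duv at which each occurs.  Note that
#' `delta_gamma_tilde` is a within-target (truly metameric) quantity; the
#' hat extremes compare across chromaticities of the same CCT and are not
#' a metameric tuning range.
#'
#' @param summaries Data frame of [summarize_target()] rows.
#' @return Data frame with one row per `cct_level`.
#' @export
summarize_cct <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  parts <- split(summaries, summaries$cct_level)
  out <- do.call(rbind, lapply(parts, function(g) {
    i_min <- which.min(g$gamma_min)
    i_max <- which.max(g$gamma_max)
    i_del <- which.max(g$delta_gamma)
    data.frame(cct_level = g$cct_level[1], cct_K = g$cct_K[1],
               n_targets = nrow(g),
               gamma_hat_min = g$gamma_min[i_min],
               duv_at_gamma_min = g$duv[i_min],
               gamma_hat_max = g$gamma_max[i_max],
               duv_at_gamma_max = g$duv[i_max],
               delta_gamma_tilde = g$delta_gamma[i_del],
               duv_at_delta_gamma = g$duv[i_del])
  }))
  rownames(out) <- NULL
  out[order(out$cct_K), ]
}

#' Build the CIExy atlas of melanopic tuning metrics
#'
#' Interpolates the per-target `delta_gamma` and `c_m` fields onto a
#' regular raster in CIE 1931 xy by piecewise-linear (barycentric)
#' interpolation over the structured target grid: each cell of the
#' (CCT level, Duv level) lattice whose four corners were all optimised is
#' split into two triangles in xy.  No extrapolation is performed — raster
#' points outside the optimised cells stay `NA`, so gamut holes show as
#' gaps, and interpolated values never exceed the data extremes.  Global
#' maxima are located by brute force over the raw per-target values (ties
#' broken by the lowest (CCT level, Duv level) index).
#'
#' @param summaries Data frame of [summarize_target()] rows for one
#'   (luminaire, criterion) pair, on a [build_grid()] layout.
#' @param raster_n Raster resolution per axis.
#' @return An `atlas`: list with `summaries`, `raster` (vectors `x`, `y`
#'   and matrices `delta_gamma`, `c_m`), `maxima` (one row per metric) and
#'   `meta`.
#' @export
build_atlas <- function(summaries, raster_n = 120) {
  stopifnot(nrow(summaries) >= 3)
  if (length(unique(paste(summaries$luminaire, summaries$criterion))) > 1)
    stop("atlas expects summaries of a single (luminaire, criterion) pair",
         call. = FALSE)
  xs <- seq(min(summaries$x), max(summaries$x), length.out = raster_n)
  ys <- seq(min(summaries$y), max(summaries$y), length.out = raster_n)
  fields <- c("delta_gamma", "c_m")
  px <- rep(xs, times = raster_n)
  py <- rep(ys, each = raster_n)
  vals <- .atlas_interp(summaries, px, py, fields)
  rast <- lapply(vals, matrix, nrow = raster_n, ncol = raster_n)
  ord <- order(summaries$cct_level, summaries$duv_level)
  maxima <- do.call(rbind, lapply(fields, function(f) {
    v <- summaries[[f]][ord]
    i <- ord[which.max(v)]
    data.frame(metric = f, value = summaries[[f]][i],
               x = summaries$x[i], y = summaries$y[i],
               cct_K = summaries$cct_K[i], duv = summaries$duv[i])
  }))
  structure(list(summaries = summaries,
                 raster = list(x = xs, y = ys,
                               delta_gamma = rast$delta_gamma,
                               c_m = rast$c_m),
                 maxima = maxima,
                 meta = list(luminaire = summaries$luminaire[1],
                             criterion = summaries$criterion[1],
                             tables = ref_tables()$version)),
            class = "atlas")
}

# Piecewise-linear interpolation of per-target fields at arbitrary xy
# points.  Cells of the structured (cct_level, duv_level) lattice with all
# four corners present are split into two triangles in the xy plane;
# points outside every complete cell get NA.
.atlas_interp <- function(summaries, px, py, fields) {
  out <- lapply(fields, function(f) rep(NA_real_, length(px)))
  names(out) <- fields
  key <- paste(summaries$cct_level, summaries$duv_level)
  idx <- function(cl, dl) match(paste(cl, dl), key)
  cls <- sort(unique(summaries$cct_level))
  dls <- sort(unique(summaries$duv_level))
  for (ci in seq_len(max(length(cls) - 1, 0)))
    for (di in seq_len(max(length(dls) - 1, 0))) {
      corners <- c(idx(cls[ci], dls[di]), idx(cls[ci + 1], dls[di]),
                   idx(cls[ci + 1], dls[di + 1]), idx(cls[ci], dls[di + 1]))
      if (anyNA(corners)) next
      for (tri in list(corners[c(1, 2, 3)], corners[c(1, 3, 4)])) {
        tx <- summaries$x[tri]; ty <- summaries$y[tri]
        det <- (ty[2] - ty[3]) * (tx[1] - tx[3]) +
               (tx[3] - tx[2]) * (ty[1] - ty[3])
        if (abs(det) < 1e-14) next
        l1 <- ((ty[2] - ty[3]) * (px - tx[3]) +
                 (tx[3] - tx[2]) * (py - ty[3])) / det
        l2 <- ((ty[3] - ty[1]) * (px - tx[3]) +
                 (tx[1] - tx[3]) * (py - ty[3])) / det
        l3 <- 1 - l1 - l2
        inside <- l1 >= -1e-12 & l2 >= -1e-12 & l3 >= -1e-12
        if (!any(inside)) next
        for (f in fields)
          out[[f]][inside] <- l1[inside] * summaries[[f]][tri[1]] +
            l2[inside] * summaries[[f]][tri[2]] +
            l3[inside] * summaries[[f]][tri[3]]
      }
    }
  out
}

#' @export
print.atlas <- function(x, ...) {
  cat("<atlas>", x$meta$luminaire, "luminaire, fidelity criterion",
      x$meta$criterion, "-", nrow(x$summaries), "targets\n")
  print(x$maxima, digits = 3)
  invisible(x)
}
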