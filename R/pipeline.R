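# End-to-end pipeline: grid -> per-target harvest -> metamer filter ->
# fidelity gate -> summaries -> atlas, with per-target caching so a run
# can be resumed or re-gated under a different fidelity criterion without
# re-optimising.

#' Pipeline configuration
#'
#' @param luminaire Preset name for [build_luminaire()].
#' @param seed Master seed; every target/repetition seed is derived from it
#'   deterministically, so a stored config reproduces the run.
#' @param n_cct,cct_range,duv_max,duv_step,spacing Grid parameters, see
#'   [build_grid()].
#' @param repetitions Optimisation repetitions per target.
#' @param settings [optimizer_settings()].
#' @param fidelity Fidelity criterion: `"p3"`, `"p2"` or `"none"`.
#' @param e_v_out Reporting illuminance (lx).
#' @param out_dir Output/cache directory, or `NULL` for in-memory only.
#' @param max_active Optional channel-count limit.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(luminaire = "8ch", seed = 1,
                            n_cct = 17, cct_range = c(2700, 7443),
                            duv_max = 0.048, duv_step = 0.003,
                            spacing = "uv_arc",
                            repetitions = 8,
                            settings = optimizer_settings(),
                            fidelity = c("p3", "p2", "none"),
                            e_v_out = 250, out_dir = NULL,
                            max_active = NULL) {
  structure(list(luminaire = luminaire, seed = seed, n_cct = n_cct,
                 cct_range = cct_range, duv_max = duv_max,
                 duv_step = duv_step, spacing = spacing,
                 repetitions = repetitions, settings = settings,
                 fidelity = match.arg(fidelity), e_v_out = e_v_out,
                 out_dir = out_dir, max_active = max_active),
            class = "pipeline_config")
}

# FNV-1a style hash of the optimisation-relevant part of a config; the
# fidelity criterion and output settings are deliberately excluded so a
# cached harvest can be re-gated without re-optimising
.config_hash <- function(config) {
  key <- config[c("luminaire", "seed", "n_cct", "cct_range", "duv_max",
                  "duv_step", "spacing", "repetitions", "settings",
                  "max_active")]
  s <- paste(deparse(key), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full metamer-atlas pipeline
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-target progress.
#' @return List with `atlas`, `summaries` (per optimised target),
#'   `cct_summaries`, `grid`, `yield` (per-target counts incl. infeasible
#'   targets) and `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  lum <- build_luminaire(config$luminaire, max_active =
                           if (is.null(config$max_active)) NULL
                           else config$max_active)
  grid <- build_grid(config$n_cct, config$cct_range, config$duv_max,
                     config$duv_step, config$spacing)
  hash <- .config_hash(config)
  cache_dir <- NULL
  if (!is.null(config$out_dir)) {
    cache_dir <- file.path(config$out_dir, "runs")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- file.path(cache_dir, "config_hash.txt")
    if (file.exists(stamp)) {
      old <- readLines(stamp, warn = FALSE)[1]
      if (!identical(old, hash))
        stop("stale cache: ", cache_dir, " was produced by a different ",
             "configuration (hash ", old, " != ", hash, ")", call. = FALSE)
    } else writeLines(hash, stamp)
  }
  sum_rows <- vector("list", nrow(grid))
  yield <- data.frame(cct_level = grid$cct_level, duv_level = grid$duv_level,
                      n_archived = 0L, n_metamers = 0L, n_gated = 0L,
                      infeasible = FALSE, cached = FALSE)
  for (i in seq_len(nrow(grid))) {
    target <- grid[i, ]
    cache_file <- if (is.null(cache_dir)) NULL else
      file.path(cache_dir, sprintf("target_%03d_weights.csv", i))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      W <- as.matrix(utils::read.csv(cache_file))
      dimnames(W) <- NULL
      run <- structure(list(target = target, luminaire = lum$name,
                            primaries = lum$primaries, seed = config$seed,
                            repetitions = config$repetitions,
                            settings = config$settings,
                            weights = if (nrow(W)) W else NULL,
                            n_feasible = nrow(W),
                            infeasible = nrow(W) == 0L),
                       class = "opt_run")
      yield$cached[i] <- TRUE
    } else {
      run <- optimize_target(lum, target, seed = derive_seed(config$seed, i),
                             repetitions = config$repetitions,
                             settings = config$settings)
      if (!is.null(cache_file))
        utils::write.csv(as.data.frame(
          if (is.null(run$weights)) matrix(0, 0, ncol(lum$primaries))
          else run$weights), cache_file, row.names = FALSE)
    }
    yield$n_archived[i] <- run$n_feasible
    yield$infeasible[i] <- run$infeasible
    ms <- filter_metamers(run, e_v_out = config$e_v_out)
    yield$n_metamers[i] <- ms$n
    ms <- apply_fidelity_criterion(ms, config$fidelity)
    yield$n_gated[i] <- ms$n
    sum_rows[[i]] <- summarize_target(ms)
    if (verbose)
      message(sprintf("target %3d/%d (%.0f K, %+0.3f): %d metamers, %d gated%s",
                      i, nrow(grid), target$cct_K, target$duv,
                      yield$n_metamers[i], ms$n,
                      if (yield$cached[i]) " [cached]" else ""))
  }
  summaries <- do.call(rbind, sum_rows)
  if (is.null(summaries) || nrow(summaries) < 3) {
    warning("fewer than 3 targets yielded metamers; no atlas built",
            call. = FALSE)
    atlas <- NULL
    cct_sum <- if (is.null(summaries)) NULL else summarize_cct(summaries)
  } else {
    cct_sum <- summarize_cct(summaries)
    atlas <- build_atlas(summaries)
    atlas$meta$seed <- config$seed
    atlas$meta$config_hash <- hash
  }
  out <- list(atlas = atlas, summaries = summaries,
              cct_summaries = cct_sum, grid = grid, yield = yield,
              config = config)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, hash)
  out
}

.write_pipeline_outputs <- function(out, hash) {
  dir <- out$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$yield, file.path(dir, "yield.csv"), row.names = FALSE)
  write_grid_csv(out$grid, file.path(dir, "grid.csv"))
  if (!is.null(out$summaries))
    utils::write.csv(out$summaries,
                     file.path(dir, "target_summaries.csv"), row.names = FALSE)
  if (!is.null(out$cct_summaries))
    utils::write.csv(out$cct_summaries,
                     file.path(dir, "cct_summaries.csv"), row.names = FALSE)
  if (is.null(out$atlas)) return(invisible(dir))
  for (f in c("delta_gamma", "c_m")) {
    m <- out$atlas$raster[[f]]
    utils::write.csv(data.frame(x = rep(out$atlas$raster$x,
                                        times = length(out$atlas$raster$y)),
                                y = rep(out$atlas$raster$y,
                                        each = length(out$atlas$raster$x)),
                                value = as.vector(m)),
                     file.path(dir, paste0("atlas_raster_", f, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(maxima = out$atlas$maxima,
         luminaire = out$atlas$meta$luminaire,
         criterion = out$atlas$meta$criterion,
         seed = out$config$seed,
         config_hash = hash,
         tables = out$atlas$meta$tables),
    file.path(dir, "atlas.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
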