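# Metamer harvesting by stochastic constrained search.
#
# For every chromaticity target the package runs a differential-evolution
# style population search over the channel weights.  The objective is the
# Euclidean chromaticity error in u'v' plus a hinge penalty when the
# photopic illuminance leaves the 220 +/- 2 lx working window; every
# distinct feasible weight vector visited anywhere in the search is
# archived, not just the optimum, because the analysis needs the whole
# metamer set rather than a single solution.  Survivors are rescaled to
# the 250 lx reporting illuminance afterwards, mirroring the
# optimise-at-220-then-rescale order of the study design.

#' Optimiser settings
#'
#' @param population Population size of the search.
#' @param generations Number of generations per repetition.
#' @param f,cr Differential weight and crossover rate.
#' @param working_lx,working_tol Illuminance window enforced during the
#'   search (lx): `working_lx +/- working_tol`.
#' @param chroma_tol Per-axis chromaticity tolerance (|du'| and |dv'|)
#'   defining a metamer.
#' @param dedup_tol Weight-vector resolution below which two solutions
#'   collapse into one archived member (max-norm box size).
#' @param max_archive Cap on archived members per repetition (a safety
#'   valve; the cap is far above typical yields).
#' @return A list of class `optimizer_settings`.
#' @export
optimizer_settings <- function(population = 60, generations = 400,
                               f = 0.7, cr = 0.9,
                               working_lx = 220, working_tol = 2,
                               chroma_tol = 0.001, dedup_tol = 1e-3,
                               max_archive = 4000) {
  structure(list(population = population, generations = generations,
                 f = f, cr = cr, working_lx = working_lx,
                 working_tol = working_tol, chroma_tol = chroma_tol,
                 dedup_tol = dedup_tol, max_archive = max_archive),
            class = "optimizer_settings")
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based fan-out used to give every (target,
#' repetition) pair its own reproducible random stream.  The result is
#' always a valid 32-bit integer seed.
#'
#' @param master Master seed (integer).
#' @param a,b Counters (e.g. target index, repetition index).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, a = 0L, b = 0L) {
  as.integer(((master %% 1000003) * 8191 + a * 131071 + b * 131 + 17) %%
               2147483647)
}

#' Harvest spectra for one chromaticity target
#'
#' Runs `repetitions` independently seeded searches and archives every
#' distinct weight vector whose mixture satisfies both the chromaticity
#' tolerance (per-axis |du'|, |dv'| <= `chroma_tol`) and the working
#' illuminance window.  A target for which all repetitions return an empty
#' archive is flagged infeasible rather than raising an error.
#'
#' @param config A [build_luminaire()] object.
#' @param target One row of a [build_grid()] data frame (or the `target`
#'   element of [random_feasible_target()]).
#' @param seed Master seed for this target; repetitions use seeds derived
#'   from it, so the whole harvest is reproducible.
#' @param repetitions Number of search repetitions (the study design used
#'   six to eight; default 8).
#' @param settings An [optimizer_settings()] list.
#' @return An `opt_run`: list with `target`, `luminaire`, `primaries`,
#'   `seed`, `repetitions`, `settings`, `weights` (archived members x
#'   channels matrix), `n_feasible` and `infeasible`.
#' @export
optimize_target <- function(config, target, seed, repetitions = 8,
                            settings = optimizer_settings()) {
  stopifnot(inherits(config, "luminaire"))
  target <- as.data.frame(target)[1, ]
  P <- config$primaries
  n <- ncol(P)
  tab <- ref_tables()
  A <- t(P) %*% cbind(tab$xbar, tab$ybar, tab$zbar)   # n x 3 channel tristimulus
  seen <- new.env(parent = emptyenv(), size = 4096L)
  archives <- vector("list", repetitions)
  for (rep in seq_len(repetitions)) {
    set.seed(derive_seed(seed, rep))
    archives[[rep]] <- .de_harvest(A, n, target$u_prime, target$v_prime,
                                   settings, config$max_active, seen)
  }
  W <- do.call(rbind, archives)
  structure(list(target = target, luminaire = config$name, primaries = P,
                 seed = seed, repetitions = repetitions, settings = settings,
                 weights = W, n_feasible = if (is.null(W)) 0L else nrow(W),
                 infeasible = is.null(W) || nrow(W) == 0L),
            class = "opt_run")
}

# one DE repetition; archives feasible visits into a matrix, deduplicating
# through the shared hash set `seen` (weight vectors rounded to dedup_tol
# boxes; vectors in the same box collapse to one member)
.de_harvest <- function(A, n, ut, vt, st, max_active, seen) {
  pop <- st$population
  W <- matrix(stats::runif(pop * n), pop, n)
  if (max_active < n) W <- t(apply(W, 1, enforce_channel_limit, max_active))
  keep <- matrix(0, 0, n)
  score <- rep(Inf, pop)
  eval_batch <- function(M) {
    TS <- M %*% A
    den <- TS[, 1] + 15 * TS[, 2] + 3 * TS[, 3]
    den[den <= 0] <- NA
    up <- 4 * TS[, 1] / den
    vp <- 9 * TS[, 2] / den
    ev <- 683 * TS[, 2]
    err <- sqrt((up - ut)^2 + (vp - vt)^2) +
      1e-3 * pmax(0, abs(ev - st$working_lx) - st$working_tol)
    err[is.na(err)] <- Inf
    feas <- !is.na(up) &
      abs(up - ut) <= st$chroma_tol & abs(vp - vt) <= st$chroma_tol &
      abs(ev - st$working_lx) <= st$working_tol
    list(err = err, feas = feas)
  }
  take <- function(M, feas) {
    if (!any(feas) || nrow(keep) >= st$max_archive) return(invisible())
    idx <- which(feas)
    for (i in idx) {
      key <- paste(round(M[i, ] / st$dedup_tol), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        keep <<- rbind(keep, M[i, ])
        if (nrow(keep) >= st$max_archive) break
      }
    }
  }
  e <- eval_batch(W); score <- e$err; take(W, e$feas)
  for (g in seq_len(st$generations)) {
    r1 <- sample.int(pop); r2 <- sample.int(pop); r3 <- sample.int(pop)
    V <- W[r1, ] + st$f * (W[r2, ] - W[r3, ])
    V[V < 0] <- 0; V[V > 1] <- 1
    mask <- matrix(stats::runif(pop * n) < st$cr, pop, n)
    jr <- cbind(seq_len(pop), sample.int(n, pop, replace = TRUE))
    mask[jr] <- TRUE
    U <- ifelse(mask, V, W)
    if (max_active < n) U <- t(apply(U, 1, enforce_channel_limit, max_active))
    e <- eval_batch(U)
    better <- e$err < score
    W[better, ] <- U[better, ]
    score[better] <- e$err[better]
    take(U, e$feas)
  }
  keep
}

#' Limit the number of active channels in a weight vector
#'
#' When more than `max_active` weights are non-zero, the smallest ones are
#' zeroed until the limit holds.  Idempotent; vectors already within the
#' limit are returned unchanged.
#'
#' @param weights Numeric weight vector.
#' @param max_active Maximum number of non-zero entries.
#' @return The constrained weight vector.
#' @export
enforce_channel_limit <- function(weights, max_active) {
  stopifnot(max_active <= length(weights))
  nz <- which(weights > 0)
  if (length(nz) <= max_active) return(weights)
  drop <- nz[order(weights[nz])][seq_len(length(nz) - max_active)]
  weights[drop] <- 0
  weights
}

#' Filter an optimisation run into a metamer set
#'
#' Re-checks every archived solution against the per-axis chromaticity
#' tolerance, deduplicates, and rescales the survivors to the reporting
#' illuminance (250 lx by default).  Rescaling is linear so chromaticity
#' and melanopic DER are untouched.
#'
#' @param run An [optimize_target()] result.
#' @param e_v_out Reporting illuminance in lx.
#' @param chroma_tol Per-axis chromaticity tolerance.
#' @return A `metamer_set`: list with `target`, `luminaire`, `n`,
#'   `weights`, `spectra` (401 x n matrix, every column at `e_v_out` lx),
#'   and `metrics` (data frame with one row per member).  Empty sets are
#'   legal (`n = 0`).
#' @export
filter_metamers <- function(run, e_v_out = 250,
                            chroma_tol = run$settings$chroma_tol) {
  stopifnot(inherits(run, "opt_run"))
  tab <- ref_tables()
  empty <- function() {
    structure(list(target = run$target, luminaire = run$luminaire, n = 0L,
                   weights = matrix(0, 0, ncol(run$primaries)),
                   spectra = matrix(0, .grid_n, 0),
                   metrics = data.frame()),
              class = "metamer_set")
  }
  if (run$infeasible || is.null(run$weights) || nrow(run$weights) == 0L)
    return(empty())
  S <- run$primaries %*% t(run$weights)          # 401 x N
  X <- colSums(S * tab$xbar); Y <- colSums(S * tab$ybar); Z <- colSums(S * tab$zbar)
  den <- X + 15 * Y + 3 * Z
  up <- 4 * X / den; vp <- 9 * Y / den
  ok <- abs(up - run$target$u_prime) <= chroma_tol &
        abs(vp - run$target$v_prime) <= chroma_tol
  if (!any(ok)) return(empty())
  S <- S[, ok, drop = FALSE]
  Wk <- run$weights[ok, , drop = FALSE]
  up <- up[ok]; vp <- vp[ok]
  ev <- 683 * colSums(S * tab$vlambda)
  S <- sweep(S, 2, e_v_out / ev, "*")
  emel <- colSums(S * tab$smel) / tab$k_mel_d65
  metrics <- data.frame(
    e_v = rep(e_v_out, ncol(S)), e_mel = emel, gamma_mel = emel / e_v_out,
    u_prime = up, v_prime = vp,
    du_prime = up - run$target$u_prime, dv_prime = vp - run$target$v_prime)
  structure(list(target = run$target, luminaire = run$luminaire,
                 n = ncol(S), weights = Wk, spectra = S, metrics = metrics),
            class = "metamer_set")
}

#' @export
print.metamer_set <- function(x, ...) {
  cat("<metamer_set>", x$luminaire, "luminaire,",
      x$n, "members at target",
      sprintf("(%.0f K, Duv %+.3f)\n",
              x$target$cct_K, x$target$duv))
  invisible(x)
}
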