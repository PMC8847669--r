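## Calibration: weighted least-squares cost on max-normalized data and the
## staged hybrid estimation pipeline (Latin hypercube starts, derivative-free
## pattern search, local quasi-Newton refinement).

#' Weighted, max-normalized sum-of-squares cost
#'
#' For every observation `y_i(t_j)` with matching simulated value
#' `yhat_i(t_j)` the cost accumulates
#' `((y - yhat) / (max_j y_i * sd_ij))^2`, where `max_j y_i` is the maximum
#' of observable `i` within its dataset (guarding against scale bias across
#' assays) and `sd` defaults to 1 when absent. Simulated values are linearly
#' interpolated on the simulation grid per observable and arm.
#'
#' @param datasets A `dcvax_dataset` tibble (or list of them) with columns
#'   `observable`, `arm`, `time`, `value` and optionally `sd`.
#' @param simulated Tibble with columns `observable`, `arm`, `time`,
#'   `value`: the model prediction, on a grid covering all observation
#'   times.
#' @return Non-negative scalar cost; 0 iff the simulation matches every
#'   observation exactly.
#' @export
cost_function <- function(datasets, simulated) {
  if (!is.data.frame(datasets)) {
    return(sum(vapply(datasets, cost_function, numeric(1),
                      simulated = simulated)))
  }
  obs <- datasets
  if (!"sd" %in% names(obs)) obs$sd <- 1
  obs$sd[is.na(obs$sd) | obs$sd == 0] <- 1
  if (!"arm" %in% names(obs)) obs$arm <- "default"
  sim <- simulated
  if (!"arm" %in% names(sim)) sim$arm <- "default"
  total <- 0
  for (key in split(obs, paste(obs$observable, obs$arm))) {
    ymax <- max(key$value)
    if (ymax == 0) stop("dataset maximum is 0 for observable ",
                        key$observable[1], "; cannot normalize")
    s <- sim[sim$observable == key$observable[1] & sim$arm == key$arm[1], ]
    if (nrow(s) == 0) stop("no simulated values for observable ",
                           key$observable[1])
    if (min(key$time) < min(s$time) || max(key$time) > max(s$time)) {
      stop("observation time outside simulated range for ",
           key$observable[1])
    }
    yhat <- stats::approx(s$time, s$value, xout = key$time)$y
    total <- total + sum(((key$value - yhat) / (ymax * key$sd))^2)
  }
  total
}

#' Latin hypercube sample over a bounded box
#'
#' Stratified uniform sampling: in each dimension exactly one point falls in
#' each of the `n` equal-width strata.
#'
#' @param n Number of samples.
#' @param bounds Data frame with columns `name`, `lower`, `upper` (or a
#'   2-column matrix with rownames).
#' @param seed RNG seed.
#' @return Tibble of `n` rows, one column per parameter.
#' @export
lhs_sample <- function(n, bounds, seed = 1L) {
  stopifnot(n >= 1)
  if (is.matrix(bounds)) {
    bounds <- tibble::tibble(name = rownames(bounds), lower = bounds[, 1],
                             upper = bounds[, 2])
  }
  if (any(bounds$lower > bounds$upper)) stop("lower bound exceeds upper")
  d <- nrow(bounds)
  set.seed(seed)
  u <- lhs::randomLHS(n, d)
  x <- sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"), 2,
             bounds$lower, "+")
  colnames(x) <- bounds$name
  tibble::as_tibble(x)
}

## One bound-constrained coordinate pattern search (on 0-1 scaled
## coordinates): poll +/- mesh along each axis; move & expand on success,
## halve mesh on failure; stop at mesh < tol or evaluation budget.
pattern_search_one <- function(fn, x0, lower, upper, budget = 2000,
                               mesh_tol = 1e-6) {
  rng <- upper - lower
  rng[rng == 0] <- 1
  z <- (x0 - lower) / rng
  clamp <- function(z) pmin(1, pmax(0, z))
  fz <- function(z) fn(lower + z * rng)
  f0 <- fz(z)
  evals <- 1L
  if (!is.finite(f0)) {
    return(list(par = x0, value = Inf, evals = evals, failed = TRUE))
  }
  mesh <- 0.25
  d <- length(z)
  while (mesh >= mesh_tol && evals < budget) {
    improved <- FALSE
    for (i in seq_len(d)) {
      for (s in c(1, -1)) {
        if (evals >= budget) break
        zc <- z
        zc[i] <- z[i] + s * mesh
        zc <- clamp(zc)
        if (identical(zc[i], z[i])) next
        fc <- fz(zc)
        evals <- evals + 1L
        if (is.finite(fc) && fc < f0) {
          z <- zc
          f0 <- fc
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    mesh <- if (improved) min(0.5, mesh * 2) else mesh / 2
  }
  list(par = lower + z * rng, value = f0, evals = evals, failed = FALSE)
}

#' Global stage of the hybrid search (pattern search per start)
#'
#' Runs a derivative-free, bound-constrained coordinate pattern search from
#' each start vector and returns all solutions ranked by cost. Starts whose
#' objective is non-finite are marked failed rather than aborting the
#' search.
#'
#' @param objective Function mapping a named parameter vector to a finite
#'   scalar cost.
#' @param starts Data frame of start vectors (one row per start, columns =
#'   parameters), e.g. from [lhs_sample()].
#' @param bounds Data frame with `name`, `lower`, `upper` matching the
#'   columns of `starts`.
#' @param budget Evaluation budget per start.
#' @param mesh_tol Relative mesh size below which a search stops.
#' @param top Number of best solutions flagged for the local stage
#'   (default 100).
#' @return Tibble with columns `cost`, `evals`, `failed`, `rank`, `top` and
#'   one column per parameter, sorted by cost.
#' @export
global_search <- function(objective, starts, bounds, budget = 2000,
                          mesh_tol = 1e-6, top = 100) {
  starts <- as.data.frame(starts)[, bounds$name, drop = FALSE]
  sols <- purrr::map(seq_len(nrow(starts)), function(i) {
    x0 <- stats::setNames(as.numeric(starts[i, ]), bounds$name)
    res <- pattern_search_one(function(x) objective(stats::setNames(x, bounds$name)),
                              x0, bounds$lower, bounds$upper,
                              budget = budget, mesh_tol = mesh_tol)
    c(list(cost = res$value, evals = res$evals, failed = res$failed),
      as.list(stats::setNames(res$par, bounds$name)))
  })
  out <- dplyr::bind_rows(sols)
  out <- dplyr::arrange(out, .data$cost)
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top & !out$failed
  tibble::as_tibble(out)
}

#' Local refinement stage (bound-constrained quasi-Newton)
#'
#' Refines each start with `L-BFGS-B` (finite-difference gradients) and
#' never returns a cost above the start's own. The best `n_best` refined
#' solutions (default 15) are flagged for downstream identifiability
#' analysis.
#'
#' @param objective,bounds As in [global_search()].
#' @param starts Data frame of start vectors (typically the top solutions of
#'   the global stage).
#' @param n_best Size of the best-solution subset to flag.
#' @return Tibble like [global_search()]'s, with a `best` flag column.
#' @export
local_refine <- function(objective, starts, bounds, n_best = 15) {
  starts <- as.data.frame(starts)[, bounds$name, drop = FALSE]
  if (nrow(starts) < 1) stop("at least one start is required")
  sols <- purrr::map(seq_len(nrow(starts)), function(i) {
    x0 <- stats::setNames(as.numeric(starts[i, ]), bounds$name)
    f0 <- objective(x0)
    res <- try(stats::optim(
      x0, function(x) objective(stats::setNames(x, bounds$name)),
      method = "L-BFGS-B", lower = bounds$lower, upper = bounds$upper,
      control = list(factr = 1e4)
    ), silent = TRUE)
    if (inherits(res, "try-error") || res$value > f0) {
      list(par = x0, value = f0, failed = inherits(res, "try-error"))
    } else {
      list(par = res$par, value = res$value, failed = FALSE)
    }
  })
  if (all(vapply(sols, `[[`, logical(1), "failed"))) {
    stop("all local refinements failed")
  }
  out <- dplyr::bind_rows(purrr::map(sols, function(s) {
    c(list(cost = s$value, failed = s$failed),
      as.list(stats::setNames(s$par, bounds$name)))
  }))
  out <- dplyr::arrange(out, .data$cost)
  out$rank <- seq_len(nrow(out))
  out$best <- out$rank <= n_best & !out$failed
  tibble::as_tibble(out)
}

#' The staged calibration plan
#'
#' The model is calibrated module by module, each stage fixing its estimates
#' before the next runs:
#'
#' 1. `biodistribution`: the six DC trafficking rates, against the organ
#'    uptake curves (organ volumes stay fixed at physiological values).
#' 2. `nfkb`: the 15 receptor-proximal/IKK/NF-kB-core constants, against
#'    the LPS time courses (`k_ph2` is a single shared constant).
#' 3. `cytokine`: the 16 cytokine/CD70 constants, against the
#'    post-electroporation panels.
#' 4. `tcell`: exactly one free parameter, the Michaelis constant `K_4`,
#'    against the weekly T-cell counts.
#'
#' Rate constants are searched in log10 space within their bounds.
#'
#' @param params Parameter tibble providing names, values and bounds.
#' @param stages Character vector selecting a subset of stages (in order).
#' @return List of stage descriptors (`name`, `kind`, `free`).
#' @export
calibration_plan <- function(params = reference_parameters(),
                             stages = c("biodistribution", "nfkb",
                                        "cytokine", "tcell")) {
  free <- list(
    biodistribution = c("mu_BS", "mu_BLu", "mu_BLi", "mu", "mu_S0",
                        "mu_Lu0"),
    nfkb = c("k_ph1_TRAF2", "k_ph1_IRAK1", "k_ph2", "k_deg_TRAF2p",
             "k_deg_IRAK1p", "k_syn_IKK", "k_act_IKK", "k_deg_IKK",
             "k_deg_IKKb", "N_tot", "k_ass", "k_transc_mIkBa",
             "k_deg_mIkBa", "k_tranl_IkBa", "k_loss_IkBa"),
    cytokine = params$name[params$group == "cytokine"],
    tcell = "K_4"
  )
  stopifnot(all(stages %in% names(free)))
  fixed <- params$name[params$fixed]
  purrr::map(stages, function(st) {
    fr <- setdiff(free[[st]], fixed)
    list(name = st, kind = st, free = fr)
  })
}

## Objective factory for one stage: log10-space cost of the stage's
## dataset(s) given the current full parameter vector.
stage_objective <- function(stage, dataset, params_full, constants) {
  force(stage)
  function(theta) {
    v <- params_full
    v[names(theta)] <- 10^theta
    sim <- try(synthetic_truth(stage$kind, list(
      params = v, constants = constants,
      times = stats::setNames(list(sort(unique(dataset$time))), stage$kind)
    )), silent = TRUE)
    if (inherits(sim, "try-error") || any(!is.finite(sim$value))) {
      return(NaN)
    }
    cost_function(dataset, sim)
  }
}

#' Run the staged hybrid calibration
#'
#' Executes the stages of a [calibration_plan()] in order: Latin hypercube
#' starts in log10 space, pattern search from every start, local refinement
#' of the top solutions, then the stage's best estimates are fixed before
#' the next stage. The full per-stage solution archives are kept for
#' practical-identifiability analysis.
#'
#' @param plan A [calibration_plan()].
#' @param datasets Named list of `dcvax_dataset` objects keyed by stage
#'   kind.
#' @param params Starting parameter tibble (values of non-free parameters
#'   are used as-is).
#' @param constants Design constants.
#' @param seed RNG seed (drives the Latin hypercube draws).
#' @param control List with elements `n_lhs` (starts per stage, default
#'   1000), `budget` (pattern-search evaluations per start, default 2000),
#'   `top` (solutions passed to refinement, default 100), `n_best` (refined
#'   subset, default 15).
#' @return A `dcvax_calibration`: list of per-stage results (`global`,
#'   `refined`, `best` named vector, `cost`) plus the final parameter
#'   tibble.
#' @export
calibrate <- function(plan, datasets, params = reference_parameters(),
                      constants = design_constants(), seed = 1L,
                      control = list()) {
  ctl <- utils::modifyList(list(n_lhs = 1000, budget = 2000, top = 100,
                                n_best = 15), control)
  v <- param_values(params)
  stage_results <- list()
  for (si in seq_along(plan)) {
    stage <- plan[[si]]
    ds <- datasets[[stage$kind]]
    if (is.null(ds)) stop("missing dataset for stage ", stage$kind)
    rows <- match(stage$free, params$name)
    bounds <- tibble::tibble(
      name = stage$free,
      lower = log10(pmax(params$lower[rows], 1e-12)),
      upper = log10(params$upper[rows])
    )
    obj <- stage_objective(stage, ds, v, constants)
    starts <- lhs_sample(ctl$n_lhs, bounds, seed = seed + si)
    glob <- global_search(obj, starts, bounds, budget = ctl$budget,
                          top = ctl$top)
    ref <- local_refine(obj, glob[glob$top, bounds$name], bounds,
                        n_best = ctl$n_best)
    best <- stats::setNames(as.numeric(ref[1, bounds$name]), bounds$name)
    v[bounds$name] <- 10^best
    stage_results[[stage$name]] <- list(
      stage = stage$name, global = glob, refined = ref,
      best = 10^best, cost = ref$cost[1], bounds = bounds, seed = seed + si
    )
  }
  out_params <- params
  out_params$value <- unname(v[params$name])
  structure(list(stages = stage_results, params = out_params, seed = seed,
                 control = ctl),
            class = "dcvax_calibration")
}

#' @export
print.dcvax_calibration <- function(x, ...) {
  cat("<dcvax_calibration>", length(x$stages), "stage(s)\n")
  for (s in x$stages) {
    cat(sprintf("  %-16s cost %.4g  (%d free parameters)\n",
                s$stage, s$cost, length(s$best)))
  }
  invisible(x)
}

#' Tidy a calibration result
#'
#' @param x A `dcvax_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter: `stage`, `name`,
#'   `estimate`.
#' @export
tidy.dcvax_calibration <- function(x, ...) {
  purrr::map_dfr(x$stages, function(s) {
    tibble::tibble(stage = s$stage, name = names(s$best),
                   estimate = unname(s$best))
  })
}

#' @describeIn tidy.dcvax_calibration One-row summary per stage (final cost,
#'   numbers of starts and refined solutions).
#' @export
glance.dcvax_calibration <- function(x, ...) {
  purrr::map_dfr(x$stages, function(s) {
    tibble::tibble(stage = s$stage, cost = s$cost,
                   n_starts = nrow(s$global), n_refined = nrow(s$refined))
  })
}
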