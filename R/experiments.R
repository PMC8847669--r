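## Virtual experiments: vaccine-arm comparison and single/pairwise
## parameter-perturbation scans on the steady-state memory T-cell count.

#' Compare the normal-DC and caIKK-DC vaccine arms
#'
#' Simulates both arms from identical initial conditions (injected dose
#' `DC_in`, naive pool `T_0`) with the only difference being the IKK-beta
#' degradation rate (0.840 vs 0.216 per hour by default), and reports the
#' caIKK/normal ratios of the short-lived effector and memory pools at the
#' steady-state horizon, together with the full trajectories and the
#' time-integrated free NF-kB of each arm.
#'
#' @param params Parameter tibble.
#' @param constants Design constants.
#' @param k_deg_IKKb_caikk caIKK-arm override of `k_deg_IKKb`.
#' @return A `dcvax_vaccine_comparison` list: `fold_memory`, `fold_sle`,
#'   `memory` / `sle` per arm, `nfkb_integral` per arm, `trajectories`.
#' @export
compare_vaccines <- function(params = reference_parameters(),
                             constants = design_constants(),
                             k_deg_IKKb_caikk = 0.216) {
  sc_n <- default_scenario("normal_dc", params, constants)
  sc_c <- default_scenario("caikk_dc", params, constants)
  sc_c$overrides["k_deg_IKKb"] <- k_deg_IKKb_caikk
  h <- constants$horizon_steady
  times <- c(seq(0, 400, by = 1), seq(402, h, by = 2))
  arms <- list(normal = sc_n, caikk = sc_c)
  trs <- purrr::map(arms, function(sc) {
    simulate_model(sc, params, constants, times = times)
  })
  at_end <- function(tr, var) tr$state[nrow(tr$state), var]
  m <- purrr::map_dbl(trs, at_end, var = "memory")
  sle <- purrr::map_dbl(trs, at_end, var = "short_lived_effector")
  if (m[["normal"]] <= 0) stop("degenerate baseline: normal-arm memory is 0")
  nfkb_int <- purrr::map_dbl(trs, function(tr) {
    x <- tr$state[, "nfkb"]
    sum((x[-1] + x[-length(x)]) / 2 * diff(tr$time))
  })
  structure(
    list(fold_memory = unname(m[["caikk"]] / m[["normal"]]),
         fold_sle = unname(sle[["caikk"]] / sle[["normal"]]),
         memory = m, sle = sle, nfkb_integral = nfkb_int,
         trajectories = trs, k_deg_IKKb_caikk = k_deg_IKKb_caikk),
    class = "dcvax_vaccine_comparison"
  )
}

#' @export
print.dcvax_vaccine_comparison <- function(x, ...) {
  cat("<dcvax_vaccine_comparison> caIKK vs normal:\n")
  cat(sprintf("  memory fold-change: %.3f\n", x$fold_memory))
  cat(sprintf("  SLE fold-change:    %.3f\n", x$fold_sle))
  invisible(x)
}

#' @describeIn compare_vaccines One-row summary tibble.
#' @param x A `dcvax_vaccine_comparison`.
#' @param ... Unused.
#' @export
glance.dcvax_vaccine_comparison <- function(x, ...) {
  tibble::tibble(
    fold_memory = x$fold_memory, fold_sle = x$fold_sle,
    memory_normal = unname(x$memory["normal"]),
    memory_caikk = unname(x$memory["caikk"]),
    nfkb_integral_normal = unname(x$nfkb_integral["normal"]),
    nfkb_integral_caikk = unname(x$nfkb_integral["caikk"])
  )
}

#' Log-spaced fold-factor grid
#'
#' @param n Number of points (default 25).
#' @param from,to Grid limits (default 0.1 and 10, inclusive).
#' @return Numeric vector including both endpoints.
#' @export
fold_grid <- function(n = 25, from = 0.1, to = 10) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Single-parameter perturbation scan of steady-state memory
#'
#' Multiplies one parameter by each factor of a log-spaced grid spanning
#' `[0.1, 10]`, recomputes the steady-state memory T-cell count under the
#' scan scenario (the caIKK arm by default, the therapeutic context of the
#' perturbation experiments), and reports the fold-change relative to the
#' unperturbed baseline. Solver failures at individual grid points are
#' flagged and the scan continues.
#'
#' @param param Parameter name to perturb.
#' @param params Parameter tibble.
#' @param constants Design constants.
#' @param grid Fold-factor grid from [fold_grid()].
#' @param scenario Scenario object or name (default `"caikk_dc"`).
#' @return A `dcvax_scan` tibble: `fold`, `value` (M*), `fold_change`,
#'   `converged`, `failed`; attributes `param`, `baseline`.
#' @export
perturb_scan_single <- function(param, params = reference_parameters(),
                                constants = design_constants(),
                                grid = fold_grid(),
                                scenario = "caikk_dc") {
  stopifnot(param %in% params$name)
  if (is.character(scenario)) {
    scenario <- default_scenario(scenario, params, constants)
  }
  base_v <- scan_base_value(param, params, scenario)
  baseline <- steady_state_memory(scenario, params, constants)
  rows <- purrr::map(grid, function(f) {
    ov <- stats::setNames(base_v * f, param)
    m <- try(steady_state_memory(scenario, params, constants,
                                 overrides = ov), silent = TRUE)
    if (inherits(m, "try-error")) {
      tibble::tibble(fold = f, value = NA_real_, converged = NA,
                     failed = TRUE)
    } else {
      tibble::tibble(fold = f, value = as.numeric(m),
                     converged = attr(m, "converged"), failed = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$fold_change <- out$value / as.numeric(baseline)
  structure(tibble::as_tibble(out), param = param,
            baseline = as.numeric(baseline),
            class = c("dcvax_scan", class(tibble::tibble())))
}

## Effective baseline value of a scanned parameter under a scenario (the
## scenario override wins over the table value, e.g. k_deg_IKKb = 0.216 in
## the caIKK arm).
scan_base_value <- function(param, params, scenario) {
  if (!is.null(scenario$overrides) && param %in% names(scenario$overrides)) {
    unname(scenario$overrides[[param]])
  } else {
    params$value[params$name == param]
  }
}

#' Pairwise perturbation scan of steady-state memory
#'
#' Full factorial over the log-spaced fold grids of two parameters. Besides
#' the steady-state memory matrix, reports the combined-modulation gain:
#' the percent increase of M* at the jointly beneficial extreme corner over
#' the better of the two single-parameter extremes.
#'
#' @param param1,param2 Distinct parameter names.
#' @param params Parameter tibble.
#' @param constants Design constants.
#' @param grid1,grid2 Fold grids (default [fold_grid()] with 25 points).
#' @param scenario Scenario object or name (default `"caikk_dc"`).
#' @param extreme1,extreme2 The beneficial extreme fold of each parameter
#'   used for the gain summary (defaults 0.1 for degradation-type first
#'   parameter and 10 for the second, matching the IKK-beta down /
#'   IkB-alpha-mRNA up experiment).
#' @return A `dcvax_scan2` list: `grid` (long tibble `fold1`, `fold2`,
#'   `value`, `fold_change`), `matrix` (fold1 x fold2), `baseline`,
#'   `gain_percent`, `single_extremes`.
#' @export
perturb_scan_pairwise <- function(param1, param2,
                                  params = reference_parameters(),
                                  constants = design_constants(),
                                  grid1 = fold_grid(), grid2 = fold_grid(),
                                  scenario = "caikk_dc",
                                  extreme1 = 0.1, extreme2 = 10) {
  stopifnot(param1 %in% params$name, param2 %in% params$name,
            param1 != param2)
  if (is.character(scenario)) {
    scenario <- default_scenario(scenario, params, constants)
  }
  b1 <- scan_base_value(param1, params, scenario)
  b2 <- scan_base_value(param2, params, scenario)
  baseline <- as.numeric(steady_state_memory(scenario, params, constants))
  eval_point <- function(f1, f2) {
    ov <- stats::setNames(c(b1 * f1, b2 * f2), c(param1, param2))
    m <- try(steady_state_memory(scenario, params, constants,
                                 overrides = ov), silent = TRUE)
    if (inherits(m, "try-error")) NA_real_ else as.numeric(m)
  }
  cells <- tidyr::expand_grid(fold1 = grid1, fold2 = grid2)
  cells$value <- purrr::map2_dbl(cells$fold1, cells$fold2, eval_point)
  cells$fold_change <- cells$value / baseline
  mat <- matrix(cells$value, nrow = length(grid1), byrow = TRUE,
                dimnames = list(signif(grid1, 4), signif(grid2, 4)))
  m_comb <- eval_point(extreme1, extreme2)
  m_s1 <- eval_point(extreme1, 1)
  m_s2 <- eval_point(1, extreme2)
  gain <- 100 * (m_comb / max(m_s1, m_s2) - 1)
  structure(
    list(grid = cells, matrix = mat, baseline = baseline,
         param1 = param1, param2 = param2,
         gain_percent = gain,
         single_extremes = c(stats::setNames(m_s1, param1),
                             stats::setNames(m_s2, param2)),
         combined_extreme = m_comb),
    class = "dcvax_scan2"
  )
}

#' @export
print.dcvax_scan2 <- function(x, ...) {
  cat("<dcvax_scan2>", x$param1, "x", x$param2, "|",
      nrow(x$matrix), "x", ncol(x$matrix), "grid\n")
  cat(sprintf("  combined-modulation gain: %.1f%%\n", x$gain_percent))
  invisible(x)
}

#' Tidy a perturbation scan
#'
#' @param x A `dcvax_scan` or `dcvax_scan2`.
#' @param ... Unused.
#' @return Long tibble of scan results.
#' @export
tidy.dcvax_scan2 <- function(x, ...) x$grid
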