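## Sobol global sensitivity analysis: Saltelli-style sampling with the
## Saltelli (2010) first-order and Jansen (1999) total-order estimators.

## Core engine: batch_fn maps a matrix of points (rows) to a matrix of
## outputs (rows x n_out). Returns S1/ST matrices (parameter x output).
sobol_engine <- function(batch_fn, ranges, N, seed) {
  if (N < 64 || bitwAnd(N, N - 1L) != 0) {
    stop("N must be a power of 2 and at least 64")
  }
  if (any(!is.finite(ranges$lower)) || any(!is.finite(ranges$upper))) {
    stop("ranges must be finite")
  }
  d <- nrow(ranges)
  set.seed(seed)
  scale_mat <- function(u) {
    x <- sweep(sweep(u, 2, ranges$upper - ranges$lower, "*"), 2,
               ranges$lower, "+")
    colnames(x) <- ranges$name
    x
  }
  A <- scale_mat(lhs::randomLHS(N, d))
  B <- scale_mat(lhs::randomLHS(N, d))
  fA <- batch_fn(A)
  fB <- batch_fn(B)
  if (is.null(dim(fA))) fA <- matrix(fA, ncol = 1)
  if (is.null(dim(fB))) fB <- matrix(fB, ncol = 1)
  n_out <- ncol(fA)
  bad <- sum(!is.finite(fA)) + sum(!is.finite(fB))
  S1 <- matrix(NA_real_, d, n_out, dimnames = list(ranges$name, colnames(fA)))
  ST <- S1
  V <- apply(rbind(fA, fB), 2, stats::var)
  fAB_list <- vector("list", d)
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- batch_fn(ABi)
    if (is.null(dim(fABi))) fABi <- matrix(fABi, ncol = 1)
    bad <- bad + sum(!is.finite(fABi))
    fAB_list[[i]] <- fABi
    for (j in seq_len(n_out)) {
      if (V[j] <= 0 || !is.finite(V[j])) {
        ## zero-variance output: indices reported as 0 by convention
        S1[i, j] <- 0
        ST[i, j] <- 0
      } else {
        S1[i, j] <- mean(fB[, j] * (fABi[, j] - fA[, j])) / V[j]
        ST[i, j] <- mean((fA[, j] - fABi[, j])^2) / (2 * V[j])
      }
    }
  }
  total_evals <- N * (d + 2) * n_out
  if (bad > 0.01 * total_evals) {
    stop("more than 1% of model evaluations returned non-finite values")
  }
  list(S1 = S1, ST = ST, V = V, fA = fA, fB = fB, fAB = fAB_list)
}

## Bootstrap standard errors of the indices of one output column.
sobol_se <- function(eng, out_col = 1, n_boot = 100, seed = 1L) {
  set.seed(seed)
  N <- nrow(eng$fA)
  d <- length(eng$fAB)
  se <- matrix(NA_real_, d, 2,
               dimnames = list(rownames(eng$S1), c("S1", "ST")))
  draws <- replicate(n_boot, sample.int(N, N, replace = TRUE))
  for (i in seq_len(d)) {
    s1b <- stb <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- draws[, b]
      fa <- eng$fA[idx, out_col]
      fb <- eng$fB[idx, out_col]
      fab <- eng$fAB[[i]][idx, out_col]
      v <- stats::var(c(fa, fb))
      s1b[b] <- mean(fb * (fab - fa)) / v
      stb[b] <- mean((fa - fab)^2) / (2 * v)
    }
    se[i, ] <- c(stats::sd(s1b), stats::sd(stb))
  }
  se
}

#' Sobol first- and total-order indices of a scalar model
#'
#' Saltelli-style sampling with `N * (d + 2)` model evaluations; first-order
#' indices use the Saltelli (2010) estimator, total-order indices the
#' Jansen (1999) estimator. Negative estimates (possible within estimator
#' noise) are reported as-is.
#'
#' @param output_fn Function mapping a named parameter vector to a scalar.
#' @param ranges Data frame with columns `name`, `lower`, `upper`.
#' @param N Base sample size; a power of 2, at least 64.
#' @param seed RNG seed.
#' @return A `dcvax_sobol` object; see [timedependent_sobol()].
#' @export
sobol_indices <- function(output_fn, ranges, N = 1024, seed = 1L) {
  batch_fn <- function(X) {
    apply(X, 1, function(row) output_fn(stats::setNames(row, ranges$name)))
  }
  eng <- sobol_engine(batch_fn, ranges, N, seed)
  colnames(eng$S1) <- colnames(eng$ST) <- "output"
  new_sobol(eng, ranges, N, seed, outputs = "output")
}

new_sobol <- function(eng, ranges, N, seed, outputs) {
  colnames(eng$S1) <- outputs
  colnames(eng$ST) <- outputs
  structure(list(S1 = eng$S1, ST = eng$ST, variance = eng$V,
                 ranges = ranges, N = N, seed = seed, outputs = outputs,
                 engine = eng),
            class = "dcvax_sobol")
}

#' Default sensitivity ranges around the reference parameterization
#'
#' All non-fixed kinetic parameters plus the injected DC dose `DC_in`,
#' each varied by `+/- width` (fraction of its reference value; default 0.5,
#' with a 0.9 robustness mode mirroring the stress test).
#'
#' @param params Parameter tibble.
#' @param constants Design constants (supplies the `DC_in` reference).
#' @param width Half-width of the relative range (0.5 = +/-50%).
#' @return Tibble with columns `name`, `lower`, `upper`.
#' @export
sensitivity_ranges <- function(params = reference_parameters(),
                               constants = design_constants(),
                               width = 0.5) {
  stopifnot(width > 0, width < 1)
  free <- params[!params$fixed, ]
  tibble::tibble(
    name = c(free$name, "DC_in"),
    lower = c(free$value, constants$DC_in) * (1 - width),
    upper = c(free$value, constants$DC_in) * (1 + width)
  )
}

#' Time-resolved Sobol indices of the memory T-cell output
#'
#' Computes first- and total-order indices of the memory T-cell count at
#' each grid time over the simulation window (default `[0, 200]` h, with a
#' 500 h robustness mode) and of its trapezoid time integral, all from one
#' shared Saltelli sample. `DC_in` is treated as an input alongside the
#' kinetic parameters. Outputs with zero variance (e.g. `M` at t = 0)
#' report indices of 0 by convention.
#'
#' @param scenario Scenario object or name (default `"normal_dc"`). Any
#'   scenario parameter overrides are re-applied before sampling, and the
#'   sampled values win, so every input in `ranges` is genuinely varied.
#' @param params Parameter tibble.
#' @param constants Design constants.
#' @param ranges As from [sensitivity_ranges()].
#' @param times Output time grid (h).
#' @param N Base sample size (power of 2, >= 64).
#' @param seed RNG seed.
#' @return A `dcvax_sobol` with one output per grid time (`"M_t<h>"`) plus
#'   `"integral"`.
#' @export
timedependent_sobol <- function(scenario = "normal_dc",
                                params = reference_parameters(),
                                constants = design_constants(),
                                ranges = sensitivity_ranges(params,
                                                            constants),
                                times = seq(0, 200, by = 10),
                                N = 1024, seed = 1L) {
  if (is.character(scenario)) {
    scenario <- default_scenario(scenario, params, constants)
  }
  ## sampled values are applied after any scenario overrides, so every
  ## input listed in `ranges` is genuinely varied
  v0 <- param_values_with_overrides(param_values(params),
                                    scenario$overrides)
  scenario_clean <- scenario
  scenario_clean$overrides <- NULL
  eval_one <- function(row) {
    v <- v0
    con <- constants
    nm <- names(row)
    if ("DC_in" %in% nm) {
      con$DC_in <- row[["DC_in"]]
      row <- row[nm != "DC_in"]
    }
    v[names(row)] <- row
    tr <- try(simulate_model(scenario_clean, v, con, times = times,
                             rtol = 1e-6, atol = 1e-8), silent = TRUE)
    if (inherits(tr, "try-error")) return(rep(NA_real_, length(times) + 1))
    M <- tr$state[, "memory"]
    dt <- diff(times)
    integral <- sum((M[-1] + M[-length(M)]) / 2 * dt)
    c(M, integral)
  }
  batch_fn <- function(X) {
    out <- apply(X, 1, function(row) eval_one(stats::setNames(row, ranges$name)))
    t(out)
  }
  outputs <- c(paste0("M_t", times), "integral")
  eng <- sobol_engine(batch_fn, ranges, N, seed)
  new_sobol(eng, ranges, N, seed, outputs = outputs)
}

#' @export
print.dcvax_sobol <- function(x, ...) {
  cat("<dcvax_sobol>", nrow(x$S1), "parameters x", length(x$outputs),
      "output(s), N =", x$N, "\n")
  invisible(x)
}

#' Tidy Sobol indices into long format
#'
#' @param x A `dcvax_sobol`.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `output`, `S1`, `ST`.
#' @export
tidy.dcvax_sobol <- function(x, ...) {
  s1 <- tibble::as_tibble(x$S1, rownames = "parameter")
  s1 <- tidyr::pivot_longer(s1, -"parameter", names_to = "output",
                            values_to = "S1")
  st <- tibble::as_tibble(x$ST, rownames = "parameter")
  st <- tidyr::pivot_longer(st, -"parameter", names_to = "output",
                            values_to = "ST")
  dplyr::left_join(s1, st, by = c("parameter", "output"))
}

#' Rank parameters by total-order influence
#'
#' Descending by the total-order index of the integral output (or the only
#' output for scalar analyses); ties broken by first-order index, then by
#' name. Negative estimates are clamped to 0 for ranking only.
#'
#' @param result A `dcvax_sobol`.
#' @param k Number of parameters to return.
#' @return Tibble with columns `rank`, `parameter`, `S1`, `ST`.
#' @export
rank_parameters <- function(result, k = nrow(result$ST)) {
  stopifnot(inherits(result, "dcvax_sobol"))
  if (k > nrow(result$ST)) stop("k exceeds the number of parameters")
  out_col <- if ("integral" %in% result$outputs) "integral"
             else result$outputs[length(result$outputs)]
  st <- pmax(result$ST[, out_col], 0)
  s1 <- pmax(result$S1[, out_col], 0)
  ord <- order(-st, -s1, names(st))
  tibble::tibble(rank = seq_len(k), parameter = names(st)[ord][seq_len(k)],
                 S1 = unname(result$S1[ord, out_col][seq_len(k)]),
                 ST = unname(result$ST[ord, out_col][seq_len(k)]))
}

#' Bootstrap standard errors of Sobol index estimates
#'
#' Resamples the stored Saltelli evaluations to give standard errors for
#' the indices of one output (default: the integral / last output).
#'
#' @param result A `dcvax_sobol`.
#' @param output Output name.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return Matrix (parameter x c("S1", "ST")) of standard errors.
#' @export
sobol_standard_errors <- function(result, output = NULL, n_boot = 100,
                                  seed = 1L) {
  stopifnot(inherits(result, "dcvax_sobol"))
  if (is.null(output)) output <- result$outputs[length(result$outputs)]
  out_col <- match(output, result$outputs)
  sobol_se(result$engine, out_col = out_col, n_boot = n_boot, seed = seed)
}
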