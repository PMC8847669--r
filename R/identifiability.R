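## Practical identifiability: linear dependence among top estimates and
## bootstrap confidence intervals from the best estimates.

#' Pearson correlations among top parameter estimates
#'
#' Correlation matrix of the estimated parameter vectors (rows = estimates,
#' columns = parameters). Pairs in which either column is constant get a
#' correlation of 0 by convention: a parameter whose estimate is unique
#' across solutions carries no linear dependence information.
#'
#' @param estimates Data frame or matrix of parameter estimates (top-100 of
#'   the global stage, typically); at least 3 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(estimates) {
  x <- as.matrix(estimates)
  if (nrow(x) < 3) stop("at least 3 estimate vectors are required")
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  const <- sds == 0 | !is.finite(sds)
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  r
}

#' Bootstrap confidence intervals for parameter estimates
#'
#' For each parameter, draws `n_boot` bootstrap resamples (with
#' replacement) of its values across the best estimates, takes the mean of
#' each resample, and reports a normal-theory interval
#' `mean_boot +/- z * sd_boot` at the requested level. Percentile intervals
#' are available via `type = "percentile"`.
#'
#' @param best Data frame/matrix of the best parameter estimates (rows =
#'   solutions, typically the best 15), or a numeric vector for a single
#'   parameter; at least 2 rows.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @param type `"normal"` (mean +/- z * sd of the bootstrap means, default)
#'   or `"percentile"`.
#' @return Tibble with columns `name`, `estimate` (sample mean),
#'   `boot_mean`, `boot_sd`, `low`, `high`.
#' @export
bootstrap_ci <- function(best, n_boot = 1000, level = 0.95, seed = 1L,
                         type = c("normal", "percentile")) {
  type <- match.arg(type)
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (is.null(dim(best))) best <- matrix(best, ncol = 1,
                                         dimnames = list(NULL, "value"))
  x <- as.matrix(best)
  if (nrow(x) < 2) stop("at least 2 values per parameter are required")
  set.seed(seed)
  z <- stats::qnorm(1 - (1 - level) / 2)
  purrr::map_dfr(colnames(x), function(nm) {
    vals <- x[, nm]
    boots <- vapply(seq_len(n_boot), function(b) {
      mean(sample(vals, length(vals), replace = TRUE))
    }, numeric(1))
    m <- mean(boots)
    s <- stats::sd(boots)
    if (type == "normal") {
      low <- m - z * s
      high <- m + z * s
    } else {
      q <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                           names = FALSE)
      low <- q[1]
      high <- q[2]
    }
    tibble::tibble(name = nm, estimate = mean(vals), boot_mean = m,
                   boot_sd = s, low = low, high = high)
  })
}

#' Practical-identifiability report for a calibration stage
#'
#' Combines the estimate correlations (over the top global solutions) with
#' bootstrap confidence intervals (over the best refined solutions) and
#' flags parameters as practically non-identifiable when their estimates
#' both spread widely across top solutions (relative spread above
#' `spread_threshold`) and are strongly linearly coupled to another
#' parameter (|r| above `cor_threshold`).
#'
#' @param calibration A `dcvax_calibration` from [calibrate()].
#' @param stage Stage name (default: first stage).
#' @param cor_threshold Absolute correlation above which a pair counts as
#'   coupled (default 0.8).
#' @param spread_threshold Relative spread (sd/|mean|) above which a
#'   parameter counts as poorly determined (default 0.1).
#' @param n_boot,level,seed Passed to [bootstrap_ci()].
#' @return A `dcvax_identifiability` list: `correlations` (matrix), `ci`
#'   (tibble), `flags` (tibble with `name`, `spread`, `max_abs_cor`,
#'   `non_identifiable`).
#' @export
identifiability_report <- function(calibration, stage = NULL,
                                   cor_threshold = 0.8,
                                   spread_threshold = 0.1,
                                   n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(calibration, "dcvax_calibration"))
  st <- if (is.null(stage)) calibration$stages[[1]]
        else calibration$stages[[stage]]
  pnames <- st$bounds$name
  top <- as.matrix(st$global[st$global$top, pnames, drop = FALSE])
  top <- 10^top  # archives are in log10 space
  best <- 10^as.matrix(st$refined[st$refined$best, pnames, drop = FALSE])
  corr <- correlation_matrix(top)
  ci <- bootstrap_ci(best, n_boot = n_boot, level = level, seed = seed)
  spread <- apply(top, 2, function(v) stats::sd(v) / max(abs(mean(v)),
                                                         .Machine$double.eps))
  offdiag <- corr
  diag(offdiag) <- 0
  max_cor <- apply(abs(offdiag), 2, max)
  spread_v <- unname(spread[pnames])
  max_cor_v <- unname(max_cor[pnames])
  flags <- tibble::tibble(
    name = pnames, spread = spread_v, max_abs_cor = max_cor_v,
    non_identifiable = spread_v > spread_threshold &
      max_cor_v > cor_threshold
  )
  structure(list(stage = st$stage, correlations = corr, ci = ci,
                 flags = flags),
            class = "dcvax_identifiability")
}

#' @export
print.dcvax_identifiability <- function(x, ...) {
  cat("<dcvax_identifiability> stage:", x$stage, "\n")
  cat("  non-identifiable:",
      paste(x$flags$name[x$flags$non_identifiable], collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an identifiability report
#'
#' @param x A `dcvax_identifiability`.
#' @param ... Unused.
#' @return The per-parameter tibble joining CI and flags.
#' @export
tidy.dcvax_identifiability <- function(x, ...) {
  dplyr::left_join(x$ci, x$flags, by = "name")
}
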