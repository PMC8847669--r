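## Synthetic calibration datasets.
##
## The four assay families the model is calibrated against are emulated by
## simulating the reference model under the matching scenario, sampling at
## assay-typical times, and applying an observation-noise model:
## multiplicative lognormal noise for counts/concentrations, additive
## Gaussian noise for max-normalized signals.

#' Generator configuration for synthetic datasets
#'
#' @param params Reference parameter tibble used for the underlying
#'   simulation.
#' @param constants Design constants.
#' @param sigma_lognormal Multiplicative lognormal noise sigma for
#'   count/concentration observables (default 0.1).
#' @param sd_additive Additive Gaussian noise sd for max-normalized
#'   observables (default 0.05).
#' @param n_replicates Named list of replicate counts per kind; defaults:
#'   1 for the single-patient organ-uptake curves, 4 for the cytometric
#'   cytokine panel, 3 elsewhere.
#' @param times Named list of sampling-time vectors per kind; defaults span
#'   the assay ranges (72 h for DC distribution and molecular panels, three
#'   weekly stimulations for T cells).
#' @param seed RNG seed; a fixed seed makes generation fully reproducible.
#' @return A `dcvax_generator_config` list.
#' @export
generator_config <- function(params = reference_parameters(),
                             constants = design_constants(),
                             sigma_lognormal = 0.1, sd_additive = 0.05,
                             n_replicates = NULL, times = NULL, seed = 1L) {
  stopifnot(sigma_lognormal >= 0, sd_additive >= 0)
  default_times <- list(
    biodistribution = c(0.5, 1, 2, 4, 8, 24, 48, 72),
    nfkb = c(0.25, 0.5, 1, 2, 4, 8, 24),
    cytokine = c(4, 24, 48, 72),
    tcell = c(168, 336, 504)
  )
  ## the organ-uptake radioactivity curves come from a single patient, so
  ## that kind has no replicate structure (and hence no sd weights)
  default_n <- list(biodistribution = 1L, nfkb = 3L, cytokine = 4L,
                    tcell = 3L)
  if (!is.null(times)) default_times[names(times)] <- times
  if (!is.null(n_replicates)) default_n[names(n_replicates)] <- n_replicates
  structure(
    list(params = params, constants = constants,
         sigma_lognormal = sigma_lognormal, sd_additive = sd_additive,
         times = default_times, n_replicates = default_n, seed = seed),
    class = "dcvax_generator_config"
  )
}

## Noiseless observable tables per kind (the "truth" the generator draws
## around). Returns tibble(observable, arm, time, value, normalized).
synthetic_truth <- function(kind, config) {
  p <- config$params
  con <- config$constants
  tt <- config$times[[kind]]
  grid <- sort(unique(c(0, tt)))
  if (kind == "biodistribution") {
    tr <- simulate_model("normal_dc", p, con, times = grid)
    obs <- tr$observables[match(tt, tr$observables$time), ]
    out <- tidyr::pivot_longer(
      obs[, c("time", "dc_count_blood", "dc_count_lung", "dc_count_liver",
              "dc_count_spleen")],
      -"time", names_to = "observable", values_to = "value"
    )
    out$arm <- "normal_dc"
    out$normalized <- FALSE
  } else if (kind == "nfkb") {
    tr <- simulate_model("lps", p, con, times = grid)
    idx <- match(tt, tr$time)
    raw <- tibble::tibble(
      time = rep(tt, 3),
      observable = rep(c("nfkb_activity", "ikba_mrna", "ikba_protein"),
                       each = length(tt)),
      value = c(tr$state[idx, "nfkb"], tr$state[idx, "m_ikba"],
                tr$state[idx, "ikba"] + tr$state[idx, "nfkb_ikba"])
    )
    ## max-normalized, as the binding-activity / qPCR / blot data are
    out <- dplyr::mutate(
      dplyr::group_by(raw, .data$observable),
      value = .data$value / max(.data$value)
    )
    out <- dplyr::ungroup(out)
    out$arm <- "lps"
    out$normalized <- TRUE
  } else if (kind == "cytokine") {
    tr <- simulate_model("caikk_dc", p, con, times = grid)
    idx <- match(tt, tr$time)
    out <- tibble::tibble(
      time = rep(tt, 4),
      observable = rep(c("il12", "il6", "il8", "cd70"), each = length(tt)),
      value = c(tr$state[idx, "il12"], tr$state[idx, "il6"],
                tr$state[idx, "il8"], tr$state[idx, "cd70"])
    )
    out$arm <- "caikk_dc"
    out$normalized <- FALSE
  } else if (kind == "tcell") {
    arms <- c(mock = "tcell_invitro_mock", caikk = "tcell_invitro_caikk")
    out <- purrr::imap_dfr(arms, function(scen, nm) {
      tr <- simulate_model(scen, p, con, times = grid)
      idx <- match(tt, tr$time)
      tibble::tibble(time = tt, observable = "sle_count",
                     value = tr$state[idx, "short_lived_effector"],
                     arm = nm)
    })
    out$normalized <- FALSE
  } else {
    stop("unknown dataset kind: ", kind)
  }
  out[, c("observable", "arm", "time", "value", "normalized")]
}

#' Generate a synthetic calibration dataset
#'
#' Simulates the reference model under the scenario matching `kind`, samples
#' the assay's observables at the configured times, draws replicate
#' observations under the noise model, and summarises them as mean and
#' empirical sd per time point:
#'
#' * `biodistribution`: per-organ DC counts over 72 h after intravenous
#'   injection (normal-DC arm).
#' * `nfkb`: max-normalized NF-kB activity, IkB-alpha mRNA and protein after
#'   sustained LPS stimulation.
#' * `cytokine`: IL-12, IL-6, IL-8 and CD70 levels at 4-72 h after caIKK
#'   electroporation (caIKK arm), n = 4 replicates.
#' * `tcell`: short-lived effector T-cell counts under three weekly DC
#'   stimulations, mock vs caIKK arms.
#'
#' With all noise parameters 0 the returned values equal the reference
#' trajectory exactly.
#'
#' @param kind One of `"biodistribution"`, `"nfkb"`, `"cytokine"`,
#'   `"tcell"`.
#' @param config A [generator_config()].
#' @return A `dcvax_dataset`: tibble with columns `observable`, `arm`,
#'   `time`, `value`, `sd`, `n`, `normalized`, plus attributes `kind` and
#'   `reference_max` (per-observable maxima used for normalization).
#' @export
generate_dataset <- function(kind, config = generator_config()) {
  stopifnot(inherits(config, "dcvax_generator_config"))
  truth <- synthetic_truth(kind, config)
  if (any(!is.finite(truth$value))) stop("non-finite simulated values")
  set.seed(config$seed + match(kind, names(config$times)))
  n <- config$n_replicates[[kind]]
  out <- dplyr::group_by(truth, .data$observable, .data$arm, .data$time)
  out <- dplyr::reframe(out, normalized = .data$normalized, draw = {
    if (.data$normalized[1]) {
      .data$value + stats::rnorm(n, 0, config$sd_additive)
    } else if (config$sigma_lognormal > 0) {
      .data$value * stats::rlnorm(n, -config$sigma_lognormal^2 / 2,
                                  config$sigma_lognormal)
    } else {
      rep(.data$value, n)
    }
  })
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$observable, .data$arm, .data$time,
                    .data$normalized),
    value = mean(.data$draw),
    sd = if (n > 1) stats::sd(.data$draw) else 0,
    n = n, .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$observable, .data$arm, .data$time)
  out <- out[, c("observable", "arm", "time", "value", "sd", "n",
                 "normalized")]
  ref_max <- tapply(truth$value, truth$observable, max)
  structure(tibble::as_tibble(out), kind = kind,
            reference_max = ref_max, class = c("dcvax_dataset",
                                               class(tibble::tibble())))
}

#' Write / read a dataset as CSV
#'
#' @param dataset A `dcvax_dataset`.
#' @param path File path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns the dataset tibble.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$kind <- attr(dataset, "kind") %||% NA_character_
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kind <- if ("kind" %in% names(df)) df$kind[1] else NA_character_
  df$kind <- NULL
  structure(tibble::as_tibble(df), kind = kind,
            class = c("dcvax_dataset", class(tibble::tibble())))
}
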