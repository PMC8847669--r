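## Canonical parameter order (single source of truth for the packed vector
## handed to the compiled right-hand side).
.param_names <- c(
  "mu_BS", "mu_BLu", "mu_BLi", "mu", "mu_S0", "mu_Lu0",
  "Q_Blood", "Q_Spleen", "Q_Lung", "Q_Liver",
  "k_ph1_TRAF2", "k_ph1_IRAK1", "k_ph2", "k_deg_TRAF2p", "k_deg_IRAK1p",
  "k_syn_IKK", "k_act_IKK", "k_deg_IKK", "k_deg_IKKb",
  "N_tot", "k_ass", "k_transc_mIkBa", "k_deg_mIkBa", "k_tranl_IkBa",
  "k_loss_IkBa",
  "k_transc1_mIL8", "k_transc2_mIL8", "k_deg_mIL8", "k_transl_IL8",
  "k_deg_IL8", "k_sec_IL8",
  "k_transc2_mIL6", "k_deg_mIL6", "k_transl_IL6", "k_deg_IL6",
  "k_transc2_mIL12", "k_deg_mIL12", "k_transl_IL12", "k_deg_IL12",
  "k_transc2_CD70", "k_deg_CD70",
  "k_act_N", "K_4", "k_diff1_EE", "k_diff2_EE", "k_deg_SLE"
)

#' Reference kinetic parameterization
#'
#' Returns the shipped reference parameter set of the multi-level
#' dendritic-cell (DC) vaccination model as a tibble with one row per named
#' parameter. The set contains exactly 46 entries in five functional groups:
#'
#' * `distribution` (10): first-order trafficking rates of injected DCs from
#'   blood into spleen (`mu_BS`), lung (`mu_BLu`), liver (`mu_BLi`) and other
#'   periphery (`mu`), the spleen and lung efflux rates `mu_S0`, `mu_Lu0`
#'   (the liver is a terminal reservoir), and the four organ volumes
#'   `Q_Blood`, `Q_Spleen`, `Q_Lung`, `Q_Liver` in cubic millimetres.
#' * `signaling` (9): receptor-proximal activation of TRAF2/IRAK1
#'   (saturable phosphorylation with a shared constant `k_ph2`), and the IKK
#'   module (synthesis, activation and turnover of the kinase pool, with
#'   `k_deg_IKKb` the degradation rate of active IKK-beta).
#' * `nfkb` (6): the NF-kB/IkB-alpha negative-feedback core, with a conserved
#'   NF-kB total `N_tot`, complex association `k_ass`, NF-kB-driven IkB-alpha
#'   mRNA transcription/degradation, translation, and IKK-beta-dependent loss
#'   of IkB-alpha (`k_loss_IkBa`).
#' * `cytokine` (16): transcription, translation, degradation and (for IL-8)
#'   secretion of IL-8, IL-6, IL-12 and the surface marker CD70. Only IL-8
#'   carries a basal NF-kB-independent transcription term.
#' * `tcell` (5): naive T-cell activation `k_act_N` with Michaelis constant
#'   `K_4` on the DC stimulation signal, the early-effector differentiation
#'   splits `k_diff1_EE` (to short-lived effectors) and `k_diff2_EE` (to
#'   memory), and short-lived effector decay `k_deg_SLE`.
#'
#' Rates are per hour; signaling species are non-dimensional, so their rate
#' constants are in normalized concentration units per hour. Organ volumes
#' are fixed to physiological values (and excluded from estimation); the
#' remaining values reproduce the qualitative organ kinetics of injected DCs
#' and the reported memory T-cell fold-changes of the vaccine-comparison and
#' perturbation experiments (see the package vignette).
#'
#' @param file Optional path to a parameter JSON file (as written by
#'   [write_parameters()]); when `NULL` the built-in reference set is
#'   returned.
#' @return A tibble with columns `name`, `value`, `lower`, `upper`, `unit`,
#'   `fixed`, `group`.
#' @seealso [design_constants()], [write_parameters()], [read_parameters()]
#' @export
#' @examples
#' p <- reference_parameters()
#' nrow(p) # 46
reference_parameters <- function(file = NULL) {
  if (!is.null(file)) {
    return(read_parameters(file))
  }
  def <- function(name, value, group, unit = "1/h", lower = 1e-4,
                  upper = 1e2, fixed = FALSE) {
    tibble::tibble(name = name, value = value, lower = lower, upper = upper,
                   unit = unit, fixed = fixed, group = group)
  }
  p <- dplyr::bind_rows(
    ## DC bio-distribution (rates bounded by a physiological window:
    ## trafficking and clearance are minutes-to-days scale)
    def("mu_BS",   0.015, "distribution", lower = 1e-3, upper = 10),
    def("mu_BLu",  0.30,  "distribution", lower = 1e-3, upper = 10),
    def("mu_BLi",  0.25,  "distribution", lower = 1e-3, upper = 10),
    def("mu",      0.10,  "distribution", lower = 1e-3, upper = 10),
    def("mu_S0",   0.02,  "distribution", lower = 1e-3, upper = 10),
    def("mu_Lu0",  0.15,  "distribution", lower = 1e-3, upper = 10),
    def("Q_Blood",  5e6,   "distribution", unit = "mm3", fixed = TRUE,
        lower = 5e6, upper = 5e6),
    def("Q_Spleen", 1e5,   "distribution", unit = "mm3", fixed = TRUE,
        lower = 1e5, upper = 1e5),
    def("Q_Lung",   1.3e6, "distribution", unit = "mm3", fixed = TRUE,
        lower = 1.3e6, upper = 1.3e6),
    def("Q_Liver",  1.5e6, "distribution", unit = "mm3", fixed = TRUE,
        lower = 1.5e6, upper = 1.5e6),
    ## Receptor-proximal signaling -----------------------------------------
    def("k_ph1_TRAF2",  1.5, "signaling"),
    def("k_ph1_IRAK1",  1.2, "signaling"),
    def("k_ph2",        0.5, "signaling", unit = "1"),
    def("k_deg_TRAF2p", 2.0, "signaling"),
    def("k_deg_IRAK1p", 2.0, "signaling"),
    ## IKK module -----------------------------------------------------------
    def("k_syn_IKK",  0.06,  "signaling"),
    def("k_act_IKK",  0.60,  "signaling"),
    def("k_deg_IKK",  0.06,  "signaling"),
    def("k_deg_IKKb", 0.840, "signaling"),
    ## NF-kB / IkB-alpha core ----------------------------------------------
    def("N_tot",          1.0,  "nfkb", unit = "1", upper = 10),
    def("k_ass",          184,  "nfkb", upper = 1e4),
    def("k_transc_mIkBa", 280,  "nfkb", upper = 1e4),
    def("k_deg_mIkBa",    12,   "nfkb", upper = 1e3),
    def("k_tranl_IkBa",   280,  "nfkb", upper = 1e4),
    def("k_loss_IkBa",    300,  "nfkb", upper = 1e4),
    ## Cytokines and CD70 ---------------------------------------------------
    def("k_transc1_mIL8", 0.002, "cytokine"),
    def("k_transc2_mIL8", 2.0,   "cytokine"),
    def("k_deg_mIL8",     2.0,   "cytokine"),
    def("k_transl_IL8",   1.0,   "cytokine"),
    def("k_deg_IL8",      1.0,   "cytokine"),
    def("k_sec_IL8",      1.0,   "cytokine"),
    def("k_transc2_mIL6", 2.0,   "cytokine"),
    def("k_deg_mIL6",     2.0,   "cytokine"),
    def("k_transl_IL6",   1.0,   "cytokine"),
    def("k_deg_IL6",      2.0,   "cytokine"),
    def("k_transc2_mIL12", 2.0,  "cytokine"),
    def("k_deg_mIL12",     2.0,  "cytokine"),
    def("k_transl_IL12",   1.0,  "cytokine"),
    def("k_deg_IL12",      2.0,  "cytokine"),
    def("k_transc2_CD70",  2.0,  "cytokine"),
    def("k_deg_CD70",      2.0,  "cytokine"),
    ## T-cell module ---------------------------------------------------------
    def("k_act_N",    0.05,  "tcell"),
    def("K_4",        2e4,   "tcell", unit = "signal", lower = 1, upper = 1e8),
    def("k_diff1_EE", 0.04,  "tcell"),
    def("k_diff2_EE", 0.008, "tcell"),
    def("k_deg_SLE",  0.002, "tcell")
  )
  stopifnot(identical(p$name, .param_names))
  validate_parameters(p)
  p
}

#' Fixed design constants of the model
#'
#' Constants that are part of the model design rather than of the 46
#' calibrated kinetic parameters: the DC-to-T-cell signaling delay `tau`
#' (hours), the clonal amplification factor `A` applied to naive-to-early
#' effector conversion, the basal IkB-alpha protein turnover `delta_IkBa`
#' (per hour, keeps the resting state finite when IKK-beta is absent), the
#' fixed fraction `f_SLE2M = 0.1` of the short-lived effector outflux that
#' enters the memory pool, the injected DC dose `DC_in` and initial
#' antigen-specific naive T-cell count `T_0`, and the two simulation
#' horizons used by the sensitivity analysis (200 h) and the steady-state
#' readout (4000 h).
#'
#' @param ... Named overrides of individual constants.
#' @return A named list.
#' @export
design_constants <- function(...) {
  con <- list(
    tau = 24, A = 10, delta_IkBa = 0.05, f_SLE2M = 0.1,
    DC_in = 1e5, T_0 = 1e6,
    horizon_sensitivity = 200, horizon_steady = 4000
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(con))
  if (length(bad) > 0) {
    stop("unknown design constant(s): ", paste(bad, collapse = ", "))
  }
  con[names(dots)] <- dots
  stopifnot(con$f_SLE2M == 0.1, all(unlist(con) > 0))
  con
}

#' Validate a parameter tibble
#'
#' Checks the structural invariants of a parameter set: exactly 46 uniquely
#' named entries, non-negative values, strictly positive volumes, and
#' consistent bounds.
#'
#' @param params Parameter tibble as returned by [reference_parameters()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.data.frame(params))
  needed <- c("name", "value", "lower", "upper", "fixed")
  if (!all(needed %in% names(params))) {
    stop("parameter table must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(params) != 46L) {
    stop("parameter set must contain exactly 46 entries, got ", nrow(params))
  }
  if (anyDuplicated(params$name)) stop("duplicated parameter names")
  if (any(params$value < 0)) stop("parameter values must be non-negative")
  vols <- params$value[params$name %in%
                         c("Q_Blood", "Q_Spleen", "Q_Lung", "Q_Liver")]
  if (length(vols) != 4L || any(vols <= 0)) {
    stop("the four organ volumes must be present and strictly positive")
  }
  if (any(params$lower > params$upper)) stop("lower bound exceeds upper bound")
  invisible(params)
}

#' Extract parameter values as a named vector
#'
#' @param params Parameter tibble.
#' @param overrides Optional named numeric vector or list applied on top of
#'   the table values; names must exist in the parameter set.
#' @return Named numeric vector of length 46 in table order.
#' @export
param_values <- function(params, overrides = NULL) {
  v <- stats::setNames(params$value, params$name)
  if (!is.null(overrides) && length(overrides) > 0) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(v))
    if (length(bad) > 0) {
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    }
    v[names(overrides)] <- overrides
  }
  v
}

#' Write / read a parameter set as flat JSON
#'
#' The on-disk format is a flat map `name -> {value, lower, upper, unit,
#' fixed}`, convenient for versioning parameterizations next to scenario
#' files.
#'
#' @param params Parameter tibble.
#' @param path File path.
#' @return `write_parameters()` returns `path` invisibly; `read_parameters()`
#'   returns a parameter tibble.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  entries <- purrr::map(seq_len(nrow(params)), function(i) {
    row <- params[i, ]
    list(value = row$value, lower = row$lower, upper = row$upper,
         unit = row$unit, fixed = row$fixed, group = row$group)
  })
  names(entries) <- params$name
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path)
  p <- purrr::imap_dfr(raw, function(e, nm) {
    tibble::tibble(
      name = nm, value = as.numeric(e$value),
      lower = as.numeric(e$lower %||% 1e-4),
      upper = as.numeric(e$upper %||% 1e2),
      unit = as.character(e$unit %||% "1/h"),
      fixed = isTRUE(e$fixed),
      group = as.character(e$group %||% NA_character_)
    )
  })
  validate_parameters(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
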