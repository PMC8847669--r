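## Model core: the 25-state, 46-parameter ODE/DDE system.
##
## State layout (canonical order, 25 components):
##   1-4   organ DC concentrations (cells/mm3): dc_blood, dc_lung, dc_liver,
##         dc_spleen
##   5-21  DC-intracellular signaling (non-dimensional): traf2, traf2p,
##         irak1, irak1p, ikk, ikkb, m_ikba, ikba, nfkb_ikba, nfkb,
##         m_il12, il12, m_il6, il6, m_il8, il8, cd70
##   22-25 T-cell pools (counts): naive, early_effector,
##         short_lived_effector, memory

#' Canonical state variable names
#'
#' @return Character vector of the 25 state names in canonical order.
#' @export
state_names <- function() {
  c("dc_blood", "dc_lung", "dc_liver", "dc_spleen",
    "traf2", "traf2p", "irak1", "irak1p", "ikk", "ikkb",
    "m_ikba", "ikba", "nfkb_ikba", "nfkb",
    "m_il12", "il12", "m_il6", "il6", "m_il8", "il8", "cd70",
    "naive", "early_effector", "short_lived_effector", "memory")
}

#' Bio-distribution right-hand side
#'
#' Derivatives of the four organ DC concentrations. Blood loses DCs to
#' spleen, lung, liver and other periphery; spleen and lung have first-order
#' efflux; the liver is a terminal reservoir with no efflux. Transfer terms
#' are scaled by volume ratios because organ variables are concentrations.
#'
#' @param organ Named numeric vector with `dc_blood`, `dc_lung`, `dc_liver`,
#'   `dc_spleen` (cells/mm3).
#' @param params Parameter tibble or named value vector.
#' @return Named numeric vector of the four derivatives.
#' @export
rhs_biodistribution <- function(organ, params) {
  v <- if (is.data.frame(params)) param_values(params) else params
  rates <- v[c("mu_BS", "mu_BLu", "mu_BLi", "mu", "mu_S0", "mu_Lu0")]
  vols <- v[c("Q_Blood", "Q_Spleen", "Q_Lung", "Q_Liver")]
  if (any(rates < 0)) stop("distribution rates must be non-negative")
  if (any(vols <= 0)) stop("organ volumes must be strictly positive")
  b <- organ[["dc_blood"]]
  c(
    dc_blood = -(v[["mu_BS"]] + v[["mu_BLu"]] + v[["mu_BLi"]] + v[["mu"]]) * b,
    dc_lung = v[["mu_BLu"]] * (v[["Q_Blood"]] / v[["Q_Lung"]]) * b -
      v[["mu_Lu0"]] * organ[["dc_lung"]],
    dc_liver = v[["mu_BLi"]] * (v[["Q_Blood"]] / v[["Q_Liver"]]) * b,
    dc_spleen = v[["mu_BS"]] * (v[["Q_Blood"]] / v[["Q_Spleen"]]) * b -
      v[["mu_S0"]] * organ[["dc_spleen"]]
  )
}

#' DC maturation signaling right-hand side
#'
#' Derivatives of the 17 intracellular species: saturable, stimulus-driven
#' phosphorylation of TRAF2 and IRAK1 (deactivation recycles, so the
#' phosphorylated plus unphosphorylated totals are conserved at 1), IKK
#' synthesis/activation/turnover, the NF-kB/IkB-alpha negative-feedback core
#' with moiety conservation `nfkb + nfkb_ikba = N_tot`, and downstream
#' transcription/translation of IL-12, IL-6, IL-8 (with basal transcription
#' and secretion) and CD70.
#'
#' @param dc Named numeric vector of the 17 signaling states.
#' @param u Stimulus value in `[0, 1]`.
#' @param params Parameter tibble or named value vector.
#' @param constants Design constants, see [design_constants()].
#' @return Named numeric vector of the 17 derivatives.
#' @export
rhs_dc_signaling <- function(dc, u, params, constants = design_constants()) {
  if (u < 0 || u > 1) stop("stimulus u must lie in [0, 1]")
  v <- if (is.data.frame(params)) param_values(params) else params
  delta <- constants$delta_IkBa

  d_traf2p <- v[["k_ph1_TRAF2"]] * u * dc[["traf2"]] /
    (v[["k_ph2"]] + dc[["traf2"]]) - v[["k_deg_TRAF2p"]] * dc[["traf2p"]]
  d_irak1p <- v[["k_ph1_IRAK1"]] * u * dc[["irak1"]] /
    (v[["k_ph2"]] + dc[["irak1"]]) - v[["k_deg_IRAK1p"]] * dc[["irak1p"]]
  act <- dc[["traf2p"]] + dc[["irak1p"]]
  d_ikk <- v[["k_syn_IKK"]] - v[["k_deg_IKK"]] * dc[["ikk"]] -
    v[["k_act_IKK"]] * act * dc[["ikk"]]
  d_ikkb <- v[["k_act_IKK"]] * act * dc[["ikk"]] -
    v[["k_deg_IKKb"]] * dc[["ikkb"]]

  loss <- v[["k_loss_IkBa"]] * dc[["ikkb"]] + delta
  d_m_ikba <- v[["k_transc_mIkBa"]] * dc[["nfkb"]] -
    v[["k_deg_mIkBa"]] * dc[["m_ikba"]]
  assoc <- v[["k_ass"]] * dc[["nfkb"]] * dc[["ikba"]]
  d_ikba <- v[["k_tranl_IkBa"]] * dc[["m_ikba"]] - assoc - loss * dc[["ikba"]]
  d_complex <- assoc - loss * dc[["nfkb_ikba"]]

  cyt <- function(k2, kdm, m, ktr, kdp, prot, basal = 0, ksec = 0) {
    c(basal + k2 * dc[["nfkb"]] - kdm * dc[[m]],
      ktr * dc[[m]] - (kdp + ksec) * dc[[prot]])
  }
  il12 <- cyt(v[["k_transc2_mIL12"]], v[["k_deg_mIL12"]], "m_il12",
              v[["k_transl_IL12"]], v[["k_deg_IL12"]], "il12")
  il6 <- cyt(v[["k_transc2_mIL6"]], v[["k_deg_mIL6"]], "m_il6",
             v[["k_transl_IL6"]], v[["k_deg_IL6"]], "il6")
  il8 <- cyt(v[["k_transc2_mIL8"]], v[["k_deg_mIL8"]], "m_il8",
             v[["k_transl_IL8"]], v[["k_deg_IL8"]], "il8",
             basal = v[["k_transc1_mIL8"]], ksec = v[["k_sec_IL8"]])
  d_cd70 <- v[["k_transc2_CD70"]] * dc[["nfkb"]] -
    v[["k_deg_CD70"]] * dc[["cd70"]]

  c(traf2 = -d_traf2p, traf2p = d_traf2p,
    irak1 = -d_irak1p, irak1p = d_irak1p,
    ikk = d_ikk, ikkb = d_ikkb,
    m_ikba = d_m_ikba, ikba = d_ikba,
    nfkb_ikba = d_complex, nfkb = -d_complex,
    m_il12 = il12[1], il12 = il12[2],
    m_il6 = il6[1], il6 = il6[2],
    m_il8 = il8[1], il8 = il8[2],
    cd70 = d_cd70)
}

#' DC-to-T-cell stimulation signal
#'
#' The scalar signal that drives naive T-cell activation: the spleen DC
#' count (concentration times spleen volume) multiplied by the summed
#' intracellular levels of IL-6, IL-8, IL-12 and CD70, with equal unit
#' weights.
#'
#' @param state Named numeric vector of the full 25-component state.
#' @param params Parameter tibble or named value vector.
#' @return Non-negative scalar `S`.
#' @export
stimulation_signal <- function(state, params) {
  v <- if (is.data.frame(params)) param_values(params) else params
  (v[["Q_Spleen"]] * state[["dc_spleen"]]) *
    (state[["il6"]] + state[["il8"]] + state[["il12"]] + state[["cd70"]])
}

#' T-cell differentiation right-hand side
#'
#' Derivatives of the four T-cell pools driven by the delayed stimulation
#' signal. Naive cells are consumed at rate `k_act_N * H` where
#' `H = S_delayed / (K_4 + S_delayed)`; each consumed naive cell yields `A`
#' early effectors (clonal amplification); early effectors split into
#' short-lived effectors (`k_diff1_EE`) and memory (`k_diff2_EE`); a fixed
#' 10% of the short-lived effector outflux enters the memory pool.
#'
#' @param tcell Named numeric vector with `naive`, `early_effector`,
#'   `short_lived_effector`, `memory`.
#' @param S_delayed The stimulation signal evaluated a delay `tau` ago
#'   (0 before the delay horizon); must be non-negative.
#' @param params Parameter tibble or named value vector.
#' @param constants Design constants, see [design_constants()].
#' @return Named numeric vector of the four derivatives.
#' @export
rhs_tcell <- function(tcell, S_delayed, params,
                      constants = design_constants()) {
  if (S_delayed < 0) stop("S_delayed must be non-negative")
  v <- if (is.data.frame(params)) param_values(params) else params
  H <- S_delayed / (v[["K_4"]] + S_delayed)
  act <- v[["k_act_N"]] * tcell[["naive"]] * H
  d_ee <- constants$A * act -
    (v[["k_diff1_EE"]] + v[["k_diff2_EE"]]) * tcell[["early_effector"]]
  d_sle <- v[["k_diff1_EE"]] * tcell[["early_effector"]] -
    v[["k_deg_SLE"]] * tcell[["short_lived_effector"]]
  d_m <- v[["k_diff2_EE"]] * tcell[["early_effector"]] +
    constants$f_SLE2M * v[["k_deg_SLE"]] * tcell[["short_lived_effector"]]
  c(naive = -act, early_effector = d_ee,
    short_lived_effector = d_sle, memory = d_m)
}

## Full coupled right-hand side in plain R (reference implementation; the
## compiled C version in src/ is used by simulate() for speed and must agree
## with this one).
rhs_full_r <- function(t, y, parms) {
  v <- parms$values
  con <- parms$constants
  u <- eval_stimulus(parms$stim_times, parms$stim_values, t)
  names(y) <- state_names()
  d_organ <- rhs_biodistribution(y[1:4], v)
  d_dc <- rhs_dc_signaling(y[5:21], u, v, con)
  if (t <= con$tau) {
    S_lag <- 0
  } else {
    idx <- c(4L, 18L, 20L, 16L, 21L) # dc_spleen, il6, il8, il12, cd70
    ylag <- deSolve::lagvalue(t - con$tau, idx)
    S_lag <- max(0, v[["Q_Spleen"]] * ylag[1]) *
      max(0, sum(pmax(ylag[2:5], 0)))
    # smooth onset of the delayed drive over 0.25 h (continuity at t = tau)
    S_lag <- S_lag * min(1, (t - con$tau) / 0.25)
  }
  d_t <- rhs_tcell(y[22:25], S_lag, v, con)
  S_now <- stimulation_signal(y, v)
  list(c(d_organ, d_dc, d_t), S = S_now, S_lag = S_lag, u = u)
}

## Piecewise-constant stimulus evaluation: value[i] holds on
## [time[i], time[i+1]); 0 before the first breakpoint.
eval_stimulus <- function(times, values, t) {
  if (length(times) == 0 || t < times[1]) return(0)
  values[findInterval(t, times)]
}

#' Resting state of the signaling module
#'
#' Fixed point of the 17 intracellular species at zero stimulus, used as the
#' initial condition of injected DCs. TRAF2/IRAK1 are unphosphorylated, the
#' IKK pool sits at its synthesis/turnover balance with no active IKK-beta,
#' and the NF-kB/IkB-alpha core equilibrates against the basal IkB-alpha
#' turnover `delta_IkBa`, leaving a small free NF-kB fraction that sets
#' basal cytokine tone.
#'
#' @param params Parameter tibble or named value vector.
#' @param constants Design constants.
#' @return Named numeric vector of the 17 signaling states.
#' @export
signaling_rest_state <- function(params, constants = design_constants()) {
  v <- if (is.data.frame(params)) param_values(params) else params
  delta <- constants$delta_IkBa
  ikk0 <- v[["k_syn_IKK"]] / v[["k_deg_IKK"]]
  N <- v[["N_tot"]]
  Tfb <- v[["k_tranl_IkBa"]] * v[["k_transc_mIkBa"]] / v[["k_deg_mIkBa"]]
  ## free NF-kB x solves x + k_ass*x*b(x)/delta = N with
  ## b(x) = Tfb*x/(k_ass*x + delta)
  g <- function(x) {
    b <- Tfb * x / (v[["k_ass"]] * x + delta)
    x + v[["k_ass"]] * x * b / delta - N
  }
  x <- stats::uniroot(g, c(0, N), tol = 1e-14)$root
  b <- Tfb * x / (v[["k_ass"]] * x + delta)
  cplx <- N - x
  m_ikba <- v[["k_transc_mIkBa"]] * x / v[["k_deg_mIkBa"]]
  m12 <- v[["k_transc2_mIL12"]] * x / v[["k_deg_mIL12"]]
  m6 <- v[["k_transc2_mIL6"]] * x / v[["k_deg_mIL6"]]
  m8 <- (v[["k_transc1_mIL8"]] + v[["k_transc2_mIL8"]] * x) / v[["k_deg_mIL8"]]
  c(traf2 = 1, traf2p = 0, irak1 = 1, irak1p = 0, ikk = ikk0, ikkb = 0,
    m_ikba = m_ikba, ikba = b, nfkb_ikba = cplx, nfkb = x,
    m_il12 = m12, il12 = v[["k_transl_IL12"]] * m12 / v[["k_deg_IL12"]],
    m_il6 = m6, il6 = v[["k_transl_IL6"]] * m6 / v[["k_deg_IL6"]],
    m_il8 = m8,
    il8 = v[["k_transl_IL8"]] * m8 / (v[["k_deg_IL8"]] + v[["k_sec_IL8"]]),
    cd70 = v[["k_transc2_CD70"]] * x / v[["k_deg_CD70"]])
}

#' Initial model state for a scenario
#'
#' Injected dose enters the blood compartment as a concentration
#' (`DC_in / Q_Blood`); signaling starts at its resting fixed point; T cells
#' start at `(T_0, 0, 0, 0)`. Scenario initial-condition overrides are
#' applied last.
#'
#' @param scenario A [scenario()] object.
#' @param params Parameter tibble or named value vector.
#' @param constants Design constants.
#' @return Named numeric vector of length 25.
#' @export
initial_state <- function(scenario, params, constants = design_constants()) {
  v <- if (is.data.frame(params)) param_values(params) else params
  v <- param_values_with_overrides(v, scenario$overrides)
  y0 <- c(
    dc_blood = constants$DC_in / v[["Q_Blood"]],
    dc_lung = 0, dc_liver = 0, dc_spleen = 0,
    signaling_rest_state(v, constants),
    naive = constants$T_0, early_effector = 0,
    short_lived_effector = 0, memory = 0
  )
  names(y0) <- state_names()
  init <- scenario$init
  if (!is.null(init) && length(init) > 0) {
    bad <- setdiff(names(init), state_names())
    if (length(bad) > 0) {
      stop("unknown initial-condition override(s): ", paste(bad, collapse = ", "))
    }
    y0[names(init)] <- unlist(init)
  }
  y0
}

## Coerce a parameter tibble or named vector to the canonical named
## 46-vector (canonical order).
as_param_vector <- function(params) {
  if (is.data.frame(params)) return(param_values(params))
  nm <- .param_names
  missing <- setdiff(nm, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  params[nm]
}

param_values_with_overrides <- function(v, overrides) {
  if (is.null(overrides) || length(overrides) == 0) return(v)
  overrides <- unlist(overrides)
  bad <- setdiff(names(overrides), names(v))
  if (length(bad) > 0) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
  }
  v[names(overrides)] <- overrides
  v
}
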