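test_that("bio-distribution rates follow the volume-scaled transfer law", {
  v <- ref_v
  v[c("mu_BS", "Q_Blood", "Q_Spleen", "mu_S0")] <- c(0.02, 5000, 1e5, 0.01)
  organ <- c(dc_blood = 100, dc_lung = 0, dc_liver = 0, dc_spleen = 10)
  d <- rhs_biodistribution(organ, v)
  ## influx 0.02 * (5000/1e5) * 100 exactly balances efflux 0.01 * 10
  expect_equal(unname(d["dc_spleen"]), 0)
  expect_lt(d[["dc_blood"]], 0)
  expect_error(rhs_biodistribution(organ, replace(v, "Q_Lung", -1)),
               "positive")
})

test_that("with no blood input the spleen pool decays exponentially", {
  sc <- scenario("decay", stimulus = tibble::tibble(time = 0, value = 0),
                 init = c(dc_blood = 0, dc_spleen = 0.5))
  tr <- simulate_model(sc, ref_p, times = seq(0, 50, 1))
  expect_equal(tr$state[, "dc_spleen"],
               0.5 * exp(-ref_v[["mu_S0"]] * tr$time), tolerance = 1e-6)
})

test_that("DC mass balance closes against a fine-step Euler integration", {
  v <- ref_v
  con <- ref_con
  y <- c(dc_blood = con$DC_in / v[["Q_Blood"]], dc_lung = 0, dc_liver = 0,
         dc_spleen = 0)
  Q <- v[c("Q_Blood", "Q_Lung", "Q_Liver", "Q_Spleen")]
  h <- 0.002
  loss_int <- 0
  for (i in seq_len(72 / h)) {
    d <- rhs_biodistribution(y, v)
    loss_int <- loss_int + h * (v[["mu"]] * y[["dc_blood"]] * Q[[1]] +
                                  v[["mu_Lu0"]] * y[["dc_lung"]] * Q[[2]] +
                                  v[["mu_S0"]] * y[["dc_spleen"]] * Q[[4]])
    y <- y + h * d
  }
  total <- sum(y * Q[c("Q_Blood", "Q_Lung", "Q_Liver", "Q_Spleen")])
  expect_lt(abs(total + loss_int - con$DC_in) / con$DC_in, 1e-3)

  ## and the solver trajectory satisfies the same balance to < 0.1%
  tr <- simulate_model("normal_dc", ref_p, times = seq(0, 72, 0.1))
  st <- tr$state
  counts <- st[, "dc_blood"] * Q[[1]] + st[, "dc_lung"] * Q[[2]] +
    st[, "dc_liver"] * Q[[3]] + st[, "dc_spleen"] * Q[[4]]
  rate <- v[["mu"]] * st[, "dc_blood"] * Q[[1]] +
    v[["mu_Lu0"]] * st[, "dc_lung"] * Q[[2]] +
    v[["mu_S0"]] * st[, "dc_spleen"] * Q[[4]]
  cum <- c(0, cumsum((utils::head(rate, -1) + utils::tail(rate, -1)) / 2 *
                       diff(tr$time)))
  expect_lt(max(abs(counts + cum - con$DC_in)) / con$DC_in, 1e-3)
})

test_that("signaling rate laws match hand evaluation and conserve moieties", {
  dc <- signaling_rest_state(ref_p)
  v <- ref_v

  ## basal transcription only when NF-kB and mRNA are absent
  dc0 <- dc
  dc0[["nfkb"]] <- 0
  dc0[["m_il8"]] <- 0
  d0 <- rhs_dc_signaling(dc0, 0, v)
  expect_equal(unname(d0["m_il8"]), v[["k_transc1_mIL8"]])

  ## hand evaluation of the IL-8 mRNA law
  v2 <- v
  v2[c("k_transc1_mIL8", "k_transc2_mIL8", "k_deg_mIL8")] <- c(1, 2, 0.1)
  dc2 <- dc
  dc2[["nfkb"]] <- 0.5
  dc2[["m_il8"]] <- 5
  d2 <- rhs_dc_signaling(dc2, 0, v2)
  expect_equal(unname(d2["m_il8"]), 1 + 2 * 0.5 - 0.1 * 5)

  ## conservation identities at arbitrary states and stimulus
  set.seed(42)
  for (i in 1:5) {
    dcr <- dc * stats::runif(length(dc), 0.2, 2)
    dr <- rhs_dc_signaling(dcr, stats::runif(1), v)
    expect_equal(unname(dr["nfkb"] + dr["nfkb_ikba"]), 0, tolerance = 1e-12)
    expect_equal(unname(dr["traf2"] + dr["traf2p"]), 0, tolerance = 1e-12)
    expect_equal(unname(dr["irak1"] + dr["irak1p"]), 0, tolerance = 1e-12)
  }
  expect_error(rhs_dc_signaling(dc, 1.5, v), "\\[0, 1\\]")
})

test_that("stimulation signal is a volume-scaled linear read-out", {
  st <- rest_state_full()
  st[["dc_spleen"]] <- 0
  expect_equal(stimulation_signal(st, ref_v), 0)
  v <- ref_v
  v[["Q_Spleen"]] <- 1e5
  st[["dc_spleen"]] <- 1e-3
  st[c("il6", "il8", "il12", "cd70")] <- 0.25
  expect_equal(stimulation_signal(st, v), 100)
  st2 <- st
  st2[c("il6", "il8", "il12", "cd70")] <- 0.5
  expect_equal(stimulation_signal(st2, v), 2 * stimulation_signal(st, v))
})

test_that("T-cell derivatives follow the memory-influx law", {
  v <- ref_v
  v[c("k_diff2_EE", "k_deg_SLE")] <- c(0.01, 0.1)
  tc <- c(naive = 0, early_effector = 100, short_lived_effector = 200,
          memory = 0)
  d <- rhs_tcell(tc, 0, v)
  expect_equal(unname(d["memory"]), 0.01 * 100 + 0.1 * 0.1 * 200)
  d0 <- rhs_tcell(c(naive = 1e6, early_effector = 0,
                    short_lived_effector = 0, memory = 0), 0, v)
  expect_equal(unname(d0), c(0, 0, 0, 0))
  expect_error(rhs_tcell(tc, -1, v), "non-negative")
})

test_that("compiled and plain-R engines integrate the same system", {
  tt <- seq(0, 120, 1)
  trc <- simulate_model("caikk_dc", ref_p, times = tt)
  trr <- simulate_model("caikk_dc", ref_p, times = tt, engine = "r")
  scale <- pmax(apply(abs(trc$state), 2, max), 1e-8)
  rel <- max(abs(trc$state - trr$state) / rep(scale, each = length(tt)))
  expect_lt(rel, 1e-5)
})

test_that("unstimulated model stays at its rest fixed point", {
  sc <- scenario("nil", stimulus = tibble::tibble(time = 0, value = 0),
                 init = c(dc_blood = 0))
  tr <- simulate_model(sc, ref_p, times = seq(0, 200, 5))
  drift <- apply(tr$state, 2, function(x) max(abs(x - x[1])))
  scale <- pmax(abs(tr$state[1, ]), 1e-6)
  expect_lt(max(drift / scale), 1e-4)
  expect_equal(unname(tr$state[nrow(tr$state), "naive"]), ref_con$T_0)
  expect_equal(unname(tr$state[nrow(tr$state), "memory"]), 0)
})

test_that("trajectories keep NF-kB conservation, positivity and monotone memory", {
  for (scen in c("normal_dc", "caikk_dc")) {
    tr <- simulate_model(scen, ref_p, times = seq(0, 300, 0.5))
    expect_lt(tr$diagnostics$moiety_drift, 1e-6 * ref_v[["N_tot"]])
    expect_gt(tr$diagnostics$min_state, -1e-9)
    expect_true(all(diff(tr$state[, "memory"]) > -1e-9))
  }
})

test_that("halving solver tolerances leaves M(200 h) unchanged to < 0.1%", {
  tt <- seq(0, 200, 2)
  m1 <- simulate_model("caikk_dc", ref_p, times = tt,
                       rtol = 1e-8, atol = 1e-10)$state[101, "memory"]
  m2 <- simulate_model("caikk_dc", ref_p, times = tt,
                       rtol = 5e-9, atol = 5e-11)$state[101, "memory"]
  expect_lt(abs(m1 - m2) / m1, 1e-3)
})

test_that("steady-state memory agrees with a long-horizon integration", {
  m <- steady_state_memory("caikk_dc", ref_p)
  expect_true(attr(m, "converged"))
  tr <- simulate_model("caikk_dc", ref_p,
                       times = c(seq(0, 400, 2), seq(410, 16000, 20)))
  m_long <- tr$state[nrow(tr$state), "memory"]
  expect_lt(abs(as.numeric(m) - m_long) / m_long, 0.01)
  expect_gte(as.numeric(m), tr$state[which.min(abs(tr$time - 200)), "memory"])
  ## no stimulation: steady-state memory is 0
  sc <- scenario("nil", stimulus = tibble::tibble(time = 0, value = 0),
                 init = c(dc_blood = 0))
  expect_equal(as.numeric(steady_state_memory(sc, ref_p)), 0)
})

test_that("caIKK arm shows higher IKKb and integrated free NF-kB than normal", {
  tt <- seq(0, 200, 0.5)
  trn <- simulate_model("normal_dc", ref_p, times = tt)
  trc <- simulate_model("caikk_dc", ref_p, times = tt)
  ## pointwise comparison away from the shared zero start
  expect_true(all(trc$state[-1, "ikkb"] >= trn$state[-1, "ikkb"] - 1e-12))
  expect_gt(sum(trc$state[, "nfkb"]), sum(trn$state[, "nfkb"]))
})

test_that("organ kinetics reproduce the qualitative uptake shapes", {
  tr <- simulate_model("normal_dc", ref_p, times = seq(0, 72, 0.25))
  st <- tr$state
  ## blood decays towards zero
  expect_lt(st[nrow(st), "dc_blood"] / st[1, "dc_blood"], 1e-3)
  ## lung: early peak then drop to a low level
  i_lung <- which.max(st[, "dc_lung"])
  expect_lt(tr$time[i_lung], 12)
  expect_lt(st[nrow(st), "dc_lung"] / max(st[, "dc_lung"]), 0.05)
  ## spleen: peak then gradual decline
  i_sp <- which.max(st[, "dc_spleen"])
  expect_lt(tr$time[i_sp], 24)
  expect_lt(st[nrow(st), "dc_spleen"], max(st[, "dc_spleen"]))
  ## liver: accumulates and stays near its plateau (no efflux)
  expect_gt(st[nrow(st), "dc_liver"], 0.97 * max(st[, "dc_liver"]))
})

test_that("restimulation events reset the DC pool and boost T-cell output", {
  tr <- simulate_model("tcell_invitro_caikk", ref_p, times = seq(0, 504, 1))
  i_pre <- which(tr$time == 168)[1]
  i_post <- which(tr$time == 168)
  i_post <- i_post[length(i_post)]
  ## the DC pool is replenished at the restimulation time
  expect_gt(tr$state[i_post + 1, "dc_spleen"],
            tr$state[i_pre - 1, "dc_spleen"])
  ## SLE counts keep growing across the three stimulations
  idx <- match(c(168, 336, 504), tr$time)
  expect_true(all(diff(tr$state[idx, "short_lived_effector"]) > 0))
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(scenario("x", stimulus = tibble::tibble(time = c(2, 1),
                                                       value = c(1, 0))),
               "increasing")
  expect_error(scenario("x", stimulus = tibble::tibble(time = 0, value = 2)),
               "\\[0, 1\\]")
  expect_error(simulate_model(scenario("x", overrides = c(nope = 1)),
                              ref_p, times = 0:10), "unknown")
})

test_that("shipped scenario fixture defines the two arms via k_deg_IKKb", {
  scs <- read_scenarios()
  expect_setequal(names(scs), c("normal_dc", "caikk_dc"))
  expect_null(scs$normal_dc$overrides)
  expect_equal(unname(scs$caikk_dc$overrides["k_deg_IKKb"]), 0.216)
})
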