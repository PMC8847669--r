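test_that("Sobol indices match the closed form for an additive linear model", {
  r <- tibble::tibble(name = c("x1", "x2"), lower = 0, upper = 1)
  sb <- sobol_indices(function(v) v[["x1"]] + 2 * v[["x2"]], r, N = 4096,
                      seed = 1)
  expect_lt(abs(sb$S1["x1", 1] - 0.2), 0.05)
  expect_lt(abs(sb$S1["x2", 1] - 0.8), 0.05)
  ## additive model: total-order equals first-order
  expect_lt(max(abs(sb$ST[, 1] - sb$S1[, 1])), 0.05)
})

test_that("Sobol indices match the closed form for the Ishigami function", {
  ri <- tibble::tibble(name = c("x1", "x2", "x3"), lower = -pi, upper = pi)
  ish <- function(v) sin(v[["x1"]]) + 7 * sin(v[["x2"]])^2 +
    0.1 * v[["x3"]]^4 * sin(v[["x1"]])
  sb <- sobol_indices(ish, ri, N = 4096, seed = 2)
  expect_lt(abs(sb$S1["x1", 1] - 0.3139), 0.05)
  expect_lt(abs(sb$S1["x2", 1] - 0.4424), 0.05)
  expect_lt(abs(sb$S1["x3", 1] - 0), 0.05)
  expect_lt(abs(sb$ST["x3", 1] - 0.2437), 0.05)
})

test_that("inactive and zero-range parameters read as non-influential", {
  r <- tibble::tibble(name = c("x1", "dummy", "frozen"),
                      lower = c(0, 0, 0.5), upper = c(1, 1, 0.5))
  sb <- sobol_indices(function(v) v[["x1"]]^2, r, N = 1024, seed = 3)
  expect_lt(abs(sb$S1["dummy", 1]), 0.05)
  expect_lt(abs(sb$ST["dummy", 1]), 0.05)
  expect_equal(unname(sb$ST["frozen", 1]), 0)
  rk <- rank_parameters(sb)
  expect_equal(rk$parameter[1], "x1")
  expect_equal(rk$parameter[3], "frozen")
  expect_error(rank_parameters(sb, k = 10), "exceeds")
})

test_that("doubling N moves the estimates by less than the bootstrap error", {
  ri <- tibble::tibble(name = c("x1", "x2", "x3"), lower = -pi, upper = pi)
  ish <- function(v) sin(v[["x1"]]) + 7 * sin(v[["x2"]])^2 +
    0.1 * v[["x3"]]^4 * sin(v[["x1"]])
  sb1 <- sobol_indices(ish, ri, N = 1024, seed = 5)
  sb2 <- sobol_indices(ish, ri, N = 2048, seed = 5)
  se <- sobol_standard_errors(sb1, n_boot = 200, seed = 6)
  ## 3-sigma comparison per parameter, total-order index
  expect_true(all(abs(sb2$ST[, 1] - sb1$ST[, 1]) < 3.5 * se[, "ST"] + 0.01))
})

test_that("sampling preconditions are enforced", {
  r <- tibble::tibble(name = "x", lower = 0, upper = 1)
  expect_error(sobol_indices(identity, r, N = 100), "power of 2")
  expect_error(sobol_indices(identity, r, N = 32), "power of 2")
  r_inf <- tibble::tibble(name = "x", lower = 0, upper = Inf)
  expect_error(sobol_indices(function(v) v[["x"]], r_inf, N = 64), "finite")
  expect_error(
    sobol_indices(function(v) NaN, r, N = 64, seed = 1),
    "non-finite"
  )
})

test_that("time-resolved indices are zero before the response and defined after", {
  ranges <- sensitivity_ranges(ref_p)
  expect_equal(nrow(ranges), 43)  # 42 non-fixed parameters + DC_in
  expect_true("DC_in" %in% ranges$name)
  sb <- timedependent_sobol(ranges = ranges, times = c(0, 24, 100, 200),
                            N = 64, seed = 1)
  ## M(0) = 0 for every draw: zero-variance convention
  expect_true(all(sb$S1[, "M_t0"] == 0))
  expect_true(all(sb$ST[, "M_t0"] == 0))
  ## M at 200 h and the integral output carry signal
  expect_gt(max(sb$ST[, "M_t200"]), 0.01)
  expect_true("integral" %in% sb$outputs)
  td <- generics::tidy(sb)
  expect_setequal(names(td), c("parameter", "output", "S1", "ST"))
})

test_that("IKK-beta degradation ranks among the most influential inputs", {
  ## modest N keeps this a ranking (not index-value) check; at this sample
  ## size only coarse rank statements are estimator-stable
  sb <- timedependent_sobol(N = 128, seed = 42)
  rk <- rank_parameters(sb)
  expect_lte(which(rk$parameter == "k_deg_IKKb"), 8)
  ## cytokine-module constants sit below the signaling/T-cell core
  cyto_ranks <- which(rk$parameter %in%
                        c("k_deg_mIL12", "k_transl_IL12", "k_deg_IL12"))
  expect_gt(min(cyto_ranks), 8)
})
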