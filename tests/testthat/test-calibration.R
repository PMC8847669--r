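test_that("cost function matches hand evaluation and its invariances", {
  obs <- tibble::tibble(observable = "y", time = c(1, 2), value = c(2, 4),
                        sd = c(1, 2))
  sim <- tibble::tibble(observable = "y", time = c(1, 2), value = c(2, 2))
  expect_equal(cost_function(obs, sim), (2 / (4 * 2))^2)
  ## zero iff exact match
  sim2 <- sim
  sim2$value <- obs$value
  expect_equal(cost_function(obs, sim2), 0)
  ## row order does not matter
  expect_equal(cost_function(obs[2:1, ], sim), cost_function(obs, sim))
  ## scaling all sd by c scales the cost by 1/c^2
  obs3 <- obs
  obs3$sd <- obs$sd * 3
  expect_equal(cost_function(obs3, sim), cost_function(obs, sim) / 9)
  ## interpolation on the simulation grid
  simd <- tibble::tibble(observable = "y", time = c(0, 4), value = c(0, 8))
  expect_equal(cost_function(obs, simd), 0)  # linear through both points
  ## error paths
  obs0 <- obs
  obs0$value <- 0
  expect_error(cost_function(obs0, sim), "normalize")
  obs_out <- obs
  obs_out$time[2] <- 10
  expect_error(cost_function(obs_out, sim), "outside")
})

test_that("Latin hypercube samples are exactly stratified and reproducible", {
  b <- tibble::tibble(name = c("a", "b"), lower = c(0, 10),
                      upper = c(1, 20))
  s <- lhs_sample(4, b, seed = 3)
  expect_equal(sort(floor(s$a * 4)), 0:3)
  expect_equal(sort(floor((s$b - 10) / 2.5)), 0:3)
  expect_identical(lhs_sample(4, b, seed = 3), s)
  ## per-dimension mean approaches the midpoint
  s2 <- lhs_sample(1000, b, seed = 4)
  expect_lt(abs(mean(s2$a) - 0.5) / 0.5, 2 / sqrt(1000))
  b_bad <- b
  b_bad$lower[1] <- 2
  expect_error(lhs_sample(4, b_bad, seed = 1), "bound")
})

test_that("pattern search solves convex and multimodal benchmarks", {
  bs <- tibble::tibble(name = c("x", "y"), lower = -1, upper = 1)
  g <- global_search(function(v) sum(v^2), lhs_sample(5, bs, 1), bs,
                     budget = 1500, top = 3)
  expect_lt(g$cost[1], 1e-8)
  expect_true(all(abs(as.numeric(g[1, c("x", "y")])) < 1e-4))
  ## costs are sorted and the top flag marks the best solutions
  expect_true(!is.unsorted(g$cost))
  expect_equal(sum(g$top), 3)

  rosen <- function(v) (1 - v[["x"]])^2 + 100 * (v[["y"]] - v[["x"]]^2)^2
  br <- tibble::tibble(name = c("x", "y"), lower = -2, upper = 2)
  gr <- global_search(rosen, lhs_sample(50, br, 7), br, budget = 2000,
                      top = 10)
  best <- local_refine(rosen, gr[gr$top, c("x", "y")], br, n_best = 3)
  expect_lt(max(abs(as.numeric(best[1, c("x", "y")]) - 1)), 1e-3)

  ## NaN objectives mark a start failed without aborting
  gn <- global_search(function(v) if (v[["x"]] < 0) NaN else sum(v^2),
                      tibble::tibble(x = c(-0.5, 0.5), y = c(0, 0)), bs,
                      budget = 200, top = 2)
  expect_true(any(gn$failed))
  expect_true(any(!gn$failed))
})

test_that("local refinement is exact on quadratics and never increases cost", {
  bs <- tibble::tibble(name = c("x", "y"), lower = -1, upper = 1)
  quad <- function(v) sum((v - 0.3)^2)
  starts <- lhs_sample(4, bs, 2)
  r <- local_refine(quad, starts, bs)
  expect_lt(r$cost[1], 1e-8)
  start_costs <- apply(starts, 1, function(row) quad(row))
  expect_true(all(r$cost <= sort(start_costs) + 1e-12))
})

test_that("free IL-8 parameters are recovered from noiseless synthetic data", {
  ds <- generate_dataset("cytokine", noiseless_config)
  free <- c("k_transc2_mIL8", "k_deg_mIL8", "k_transl_IL8")
  stage <- list(name = "cytokine", kind = "cytokine", free = free)
  obj <- dcvax:::stage_objective(stage, ds, ref_v, ref_con)
  rows <- match(free, ref_p$name)
  bounds <- tibble::tibble(name = free, lower = log10(ref_p$lower[rows]),
                           upper = log10(ref_p$upper[rows]))
  g <- global_search(obj, lhs_sample(12, bounds, seed = 4), bounds,
                     budget = 120, top = 4)
  r <- local_refine(obj, g[g$top, free], bounds, n_best = 3)
  est <- 10^as.numeric(r[1, free])
  truth <- ref_v[free]
  expect_true(all(abs(est - truth) / truth < 0.10))
  ## the hybrid never ends above its best start
  start_costs <- apply(lhs_sample(12, bounds, seed = 4), 1,
                       function(row) obj(stats::setNames(row, free)))
  expect_lte(r$cost[1], min(start_costs, na.rm = TRUE))
})

test_that("the staged plan frees the documented subsets and only K_4 last", {
  plan <- calibration_plan(ref_p)
  expect_equal(vapply(plan, `[[`, character(1), "name"),
               c("biodistribution", "nfkb", "cytokine", "tcell"))
  expect_equal(plan[[4]]$free, "K_4")
  expect_length(plan[[1]]$free, 6)
  expect_length(plan[[2]]$free, 15)
  expect_length(plan[[3]]$free, 16)
  ## free subsets are disjoint and exclude fixed volumes
  all_free <- unlist(purrr::map(plan, "free"))
  expect_false(anyDuplicated(all_free) > 0)
  expect_false(any(grepl("^Q_", all_free)))
})

test_that("staged calibration is self-consistent and seed-reproducible", {
  ds <- list(tcell = generate_dataset("tcell", noiseless_config))
  plan <- calibration_plan(ref_p, stages = "tcell")
  ctl <- list(n_lhs = 8, budget = 60, top = 3, n_best = 2)
  cal1 <- calibrate(plan, ds, ref_p, seed = 9, control = ctl)
  cal2 <- calibrate(plan, ds, ref_p, seed = 9, control = ctl)
  expect_identical(cal1$stages$tcell$best, cal2$stages$tcell$best)
  expect_lt(cal1$stages$tcell$cost, 1e-6)
  expect_lt(abs(cal1$stages$tcell$best[["K_4"]] - ref_v[["K_4"]]) /
              ref_v[["K_4"]], 0.05)
  expect_error(calibrate(plan, list(), ref_p), "missing dataset")
  td <- generics::tidy(cal1)
  expect_equal(td$name, "K_4")
})
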