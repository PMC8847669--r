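test_that("identical IKK-beta degradation in both arms gives fold-changes of 1", {
  cmp <- compare_vaccines(ref_p, k_deg_IKKb_caikk = 0.840)
  expect_equal(cmp$fold_memory, 1, tolerance = 1e-6)
  expect_equal(cmp$fold_sle, 1, tolerance = 1e-6)
})

test_that("the caIKK arm outperforms the normal arm and activates NF-kB more", {
  cmp <- compare_vaccines(ref_p)
  expect_gt(cmp$fold_memory, 1)
  expect_gt(cmp$fold_sle, 1)
  expect_gt(cmp$nfkb_integral[["caikk"]], cmp$nfkb_integral[["normal"]])
  ## any k_deg_IKKb reduction below baseline helps
  cmp2 <- compare_vaccines(ref_p, k_deg_IKKb_caikk = 0.5)
  expect_gt(cmp2$fold_memory, 1)
  expect_lt(cmp2$fold_memory, cmp$fold_memory)
  g <- generics::glance(cmp)
  expect_equal(g$fold_memory, cmp$fold_memory)
})

test_that("single-parameter scans satisfy grid and identity contracts", {
  g <- fold_grid()
  expect_length(g, 25)
  expect_equal(g[1], 0.1)
  expect_equal(g[25], 10)
  sc <- perturb_scan_single("k_deg_mIkBa", ref_p, grid = c(0.1, 1, 10))
  expect_equal(sc$fold_change[sc$fold == 1], 1, tolerance = 1e-6)
  expect_false(any(sc$failed))
  expect_true(all(sc$converged))
  expect_error(perturb_scan_single("nope", ref_p), "param")
})

test_that("perturbation directions match the pathway logic", {
  five <- fold_grid(9)
  ## IkB-alpha mRNA degradation releases NF-kB: positive modulator
  sc_up <- perturb_scan_single("k_deg_mIkBa", ref_p, grid = five)
  expect_true(all(diff(sc_up$value) > 0))
  ## IKK-beta, IL-6 mRNA and IL-8 mRNA degradation: negative modulators
  for (par in c("k_deg_IKKb", "k_deg_mIL6", "k_deg_mIL8")) {
    sc_dn <- perturb_scan_single(par, ref_p, grid = five)
    expect_true(all(diff(sc_dn$value) < 0), info = par)
  }
  ## the N_tot scan rises to its maximum and never exceeds it afterwards
  sc_n <- perturb_scan_single("N_tot", ref_p, grid = five)
  i_max <- which.max(sc_n$value)
  expect_true(all(diff(sc_n$value[seq_len(i_max)]) > 0))
  expect_gt(sc_n$fold[i_max], 3)
  ## losing 90% of NF-kB collapses the memory response
  expect_lt(sc_n$fold_change[1], 0.5)
})

test_that("the caIKK scenario override anchors the scan baseline", {
  sc <- perturb_scan_single("k_deg_IKKb", ref_p, grid = c(1),
                            scenario = "caikk_dc")
  base <- as.numeric(steady_state_memory("caikk_dc", ref_p))
  expect_equal(sc$value[1], base, tolerance = 1e-9)
})

test_that("pairwise scans report the matrix and the combined-modulation gain", {
  g3 <- c(0.1, 1, 10)
  ps <- perturb_scan_pairwise("k_deg_IKKb", "k_deg_mIkBa", ref_p,
                              grid1 = g3, grid2 = g3)
  expect_equal(dim(ps$matrix), c(3, 3))
  ## grid center equals the unperturbed baseline
  expect_equal(ps$matrix["1", "1"], ps$baseline, tolerance = 1e-6)
  ## combined beneficial extreme beats both singles
  expect_gt(ps$combined_extreme, max(ps$single_extremes))
  expect_gt(ps$gain_percent, 0)
  ## deterministic pipeline: bit-identical on re-run
  ps2 <- perturb_scan_pairwise("k_deg_IKKb", "k_deg_mIkBa", ref_p,
                               grid1 = g3, grid2 = g3)
  expect_identical(ps$matrix, ps2$matrix)
  expect_error(perturb_scan_pairwise("k_deg_IKKb", "k_deg_IKKb", ref_p),
               "param")
  td <- generics::tidy(ps)
  expect_equal(nrow(td), 9)
})

test_that("plot front-ends return ggplot objects", {
  tr <- simulate_model("caikk_dc", ref_p, times = seq(0, 100, 2))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  ds <- generate_dataset("cytokine", noiseless_config)
  expect_s3_class(ggplot2::autoplot(ds), "ggplot")
  sc <- perturb_scan_single("k_deg_mIkBa", ref_p, grid = c(0.1, 1, 10))
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
})
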