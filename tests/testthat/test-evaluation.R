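test_that("the eight digital phantoms carry the prescribed compartment values", {
  phs <- build_digital_phantoms(seed = 1)
  expect_length(phs, 8)
  expect_equal(phs$ksw$values, c(50, 150, 250, 350, 500))
  expect_equal(phs$m0s$values, c(1, 125, 250, 375, 500))
  expect_equal(phs$kmw$values, c(5, 25, 50, 75, 100))
  expect_equal(phs$m0m$values, c(5, 10, 15, 20, 25))
  expect_equal(phs$t2m$values, c(1, 25, 50, 75, 100))
  expect_equal(phs$dmw$values, 1:5)
  expect_equal(phs$t1w$values, c(0.2, 0.9, 1.6, 2.3, 3.0))
  expect_equal(phs$db0$values, c(-80, -40, 0, 40, 80))
  for (ph in phs) {
    expect_equal(length(unique(ph$mask[ph$mask > 0])), 5)
    expect_equal(nrow(ph$nuisance), 1)   # nuisance drawn once per phantom
  }
  tr <- stmrf:::phantom_truth(phs$ksw)
  expect_equal(sort(unique(tr$tissue[, "ksw"])), phs$ksw$values)
})

test_that("precision phantoms have the fine compartment ladders", {
  pk <- build_precision_phantom("ksw", seed = 1)
  pm <- build_precision_phantom("m0s", seed = 1)
  expect_length(pk$values, 46)
  expect_length(pm$values, 50)
  expect_true(all(diff(pk$values) == 10))
  expect_true(all(diff(pm$values) == 10))
  expect_equal(range(pk$values), c(50, 500))
  expect_equal(range(pm$values), c(10, 500))
})

test_that("nrmse and mae agree with brute-force implementations", {
  set.seed(3)
  b <- tissue_bounds()
  for (i in 1:100) {
    p <- sample(b$param, 1)
    rng <- b$upper[match(p, b$param)] - b$lower[match(p, b$param)]
    n <- sample(5:50, 1)
    truth <- runif(n); est <- truth + rnorm(n, sd = 0.3)
    brute_rmse <- sqrt(sum((est - truth)^2) / n)
    expect_equal(nrmse(est, truth, param = p), 100 * brute_rmse / rng,
                 tolerance = 1e-12)
    expect_equal(mae(est, truth), sum(abs(est - truth)) / n,
                 tolerance = 1e-12)
  }
  expect_equal(nrmse(1:5, 1:5, param = "ksw"), 0)
  expect_equal(mae(1:5, 1:5), 0)
  # constant offset closed form
  expect_equal(nrmse(1:5 + 49.5, 1:5, param = "ksw"), 10)
  expect_error(nrmse(1:3, 1:3, norm = 0), "zero")
})

test_that("adjacent-compartment t-tests behave as a two-sided test should", {
  set.seed(4)
  lab <- rep(1:3, each = 100)
  x <- rnorm(300, mean = c(0, 5, 5.2)[lab])  # 5 sigma, then 0.2 sigma apart
  p <- compare_adjacent_compartments(x, lab)
  expect_lt(p$p[1], 0.05)
  expect_gt(p$p[2], 0.001)
  # symmetry in argument order
  a <- x[lab == 1]; bb <- x[lab == 2]
  expect_equal(t.test(a, bb)$p.value, t.test(bb, a)$p.value)
  # degenerate zero-variance input flagged
  expect_warning(pz <- compare_adjacent_compartments(rep(1, 20), rep(1:2, 10)),
                 "zero-variance")
  expect_true(is.na(pz$p[1]))
})

test_that("phantom experiment with an oracle quantifier scores zero error", {
  phs <- build_digital_phantoms(seed = 2)[c("ksw", "db0")]
  sched <- linear_schedule()[seq(1, 63, 4), ]
  for (ph in phs) {
    # oracle quantifier: a closure returning the phantom's own truth
    tr <- stmrf:::phantom_truth(ph)
    stub <- function(S, rb1)
      as.data.frame(tr$tissue[, stmrf:::.ptq_names, drop = FALSE])
    m <- run_phantom_experiment(ph, sched, stub, snr_db = Inf, seed = 5)
    expect_equal(m$nrmse, 0)
    expect_equal(m$mae, 0)
  }
})

test_that("synthetic signal maps round-trip and respect voxel independence", {
  pt <- sample_tissue_parameters(6, seed = 6)
  sched <- pseudo_random_schedule(7)[1:20, ]
  S <- simulate_signals(pt, sched)
  expect_equal(synthesize_from_maps(pt, sched), S)
  expect_equal(ncol(S), 20)
  # permuting voxels permutes outputs identically
  ord <- c(4, 1, 6, 2, 5, 3)
  expect_equal(synthesize_from_maps(pt[ord, ], sched), S[ord, ])
  # missing parameters filled from defaults
  partial <- pt[, c("t1w", "t1t2_ratio", "ksw", "m0s")]
  S2 <- synthesize_from_maps(partial, sched)
  expect_equal(dim(S2), dim(S))
  expect_error(synthesize_from_maps(partial, sched, defaults = list(db0 = 0)),
               "incomplete")
})

test_that("parameter maps export to NIfTI volumes", {
  skip_if_not_installed("RNifti")
  ph <- build_precision_phantom("ksw", seed = 8)
  tr <- stmrf:::phantom_truth(ph)
  est <- data.frame(ksw = tr$tissue[, "ksw"])
  d <- tempfile(); paths <- write_parameter_maps(est, tr$voxels, dim(ph$mask), d)
  expect_true(file.exists(paths[["ksw"]]))
  img <- RNifti::readNifti(paths[["ksw"]])
  expect_equal(sum(img != 0), sum(tr$tissue[, "ksw"] != 0))
})
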