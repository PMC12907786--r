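test_that("sampled parameters respect the bounds with uniform moments", {
  p <- sample_parameters(30000, seed = 1)
  b <- tissue_bounds()
  for (i in seq_len(nrow(b))) {
    x <- p$tissue[[b$param[i]]]
    expect_true(all(x >= b$lower[i] & x <= b$upper[i]))
  }
  expect_true(all(p$tissue$ksw >= 5 & p$tissue$ksw <= 500))
  expect_true(all(p$tissue$rb1 >= 0.5 & p$tissue$rb1 <= 1.5))
  # uniform-moment check: mean T1w ~ 1.6 within 3 standard errors
  se <- (3.0 - 0.2) / sqrt(12) / sqrt(30000)
  expect_lt(abs(mean(p$tissue$t1w) - 1.6), 3 * se)
  # offsets live in the three bands
  o <- p$scan$offset
  expect_true(all((abs(o) <= 1) | (o >= 3 & o <= 4) | (abs(o) >= 8 & abs(o) <= 40)))
  expect_identical(sample_parameters(50, seed = 2), sample_parameters(50, seed = 2))
})

test_that("training set pairs normalized inputs with exact simulator targets", {
  p <- sample_parameters(50, seed = 3)
  ds <- build_training_set(p)
  expect_equal(dim(ds$X), c(50, 15))
  expect_true(all(ds$X >= 0 & ds$X <= 1))
  expect_true(all(ds$Y >= 0 & ds$Y <= 1))
  expect_equal(drop(ds$Y),
               stmrf:::simulate_signal_pairs(p$tissue, p$scan))
  # normalization round trip
  b <- tissue_bounds()
  ptm <- stmrf:::as_tissue_matrix(p$tissue)
  expect_equal(denormalize_params(normalize_params(ptm, b), b), ptm,
               tolerance = 1e-12)
})

test_that("surrogate predicts in (0,1), preserves order, clamps out-of-range input", {
  m <- train_dbes(n_samples = 3000, seed = 4, preset = "small", epochs = 3,
                  hidden = c(16, 16))
  sched <- pseudo_random_schedule(2)
  pt <- sample_tissue_parameters(1, seed = 5)
  y <- dbes_predict(m, pt, sched)
  expect_length(y, 63)
  expect_true(all(y > 0 & y < 1))
  expect_equal(y[63], dbes_predict(m, pt, sched[63, ]))
  bad <- pt; bad$ksw <- 1000
  expect_warning(dbes_predict(m, bad, sched[1, ]), "clamped")
})

test_that("surrogate input gradients match finite differences", {
  m <- train_dbes(n_samples = 3000, seed = 6, preset = "small", epochs = 3,
                  hidden = c(16, 16))
  set.seed(7)
  X <- matrix(runif(20 * 15), 20)
  dOut <- matrix(1, 20, 1)
  g <- stmrf:::dbes_input_grad(m, X, dOut)
  h <- 1e-5
  for (k in sample(15, 6)) {
    Xp <- X; Xp[, k] <- Xp[, k] + h
    Xm <- X; Xm[, k] <- Xm[, k] - h
    fd <- (stmrf:::dbes_forward_norm(m, Xp)$out -
           stmrf:::dbes_forward_norm(m, Xm)$out) / (2 * h)
    expect_equal(g[, k], drop(fd), tolerance = 1e-4)
  }
})

test_that("surrogate fidelity improves with training-set size", {
  m_small <- train_dbes(n_samples = 2e3, seed = 8, preset = "slice",
                        epochs = 12)
  m_large <- train_dbes(n_samples = 2e4, seed = 8, preset = "slice",
                        epochs = 12)
  grid <- expand.grid(ksw = seq(10, 490, length.out = 15),
                      m0s = seq(5, 545, length.out = 15))
  pt <- stmrf:::slice_context()$tissue[rep(1, nrow(grid)), ]
  pt$ksw <- grid$ksw; pt$m0s <- grid$m0s
  e_small <- evaluate_surrogate(m_small, list(tissue = pt))$mae_pct
  e_large <- evaluate_surrogate(m_large, list(tissue = pt))$mae_pct
  expect_gt(e_small, 0)
  expect_lt(e_large, e_small)
})

test_that("checkpoints round-trip and detect tampering", {
  m <- train_dbes(n_samples = 2000, seed = 10, preset = "small", epochs = 2,
                  hidden = c(8, 8))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$net$W, m$net$W)
  tampered <- readRDS(f)
  tampered$meta$seed <- 999L
  saveRDS(tampered, f)
  expect_error(load_checkpoint(f), "integrity")
})
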