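test_that("noise model follows the dB definition", {
  expect_equal(stmrf:::noise_sigma(40), 0.01)
  x <- runif(100)
  expect_equal(add_noise(x, Inf, seed = 1), x)
  set.seed(2)
  d <- add_noise(rep(0, 1e5), 46) # residuals are pure noise
  sd_hat <- sd(d)
  sigma <- 10^(-46 / 20)
  se <- sigma / sqrt(2 * 1e5)
  expect_lt(abs(sd_hat - sigma), 3 * se)
  expect_equal(sigma, 0.00501187, tolerance = 1e-6)
  # per-row SNR on matrices
  M <- add_noise(matrix(0, 2, 1e4), c(40, 46), seed = 3)
  expect_gt(sd(M[1, ]), sd(M[2, ]))
})

test_that("quantifier training converges and beats the mean predictor", {
  sched <- pseudo_random_schedule(1)
  q <- train_dtpq(sched, forward = "exact", n_samples = 8000, seed = 1,
                  preset = "small", epochs = 15)
  expect_lt(q$meta$history$val_loss[15], q$meta$history$val_loss[1])
  # held-out recovery vs predicting the training mean
  pt <- sample_tissue_parameters(400, seed = 99,
                                 bounds = tissue_bounds(db0_range = c(-128, 128)))
  S <- simulate_signals(pt, sched)
  est <- dtpq_predict(q, S, pt$rb1)
  for (p in colnames(est)) {
    rmse <- sqrt(mean((est[[p]] - pt[[p]])^2))
    base <- sqrt(mean((mean(pt[[p]]) - pt[[p]])^2))
    expect_lt(rmse, base)
  }
  # bounded outputs inside the sampling box even for garbage input
  junk <- matrix(runif(5 * 63), 5)
  ej <- dtpq_predict(q, junk, 1)
  b <- tissue_bounds(db0_range = c(-128, 128))
  for (p in colnames(ej)) {
    i <- match(p, b$param)
    expect_true(all(ej[[p]] >= b$lower[i] & ej[[p]] <= b$upper[i]))
  }
})

test_that("predicting with the wrong schedule is a hard error", {
  sched <- pseudo_random_schedule(5)
  q <- train_dtpq(sched, forward = "exact", n_samples = 1500, seed = 2,
                  preset = "small", epochs = 2)
  expect_error(dtpq_predict(q, runif(20), 1), "does not match")
  other <- pseudo_random_schedule(6)
  expect_error(dtpq_predict(q, runif(63), 1, schedule = other), "hash mismatch")
  expect_silent(dtpq_predict(q, runif(63), 1, schedule = sched))
  expect_warning(dtpq_predict(q, runif(63), rb1 = 2), "clamped")
})

test_that("surrogate-based signal synthesis matches per-pair prediction", {
  m <- train_dbes(n_samples = 2000, seed = 3, preset = "small", epochs = 2,
                  hidden = c(8, 8))
  sched <- linear_schedule()[seq(1, 63, by = 7), ]
  pt <- sample_tissue_parameters(4, seed = 4)
  S <- stmrf:::dbes_signals(m, stmrf:::as_tissue_matrix(pt), sched)
  expect_equal(S[2, 5], dbes_predict(m, pt[2, ], sched[5, ]), tolerance = 1e-12)
})

test_that("B0 shift correction interpolates the APT band only", {
  sched <- linear_schedule()
  sig <- runif(63)
  expect_equal(b0_shift_correction(sig, sched, 0), sig)
  # constant band is invariant under any shift
  sig2 <- sig; sig2[sched$band == "apt"] <- 0.7
  out <- b0_shift_correction(sig2, sched, 50)
  expect_equal(out[sched$band == "apt"], rep(0.7, 40))
  expect_equal(out[sched$band != "apt"], sig2[sched$band != "apt"])
  # linear profile shifts by exactly dB0 x slope (away from band edges)
  slope <- 0.1
  sig3 <- sig; apt <- sched$band == "apt"
  sig3[apt] <- slope * sched$offset_ppm[apt]
  db0 <- 12.773  # 0.1 ppm
  out3 <- b0_shift_correction(sig3, sched, db0)
  interior <- apt & sched$offset_ppm > 3.12
  expect_equal(out3[interior],
               slope * (sched$offset_ppm[interior] - 0.1), tolerance = 1e-9)
  # degenerate single-offset band
  s1 <- sched; s1$offset_ppm[apt] <- 3.5
  expect_warning(b0_shift_correction(sig, s1, 10), "fewer than two")
})
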