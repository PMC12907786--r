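test_that("SAR penalty arithmetic and monotonicity", {
  s <- linear_schedule()
  expect_equal(sar_penalty(s), 0)
  s$B1_uT[5] <- 2.4; s$Ts_s[5] <- 2.5
  expect_equal(sar_penalty(s), 2.0)
  s2 <- s; s2$Ts_s[5] <- 2.6
  expect_gt(sar_penalty(s2), sar_penalty(s))
})

test_that("logit decoding keeps schedules inside band-specific physical ranges", {
  init <- pseudo_random_schedule(4)
  bnd <- stmrf:::loas_bounds(init)
  Z <- stmrf:::schedule_to_logits(init, bnd)
  # round trip: exact up to the +/-6 logit clamp (3e-3 in normalized units)
  back <- stmrf:::logits_to_schedule(Z, init$band, bnd)
  expect_lt(max(abs(back$B1_uT - init$B1_uT) / (2.4 - 0.5)), 3e-3)
  expect_lt(max(abs(back$offset_ppm - init$offset_ppm) /
                (bnd$hi[, "offset"] - bnd$lo[, "offset"])), 3e-3)
  # extreme logits stay within bounds and bands
  Zx <- matrix(rnorm(63 * 4, sd = 50), 63, 4,
               dimnames = dimnames(Z))
  sx <- stmrf:::logits_to_schedule(Zx, init$band, bnd)
  expect_equal(nrow(validate_schedule(sx)[
    validate_schedule(sx)$rule != "SAR bound", , drop = FALSE]), 0)
  # MTC offset signs preserved from initialization
  mtc <- init$band == "mtc"
  expect_equal(sign(sx$offset_ppm[mtc]), sign(init$offset_ppm[mtc]))
})

test_that("quantification loss is zero for an oracle stub and non-negative", {
  pt <- sample_tissue_parameters(30, seed = 1)
  sched <- pseudo_random_schedule(1)
  oracle <- function(S, rb1) {
    normalize_params(stmrf:::as_tissue_matrix(pt)[, stmrf:::.ptq_names])
  }
  L <- quantification_loss(pt, sched, dbes = NULL, dtpq = oracle,
                           snr_db = Inf)
  expect_equal(L, 0)
  bad <- function(S, rb1) oracle(S, rb1) * 0 + 0.5
  expect_gt(quantification_loss(pt, sched, NULL, bad, snr_db = Inf), 0)
})

test_that("loss gradient w.r.t. scan logits matches finite differences", {
  dbes <- train_dbes(n_samples = 4000, seed = 2, preset = "small",
                     epochs = 4, hidden = c(24, 24))
  init <- pseudo_random_schedule(3)
  bnd <- stmrf:::loas_bounds(init)
  Z <- stmrf:::schedule_to_logits(init, bnd)
  pt <- stmrf:::as_tissue_matrix(sample_tissue_parameters(16, seed = 4))
  Xt <- normalize_params(pt)
  Yt <- Xt[, stmrf:::.ptq_names]
  rb1n <- (pt[, "rb1"] - 0.5)
  qnet <- stmrf:::mlp_new(64, c(16, 16), 8, "sigmoid", seed = 5)
  f <- function(Z) stmrf:::loas_loss_grad(Z, qnet, dbes, Xt, Yt, rb1n, bnd,
                                          want_grad = FALSE)$loss
  g <- stmrf:::loas_loss_grad(Z, qnet, dbes, Xt, Yt, rb1n, bnd)$dZ
  h <- 1e-4
  for (idx in list(c(5, 1), c(17, 2), c(33, 3), c(52, 4))) {
    Zp <- Z; Zp[idx[1], idx[2]] <- Zp[idx[1], idx[2]] + h
    Zm <- Z; Zm[idx[1], idx[2]] <- Zm[idx[1], idx[2]] - h
    fd <- (f(Zp) - f(Zm)) / (2 * h)
    expect_equal(unname(g[idx[1], idx[2]]), fd, tolerance = 1e-3)
  }
})

test_that("short optimization run respects constraints and freezes the surrogate", {
  dbes <- train_dbes(n_samples = 6000, seed = 6, preset = "small",
                     epochs = 6, hidden = c(32, 32))
  W_before <- dbes$net$W
  opt <- loas_optimize(dbes, init = "pr", n_samples = 512, seed = 7,
                       epochs = 4, batch = 128, hidden = c(32, 32))
  expect_identical(dbes$net$W, W_before)    # frozen surrogate
  expect_equal(sar_penalty(opt$schedule), 0, tolerance = 1e-6)
  expect_equal(nrow(validate_schedule(opt$schedule)), 0)
  expect_lt(min(opt$history$val_loss), opt$history$val_loss[1] + 1e-12)
  expect_equal(unname(table(opt$schedule$band)[c("water", "mtc", "apt")]),
               c(3, 20, 40), ignore_attr = TRUE)
  # slice surrogate is rejected
  sl <- train_dbes(n_samples = 1000, seed = 8, preset = "slice", epochs = 2)
  expect_error(loas_optimize(sl), "full-input")
})
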