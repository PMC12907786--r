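test_that("evolution matrix decouples pools when exchange and RF are off", {
  pt <- midpoint_pt(); pt$ksw <- 0; pt$kmw <- 0
  sys <- build_system(pt, data.frame(b1 = 0, offset = 3.5, ts = 1, td = 3))
  A <- sys$A
  w <- 1:3; s <- 4:6; m <- 7
  expect_true(all(A[w, c(s, m)] == 0))
  expect_true(all(A[s, c(w, m)] == 0))
  expect_true(all(A[m, c(w, s)] == 0))
})

test_that("exchange entries satisfy detailed balance under the 111 M convention", {
  pt <- midpoint_pt(); pt$ksw <- 100; pt$m0s <- 111
  sys <- build_system(pt, quick_scans()[1, ])
  # kws = ksw * fs with fs = 111 mM / 111000 mM = 1e-3
  expect_equal(sys$A["xs", "xw"], 0.1)
  # water gains solute magnetization at rate ksw
  expect_equal(sys$A["xw", "xs"], 100)
  # semisolid reverse rate kwm = kmw * fm
  fm <- pt$m0m / 111
  expect_equal(sys$A["zm", "zw"], pt$kmw * fm)
})

test_that("evolution matrix is stable for parameters across the sampling box", {
  for (i in 1:10) {
    pt <- sample_tissue_parameters(1, seed = i)
    sp <- sample_parameters(1, seed = 100 + i)$scan
    sys <- build_system(pt, sp)
    expect_true(all(Re(eigen(sys$A, only.values = TRUE)$values) < 0))
  }
})

test_that("zero saturation time returns the recovery initial condition", {
  pt <- midpoint_pt()
  sp <- data.frame(b1 = 1.5, offset = 3.5, ts = 1e-12, td = 2.5)
  sys <- build_system(pt, sp)
  M <- evolve(pt, sp)
  expect_equal(unname(M), as.numeric(sys$Meq * (1 - exp(-2.5 / pt$t1w))),
               tolerance = 1e-8)
})

test_that("single-pool reduction reproduces the scalar relaxation closed form", {
  pt <- midpoint_pt(); pt$m0s <- 0; pt$m0m <- 0; pt$db0 <- 0
  sp <- data.frame(b1 = 0, offset = 3.5, ts = 2, td = 5)
  M <- evolve(pt, sp)
  expect_equal(unname(M["zw"]), 1 - exp(-(5 + 2) / pt$t1w), tolerance = 1e-12)
  expect_equal(simulate_signal(pt, sp), 1 - exp(-(5 + 2) / pt$t1w),
               tolerance = 1e-12)
})

test_that("matrix-exponential solution agrees with adaptive ODE integration", {
  worst <- 0
  for (i in 1:25) {
    pt <- sample_tissue_parameters(1, seed = 200 + i)
    sp <- sample_parameters(1, seed = 300 + i)$scan
    M <- evolve(pt, sp)
    Mode <- ode_oracle_state(pt, sp)
    worst <- max(worst, max(abs(M - Mode)) / max(abs(M)))
  }
  expect_lt(worst, 1e-6)
})

test_that("long saturation converges to the steady state independent of Td", {
  for (i in 1:10) {
    pt <- sample_tissue_parameters(1, seed = 400 + i)
    sp <- sample_parameters(1, seed = 500 + i)$scan
    sp$ts <- 50
    ss <- steady_state(pt, sp)
    expect_lt(max(abs(evolve(pt, sp) - ss)), 1e-6)
    sp2 <- sp; sp2$td <- if (sp$td < 3) 5 else 1.5
    expect_equal(ss, steady_state(pt, sp2))
  }
  # no RF: steady state is thermal equilibrium
  pt <- midpoint_pt()
  sp0 <- data.frame(b1 = 0, offset = 10, ts = 1, td = 3)
  ss0 <- steady_state(pt, sp0)
  expect_equal(unname(ss0["zw"]), 1, tolerance = 1e-10)
})

test_that("signal at the amide offset decreases with exchange rate and concentration", {
  pt <- midpoint_pt(); pt$db0 <- 0; pt$rb1 <- 1
  sp <- data.frame(b1 = 1.5, offset = 3.5, ts = 2, td = 5)
  ks <- seq(5, 500, length.out = 20)
  ms <- seq(0, 550, length.out = 20)
  grid <- expand.grid(ksw = ks, m0s = ms)
  ptm <- pt[rep(1, nrow(grid)), ]
  ptm$ksw <- grid$ksw; ptm$m0s <- grid$m0s
  S <- matrix(simulate_signals(ptm, sp), 20, 20)
  # ksw: non-increasing up to the known fast-exchange saturation of the
  # labeling efficiency (omega_1-limited), which flattens the curve at the
  # top of the range by < 1e-3
  expect_true(all(diff(S) <= 1e-3))
  expect_lt(S[20, 10], S[1, 10])
  expect_true(all(t(diff(t(S))) <= 1e-12))  # strictly decreasing in m0s
})

test_that("spectrum is symmetric without solute, semisolid shift, or B0 offset", {
  pt <- midpoint_pt(); pt$m0s <- 0; pt$dmw <- 0; pt$db0 <- 0
  for (o in c(1, 3.5, 12, 30)) {
    sp_p <- data.frame(b1 = 1.2, offset = o, ts = 1.5, td = 3)
    sp_m <- sp_p; sp_m$offset <- -o
    expect_equal(simulate_signal(pt, sp_p), simulate_signal(pt, sp_m),
                 tolerance = 1e-10)
  }
})

test_that("noiseless signals are normalized to [0, 1] and assemble per scan", {
  sched <- linear_schedule()
  pt <- sample_tissue_parameters(20, seed = 7)
  S <- simulate_signals(pt, sched)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(dim(S), c(20, 63))
  # row of the batch equals scan-wise assembly for one tissue set
  s1 <- vapply(seq_len(63), function(j)
    abs(unname(evolve(pt[3, ], sched[j, ])["zw"])), numeric(1))
  expect_equal(unname(S[3, ]), s1, tolerance = 1e-10)
})
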