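# Shared fixtures and the independent ODE oracle.

# Representative parameter set at the middle of every sampling bound.
midpoint_pt <- function() stmrf:::tissue_midpoint()

# A short scan table for quick checks.
quick_scans <- function() {
  data.frame(b1 = c(1.0, 1.5, 2.0), offset = c(3.5, -10, 0.5),
             ts = c(1.0, 2.0, 0.5), td = c(3.0, 4.0, 2.0))
}

# --- Independent ODE oracle -------------------------------------------------
# Adaptive integration of dM/dt = A M + B with deSolve, from the same
# initial condition as the closed form. The right-hand side is compiled
# once per test session (the system is stiff and oscillatory, so an
# interpreted RHS would be impractically slow); if compilation is
# unavailable the interpreted RHS is used.

.oracle_env <- new.env()

ode_oracle_dll <- function() {
  if (!is.null(.oracle_env$dll)) return(.oracle_env$dll)
  dir <- tempfile("bmode")
  dir.create(dir)
  src <- file.path(dir, "bmode.c")
  writeLines(c(
    "#include <R.h>",
    "static double parms[56];",
    "void bm_initmod(void (* odeparms)(int *, double *)) {",
    "  int N = 56; odeparms(&N, parms);",
    "}",
    "void bm_deriv(int *neq, double *t, double *y, double *ydot,",
    "              double *yout, int *ip) {",
    "  int i, j;",
    "  for (i = 0; i < 7; i++) {",
    "    double s = parms[49 + i];",
    "    for (j = 0; j < 7; j++) s += parms[i + 7 * j] * y[j];",
    "    ydot[i] = s;",
    "  }",
    "}"), src)
  ok <- system2(file.path(R.home("bin"), "R"),
                c("CMD", "SHLIB", shQuote(src)),
                stdout = FALSE, stderr = FALSE) == 0
  so <- file.path(dir, paste0("bmode", .Platform$dynlib.ext))
  if (ok && file.exists(so)) {
    dyn.load(so)
    .oracle_env$dll <- so
  } else {
    .oracle_env$dll <- NA
  }
  .oracle_env$dll
}

# Water Mz (and full state) at end of saturation by adaptive ODE
# integration; independent of the matrix-exponential path.
ode_oracle_state <- function(pt, sp, rtol = 1e-9) {
  sys <- build_system(pt, sp)
  Minit <- as.numeric(sys$Meq * (1 - exp(-sp$td / pt$t1w)))
  dll <- ode_oracle_dll()
  if (!is.na(dll)) {
    sol <- deSolve::lsoda(Minit, c(0, sp$ts), func = "bm_deriv",
                          parms = c(sys$A, sys$B), dllname = "bmode",
                          initfunc = "bm_initmod", rtol = rtol,
                          atol = 1e-12, maxsteps = 1e6)
  } else {
    f <- function(t, y, p) list(sys$A %*% y + sys$B)
    sol <- deSolve::lsoda(Minit, c(0, sp$ts), f, rtol = rtol, atol = 1e-12,
                          jacfunc = function(t, y, p) sys$A,
                          jactype = "fullusr", maxsteps = 1e6)
  }
  sol[2, -1]
}

# High-resolution quadrature of the super-Lorentzian orientation integral
# (independent of the package's 256-node rule and of its spline region).
sl_oracle <- function(delta_hz, t2m_s) {
  f <- function(u) sqrt(2 / pi) * (t2m_s / abs(3 * u^2 - 1)) *
    exp(-2 * (2 * pi * delta_hz * t2m_s / (3 * u^2 - 1))^2)
  stats::integrate(f, 0, 1, subdivisions = 2000, rel.tol = 1e-10)$value
}
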