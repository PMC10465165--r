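test_that("neuronal drift is the bilinear form (A + uB)x + Cu", {
  p <- fx_params()
  # zero state, zero drive -> zero derivative
  expect_equal(neuronal_drift(rep(0, 4), 0, 0, p), rep(0, 4))
  # pure self-decay
  pd <- plain_params()
  expect_equal(neuronal_drift(rep(1, 4), 0, 0, pd), rep(-0.5, 4))
  # u_mod = 1 is equivalent to coupling A' = A + B without modulation
  x <- c(0.3, -0.1, 0.2, 0.05)
  p2 <- p; p2$A <- p$A + p$B[[1]]; p2$B[[1]][] <- 0
  expect_equal(neuronal_drift(x, 0.7, 1, p), neuronal_drift(x, 0.7, 0, p2))
  expect_error(neuronal_drift(rep(0, 3), 0, 0, p), "dimension")
})

test_that("hemodynamic drift has the resting fixed point and df/dt = s", {
  p <- fx_params()
  expect_equal(hemodynamic_drift(c(0, 1, 1, 1), 0, p), rep(0, 4))
  d <- hemodynamic_drift(c(0.1, 1, 1, 1), 0, p)
  expect_equal(d[2], 0.1)   # df/dt = s
  expect_error(hemodynamic_drift(c(0, -1, 1, 1), 0, p), "non-positive")
})

test_that("BOLD observation is calibrated to zero at rest and reduces algebraically", {
  p <- fx_params()
  expect_equal(bold_observation(c(0, 1, 1, 1), p), 0)
  hc <- p$hemo
  k1 <- 7 * hc$E0; k2 <- 2; k3 <- 2 * hc$E0 - 0.2
  # v = 1: the volume term vanishes and q/v reduces to q
  expect_equal(bold_observation(c(0, 1, 1, 0.9), p),
               100 * hc$V0 * (k1 + k2) * (1 - 0.9))
  # q = v: the flow-dilution term vanishes
  expect_equal(bold_observation(c(0, 1, 0.95, 0.95), p),
               100 * hc$V0 * (k1 + k3) * (1 - 0.95))
  # tabulated pair, direct formula
  v <- 1.1; q <- 0.85
  expect_equal(bold_observation(c(0, 1, v, q), p),
               100 * hc$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v)))
})

test_that("full cascade matches an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- fx_params()
  inp <- quick_inputs()
  ours <- integrate_dcm(p, inp)
  # u(t) lookup on the microtime grid
  dtb <- inp$TR / inp$bins_per_tr
  u_at <- function(t, u) u[pmin(length(u), pmax(1, ceiling(t / dtb + 1e-12)))]
  deriv <- function(t, y, parms) {
    x <- y[1:4]; h <- matrix(y[5:20], 4, 4)  # rows: s f v q per region? cols
    hs <- matrix(y[5:20], nrow = 4)          # 4 states x 4 regions
    dx <- neuronal_drift(x, u_at(t, inp$u_drive[, 1]), u_at(t, inp$u_mod[, 1]), p)
    dh <- vapply(1:4, function(r) hemodynamic_drift(hs[, r], x[r], p, r),
                 numeric(4))
    list(c(dx, as.numeric(dh)))
  }
  y0 <- c(rep(0, 4), as.numeric(rbind(0, 1, 1, 1)[, rep(1, 4)]))
  y0 <- c(rep(0, 4), rep(c(0, 1, 1, 1), 4))
  tt <- seq_len(inp$n_volumes) * inp$TR
  sol <- deSolve::ode(y0, c(0, tt), deriv, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  bold_ref <- t(apply(sol[-1, -1, drop = FALSE], 1, function(y) {
    hs <- matrix(y[5:20], nrow = 4)
    vapply(1:4, function(r) bold_observation(c(hs[, r]), p), numeric(1))
  }))
  expect_lt(max(abs(bold_ref - ours$data)), 1e-4)
})

test_that("neuronal subsystem matches the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  p <- fx_params()
  p$B[[1]][] <- 0   # linear system
  inp <- quick_inputs()
  ours <- attr(integrate_dcm(p, inp, return_states = TRUE), "states")
  dtb <- inp$TR / inp$bins_per_tr
  E <- as.matrix(Matrix::expm(p$A * dtb))
  Ainv <- solve(p$A)
  x <- rep(0, 4); k <- 0; ref <- matrix(0, inp$n_volumes, 4)
  for (b in seq_len(nrow(inp$u_drive))) {
    u <- inp$u_drive[b, 1]
    x <- as.numeric(E %*% x + Ainv %*% (E - diag(4)) %*% (p$C[, 1] * u))
    if (b %% inp$bins_per_tr == 0) { k <- k + 1; ref[k, ] <- x }
  }
  expect_lt(max(abs(ours - ref)), 1e-6)
})

test_that("zero input gives exactly zero output and C = 0 is silent", {
  p <- fx_params()
  p$C[] <- 0
  inp <- quick_inputs()
  out <- integrate_dcm(p, inp)
  expect_true(all(out$data == 0))
})

test_that("integrator converges under microtime refinement", {
  p <- fx_params()
  d <- quick_design()
  y16 <- integrate_dcm(p, design_to_inputs(d, TR = 2, bins_per_tr = 16))
  y32 <- integrate_dcm(p, design_to_inputs(d, TR = 2, bins_per_tr = 32))
  expect_lt(max(abs(y16$data - y32$data)), 1e-4)
})

test_that("small driving gains scale the peak neuronal response linearly", {
  p <- plain_params(c_gain = 0.05)
  inp <- quick_inputs()
  s1 <- attr(integrate_dcm(p, inp, return_states = TRUE), "states")
  p2 <- plain_params(c_gain = 0.1)
  s2 <- attr(integrate_dcm(p2, inp, return_states = TRUE), "states")
  expect_lt(abs(max(s2[, 1]) / max(s1[, 1]) - 2), 0.05 * 2)
})

test_that("stable coupling keeps long runs bounded; unstable coupling warns", {
  p <- fx_params()
  long_d <- make_block_design(60)
  inp <- design_to_inputs(long_d, TR = 2, bins_per_tr = 8)
  out <- integrate_dcm(p, inp)
  expect_true(all(abs(out$data) < 50))
  pu <- p; pu$A[1, 2] <- 5; pu$A[2, 1] <- 5   # positive eigenvalue
  expect_warning(try(integrate_dcm(pu, quick_inputs()), silent = TRUE),
                 "unstable")
})

test_that("parameters are checked against the model's masks", {
  p <- fx_params()
  spec <- winning_architecture()   # no modulation allowed
  expect_error(integrate_dcm(p, quick_inputs(), spec = spec), "b_mask")
})
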