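test_that("the Dirichlet update matches an independent reference to 1e-6", {
  set.seed(21)
  L <- matrix(rnorm(48, sd = 2), 12, 4)
  fit <- rfx_dirichlet(L)
  expect_lt(max(abs(fit$alpha - .ref_rfx(L))), 1e-6)
  expect_equal(sum(fit$expected_freq), 1, tolerance = 1e-9)
})

test_that("symmetric and saturated evidence give the textbook concentrations", {
  L <- matrix(0, 5, 2)
  fit <- rfx_dirichlet(L)
  expect_equal(fit$alpha[1], fit$alpha[2], tolerance = 1e-8)
  expect_equal(fit$expected_freq, c(0.5, 0.5), tolerance = 1e-8)
  # one subject with overwhelming evidence for model 1
  a0 <- 1
  fit1 <- rfx_dirichlet(matrix(c(0, -100), 1, 2), alpha0 = a0)
  expect_equal(fit1$expected_freq, c(a0 + 1, a0) / (2 * a0 + 1),
               tolerance = 1e-6)
  expect_error(rfx_dirichlet(matrix(c(0, NA), 1, 2)), "finite")
})

test_that("the fixed point is invariant to subject order", {
  set.seed(22)
  L <- matrix(rnorm(30), 10, 3)
  f1 <- rfx_dirichlet(L)
  f2 <- rfx_dirichlet(L[10:1, ])
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-8)
})

test_that("exceedance probabilities behave and match the K=2 closed form", {
  expect_equal(exceedance_prob(c(1, 1)), c(0.5, 0.5), tolerance = 0.01)
  xp_mc <- exceedance_prob(c(100, 1), n_samples = 1e6, seed = 2,
                           method = "montecarlo")
  expect_lt(abs(xp_mc[1] - 1), 0.001)
  a <- c(7.3, 3.7)
  xp_exact <- exceedance_prob(a, method = "exact")
  expect_equal(xp_exact[1], 1 - pbeta(0.5, a[1], a[2]), tolerance = 1e-12)
  xp_mc2 <- exceedance_prob(a, n_samples = 2e5, seed = 3, method = "montecarlo")
  expect_lt(max(abs(xp_mc2 - xp_exact)), 0.005)
  expect_equal(sum(xp_mc2), 1, tolerance = 1e-9)
})

test_that("Monte Carlo error shrinks roughly as 1/sqrt(n)", {
  a <- c(3, 2, 1)
  truth <- exceedance_prob(a, n_samples = 4e5, seed = 99, method = "montecarlo")
  err_at <- function(n) {
    mean(vapply(1:8, function(s) {
      max(abs(exceedance_prob(a, n_samples = n, seed = 1000 + s,
                              method = "montecarlo") - truth))
    }, numeric(1)))
  }
  e_small <- err_at(500)
  e_big <- err_at(8000)   # 16x more samples -> ~4x smaller error
  expect_lt(e_big, e_small / 2)
})

test_that("the omnibus risk separates null from informative cohorts", {
  L0 <- matrix(0, 18, 3)
  expect_gt(bayesian_omnibus_risk(L0), 0.85)
  L1 <- matrix(0, 18, 3); L1[, 1] <- 10
  expect_lt(bayesian_omnibus_risk(L1), 0.05)
  # invariant to per-subject constants
  set.seed(4)
  L <- matrix(rnorm(36), 12, 3)
  shift <- L + rnorm(12)  # adds a constant to each row
  expect_equal(bayesian_omnibus_risk(L), bayesian_omnibus_risk(shift),
               tolerance = 1e-8)
})

test_that("protection mixes exceedance with uniform by the omnibus risk", {
  expect_equal(protected_xp(c(0.9, 0.1), 0), c(0.9, 0.1))
  expect_equal(protected_xp(c(0.9, 0.1), 1), c(0.5, 0.5))
  expect_equal(protected_xp(c(0.9, 0.1), 0.5), c(0.7, 0.3))
  # bounds: pxp in [bor/K, 1 - bor (K-1)/K]
  xp <- c(0.97, 0.02, 0.01); bor <- 0.3
  pxp <- protected_xp(xp, bor)
  expect_true(all(pxp >= bor / 3 - 1e-12))
  expect_true(all(pxp <= 1 - bor * 2 / 3 + 1e-12))
  expect_equal(sum(pxp), 1, tolerance = 1e-9)
})

test_that("family inference corrects for family size", {
  part <- family_partition(list(frontal = 1:3, acc = 4:10, striatal = 11:13),
                           "second_step", 13)
  # exchangeable evidence: families get 1/3 each despite sizes (3, 7, 3)
  L <- matrix(0, 10, 13)
  fam <- family_inference(L, part, seed = 1)
  expect_equal(unname(fam$expected_freq), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(max(abs(fam$pxp - 1 / 3)), 0, tolerance = 0.01)
  # all evidence mass inside family 1
  L2 <- matrix(0, 10, 13); L2[, 1] <- 8
  fam2 <- family_inference(L2, part, seed = 2)
  expect_gt(fam2$pxp[1], 0.95)
  expect_lt(fam2$pxp[2], 0.05)
  # two equal families, exchangeable -> 0.5 each
  p2 <- family_partition(list(a = 1:2, b = 3:4), "first_step", 4)
  fam3 <- family_inference(matrix(0, 8, 4), p2, seed = 3)
  expect_equal(fam3$pxp, c(0.5, 0.5), tolerance = 0.01)
  expect_error(family_inference(matrix(0, 4, 12), part))
})

test_that("model averaging weights posterior means by model probability", {
  mk_fit <- function(mean, fe) structure(list(mean = mean, free_energy = fe),
                                         class = "dcm_fit")
  f1 <- mk_fit(c(a = 1, b = 2), 0)
  f2 <- mk_fit(c(a = 3), 0)
  # single-model scope: identity
  expect_equal(bma(list(f1, f2), scope = 1)$mean, c(a = 1, b = 2))
  # equal evidence, parameter absent from one model counts as zero
  avg <- bma(list(f1, f2))
  expect_equal(avg$mean[["a"]], 2)
  expect_equal(avg$mean[["b"]], 1)
  # softmax weights for staggered evidence
  f3 <- mk_fit(c(a = 0), -1); f4 <- mk_fit(c(a = 0), -2)
  w <- bma(list(f1, f3, f4))$weights
  ref <- exp(c(0, -1, -2)); ref <- ref / sum(ref)
  expect_equal(unname(w), ref, tolerance = 1e-12)
  expect_error(bma(list(f1), scope = integer(0)), "empty")
})
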