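test_that("the principal eigenvariate summarises an ROI faithfully", {
  set.seed(5)
  # single voxel: centered, rescaled copy of itself
  x <- matrix(rnorm(50), 1, 50)
  ev <- principal_eigenvariate(x)
  expect_equal(cor(ev, as.numeric(x)), 1, tolerance = 1e-12)
  expect_equal(sqrt(mean(ev^2)), sd(as.numeric(x)) * sqrt(49 / 50),
               tolerance = 1e-10)
  # rank-1 matrix: recovers the temporal factor
  tfac <- sin(seq(0, 4 * pi, length.out = 80))
  loads <- runif(30, 0.5, 2)
  Y <- outer(loads, tfac) + matrix(rnorm(30 * 80, sd = 1e-4), 30, 80)
  ev2 <- principal_eigenvariate(Y)
  expect_gte(abs(cor(ev2, tfac)), 0.999)
  # sign contract: never negatively correlated with the ROI mean
  for (s in 1:5) {
    Z <- matrix(rnorm(20 * 40), 20, 40)
    evz <- principal_eigenvariate(Z)
    expect_gte(sum(evz * colMeans(Z - rowMeans(Z))), 0)
  }
  expect_error(principal_eigenvariate(matrix(1, 3, 10)), "variance")
})

test_that("SMA samples respect the volume scope", {
  p <- fx_params()
  d <- quick_design()
  run <- simulate_run(p, d, noise_sd = 0.1, seed = 1, TR = 2, bins_per_tr = 8)
  expect_length(mean_sma_activity(run, "run"), 70)
  expect_length(mean_sma_activity(run, "up-regulation"), 30)  # 3 of 7 blocks
  expect_length(mean_sma_activity(run, "baseline"), 40)
  cr <- roi_ts(matrix(2.5, 10, 4), TR = 2)
  expect_true(all(mean_sma_activity(cr, "run") == 2.5))
  expect_error(mean_sma_activity(cr, "up-regulation"), "empty scope")
})

test_that("the Gaussian KDE is normalised and consistent", {
  set.seed(6)
  x <- rnorm(10000)
  kd <- kde_density(x)
  dx <- kd$x[2] - kd$x[1]
  expect_equal(sum(kd$y) * dx, 1, tolerance = 1e-6)
  at0 <- kd$y[which.min(abs(kd$x))]
  expect_lt(abs(at0 - dnorm(0)) / dnorm(0), 0.05)
  expect_true(kde_density(rep(1, 5))$degenerate)
  # shared grid spans both sample sets
  a <- rnorm(100); b <- rnorm(100) + 5
  ka <- kde_density(a, other = b); kb <- kde_density(b, other = a)
  expect_equal(ka$x, kb$x)
  expect_lt(min(ka$x), min(a)); expect_gt(max(ka$x), max(b))
})

test_that("the 1-D Wasserstein distance has its analytic values", {
  set.seed(7)
  x <- rnorm(500)
  expect_equal(wasserstein_1d(x, x), 0)
  # point masses
  expect_equal(wasserstein_1d(rep(1.5, 4), rep(-0.75, 4)), 2.25)
  # shifted normals: W1 = |shift|
  a <- rnorm(10000); b <- rnorm(10000) + 0.7
  expect_lt(abs(wasserstein_1d(a, b) - 0.7), 0.05)
  ka <- kde_density(a, other = b); kb <- kde_density(b, other = a)
  expect_lt(abs(wasserstein_1d(ka, kb) - 0.7), 0.05)
  # kde and raw estimators agree
  expect_lt(abs(wasserstein_1d(ka, kb) - wasserstein_1d(a, b)), 0.03)
  kc <- kde_density(a)
  expect_error(wasserstein_1d(ka, kc), "grid")
})

test_that("W1 is a distance: symmetry, triangle inequality, translation", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(80, sd = runif(1, 0.5, 2))
    y <- rgamma(60, shape = 2)
    z <- runif(70, -2, 2)
    dxy <- wasserstein_1d(x, y); dyz <- wasserstein_1d(y, z)
    dxz <- wasserstein_1d(x, z)
    expect_gte(dxy, 0)
    expect_equal(dxy, wasserstein_1d(y, x), tolerance = 1e-12)
    expect_lte(dxz, dxy + dyz + 1e-9)
    delta <- runif(1, -1, 1)
    expect_equal(wasserstein_1d(x, x + delta), abs(delta), tolerance = 1e-9)
  }
})

test_that("cohort ranking uses signed distances with the sign label rule", {
  p <- fx_params()
  base <- simulate_run(p, quick_design("baseline"), noise_sd = 0.2, seed = 1,
                       TR = 2, bins_per_tr = 8)
  shift_run <- function(run, delta) {
    run$data <- run$data + delta
    run
  }
  tr_design <- quick_design("transfer")
  tr <- simulate_run(p, tr_design, noise_sd = 0.2, seed = 2, TR = 2,
                     bins_per_tr = 8)
  fake <- list(runs = list(
    up = list(baseline = base, transfer = shift_run(tr, 3)),
    flat = list(baseline = base,
                transfer = roi_ts(base$data, TR = 2, run_type = "transfer",
                                  condition = tr$condition)),
    down = list(baseline = base, transfer = shift_run(tr, -3))
  ))
  rk <- rank_cohort(fake, scope = "run")
  rk <- rk[match(c("up", "flat", "down"), rk$subject_id), ]
  expect_equal(rk$label, c("learner", "non_learner", "non_learner"))
  expect_equal(rk$signed_wd[2], 0, tolerance = 1e-9)   # exact copy -> 0, tie
  expect_gt(rk$signed_wd[1], 0); expect_lt(rk$signed_wd[3], 0)
  # once a subject clearly up-regulates, shifting the transfer run by
  # delta moves the signed score by about delta (translation property)
  rk2 <- rank_cohort(list(runs = list(
    a = list(baseline = base, transfer = shift_run(tr, 4)),
    b = list(baseline = base, transfer = shift_run(tr, 4.5))
  )), scope = "run")
  dd <- rk2$signed_wd[rk2$subject_id == "b"] -
    rk2$signed_wd[rk2$subject_id == "a"]
  expect_lt(abs(dd - 0.5), 0.1)
  # ranking invariant to subject order
  rk3 <- rank_cohort(list(runs = rev(fake$runs)), scope = "run")
  expect_equal(sort(rk3$signed_wd), sort(rk$signed_wd), tolerance = 1e-9)
  expect_error(rank_cohort(list(runs = list(x = list(baseline = base)))),
               "missing")
})

test_that("synthetic cohorts split into the designed learner groups", {
  coh <- sample_cohort(3, 3, seed = 17,
                       config = cohort_config(n_training_runs = 0))
  rk <- rank_cohort(coh)
  expect_equal(nrow(rk), 6)
  expect_equal(rk$label, rk$true_label)
  expect_equal(rk$rank, 1:6)
  # median rule labels exactly half learners
  rkm <- rank_cohort(coh, rule = "median")
  expect_equal(sum(rkm$label == "learner"), 3)
})
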