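test_that("run concatenation stacks volumes and builds per-run confounds", {
  p <- fx_params()
  d <- quick_design()
  runs <- lapply(1:3, function(r) simulate_run(p, d, noise_sd = 0.1,
                                               seed = r, TR = 2,
                                               bins_per_tr = 8))
  cc <- concatenate_runs(runs)
  expect_equal(nrow(cc$data), 3 * 70)
  expect_equal(ncol(cc$confounds), 3)
  expect_equal(colSums(cc$confounds), rep(70, 3))
  # single run: pass-through with one confound
  c1 <- concatenate_runs(runs[[1]])
  expect_equal(c1$data, runs[[1]]$data)
  expect_equal(ncol(c1$confounds), 1)
  bad <- runs; bad[[2]]$TR <- 3
  expect_error(concatenate_runs(bad), "TR")
})

test_that("priors cover exactly the free parameters", {
  spec <- full_modulation_spec()
  pr <- default_priors(spec)
  # 10 A + 10 B + 1 C + 4 transit deviations
  expect_length(pr$mean, 25)
  expect_equal(sum(grepl("^A\\[", names(pr$mean))), 10)
  expect_equal(sum(grepl("^B1\\[", names(pr$mean))), 10)
  expect_equal(sum(grepl("^C\\[", names(pr$mean))), 1)
  # fixed self-connections are not free parameters
  expect_false(any(grepl("\\[F<-F\\]|\\[ACC<-ACC\\]|\\[S<-S\\]|\\[SMA<-SMA\\]",
                         names(pr$mean))))
  expect_true(all(pr$var > 0))
  pr2 <- default_priors(winning_architecture(), hemo_deviations = FALSE)
  expect_length(pr2$mean, 11)
})

test_that("the free energy equals the analytic evidence on conjugate problems", {
  set.seed(11)
  n <- 40; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  sigma <- 0.5
  y <- X %*% c(1, -0.5, 0, 0.25) + rnorm(n, 0, sigma)
  pv <- rep(1.5, p)
  pm <- setNames(rep(0, p), paste0("b", 1:p))
  fit <- vl_invert(y, function(th) X %*% th, pm, pv,
                   control = dcm_control(lambda_fixed = -2 * log(sigma)))
  L <- chol(sigma^2 * diag(n) + X %*% diag(pv) %*% t(X))
  log_z <- -0.5 * n * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(backsolve(L, y, transpose = TRUE)^2)
  expect_lte(fit$free_energy, log_z + 1e-9)      # evidence bound
  expect_lt(abs(fit$free_energy - log_z), 1e-3)  # tight at convergence
  expect_true(all(diff(fit$fe_trace) >= -1e-9))  # monotone ascent
  expect_true(fit$converged)
  # posterior matches the conjugate solution
  Sp <- solve(crossprod(X) / sigma^2 + diag(1 / pv))
  expect_equal(unname(fit$mean),
               as.numeric(Sp %*% crossprod(X, y) / sigma^2), tolerance = 1e-5)
  expect_equal(unname(fit$cov), Sp, tolerance = 1e-6)
})

test_that("posterior covariance is symmetric positive semidefinite", {
  p <- fx_params()
  d <- quick_design()
  run <- simulate_run(p, d, noise_sd = 0.5, seed = 2, TR = 2, bins_per_tr = 8)
  fit <- dcm_fit(run, quick_inputs(), full_modulation_spec(),
                 control = dcm_control(max_iter = 12))
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-10)
  expect_gte(min(eigen(fit$cov, only.values = TRUE)$values), -1e-10)
  expect_equal(fit$free_energy, fit$fe_trace[length(fit$fe_trace)])
  expect_true(all(diff(fit$fe_trace) >= -1e-9))
})

test_that("the generating model beats a model missing a true connection", {
  p <- fx_params()
  d <- quick_design()
  inp <- quick_inputs()
  run <- simulate_run(p, d, noise_sd = 0.2, seed = 4, TR = 2, bins_per_tr = 8)
  spec_true <- full_modulation_spec()
  spec_cut <- spec_true
  spec_cut$a_mask["SMA", "F"] <- FALSE          # remove the F->SMA connection
  spec_cut$b_mask[[1]]["SMA", "F"] <- FALSE
  f_true <- dcm_fit(run, inp, spec_true)
  f_cut <- dcm_fit(run, inp, spec_cut)
  expect_gt(f_true$free_energy, f_cut$free_energy)
})

test_that("irrelevant extra parameters do not inflate the evidence", {
  # generating model: winning architecture, no modulation; competitor adds
  # a direct F-S connection that is absent from the truth
  d <- quick_design()
  inp <- quick_inputs()
  g_spec <- winning_architecture()
  bigger <- g_spec
  bigger$a_mask["S", "F"] <- TRUE; bigger$a_mask["F", "S"] <- TRUE
  cfg <- effect_config(spec = g_spec)
  dF <- vapply(1:6, function(s) {
    p <- sample_subject_params("learner", seed = 600 + s, config = cfg)
    run <- simulate_run(p, d, noise_sd = 0.5, seed = 700 + s, TR = 2,
                        bins_per_tr = 8)
    dcm_fit(run, inp, bigger)$free_energy -
      dcm_fit(run, inp, g_spec)$free_energy
  }, numeric(1))
  expect_lt(mean(dF), 1)   # no systematic advantage for the larger model
})

test_that("fitted-model methods behave coherently", {
  p <- fx_params()
  d <- quick_design()
  run <- simulate_run(p, d, noise_sd = 0.3, seed = 8, TR = 2, bins_per_tr = 8)
  fit <- dcm_fit(run, quick_inputs(), full_modulation_spec(),
                 control = dcm_control(max_iter = 16))
  expect_s3_class(fit, "dcm_fit")
  expect_equal(unname(logLik(fit)[1]), fit$free_energy)
  expect_equal(coef(fit), fit$mean)
  expect_equal(dim(vcov(fit)), c(25, 25))
  expect_equal(fitted(fit) + residuals(fit), run$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(predict(fit), fitted(fit))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]], sims[[2]]))
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("free energy", out, ignore.case = TRUE)))
})

test_that("inversion is deterministic and the evidence matrix has the right shape", {
  cfg <- cohort_config(block_duration_s = 20, TR = 2, bins_per_tr = 8,
                       n_training_runs = 1)
  coh <- sample_cohort(1, 1, seed = 5, config = cfg)
  models <- list(winning_architecture(), full_modulation_spec())
  lev1 <- log_evidence_matrix(coh, models, control = dcm_control(max_iter = 10))
  lev2 <- log_evidence_matrix(coh, models, control = dcm_control(max_iter = 10))
  expect_equal(dim(lev1$log_ev), c(2, 2))
  expect_true(all(is.finite(lev1$log_ev)))
  expect_identical(lev1$log_ev, lev2$log_ev)
})
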