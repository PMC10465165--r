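test_that("degenerate draws equal the group means and seeds are honoured", {
  cfg <- effect_config()
  cfg0 <- cfg; cfg0$sd[] <- 0
  p <- sample_subject_params("learner", seed = 1, config = cfg0)
  expect_equal(attr(p, "theta"), cfg0$mean$learner)
  p1 <- sample_subject_params("non_learner", seed = 7, config = cfg)
  p2 <- sample_subject_params("non_learner", seed = 7, config = cfg)
  expect_identical(attr(p1, "theta"), attr(p2, "theta"))
  p3 <- sample_subject_params("non_learner", seed = 8, config = cfg)
  expect_false(identical(attr(p1, "theta"), attr(p3, "theta")))
})

test_that("an incomplete effect configuration is rejected", {
  cfg <- effect_config()
  cfg$mean$learner <- cfg$mean$learner[-1]
  expect_error(sample_subject_params("learner", seed = 1, config = cfg),
               "missing entries")
})

test_that("population means are recovered by Monte Carlo without margins", {
  # narrow spreads keep stability/feasibility rejections negligible, so
  # the draws are effectively untruncated Gaussians
  cfg <- effect_config(regulation_margin = NULL, b_fsma_sd = 0.05,
                       b_other_sd = 0.02, a_sd = 0.02, c_sd = 0.02)
  # a weak drive keeps steady states far from the feasibility boundary
  cfg$mean$learner["C[F<-u1]"] <- 0.05
  cfg$mean$non_learner["C[F<-u1]"] <- 0.05
  draw <- function(group, n, seed) {
    .with_seed(seed, vapply(seq_len(n), function(i) {
      attr(sample_subject_params(group, config = cfg), "theta")["B1[SMA<-F]"]
    }, numeric(1)))
  }
  n <- 1000
  for (grp in c("learner", "non_learner")) {
    x <- draw(grp, n, seed = 31)
    mu <- cfg$mean[[grp]]["B1[SMA<-F]"]
    se <- cfg$sd["B1[SMA<-F]"] / sqrt(n)
    expect_lt(abs(mean(x) - mu), 3 * se)
  }
})

test_that("groups are separated in the focal modulation and net regulation", {
  cfg <- effect_config()
  l <- vapply(1:20, function(i)
    attr(sample_subject_params("learner", seed = 100 + i), "theta")["B1[SMA<-F]"],
    numeric(1))
  nl <- vapply(1:20, function(i)
    attr(sample_subject_params("non_learner", seed = 200 + i), "theta")["B1[SMA<-F]"],
    numeric(1))
  expect_gt(mean(l), mean(nl))
  # margin truncation: group-consistent steady-state regulation direction
  net <- function(p) {
    x <- solve(p$A + Reduce(`+`, p$B), -rowSums(p$C)); x[4]
  }
  expect_true(all(vapply(1:10, function(i)
    net(sample_subject_params("learner", seed = 300 + i)) >=
      cfg$regulation_margin["learner"], logical(1))))
  expect_true(all(vapply(1:10, function(i)
    net(sample_subject_params("non_learner", seed = 400 + i)) <=
      cfg$regulation_margin["non_learner"], logical(1))))
})

test_that("simulated runs are signal plus reproducible i.i.d. noise", {
  p <- fx_params()
  d <- quick_design()
  inp <- quick_inputs()
  clean <- integrate_dcm(p, inp, design = d)
  r0 <- simulate_run(p, d, noise_sd = 0, TR = 2, bins_per_tr = 8)
  expect_equal(r0$data, clean$data)
  ra <- simulate_run(p, d, noise_sd = 0.5, seed = 5, TR = 2, bins_per_tr = 8)
  rb <- simulate_run(p, d, noise_sd = 0.5, seed = 5, TR = 2, bins_per_tr = 8)
  rc <- simulate_run(p, d, noise_sd = 0.5, seed = 6, TR = 2, bins_per_tr = 8)
  expect_identical(ra$data, rb$data)
  expect_false(identical(ra$data, rc$data))
  expect_equal(ra$data - clean$data, rb$data - clean$data)
  # large-sample noise SD calibration (many volumes via a long design)
  dl <- make_block_design(200)
  rl <- simulate_run(p, dl, noise_sd = 1, seed = 11, TR = 2, bins_per_tr = 4)
  cl <- integrate_dcm(p, design_to_inputs(dl, TR = 2, bins_per_tr = 4))
  expect_lt(abs(sd(rl$data - cl$data) - 1), 0.02)
  # condition labels follow the design
  expect_equal(sum(ra$condition == "up-regulation") / length(ra$condition),
               3 / 7)
})

test_that("cohorts have the protocol shape and are bit-reproducible", {
  cfg <- cohort_config(n_training_runs = 2)
  coh <- sample_cohort(2, 2, seed = 3, config = cfg)
  expect_length(coh$subjects, 4)
  expect_equal(vapply(coh$subjects, `[[`, "", "group_label"),
               c("learner", "learner", "non_learner", "non_learner"))
  r1 <- coh$runs[["sub-01"]]
  expect_length(r1$training, 2)
  expect_equal(r1$baseline$run_type, "baseline")
  expect_equal(r1$transfer$run_type, "transfer")
  coh2 <- sample_cohort(2, 2, seed = 3, config = cfg)
  expect_identical(coh$runs[["sub-02"]]$training[[1]]$data,
                   coh2$runs[["sub-02"]]$training[[1]]$data)
  expect_identical(vapply(coh$subjects, `[[`, "", "subject_id"),
                   c("sub-01", "sub-02", "sub-03", "sub-04"))
})

test_that("default cohorts give 18 subjects with 8 training runs", {
  cfg <- cohort_config()
  expect_equal(cfg$n_training_runs, 8)
  coh <- sample_cohort(seed = 2)
  expect_length(coh$subjects, 18)
  expect_length(coh$runs[["sub-10"]]$training, 8)
  labs <- vapply(coh$subjects, `[[`, "", "group_label")
  expect_equal(unname(table(labs)["learner"]), 9L)
})
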