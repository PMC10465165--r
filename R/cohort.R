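#' Population effect configuration for the synthetic cohort
#'
#' Ground-truth population means and standard deviations for every free
#' parameter of the generating model. Defaults encode the study conditions
#' the generator emulates: a stable bilateral F-ACC-S architecture driven at
#' F, a negative baseline F->SMA coupling (so that subjects without learned
#' up-regulation show net SMA suppression during regulation attempts), and a
#' learner vs non-learner contrast carried exclusively by the up-regulation
#' modulation of the F->SMA connection: mean 0.4 1/s in learners vs 0.0 in
#' non-learners, SD 0.1.
#'
#' @param spec generating model structure (free-parameter masks).
#' @param b_fsma_mean named vector `c(learner =, non_learner =)` for the
#'   focal F->SMA modulation mean.
#' @param b_fsma_sd SD of the focal modulation.
#' @param b_other_sd SD of all non-focal modulation entries (mean 0).
#' @param a_sd,c_sd SDs of baseline coupling and driving gain.
#' @param regulation_margin named vector `c(learner =, non_learner =)`:
#'   draws are truncated so the steady-state SMA response to a sustained
#'   modulated drive is at least the learner margin (up-regulation) or at
#'   most the non-learner margin (down-regulation). The margin is enforced
#'   by redrawing only the focal F->SMA modulation, so all other population
#'   distributions stay identical across groups. This makes the group
#'   labels generatively meaningful (learners are subjects who actually
#'   up-regulate) with enough separation that a per-subject sign test has
#'   roughly 2.5-sigma power at the default noise level.
#' @return A list with `mean` (named list per group) and `sd` (named vector)
#'   covering every free parameter of `spec`.
#' @export
effect_config <- function(spec = full_modulation_spec(winning_architecture()),
                          b_fsma_mean = c(learner = 0.4, non_learner = 0.0),
                          b_fsma_sd = 0.1, b_other_sd = 0.05,
                          a_sd = 0.05, c_sd = 0.05,
                          regulation_margin = c(learner = 0.2,
                                                non_learner = -0.2)) {
  a_means <- c("A[ACC<-F]" = 0.2, "A[F<-ACC]" = 0.1,
               "A[S<-ACC]" = 0.2, "A[ACC<-S]" = 0.1,
               "A[SMA<-F]" = -0.2, "A[F<-SMA]" = 0.05,
               "A[SMA<-ACC]" = 0.05, "A[ACC<-SMA]" = 0.05,
               "A[SMA<-S]" = 0.05, "A[S<-SMA]" = 0.05)
  nm <- spec_param_names(spec)
  mk_group <- function(group) {
    mu <- setNames(numeric(length(nm)), nm)
    present <- intersect(names(a_means), nm)
    mu[present] <- a_means[present]
    mu[grepl("^C\\[", nm)] <- 0.25
    if ("B1[SMA<-F]" %in% nm) mu["B1[SMA<-F]"] <- unname(b_fsma_mean[group])
    mu
  }
  sds <- setNames(numeric(length(nm)), nm)
  sds[grepl("^A\\[", nm)] <- a_sd
  sds[grepl("^B", nm)] <- b_other_sd
  if ("B1[SMA<-F]" %in% nm) sds["B1[SMA<-F]"] <- b_fsma_sd
  sds[grepl("^C\\[", nm)] <- c_sd
  list(spec = spec,
       mean = list(learner = mk_group("learner"),
                   non_learner = mk_group("non_learner")),
       sd = sds,
       regulation_margin = regulation_margin)
}

# evaluate RNG-consuming code under an optional fixed seed without
# disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# build dcm_params from a named free-parameter vector + spec
params_from_vector <- function(theta, spec, self_inhibition = -0.5,
                               hemo = list()) {
  n <- n_regions()
  A <- matrix(0, n, n); diag(A) <- self_inhibition
  nm <- names(theta)
  ia <- which(spec$a_mask, arr.ind = TRUE)
  lab <- region_labels()
  for (k in seq_len(nrow(ia))) {
    A[ia[k, 1], ia[k, 2]] <- theta[[paste0("A[", lab[ia[k, 1]], "<-", lab[ia[k, 2]], "]")]]
  }
  Bl <- lapply(seq_along(spec$b_mask), function(j) {
    m <- matrix(0, n, n)
    ib <- which(spec$b_mask[[j]], arr.ind = TRUE)
    for (k in seq_len(nrow(ib))) {
      m[ib[k, 1], ib[k, 2]] <- theta[[paste0("B", j, "[", lab[ib[k, 1]], "<-", lab[ib[k, 2]], "]")]]
    }
    m
  })
  C <- matrix(0, n, ncol(spec$c_mask))
  ic <- which(spec$c_mask, arr.ind = TRUE)
  for (k in seq_len(nrow(ic))) {
    C[ic[k, 1], ic[k, 2]] <- theta[[paste0("C[", lab[ic[k, 1]], "<-u", ic[k, 2], "]")]]
  }
  dcm_params(A = A, B = Bl, C = C, hemo = hemo)
}

#' Draw ground-truth parameters for one synthetic subject
#'
#' Each free parameter is drawn from its configured population Gaussian,
#' truncated to the stability region: all eigenvalues of A and of A + sum B
#' must have negative real part, and the steady-state neural activity under
#' a sustained unit drive must keep the hemodynamic inflow positive
#' (steady-state f = 1 + x/gamma > 0.3 per region, so sustained suppression
#' cannot collapse the balloon model), and the net steady-state SMA
#' regulation direction must match the group label with the configured
#' margin (see [effect_config()]). Draws violating a constraint are
#' rejected and repeated. With all SDs zero the draw equals the group means
#' exactly (margins are then ignored if they conflict).
#'
#' @param group_label `"learner"` or `"non_learner"`.
#' @param seed optional integer for a reproducible draw.
#' @param config an [effect_config()].
#' @return A [dcm_params()] object with attribute `"theta"` (the named
#'   free-parameter vector) and `"group_label"`.
#' @export
sample_subject_params <- function(group_label = c("learner", "non_learner"),
                                  seed = NULL, config = effect_config()) {
  group_label <- match.arg(group_label)
  spec <- config$spec
  nm <- spec_param_names(spec)
  missing <- setdiff(nm, names(config$mean[[group_label]]))
  if (length(missing)) {
    stop("effect_config is missing entries for free parameters: ",
         paste(missing, collapse = ", "))
  }
  mu <- config$mean[[group_label]][nm]
  sd <- config$sd[nm]
  focal <- "B1[SMA<-F]"
  .with_seed(seed, {
    for (try in 1:200) {
      theta <- stats::rnorm(length(nm), mu, sd)
      names(theta) <- nm
      # enforce the group's regulation margin through the focal learning
      # parameter alone, so non-focal population distributions stay
      # identical across groups
      if (!is.null(config$regulation_margin) && focal %in% nm &&
          any(sd > 0)) {
        marg <- config$regulation_margin[[group_label]]
        for (retry in 1:100) {
          p0 <- params_from_vector(theta, spec)
          x <- try(solve(p0$A + Reduce(`+`, p0$B), -rowSums(p0$C)),
                   silent = TRUE)
          okm <- !inherits(x, "try-error") &&
            (if (group_label == "learner") x[.ridx("SMA")] >= marg
             else x[.ridx("SMA")] <= marg)
          if (okm) break
          theta[focal] <- stats::rnorm(1, mu[focal], sd[focal])
        }
      }
      p <- params_from_vector(theta, spec)
      Bsum <- Reduce(`+`, p$B)
      stable <- max(Re(eigen(p$A, only.values = TRUE)$values)) < 0 &&
        max(Re(eigen(p$A + Bsum, only.values = TRUE)$values)) < 0
      if (stable) {
        # hemodynamic feasibility: steady-state inflow must stay positive
        # under sustained drive, with and without modulation
        drv <- rowSums(p$C)
        xA <- solve(p$A, -drv); xAB <- solve(p$A + Bsum, -drv)
        fmin <- 1 + min(c(xA, xAB)) / min(p$hemo$gamma)
        stable <- fmin > 0.3
        # group-consistent regulation direction with margin
        if (stable && !is.null(config$regulation_margin) && any(sd > 0) &&
            focal %in% nm) {
          marg <- config$regulation_margin[[group_label]]
          x_sma <- xAB[.ridx("SMA")]
          stable <- if (group_label == "learner") x_sma >= marg else x_sma <= marg
        }
      }
      if (stable) {
        attr(p, "theta") <- theta
        attr(p, "group_label") <- group_label
        return(p)
      }
    }
    stop("could not draw stable parameters in 200 attempts; check effect_config")
  })
}

#' Simulate one run of ROI BOLD data
#'
#' Noise-free forward integration of the subject's ground-truth model for the
#' given block design, plus i.i.d. Gaussian observation noise per region and
#' volume and an optional low-order cosine drift.
#'
#' @param params subject [dcm_params()].
#' @param design a [make_block_design()].
#' @param noise_sd observation noise SD (percent signal change units).
#' @param drift_config optional `list(order =, amplitude =)` discrete-cosine
#'   drift added to every region.
#' @param seed optional integer for reproducible noise.
#' @param TR,bins_per_tr sampling grid.
#' @param transfer_drive_scale gain of the volitional engagement input in
#'   transfer runs (the feedback input itself is absent there).
#' @param run_id annotation.
#' @return A `roi_ts`.
#' @export
simulate_run <- function(params, design, noise_sd = 0, drift_config = NULL,
                         seed = NULL, TR = 1.5, bins_per_tr = 16,
                         transfer_drive_scale = 1, run_id = "run-01") {
  stopifnot(noise_sd >= 0)
  inputs <- design_to_inputs(design, TR = TR, bins_per_tr = bins_per_tr,
                             drive_scale = transfer_drive_scale)
  clean <- integrate_dcm(params, inputs, run_id = run_id,
                         run_type = design$run_type, design = design)
  y <- clean$data
  if (!is.null(drift_config)) {
    t01 <- (seq_len(nrow(y)) - 0.5) / nrow(y)
    for (k in seq_len(drift_config$order)) {
      y <- y + drift_config$amplitude * cos(pi * k * t01) / k
    }
  }
  if (noise_sd > 0) {
    y <- y + .with_seed(seed, matrix(stats::rnorm(length(y), 0, noise_sd),
                                     nrow(y), ncol(y)))
  }
  out <- roi_ts(y, TR = TR, run_id = run_id, run_type = design$run_type,
                condition = clean$condition)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Cohort-level simulation settings
#'
#' @param block_duration_s block length (s).
#' @param TR repetition time (s).
#' @param bins_per_tr microtime resolution.
#' @param n_training_runs training runs per subject (two sessions of four).
#' @param snr peak-signal-to-noise ratio defining the observation noise SD
#'   (noise SD = peak absolute noise-free signal / snr).
#' @param transfer_drive_scale see [simulate_run()].
#' @param effects an [effect_config()].
#' @param drift_config optional cosine drift, see [simulate_run()].
#' @return list of settings for [sample_cohort()].
#' @export
cohort_config <- function(block_duration_s = 30, TR = 1.5, bins_per_tr = 16,
                          n_training_runs = 8, snr = 1,
                          transfer_drive_scale = 1,
                          effects = effect_config(),
                          drift_config = NULL) {
  list(block_duration_s = block_duration_s, TR = TR, bins_per_tr = bins_per_tr,
       n_training_runs = n_training_runs, snr = snr,
       transfer_drive_scale = transfer_drive_scale, effects = effects,
       drift_config = drift_config)
}

#' Generate a complete synthetic neurofeedback cohort
#'
#' Emulates the training protocol: per subject, `n_training_runs` training
#' runs (each 4 baseline / 3 up-regulation blocks), one rest
#' baseline-reference run and one transfer run (regulation attempt without
#' feedback), with ground-truth parameters retained for recovery tests.
#' Defaults give 9 learners and 9 non-learners (18 subjects) with 8 training
#' runs each.
#'
#' @param n_learners,n_non_learners group sizes (>= 1).
#' @param seed integer master seed; identical (seed, config) gives a
#'   bit-identical cohort.
#' @param config a [cohort_config()].
#' @return An object of class `nf_cohort`: list with `subjects` (profiles:
#'   id, group label, training-group annotation, true parameter vector),
#'   `runs` (per subject: `training` list, `baseline`, `transfer`), `seed`,
#'   `config`.
#' @export
sample_cohort <- function(n_learners = 9, n_non_learners = 9, seed = 1,
                          config = cohort_config()) {
  stopifnot(n_learners >= 1, n_non_learners >= 1)
  labels <- c(rep("learner", n_learners), rep("non_learner", n_non_learners))
  tg <- rep_len(c("F", "F+I", "F+R", "F+I+R"), length(labels))
  designs <- list(
    training = make_block_design(config$block_duration_s, "training"),
    baseline = make_block_design(config$block_duration_s, "baseline"),
    transfer = make_block_design(config$block_duration_s, "transfer")
  )
  subjects <- list(); runs <- list()
  .with_seed(seed, {
    for (i in seq_along(labels)) {
      id <- sprintf("sub-%02d", i)
      p <- sample_subject_params(labels[i], seed = NULL, config = config$effects)
      # noise level anchored at this subject's peak training-run signal
      inp <- design_to_inputs(designs$training, TR = config$TR,
                              bins_per_tr = config$bins_per_tr)
      clean <- integrate_dcm(p, inp, design = designs$training)
      noise_sd <- max(abs(clean$data)) / config$snr
      tr_runs <- lapply(seq_len(config$n_training_runs), function(r) {
        simulate_run(p, designs$training, noise_sd = noise_sd,
                     drift_config = config$drift_config, TR = config$TR,
                     bins_per_tr = config$bins_per_tr,
                     run_id = sprintf("%s_task-train_run-%02d", id, r))
      })
      base_run <- simulate_run(p, designs$baseline, noise_sd = noise_sd,
                               drift_config = config$drift_config,
                               TR = config$TR, bins_per_tr = config$bins_per_tr,
                               run_id = paste0(id, "_task-baseline"))
      trans_run <- simulate_run(p, designs$transfer, noise_sd = noise_sd,
                                drift_config = config$drift_config,
                                TR = config$TR, bins_per_tr = config$bins_per_tr,
                                transfer_drive_scale = config$transfer_drive_scale,
                                run_id = paste0(id, "_task-transfer"))
      subjects[[i]] <- list(subject_id = id, group_label = labels[i],
                            training_group = tg[i],
                            true_params = attr(p, "theta"),
                            noise_sd = noise_sd)
      runs[[id]] <- list(training = tr_runs, baseline = base_run,
                         transfer = trans_run)
    }
  })
  structure(list(subjects = subjects, runs = runs, seed = seed, config = config,
                 designs = designs),
            class = "nf_cohort")
}

#' @export
print.nf_cohort <- function(x, ...) {
  lab <- vapply(x$subjects, `[[`, "", "group_label")
  cat(sprintf("Synthetic neurofeedback cohort: %d subjects (%d learners / %d non-learners)\n",
              length(lab), sum(lab == "learner"), sum(lab == "non_learner")))
  cat(sprintf("  %d training runs + baseline + transfer per subject, TR = %g s, seed = %d\n",
              x$config$n_training_runs, x$config$TR, x$seed))
  invisible(x)
}
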