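#' Pipeline configuration
#'
#' Resolved settings for [run_all()]. Defaults reproduce the study
#' conditions (18 subjects, 8 training runs, the full 14- and 13-model
#' spaces); tests and examples pass smaller cohorts and reduced spaces.
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param n_learners,n_non_learners cohort sizes.
#' @param cohort a [cohort_config()].
#' @param runs_for_inversion training runs concatenated per subject
#'   (default: all).
#' @param control a [dcm_control()].
#' @param alpha0 Dirichlet prior concentration for BMS.
#' @param n_samples Monte Carlo samples for exceedance probabilities.
#' @param group_alpha familywise level of the group comparison.
#' @param ranking_rule `"sign"` or `"median"`.
#' @param step1_subset,step2_subset optional model indices to reduce the
#'   candidate spaces.
#' @export
nf_config <- function(seed = 1, n_learners = 9, n_non_learners = 9,
                      cohort = cohort_config(), runs_for_inversion = NULL,
                      control = dcm_control(), alpha0 = 1, n_samples = 1e6,
                      group_alpha = 0.05, ranking_rule = "sign",
                      step1_subset = NULL, step2_subset = NULL) {
  list(seed = seed, n_learners = n_learners, n_non_learners = n_non_learners,
       cohort = cohort, runs_for_inversion = runs_for_inversion,
       control = control, alpha0 = alpha0, n_samples = n_samples,
       group_alpha = group_alpha, ranking_rule = ranking_rule,
       step1_subset = step1_subset, step2_subset = step2_subset)
}

.subset_space <- function(space, idx) {
  if (is.null(idx)) return(space)
  fam_of <- .family_of(space$partition)[idx]
  fams <- split(seq_along(idx), fam_of)
  fams <- fams[unique(fam_of)]
  list(models = space$models[idx],
       partition = family_partition(fams, space$partition$level, length(idx)))
}

#' Run the full two-step analysis end to end
#'
#' Simulate a cohort, invert the step-one candidate models on the
#' concatenated training runs, select the winning architecture family,
#' invert the step-two modulation space, run family-level BMS at both steps,
#' model-average the fully modulated model's parameters per subject, compare
#' learners and non-learners, and rank learning by signed Wasserstein
#' distance. When `out_dir` is given, every stage writes its artifacts
#' (TSV/JSON) together with the resolved configuration and a manifest of
#' content hashes.
#'
#' @param config an [nf_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return list with `cohort`, `step1` (log_ev, model bms, family bms),
#'   `step2`, `bma` (subjects x parameters matrix), `groups`, `ranking` and
#'   `manifest`.
#' @export
run_all <- function(config = nf_config(), out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   stages = list())
  stamp <- function(stage, files = character(0)) {
    manifest$stages[[stage]] <<- list(
      time = format(Sys.time()),
      hashes = if (length(files)) as.list(tools::md5sum(files)) else list()
    )
  }

  say("stage 1/7: simulating cohort (%d + %d subjects)",
      config$n_learners, config$n_non_learners)
  cohort <- sample_cohort(config$n_learners, config$n_non_learners,
                          seed = config$seed, config = config$cohort)
  stamp("simulate")

  say("stage 2/7: step-one model space + inversion")
  s1 <- .subset_space(build_first_step_space(), config$step1_subset)
  lev1 <- log_evidence_matrix(cohort, s1$models,
                              n_runs = config$runs_for_inversion,
                              control = config$control)
  bms1_model <- bms(lev1$log_ev, alpha0 = config$alpha0,
                    n_samples = config$n_samples, seed = config$seed + 101)
  bms1_family <- family_inference(lev1$log_ev, s1$partition,
                                  alpha0 = config$alpha0,
                                  n_samples = config$n_samples,
                                  seed = config$seed + 102)
  stamp("step1")

  say("stage 3/7: winning architecture")
  win_family <- names(s1$partition$families)[which.max(bms1_family$pxp)]
  base <- winning_architecture()
  stamp("winner")

  say("stage 4/7: step-two modulation space + inversion")
  s2 <- .subset_space(build_second_step_space(base), config$step2_subset)
  lev2 <- log_evidence_matrix(cohort, s2$models,
                              n_runs = config$runs_for_inversion,
                              control = config$control)
  bms2_model <- bms(lev2$log_ev, alpha0 = config$alpha0,
                    n_samples = config$n_samples, seed = config$seed + 201)
  bms2_family <- family_inference(lev2$log_ev, s2$partition,
                                  alpha0 = config$alpha0,
                                  n_samples = config$n_samples,
                                  seed = config$seed + 202)
  stamp("step2")

  say("stage 5/7: Bayesian model averaging (full-modulation summary model)")
  full_spec <- full_modulation_spec(base)
  ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  n_runs <- config$runs_for_inversion %||% cohort$config$n_training_runs
  inp <- design_to_inputs(cohort$designs$training, TR = cohort$config$TR,
                          bins_per_tr = cohort$config$bins_per_tr)
  full_fits <- lapply(ids, function(id) {
    dcm_fit(cohort$runs[[id]]$training[seq_len(n_runs)],
            rep(list(inp), n_runs), full_spec, control = config$control)
  })
  bma_rows <- lapply(seq_along(ids), function(i) {
    fits_i <- c(lev2$fits[[i]], list(full_fits[[i]]))
    bma(fits_i)$mean
  })
  all_nm <- unique(unlist(lapply(bma_rows, names)))
  bma_mat <- t(vapply(bma_rows, function(r) {
    v <- setNames(numeric(length(all_nm)), all_nm); v[names(r)] <- r; v
  }, numeric(length(all_nm))))
  rownames(bma_mat) <- ids
  stamp("bma")

  say("stage 6/7: learner vs non-learner group comparison")
  labels <- vapply(cohort$subjects, `[[`, "", "group_label")
  groups <- compare_groups(bma_mat, labels, alpha = config$group_alpha)
  stamp("group")

  say("stage 7/7: Wasserstein learning ranking")
  ranking <- rank_cohort(cohort, rule = config$ranking_rule)
  stamp("rank")

  out <- list(cohort = cohort,
              step1 = list(space = s1, log_ev = lev1$log_ev,
                           bms_model = bms1_model, bms_family = bms1_family,
                           winning_family = win_family),
              step2 = list(space = s2, log_ev = lev2$log_ev,
                           bms_model = bms2_model, bms_family = bms2_family),
              bma = bma_mat, groups = groups, ranking = ranking,
              config = config, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    f <- file.path(out_dir, "step1_log_evidence.tsv")
    write_logev(lev1$log_ev, f); files <- c(files, f)
    f <- file.path(out_dir, "step2_log_evidence.tsv")
    write_logev(lev2$log_ev, f); files <- c(files, f)
    f <- file.path(out_dir, "step1_space.json")
    write_model_space(s1, f); files <- c(files, f)
    f <- file.path(out_dir, "step2_space.json")
    write_model_space(s2, f); files <- c(files, f)
    f <- file.path(out_dir, "ranking.tsv")
    utils::write.table(as.data.frame(ranking), f, sep = "\t", quote = FALSE,
                       row.names = FALSE); files <- c(files, f)
    f <- file.path(out_dir, "group_comparison.tsv")
    utils::write.table(as.data.frame(groups), f, sep = "\t", quote = FALSE,
                       row.names = FALSE); files <- c(files, f)
    jsonlite::write_json(list(
      step1 = list(family = as.list(setNames(bms1_family$pxp,
                                             names(s1$partition$families))),
                   bor = bms1_family$bor),
      step2 = list(family = as.list(setNames(bms2_family$pxp,
                                             names(s2$partition$families))),
                   bor = bms2_family$bor)
    ), file.path(out_dir, "bms_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "bms_summary.json"))
    cfg <- config; cfg$cohort$effects$spec <- cfg$cohort$effects$spec$name
    cfg$step1_subset <- cfg$step1_subset %||% "all"
    cfg$step2_subset <- cfg$step2_subset %||% "all"
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    out$manifest$stages[["write"]] <- list(
      time = format(Sys.time()), hashes = as.list(tools::md5sum(files)))
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
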