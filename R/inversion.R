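#' Concatenate runs for subject-level inversion
#'
#' Stacks runs volume-wise (all runs must share TR and region order) and
#' builds one intercept confound regressor per run so that model evidence is
#' not driven by between-run offsets. Run boundaries are retained: the
#' forward model integrates each run separately from rest.
#'
#' @param runs a `roi_ts` or list of `roi_ts`.
#' @param drift_order number of discrete-cosine drift confounds per run
#'   (0 = intercept only).
#' @return An object of class `concat_ts`: `data` (total volumes x regions),
#'   `confounds` (total volumes x k matrix), `run_lengths`, `run_id` per
#'   volume, `TR`, `condition`.
#' @export
concatenate_runs <- function(runs, drift_order = 0) {
  if (inherits(runs, "roi_ts")) runs <- list(runs)
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "roi_ts")))
  TRs <- vapply(runs, `[[`, 0, "TR")
  if (any(abs(TRs - TRs[1]) > 1e-9)) stop("runs have mismatching TR")
  for (r in runs) {
    if (!identical(colnames(r$data), region_labels())) stop("runs have mismatching region order")
  }
  lens <- vapply(runs, function(r) nrow(r$data), 0L)
  total <- sum(lens)
  X <- matrix(0, total, 0)
  off <- 0L
  for (i in seq_along(runs)) {
    xi <- matrix(0, total, 1 + drift_order)
    idx <- off + seq_len(lens[i])
    xi[idx, 1] <- 1
    if (drift_order > 0) {
      t01 <- (seq_len(lens[i]) - 0.5) / lens[i]
      for (k in seq_len(drift_order)) xi[idx, 1 + k] <- cos(pi * k * t01)
    }
    X <- cbind(X, xi)
    off <- off + lens[i]
  }
  structure(list(
    data = do.call(rbind, lapply(runs, `[[`, "data")),
    confounds = X,
    run_lengths = lens,
    run_id = rep(vapply(runs, `[[`, "", "run_id"), lens),
    condition = unlist(lapply(runs, `[[`, "condition")),
    TR = TRs[1]
  ), class = "concat_ts")
}

#' Shrinkage priors for a model structure
#'
#' Zero-mean Gaussian shrinkage priors on every free coupling parameter
#' (variance 0.0625 for A and B entries, 0.25 for driving gains), tight
#' zero-mean Gaussians on per-region log transit-time deviations (variance
#' 0.0025, i.e. the hemodynamics are nearly fixed), and a Gaussian prior on
#' the observation-noise log precision (mean 0, variance 2). Fixed
#' self-connections are not part of the free-parameter vector.
#'
#' @param spec a [model_spec()].
#' @param a_var,b_var,c_var,transit_var,lambda_mean,lambda_var overridable
#'   prior moments.
#' @param hemo_deviations include per-region log transit-time deviations as
#'   free parameters.
#' @return An object of class `prior_spec` with named `mean` and `var`
#'   vectors plus the noise-precision prior.
#' @export
default_priors <- function(spec, a_var = 0.0625, b_var = 0.0625, c_var = 0.25,
                           transit_var = 0.0025, lambda_mean = 0,
                           lambda_var = 2, hemo_deviations = TRUE) {
  nm <- spec_param_names(spec)
  v <- setNames(numeric(length(nm)), nm)
  v[grepl("^A\\[", nm)] <- a_var
  v[grepl("^B", nm)] <- b_var
  v[grepl("^C\\[", nm)] <- c_var
  if (hemo_deviations) {
    hn <- paste0("transit[", region_labels(), "]")
    v <- c(v, setNames(rep(transit_var, n_regions()), hn))
  }
  structure(list(mean = setNames(rep(0, length(v)), names(v)), var = v,
                 lambda_mean = lambda_mean, lambda_var = lambda_var,
                 spec_name = spec$name),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Priors for %s: %d free parameters + noise log precision\n",
              x$spec_name, length(x$mean)))
  invisible(x)
}

#' Inversion control settings
#'
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence tolerance on the free-energy increment (nats);
#'   convergence is declared after 3 consecutive increments below it.
#' @param fd_step finite-difference step for the prediction Jacobian.
#' @param max_halvings step halvings tried before a Gauss-Newton proposal is
#'   rejected and damping increased.
#' @param lambda_fixed optional fixed noise log precision (skips noise
#'   estimation; used for conjugate checks).
#' @param drift_order cosine drift confounds per run.
#' @param verbose print per-iteration free energy.
#' @export
dcm_control <- function(max_iter = 128, tol = 0.01, fd_step = 1e-3,
                        max_halvings = 6, lambda_fixed = NULL,
                        drift_order = 0, verbose = FALSE) {
  list(max_iter = max_iter, tol = tol, fd_step = fd_step,
       max_halvings = max_halvings, lambda_fixed = lambda_fixed,
       drift_order = drift_order, verbose = verbose)
}

# ---------------------------------------------------------------------------
# Variational Laplace engine
# ---------------------------------------------------------------------------

#' Variational Laplace inversion of a nonlinear observation model
#'
#' Fits `y = g(theta) + confounds + noise` with a Gaussian prior on `theta`
#' and i.i.d. Gaussian noise of precision `exp(lambda)`, by Gauss-Newton
#' ascent on the variational free energy of a fixed-form Gaussian posterior
#' (Levenberg-Marquardt damping, step halving on any free-energy decrease,
#' confounds projected out of data and predictions). The free energy is an
#' evidence lower bound; on linear-Gaussian problems with fixed `lambda` it
#' equals the analytic log evidence at convergence.
#'
#' @param y data: numeric vector or T x R matrix.
#' @param g prediction function mapping a named parameter vector to the shape
#'   of `y`.
#' @param prior_mean,prior_var named prior moments (diagonal prior).
#' @param confounds optional T x k confound matrix (projected out per
#'   column of `y`).
#' @param lambda_prior `c(mean, var)` prior for the noise log precision.
#' @param control a [dcm_control()].
#' @return list with `mean`, `cov`, `free_energy`, `fe_trace`, `converged`,
#'   `lambda`, `lambda_var`, `fitted`, `residuals`, `iterations`, `n_eff`.
#' @export
vl_invert <- function(y, g, prior_mean, prior_var, confounds = NULL,
                      lambda_prior = c(0, 2), control = dcm_control()) {
  y <- as.matrix(y)
  Tn <- nrow(y); Rn <- ncol(y)
  p <- length(prior_mean)
  stopifnot(length(prior_var) == p, all(prior_var > 0))
  qrX <- NULL; rankX <- 0L
  if (!is.null(confounds) && ncol(confounds) > 0) {
    qrX <- qr(confounds)
    rankX <- qrX$rank
  }
  proj <- function(M) if (is.null(qrX)) M else qr.resid(qrX, M)
  n_eff <- (Tn - rankX) * Rn
  y_p <- proj(y)

  Pi <- diag(1 / prior_var, p)
  mu <- prior_mean
  lam_fixed <- !is.null(control$lambda_fixed)
  lam <- if (lam_fixed) control$lambda_fixed else lambda_prior[1]
  pi_l <- 1 / lambda_prior[2]

  eval_g <- function(m) {
    out <- try(g(m), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    out <- as.matrix(out)
    if (any(!is.finite(out))) return(NULL)
    out
  }

  jacobian <- function(m, G0) {
    J <- matrix(0, Tn * Rn, p)
    h <- control$fd_step
    for (i in seq_len(p)) {
      mi <- m; mi[i] <- mi[i] + h
      Gi <- eval_g(mi)
      if (is.null(Gi)) { # try backward difference at hard boundaries
        mi[i] <- m[i] - h
        Gi <- eval_g(mi)
        if (is.null(Gi)) stop(sprintf("forward model failed while differentiating parameter %d", i))
        J[, i] <- as.numeric(G0 - Gi) / h
      } else {
        J[, i] <- as.numeric(Gi - G0) / h
      }
    }
    # project confounds out of each Jacobian column (columns are T*R stacks)
    if (!is.null(qrX)) {
      J <- apply(J, 2, function(col) as.numeric(proj(matrix(col, Tn, Rn))))
      J <- matrix(J, Tn * Rn, p)
    }
    J
  }

  logdet_chol <- function(M) 2 * sum(log(diag(chol(M))))

  # free energy for residual e (projected), given Sinv (= exp(lam) J'J + Pi)
  fe <- function(e2, dm, lam, Sinv, W = NULL) {
    f <- -0.5 * exp(lam) * e2 + 0.5 * n_eff * lam - 0.5 * n_eff * log(2 * pi) -
      0.5 * sum(dm * (Pi %*% dm)) + 0.5 * (-logdet_chol(Sinv) + sum(log(1 / prior_var)))
    if (!lam_fixed) {
      Sl <- 1 / (0.5 * exp(lam) * (if (is.null(W)) e2 else W) + pi_l)
      f <- f - 0.5 * pi_l * (lam - lambda_prior[1])^2 + 0.5 * log(Sl * pi_l)
    }
    f
  }

  m <- mu
  G <- eval_g(m)
  if (is.null(G)) stop("forward model failed at the prior mean")
  damping <- 1
  fe_trace <- numeric(0)
  converged <- FALSE
  n_small <- 0L
  it_done <- 0L
  J <- NULL

  for (it in seq_len(control$max_iter)) {
    it_done <- it
    E <- y_p - proj(G)
    J <- jacobian(m, G)
    H <- crossprod(J)
    e_vec <- as.numeric(E)
    e2 <- sum(e_vec^2)

    if (!lam_fixed) {
      # Newton updates of the noise log precision
      for (k in 1:5) {
        Sinv_l <- exp(lam) * H + Pi
        S_l <- chol2inv(chol(Sinv_l))
        W <- e2 + sum(H * S_l)
        g1 <- -0.5 * exp(lam) * W + 0.5 * n_eff - pi_l * (lam - lambda_prior[1])
        g2 <- -0.5 * exp(lam) * W - pi_l
        step <- g1 / g2
        lam <- lam - sign(step) * min(abs(step), 4)
      }
    }
    Sinv <- exp(lam) * H + Pi
    W <- e2 + sum(H * chol2inv(chol(Sinv)))
    F_here <- fe(e2, m - mu, lam, Sinv, W)
    if (length(fe_trace) == 0) fe_trace <- F_here
    F_ref <- max(F_here, fe_trace[length(fe_trace)])

    grad <- exp(lam) * crossprod(J, e_vec) - Pi %*% (m - mu)
    accepted <- FALSE
    for (attempt in 0:2) {
      Sd <- Sinv + damping * diag(diag(Sinv), p)
      full_step <- as.numeric(solve(Sd, grad))
      scl <- 1
      for (h in 0:control$max_halvings) {
        m_new <- m + scl * full_step
        G_new <- eval_g(m_new)
        if (!is.null(G_new)) {
          E_new <- y_p - proj(G_new)
          e2_new <- sum(E_new^2)
          W_new <- e2_new + sum(H * chol2inv(chol(Sinv)))
          F_new <- fe(e2_new, m_new - mu, lam, Sinv, W_new)
          if (is.finite(F_new) && F_new >= F_ref) {
            m <- m_new; G <- G_new
            fe_trace <- c(fe_trace, F_new)
            accepted <- TRUE
            damping <- max(damping / 2, 1e-8)
            break
          }
        }
        scl <- scl / 2
      }
      if (accepted) break
      damping <- damping * 8
    }
    if (control$verbose) {
      message(sprintf("it %3d  F = %.4f  %s", it, fe_trace[length(fe_trace)],
                      if (accepted) "" else "(no step accepted)"))
    }
    if (!accepted) {
      # no ascent direction improves F: treat as converged at current m
      converged <- n_small >= 0
      break
    }
    dF <- fe_trace[length(fe_trace)] - F_ref
    n_small <- if (dF < control$tol) n_small + 1L else 0L
    if (n_small >= 3L) { converged <- TRUE; break }
  }

  # final posterior at m
  E <- y_p - proj(G)
  J <- jacobian(m, G)
  H <- crossprod(J)
  e2 <- sum(as.numeric(E)^2)
  Sinv <- exp(lam) * H + Pi
  S <- chol2inv(chol(Sinv))
  W <- e2 + sum(H * S)
  F_fin <- fe(e2, m - mu, lam, Sinv, W)
  fe_trace <- c(fe_trace, max(F_fin, fe_trace[length(fe_trace)]))
  lam_var <- if (lam_fixed) 0 else 1 / (0.5 * exp(lam) * W + pi_l)

  names(m) <- names(prior_mean)
  dimnames(S) <- list(names(m), names(m))
  list(mean = m, cov = S, free_energy = fe_trace[length(fe_trace)],
       fe_trace = fe_trace, converged = converged, lambda = lam,
       lambda_var = lam_var, fitted = G, residuals = y - G,
       iterations = it_done, n_eff = n_eff)
}

# ---------------------------------------------------------------------------
# DCM fitting
# ---------------------------------------------------------------------------

# forward prediction over (possibly several) runs for a free-parameter
# vector; runs with identical inputs share one integration
.dcm_predict <- function(theta, spec, inputs_list, self_inhibition = -0.5) {
  hn <- paste0("transit[", region_labels(), "]")
  hemo <- list()
  if (all(hn %in% names(theta))) {
    hemo$tau <- default_hemo()$tau * exp(unname(theta[hn]))
  }
  pars <- params_from_vector(theta, spec, self_inhibition = self_inhibition,
                             hemo = hemo)
  if (length(inputs_list) > 1 &&
      all(vapply(inputs_list[-1], identical, TRUE, inputs_list[[1]]))) {
    one <- suppressWarnings(integrate_dcm(pars, inputs_list[[1]])$data)
    return(one[rep(seq_len(nrow(one)), length(inputs_list)), , drop = FALSE])
  }
  preds <- lapply(inputs_list, function(inp) {
    suppressWarnings(integrate_dcm(pars, inp)$data)
  })
  do.call(rbind, preds)
}

#' Fit a dynamic causal model to ROI time series
#'
#' The central model-fitting function: variational-Laplace estimation of the
#' free coupling parameters (and per-region transit-time deviations) of one
#' candidate network structure from one subject's runs, returning the
#' Gaussian posterior and the variational free energy, an evidence lower
#' bound used for model comparison. Runs are concatenated with per-run
#' intercept confounds; the forward model integrates each run from rest.
#' Estimation is deterministic: initialization at the prior mean, no random
#' restarts.
#'
#' @param runs a `roi_ts` or list of `roi_ts` (a subject's training runs).
#' @param inputs an [input_set()] or list matching `runs`.
#' @param spec the candidate [model_spec()].
#' @param priors a [default_priors()] object.
#' @param control a [dcm_control()].
#' @param self_inhibition fixed diagonal of A (1/s).
#' @return An object of class `dcm_fit`.
#' @examples
#' \donttest{
#' p <- sample_subject_params("learner", seed = 1)
#' d <- make_block_design(20)
#' run <- simulate_run(p, d, noise_sd = 0.1, seed = 2, TR = 2)
#' fit <- dcm_fit(run, design_to_inputs(d, TR = 2),
#'                full_modulation_spec(), control = dcm_control(max_iter = 8))
#' coef(fit)[1:3]
#' }
#' @export
dcm_fit <- function(runs, inputs, spec, priors = default_priors(spec),
                    control = dcm_control(), self_inhibition = -0.5) {
  if (inherits(runs, "roi_ts")) runs <- list(runs)
  if (inherits(inputs, "input_set")) inputs <- list(inputs)
  stopifnot(length(runs) == length(inputs))
  cc <- concatenate_runs(runs, drift_order = control$drift_order)
  if (any(!is.finite(cc$data))) stop("data must be finite")
  gfun <- function(theta) .dcm_predict(theta, spec, inputs, self_inhibition)
  res <- vl_invert(cc$data, gfun, priors$mean, priors$var,
                   confounds = cc$confounds,
                   lambda_prior = c(priors$lambda_mean, priors$lambda_var),
                   control = control)
  structure(
    c(res, list(spec = spec, priors = priors, control = control,
                inputs = inputs, data = cc, self_inhibition = self_inhibition)),
    class = "dcm_fit"
  )
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("Dynamic causal model fit:", x$spec$name, "\n")
  cat(sprintf("  %d free parameters, %d volumes, free energy = %.2f nats (%s, %d iterations)\n",
              length(x$mean), nrow(x$data$data), x$free_energy,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' @export
summary.dcm_fit <- function(object, ...) {
  sd <- sqrt(diag(object$cov))
  tab <- data.frame(estimate = object$mean, sd = sd,
                    z = object$mean / pmax(sd, .Machine$double.eps))
  out <- list(table = tab, free_energy = object$free_energy,
              lambda = object$lambda, converged = object$converged,
              name = object$spec$name)
  class(out) <- "summary.dcm_fit"
  out
}

#' @export
print.summary.dcm_fit <- function(x, ...) {
  cat("Model:", x$name, "\n")
  cat(sprintf("Free energy (ELBO): %.2f nats | noise log precision: %.2f | converged: %s\n",
              x$free_energy, x$lambda, x$converged))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.dcm_fit <- function(object, ...) object$mean

#' @export
vcov.dcm_fit <- function(object, ...) object$cov

#' @export
logLik.dcm_fit <- function(object, ...) {
  structure(object$free_energy, df = length(object$mean), class = "logLik")
}

#' @export
fitted.dcm_fit <- function(object, ...) object$fitted

#' @export
residuals.dcm_fit <- function(object, ...) object$residuals

#' Predict BOLD responses from a fitted DCM
#'
#' @param object a `dcm_fit`.
#' @param inputs optional [input_set()] (or list of them) for new
#'   experimental inputs; defaults to the fitted ones.
#' @param ... unused.
#' @return volumes x regions matrix of noise-free predicted BOLD.
#' @export
predict.dcm_fit <- function(object, inputs = NULL, ...) {
  if (is.null(inputs)) inputs <- object$inputs
  if (inherits(inputs, "input_set")) inputs <- list(inputs)
  .dcm_predict(object$mean, object$spec, inputs, object$self_inhibition)
}

#' @export
simulate.dcm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  sdn <- exp(-object$lambda / 2)
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    mu + matrix(stats::rnorm(length(mu), 0, sdn), nrow(mu), ncol(mu))
  }))
}

#' @export
plot.dcm_fit <- function(x, regions = region_labels(), ...) {
  op <- graphics::par(mfrow = c(length(regions), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  t <- seq_len(nrow(x$data$data)) * x$data$TR
  for (r in regions) {
    graphics::plot(t, x$data$data[, r], type = "l", col = "grey50",
                   xlab = "time (s)", ylab = r, ...)
    graphics::lines(t, x$fitted[, r], col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Log-evidence matrix over a model space
#'
#' Inverts every candidate model for every subject of a cohort on the
#' concatenated training runs and collects the variational free energies.
#'
#' @param cohort an `nf_cohort`.
#' @param models list of [model_spec()] candidates.
#' @param n_runs number of training runs to use (default all).
#' @param control a [dcm_control()].
#' @param progress print progress.
#' @return list with `log_ev` (subjects x models matrix of free energies,
#'   `NA` for failed inversions) and `fits` (per subject, per model
#'   `dcm_fit` objects).
#' @export
log_evidence_matrix <- function(cohort, models, n_runs = NULL,
                                control = dcm_control(), progress = FALSE) {
  stopifnot(inherits(cohort, "nf_cohort"))
  ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  if (is.null(n_runs)) n_runs <- cohort$config$n_training_runs
  inp <- design_to_inputs(cohort$designs$training, TR = cohort$config$TR,
                          bins_per_tr = cohort$config$bins_per_tr)
  inputs <- rep(list(inp), n_runs)
  L <- matrix(NA_real_, length(ids), length(models),
              dimnames = list(ids, vapply(models, `[[`, "", "name")))
  fits <- vector("list", length(ids)); names(fits) <- ids
  for (i in seq_along(ids)) {
    runs <- cohort$runs[[ids[i]]]$training[seq_len(n_runs)]
    fits[[i]] <- vector("list", length(models))
    for (k in seq_along(models)) {
      fit <- try(dcm_fit(runs, inputs, models[[k]], control = control),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        warning(sprintf("inversion failed for %s, model %s", ids[i],
                        models[[k]]$name))
      } else {
        L[i, k] <- fit$free_energy
        fits[[i]][[k]] <- fit
      }
      if (progress) message(sprintf("%s x %s: F = %.1f", ids[i],
                                    models[[k]]$name, L[i, k]))
    }
    if (all(is.na(L[i, ]))) stop(sprintf("all models failed for subject %s", ids[i]))
  }
  list(log_ev = L, fits = fits)
}
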