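#' Random-effects Bayesian model selection (Dirichlet variational scheme)
#'
#' Treats the model identity as a random effect across subjects: population
#' model frequencies r follow a Dirichlet(alpha) posterior estimated by the
#' standard variational fixed point. Subject-wise responsibilities are
#' `u_nk proportional to exp(l_nk + psi(alpha_k) - psi(sum alpha))` and the
#' concentrations update as `alpha = alpha0 + sum_n u_nk`, iterated to
#' convergence.
#'
#' @param log_ev subjects x models matrix of log evidences (free energies).
#' @param alpha0 prior Dirichlet concentration (scalar or per model).
#' @param max_iter,tol fixed-point iteration controls.
#' @return list with `alpha`, `expected_freq` (= alpha / sum alpha), `u`
#'   (responsibilities), `iterations`.
#' @export
rfx_dirichlet <- function(log_ev, alpha0 = 1, max_iter = 500, tol = 1e-10) {
  log_ev <- as.matrix(log_ev)
  if (any(!is.finite(log_ev))) stop("log-evidence matrix must be finite")
  N <- nrow(log_ev); K <- ncol(log_ev)
  stopifnot(N >= 1, K >= 2)
  a0 <- rep_len(alpha0, K)
  alpha <- a0 + N / K
  u <- matrix(1 / K, N, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(log_ev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu); u <- u / rowSums(u)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  list(alpha = alpha, expected_freq = alpha / sum(alpha), u = u,
       iterations = it)
}

#' Exceedance probabilities of Dirichlet frequencies
#'
#' `xp_k = P(r_k > r_j for all j)` under `r ~ Dirichlet(alpha)`. For two
#' models the exact Beta form `P(r_1 > 1/2)` is used; otherwise Monte Carlo
#' with `n_samples` draws.
#'
#' @param alpha Dirichlet concentrations (> 0).
#' @param n_samples Monte Carlo sample count.
#' @param seed RNG seed for the Monte Carlo estimate.
#' @param method `"auto"` (exact when K = 2), `"exact"` or `"montecarlo"`.
#' @return exceedance probability vector summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1,
                            method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  stopifnot(all(alpha > 0), n_samples >= 1)
  K <- length(alpha)
  if (method == "exact" || (method == "auto" && K == 2)) {
    if (K != 2) stop("exact exceedance is only available for K = 2")
    x1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    return(c(x1, 1 - x1))
  }
  .with_seed(seed, {
    counts <- integer(K)
    chunk <- 1e5
    done <- 0
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      gm <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      counts <- counts + tabulate(max.col(gm, ties.method = "first"), K)
      done <- done + m
    }
    counts / n_samples
  })
}

# variational free energy of the RFX model (for the omnibus risk)
.rfx_free_energy <- function(log_ev, alpha0 = 1) {
  fit <- rfx_dirichlet(log_ev, alpha0)
  a <- fit$alpha; u <- fit$u
  K <- ncol(log_ev)
  a0 <- rep_len(alpha0, K)
  Elogr <- digamma(a) - digamma(sum(a))
  kl_dir <- lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((a - a0) * Elogr)
  ent_u <- -sum(u[u > 0] * log(u[u > 0]))
  sum(u * log_ev) + sum(sweep(u, 2, Elogr, `*`)) + ent_u - kl_dir
}

#' Bayesian omnibus risk
#'
#' Posterior probability that the observed log evidences arose under the
#' null hypothesis of equal model frequencies rather than the random-effects
#' alternative: `BOR = 1 / (1 + exp(F1 - F0))`, where `F0` is the null log
#' evidence (each subject's evidence averaged under the uniform frequency
#' profile) and `F1` the variational free energy of the RFX model. Values
#' near 1 mean the apparent model preferences are indistinguishable from
#' chance; exceedance probabilities are then "protected" toward uniform.
#'
#' @inheritParams rfx_dirichlet
#' @param prior0 optional per-model prior used by the null (defaults to
#'   uniform; used by family-level inference with unequal family sizes).
#' @return scalar risk in `[0, 1]`.
#' @export
bayesian_omnibus_risk <- function(log_ev, alpha0 = 1, prior0 = NULL) {
  log_ev <- as.matrix(log_ev)
  K <- ncol(log_ev)
  if (is.null(prior0)) prior0 <- rep(1 / K, K)
  # null: r fixed at prior0
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  F0 <- sum(apply(log_ev, 1, function(l) lse(l + log(prior0))))
  F1 <- .rfx_free_energy(log_ev, alpha0)
  1 / (1 + exp(F1 - F0))
}

#' Protected exceedance probabilities
#'
#' `pxp_k = xp_k (1 - BOR) + BOR / K`: exceedance probabilities shrunk to
#' uniform in proportion to the risk that all models are equally frequent.
#'
#' @param xp exceedance probabilities (sum to 1).
#' @param bor Bayesian omnibus risk in `[0, 1]`.
#' @param K number of models (defaults to `length(xp)`).
#' @export
protected_xp <- function(xp, bor, K = length(xp)) {
  stopifnot(abs(sum(xp) - 1) < 1e-6, bor >= 0, bor <= 1)
  xp * (1 - bor) + bor / K
}

#' Group-level BMS over a model space
#'
#' Runs the Dirichlet RFX scheme on a log-evidence matrix and assembles
#' concentrations, expected frequencies, exceedance, omnibus risk and
#' protected exceedance probabilities into a `bms_result`.
#'
#' @inheritParams rfx_dirichlet
#' @inheritParams exceedance_prob
#' @param level annotation: `"model"` or `"family"`.
#' @export
bms <- function(log_ev, alpha0 = 1, n_samples = 1e6, seed = 1,
                level = "model") {
  log_ev <- as.matrix(log_ev)
  fit <- rfx_dirichlet(log_ev, alpha0)
  xp <- exceedance_prob(fit$alpha, n_samples = n_samples, seed = seed)
  bor <- bayesian_omnibus_risk(log_ev, alpha0)
  pxp <- protected_xp(xp, bor)
  structure(list(alpha = fit$alpha, expected_freq = fit$expected_freq,
                 xp = xp, bor = bor, pxp = pxp, level = level,
                 names = colnames(log_ev), n_subjects = nrow(log_ev),
                 alpha0 = alpha0, n_samples = n_samples, seed = seed),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("RFX Bayesian model selection (%s level), %d subjects, BOR = %.3f\n",
              x$level, x$n_subjects, x$bor))
  tab <- data.frame(alpha = x$alpha, expected_freq = x$expected_freq,
                    xp = x$xp, pxp = x$pxp)
  rownames(tab) <- if (!is.null(x$names)) x$names else seq_along(x$alpha)
  print(round(tab, 4))
  invisible(x)
}

#' Family-level inference
#'
#' Pools model evidence within each family under a uniform conditional model
#' prior (family log evidence per subject = logsumexp of member evidences
#' minus log family size) and runs the RFX scheme over families. The pooling
#' gives every family equal prior mass regardless of its size, so that with
#' exchangeable evidences a 3/7/3 partition yields expected family
#' frequencies of one third each.
#'
#' @param log_ev subjects x models log-evidence matrix.
#' @param partition a [family_partition()] covering the columns of `log_ev`.
#' @inheritParams bms
#' @return a `bms_result` at family level.
#' @export
family_inference <- function(log_ev, partition, alpha0 = 1, n_samples = 1e6,
                             seed = 1) {
  log_ev <- as.matrix(log_ev)
  stopifnot(inherits(partition, "family_partition"),
            partition$n_models == ncol(log_ev))
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  fam_ev <- sapply(names(partition$families), function(f) {
    idx <- partition$families[[f]]
    apply(log_ev[, idx, drop = FALSE], 1, lse) - log(length(idx))
  })
  fam_ev <- matrix(fam_ev, nrow = nrow(log_ev),
                   dimnames = list(rownames(log_ev), names(partition$families)))
  bms(fam_ev, alpha0 = alpha0, n_samples = n_samples, seed = seed,
      level = "family")
}

#' Bayesian model averaging for one subject
#'
#' Averages per-model posterior means weighted by the subject's posterior
#' model probabilities (softmax of free energies under a uniform model prior
#' within the scope). Parameters absent from a model are treated as 0 with
#' zero variance, so averaging is over the union of parameter names.
#'
#' @param fits list of `dcm_fit` objects (one subject, one per model).
#' @param log_ev_row that subject's log evidences (defaults to the fits'
#'   free energies).
#' @param scope indices of the models to average over (default all).
#' @return list with `mean` (named averaged posterior means), `weights`,
#'   `scope`.
#' @export
bma <- function(fits, log_ev_row = vapply(fits, `[[`, 0, "free_energy"),
                scope = seq_along(fits)) {
  if (length(scope) == 0) stop("empty model scope")
  l <- log_ev_row[scope] - max(log_ev_row[scope])
  w <- exp(l) / sum(exp(l))
  all_nm <- unique(unlist(lapply(fits[scope], function(f) names(f$mean))))
  avg <- setNames(numeric(length(all_nm)), all_nm)
  for (i in seq_along(scope)) {
    m <- fits[[scope[i]]]$mean
    avg[names(m)] <- avg[names(m)] + w[i] * m
  }
  list(mean = avg, weights = setNames(w, names(log_ev_row)[scope]),
       scope = scope)
}
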