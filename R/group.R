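#' Pooled-variance two-sample t-test
#'
#' Student's two-sided two-sample t-test with pooled variance and
#' `n_a + n_b - 2` degrees of freedom (a Welch variant is available via
#' `welch = TRUE`). The degenerate case of zero pooled variance returns
#' `t = 0, p = 1` when the group means are equal and errors otherwise.
#'
#' @param a,b numeric vectors (each of length >= 2, finite).
#' @param welch use the Welch (unequal-variance) test instead.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    }
    stop("zero pooled variance with unequal means: t is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Bonferroni correction
#'
#' Flags `p_i < alpha / m` with `m = length(pvals)`: familywise control at
#' level `alpha` over the m modulatory-connection tests.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param alpha familywise level.
#' @return logical significance flags.
#' @export
bonferroni_correct <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  pvals < alpha / length(pvals)
}

#' Learner vs non-learner comparison of modulatory parameters
#'
#' Tests each modulatory (B) parameter of the subjects' model-averaged
#' posteriors for a group difference with a two-sample t-test, Bonferroni
#' corrected over the number of modulatory connections tested.
#'
#' @param bma_means subjects x parameters matrix of BMA posterior means
#'   (rows named by subject).
#' @param labels per-subject `"learner"` / `"non_learner"` labels.
#' @param alpha familywise level.
#' @param params which columns to test; defaults to all modulatory (B)
#'   parameters.
#' @param welch use Welch's t-test.
#' @return An object of class `group_comparison`: data frame (one row per
#'   connection: group means, t, p, corrected flag) sorted by corrected
#'   significance then |t|, with attributes `m` and `alpha`.
#' @export
compare_groups <- function(bma_means, labels, alpha = 0.05, params = NULL,
                           welch = FALSE) {
  bma_means <- as.matrix(bma_means)
  stopifnot(length(labels) == nrow(bma_means),
            all(labels %in% c("learner", "non_learner")))
  if (sum(labels == "learner") < 2 || sum(labels == "non_learner") < 2) {
    stop("each group needs at least 2 subjects")
  }
  if (is.null(params)) params <- grep("^B", colnames(bma_means), value = TRUE)
  if (length(params) == 0) stop("no modulatory (B) parameters to test")
  res <- lapply(params, function(pn) {
    va <- bma_means[labels == "learner", pn]
    vb <- bma_means[labels == "non_learner", pn]
    tt <- two_sample_ttest(va, vb, welch = welch)
    data.frame(connection = pn, mean_learner = mean(va),
               mean_non_learner = mean(vb), t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$significant <- bonferroni_correct(tab$p, alpha)
  tab <- tab[order(-tab$significant, -abs(tab$t)), ]
  rownames(tab) <- NULL
  structure(tab, m = length(params), alpha = alpha,
            class = c("group_comparison", "data.frame"))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Learner vs non-learner comparison: %d modulatory connections, Bonferroni at alpha = %g\n",
              attr(x, "m"), attr(x, "alpha")))
  NextMethod()
  invisible(x)
}
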