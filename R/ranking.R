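#' Principal eigenvariate of a voxel time-series matrix
#'
#' ROI summary time series: the first right singular vector of the
#' time-centered voxels x volumes matrix, rescaled to the ROI's
#' root-mean-square amplitude, with its sign chosen so that it correlates
#' non-negatively with the ROI mean time series.
#'
#' @param voxel_ts voxels x volumes numeric matrix (>= 1 voxel, >= 2
#'   volumes, finite, not all zero after centering).
#' @return numeric vector of length `ncol(voxel_ts)`.
#' @export
principal_eigenvariate <- function(voxel_ts) {
  X <- as.matrix(voxel_ts)
  stopifnot(nrow(X) >= 1, ncol(X) >= 2, all(is.finite(X)))
  Xc <- X - rowMeans(X)
  if (all(Xc == 0)) stop("voxel matrix has no temporal variance")
  sv <- svd(Xc, nu = 0, nv = 1)
  ts <- sv$v[, 1]
  rms_x <- sqrt(mean(Xc^2))
  ts <- ts / sqrt(mean(ts^2)) * rms_x
  mts <- colMeans(Xc)
  if (sum(ts * mts) < 0) ts <- -ts
  ts
}

#' SMA activity samples of a run
#'
#' The per-volume SMA BOLD values of a run, restricted to a scope: the whole
#' run, its up-regulation blocks or its baseline blocks. These samples form
#' the empirical distribution whose density enters the Wasserstein learning
#' score.
#'
#' @param run a `roi_ts`.
#' @param scope `"run"`, `"up-regulation"` or `"baseline"`.
#' @return numeric sample vector.
#' @export
mean_sma_activity <- function(run, scope = c("run", "up-regulation", "baseline")) {
  scope <- match.arg(scope)
  stopifnot(inherits(run, "roi_ts"))
  y <- run$data[, "SMA"]
  if (scope != "run") {
    keep <- !is.na(run$condition) & run$condition == scope
    y <- y[keep]
  }
  if (length(y) == 0) stop("empty scope: no volumes selected")
  y
}

#' Gaussian kernel density estimate on a shared grid
#'
#' Scott's bandwidth (`sd * n^(-1/5)`) by default. When a second sample set
#' is supplied the grid spans both sets plus three bandwidths on either
#' side, so two densities can be compared point-wise. The returned density
#' integrates to 1 on the grid (up to 1e-6).
#'
#' @param samples numeric samples (>= 2, positive spread unless the
#'   degenerate flag is acceptable).
#' @param bandwidth_rule `"scott"` or a positive number.
#' @param other optional second sample set used to define the shared grid.
#' @param n_grid grid resolution.
#' @return list with `x`, `y`, `bw`, `degenerate`.
#' @export
kde_density <- function(samples, bandwidth_rule = "scott", other = NULL,
                        n_grid = 1024) {
  stopifnot(length(samples) >= 2, all(is.finite(samples)))
  bw_of <- function(s) {
    if (is.numeric(bandwidth_rule)) return(bandwidth_rule)
    stats::sd(s) * length(s)^(-1 / 5)
  }
  bw <- bw_of(samples)
  if (!is.finite(bw) || bw <= 0) {
    return(list(x = unique(samples), y = Inf, bw = 0, degenerate = TRUE))
  }
  all_s <- c(samples, other)
  bw2 <- if (is.null(other)) bw else max(bw, bw_of(other), na.rm = TRUE)
  lo <- min(all_s) - 3 * bw2
  hi <- max(all_s) + 3 * bw2
  d <- stats::density(samples, bw = bw, kernel = "gaussian",
                      from = lo, to = hi, n = n_grid)
  dx <- d$x[2] - d$x[1]
  y <- d$y / (sum(d$y) * dx)
  list(x = d$x, y = y, bw = bw, degenerate = FALSE)
}

#' 1-D Wasserstein distance
#'
#' First Wasserstein (earth mover's) distance between two one-dimensional
#' distributions, computed as the integral of the absolute difference of
#' their cumulative distribution functions. Accepts two [kde_density()]
#' objects on a common grid, or two raw sample vectors (empirical CDFs on
#' the pooled support).
#'
#' @param dist_a,dist_b `kde_density()` results (matching grids) or numeric
#'   sample vectors.
#' @return nonnegative distance (BOLD units).
#' @export
wasserstein_1d <- function(dist_a, dist_b) {
  if (is.list(dist_a) && is.list(dist_b)) {
    if (length(dist_a$x) != length(dist_b$x) ||
        max(abs(dist_a$x - dist_b$x)) > 1e-8) {
      stop("densities must be evaluated on the same grid (use kde_density(..., other = ))")
    }
    dx <- dist_a$x[2] - dist_a$x[1]
    ca <- cumsum(dist_a$y) * dx
    cb <- cumsum(dist_b$y) * dx
    return(sum(abs(ca / ca[length(ca)] - cb / cb[length(cb)])) * dx)
  }
  a <- sort(as.numeric(dist_a)); b <- sort(as.numeric(dist_b))
  xs <- sort(c(a, b))
  dx <- diff(xs)
  Fa <- (findInterval(xs, a) / length(a))[-length(xs)]
  Fb <- (findInterval(xs, b) / length(b))[-length(xs)]
  sum(abs(Fa - Fb) * dx)
}

#' Wasserstein learning ranking of a cohort
#'
#' Per subject, the signed Wasserstein score is the W1 distance between the
#' SMA BOLD distributions of the initial baseline (rest reference run, all
#' volumes) and the post-training test (the transfer run's up-regulation
#' trials by default), signed by the direction of the mean change (positive
#' = up-regulation). Subjects are ranked by descending signed score; the
#' default label rule calls a subject a learner iff the signed score is
#' positive (a median split is available instead).
#'
#' @param cohort an `nf_cohort` (or any list with per-subject `baseline` and
#'   `transfer` `roi_ts` runs under `$runs`).
#' @param rule `"sign"` or `"median"`.
#' @param scope volume scope of the transfer run passed to
#'   [mean_sma_activity()] (the baseline reference always uses all volumes).
#' @param use_kde compute W1 on Gaussian kernel density estimates
#'   rather than on raw empirical CDFs.
#' @return data frame of class `wd_ranking`: subject_id, wd, sign,
#'   signed_wd, rank, label (plus the true group label when available).
#' @export
rank_cohort <- function(cohort, rule = c("sign", "median"),
                        scope = "up-regulation", use_kde = TRUE) {
  rule <- match.arg(rule)
  ids <- names(cohort$runs)
  rec <- lapply(ids, function(id) {
    rr <- cohort$runs[[id]]
    if (is.null(rr$baseline) || is.null(rr$transfer)) {
      stop(sprintf("subject %s is missing a baseline or transfer run", id))
    }
    sa <- mean_sma_activity(rr$baseline, scope = "run")
    sb <- mean_sma_activity(rr$transfer, scope = scope)
    if (use_kde) {
      da <- kde_density(sa, other = sb)
      db <- kde_density(sb, other = sa)
      wd <- if (da$degenerate || db$degenerate) abs(mean(sb) - mean(sa))
            else wasserstein_1d(da, db)
    } else {
      wd <- wasserstein_1d(sa, sb)
    }
    sgn <- sign(mean(sb) - mean(sa))
    data.frame(subject_id = id, wd = wd, sign = sgn, signed_wd = sgn * wd,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rec)
  tab$rank <- rank(-tab$signed_wd, ties.method = "first")
  tab <- tab[order(tab$rank), ]
  thr <- if (rule == "sign") 0 else stats::median(tab$signed_wd)
  tab$label <- ifelse(tab$signed_wd > thr, "learner", "non_learner")
  if (!is.null(cohort$subjects)) {
    truth <- setNames(vapply(cohort$subjects, `[[`, "", "group_label"),
                      vapply(cohort$subjects, `[[`, "", "subject_id"))
    tab$true_label <- unname(truth[tab$subject_id])
  }
  rownames(tab) <- NULL
  structure(tab, rule = rule, class = c("wd_ranking", "data.frame"))
}

#' @export
print.wd_ranking <- function(x, ...) {
  cat(sprintf("Wasserstein learning ranking (%s rule): %d subjects, %d labeled learner\n",
              attr(x, "rule"), nrow(x), sum(x$label == "learner")))
  NextMethod()
  invisible(x)
}

#' @export
plot.wd_ranking <- function(x, ...) {
  cols <- ifelse(x$signed_wd > 0, "forestgreen", "darkorange")
  graphics::barplot(x$signed_wd, names.arg = x$subject_id, col = cols,
                    las = 2, ylab = "signed Wasserstein distance", ...)
  invisible(x)
}
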