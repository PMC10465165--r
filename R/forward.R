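#' Dynamic causal model parameters
#'
#' Bundles the neural coupling matrices and hemodynamic constants of the
#' four-region bilinear model. `A` is the baseline coupling matrix in 1/s
#' (row = target, column = source) whose diagonal carries the fixed
#' self-inhibitory connections; each matrix in `B` holds the modulation of
#' coupling by one experimental input; `C` maps driving inputs to regions.
#' Hemodynamic constants follow the standard balloon-Windkessel values:
#' signal decay kappa = 0.64 1/s, autoregulatory feedback gamma = 0.32 1/s,
#' mean transit time tau = 2 s, vessel stiffness alpha = 0.32, resting oxygen
#' extraction E0 = 0.4 and resting venous volume fraction V0 = 0.04.
#'
#' @param A 4x4 coupling matrix; diagonal must be strictly negative.
#' @param B list of 4x4 modulation matrices (or a single matrix).
#' @param C 4 x n_inputs driving-gain matrix.
#' @param hemo named list overriding any of `kappa`, `gamma`, `tau` (length-1
#'   or per-region), `alpha`, `E0`, `V0`.
#' @param noise_log_precision scalar log precision of the observation noise
#'   (annotation used by simulators; the inversion estimates its own).
#' @return An object of class `dcm_params`.
#' @export
dcm_params <- function(A, B = NULL, C = NULL, hemo = list(),
                       noise_log_precision = NA_real_) {
  n <- n_regions()
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(n, n)))
  if (any(diag(A) >= 0)) stop("diagonal of A (self-inhibition) must be strictly negative")
  if (is.null(B)) B <- list(matrix(0, n, n))
  if (!is.list(B)) B <- list(B)
  B <- lapply(B, function(m) { m <- as.matrix(m); stopifnot(all(dim(m) == c(n, n))); m })
  if (is.null(C)) C <- matrix(0, n, 1)
  C <- as.matrix(C)
  stopifnot(nrow(C) == n)
  h <- default_hemo()
  h[names(hemo)] <- hemo
  h$kappa <- rep_len(h$kappa, n); h$gamma <- rep_len(h$gamma, n)
  h$tau <- rep_len(h$tau, n)
  if (any(c(h$kappa, h$gamma, h$tau) <= 0) || h$alpha <= 0 || h$alpha >= 1 ||
      h$E0 <= 0 || h$E0 >= 1 || h$V0 <= 0) {
    stop("hemodynamic constants out of range (kappa, gamma, tau, V0 > 0; alpha, E0 in (0,1))")
  }
  lab <- region_labels()
  dimnames(A) <- list(lab, lab)
  B <- lapply(B, function(m) { dimnames(m) <- list(lab, lab); m })
  rownames(C) <- lab
  structure(list(A = A, B = B, C = C, hemo = h,
                 noise_log_precision = noise_log_precision),
            class = "dcm_params")
}

#' @rdname dcm_params
#' @export
default_hemo <- function() {
  list(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32, E0 = 0.4, V0 = 0.04)
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("DCM parameters (1/s):\nA =\n"); print(round(x$A, 3))
  nb <- sum(vapply(x$B, function(m) sum(m != 0), 0L))
  cat("nonzero B entries:", nb, " | driving gains:",
      paste(sprintf("%s=%.3g", rownames(x$C)[rowSums(x$C != 0) > 0],
                    x$C[rowSums(x$C != 0) > 0, 1]), collapse = ", "), "\n")
  invisible(x)
}

# check that params respect a spec's masks (free pattern only where mask on)
.check_conform <- function(params, spec) {
  offA <- params$A; diag(offA) <- 0
  if (any(offA[!spec$a_mask] != 0)) stop("A has nonzero entries outside the model's a_mask")
  nb <- max(length(params$B), length(spec$b_mask))
  for (j in seq_len(nb)) {
    Bm <- if (j <= length(params$B)) params$B[[j]] else matrix(0, n_regions(), n_regions())
    mk <- if (j <= length(spec$b_mask)) spec$b_mask[[j]] else matrix(FALSE, n_regions(), n_regions())
    if (any(Bm[!mk] != 0)) stop("B has nonzero entries outside the model's b_mask")
  }
  if (ncol(params$C) >= 1 && ncol(spec$c_mask) >= 1) {
    j <- seq_len(min(ncol(params$C), ncol(spec$c_mask)))
    if (any(params$C[, j][!spec$c_mask[, j]] != 0)) stop("C has nonzero entries outside the model's c_mask")
  }
  invisible(TRUE)
}

#' Neural drift of the bilinear model
#'
#' `dx/dt = (A + sum_j u_mod_j B_j) x + C u_drive`: linear dynamics whose
#' effective coupling is shifted by the modulatory inputs.
#'
#' @param x neural state vector (one element per region).
#' @param u_drive driving input value(s) (scalar or one per input column of C).
#' @param u_mod modulatory input value(s) (scalar or one per B matrix).
#' @param params a [dcm_params()] object.
#' @return state derivative in 1/s.
#' @export
neuronal_drift <- function(x, u_drive, u_mod, params) {
  if (length(x) != nrow(params$A)) stop("state dimension does not match A")
  Aeff <- params$A
  u_mod <- rep_len(u_mod, length(params$B))
  for (j in seq_along(params$B)) Aeff <- Aeff + u_mod[j] * params$B[[j]]
  u_drive <- rep_len(u_drive, ncol(params$C))
  as.numeric(Aeff %*% x + params$C %*% u_drive)
}

#' Hemodynamic drift (balloon-Windkessel cascade) for one region
#'
#' State `h = (s, f, v, q)`: vasodilatory signal, normalized blood inflow,
#' normalized venous volume, normalized deoxyhemoglobin content. Driven by
#' the neural activity `z` of the region:
#' `ds/dt = z - kappa s - gamma (f - 1)`, `df/dt = s`,
#' `tau dv/dt = f - v^(1/alpha)`,
#' `tau dq/dt = f (1 - (1-E0)^(1/f))/E0 - v^(1/alpha) q / v`.
#'
#' @param h hemodynamic state vector `(s, f, v, q)` with `f, v, q > 0`.
#' @param z neural activity (scalar).
#' @param params a [dcm_params()] object.
#' @param region region index for the per-region constants.
#' @return derivative of `(s, f, v, q)`.
#' @export
hemodynamic_drift <- function(h, z, params, region = 1L) {
  s <- h[1]; f <- h[2]; v <- h[3]; q <- h[4]
  if (f <= 0 || v <= 0 || q <= 0) {
    stop(sprintf("non-positive hemodynamic state (f, v or q) in region %s",
                 region_labels()[region]))
  }
  hc <- params$hemo
  fv <- v^(1 / hc$alpha)
  E <- (1 - (1 - hc$E0)^(1 / f)) / hc$E0
  c(z - hc$kappa[region] * s - hc$gamma[region] * (f - 1),
    s,
    (f - fv) / hc$tau[region],
    (f * E - fv * q / v) / hc$tau[region])
}

#' BOLD observation equation
#'
#' Classical (non-revised) balloon observation:
#' `y = 100 V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v))` in percent signal
#' change, with `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`. Zero at the resting
#' state `f = v = q = 1`.
#'
#' @param h hemodynamic state `(s, f, v, q)` or a matrix with such rows.
#' @param params a [dcm_params()] object.
#' @return BOLD percent signal change.
#' @export
bold_observation <- function(h, params) {
  hc <- params$hemo
  k1 <- 7 * hc$E0; k2 <- 2; k3 <- 2 * hc$E0 - 0.2
  if (is.matrix(h)) { v <- h[, 3]; q <- h[, 4] } else { v <- h[3]; q <- h[4] }
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be positive")
  100 * hc$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Integrate the DCM forward model
#'
#' Deterministic, noise-free multi-region BOLD prediction: the bilinear
#' neural model is integrated jointly with the hemodynamic cascade by a
#' fixed-step 4th-order Runge-Kutta scheme on the microtime grid, starting
#' from rest, and the BOLD observation is sampled at the end of every volume.
#'
#' @param params a [dcm_params()] object.
#' @param inputs an [input_set()].
#' @param spec optional [model_spec()]; if given, `params` are checked to
#'   conform to its masks.
#' @param run_id,run_type annotations stored on the output.
#' @param design optional [make_block_design()] used to attach per-volume
#'   condition labels.
#' @param return_states if `TRUE`, attach the neural states at volume times
#'   as attribute `"states"`.
#' @return A `roi_ts` object (volumes x regions BOLD matrix in percent signal
#'   change with `TR`, `run_id` and condition annotations). If the effective
#'   coupling is unstable (an eigenvalue of A or A + sum B has positive real
#'   part) a warning is raised and the output carries attribute
#'   `"unstable" = TRUE`.
#' @export
integrate_dcm <- function(params, inputs, spec = NULL, run_id = "run-01",
                          run_type = "training", design = NULL,
                          return_states = FALSE) {
  stopifnot(inherits(params, "dcm_params"), inherits(inputs, "input_set"))
  if (!is.null(spec)) .check_conform(params, spec)
  n <- n_regions()
  Bsum <- Reduce(`+`, params$B)
  unstable <- max(Re(eigen(params$A, only.values = TRUE)$values)) > 0 ||
    max(Re(eigen(params$A + Bsum, only.values = TRUE)$values)) > 0
  if (unstable) warning("effective coupling matrix is unstable (positive real eigenvalue)")
  nmod <- length(params$B)
  Bc <- array(unlist(params$B), dim = c(n, n, nmod))
  um <- inputs$u_mod
  if (ncol(um) < nmod) um <- matrix(um[, 1], nrow(um), nmod)
  dt <- inputs$TR / inputs$bins_per_tr
  res <- .dcm_forward_cpp(params$A, Bc, params$C,
                          inputs$u_drive, um[, seq_len(nmod), drop = FALSE],
                          inputs$bins_per_tr, dt,
                          params$hemo$kappa, params$hemo$gamma, params$hemo$tau,
                          params$hemo$alpha, params$hemo$E0, params$hemo$V0,
                          return_states)
  if (!res$ok) {
    stop(sprintf("numerical failure of the hemodynamic integration at microtime bin %d (t = %.2f s)",
                 res$bad_bin, res$bad_bin * dt))
  }
  y <- res$bold
  colnames(y) <- region_labels()
  cl <- if (!is.null(design)) condition_labels(design, inputs$TR, inputs$n_volumes)
        else rep(NA_character_, inputs$n_volumes)
  out <- roi_ts(y, TR = inputs$TR, run_id = run_id, run_type = run_type,
                condition = cl)
  if (unstable) attr(out, "unstable") <- TRUE
  if (return_states) {
    st <- res$states
    colnames(st) <- region_labels()
    attr(out, "states") <- st
  }
  out
}

#' ROI BOLD time series
#'
#' @param data volumes x regions numeric matrix (percent signal change),
#'   columns in the canonical region order F, ACC, S, SMA.
#' @param TR repetition time, seconds.
#' @param run_id run identifier.
#' @param run_type `"training"`, `"transfer"` or `"baseline"`.
#' @param condition per-volume condition label.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, TR, run_id = "run-01", run_type = "training",
                   condition = rep(NA_character_, nrow(data))) {
  data <- as.matrix(data)
  if (ncol(data) != n_regions()) stop("roi_ts needs one column per region")
  if (any(!is.finite(data))) stop("roi_ts must not contain missing values")
  if (length(condition) != nrow(data)) stop("one condition label per volume required")
  colnames(data) <- region_labels()
  structure(list(data = data, TR = TR, run_id = run_id, run_type = run_type,
                 condition = condition),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series %s (%s): %d volumes x %d regions, TR = %g s\n",
              x$run_id, x$run_type, nrow(x$data), ncol(x$data), x$TR))
  invisible(x)
}
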