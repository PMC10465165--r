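#' Block designs for neurofeedback runs
#'
#' Training runs alternate 4 baseline (rest) and 3 up-regulation blocks,
#' starting at rest. Transfer runs use the same alternation but without
#' feedback (post-training test). A `"baseline"` run is a rest run of equal
#' total length, used as the reference for the learning ranking.
#'
#' @param block_duration_s block duration in seconds (> 0).
#' @param run_type one of `"training"`, `"transfer"`, `"baseline"`.
#' @return An object of class `block_design`: list with `blocks` (data frame
#'   with columns `condition`, `onset`, `duration`) and `run_type`.
#' @examples
#' d <- make_block_design(30, "training")
#' nrow(d$blocks)  # 7
#' @export
make_block_design <- function(block_duration_s = 30, run_type = c("training", "transfer", "baseline")) {
  run_type <- match.arg(run_type)
  if (!is.numeric(block_duration_s) || block_duration_s <= 0) {
    stop("block_duration_s must be a positive number")
  }
  d <- block_duration_s
  if (run_type == "baseline") {
    blocks <- data.frame(condition = "baseline", onset = 0, duration = 7 * d,
                         stringsAsFactors = FALSE)
  } else {
    cond <- c("baseline", "up-regulation", "baseline", "up-regulation",
              "baseline", "up-regulation", "baseline")
    blocks <- data.frame(condition = cond,
                         onset = d * (seq_along(cond) - 1),
                         duration = d,
                         stringsAsFactors = FALSE)
  }
  structure(list(blocks = blocks, run_type = run_type), class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("Block design (%s): %d blocks, %g s total\n", x$run_type,
              nrow(x$blocks), sum(x$blocks$duration)))
  invisible(x)
}

design_duration <- function(design) {
  with(design$blocks, max(onset + duration))
}

#' Experimental inputs on the microtime grid
#'
#' Builds the box-car driving and modulatory inputs of a run from its block
#' design, sampled on a microtime grid of `bins_per_tr` bins per repetition
#' time. The up-regulation condition acts as the modulatory input. The
#' driving input is the visual feedback information, present from the onset
#' of every training run: the display is static during baseline blocks
#' (input level 0.5) and actively updating during up-regulation blocks
#' (level 1), giving a two-level box-car. In transfer runs the feedback is
#' replaced by the cue/display that still paces the attempt, modelled as
#' the same two-level input scaled by `drive_scale`; rest
#' (baseline-reference) runs have no input at all.
#'
#' @param design a [make_block_design()] object.
#' @param TR repetition time in seconds; the run duration must be an integer
#'   multiple of it.
#' @param bins_per_tr microtime bins per TR.
#' @param drive_scale multiplier on the driving box-car (0 silences it).
#' @return An object of class `input_set` with `times` (bin midpoints, s),
#'   `u_drive` and `u_mod` (bins x 1 matrices), `TR`, `n_volumes`,
#'   `bins_per_tr`.
#' @export
design_to_inputs <- function(design, TR = 1.5, bins_per_tr = 16, drive_scale = 1) {
  stopifnot(inherits(design, "block_design"))
  total <- design_duration(design)
  nv <- total / TR
  if (abs(nv - round(nv)) > 1e-9) {
    stop(sprintf("run duration %g s is not a multiple of TR = %g s", total, TR))
  }
  nv <- as.integer(round(nv))
  nb <- nv * bins_per_tr
  dt <- TR / bins_per_tr
  times <- (seq_len(nb) - 0.5) * dt
  up <- design$blocks[design$blocks$condition == "up-regulation", , drop = FALSE]
  u_up <- rep(0, nb)
  for (i in seq_len(nrow(up))) {
    u_up[times >= up$onset[i] & times < up$onset[i] + up$duration[i]] <- 1
  }
  drive_on <- switch(design$run_type,
                     training = 1,
                     transfer = drive_scale,
                     baseline = 0)
  input_set(times = times,
            u_drive = matrix(drive_on * (0.5 + 0.5 * u_up), ncol = 1),
            u_mod = matrix(u_up, ncol = 1),
            TR = TR, n_volumes = nv, bins_per_tr = bins_per_tr)
}

#' @rdname design_to_inputs
#' @param times,u_drive,u_mod,n_volumes components; see above.
#' @export
input_set <- function(times, u_drive, u_mod, TR, n_volumes,
                      bins_per_tr = length(times) / n_volumes) {
  u_drive <- as.matrix(u_drive)
  u_mod <- as.matrix(u_mod)
  nb <- length(times)
  if (nrow(u_drive) != nb || nrow(u_mod) != nb) {
    stop("u_drive and u_mod must have one row per microtime bin")
  }
  if (abs(bins_per_tr - round(bins_per_tr)) > 1e-9 ||
      nb != n_volumes * round(bins_per_tr)) {
    stop("microtime bins must evenly divide volumes (length(times) = n_volumes * bins_per_tr)")
  }
  if (any(!is.finite(u_drive)) || any(!is.finite(u_mod)) ||
      any(u_drive < 0) || any(u_mod < 0)) {
    stop("inputs must be finite and non-negative box-cars")
  }
  structure(list(times = times, u_drive = u_drive, u_mod = u_mod, TR = TR,
                 n_volumes = as.integer(n_volumes),
                 bins_per_tr = as.integer(round(bins_per_tr))),
            class = "input_set")
}

# per-volume condition labels from a design (label by volume midpoint)
condition_labels <- function(design, TR, n_volumes) {
  mid <- (seq_len(n_volumes) - 0.5) * TR
  lab <- rep("baseline", n_volumes)
  up <- design$blocks[design$blocks$condition == "up-regulation", , drop = FALSE]
  for (i in seq_len(nrow(up))) {
    lab[mid >= up$onset[i] & mid < up$onset[i] + up$duration[i]] <- "up-regulation"
  }
  lab
}
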