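#' Construct a candidate network structure (model specification)
#'
#' A model specification is a set of Boolean masks declaring which dynamic
#' causal model parameters are free: `a_mask` for baseline between-region
#' coupling (off-diagonal; the diagonal holds the fixed self-inhibitory
#' connections and is never a free parameter), one `b_mask` per modulatory
#' input for input-dependent changes of coupling, and `c_mask` for driving
#' input gains. Modulation is only allowed on connections that exist at
#' baseline (`b_mask` must be a subset of `a_mask`).
#'
#' @param name model name.
#' @param a_mask 4x4 logical/0-1 matrix of free baseline connections,
#'   row = target, column = source. Diagonal entries are ignored (fixed
#'   self-inhibition).
#' @param b_mask 4x4 matrix or list of such matrices, one per modulatory
#'   input. Defaults to no modulation.
#' @param c_mask 4 x n_inputs matrix of driving-input gains. Defaults to a
#'   single all-off column.
#' @param family_id optional family label used by family-level inference.
#' @return An object of class `dcm_spec`.
#' @seealso [validate_spec()], [build_first_step_space()],
#'   [build_second_step_space()]
#' @export
model_spec <- function(name, a_mask, b_mask = NULL, c_mask = NULL,
                       family_id = NA_character_) {
  n <- n_regions()
  lab <- region_labels()
  a_mask <- .as_mask(a_mask, n, n)
  if (is.null(b_mask)) b_mask <- matrix(FALSE, n, n)
  if (!is.list(b_mask)) b_mask <- list(b_mask)
  b_mask <- lapply(b_mask, .as_mask, nr = n, nc = n)
  if (is.null(c_mask)) c_mask <- matrix(FALSE, n, 1)
  c_mask <- .as_mask(c_mask, n, ncol(as.matrix(c_mask)))
  diag(a_mask) <- FALSE
  dimnames(a_mask) <- list(lab, lab)
  b_mask <- lapply(b_mask, function(m) { diag(m) <- FALSE; dimnames(m) <- list(lab, lab); m })
  rownames(c_mask) <- lab
  colnames(c_mask) <- paste0("u", seq_len(ncol(c_mask)))
  structure(
    list(name = name, a_mask = a_mask, b_mask = b_mask, c_mask = c_mask,
         family_id = family_id),
    class = "dcm_spec"
  )
}

.as_mask <- function(m, nr, nc) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(nr, nc))) {
    stop(sprintf("mask must be %d x %d, got %d x %d", nr, nc, nrow(m), ncol(m)))
  }
  storage.mode(m) <- "logical"
  m
}

#' Validate a model specification
#'
#' Checks the structural invariants of a [model_spec()]: square masks with
#' fixed (non-free) diagonal, modulation restricted to existing baseline
#' connections, and (for first-step candidate models) a single driving-input
#' region per input column. Violations are returned as data, not raised.
#'
#' @param spec a `dcm_spec`.
#' @param single_input if `TRUE`, additionally require that exactly one
#'   region receives each driving input (the first-step model-space rule).
#' @return `TRUE` if the spec passes, otherwise a character vector of
#'   violation codes.
#' @export
validate_spec <- function(spec, single_input = FALSE) {
  v <- character(0)
  n <- n_regions()
  if (!inherits(spec, "dcm_spec")) return("not-a-dcm-spec")
  if (!all(dim(spec$a_mask) == c(n, n))) v <- c(v, "a-mask-shape")
  if (any(diag(spec$a_mask))) v <- c(v, "free-self-connection")
  for (bm in spec$b_mask) {
    if (any(diag(bm))) v <- c(v, "self-modulation")
    if (any(bm & !spec$a_mask)) v <- c(v, "modulation-without-connection")
  }
  if (nrow(spec$c_mask) != n) v <- c(v, "c-mask-shape")
  if (single_input) {
    for (j in seq_len(ncol(spec$c_mask))) {
      if (sum(spec$c_mask[, j]) != 1L) v <- c(v, "driving-input-not-single-region")
    }
    if (ncol(spec$c_mask) != 1L || sum(colSums(spec$c_mask) > 0) != 1L) {
      if (sum(colSums(spec$c_mask) > 0) != 1L) v <- c(v, "multiple-driving-columns")
    }
  }
  if (length(v) == 0) TRUE else v
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("DCM model spec:", x$name,
      if (!is.na(x$family_id)) paste0("(family ", x$family_id, ")"), "\n")
  cat("  free A connections:", sum(x$a_mask), "\n")
  cat("  free B entries:", sum(vapply(x$b_mask, sum, 0L)),
      sprintf("(%d modulatory input%s)", length(x$b_mask),
              if (length(x$b_mask) == 1) "" else "s"), "\n")
  cat("  driving input ->",
      paste(rownames(x$c_mask)[rowSums(x$c_mask) > 0], collapse = ", "), "\n")
  invisible(x)
}

# edge helpers ---------------------------------------------------------------

# mask with directed edges given as "SRC->TGT" strings
.edges_mask <- function(edges) {
  n <- n_regions()
  m <- matrix(FALSE, n, n)
  for (e in edges) {
    p <- strsplit(e, "->", fixed = TRUE)[[1]]
    m[.ridx(p[2]), .ridx(p[1])] <- TRUE   # row = target, col = source
  }
  m
}

# directed edge names of a mask
.mask_edges <- function(m) {
  lab <- region_labels()
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  sort(paste0(lab[idx[, 2]], "->", lab[idx[, 1]]))
}

# free-parameter names of a spec (stable naming shared across models so that
# Bayesian model averaging can align parameters)
spec_param_names <- function(spec) {
  lab <- region_labels()
  nm <- character(0)
  ia <- which(spec$a_mask, arr.ind = TRUE)
  if (nrow(ia)) nm <- c(nm, paste0("A[", lab[ia[, 1]], "<-", lab[ia[, 2]], "]"))
  for (j in seq_along(spec$b_mask)) {
    ib <- which(spec$b_mask[[j]], arr.ind = TRUE)
    if (nrow(ib)) nm <- c(nm, paste0("B", j, "[", lab[ib[, 1]], "<-", lab[ib[, 2]], "]"))
  }
  ic <- which(spec$c_mask, arr.ind = TRUE)
  if (nrow(ic)) nm <- c(nm, paste0("C[", lab[ic[, 1]], "<-u", ic[, 2], "]"))
  nm
}
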