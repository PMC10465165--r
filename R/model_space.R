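#' Candidate model spaces for the two-step family-level inference
#'
#' The analysis proceeds in two steps. Step one asks which baseline
#' effective-connectivity architecture (matrix A) and which driving-input
#' region (matrix C) best explain the data: seven architecture variants along
#' the F-ACC-S axis (with differing axis directionality and node-to-SMA
#' links, plus one variant with a direct S-F connection bypassing the ACC)
#' are each paired with a frontal ("top-down") or striatal ("bottom-up")
#' driving input, giving fourteen models in two families of seven. Each
#' step-one candidate models the up-regulation condition as modulation of
#' all of its own connections, so the architecture comparison is not
#' confounded by unmodelled block effects. Step two
#' fixes the winning architecture and asks which connections the
#' up-regulation condition modulates (matrix B): thirteen models partitioned
#' into three families by the source node of modulation (frontal, ACC,
#' striatal), enumerating all non-empty subsets of each source's outgoing
#' baseline connections.
#'
#' @return `build_first_step_space()` returns a list with `models` (list of
#'   [model_spec()] objects) and `partition` (a `family_partition`).
#' @examples
#' sp <- build_first_step_space()
#' length(sp$models)           # 14
#' lengths(sp$partition$families)
#' @name model_space
NULL

# Step-one models carry full modulation of their own architecture (b_mask =
# a_mask): the baseline-architecture / driving-input comparison is made with
# the up-regulation effect modelled, so that block-related variance does not
# penalise both families alike.
#
# the seven baseline-architecture variants, as directed edge lists.
# row convention throughout: A[target, source].
.ae_variants <- function() {
  list(
    bilateral_full = c("F->ACC", "ACC->F", "ACC->S", "S->ACC",
                       "F->SMA", "SMA->F", "ACC->SMA", "SMA->ACC",
                       "S->SMA", "SMA->S"),
    topdown_axis_all_sma = c("F->ACC", "ACC->S", "F->SMA", "ACC->SMA", "S->SMA"),
    bottomup_axis_all_sma = c("S->ACC", "ACC->F", "F->SMA", "ACC->SMA", "S->SMA"),
    bilateral_axis_forward_sma = c("F->ACC", "ACC->F", "ACC->S", "S->ACC",
                                   "F->SMA", "ACC->SMA", "S->SMA"),
    topdown_axis_f_sma = c("F->ACC", "ACC->S", "F->SMA"),
    bottomup_axis_s_sma = c("S->ACC", "ACC->F", "S->SMA"),
    direct_sf = c("S->F", "F->S", "F->SMA", "SMA->F", "S->SMA", "SMA->S")
  )
}

.c_mask_at <- function(region) {
  m <- matrix(FALSE, n_regions(), 1)
  m[.ridx(region), 1] <- TRUE
  m
}

#' @describeIn model_space the 14-model step-one space (7 architectures x
#'   frontal/striatal driving input; families "frontal" and "striatal").
#' @export
build_first_step_space <- function() {
  vars <- .ae_variants()
  models <- list()
  fam <- list(frontal = integer(0), striatal = integer(0))
  k <- 0L
  for (input in c("frontal", "striatal")) {
    node <- if (input == "frontal") "F" else "S"
    for (vn in names(vars)) {
      k <- k + 1L
      am <- .edges_mask(vars[[vn]])
      models[[k]] <- model_spec(
        name = paste0(input, ".", vn),
        a_mask = am,
        b_mask = am,
        c_mask = .c_mask_at(node),
        family_id = input
      )
      fam[[input]] <- c(fam[[input]], k)
    }
  }
  partition <- family_partition(fam, level = "first_step", n_models = k)
  list(models = models, partition = partition)
}

#' @describeIn model_space the winning step-one architecture: bilateral
#'   F-ACC-S axis, bilateral node-to-SMA connections, driving input at F.
#' @export
winning_architecture <- function() {
  model_spec(
    name = "frontal.bilateral_full",
    a_mask = .edges_mask(.ae_variants()$bilateral_full),
    c_mask = .c_mask_at("F"),
    family_id = "frontal"
  )
}

#' @describeIn model_space the 13-model step-two modulation space built on a
#'   fixed architecture `base`; families "frontal" (3), "acc" (7) and
#'   "striatal" (3) by modulation source node.
#' @param base a `dcm_spec`, normally [winning_architecture()].
#' @export
build_second_step_space <- function(base = winning_architecture()) {
  stopifnot(inherits(base, "dcm_spec"))
  lab <- region_labels()
  sources <- c(frontal = "F", acc = "ACC", striatal = "S")
  models <- list()
  fam <- list(frontal = integer(0), acc = integer(0), striatal = integer(0))
  k <- 0L
  for (fid in names(sources)) {
    src <- sources[[fid]]
    out_edges <- .mask_edges(base$a_mask)
    out_edges <- out_edges[startsWith(out_edges, paste0(src, "->"))]
    if (length(out_edges) == 0) {
      stop(sprintf("base architecture has no outgoing connections from %s; cannot build the %s modulation family", src, fid))
    }
    # all non-empty subsets, ordered by size then lexicographically
    subs <- list()
    for (sz in seq_along(out_edges)) {
      cmb <- utils::combn(out_edges, sz, simplify = FALSE)
      subs <- c(subs, cmb)
    }
    for (su in subs) {
      k <- k + 1L
      sp <- model_spec(
        name = paste0(fid, ".mod.", paste(gsub("->", "_", su), collapse = ".")),
        a_mask = base$a_mask,
        b_mask = .edges_mask(su),
        c_mask = base$c_mask,
        family_id = fid
      )
      models[[k]] <- sp
      fam[[fid]] <- c(fam[[fid]], k)
    }
  }
  partition <- family_partition(fam, level = "second_step", n_models = k)
  list(models = models, partition = partition)
}

#' @describeIn model_space a fully modulated model: every baseline connection
#'   of `base` is also modulated (used for the group-comparison BMA).
#' @export
full_modulation_spec <- function(base = winning_architecture()) {
  stopifnot(inherits(base, "dcm_spec"))
  model_spec(
    name = paste0(base$name, ".fullmod"),
    a_mask = base$a_mask,
    b_mask = base$a_mask,
    c_mask = base$c_mask,
    family_id = base$family_id
  )
}

#' Family partition of a model space
#'
#' @param families named list mapping family id to model indices.
#' @param level `"first_step"` or `"second_step"`.
#' @param n_models total number of models the partition must cover.
#' @return An object of class `family_partition`.
#' @export
family_partition <- function(families, level, n_models) {
  idx <- sort(unlist(families, use.names = FALSE))
  if (!identical(idx, seq_len(n_models))) {
    stop("families must be disjoint and cover all models exactly once")
  }
  structure(list(families = families, level = level, n_models = n_models),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  cat(sprintf("Family partition (%s): %d models in %d families\n",
              x$level, x$n_models, length(x$families)))
  for (f in names(x$families)) {
    cat(sprintf("  %-10s %s\n", f, paste(x$families[[f]], collapse = " ")))
  }
  invisible(x)
}

# family id per model index
.family_of <- function(partition) {
  out <- character(partition$n_models)
  for (f in names(partition$families)) out[partition$families[[f]]] <- f
  out
}
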