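#' Read and write ROI runs, events and log-evidence tables
#'
#' Runs are stored as TSV (one row per volume; columns F, ACC, S, SMA,
#' run_id, condition) with the TR and run type in a sidecar JSON next to the
#' file (`<file>.json`). Events follow the BIDS events dialect: tab-separated
#' with a header `onset  duration  trial_type`.
#'
#' @param run a `roi_ts`.
#' @param path file path (.tsv).
#' @return `read_run_tsv()` returns a `roi_ts`; writers return the path
#'   invisibly.
#' @name run_io
NULL

#' @rdname run_io
#' @export
write_run_tsv <- function(run, path) {
  stopifnot(inherits(run, "roi_ts"))
  df <- as.data.frame(run$data)
  df$run_id <- run$run_id
  df$condition <- run$condition
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(TR = run$TR, run_type = run$run_type,
               n_volumes = nrow(run$data), units = "percent signal change")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_io
#' @export
read_run_tsv <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing TR sidecar: expected ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- region_labels()
  if (!all(need %in% names(df))) {
    stop("run TSV must contain columns ", paste(need, collapse = ", "))
  }
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(!grepl("^-?[0-9.eE+]+$", as.character(df[[cn]])))[1]
      stop(sprintf("non-numeric value in column %s, line %d", cn, bad + 1L))
    }
  }
  roi_ts(as.matrix(df[, need]), TR = side$TR,
         run_id = if ("run_id" %in% names(df)) df$run_id[1] else "run-01",
         run_type = side$run_type %||% "training",
         condition = if ("condition" %in% names(df)) df$condition
                     else rep(NA_character_, nrow(df)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_io
#' @param design a [make_block_design()].
#' @export
write_events <- function(design, path) {
  stopifnot(inherits(design, "block_design"))
  df <- data.frame(onset = design$blocks$onset,
                   duration = design$blocks$duration,
                   trial_type = design$blocks$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname run_io
#' @param run_type run type to attach to the design read back.
#' @export
read_events <- function(path, run_type = "training") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df))) {
    stop("events file needs columns onset, duration, trial_type")
  }
  for (cn in c("onset", "duration")) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("non-numeric %s in events file, line %d", cn, bad + 1L))
    }
  }
  o <- order(df$onset)
  df <- df[o, ]
  ends <- df$onset + df$duration
  if (any(df$onset[-1] < ends[-length(ends)] - 1e-9)) {
    stop("events overlap: block onsets must not precede the previous block's end")
  }
  structure(list(blocks = data.frame(condition = df$trial_type,
                                     onset = df$onset, duration = df$duration,
                                     stringsAsFactors = FALSE),
                 run_type = run_type),
            class = "block_design")
}

#' @rdname run_io
#' @param log_ev subjects x models matrix.
#' @export
write_logev <- function(log_ev, path) {
  df <- data.frame(subject = rownames(log_ev), as.data.frame(log_ev),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname run_io
#' @export
read_logev <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.numeric(m)) stop("log-evidence table contains non-numeric cells")
  m
}

#' Serialize a model space to JSON and back
#'
#' Masks are written as 0/1 matrices with the family map, so users can audit
#' or substitute the candidate structures.
#'
#' @param space list with `models` and `partition` as returned by the space
#'   constructors.
#' @param path JSON path.
#' @export
write_model_space <- function(space, path) {
  ser <- list(
    level = space$partition$level,
    families = space$partition$families,
    models = lapply(space$models, function(m) {
      list(name = m$name, family_id = m$family_id,
           a_mask = unname(apply(m$a_mask, 2, as.integer)),
           b_mask = lapply(m$b_mask, function(bm) unname(apply(bm, 2, as.integer))),
           c_mask = unname(apply(m$c_mask, 2, as.integer)))
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_space
#' @export
read_model_space <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  models <- lapply(seq_len(nrow_of(ser$models)), function(i) {
    m <- if (is.data.frame(ser$models)) lapply(ser$models, `[[`, i) else ser$models[[i]]
    bm <- m$b_mask
    if (is.array(bm) && length(dim(bm)) == 3) {
      bm <- lapply(seq_len(dim(bm)[1]), function(j) matrix(bm[j, , ], n_regions()))
    } else if (!is.list(bm)) bm <- list(as.matrix(bm))
    model_spec(name = m$name, a_mask = as.matrix(m$a_mask), b_mask = bm,
               c_mask = as.matrix(m$c_mask), family_id = m$family_id)
  })
  fams <- lapply(ser$families, as.integer)
  list(models = models,
       partition = family_partition(fams, ser$level, length(models)))
}

nrow_of <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
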