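#' The four-region self-regulation network
#'
#' Canonical region set used throughout the package: frontal cortex (F,
#' superior and middle frontal gyrus), anterior cingulate cortex (ACC,
#' subgenual/pregenual/supracallosal parts), striatum (S, putamen and nucleus
#' accumbens) and the supplementary motor area (SMA), the neurofeedback
#' target. Anatomical codes are the AAL3 atlas label numbers for each region,
#' used when extracting ROI summaries from voxel data.
#'
#' @return An object of class `region_set`: a list with `labels` (ordered
#'   region names) and `anatomical_codes` (named list of AAL3 integers).
#' @examples
#' region_set()
#' @export
region_set <- function() {
  structure(
    list(
      labels = c("F", "ACC", "S", "SMA"),
      anatomical_codes = list(
        F   = c(3L, 4L, 5L, 6L),
        ACC = c(151L, 152L, 153L, 154L, 155L, 156L),
        S   = c(78L, 80L, 157L, 158L),
        SMA = 16L
      )
    ),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", paste(x$labels, collapse = ", "), "\n")
  for (r in x$labels) {
    cat(sprintf("  %-4s AAL3 %s\n", r,
                paste(x$anatomical_codes[[r]], collapse = ",")))
  }
  invisible(x)
}

n_regions <- function() 4L

region_labels <- function() region_set()$labels

# index helper, accepts label or integer
.ridx <- function(r) {
  if (is.character(r)) match(r, region_labels()) else as.integer(r)
}
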