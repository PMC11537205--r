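#' Named multichannel intensity image
#'
#' Bundles a set of equally shaped, non-negative 2-D intensity arrays (one per
#' stain channel) with the physical pixel size. This is the raw substrate for
#' marker gating and nucleus localization.
#'
#' @param channels Named list of numeric matrices, all of identical dimension.
#'   Names are stain channel names (e.g. \code{"DAPI"}, \code{"CD4"}) and must
#'   be unique.
#' @param resolution_um_per_px Positive scalar, physical size of one pixel in
#'   micrometres.
#' @return An object of class \code{multiplex_image}.
#' @export
multiplex_image <- function(channels, resolution_um_per_px) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "") || anyDuplicated(names(channels))) {
    stop("`channels` must be a list with unique, non-empty names")
  }
  dims <- lapply(channels, dim)
  if (length(channels) > 0L) {
    d0 <- dims[[1L]]
    for (i in seq_along(channels)) {
      if (!is.matrix(channels[[i]]) || !is.numeric(channels[[i]])) {
        stop("channel '", names(channels)[i], "' is not a numeric matrix")
      }
      if (!identical(dims[[i]], d0)) {
        stop("channel '", names(channels)[i], "' has a different shape")
      }
      if (any(channels[[i]] < 0)) {
        stop("channel '", names(channels)[i], "' contains negative intensities")
      }
    }
  }
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      resolution_um_per_px <= 0) {
    stop("`resolution_um_per_px` must be a positive scalar")
  }
  structure(
    list(channels = channels, resolution_um_per_px = resolution_um_per_px),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- if (length(x$channels)) dim(x$channels[[1L]]) else c(0L, 0L)
  cat(sprintf(
    "<multiplex_image> %d x %d px, %.3g um/px, %d channel(s): %s\n",
    d[1L], d[2L], x$resolution_um_per_px, length(x$channels),
    paste(utils::head(names(x$channels), 8L), collapse = ", ")
  ))
  invisible(x)
}

#' Integer instance label map
#'
#' A single 2-D integer array assigning each pixel to one instance; 0 is
#' background, positive integers are instance ids (not necessarily
#' contiguous). Shared by segmentation, gating, patch extraction and matching.
#'
#' @param labels Integer (or whole-number numeric) matrix with values >= 0.
#' @return An object of class \code{instance_map} (the matrix, classed).
#' @export
instance_map <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop("`labels` must be a numeric matrix")
  }
  if (any(labels < 0) || any(labels != floor(labels))) {
    stop("`labels` must contain non-negative integers")
  }
  storage.mode(labels) <- "integer"
  structure(labels, class = c("instance_map", "matrix", "array"))
}

#' @export
print.instance_map <- function(x, ...) {
  ids <- instance_ids(x)
  cat(sprintf("<instance_map> %d x %d px, %d instance(s)\n",
              nrow(x), ncol(x), length(ids)))
  invisible(x)
}

#' Instance ids present in an instance map
#'
#' @param labels An \code{instance_map} or integer matrix.
#' @return Sorted integer vector of positive ids.
#' @export
instance_ids <- function(labels) {
  ids <- sort(unique(as.integer(labels)))
  ids[ids > 0L]
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so all package randomness flows through
# explicit seeds.
with_private_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
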