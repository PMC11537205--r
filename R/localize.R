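#' Segmentation configuration for the classical fallback segmenter
#'
#' @param smoothing_sigma_um Gaussian smoothing sigma in micrometres
#'   (>= 0; converted to pixels at run time).
#' @param threshold_method \code{"otsu"} or \code{"fixed"}.
#' @param fixed_threshold Required iff \code{threshold_method = "fixed"};
#'   intensity threshold on the merged channel.
#' @param min_instance_area_um2 Instances smaller than this are removed.
#' @param split_touching If \code{TRUE}, a distance-transform watershed
#'   splits merged blobs into separate instances.
#' @param include_goblets If \code{TRUE}, the nuclear merge adds Muc2 to
#'   DAPI so goblets are segmented alongside nuclei; if \code{FALSE}, only
#'   nuclei (DAPI) are segmented.
#' @return A list of class \code{seg_config}.
#' @export
seg_config <- function(smoothing_sigma_um = 1.0,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       min_instance_area_um2 = 3,
                       split_touching = TRUE,
                       include_goblets = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold is required when threshold_method = 'fixed'")
  }
  if (threshold_method == "otsu" && !is.null(fixed_threshold)) {
    stop("fixed_threshold must be NULL when threshold_method = 'otsu'")
  }
  if (smoothing_sigma_um < 0 || min_instance_area_um2 < 0) {
    stop("sigma and minimum area must be non-negative")
  }
  structure(list(smoothing_sigma_um = smoothing_sigma_um,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_instance_area_um2 = min_instance_area_um2,
                 split_touching = split_touching,
                 include_goblets = include_goblets),
            class = "seg_config")
}

#' Merge nuclear channels into one localization substrate
#'
#' Pixelwise sum of DAPI and Muc2 when goblets are to be segmented (DAPI
#' finds nuclei, Muc2 finds the goblets of goblet cells), else DAPI alone.
#'
#' @param image A \code{multiplex_image}.
#' @param include_goblets Logical.
#' @return A numeric matrix.
#' @export
merge_nuclear_channels <- function(image, include_goblets = TRUE) {
  if (is.null(image$channels$DAPI)) stop("channel error: DAPI channel missing")
  if (!include_goblets) return(image$channels$DAPI)
  if (is.null(image$channels$Muc2)) stop("channel error: Muc2 channel missing")
  image$channels$DAPI + image$channels$Muc2
}

#' Classical fallback instance segmenter
#'
#' Gaussian smoothing, global threshold (Otsu or fixed), connected
#' components, optional distance-transform watershed to split touching
#' blobs, and removal of instances below the minimum area. Output ids are
#' contiguous from 1. This is a dependency-free stand-in for a learned
#' instance segmenter so the pipeline runs with no pretrained weights; it
#' makes no claim of matching one.
#'
#' @param merged Numeric matrix (e.g. from
#'   \code{\link{merge_nuclear_channels}}).
#' @param config A \code{seg_config}.
#' @param resolution_um_per_px Pixel size of \code{merged}.
#' @return An \code{instance_map} (possibly empty).
#' @export
segment_fallback <- function(merged, config = seg_config(),
                             resolution_um_per_px) {
  stopifnot(inherits(config, "seg_config"))
  if (length(merged) == 0L) stop("merged image is empty")
  res <- resolution_um_per_px
  top <- max(merged)
  if (top <= 0) return(instance_map(matrix(0L, nrow(merged), ncol(merged))))
  img <- merged / top
  sigma_px <- config$smoothing_sigma_um / res
  if (sigma_px > 0) img <- EBImage::gblur(img, sigma = sigma_px)
  thr <- if (config$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  } else {
    config$fixed_threshold / top
  }
  mask <- img > thr
  if (!any(mask)) return(instance_map(matrix(0L, nrow(merged), ncol(merged))))
  lab <- if (config$split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(EBImage::Image(mask * 1))
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(merged), ncol(merged))
  min_px <- config$min_instance_area_um2 / res^2
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas > 0 & areas < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel contiguous from 1
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  instance_map(lab)
}

#' Validate and ingest an externally produced instance mask
#'
#' @param path Path to a single-channel integer TIFF/PNG mask
#'   (0 = background).
#' @param expected_dim Optional \code{c(rows, cols)} the mask must match.
#' @return An \code{instance_map}.
#' @export
ingest_mask <- function(path, expected_dim = NULL) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path) * 65535
  } else {
    tiff::readTIFF(path) * 65535
  }
  if (length(dim(m)) == 3L) stop("mask must be single-channel")
  imap <- instance_map(matrix(as.integer(round(m)), nrow(m), ncol(m)))
  if (!is.null(expected_dim) && !identical(dim(imap), as.integer(expected_dim))) {
    stop("mask dimensions ", paste(dim(imap), collapse = "x"),
         " do not match expected ", paste(expected_dim, collapse = "x"))
  }
  imap
}

# Keys cubic-convolution kernel, a = -0.5
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at < 1
  i2 <- !i1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * (at[i2]^3 - 5 * at[i2]^2 + 8 * at[i2] - 4)
  w
}

# n_out x n_in interpolation weight matrix for one axis, pixel-centre aligned
cubic_weight_matrix <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5   # 0-based source coords
  base <- floor(src)
  W <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    j <- base + k
    wt <- cubic_kernel(src - j)
    jc <- pmin(pmax(j, 0), n_in - 1)                     # clamp at the edges
    W[cbind(seq_len(n_out), jc + 1)] <-
      W[cbind(seq_len(n_out), jc + 1)] + wt
  }
  W / rowSums(W)
}

#' Resample an intensity image between physical resolutions
#'
#' Separable cubic-convolution (Keys, a = -0.5) interpolation with
#' pixel-centre alignment. Cubic interpolation can overshoot into small
#' negative intensities; those are clipped at 0 because intensities are
#' physical. Output shape is \code{round(shape * from_res / to_res)}.
#'
#' @param x Numeric matrix or \code{h x w x k} array.
#' @param from_res,to_res Positive resolutions in um/px.
#' @return Resampled matrix/array with a \code{resolution_um_per_px}
#'   attribute.
#' @export
resample_image <- function(x, from_res, to_res) {
  if (from_res <= 0 || to_res <= 0) stop("resolutions must be positive")
  d <- dim(x)
  n_out <- pmax(1L, as.integer(round(d[1:2] * from_res / to_res)))
  if (identical(as.integer(d[1:2]), n_out) && isTRUE(all.equal(from_res, to_res))) {
    attr(x, "resolution_um_per_px") <- to_res
    return(x)
  }
  Wr <- cubic_weight_matrix(d[1], n_out[1])
  Wc <- cubic_weight_matrix(d[2], n_out[2])
  resample_plane <- function(m) pmax(Wr %*% m %*% t(Wc), 0)
  out <- if (length(d) == 2L) {
    resample_plane(x)
  } else {
    arr <- array(0, c(n_out, d[3]))
    for (k in seq_len(d[3])) arr[, , k] <- resample_plane(x[, , k])
    arr
  }
  attr(out, "resolution_um_per_px") <- to_res
  out
}

#' Resample an instance map between physical resolutions
#'
#' Nearest-neighbour lookup so labels are preserved: the output value set is
#' always a subset of the input's ids (no new ids can appear).
#'
#' @param instances An \code{instance_map}.
#' @param from_res,to_res Positive resolutions in um/px.
#' @return An \code{instance_map} of shape
#'   \code{round(shape * from_res / to_res)}.
#' @export
resample_labels <- function(instances, from_res, to_res) {
  if (from_res <= 0 || to_res <= 0) stop("resolutions must be positive")
  d <- dim(instances)
  n_out <- pmax(1L, as.integer(round(d * from_res / to_res)))
  nearest_idx <- function(n_in, n_o) {
    src <- (seq_len(n_o) - 0.5) * (n_in / n_o) - 0.5
    pmin(pmax(round(src), 0), n_in - 1) + 1
  }
  ri <- nearest_idx(d[1], n_out[1])
  ci <- nearest_idx(d[2], n_out[2])
  instance_map(unclass(instances)[ri, ci, drop = FALSE])
}
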