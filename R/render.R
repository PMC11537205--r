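#' Deterministic pseudo-H&E rendering
#'
#' Maps a synthetic MxIF tissue to a fixed analytic 3-channel colour image:
#' instance pixels whose DAPI dominates render hematoxylin purple-blue
#' scaled by DAPI intensity, Muc2-dominated instance pixels (goblets) render
#' pale, and all remaining pixels render eosin pink. The mapping is a fixed
#' colour map, not a learned model, so identical tissues give identical
#' renderings; class-correlated morphology (size, eccentricity, chromatin
#' texture) passes straight through from the instance geometry and the DAPI
#' channel, which is what makes a subset of classes learnable from the
#' rendering alone.
#'
#' @param tissue A \code{synthetic_tissue}.
#' @param intensity_scale Nominal full-scale nuclear intensity used to map
#'   DAPI/Muc2 to [0, 1] (default 200).
#' @return An \code{height x width x 3} array in [0, 1] with a
#'   \code{resolution_um_per_px} attribute.
#' @export
render_pseudo_he <- function(tissue, intensity_scale = 200) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  chans <- tissue$image$channels
  if (is.null(chans$DAPI)) stop("channel error: DAPI channel is required")
  muc2 <- chans$Muc2
  if (is.null(muc2)) muc2 <- matrix(0, nrow(chans$DAPI), ncol(chans$DAPI))

  pink <- c(0.91, 0.70, 0.80)    # eosin tissue
  purple <- c(0.33, 0.23, 0.52)  # hematoxylin nuclei
  pale <- c(0.93, 0.91, 0.95)    # goblet mucin

  h <- nrow(chans$DAPI); w <- ncol(chans$DAPI)
  fg <- tissue$instances > 0L
  dapi_v <- pmin(pmax(chans$DAPI / intensity_scale, 0), 1)
  muc_v <- pmin(pmax(muc2 / intensity_scale, 0), 1)
  nuc <- fg & (chans$DAPI >= muc2)
  gob <- fg & (chans$DAPI < muc2)

  out <- array(0, c(h, w, 3L))
  for (k in 1:3) {
    plane <- matrix(pink[k], h, w)
    plane[nuc] <- pink[k] + (purple[k] - pink[k]) * dapi_v[nuc]
    plane[gob] <- pink[k] + (pale[k] - pink[k]) * muc_v[gob]
    out[, , k] <- plane
  }
  attr(out, "resolution_um_per_px") <- tissue$image$resolution_um_per_px
  out
}

#' Relative luminance of an RGB array
#'
#' @param rgb An \code{h x w x 3} array in [0, 1].
#' @return Matrix of Rec. 709 luminance values.
#' @export
luminance <- function(rgb) {
  0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
}
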