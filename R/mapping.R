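#' Fine-to-parent class mapping
#'
#' Scoring fine-grained predictions against coarser labels needs a total map
#' from each evaluated fine class to a parent class, plus a set of fine
#' classes that are simply dropped because the coarse label set has no
#' counterpart (goblets, whose label is the mucin blob rather than a
#' nucleus, are the canonical example).
#'
#' @param map Named character vector: fine class -> parent class.
#' @param droppable Character vector of fine classes with no parent.
#' @return An object of class \code{class_mapping}.
#' @export
class_mapping <- function(map, droppable = character()) {
  map <- unlist(map)
  if (length(map) && (is.null(names(map)) || any(names(map) == ""))) {
    stop("`map` must be named by fine class")
  }
  if (anyDuplicated(names(map))) stop("duplicate fine classes in `map`")
  if (length(intersect(names(map), droppable))) {
    stop("a fine class cannot be both mapped and droppable")
  }
  structure(list(map = map, droppable = as.character(droppable)),
            class = "class_mapping")
}

#' Default colon fine-to-parent mapping
#'
#' The five documented correspondences — helper T to lymphocyte, enterocyte
#' to epithelial, progenitor to epithelial, fibroblast to connective,
#' stromal (undetermined) to connective — extended with the natural lineage
#' parents for the remaining lymphocyte subtypes; goblet and the myeloid/
#' leukocyte catch-all classes are droppable (no counterpart among the six
#' coarse nucleus classes).
#'
#' @return A \code{class_mapping}.
#' @export
default_class_mapping <- function() {
  class_mapping(
    c(helper_t = "lymphocyte", cytotoxic_t = "lymphocyte",
      cd3_t = "lymphocyte", b_cell = "lymphocyte",
      enterocyte = "epithelial", progenitor = "epithelial",
      enteroendocrine = "epithelial",
      fibroblast = "connective", stromal_undetermined = "connective"),
    droppable = c("goblet", "macrophage", "monocyte", "myeloid_other",
                  "leukocyte_other")
  )
}

#' Read / write a class mapping as JSON
#'
#' On-disk form: \code{{"map": {"helper_t": "lymphocyte", ...},
#' "droppable": [...]}}.
#'
#' @param path JSON path.
#' @param mapping A \code{class_mapping}.
#' @return \code{read_class_mapping}: a \code{class_mapping};
#'   \code{write_class_mapping}: invisibly, \code{path}.
#' @export
read_class_mapping <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  class_mapping(raw$map, raw$droppable %||% character())
}

#' @rdname read_class_mapping
#' @export
write_class_mapping <- function(mapping, path) {
  jsonlite::write_json(
    list(map = as.list(mapping$map), droppable = mapping$droppable),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Map fine class labels to parent labels
#'
#' @param classes Character vector of fine class names.
#' @param mapping A \code{class_mapping}.
#' @return Character vector of parent labels; droppable classes become
#'   \code{NA}. An unmapped, undroppable class is an error naming the class.
#' @export
apply_class_mapping <- function(classes, mapping) {
  out <- rep(NA_character_, length(classes))
  mapped <- classes %in% names(mapping$map)
  out[mapped] <- unname(mapping$map[classes[mapped]])
  bad <- !mapped & !(classes %in% mapping$droppable)
  if (any(bad)) {
    stop("mapping error: unmapped, undropped class(es): ",
         paste(unique(classes[bad]), collapse = ", "))
  }
  out
}

#' Build a coarse-parent-labeled evaluation set
#'
#' Emulates an external real-H&E evaluation set: each tissue is rendered to
#' pseudo-H&E, resampled to 0.5 um/px, given a per-site affine colour shift
#' (a deterministic stand-in for inter-site stain variation), and cut into
#' square tiles. Fine truth labels are replaced by parent labels via the
#' mapping; instances of droppable classes (always the goblets when
#' \code{include_goblets = FALSE}) are removed from the label tables.
#'
#' @param tissues List of \code{synthetic_tissue} objects.
#' @param mapping A \code{class_mapping}; must cover (or drop) every fine
#'   class present.
#' @param tile_px Tile side in pixels (default 256).
#' @param target_res_um_per_px Output resolution (default 0.5 um/px).
#' @param include_goblets If \code{FALSE} (the nuclei-only regime), goblet
#'   instances are dropped from the label tables even when mapped.
#' @param site_gain,site_offset Optional named numeric vectors (by site id)
#'   of affine colour-shift parameters; unnamed sites get deterministic
#'   defaults spread around gain 1, offset 0.
#' @return List of tile records: each a list with \code{tile}
#'   (\code{tile_px x tile_px x 3} in [0, 1]), \code{instances}
#'   (\code{instance_map} crop), \code{cells} (parent-labeled table with
#'   tile-local 0-based centroids) and \code{site_id}.
#' @export
generate_parent_labeled_set <- function(tissues, mapping = default_class_mapping(),
                                        tile_px = 256L,
                                        target_res_um_per_px = 0.5,
                                        include_goblets = FALSE,
                                        site_gain = NULL, site_offset = NULL) {
  sites <- unique(vapply(tissues, function(t) t$site_id, ""))
  if (is.null(site_gain)) {
    site_gain <- stats::setNames(1 + 0.08 * ((seq_along(sites) - 1) %% 3 - 1),
                                 sites)
  }
  if (is.null(site_offset)) {
    site_offset <- stats::setNames(0.03 * ((seq_along(sites) - 1) %% 2),
                                   sites)
  }
  records <- list()
  for (tissue in tissues) {
    he <- render_pseudo_he(tissue)
    from_res <- tissue$image$resolution_um_per_px
    rgb <- resample_image(he, from_res, target_res_um_per_px)
    rgb <- pmin(rgb, 1)
    imap <- resample_labels(tissue$instances, from_res, target_res_um_per_px)
    g <- site_gain[[tissue$site_id]] %||% 1
    b <- site_offset[[tissue$site_id]] %||% 0
    rgb <- pmin(pmax(g * rgb + b, 0), 1)

    truth <- tissue$truth
    parent <- apply_class_mapping(truth$class, mapping)
    if (!include_goblets) parent[truth$class == "goblet"] <- NA_character_
    cents <- instance_centroids(imap)

    nr <- floor(nrow(imap) / tile_px); nc <- floor(ncol(imap) / tile_px)
    for (ti in seq_len(nr)) {
      for (tj in seq_len(nc)) {
        r0 <- (ti - 1L) * tile_px; c0 <- (tj - 1L) * tile_px
        rows <- (r0 + 1L):(r0 + tile_px); cols <- (c0 + 1L):(c0 + tile_px)
        sub_map <- instance_map(unclass(imap)[rows, cols, drop = FALSE])
        keep <- cents$centroid_row >= r0 & cents$centroid_row < r0 + tile_px &
          cents$centroid_col >= c0 & cents$centroid_col < c0 + tile_px
        ids <- cents$instance_id[keep]
        tab <- data.frame(
          instance_id = ids,
          class = parent[match(ids, truth$instance_id)],
          centroid_row = cents$centroid_row[keep] - r0,
          centroid_col = cents$centroid_col[keep] - c0,
          slide_id = tissue$slide_id, patient_id = tissue$patient_id,
          site_id = tissue$site_id, stringsAsFactors = FALSE
        )
        tab <- tab[!is.na(tab$class), , drop = FALSE]
        records[[length(records) + 1L]] <- list(
          tile = rgb[rows, cols, , drop = FALSE],
          instances = sub_map, cells = tab, site_id = tissue$site_id)
      }
    }
  }
  records
}
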