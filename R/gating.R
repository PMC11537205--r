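#' Per-instance mean channel intensities and centroids
#'
#' Builds the cell table skeleton: one row per instance id with the
#' arithmetic mean of every channel over the instance's pixels and the
#' unweighted centroid of its pixel coordinates (0-based row/col).
#'
#' @param image A \code{multiplex_image}.
#' @param instances An \code{instance_map} of the same shape.
#' @return A data frame with columns \code{instance_id},
#'   \code{centroid_row}, \code{centroid_col}, \code{area_px} and one
#'   \code{mean_<channel>} column per channel. Zero rows if the map has no
#'   instances.
#' @export
mean_intensity_per_instance <- function(image, instances) {
  if (length(image$channels) > 0L &&
      !identical(dim(image$channels[[1L]]), dim(instances))) {
    stop("image channels and instance map have different shapes")
  }
  out <- instance_centroids(instances)
  if (nrow(out) == 0L) {
    for (ch in names(image$channels)) out[[paste0("mean_", ch)]] <- numeric()
    return(out)
  }
  ids <- out$instance_id
  fg <- which(instances > 0L)
  lab <- factor(instances[fg], levels = ids)
  for (ch in names(image$channels)) {
    out[[paste0("mean_", ch)]] <-
      as.numeric(rowsum(image$channels[[ch]][fg], lab)) / out$area_px
  }
  out
}

#' Instance centroids and areas
#'
#' Centroid is the unweighted mean of member pixel coordinates, 0-based
#' (row, col).
#'
#' @param instances An \code{instance_map}.
#' @return Data frame with \code{instance_id, centroid_row, centroid_col,
#'   area_px}; zero rows for an empty map.
#' @export
instance_centroids <- function(instances) {
  ids <- instance_ids(instances)
  if (length(ids) == 0L) {
    return(data.frame(instance_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer()))
  }
  fg <- which(instances > 0L)
  lab <- factor(instances[fg], levels = ids)
  # 0-based pixel coordinates; R matrices are column-major, 1-based
  rows0 <- (fg - 1L) %% nrow(instances)
  cols0 <- (fg - 1L) %/% nrow(instances)
  area <- as.integer(tabulate(lab, nbins = length(ids)))
  data.frame(
    instance_id = ids,
    centroid_row = as.numeric(rowsum(rows0, lab)) / area,
    centroid_col = as.numeric(rowsum(cols0, lab)) / area,
    area_px = area
  )
}

#' Per-slide per-channel positivity thresholds
#'
#' @param thresholds Named numeric vector (or list) of positive thresholds,
#'   one per gating channel, scoped to one slide.
#' @return Named numeric vector of class \code{threshold_set}.
#' @export
threshold_set <- function(thresholds) {
  thr <- unlist(thresholds)
  if (is.null(names(thr)) || any(names(thr) == "") || anyDuplicated(names(thr))) {
    stop("thresholds must be uniquely named by channel")
  }
  if (!is.numeric(thr) || any(thr <= 0)) stop("thresholds must be positive")
  structure(thr, class = "threshold_set")
}

#' Read per-slide thresholds from JSON or CSV
#'
#' JSON form is keyed by slide then channel
#' (\code{{"slide1": {"DAPI": 100, ...}, ...}}); CSV form has columns
#' \code{slide_id, channel, threshold}.
#'
#' @param path Path to a \code{.json} or \code{.csv} file.
#' @return Named list of \code{threshold_set}, one per slide.
#' @export
read_threshold_sets <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    sets <- split(df, df$slide_id)
    lapply(sets, function(s) threshold_set(stats::setNames(s$threshold, s$channel)))
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(raw, threshold_set)
  }
}

#' Apply stain-wise thresholds to per-instance mean intensities
#'
#' A call is positive iff the mean intensity strictly exceeds the channel's
#' threshold (a mean exactly at threshold is negative), mirroring manual
#' stain-wise gating applied per whole-slide image.
#'
#' @param cells Cell table from \code{\link{mean_intensity_per_instance}}.
#' @param thresholds A \code{threshold_set} covering every channel to call;
#'   by default every \code{mean_<channel>} column present is called.
#' @param channels Optional character vector restricting which channels get
#'   calls (e.g. the gating channels only).
#' @return The cell table with one logical \code{call_<channel>} column added
#'   per called channel.
#' @export
apply_thresholds <- function(cells, thresholds, channels = NULL) {
  have <- sub("^mean_", "", grep("^mean_", names(cells), value = TRUE))
  channels <- channels %||% have
  missing_mean <- setdiff(channels, have)
  if (length(missing_mean)) {
    stop("no mean intensity for channel(s): ", paste(missing_mean, collapse = ", "))
  }
  missing_thr <- setdiff(channels, names(thresholds))
  if (length(missing_thr)) {
    stop("missing threshold for channel(s): ", paste(missing_thr, collapse = ", "))
  }
  for (ch in channels) {
    cells[[paste0("call_", ch)]] <- cells[[paste0("mean_", ch)]] > thresholds[[ch]]
  }
  cells
}

#' Assign one class per instance by the ordered rule cascade
#'
#' Walks the rule table in order; the first rule whose required-positive
#' channels are all called positive and required-negative channels all called
#' negative assigns its class. Instances matching no rule are labelled
#' \code{"unclassified"}. Every instance receives exactly one label.
#'
#' @param cells Cell table with \code{call_<channel>} columns covering every
#'   channel any rule references.
#' @param rules A \code{rule_table}.
#' @return The cell table with a \code{class} column filled.
#' @export
assign_class <- function(cells, rules) {
  needed <- rule_channels(rules)
  missing_call <- setdiff(paste0("call_", needed), names(cells))
  if (length(missing_call)) {
    stop("rules reference uncalled channel(s): ",
         paste(sub("^call_", "", missing_call), collapse = ", "))
  }
  n <- nrow(cells)
  cls <- rep.int("unclassified", n)
  open <- rep.int(TRUE, n)
  for (r in rules) {
    if (!any(open)) break
    hit <- open
    for (ch in r$positive) hit <- hit & cells[[paste0("call_", ch)]]
    for (ch in r$negative) hit <- hit & !cells[[paste0("call_", ch)]]
    cls[hit] <- r$class
    open <- open & !hit
  }
  cells$class <- cls
  cells
}

#' Gate a multiplex image end to end
#'
#' Convenience wrapper: per-instance mean intensities, stain calls on the
#' channels the rule table references, then rule-cascade class assignment.
#'
#' @param image A \code{multiplex_image}.
#' @param instances An \code{instance_map}.
#' @param rules A \code{rule_table} (default the packaged 14-class table).
#' @param thresholds A \code{threshold_set} covering the rule channels.
#' @param slide_id,patient_id,site_id Optional provenance strings copied onto
#'   every row.
#' @return A gated cell table (one row per instance, exactly one class each).
#' @export
gate_cells <- function(image, instances, thresholds,
                       rules = default_rule_table(),
                       slide_id = NA_character_, patient_id = NA_character_,
                       site_id = NA_character_) {
  cells <- mean_intensity_per_instance(image, instances)
  cells <- apply_thresholds(cells, thresholds, channels = rule_channels(rules))
  cells <- assign_class(cells, rules)
  cells$slide_id <- slide_id
  cells$patient_id <- patient_id
  cells$site_id <- site_id
  cells
}

#' Write / read a cell table as CSV
#'
#' @param cells Cell table data frame.
#' @param path CSV path.
#' @return \code{write_cell_table}: invisibly, \code{path};
#'   \code{read_cell_table}: the data frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
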