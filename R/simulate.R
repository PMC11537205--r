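#' Default class mixture for simulated colon tissue
#'
#' Proportions loosely follow colonic mucosa composition: epithelium
#' (enterocytes, goblets, progenitors) dominates, enteroendocrine cells are
#' rare, and lamina-propria immune and stromal populations fill the rest.
#' Every one of the 14 classes is present so all gating rules are exercised.
#'
#' @return Named numeric vector over the 14 classes, summing to 1.
#' @export
default_class_mixture <- function() {
  c(enterocyte = 0.20, goblet = 0.10, progenitor = 0.08,
    enteroendocrine = 0.03, fibroblast = 0.10, stromal_undetermined = 0.10,
    leukocyte_other = 0.06, b_cell = 0.05, cd3_t = 0.04,
    helper_t = 0.08, cytotoxic_t = 0.06, macrophage = 0.04,
    monocyte = 0.03, myeloid_other = 0.03)
}

#' Default per-class nucleus/cell geometry
#'
#' Semi-major axis range (um), eccentricity range, and a chromatin "dome"
#' factor (0 = flat DAPI, larger = centre-bright) per class. Geometry is the
#' only class signal that survives pseudo-H&E rendering and per-patch
#' normalization, so it encodes which classes are learnable from the
#' rendering:
#' \itemize{
#'   \item designed-separable (distinct size/shape/texture): goblet,
#'     enterocyte, progenitor, enteroendocrine, fibroblast, macrophage;
#'   \item designed-unlearnable pair: helper_t and cytotoxic_t share
#'     identical geometry and differ only in CD4/CD8, channels invisible in
#'     the rendering;
#'   \item remaining classes overlap each other moderately, as real
#'     lamina-propria populations do on H&E.
#' }
#'
#' @return Data frame with columns \code{class, r_min_um, r_max_um, ecc_min,
#'   ecc_max, dome}.
#' @export
default_class_geometry <- function() {
  g <- rbind(
    c("goblet",               6.0, 7.5, 0.00, 0.30, 0.00),
    c("enterocyte",           5.2, 5.8, 0.75, 0.85, 0.15),
    c("progenitor",           4.1, 4.6, 0.00, 0.15, 0.55),
    c("enteroendocrine",      1.7, 2.1, 0.00, 0.20, 0.00),
    c("fibroblast",           4.3, 4.9, 0.90, 0.96, 0.10),
    c("macrophage",           5.9, 6.5, 0.00, 0.20, 0.00),
    c("stromal_undetermined", 3.8, 4.2, 0.40, 0.60, 0.25),
    c("leukocyte_other",      3.5, 3.8, 0.20, 0.40, 0.25),
    c("b_cell",               3.4, 3.7, 0.00, 0.20, 0.30),
    c("cd3_t",                3.7, 4.0, 0.10, 0.30, 0.30),
    c("helper_t",             2.9, 3.2, 0.00, 0.15, 0.30),
    c("cytotoxic_t",          2.9, 3.2, 0.00, 0.15, 0.30),
    c("monocyte",             4.9, 5.2, 0.25, 0.40, 0.20),
    c("myeloid_other",        4.3, 4.6, 0.55, 0.70, 0.15)
  )
  data.frame(class = g[, 1],
             r_min_um = as.numeric(g[, 2]), r_max_um = as.numeric(g[, 3]),
             ecc_min = as.numeric(g[, 4]), ecc_max = as.numeric(g[, 5]),
             dome = as.numeric(g[, 6]), stringsAsFactors = FALSE)
}

#' Classes designed to be learnable / unlearnable from the rendering
#'
#' @return \code{designed_separable_classes}: classes given mutually distinct
#'   geometry so a rendering-only classifier can recover them;
#'   \code{designed_unlearnable_pair}: the two classes that are identical
#'   except for gating channels invisible in the pseudo-H&E (the designed
#'   negative control).
#' @export
designed_separable_classes <- function() {
  c("goblet", "enterocyte", "progenitor", "enteroendocrine",
    "fibroblast", "macrophage")
}

#' @rdname designed_separable_classes
#' @export
designed_unlearnable_pair <- function() {
  c("helper_t", "cytotoxic_t")
}

#' Marker profile derived from a rule table
#'
#' For each class, the "on" channels are exactly the required-positive
#' channels of its rule(s) (both Sox9 and OLFM4 for progenitor); all other
#' gating channels are "off". With zero noise this realizes the key-stain
#' mapping exactly: each class sits above threshold precisely on its
#' defining stains, so the cascade recovers it.
#'
#' @param rules A \code{rule_table}.
#' @return Named list: class -> character vector of on channels.
#' @export
default_marker_profile <- function(rules = default_rule_table()) {
  prof <- list()
  for (r in rules) {
    prof[[r$class]] <- sort(unique(c(prof[[r$class]], r$positive)))
  }
  prof
}

#' Simulation configuration
#'
#' Assembles and validates the generator's study conditions. Defaults: a
#' 1024 x 1024 px slide at 0.32 um/px, 600 cells drawn from
#' \code{\link{default_class_mixture}}, marker on/off means 180/20 with
#' per-channel threshold 100, Gaussian noise SD 10, and 10 nuisance channels
#' (17 gating + 10 = a 27-channel panel).
#'
#' @param image_height_px,image_width_px Positive integers.
#' @param resolution_um_per_px Positive pixel size (um).
#' @param n_cells Non-negative integer.
#' @param class_mixture Named non-negative proportions over classes, summing
#'   to 1 within 1e-9.
#' @param geometry Per-class geometry table (see
#'   \code{\link{default_class_geometry}}).
#' @param marker_profile Named list class -> on channels.
#' @param on_mean,off_mean On/off channel means; must straddle the
#'   thresholds.
#' @param noise_sd Gaussian noise standard deviation (>= 0), applied to every
#'   channel and clipped at 0.
#' @param thresholds Named per-channel positivity thresholds.
#' @param n_nuisance_channels Non-negative integer count of extra non-gating
#'   channels.
#' @param min_gap_um Minimum clearance between cell boundaries (um).
#' @param rules Rule table used to validate that the profile gates back to
#'   the intended class at zero noise.
#' @param seed Integer; the single source of randomness.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(image_height_px = 1024L, image_width_px = 1024L,
                       resolution_um_per_px = 0.32, n_cells = 600L,
                       class_mixture = default_class_mixture(),
                       geometry = default_class_geometry(),
                       marker_profile = default_marker_profile(),
                       on_mean = 180, off_mean = 20, noise_sd = 10,
                       thresholds = NULL, n_nuisance_channels = 10L,
                       min_gap_um = 0.6, rules = default_rule_table(),
                       seed = 1L) {
  if (image_height_px < 1 || image_width_px < 1) stop("image size must be positive")
  if (resolution_um_per_px <= 0) stop("resolution must be positive")
  if (n_cells < 0) stop("n_cells must be non-negative")
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture proportions must sum to 1 (got ", sum(class_mixture), ")")
  }
  if (any(class_mixture < 0)) stop("class_mixture proportions must be non-negative")
  gating_channels <- rule_channels(rules)
  if (is.null(thresholds)) {
    thresholds <- stats::setNames(rep(100, length(gating_channels)),
                                  gating_channels)
  }
  thresholds <- threshold_set(thresholds)
  missing_chan <- setdiff(gating_channels, names(thresholds))
  if (length(missing_chan)) {
    stop("thresholds missing gating channel(s): ",
         paste(missing_chan, collapse = ", "))
  }
  if (off_mean > min(thresholds[gating_channels]) ||
      on_mean <= max(thresholds[gating_channels])) {
    stop("on/off means must straddle the thresholds (off <= thr < on)")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  used <- names(class_mixture)[class_mixture > 0]
  if (length(bad <- setdiff(used, geometry$class))) {
    stop("no geometry for class(es): ", paste(bad, collapse = ", "))
  }
  if (length(bad <- setdiff(used, names(marker_profile)))) {
    stop("no marker profile for class(es): ", paste(bad, collapse = ", "))
  }
  # zero-noise round-trip: each class's on/off pattern must gate back to it
  calls <- as.data.frame(
    lapply(stats::setNames(gating_channels, paste0("call_", gating_channels)),
           function(ch) vapply(used, function(cl) ch %in% marker_profile[[cl]], NA))
  )
  calls$instance_id <- seq_along(used)
  gated <- assign_class(calls, rules)$class
  if (!all(gated == used)) {
    off_cl <- used[gated != used]
    stop("marker profile does not gate back to its class for: ",
         paste(off_cl, collapse = ", "))
  }
  structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         resolution_um_per_px = resolution_um_per_px,
         n_cells = as.integer(n_cells), class_mixture = class_mixture,
         geometry = geometry, marker_profile = marker_profile,
         on_mean = on_mean, off_mean = off_mean, noise_sd = noise_sd,
         thresholds = thresholds,
         n_nuisance_channels = as.integer(n_nuisance_channels),
         min_gap_um = min_gap_um, rules = rules, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate one synthetic MxIF tissue
#'
#' Draws cell classes multinomially from the configured mixture, places
#' non-overlapping elliptical cells by rejection sampling of centres
#' (largest first, minimum centre distance = sum of semi-major axes plus the
#' configured gap), rasterizes them into an instance map, and fills each
#' channel with its class-consistent on/off mean plus Gaussian noise clipped
#' at zero. DAPI carries a per-class radial "dome" texture; goblets are
#' Muc2-only blobs with no DAPI. All randomness flows through
#' \code{config$seed}: equal seeds give bit-identical output.
#'
#' @param config A \code{sim_config}.
#' @param slide_id,patient_id,site_id Provenance strings recorded in the
#'   truth table.
#' @return An object of class \code{synthetic_tissue}: list with
#'   \code{image} (a \code{multiplex_image}), \code{instances} (an
#'   \code{instance_map}), \code{truth} (cell table with true \code{class}
#'   per instance) and the provenance ids.
#' @export
generate_tissue <- function(config, slide_id = "slide01",
                            patient_id = "patient01", site_id = "site01") {
  stopifnot(inherits(config, "sim_config"))
  h <- config$image_height_px; w <- config$image_width_px
  res <- config$resolution_um_per_px
  with_private_seed(config$seed, {
    labels <- matrix(0L, h, w)
    gch <- rule_channels(config$rules)
    nuisance <- if (config$n_nuisance_channels > 0L) {
      sprintf("nuisance_%02d", seq_len(config$n_nuisance_channels))
    } else character()
    all_ch <- c(gch, nuisance)

    n <- config$n_cells
    if (n == 0L) {
      channels <- lapply(stats::setNames(all_ch, all_ch), function(ch) {
        m <- matrix(config$off_mean, h, w)
        if (config$noise_sd > 0) m <- m + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
        pmax(m, 0)
      })
      truth <- data.frame(instance_id = integer(), class = character(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          area_px = integer(), slide_id = character(),
                          patient_id = character(), site_id = character())
      return(structure(
        list(image = multiplex_image(channels, res),
             instances = instance_map(labels), truth = truth,
             slide_id = slide_id, patient_id = patient_id, site_id = site_id),
        class = "synthetic_tissue"))
    }

    classes <- sample(names(config$class_mixture), n, replace = TRUE,
                      prob = config$class_mixture)
    geo <- config$geometry[match(classes, config$geometry$class), ]
    a_um <- stats::runif(n, geo$r_min_um, geo$r_max_um)
    ecc <- stats::runif(n, geo$ecc_min, geo$ecc_max)
    b_um <- a_um * sqrt(1 - ecc^2)
    theta <- stats::runif(n, 0, pi)

    ord <- order(a_um, decreasing = TRUE)   # place big cells first
    a_px <- a_um / res; b_px <- b_um / res
    gap_px <- config$min_gap_um / res
    cy <- numeric(n); cx <- numeric(n)
    placed <- logical(n)
    for (k in ord) {
      margin <- a_px[k] + 1
      if (2 * margin >= min(h, w)) {
        stop("packing error: cell radius exceeds image for ", sum(!placed),
             " remaining cell(s)")
      }
      ok <- FALSE
      for (attempt in seq_len(300L)) {
        y <- stats::runif(1, margin, h - margin)
        x <- stats::runif(1, margin, w - margin)
        if (any(placed)) {
          d2 <- (cy[placed] - y)^2 + (cx[placed] - x)^2
          mind <- (a_px[placed] + a_px[k] + gap_px)^2
          if (any(d2 < mind)) next
        }
        cy[k] <- y; cx[k] <- x; placed[k] <- TRUE; ok <- TRUE
        break
      }
      if (!ok) {
        stop("packing error: could not place ", sum(!placed),
             " of ", n, " cells; reduce n_cells or enlarge the image")
      }
    }

    # rasterize ellipses; q is the normalized squared radius inside [0, 1]
    qmap <- matrix(NA_real_, h, w)
    for (k in seq_len(n)) {
      r0 <- ceiling(max(1, cy[k] - a_px[k])):floor(min(h, cy[k] + a_px[k]))
      c0 <- ceiling(max(1, cx[k] - a_px[k])):floor(min(w, cx[k] + a_px[k]))
      dy <- r0 - cy[k]; dx <- c0 - cx[k]
      # axis-aligned offsets rotated into the ellipse frame
      u <- outer(dy, dx, function(yy, xx) yy * cos(theta[k]) + xx * sin(theta[k]))
      v <- outer(dy, dx, function(yy, xx) -yy * sin(theta[k]) + xx * cos(theta[k]))
      q <- (u / a_px[k])^2 + (v / b_px[k])^2
      inside <- q <= 1
      sub <- labels[r0, c0, drop = FALSE]
      sub[inside] <- k
      labels[r0, c0] <- sub
      qsub <- qmap[r0, c0, drop = FALSE]
      qsub[inside] <- q[inside]
      qmap[r0, c0] <- qsub
    }

    fg <- which(labels > 0L)
    lab_fg <- labels[fg]
    dome <- geo$dome[lab_fg]
    dapi_factor <- 1 - dome * qmap[fg]

    channels <- vector("list", length(all_ch))
    names(channels) <- all_ch
    for (ch in all_ch) {
      m <- matrix(config$off_mean, h, w)
      if (ch %in% gch) {
        on_cell <- vapply(classes, function(cl)
          ch %in% config$marker_profile[[cl]], NA)
        sel <- fg[on_cell[lab_fg]]
        val <- config$on_mean
        if (ch == "DAPI") {
          m[sel] <- val * dapi_factor[on_cell[lab_fg]]
        } else {
          m[sel] <- val
        }
      } else {
        # nuisance channels light up all instances at an intermediate level
        m[fg] <- (config$on_mean + config$off_mean) / 2
      }
      if (config$noise_sd > 0) {
        m <- m + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
      }
      channels[[ch]] <- pmax(m, 0)
    }

    image <- multiplex_image(channels, res)
    imap <- instance_map(labels)
    base <- instance_centroids(imap)
    truth <- data.frame(
      instance_id = base$instance_id,
      class = classes[base$instance_id],
      centroid_row = base$centroid_row,
      centroid_col = base$centroid_col,
      area_px = base$area_px,
      slide_id = slide_id, patient_id = patient_id, site_id = site_id,
      stringsAsFactors = FALSE
    )
    structure(
      list(image = image, instances = imap, truth = truth,
           slide_id = slide_id, patient_id = patient_id, site_id = site_id),
      class = "synthetic_tissue")
  })
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> %s / %s / %s: %d instance(s), %d channel(s)\n",
              x$slide_id, x$patient_id, x$site_id, nrow(x$truth),
              length(x$image$channels)))
  invisible(x)
}

#' Write a synthetic tissue to disk
#'
#' Channels go to one multichannel TIFF (channel names in a JSON sidecar),
#' the instance map to a 16-bit single-channel TIFF, the truth table to CSV,
#' and the provenance/resolution to a YAML config.
#'
#' @param tissue A \code{synthetic_tissue}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_tissue <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- tissue$image$channels
  scale <- max(1, max(vapply(chans, max, 0)))
  tiff::writeTIFF(lapply(chans, function(m) m / scale),
                  file.path(dir, "channels.tif"), bits.per.sample = 16L)
  jsonlite::write_json(
    list(channel_names = names(chans), intensity_scale = scale),
    file.path(dir, "channels.json"), auto_unbox = TRUE)
  write_instance_map(tissue$instances, file.path(dir, "instances.tif"))
  write_cell_table(tissue$truth, file.path(dir, "truth.csv"))
  yaml::write_yaml(
    list(slide_id = tissue$slide_id, patient_id = tissue$patient_id,
         site_id = tissue$site_id,
         resolution_um_per_px = tissue$image$resolution_um_per_px),
    file.path(dir, "tissue.yaml"))
  invisible(dir)
}

#' Write / read an instance map as 16-bit single-channel TIFF
#'
#' @param instances An \code{instance_map} (ids must fit in 16 bits).
#' @param path TIFF path.
#' @return \code{write_instance_map}: invisibly, \code{path};
#'   \code{read_instance_map}: an \code{instance_map}.
#' @export
write_instance_map <- function(instances, path) {
  if (max(instances, 0L) > 65535L) stop("instance ids exceed 16-bit range")
  tiff::writeTIFF(matrix(as.numeric(instances) / 65535,
                         nrow(instances), ncol(instances)),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_instance_map
#' @export
read_instance_map <- function(path) {
  m <- tiff::readTIFF(path)
  instance_map(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}
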