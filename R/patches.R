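#' Extract centered, normalized classification patches
#'
#' Cuts one square patch per cell, centered on the rounded centroid
#' (nearest integer, ties to even), from a colour image already at the
#' target resolution. Out-of-bounds regions are filled by edge replication
#' (zero-fill would paint dark corners that mimic nuclei). Each patch is
#' individually min-max normalized to [0, 1], jointly across the three
#' channels by default; a constant patch maps to all zeros. Cells labelled
#' \code{"unclassified"} (or \code{NA}) are excluded: they carry no class
#' signal for training.
#'
#' @param image \code{h x w x 3} numeric array at the target resolution.
#' @param cells Cell table with \code{instance_id}, \code{centroid_row},
#'   \code{centroid_col} (0-based), \code{class}, and optional provenance
#'   columns.
#' @param patch_px Odd patch side in pixels (default 41; at 0.5 um/px that
#'   is a 20.5 um field).
#' @param normalize \code{"joint"} (one min/max over all channels, default)
#'   or \code{"per_channel"}.
#' @return List of patch records: \code{pixels}
#'   (\code{patch_px x patch_px x 3} in [0, 1]), \code{label},
#'   \code{instance_id}, \code{slide_id}, \code{patient_id}, \code{site_id},
#'   \code{fold} (NA until folds are assigned).
#' @export
extract_patches <- function(image, cells, patch_px = 41L,
                            normalize = c("joint", "per_channel")) {
  normalize <- match.arg(normalize)
  if (patch_px %% 2L == 0L) {
    stop("patch_px must be odd so the patch has a unique centre pixel")
  }
  d <- dim(image)
  half <- (patch_px - 1L) %/% 2L
  keep <- !is.na(cells$class) & cells$class != "unclassified"
  cells <- cells[keep, , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- round(cells$centroid_row[i]); c <- round(cells$centroid_col[i])
    if (r < 0 || r >= d[1] || c < 0 || c >= d[2]) {
      stop("centroid (", r, ", ", c, ") outside image bounds")
    }
    rows <- pmin(pmax((r - half):(r + half), 0), d[1] - 1) + 1  # edge replicate
    cols <- pmin(pmax((c - half):(c + half), 0), d[2] - 1) + 1
    px <- image[rows, cols, , drop = FALSE]
    if (normalize == "joint") {
      rng <- range(px)
      px <- if (diff(rng) < 1e-12) array(0, dim(px)) else (px - rng[1]) / diff(rng)
    } else {
      for (k in seq_len(dim(px)[3])) {
        rng <- range(px[, , k])
        px[, , k] <- if (diff(rng) < 1e-12) 0 else (px[, , k] - rng[1]) / diff(rng)
      }
    }
    out[[i]] <- list(
      pixels = px, label = cells$class[i], instance_id = cells$instance_id[i],
      slide_id = cells$slide_id[i] %||% NA_character_,
      patient_id = cells$patient_id[i] %||% NA_character_,
      site_id = cells$site_id[i] %||% NA_character_, fold = NA_integer_)
  }
  out
}

#' Physical side length of a patch
#'
#' @param patch_px Patch side in pixels.
#' @param resolution_um_per_px Pixel size in um.
#' @return Side length in micrometres.
#' @export
patch_extent_um <- function(patch_px = 41L, resolution_um_per_px = 0.5) {
  patch_px * resolution_um_per_px
}

#' Patient-level cross-validation folds
#'
#' Partitions patients into \code{n_folds} groups and rotates them:
#' in fold \code{i} group \code{i} is the test set, the next group is the
#' validation set, and the rest train — so 20 patients under 5 folds give
#' 12/4/4 splits and every patient is tested exactly once. Patients are
#' dealt to groups round-robin within each stratification tag combination
#' (after a seeded shuffle), so tag combinations (e.g. tissue region x
#' disease status) appear in every split whenever counts permit. Splits are
#' by patient, so all slides of a patient always share a split.
#'
#' @param patients Data frame with a \code{patient_id} column and optional
#'   tag columns used for stratification, or a character vector of ids.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed; the split is deterministic given it.
#' @param tag_cols Columns of \code{patients} to stratify on (default: all
#'   non-\code{patient_id} columns).
#' @return An object of class \code{fold_spec}: list of folds, each with
#'   \code{train}, \code{validation}, \code{test} character vectors of
#'   patient ids.
#' @export
make_patient_folds <- function(patients, n_folds = 5L, seed = 1L,
                               tag_cols = NULL) {
  if (is.character(patients)) {
    patients <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient ids")
  n <- nrow(patients)
  if (n < n_folds) {
    stop("need at least ", n_folds, " patients for ", n_folds, " folds; got ", n)
  }
  tag_cols <- tag_cols %||% setdiff(names(patients), "patient_id")
  combo <- if (length(tag_cols)) {
    interaction(patients[tag_cols], drop = TRUE)
  } else {
    factor(rep(1L, n))
  }
  group <- integer(n)
  with_private_seed(seed, {
    start <- 0L
    for (lev in levels(combo)) {
      idx <- which(combo == lev)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across combos so group sizes stay balanced
      group[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
      start <- start + length(idx)
    }
  })
  ids <- patients$patient_id
  folds <- lapply(seq_len(n_folds), function(i) {
    test_g <- i
    val_g <- (i %% n_folds) + 1L
    list(train = ids[!(group %in% c(test_g, val_g))],
         validation = ids[group == val_g],
         test = ids[group == test_g])
  })
  structure(folds, class = "fold_spec")
}

#' @export
print.fold_spec <- function(x, ...) {
  cat(sprintf("<fold_spec> %d fold(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  fold %d: train %d / val %d / test %d\n", i,
                length(x[[i]]$train), length(x[[i]]$validation),
                length(x[[i]]$test)))
  }
  invisible(x)
}

#' Read / write a fold specification as JSON
#'
#' @param folds A \code{fold_spec}.
#' @param path JSON path.
#' @return \code{write_fold_spec}: invisibly, \code{path};
#'   \code{read_fold_spec}: a \code{fold_spec}.
#' @export
write_fold_spec <- function(folds, path) {
  jsonlite::write_json(lapply(unclass(folds), function(f)
    list(train = f$train, validation = f$validation, test = f$test)),
    path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fold_spec
#' @export
read_fold_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  structure(lapply(raw, function(f)
    list(train = unlist(f$train), validation = unlist(f$validation),
         test = unlist(f$test))), class = "fold_spec")
}

#' Class-balanced batch index stream
#'
#' Each batch slot first draws a class uniformly from \code{classes}, then
#' an example uniformly (with replacement) from that class, so each example
#' has equal likelihood of coming from any class and the expected per-class
#' share of a batch is \code{1/length(classes)}.
#'
#' @param labels Character vector of example labels.
#' @param n_batches Number of batches to emit.
#' @param batch_size Examples per batch (default 256).
#' @param classes Class list to balance over (default: the distinct labels);
#'   a class with no examples is an error naming the class.
#' @param seed Integer seed; equal seeds give identical streams.
#' @return List of \code{n_batches} integer index vectors of length
#'   \code{batch_size}.
#' @export
balanced_batch_indices <- function(labels, n_batches, batch_size = 256L,
                                   classes = NULL, seed = 1L) {
  classes <- classes %||% sort(unique(labels))
  by_class <- lapply(stats::setNames(classes, classes),
                     function(cl) which(labels == cl))
  empty <- classes[vapply(by_class, length, 0L) == 0L]
  if (length(empty)) {
    stop("sampling error: no examples for class(es): ",
         paste(empty, collapse = ", "))
  }
  with_private_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      cls <- sample.int(length(classes), batch_size, replace = TRUE)
      idx <- integer(batch_size)
      for (ci in unique(cls)) {
        slots <- which(cls == ci)
        pool <- by_class[[ci]]
        idx[slots] <- pool[sample.int(length(pool), length(slots),
                                      replace = TRUE)]
      }
      idx
    })
  })
}
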