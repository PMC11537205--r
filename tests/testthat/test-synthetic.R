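test_that("zero cells give an empty map and truth table", {
  cfg <- sim_config(image_height_px = 64L, image_width_px = 64L, n_cells = 0L,
                    seed = 1L)
  tis <- generate_tissue(cfg)
  expect_true(all(tis$instances == 0L))
  expect_equal(nrow(tis$truth), 0L)
  expect_setequal(names(tis$image$channels)[1:17],
                  rule_channels(default_rule_table()))
})

test_that("equal seeds give bit-identical tissues", {
  cfg <- sim_config(image_height_px = 256L, image_width_px = 256L,
                    n_cells = 40L, seed = 99L)
  a <- generate_tissue(cfg)
  b <- generate_tissue(cfg)
  expect_identical(a$instances, b$instances)
  expect_identical(a$truth, b$truth)
  for (ch in names(a$image$channels)) {
    expect_identical(a$image$channels[[ch]], b$image$channels[[ch]])
  }
  c2 <- generate_tissue(sim_config(image_height_px = 256L,
                                   image_width_px = 256L, n_cells = 40L,
                                   seed = 100L))
  expect_false(identical(a$instances, c2$instances))
})

test_that("instance ids and truth rows are in bijection", {
  tis <- fx_small_tissue()
  expect_setequal(instance_ids(tis$instances), tis$truth$instance_id)
  expect_equal(anyDuplicated(tis$truth$instance_id), 0L)
})

test_that("a malformed mixture is a configuration error", {
  expect_error(sim_config(class_mixture = c(goblet = 0.5, enterocyte = 0.4)),
               "sum to 1")
  expect_error(sim_config(marker_profile = list()), "profile")
})

test_that("an overfull image is a packing error naming the count", {
  cfg <- sim_config(image_height_px = 128L, image_width_px = 128L,
                    n_cells = 400L, seed = 1L)
  expect_error(generate_tissue(cfg), "packing error: could not place [0-9]+")
})

test_that("noiseless gating recovers every true class", {
  tis <- fx_small_tissue()
  cfg <- sim_config(noise_sd = 0, seed = 7L)
  cells <- gate_cells(tis$image, tis$instances, cfg$thresholds)
  expect_equal(cells$class, tis$truth$class)
})

test_that("gating accuracy degrades monotonically along a noise ladder", {
  base <- function(noise, seed) {
    cfg <- sim_config(image_height_px = 384L, image_width_px = 384L,
                      n_cells = 80L, noise_sd = noise, seed = seed)
    tis <- generate_tissue(cfg)
    cells <- gate_cells(tis$image, tis$instances, cfg$thresholds)
    mean(cells$class == tis$truth$class)
  }
  ladder <- c(10, 120, 250)
  acc <- sapply(ladder, function(ns) mean(sapply(1:5, function(s) base(ns, s))))
  expect_gte(acc[1], acc[2] - 0.02)  # sampling-error slack
  expect_gte(acc[2], acc[3] - 0.02)
  expect_gt(acc[1], acc[3])          # strict decrease across the ladder
})

test_that("class counts are multinomially consistent with the mixture", {
  tis <- fx_tissue_zero_noise()
  mix <- default_class_mixture()
  counts <- table(factor(tis$truth$class, levels = names(mix)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = mix))
  expect_gt(gof$p.value, 0.01)
})

test_that("goblets are Muc2-high blobs without nuclear DAPI", {
  tis <- fx_small_tissue()
  cells <- mean_intensity_per_instance(tis$image, tis$instances)
  gob <- tis$truth$class == "goblet"
  expect_true(any(gob))
  expect_true(all(cells$mean_Muc2[gob] > 100))
  expect_true(all(cells$mean_DAPI[gob] < 100))
  expect_true(all(cells$mean_Muc2[!gob] < 100))
})

test_that("rendering is deterministic and empty tissue renders uniformly", {
  tis <- fx_small_tissue()
  expect_identical(render_pseudo_he(tis), render_pseudo_he(tis))
  empty <- generate_tissue(sim_config(image_height_px = 32L,
                                      image_width_px = 32L, n_cells = 0L,
                                      noise_sd = 0, seed = 1L))
  he <- render_pseudo_he(empty)
  for (k in 1:3) expect_equal(length(unique(as.vector(he[, , k]))), 1L)
})

test_that("nuclei render darker than background", {
  tis <- fx_small_tissue()
  he <- render_pseudo_he(tis)
  lum <- luminance(he)
  nuc_ids <- tis$truth$instance_id[tis$truth$class != "goblet"]
  nuc <- tis$instances > 0L &
    matrix(unclass(tis$instances) %in% nuc_ids, nrow(tis$instances))
  expect_lt(mean(lum[nuc]), mean(lum[tis$instances == 0L]))
})

test_that("rendering without DAPI is a channel error", {
  tis <- fx_small_tissue()
  tis$image$channels$DAPI <- NULL
  expect_error(render_pseudo_he(tis), "DAPI")
})

test_that("identity mapping with goblets kept reproduces the fine table", {
  tis <- fx_small_tissue()
  classes <- unique(tis$truth$class)
  ident <- class_mapping(setNames(classes, classes))
  recs <- generate_parent_labeled_set(list(tis), ident, tile_px = 128L,
                                      include_goblets = TRUE)
  expect_gt(length(recs), 0L)
  got <- do.call(rbind, lapply(recs, `[[`, "cells"))
  # every retained instance keeps its fine label under the identity map
  expect_equal(got$class,
               tis$truth$class[match(got$instance_id, tis$truth$instance_id)])
})

test_that("the default mapping sends fine classes to their parents", {
  mapping <- default_class_mapping()
  expect_equal(unname(mapping$map[c("helper_t", "enterocyte", "progenitor",
                                    "fibroblast", "stromal_undetermined")]),
               c("lymphocyte", "epithelial", "epithelial", "connective",
                 "connective"))
  expect_true("goblet" %in% mapping$droppable)
  expect_error(apply_class_mapping("mystery_cell", mapping), "mystery_cell")
})

test_that("parent tiles have the requested size and goblets are dropped", {
  tis <- fx_small_tissue()
  recs <- generate_parent_labeled_set(list(tis), tile_px = 256L)
  expect_equal(dim(recs[[1]]$tile)[1:2], c(256L, 256L))
  got <- do.call(rbind, lapply(recs, `[[`, "cells"))
  expect_false(any(is.na(got$class)))
  gob_ids <- tis$truth$instance_id[tis$truth$class == "goblet"]
  expect_false(any(got$instance_id %in% gob_ids))
  expect_true(all(got$class %in% c("lymphocyte", "epithelial", "connective")))
})

test_that("tissue files round-trip through disk", {
  tis <- generate_tissue(sim_config(image_height_px = 96L, image_width_px = 96L,
                                    n_cells = 5L, seed = 3L))
  dir <- withr::local_tempdir()
  write_tissue(tis, dir)
  imap <- read_instance_map(file.path(dir, "instances.tif"))
  expect_identical(unclass(imap), unclass(tis$instances))
  truth <- read_cell_table(file.path(dir, "truth.csv"))
  expect_equal(truth$class, tis$truth$class)
})
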