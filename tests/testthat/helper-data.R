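# Shared fixtures, built once per test run and cached. Seeds here define the
# fixture identities, not tuning knobs: tissue contents come entirely from
# the generator defaults.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache, inherits = FALSE)
}

# default-profile slide with the noise switched off (exact gating expected)
fx_tissue_zero_noise <- function() {
  fx("tissue_zero_noise", function() {
    generate_tissue(sim_config(noise_sd = 0, seed = 42L))
  })
}

# default-profile slide as configured (noise SD 10)
fx_tissue_default <- function() {
  fx("tissue_default", function() generate_tissue(sim_config(seed = 43L)))
}

# render a tissue, resample to 0.5 um/px, and cut labelled patches
make_patch_set <- function(tissue) {
  he <- render_pseudo_he(tissue)
  rgb <- pmin(resample_image(he, tissue$image$resolution_um_per_px, 0.5), 1)
  imap <- resample_labels(tissue$instances,
                          tissue$image$resolution_um_per_px, 0.5)
  cents <- instance_centroids(imap)
  cells <- merge(cents,
                 tissue$truth[, c("instance_id", "class", "slide_id",
                                  "patient_id", "site_id")],
                 by = "instance_id")
  extract_patches(rgb, cells)
}

# patient-disjoint train/validation/test patch sets from five default slides
fx_patch_sets <- function() {
  fx("patch_sets", function() {
    mk <- function(seed, sl, pt) {
      make_patch_set(generate_tissue(sim_config(seed = seed),
                                     slide_id = sl, patient_id = pt))
    }
    list(
      train = c(mk(101L, "s1", "p1"), mk(102L, "s2", "p2"), mk(103L, "s3", "p3")),
      validation = mk(202L, "s4", "p4"),
      test = mk(303L, "s5", "p5"))
  })
}

# small quick tissue for cheap unit tests
fx_small_tissue <- function() {
  fx("small_tissue", function() {
    generate_tissue(sim_config(image_height_px = 512L, image_width_px = 512L,
                               n_cells = 150L, noise_sd = 0, seed = 7L))
  })
}
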