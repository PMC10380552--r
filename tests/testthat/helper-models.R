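# Heavyweight shared fixtures for the end-to-end tests: the synthetic study
# set and the trained models. Everything is memoised so the expensive work
# happens once per test run, and all randomness flows from fixed seeds so
# results are reproducible.

# the study set: 8 leaves (6 train / 2 held out), desk-scale conditions
study_leaves <- function() {
  memo("study_leaves", lapply(1:8, function(i) {
    generate_leaf(small_leaf_params(seed = 200 + i))
  }))
}

held_out_leaves <- function() study_leaves()[7:8]

# fresh leaves never seen by any training run (for the model comparison)
comparison_leaves <- function(n = 20) {
  memo(paste0("cmp_leaves_", n), lapply(seq_len(n), function(i) {
    generate_leaf(small_leaf_params(seed = 500 + i))
  }))
}

study_tracer_config <- function() {
  cfg <- scaled_tracer_config(seed = 1, epochs = 30)
  cfg$decay_at <- c(18L, 26L)
  cfg$decay_factor <- 0.3
  cfg
}

study_tracer <- function() {
  memo("tracer_model", {
    cfg <- study_tracer_config()
    ds <- build_tracer_dataset(study_leaves()[1:6], cfg,
                               augment = augment_none(), stride = 2L,
                               seed = 1)
    train_tracer(ds, cfg)
  })
}

study_grower_config <- function(loss) {
  scaled_grower_config(seed = 1, loss = loss, epochs = 40)
}

study_grower_dataset <- function() {
  memo("grower_ds", build_grower_dataset(
    study_leaves(), study_grower_config("focal"),
    augment = augment_config(color = 0.05, blur = 0), seed = 1))
}

study_grower <- function(loss = "focal") {
  memo(paste0("grower_", loss), {
    train_grower(study_grower_dataset(), study_grower_config(loss))
  })
}

study_unet_config <- function() {
  scaled_unet_config(seed = 1, tile_size = 32, widths = c(8, 16, 32),
                     epochs = 25, lr = 5e-3, batch = 32,
                     tiles_per_image = 100L)
}

study_unet_dataset <- function() {
  memo("unet_ds", build_unet_dataset(
    study_leaves(), "vein", study_unet_config(),
    augment = augment_config(color = 0.05, blur = 0), seed = 1))
}

study_unet <- function(loss = "focal") {
  memo(paste0("unet_", loss), {
    train_unet(study_unet_dataset(), loss, study_unet_config())
  })
}

# segment the comparison set with one model; returns component counts
vein_component_counts <- function(model, leaves, seed_base = 900) {
  vapply(seq_along(leaves), function(i) {
    smp <- leaves[[i]]
    scan <- leaf_scan(smp$image, 300)
    mask <- if (inherits(model, "unet_model")) {
      acc <- predict_tiled(model, scan)
      lm <- smp$leaf_mask
      m <- unet_threshold(acc, "vein")
      m
    } else {
      acc <- suppressWarnings(
        grow_veins(model, scan, smp$leaf_mask, n_seeds = 10000,
                   seed = seed_base + i))
      select_threshold(acc)$mask
    }
    as.numeric(connected_components(mask, 8)$count)
  }, numeric(1))
}
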