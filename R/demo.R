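# End-to-end demonstration pipeline on synthetic data: generate leaves,
# train the scaled-down tracer / grower / U-Nets, segment held-out images,
# extract traits, evaluate, and estimate heritability of the vein-density
# driver on a simulated clonal population.

#' Run the end-to-end synthetic demo
#'
#' Generates a small synthetic population, trains the scaled-down boundary
#' tracer, vein grower (focal loss) and vein U-Net, segments held-out
#' images, extracts traits, scores the segmentations, and estimates
#' broad-sense heritability of the latent vein-density driver on a separate
#' simulated clonal population. All randomness flows from `seed`.
#'
#' @param seed integer seed for the whole pipeline.
#' @param out_dir optional directory; when given, a markdown `report.md`,
#'   the resolved settings (`config.json`) and the per-sample traits CSV are
#'   written there.
#' @param settings optional list overriding the demo sizes (fields
#'   `n_train`, `n_test`, `tracer`, `grower`, `unet`, `h2_genotypes`,
#'   `h2_clones`); used to shrink the demo further for quick checks.
#' @return (invisibly) list with `seg_scores`, `traits`, `heritability`,
#'   `models`, `report` (character vector of report lines).
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, settings = NULL) {
  s <- utils::modifyList(list(
    n_train = 6L, n_test = 2L,
    tracer = scaled_tracer_config(seed = seed, epochs = 40),
    grower = scaled_grower_config(seed = seed, epochs = 30,
                                  max_pos_per_image = 150),
    unet = scaled_unet_config(seed = seed, epochs = 25, tiles_per_image = 80L),
    tracer_stride = 4L, h2_genotypes = 60L, h2_clones = 2L,
    n_seeds = 400L), settings %||% list())

  n_all <- s$n_train + s$n_test
  samples <- lapply(seq_len(n_all), function(i) {
    generate_leaf(small_leaf_params(seed = seed * 1000L + i))
  })
  train_set <- samples[seq_len(s$n_train)]
  test_set <- samples[(s$n_train + 1):n_all]

  tracer_ds <- build_tracer_dataset(train_set, s$tracer, stride = s$tracer_stride,
                                    seed = seed)
  tracer <- train_tracer(tracer_ds, s$tracer)
  grower_ds <- build_grower_dataset(train_set, s$grower, seed = seed)
  grower <- train_grower(grower_ds, s$grower)
  unet_ds <- build_unet_dataset(train_set, "vein", s$unet, seed = seed)
  unet <- train_unet(unet_ds, "focal", s$unet)

  scores <- list(); traits <- list()
  for (i in seq_along(test_set)) {
    smp <- test_set[[i]]
    scan <- leaf_scan(smp$image, dpi = smp$params$dpi,
                      sample_id = sprintf("test%02d", i))
    tr <- tryCatch(trace_leaf(tracer, scan),
                   leaftrace_diverged = function(e) NULL)
    leaf_mask <- if (is.null(tr)) rough_foreground(scan) & !smp$petiole_mask
    else tr$mask
    acc <- grow_veins(grower, scan, leaf_mask, n_seeds = s$n_seeds,
                      seed = seed + i)
    sel <- select_threshold(acc)
    uacc <- predict_tiled(unet, scan)
    umask <- unet_threshold(uacc, "vein")
    scores[[i]] <- dplyr::bind_rows(
      dplyr::mutate(seg_score(leaf_mask, smp$leaf_mask),
                    task = "leaf", model = "tracer", sample = i),
      dplyr::mutate(seg_score(sel$mask, smp$vein_mask & smp$leaf_mask),
                    task = "vein", model = "grower", sample = i),
      dplyr::mutate(seg_score(umask, smp$vein_mask & smp$leaf_mask),
                    task = "vein", model = "unet", sample = i))
    traits[[i]] <- extract_traits(scan, leaf_mask, sel$mask,
                                  petiole_mask = smp$petiole_mask)
  }
  seg_scores <- dplyr::bind_rows(scores)
  trait_tbl <- dplyr::bind_rows(traits)

  pop <- generate_population(s$h2_genotypes * s$h2_clones,
                             small_leaf_params(seed = seed),
                             s$h2_genotypes, s$h2_clones,
                             sigma_G = 0.1, sigma_E = 0.1,
                             seed = seed, render = FALSE)
  h2 <- heritability(pop$assignments$trait_value, pop$assignments$genotype)

  report <- c(
    "# Synthetic end-to-end demo",
    sprintf("seed: %d", seed),
    "", "## Segmentation scores (held-out synthetic leaves)",
    utils::capture.output(as.data.frame(seg_scores)),
    "", "## Traits (held-out leaves)",
    utils::capture.output(as.data.frame(trait_tbl)),
    "", "## Heritability of the latent vein-density driver",
    sprintf("H2 = %.3f (sigma2_G = %.4g, sigma2_E = %.4g, %d genotypes x %d clones)",
            h2$H2, h2$sigma2_G, h2$sigma2_E, s$h2_genotypes, s$h2_clones))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(report, file.path(out_dir, "report.md"))
    utils::write.csv(trait_tbl, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_train = s$n_train, n_test = s$n_test,
           tracer = s$tracer[c("tile_size", "N", "widths", "epochs", "batch")],
           grower = s$grower[c("tile_size", "widths", "epochs", "batch", "loss")],
           unet = s$unet[c("tile_size", "widths", "epochs", "batch")]),
      file.path(out_dir, "config.json"), auto_unbox = TRUE)
  }
  invisible(list(seg_scores = seg_scores, traits = trait_tbl,
                 heritability = h2,
                 models = list(tracer = tracer, grower = grower, unet = unet),
                 report = report))
}
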