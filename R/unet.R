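# Tiled U-Net baseline: encoder identical to the corresponding few-shot
# model, mirrored decoder with transposed-convolution upsampling and
# concatenated skip connections, overlapping tile-grid inference with
# probability averaging.

#' U-Net configuration
#'
#' Batch sizes are half those of the corresponding encoder-only model
#' (128 for leaf tiles, 512 for vein tiles at full scale).
#'
#' @param tile_size tile side in px (256 leaf / 128 vein at full scale).
#' @param widths encoder block widths (decoder mirrors them in reverse).
#' @param alpha,gamma focal-loss hyperparameters.
#' @param tiles_per_image training tiles sampled per image.
#' @param epochs,batch,patience,lr,seed,verbose training settings.
#' @param val_images images held out for validation.
#' @export
unet_config <- function(tile_size = 128, widths = c(24, 32, 48, 64, 96, 128),
                        alpha = 0.25, gamma = 2, tiles_per_image = 500L,
                        epochs = 1000, batch = 512, patience = 20,
                        lr = 1e-3, seed = 1L, val_images = 2L,
                        verbose = FALSE) {
  list(tile_size = as.integer(tile_size), widths = as.integer(widths),
       alpha = alpha, gamma = gamma,
       tiles_per_image = as.integer(tiles_per_image),
       epochs = as.integer(epochs), batch = as.integer(batch),
       patience = as.integer(patience), lr = lr, seed = as.integer(seed),
       val_images = as.integer(val_images), verbose = verbose)
}

#' @rdname unet_config
#' @param ... overrides.
#' @export
scaled_unet_config <- function(...) {
  defaults <- list(tile_size = 32, widths = c(12, 24, 48), epochs = 50,
                   batch = 32, tiles_per_image = 150L, val_images = 2L)
  do.call(unet_config, utils::modifyList(defaults, list(...)))
}

#' Overlapping tile grid for whole-image prediction
#'
#' Tiles of side `tile_size` are placed at a stride of half the tile size so
#' each interior pixel is predicted from four positions; the last row and
#' column of tiles are shifted flush with the image edge.
#'
#' @param shape image `(H, W)`.
#' @param tile_size tile side in px.
#' @param stride step between tile centres (default `tile_size / 2`).
#' @return A `tile_grid`: list with `tile_size`, `stride`, `centers`.
#' @export
tile_grid <- function(shape, tile_size, stride = tile_size / 2) {
  H <- shape[1]; W <- shape[2]
  half <- tile_size / 2
  if (H < tile_size || W < tile_size) {
    abort("image smaller than tile size")
  }
  axis_centers <- function(n) {
    cs <- seq(half + 1, n - half + 1, by = stride)
    sort(unique(c(cs, n - half + 1)))
  }
  centers <- as.matrix(expand.grid(row = axis_centers(H), col = axis_centers(W)))
  structure(list(tile_size = as.integer(tile_size), stride = stride,
                 centers = matrix(as.integer(centers), ncol = 2)),
            class = "tile_grid")
}

#' Build a U-Net training set
#'
#' Unlike the tracer's boundary-centred tiles, U-Net tiles are sampled from
#' anywhere in the leaf; the target is the corresponding crop of the task
#' mask, with out-of-bounds pixels flagged invalid so they are masked out of
#' the loss.
#'
#' @param samples list of `synthetic_sample`s (or lists with `image`,
#'   `leaf_mask`, and `vein_mask` for the vein task).
#' @param task `"leaf"` or `"vein"`.
#' @param config a [unet_config()].
#' @param augment an [augment_config()].
#' @param seed sampling seed.
#' @return A `unet_dataset` with `X`, `Y` (`S^2 x n`), `valid`, `image_id`.
#' @export
build_unet_dataset <- function(samples, task = c("leaf", "vein"),
                               config = unet_config(),
                               augment = augment_config(), seed = 1L) {
  task <- match.arg(task)
  S <- config$tile_size
  withr::with_seed(seed, {
    xs <- list(); ys <- list(); vs <- list(); ids <- integer(0)
    for (si in seq_along(samples)) {
      smp <- samples[[si]]
      img <- smp$image
      target <- if (task == "leaf") smp$leaf_mask else (smp$vein_mask & smp$leaf_mask)
      pool <- which(smp$leaf_mask)
      H <- nrow(target)
      n_t <- min(config$tiles_per_image, length(pool))
      centers_idx <- sample(pool, n_t)
      centers <- cbind((centers_idx - 1L) %% H + 1L, (centers_idx - 1L) %/% H + 1L)
      res <- cpp_extract_tiles(img, centers, S, 1)
      tgt <- cpp_extract_tiles(array(as.numeric(target), c(dim(target), 1L)),
                               centers, S, 0)
      tiles <- array(res$tiles, c(S, S, 3, n_t))
      labs <- array(tgt$tiles, c(S, S, n_t))
      pads <- array(res$pad, c(S, S, n_t))
      for (k in seq_len(n_t)) {
        tile <- tiles[, , , k, drop = FALSE]; dim(tile) <- c(S, S, 3)
        lab <- labs[, , k]; val <- !pads[, , k]
        if (augment$rotate > 0) {
          kr <- sample(0:3, 1)
          tile <- rot90_tile(tile, kr)
          lab <- rot90_mat(lab, kr)
          val <- rot90_mat(val, kr)
        }
        if (augment$flip && runif(1) < 0.5) {
          tile <- flip_tile_h(tile)
          lab <- lab[, rev(seq_len(S)), drop = FALSE]
          val <- val[, rev(seq_len(S)), drop = FALSE]
        }
        if (augment$color > 0) tile <- color_jitter(tile, augment$color)
        xs[[length(xs) + 1]] <- tile
        ys[[length(ys) + 1]] <- as.numeric(lab)
        vs[[length(vs) + 1]] <- as.numeric(val)
        ids <- c(ids, si)
      }
    }
    structure(list(X = array(unlist(xs), c(S, S, 3, length(xs))),
                   Y = matrix(unlist(ys), S * S, length(ys)),
                   valid = matrix(unlist(vs), S * S, length(vs)),
                   image_id = ids, tile_size = S, task = task),
              class = "unet_dataset")
  })
}

#' Train the U-Net baseline
#'
#' Per-pixel BCE (leaf) or BCE/focal (vein) over the sigmoid output map,
#' image-level split, Adam with early stopping. Loss at padded pixels of
#' edge tiles is masked out.
#'
#' @param dataset a `unet_dataset`.
#' @param loss `"bce"` or `"focal"`.
#' @param config a [unet_config()].
#' @return A `unet_model`.
#' @export
train_unet <- function(dataset, loss = c("bce", "focal"),
                       config = unet_config()) {
  loss <- match.arg(loss)
  ids <- unique(dataset$image_id)
  if (length(ids) < 2) abort("need at least 2 images for an image-level split")
  val_ids <- utils::tail(ids, config$val_images)
  if (length(val_ids) >= length(ids)) val_ids <- utils::tail(ids, 1)
  tr <- !(dataset$image_id %in% val_ids)
  arch <- unet_arch(dataset$tile_size, 3L, config$widths)
  loss_cfg <- list(mode = loss, alpha = config$alpha, gamma = config$gamma)
  fit <- run_training(arch, dataset$X[, , , tr, drop = FALSE],
                      dataset$Y[, tr, drop = FALSE],
                      dataset$X[, , , !tr, drop = FALSE],
                      dataset$Y[, !tr, drop = FALSE], loss_cfg, config,
                      validTr = dataset$valid[, tr, drop = FALSE],
                      validVa = dataset$valid[, !tr, drop = FALSE])
  m <- new_conv_model(arch, fit, config,
                      list(train = setdiff(ids, val_ids), val = val_ids),
                      "unet_model")
  m$task <- dataset$task
  m$loss <- loss
  m
}

#' Forward pass of the U-Net on tiles
#'
#' @param model a `unet_model`.
#' @param tiles `S x S x 3` tile or `S x S x 3 x n` array.
#' @return `S x S` probability matrix (or `S^2 x n` for a batch).
#' @export
unet_forward <- function(model, tiles) {
  single <- length(dim(tiles)) == 3
  out <- model_forward(model, tiles, batch = 16L)
  S <- model$arch$tile
  if (single) matrix(out[, 1], S, S) else out
}

#' Tiled whole-image prediction with probability averaging
#'
#' Every tile of the grid is predicted independently; probabilities are
#' summed into a [prob_accumulator()] (skipping out-of-bounds pixels) and the
#' mean map is `prob_sum / visit_count`.
#'
#' @param model a `unet_model` (or any object with a `predict_tiles`
#'   function; see details).
#' @param scan a [leaf_scan()].
#' @param grid a [tile_grid()]; defaults to the model's tile size at half-
#'   tile stride.
#' @param chunk tiles predicted per forward batch.
#' @return A [prob_accumulator()].
#' @export
predict_tiled <- function(model, scan, grid = NULL, chunk = 64L) {
  S <- model$arch$tile
  if (is.null(grid)) grid <- tile_grid(dim(scan$pixels)[1:2], S)
  acc <- prob_accumulator(dim(scan$pixels)[1:2])
  centers <- grid$centers
  for (start in seq(1, nrow(centers), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(centers))
    res <- cpp_extract_tiles(scan$pixels, centers[idx, , drop = FALSE],
                             grid$tile_size, 1)
    probs <- model_forward(model, array(res$tiles,
                                        c(S, S, 3, length(idx))), batch = 16L)
    cpp_accumulate_tiles(acc$prob_sum, acc$visit_count,
                         centers[idx, , drop = FALSE],
                         as.numeric(probs), grid$tile_size)
  }
  acc
}

#' Threshold a U-Net probability map
#'
#' Leaf task: fixed threshold 0.5. Vein task: threshold chosen by
#' connected-component minimisation ([select_threshold()]).
#'
#' @param acc a [prob_accumulator()].
#' @param task `"leaf"` or `"vein"`.
#' @return Binary mask; for the vein task the chosen threshold is attached as
#'   attribute `theta`.
#' @export
unet_threshold <- function(acc, task = c("leaf", "vein")) {
  task <- match.arg(task)
  if (task == "leaf") {
    meanp <- accumulator_mean(acc)
    return((acc$visit_count > 0) & (meanp >= 0.5))
  }
  sel <- select_threshold(acc)
  structure(sel$mask, theta = sel$theta)
}
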