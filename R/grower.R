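# Region-growing vein segmenter: positive/negative tile sampling, focal or
# BCE objectives, the recursive growing loop over a probability accumulator,
# and threshold selection by connected-component minimisation.

#' Grower configuration
#'
#' `grower_config()` holds the full-scale settings (128-px RGB tiles, the
#' tracer encoder minus its first block, batch 1024). `scaled_grower_config()`
#' is the desk-scale counterpart (32-px tiles, 3 blocks) used in tests and
#' examples.
#'
#' @param tile_size tile side in px.
#' @param widths encoder block widths.
#' @param loss `"focal"` or `"bce"`.
#' @param alpha,gamma focal-loss hyperparameters (defaults 0.25 and 2).
#' @param neg_ratio background tiles sampled per vein tile (up to).
#' @param max_pos_per_image cap on positive tiles per image.
#' @param enqueue_threshold instantaneous vein probability above which a
#'   neighbour becomes a new seed during growing.
#' @param epochs,batch,patience,lr,seed,verbose training settings.
#' @param val_images number of images held out for validation.
#' @export
grower_config <- function(tile_size = 128, widths = c(24, 32, 48, 64, 96, 128),
                          loss = c("focal", "bce"), alpha = 0.25, gamma = 2,
                          neg_ratio = 10, max_pos_per_image = Inf,
                          enqueue_threshold = 0.5,
                          epochs = 1000, batch = 1024, patience = 20,
                          lr = 1e-3, seed = 1L, val_images = 2L,
                          verbose = FALSE) {
  loss <- match.arg(loss)
  list(tile_size = as.integer(tile_size), widths = as.integer(widths),
       loss = loss, alpha = alpha, gamma = gamma, neg_ratio = neg_ratio,
       max_pos_per_image = max_pos_per_image,
       enqueue_threshold = enqueue_threshold, epochs = as.integer(epochs),
       batch = as.integer(batch), patience = as.integer(patience), lr = lr,
       seed = as.integer(seed), val_images = as.integer(val_images),
       verbose = verbose)
}

#' @rdname grower_config
#' @param ... overrides.
#' @export
scaled_grower_config <- function(...) {
  defaults <- list(tile_size = 16, widths = c(12, 24), epochs = 60,
                   batch = 64, lr = 5e-3, neg_ratio = 4,
                   max_pos_per_image = 100, val_images = 2L)
  do.call(grower_config, utils::modifyList(defaults, list(...)))
}

# 3x3 neighbourhood labels around (r, c), column-major, FALSE outside
neighborhood_labels <- function(mask, r, c) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, 3, 3)
  for (dc in -1:1) for (dr in -1:1) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) {
      out[dr + 2, dc + 2] <- 1
    }
  }
  out
}

#' Build a grower training set
#'
#' One RGB tile per vein pixel (positives) plus up to `neg_ratio` times as
#' many background tiles sampled from the leaf interior; the target of each
#' tile is the 3x3 ground-truth vein neighbourhood of its centre.
#' Augmentation applies quarter-turn rotations and flips (which permute the
#' 3x3 target exactly), color jitter and occasional Gaussian blur.
#'
#' @param samples list of `synthetic_sample`s or lists with `image`,
#'   `vein_mask`, `leaf_mask`.
#' @param config a [grower_config()].
#' @param augment an [augment_config()].
#' @param seed sampling seed.
#' @return A `grower_dataset` with `X`, `Y` (9 x n labels), `image_id`.
#' @export
build_grower_dataset <- function(samples, config = grower_config(),
                                 augment = augment_config(), seed = 1L) {
  S <- config$tile_size
  withr::with_seed(seed, {
    xs <- list(); ys <- list(); ids <- integer(0)
    for (si in seq_along(samples)) {
      smp <- samples[[si]]
      img <- smp$image
      vm <- smp$vein_mask & smp$leaf_mask
      interior <- smp$leaf_mask & !vm
      pos <- which(vm)
      if (length(pos) > config$max_pos_per_image) {
        pos <- sample(pos, config$max_pos_per_image)
      }
      n_neg_want <- round(config$neg_ratio * length(pos))
      neg_pool <- which(interior)
      if (length(neg_pool) < n_neg_want) {
        warn(sprintf("image %d: only %d background pixels available (wanted %d)",
                     si, length(neg_pool), n_neg_want))
        neg <- neg_pool
      } else {
        neg <- sample(neg_pool, n_neg_want)
      }
      centers_idx <- c(pos, neg)
      H <- nrow(vm)
      centers <- cbind((centers_idx - 1L) %% H + 1L, (centers_idx - 1L) %/% H + 1L)
      res <- cpp_extract_tiles(img, centers, S, 1)
      tiles <- array(res$tiles, c(S, S, 3, nrow(centers)))
      for (k in seq_len(nrow(centers))) {
        tile <- tiles[, , , k, drop = FALSE]
        dim(tile) <- c(S, S, 3)
        lab <- neighborhood_labels(vm, centers[k, 1], centers[k, 2])
        if (augment$rotate > 0) {
          kr <- sample(0:3, 1)
          tile <- rot90_tile_center(tile, kr)
          lab <- rot90_mat(lab, kr)
        }
        if (augment$flip && runif(1) < 0.5) {
          tile <- flip_tile_h_center(tile)
          lab <- lab[, 3:1, drop = FALSE]
        }
        if (augment$color > 0) tile <- color_jitter(tile, augment$color)
        if (augment$blur > 0 && runif(1) < augment$blur) {
          for (ch in 1:3) {
            tile[, , ch] <- as.matrix(EBImage::gblur(EBImage::Image(tile[, , ch]),
                                                     sigma = 0.8))
          }
        }
        xs[[length(xs) + 1]] <- tile
        ys[[length(ys) + 1]] <- as.numeric(lab)
        ids <- c(ids, si)
      }
    }
    X <- array(unlist(xs), c(S, S, 3, length(xs)))
    Y <- matrix(unlist(ys), 9, length(ys))
    structure(list(X = X, Y = Y, image_id = ids, tile_size = S),
              class = "grower_dataset")
  })
}

#' Train the vein grower
#'
#' Image-level split (the last `val_images` images are held out), focal or
#' BCE objective on the 3x3 softmax outputs, Adam with early stopping.
#'
#' @param dataset a `grower_dataset`.
#' @param config a [grower_config()].
#' @return A `vein_grower_model`.
#' @export
train_grower <- function(dataset, config = grower_config()) {
  ids <- unique(dataset$image_id)
  if (length(ids) < 2) abort("need at least 2 images for an image-level split")
  val_ids <- utils::tail(ids, config$val_images)
  if (length(val_ids) >= length(ids)) val_ids <- utils::tail(ids, 1)
  tr <- !(dataset$image_id %in% val_ids)
  arch <- encoder_arch(dataset$tile_size, 3L, config$widths, 18L, "softmax9")
  loss <- list(mode = config$loss, alpha = config$alpha, gamma = config$gamma)
  fit <- run_training(arch, dataset$X[, , , tr, drop = FALSE],
                      dataset$Y[, tr, drop = FALSE],
                      dataset$X[, , , !tr, drop = FALSE],
                      dataset$Y[, !tr, drop = FALSE], loss, config)
  new_conv_model(arch, fit, config,
                 list(train = setdiff(ids, val_ids), val = val_ids),
                 "vein_grower_model")
}

#' Forward pass of the grower
#'
#' @param model a `vein_grower_model`.
#' @param tiles `S x S x 3` tile or `S x S x 3 x n` array.
#' @return `3 x 3` vein-probability matrix (or `9 x n` matrix for a batch).
#' @export
grower_forward <- function(model, tiles) {
  single <- length(dim(tiles)) == 3
  out <- model_forward(model, tiles)
  if (single) matrix(out[, 1], 3, 3) else out
}

#' Plug-in oracle grower
#'
#' Emits the ground-truth 3x3 vein neighbourhood as probabilities; used to
#' validate the growing loop and threshold selection independently of model
#' quality.
#'
#' @param vein_mask ground-truth vein mask.
#' @export
oracle_grower <- function(vein_mask) {
  structure(list(vein_mask = vein_mask), class = "grower_oracle")
}

#' Probability accumulator
#'
#' Per-pixel running sum and visit count of foreground probabilities; a pixel
#' may be predicted several times (as the 3x3 neighbourhoods of different
#' centres overlap) and the final mask thresholds the average probability.
#'
#' @param shape `(H, W)`.
#' @export
prob_accumulator <- function(shape) {
  structure(list(prob_sum = matrix(0, shape[1], shape[2]),
                 visit_count = matrix(0, shape[1], shape[2])),
            class = "prob_accumulator")
}

#' Mean probability map of an accumulator
#'
#' @param acc a [prob_accumulator()].
#' @return Matrix of mean probabilities (0 where never visited).
#' @export
accumulator_mean <- function(acc) {
  m <- acc$prob_sum / pmax(acc$visit_count, 1)
  m[acc$visit_count == 0] <- 0
  m
}

#' Grow the vein segmentation from random seeds
#'
#' Seeds are sampled uniformly without replacement inside the leaf mask; each
#' popped centre is classified (3x3), all 9 probabilities are accumulated,
#' and neighbours whose instantaneous vein probability exceeds the enqueue
#' threshold become new centres. Each pixel is a centre at most once, so the
#' iteration terminates.
#'
#' @param model a `vein_grower_model` or [oracle_grower()].
#' @param scan a [leaf_scan()].
#' @param leaf_mask logical leaf-body mask.
#' @param n_seeds number of initial seed pixels (default 10000; capped at the
#'   interior size with a warning).
#' @param seed RNG seed for seed sampling.
#' @param config a [grower_config()]; defaults to the model's own.
#' @param chunk centres classified per forward batch.
#' @return A [prob_accumulator()].
#' @export
grow_veins <- function(model, scan, leaf_mask, n_seeds = 10000, seed = 1L,
                       config = NULL, chunk = 1024L) {
  if (!any(leaf_mask)) abort("leaf mask is empty")
  if (is.null(config)) {
    config <- if (inherits(model, "grower_oracle")) scaled_grower_config()
    else model$config
  }
  S <- config$tile_size
  interior <- which(leaf_mask)
  if (n_seeds > length(interior)) {
    warn(sprintf("n_seeds (%d) exceeds interior size (%d); using all pixels",
                 n_seeds, length(interior)))
    n_seeds <- length(interior)
  }
  seeds <- withr::with_seed(seed, sample(interior, n_seeds))
  H <- nrow(leaf_mask)
  acc <- prob_accumulator(dim(leaf_mask))
  queued <- matrix(FALSE, H, ncol(leaf_mask))
  queued[seeds] <- TRUE
  queue <- cbind((seeds - 1L) %% H + 1L, (seeds - 1L) %/% H + 1L)
  while (nrow(queue) > 0) {
    take <- seq_len(min(chunk, nrow(queue)))
    centers <- queue[take, , drop = FALSE]
    queue <- queue[-take, , drop = FALSE]
    if (inherits(model, "grower_oracle")) {
      probs <- vapply(seq_len(nrow(centers)), function(k) {
        as.numeric(neighborhood_labels(model$vein_mask, centers[k, 1],
                                       centers[k, 2]))
      }, numeric(9))
      probs <- matrix(probs, nrow = 9)
    } else {
      res <- cpp_extract_tiles(scan$pixels, centers, S, 1)
      probs <- model_forward(model, array(res$tiles, c(S, S, 3, nrow(centers))))
    }
    new_centers <- cpp_grow_update(acc$prob_sum, acc$visit_count, queued,
                                   leaf_mask, centers, probs,
                                   config$enqueue_threshold)
    if (nrow(new_centers) > 0) queue <- rbind(queue, new_centers)
  }
  acc
}

#' Select the vein threshold by connectivity
#'
#' For each threshold in the grid the mean-probability map is binarised and
#' its 8-connected components counted; the threshold minimising the count is
#' returned (ties towards the smaller threshold). An empty mask is assigned
#' an infinite count so the selector cannot win by predicting nothing.
#'
#' @param acc a [prob_accumulator()].
#' @param grid candidate thresholds in (0, 1).
#' @return list with `theta`, `mask`, and `counts` (tibble theta /
#'   n_components).
#' @export
select_threshold <- function(acc, grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(grid) == 0) abort("threshold grid is empty")
  if (!any(acc$visit_count > 0)) abort("accumulator is empty")
  meanp <- accumulator_mean(acc)
  visited <- acc$visit_count > 0
  counts <- vapply(grid, function(th) {
    m <- visited & (meanp >= th)
    if (!any(m)) return(Inf)
    as.numeric(cpp_label_components(m, 8L)$count)
  }, numeric(1))
  best <- which.min(counts)
  theta <- grid[best]
  mask <- visited & (meanp >= theta)
  list(theta = theta, mask = mask,
       counts = tibble(theta = grid, n_components = counts))
}
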