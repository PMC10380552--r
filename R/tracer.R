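# Boundary-tracing leaf segmenter: training-target construction from traced
# contours, the weighted-MSE objective, and the iterative tracing loop that
# follows the blade margin and closes the loop on itself.

#' Tracer configuration
#'
#' `tracer_config()` carries the full-scale settings (256-px 4-channel tiles,
#' 7 encoder blocks, 128 displacements, 32-px commits, 10-px closure radius,
#' 10 burn-in iterations). `scaled_tracer_config()` is the desk-scale
#' counterpart used in tests and examples (64-px tiles, 3 blocks, 32
#' displacements) with every length scaled by the same factor of 4.
#'
#' @param tile_size tile side in px (even).
#' @param N number of predicted displacements.
#' @param widths encoder block widths (pooling between blocks; the final
#'   block is unpooled).
#' @param overlay_len number of recent trace pixels drawn into the path
#'   overlay channel.
#' @param step_commit predicted pixels committed per iteration.
#' @param closure_radius closure distance in px.
#' @param burn_in iterations whose pixels are discarded from the final trace.
#' @param path_smooth half-window of a moving average applied to the
#'   predicted displacement sequence before pixels are committed (0 =
#'   none); suppresses sub-pixel prediction noise in the rasterized chain.
#' @param epochs,batch,patience,lr,seed training settings (Adam).
#' @param val_fraction fraction of images held out for validation.
#' @param train_augment list with `flip`, `jitter`, `color`: fresh random
#'   flips, integer translations and channel jitter applied to each tile
#'   every epoch inside the training loop (displacement targets transformed
#'   exactly). This per-epoch re-augmentation is what keeps a small tile set
#'   from being memorised; the dataset builder's own augmentation should
#'   then be limited to direction randomisation.
#' @param verbose print per-epoch losses.
#' @export
tracer_config <- function(tile_size = 256, N = 128,
                          widths = c(16, 24, 32, 48, 64, 96, 128),
                          overlay_len = 256, step_commit = 32,
                          closure_radius = 10, burn_in = 10,
                          path_smooth = 1L,
                          epochs = 1000, batch = 256, patience = 20,
                          lr = 1e-3, seed = 1L, val_fraction = 0.2,
                          train_augment = list(flip = TRUE, jitter = 8,
                                               color = 0.1),
                          verbose = FALSE) {
  list(tile_size = as.integer(tile_size), N = as.integer(N),
       widths = as.integer(widths), overlay_len = as.integer(overlay_len),
       step_commit = as.integer(step_commit), closure_radius = closure_radius,
       burn_in = as.integer(burn_in), path_smooth = as.integer(path_smooth),
       epochs = as.integer(epochs),
       batch = as.integer(batch), patience = as.integer(patience), lr = lr,
       seed = as.integer(seed), val_fraction = val_fraction,
       train_augment = train_augment, verbose = verbose)
}

#' @rdname tracer_config
#' @param ... overrides.
#' @export
scaled_tracer_config <- function(...) {
  defaults <- list(tile_size = 64, N = 32, widths = c(6, 12, 24),
                   overlay_len = 64, step_commit = 8, closure_radius = 5,
                   burn_in = 10, path_smooth = 2L, epochs = 40, batch = 32,
                   patience = 20, lr = 2e-3, seed = 1L,
                   train_augment = list(flip = TRUE, jitter = 3, color = 0.05))
  do.call(tracer_config, utils::modifyList(defaults, list(...)))
}

# sample N points ahead along a closed pixel contour at equal arc-length
# spacing, starting after `start_idx`, moving in `direction` (+1/-1).
# Returns an N x 2 matrix of (row, col) positions (real-valued).
sample_contour_ahead <- function(pts, start_idx, direction, N, spacing) {
  n <- nrow(pts)
  need <- N * spacing + 2
  idx <- start_idx
  walked <- 0
  ord <- integer(0)
  while (walked < need && length(ord) < 3 * n + 2) {
    ord <- c(ord, idx)
    nxt <- ((idx - 1 + direction) %% n) + 1
    walked <- walked + sqrt(sum((pts[nxt, ] - pts[idx, ])^2))
    idx <- nxt
  }
  ord <- c(ord, idx)
  path <- pts[ord, , drop = FALSE]
  seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                            path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  s <- seq_len(N) * spacing
  out <- matrix(0, N, 2)
  for (k in seq_len(N)) {
    j <- findInterval(s[k], cum, rightmost.closed = TRUE)
    j <- min(max(j, 1), nrow(path) - 1)
    t <- if (cum[j + 1] > cum[j]) (s[k] - cum[j]) / (cum[j + 1] - cum[j]) else 0
    out[k, ] <- path[j, ] + t * (path[j + 1, ] - path[j, ])
  }
  out
}

# clamp displacement targets where the contour exits the tile:
# the exit point replaces every subsequent target.
clamp_to_tile <- function(disp, half) {
  inside <- abs(disp[1, ]) <= (half - 1) & abs(disp[2, ]) <= (half - 1)
  if (all(inside)) return(disp)
  first_out <- which(!inside)[1]
  exit <- if (first_out == 1) c(0, 0) else disp[, first_out - 1]
  disp[, first_out:ncol(disp)] <- exit
  disp
}

# path-overlay channel: mark the K contour pixels behind `start_idx` (and the
# centre itself) in tile coordinates.
overlay_channel <- function(pts, start_idx, direction, K, center, size) {
  n <- nrow(pts)
  half <- size / 2
  ctr <- half + 1
  idx <- ((start_idx - 1 - direction * (0:K)) %% n) + 1
  rel_r <- pts[idx, 1] - center[1] + ctr
  rel_c <- pts[idx, 2] - center[2] + ctr
  keep <- rel_r >= 1 & rel_r <= size & rel_c >= 1 & rel_c <= size
  ov <- matrix(0, size, size)
  ov[cbind(rel_r[keep], rel_c[keep])] <- 1
  ov
}

#' Build one tracer training target
#'
#' A 4-channel tile (RGB plus an overlay of the recently traced path) centred
#' on a contour pixel, paired with `N` ground-truth displacements sampled at
#' equal arc-length spacing `tile_size / 2 / N` along the contour from the
#' centre towards the tile edge; targets are clamped at the tile-exit point.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param contour a closed [leaf_contour()].
#' @param start_index index of the contour pixel at the tile centre.
#' @param direction +1 (stored orientation) or -1 (reversed).
#' @param N number of displacement targets.
#' @param tile_size tile side in px.
#' @param overlay_len path pixels drawn into the overlay channel.
#' @param center_offset optional integer (row, col) jitter of the tile centre.
#' @return list with `tile` (`tile_size x tile_size x 4`), `displacements`
#'   (`2 x N`, rows = row/col offsets), `center`.
#' @export
make_trace_target <- function(image, contour, start_index, direction = 1,
                              N = 128, tile_size = 256, overlay_len = 256,
                              center_offset = c(0L, 0L)) {
  pts <- contour$points
  if (!contour$closed) abort("contour must be closed")
  if (nrow(pts) < N) abort("contour shorter than N pixels")
  half <- tile_size / 2
  center <- pts[start_index, ] + as.integer(center_offset)
  spacing <- half / N
  ahead <- sample_contour_ahead(pts, start_index, direction, N, spacing)
  disp <- t(ahead) - as.numeric(center)
  disp <- clamp_to_tile(disp, half)
  res <- cpp_extract_tiles(image, matrix(as.integer(center), 1, 2),
                           as.integer(tile_size), 1)
  tile <- array(0, c(tile_size, tile_size, 4))
  tile[, , 1:3] <- array(res$tiles, c(tile_size, tile_size, 3))
  tile[, , 4] <- overlay_channel(pts, start_index, direction, overlay_len,
                                 center, tile_size)
  list(tile = tile, displacements = disp, center = center)
}

#' Build a tracer training set from traced masks
#'
#' One target per sampled contour pixel per image, with randomized trace
#' direction and (optionally) rotation, flips, centre jitter and color
#' perturbation applied to each tile; displacement targets are transformed
#' consistently with the spatial augmentation.
#'
#' @param samples list of `synthetic_sample`s or lists with `image` and
#'   `leaf_mask`.
#' @param config a [tracer_config()].
#' @param augment an [augment_config()] (use [augment_none()] to disable).
#' @param stride keep every `stride`-th contour pixel as a tile centre.
#' @param seed RNG seed for direction/augmentation draws.
#' @return A `tracer_dataset`: list with `X` (tiles), `Y` (flattened
#'   displacement targets), `image_id`, and the geometry settings.
#' @export
build_tracer_dataset <- function(samples, config = tracer_config(),
                                 augment = augment_config(), stride = 1L,
                                 seed = 1L) {
  S <- config$tile_size; N <- config$N
  half <- S / 2
  withr::with_seed(seed, {
    xs <- list(); ys <- list(); ids <- integer(0)
    for (si in seq_along(samples)) {
      smp <- samples[[si]]
      img <- if (!is.null(smp$image)) smp$image else smp$pixels
      contour <- mask_to_contour(smp$leaf_mask)
      n <- nrow(contour$points)
      starts <- seq(1L, n, by = as.integer(stride))
      for (st in starts) {
        dir <- sample(c(1L, -1L), 1)
        jit <- if (augment$jitter > 0) {
          as.integer(round(runif(2, -augment$jitter, augment$jitter)))
        } else c(0L, 0L)
        # extract oversized when rotating so the crop stays dense
        angle <- if (augment$rotate > 0) runif(1, -augment$rotate, augment$rotate) else 0
        tgt_size <- if (angle != 0) 2L * ceiling(S * sqrt(2) / 2) else S
        tg <- make_trace_target(img, contour, st, dir, N, tgt_size,
                                config$overlay_len, jit)
        tile <- tg$tile; disp <- tg$displacements
        if (angle != 0) {
          tile <- rotate_tile(tile, angle, fill = 1)
          tile[, , 4] <- round(tile[, , 4])
          disp <- rotate_displacements(disp, angle)
          # crop the central S x S window (centres coincide)
          off <- (tgt_size - S) / 2
          tile <- tile[(off + 1):(off + S), (off + 1):(off + S), , drop = FALSE]
        }
        disp <- clamp_to_tile(disp, half)
        if (augment$flip && runif(1) < 0.5) {
          tile <- flip_tile_h_center(tile)
          disp[2, ] <- -disp[2, ]
        }
        if (augment$color > 0) tile <- color_jitter(tile, augment$color)
        xs[[length(xs) + 1]] <- tile
        ys[[length(ys) + 1]] <- c(disp[1, ], disp[2, ])
        ids <- c(ids, si)
      }
    }
    X <- array(unlist(xs), c(S, S, 4, length(xs)))
    Y <- matrix(unlist(ys), 2 * N, length(ys))
    structure(list(X = X, Y = Y, image_id = ids, tile_size = S, N = N),
              class = "tracer_dataset")
  })
}

#' Train the boundary tracer
#'
#' Splits the tile set by source image (so validation images are never seen
#' in training), minimises the displacement loss
#' with Adam, and keeps the best-validation
#' checkpoint with early stopping.
#'
#' @param dataset a `tracer_dataset` from [build_tracer_dataset()].
#' @param config a [tracer_config()].
#' @return A `leaf_tracer_model`.
#' @export
train_tracer <- function(dataset, config = tracer_config()) {
  ids <- unique(dataset$image_id)
  if (length(ids) < 2) abort("need at least 2 images for an image-level split")
  n_val <- max(1L, round(config$val_fraction * length(ids)))
  val_ids <- withr::with_seed(config$seed, sample(ids, n_val))
  tr <- dataset$image_id %in% setdiff(ids, val_ids)
  if (!any(tr) || all(tr)) abort("empty train/validation split")
  arch <- encoder_arch(dataset$tile_size, 4L, config$widths,
                       2L * dataset$N, "linear")
  loss <- list(mode = "wmse", weights = trace_weights(dataset$N))
  fit <- run_training(arch, dataset$X[, , , tr, drop = FALSE],
                      dataset$Y[, tr, drop = FALSE],
                      dataset$X[, , , !tr, drop = FALSE],
                      dataset$Y[, !tr, drop = FALSE], loss, config)
  m <- new_conv_model(arch, fit, config,
                      list(train = setdiff(ids, val_ids), val = val_ids),
                      "leaf_tracer_model")
  m$N <- dataset$N
  m
}

#' Forward pass of the tracer on tiles
#'
#' @param model a `leaf_tracer_model`.
#' @param tiles a single `S x S x 4` tile or an `S x S x 4 x n` array.
#' @return `2 x N` displacement matrix (or a list of them for a batch).
#' @export
tracer_forward <- function(model, tiles) {
  single <- length(dim(tiles)) == 3
  out <- model_forward(model, tiles)
  N <- nrow(out) / 2
  split_one <- function(v) rbind(v[seq_len(N)], v[N + seq_len(N)])
  if (single) return(split_one(out[, 1]))
  lapply(seq_len(ncol(out)), function(j) split_one(out[, j]))
}

#' Plug-in oracle tracer
#'
#' A stand-in for a trained tracer that reads displacements straight off a
#' ground-truth contour; used to validate the tracing loop independently of
#' model quality.
#'
#' @param truth a closed [leaf_contour()] or a single-component mask.
#' @param direction +1 or -1 along the stored (counter-clockwise) orientation.
#' @export
oracle_tracer <- function(truth, direction = 1L) {
  contour <- if (inherits(truth, "leaf_contour")) truth else mask_to_contour(truth)
  structure(list(contour = contour, direction = as.integer(direction)),
            class = "tracer_oracle")
}

oracle_displacements <- function(oracle, center, N, tile_size) {
  pts <- oracle$contour$points
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2
  idx <- which.min(d2)
  ahead <- sample_contour_ahead(pts, idx, oracle$direction, N, (tile_size / 2) / N)
  clamp_to_tile(t(ahead) - as.numeric(center), tile_size / 2)
}

#' Trace a leaf and fill the resulting contour
#'
#' Starts from a tile centred at the topmost pixel of the rough Otsu
#' segmentation, repeatedly commits the first `step_commit` predicted boundary
#' pixels and re-centres there. The first `burn_in` iterations are discarded
#' from the stored contour. The trace closes when a committed pixel comes
#' within `closure_radius` px of a stored contour pixel older than a guard
#' window of `2 * step_commit` pixels; a straight line then joins the trace to
#' the matched pixel and the contour interior is filled.
#'
#' @param model a `leaf_tracer_model` or an [oracle_tracer()].
#' @param scan a [leaf_scan()].
#' @param config a [tracer_config()]; defaults to the model's own.
#' @param init_direction `"cw"` or `"ccw"` initial trace direction hint taken
#'   from the rough contour.
#' @return list with `mask`, `contour`, `iterations`, `closed`.
#' @export
trace_leaf <- function(model, scan, config = NULL,
                       init_direction = c("cw", "ccw")) {
  init_direction <- match.arg(init_direction)
  if (is.null(config)) {
    config <- if (inherits(model, "tracer_oracle")) scaled_tracer_config()
    else model$config
  }
  S <- config$tile_size
  N <- if (inherits(model, "tracer_oracle")) config$N else model$N
  half <- S / 2
  img <- scan$pixels
  dims <- dim(img)[1:2]

  rough <- rough_foreground(scan)
  rc <- cpp_moore_boundary(rough)
  start <- rc[1, ]  # topmost (then leftmost) foreground pixel
  dir_sign <- if (init_direction == "cw") -1L else 1L
  n_rc <- nrow(rc)
  seed_idx <- ((1 - 1 - dir_sign * (config$overlay_len:0)) %% n_rc) + 1
  recent <- rc[seed_idx, , drop = FALSE]

  center <- start
  stored <- NULL
  guard <- 2L * config$step_commit
  cap <- ceiling(4 * n_rc / config$step_commit) + config$burn_in
  closed <- FALSE
  iter <- 0L
  close_line <- NULL

  while (!closed) {
    iter <- iter + 1L
    if (iter > cap) {
      abort("tracing diverged", class = "leaftrace_diverged",
            partial = stored, iterations = iter)
    }
    if (inherits(model, "tracer_oracle")) {
      disp <- oracle_displacements(model, center, N, S)
    } else {
      res <- cpp_extract_tiles(img, matrix(as.integer(center), 1, 2),
                               as.integer(S), 1)
      tile <- array(0, c(S, S, 4))
      tile[, , 1:3] <- array(res$tiles, c(S, S, 3))
      ctr <- half + 1
      rel_r <- recent[, 1] - center[1] + ctr
      rel_c <- recent[, 2] - center[2] + ctr
      keep <- rel_r >= 1 & rel_r <= S & rel_c >= 1 & rel_c <= S
      ov <- matrix(0, S, S)
      ov[cbind(rel_r[keep], rel_c[keep])] <- 1
      tile[, , 4] <- ov
      disp <- tracer_forward(model, tile)
    }
    pred <- cbind(center[1] + disp[1, ], center[2] + disp[2, ])
    sm <- config$path_smooth %||% 0L
    if (sm > 0 && nrow(pred) > 2 * sm + 1) {
      k <- 2 * sm + 1
      sm_col <- function(v) as.numeric(stats::filter(v, rep(1 / k, k),
                                                     sides = 2))
      sr <- sm_col(pred[, 1]); sc <- sm_col(pred[, 2])
      keep <- !is.na(sr)
      pred[keep, 1] <- sr[keep]; pred[keep, 2] <- sc[keep]
    }
    pred <- pred[seq_len(min(config$step_commit, nrow(pred))), , drop = FALSE]
    pred <- cbind(pmin(pmax(round(pred[, 1]), 1), dims[1]),
                  pmin(pmax(round(pred[, 2]), 1), dims[2]))
    # chain into an 8-connected committed path
    commit <- matrix(as.integer(center), 1, 2)
    for (k in seq_len(nrow(pred))) {
      seg <- cpp_bresenham(commit[nrow(commit), 1], commit[nrow(commit), 2],
                           pred[k, 1], pred[k, 2])
      if (nrow(seg) > 1) commit <- rbind(commit, seg[-1, , drop = FALSE])
    }
    if (nrow(commit) > 1) commit <- commit[-1, , drop = FALSE]

    # closure test against stored contour older than the guard window
    if (!is.null(stored) && nrow(stored) > guard) {
      cand <- stored[seq_len(nrow(stored) - guard), , drop = FALSE]
      for (k in seq_len(nrow(commit))) {
        d2 <- (cand[, 1] - commit[k, 1])^2 + (cand[, 2] - commit[k, 2])^2
        jmin <- which.min(d2)
        if (sqrt(d2[jmin]) <= config$closure_radius) {
          commit <- commit[seq_len(k), , drop = FALSE]
          close_line <- cpp_bresenham(commit[k, 1], commit[k, 2],
                                      cand[jmin, 1], cand[jmin, 2])
          closed <- TRUE
          break
        }
      }
    }
    if (iter > config$burn_in) {
      keep_n <- nrow(commit)
      stored <- rbind(stored, commit[seq_len(keep_n), , drop = FALSE])
    }
    recent <- utils::tail(rbind(recent, commit), config$overlay_len)
    center <- commit[nrow(commit), ]
  }

  pts <- rbind(stored, if (!is.null(close_line) && nrow(close_line) > 1)
    close_line[-1, , drop = FALSE])
  contour <- leaf_contour(pts, closed = TRUE)
  mask <- fill_contour(contour, dims)
  list(mask = mask, contour = contour, iterations = iter, closed = TRUE)
}
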