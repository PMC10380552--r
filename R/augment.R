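# Tile-level augmentation. Spatial transforms are applied to the tile raster
# and, for the tracer, to its displacement targets consistently. The grower's
# 3x3 neighbourhood labels only permute exactly under quarter-turn rotations
# and axis flips, so its spatial augmentation is restricted to those.

#' Augmentation configuration
#'
#' @param rotate maximum absolute rotation in radians (continuous, tracer and
#'   U-Net tiles; the grower uses quarter-turns only).
#' @param flip allow horizontal/vertical flips.
#' @param jitter maximum center jitter in px (tracer targets).
#' @param color strength of channel scale / brightness perturbation.
#' @param blur probability of a Gaussian blur (grower tiles).
#' @export
augment_config <- function(rotate = pi, flip = TRUE, jitter = 8,
                           color = 0.1, blur = 0.2) {
  list(rotate = rotate, flip = flip, jitter = jitter, color = color, blur = blur)
}

#' No-op augmentation
#' @export
augment_none <- function() augment_config(rotate = 0, flip = FALSE, jitter = 0,
                                          color = 0, blur = 0)

# rotate an H x W x C tile about its center pixel (size/2 + 1) by `angle`,
# nearest-neighbour sampling, out-of-support filled with `fill`.
rotate_tile <- function(tile, angle, fill = 1) {
  d <- dim(tile)
  S <- d[1]
  ctr <- S / 2 + 1
  co <- cos(angle); si <- sin(angle)
  i <- matrix(seq_len(S) - ctr, S, S)
  j <- matrix(seq_len(S) - ctr, S, S, byrow = TRUE)
  # output (i, j) samples input at R(-angle) (i, j)
  src_r <- round(co * i + si * j + ctr)
  src_c <- round(-si * i + co * j + ctr)
  ok <- src_r >= 1 & src_r <= S & src_c >= 1 & src_c <= S
  out <- array(fill, d)
  idx_ok <- which(ok)
  src_idx <- cbind(src_r[idx_ok], src_c[idx_ok])
  for (ch in seq_len(d[3])) {
    plane <- matrix(fill, S, S)
    plane[idx_ok] <- tile[, , ch][src_idx]
    out[, , ch] <- plane
  }
  out
}

# rotate displacement pairs (2 x N; rows = d_row, d_col) with the tile
rotate_displacements <- function(disp, angle) {
  co <- cos(angle); si <- sin(angle)
  rbind(co * disp[1, ] - si * disp[2, ],
        si * disp[1, ] + co * disp[2, ])
}

flip_tile_h <- function(tile) tile[, rev(seq_len(dim(tile)[2])), , drop = FALSE]
flip_tile_v <- function(tile) tile[rev(seq_len(dim(tile)[1])), , , drop = FALSE]

# channel-wise color jitter on the RGB channels only
color_jitter <- function(tile, strength, rgb_channels = 1:3) {
  if (strength <= 0) return(tile)
  sc <- runif(length(rgb_channels), 1 - strength, 1 + strength)
  sh <- runif(1, -strength / 2, strength / 2)
  for (k in seq_along(rgb_channels)) {
    ch <- rgb_channels[k]
    tile[, , ch] <- pmin(1, pmax(0, tile[, , ch] * sc[k] + sh))
  }
  tile
}

# Centre-pixel-fixed variants for even-sized tiles. A plain flip or
# quarter-turn of an even grid moves the centre pixel (S/2 + 1) by one, which
# would misalign a tile with a label tied to its centre; these versions shift
# the result by one row/column (filling the vacated edge) so the centre pixel
# stays put. Labels centred on the pixel (the grower's 3x3 grid) then
# transform exactly.
flip_tile_h_center <- function(tile, fill = 1) {
  out <- flip_tile_h(tile)
  S <- dim(out)[2]
  out <- out[, c(1, seq_len(S - 1)), , drop = FALSE]
  out[, 1, ] <- fill
  out
}

rot90_tile_center <- function(tile, k, fill = 1) {
  k <- k %% 4
  for (i in seq_len(k)) {
    tile <- rot90_tile(tile, 1)
    S <- dim(tile)[1]
    tile <- tile[c(1, seq_len(S - 1)), , , drop = FALSE]
    tile[1, , ] <- fill
  }
  tile
}

# quarter-turn rotation of a tile (k * 90 degrees counter-clockwise on screen)
rot90_tile <- function(tile, k) {
  k <- k %% 4
  if (k == 0) return(tile)
  d <- dim(tile)
  out <- tile
  for (ch in seq_len(d[3])) {
    m <- tile[, , ch]
    for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    out[, , ch] <- m
  }
  out
}

# apply the same quarter-turn to a 3 x 3 label matrix
rot90_mat <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}
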