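# Trait extraction from segmentation masks, in physical units derived from
# the scan DPI: leaf morphology and color, vein architecture with diameter
# classes, and petiole geometry.

mm_per_px <- function(dpi) 25.4 / dpi

# convex hull area of a pixel set, corrected so that a convex digital region
# recovers its pixel-count area (polygon area + boundary lattice points / 2
# + 1, Pick's relation for lattice polygons).
hull_area_px <- function(coords) {
  if (nrow(coords) < 3) return(nrow(coords))
  h <- grDevices::chull(coords[, 2], coords[, 1])
  hx <- coords[h, 2]; hy <- coords[h, 1]
  n <- length(h)
  j <- c(2:n, 1)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  b <- sum(vapply(seq_len(n), function(i) {
    dgcd(abs(hx[j[i]] - hx[i]), abs(hy[j[i]] - hy[i]))
  }, numeric(1)))
  area + b / 2 + 1
}

dgcd <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

# Kulpa-corrected boundary length: raw chain-code arc length (1 per axial
# step, sqrt(2) per diagonal step) overestimates smooth perimeters by ~5%,
# which biases circularity low; the classical correction weights axial steps
# 0.948 and diagonal steps 1.343.
perimeter_estimate <- function(contour) {
  pts <- if (inherits(contour, "leaf_contour")) contour$points else contour
  n <- nrow(pts)
  if (n < 2) return(0)
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  step <- abs(nxt - pts)
  diag <- step[, 1] > 0 & step[, 2] > 0
  sum(ifelse(diag, 1.343, 0.948) * (pmax(step[, 1], step[, 2]) > 0))
}

#' Leaf morphology and color traits
#'
#' Area (cm^2), perimeter (cm, Kulpa-corrected chain-code arc length, which
#' is close to unbiased for smooth boundaries), circularity `4*pi*A/P^2`,
#' solidity (area / convex hull area), and mean R, G, B, hue, saturation,
#' brightness over leaf pixels.
#'
#' @param leaf_mask single-component logical mask.
#' @param scan the [leaf_scan()] the mask belongs to.
#' @return One-row tibble of leaf traits.
#' @export
leaf_morphology <- function(leaf_mask, scan) {
  if (!any(leaf_mask)) abort("leaf mask is empty")
  mm <- mm_per_px(scan$dpi)
  area_px <- sum(leaf_mask)
  contour <- mask_to_contour(leaf_mask)
  per_px <- perimeter_estimate(contour)
  coords <- which(leaf_mask, arr.ind = TRUE)
  px <- scan$pixels
  rgb <- vapply(1:3, function(ch) px[, , ch][leaf_mask], numeric(area_px))
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  tibble(
    leaf_area = area_px * mm^2 / 100,
    leaf_perimeter = per_px * mm / 10,
    circularity = 4 * pi * area_px / per_px^2,
    solidity = area_px / hull_area_px(coords),
    color_mean_r = mean(rgb[, 1]), color_mean_g = mean(rgb[, 2]),
    color_mean_b = mean(rgb[, 3]),
    color_mean_hue = mean(hsv[1, ]), color_mean_saturation = mean(hsv[2, ]),
    color_mean_brightness = mean(hsv[3, ]))
}

# per-pixel arc-length weights of a skeleton: half the summed length of
# incident edges (4-neighbour edges weight 1, diagonal sqrt(2); a diagonal
# edge is only counted when not short-circuited by a shared 4-neighbour).
skeleton_length_weights <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- skel
  s <- function(dr, dc) pad[2:(H + 1) + dr, 2:(W + 1) + dc]
  wsum <- matrix(0, H, W)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    wsum <- wsum + (s(d[1], d[2]) & skel)
  }
  for (d in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    diag_ok <- s(d[1], d[2]) & skel & !(s(d[1], 0) | s(0, d[2]))
    wsum <- wsum + sqrt(2) * diag_ok
  }
  wsum / 2
}

#' Vein architecture traits
#'
#' Veins are restricted to the leaf interior, skeletonised, and measured:
#' total length (mm) from the skeleton arc length, local diameter from twice
#' the Euclidean distance transform at each skeleton pixel, mean diameter,
#' vein area (mm^2), per-class length/area for the diameter classes
#' < 0.25 mm, 0.25-0.80 mm and >= 0.80 mm, and vein density (vein pixels /
#' leaf pixels, dimensionless).
#'
#' @param vein_mask logical vein mask.
#' @param leaf_mask logical leaf mask.
#' @param dpi scan resolution.
#' @return One-row tibble of vein traits.
#' @export
vein_traits <- function(vein_mask, leaf_mask, dpi = 300) {
  mm <- mm_per_px(dpi)
  vm <- vein_mask & leaf_mask
  if (!any(vm)) {
    return(tibble(vein_total_length = 0, vein_mean_diameter = 0,
                  vein_area = 0,
                  vein_length_class_a = 0, vein_length_class_b = 0,
                  vein_length_class_c = 0, vein_area_class_a = 0,
                  vein_area_class_b = 0, vein_area_class_c = 0,
                  vein_density = 0))
  }
  skel <- cpp_skeletonize(vm)
  edt <- as.matrix(EBImage::distmap(EBImage::Image(vm * 1)))
  wlen <- skeleton_length_weights(skel)
  spx <- which(skel)
  diam_mm <- 2 * edt[spx] * mm
  len_mm <- wlen[spx] * mm
  cls <- cut(diam_mm, c(-Inf, 0.25, 0.80, Inf), labels = c("a", "b", "c"),
             right = FALSE)
  len_by <- vapply(c("a", "b", "c"),
                   function(k) sum(len_mm[cls == k]), numeric(1))
  area_by <- vapply(c("a", "b", "c"),
                    function(k) sum(len_mm[cls == k] * diam_mm[cls == k]),
                    numeric(1))
  tibble(
    vein_total_length = sum(len_mm),
    vein_mean_diameter = mean(diam_mm),
    vein_area = sum(vm) * mm^2,
    vein_length_class_a = len_by[["a"]],
    vein_length_class_b = len_by[["b"]],
    vein_length_class_c = len_by[["c"]],
    vein_area_class_a = area_by[["a"]],
    vein_area_class_b = area_by[["b"]],
    vein_area_class_c = area_by[["c"]],
    vein_density = sum(vm) / sum(leaf_mask))
}

#' Extract the petiole mask
#'
#' The petiole is the largest 8-connected component of vein-classified pixels
#' outside the leaf segmentation.
#'
#' @param vein_mask vein-classified pixels (including any outside the blade).
#' @param leaf_mask leaf-body mask.
#' @return Logical mask, or `NULL` (with a `leaftrace_no_petiole` condition
#'   message) when no vein pixel lies outside the leaf.
#' @export
petiole_extract <- function(vein_mask, leaf_mask) {
  outside <- vein_mask & !leaf_mask
  if (!any(outside)) {
    rlang::signal("no petiole found", class = "leaftrace_no_petiole")
    return(NULL)
  }
  largest_component(outside, 8)
}

# order a path-like skeleton from one endpoint; returns index matrix in order
order_skeleton_path <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  if (nrow(pix) == 0) return(pix)
  H <- nrow(skel)
  key <- function(r, c) (c - 1L) * H + r
  have <- new.env(hash = TRUE)
  for (i in seq_len(nrow(pix))) assign(as.character(key(pix[i, 1], pix[i, 2])), i, have)
  nb_count <- function(r, c) {
    cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (exists(as.character(key(r + dr, c + dc)), have, inherits = FALSE)) cnt <- cnt + 1L
    }
    cnt
  }
  deg <- vapply(seq_len(nrow(pix)), function(i) nb_count(pix[i, 1], pix[i, 2]),
                integer(1))
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- logical(nrow(pix))
  ord <- integer(0)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    ord <- c(ord, cur)
    nxt <- NA_integer_
    r <- pix[cur, 1]; c <- pix[cur, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- as.character(key(r + dr, c + dc))
      if (exists(k, have, inherits = FALSE)) {
        j <- get(k, have)
        if (!visited[j] && is.na(nxt)) nxt <- j
      }
    }
    if (is.na(nxt)) break
    cur <- nxt
  }
  pix[ord, , drop = FALSE]
}

#' Petiole measurements
#'
#' Length is the longer side of the minimum-area rotated bounding rectangle.
#' Width is the mean local diameter (2 x EDT) over skeleton pixels whose
#' arc-length position lies in the central 20% of the skeleton, matching how
#' calipers are placed near the petiole midpoint. Area from the pixel count;
#' volume as a solid of revolution (sum of local cylinder slices
#' `pi * (d/2)^2 * ds` along the skeleton).
#'
#' @param petiole_mask logical mask.
#' @param dpi scan resolution.
#' @return One-row tibble: `petiole_length`, `petiole_width`,
#'   `petiole_area` (mm^2), `petiole_volume` (mm^3); width is `NA` if the
#'   mask vanishes under skeletonisation.
#' @export
petiole_measurements <- function(petiole_mask, dpi = 300) {
  if (!any(petiole_mask)) abort("petiole mask is empty")
  mm <- mm_per_px(dpi)
  coords <- which(petiole_mask, arr.ind = TRUE)
  len_px <- min_area_rect_length(coords)
  skel <- cpp_skeletonize(petiole_mask)
  edt <- as.matrix(EBImage::distmap(EBImage::Image(petiole_mask * 1)))
  width_mm <- NA_real_
  volume_mm3 <- NA_real_
  if (any(skel)) {
    path <- order_skeleton_path(skel)
    steps <- if (nrow(path) > 1) {
      sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
    } else numeric(0)
    arc <- c(0, cumsum(steps))
    total <- max(arc, 1e-9)
    pos <- arc / total
    central <- pos >= 0.4 & pos <= 0.6
    if (!any(central)) central <- rep(TRUE, nrow(path))
    d_all <- 2 * edt[path] * mm
    width_mm <- mean(d_all[central])
    ds <- c(steps, 0) * mm
    volume_mm3 <- sum(pi * (d_all / 2)^2 * ds)
  }
  tibble(petiole_length = len_px * mm,
         petiole_width = width_mm,
         petiole_area = nrow(coords) * mm^2,
         petiole_volume = volume_mm3)
}

# rotating calipers: longer side of the minimum-area rotated bounding
# rectangle of a pixel set (+1 px so a straight bar measures its full span)
min_area_rect_length <- function(coords) {
  if (nrow(coords) == 1) return(1)
  h <- grDevices::chull(coords[, 2], coords[, 1])
  hx <- coords[h, 2]; hy <- coords[h, 1]
  n <- length(h)
  if (n < 2) return(1)
  best_area <- Inf; best_long <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    el <- sqrt(ex^2 + ey^2)
    if (el < 1e-9) next
    ux <- ex / el; uy <- ey / el
    proj_u <- hx * ux + hy * uy
    proj_v <- -hx * uy + hy * ux
    du <- diff(range(proj_u)); dv <- diff(range(proj_v))
    area <- du * dv
    if (area < best_area) {
      best_area <- area
      best_long <- max(du, dv)
    }
  }
  best_long + 1
}

#' Full trait record for one sample
#'
#' Combines [leaf_morphology()], [vein_traits()] and petiole traits into a
#' single one-row tibble. The petiole is taken from `petiole_mask` if given,
#' otherwise extracted as the largest vein component outside the leaf; when
#' absent, petiole traits are `NA`.
#'
#' @param scan a [leaf_scan()].
#' @param leaf_mask,vein_mask segmentation masks.
#' @param petiole_mask optional petiole mask.
#' @return One-row tibble keyed by `sample_id`.
#' @export
extract_traits <- function(scan, leaf_mask, vein_mask, petiole_mask = NULL) {
  if (is.null(petiole_mask)) {
    petiole_mask <- petiole_extract(vein_mask, leaf_mask)
  }
  pet <- if (is.null(petiole_mask) || !any(petiole_mask)) {
    tibble(petiole_length = NA_real_, petiole_width = NA_real_,
           petiole_area = NA_real_, petiole_volume = NA_real_)
  } else {
    petiole_measurements(petiole_mask, scan$dpi)
  }
  dplyr::bind_cols(tibble(sample_id = scan$sample_id),
                   leaf_morphology(leaf_mask, scan),
                   vein_traits(vein_mask, leaf_mask, scan$dpi),
                   pet)
}
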