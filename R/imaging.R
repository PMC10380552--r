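# Shared raster vocabulary: scans, contours, tiles, connectivity, units.
# Convention: all coordinates are 1-based (row, col), origin top-left.

#' Create a leaf scan object
#'
#' Wraps an RGB raster with its scan resolution. Pixel values are expected in
#' `[0, 1]`; 8-bit integer input is rescaled.
#'
#' @param pixels numeric array `H x W x 3`.
#' @param dpi scan resolution in dots per inch (default 300, the resolution of
#'   the flatbed scans the methods were designed for).
#' @param sample_id optional sample identifier.
#' @return An object of class `leaf_scan` with elements `pixels`, `dpi`,
#'   `sample_id`.
#' @export
leaf_scan <- function(pixels, dpi = 300, sample_id = "sample") {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("`pixels` must be an H x W x 3 array")
  }
  if (dpi <= 0) abort("`dpi` must be positive")
  if (prod(dim(pixels)) == 0) abort("raster is empty")
  if (max(pixels) > 1 + 1e-8) pixels <- pixels / 255
  structure(list(pixels = pixels, dpi = dpi, sample_id = sample_id),
            class = "leaf_scan")
}

#' @export
print.leaf_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<leaf_scan '%s': %d x %d px @ %g DPI>\n",
              x$sample_id, d[1], d[2], x$dpi))
  invisible(x)
}

#' Convert pixel lengths to millimetres
#'
#' At `dpi` dots per inch one pixel spans `25.4 / dpi` mm.
#'
#' @param length_px length(s) in pixels (non-negative).
#' @param dpi dots per inch.
#' @return Length(s) in millimetres.
#' @export
px_to_physical <- function(length_px, dpi) {
  if (dpi <= 0) abort("`dpi` must be positive")
  if (any(length_px < 0)) abort("negative length")
  length_px * 25.4 / dpi
}

#' Rough foreground mask by automatic thresholding
#'
#' Otsu threshold on grayscale intensity; the foreground is the darker side
#' (the leaf against a near-white scanner background), and only the largest
#' 8-connected component is kept. Used to initialise the boundary tracer.
#'
#' @param scan a [leaf_scan()].
#' @return Logical matrix mask.
#' @export
rough_foreground <- function(scan) {
  px <- scan$pixels
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  if (diff(range(gray)) < 1e-3) abort("no object found", class = "leaftrace_no_object")
  th <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- gray < th
  if (!any(mask)) abort("no object found", class = "leaftrace_no_object")
  lab <- cpp_label_components(mask, 8L)
  if (lab$count == 0) abort("no object found", class = "leaftrace_no_object")
  sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$count)
  lab$labels == which.max(sizes)
}

#' Extract a square tile centred at a pixel
#'
#' The centre pixel sits at index `size/2 + 1` of the tile. Out-of-bounds
#' pixels are filled with the scanner background value (white) and flagged in
#' `pad_mask`. Values are assumed already normalised to `[0, 1]`.
#'
#' @param image numeric array `H x W x C`.
#' @param center `(row, col)` integer vector, inside the image.
#' @param size even tile side length in pixels.
#' @param fill fill value for out-of-bounds pixels (default 1, white).
#' @return A `leaf_tile`: list with `pixels` (`size x size x C`), `center`,
#'   `pad_mask`.
#' @export
extract_tile <- function(image, center, size, fill = 1) {
  d <- dim(image)
  if (center[1] < 1 || center[1] > d[1] || center[2] < 1 || center[2] > d[2]) {
    abort("tile center outside image")
  }
  if (size %% 2 != 0) abort("tile size must be even")
  res <- cpp_extract_tiles(image, matrix(as.integer(center), 1, 2), as.integer(size), fill)
  structure(list(pixels = array(res$tiles, c(size, size, d[3])),
                 center = as.integer(center),
                 pad_mask = matrix(res$pad, size, size)),
            class = "leaf_tile")
}

#' Count and label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8; an 8-connected notion of adjacency
#'   is what keeps one-pixel diagonal veins connected).
#' @return list with `count` and integer `labels` matrix (0 = background).
#' @export
connected_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  cpp_label_components(mask, as.integer(connectivity))
}

#' Construct a contour object
#'
#' @param points integer matrix `n x 2` of (row, col) coordinates.
#' @param closed whether the contour wraps around.
#' @return A `leaf_contour`.
#' @export
leaf_contour <- function(points, closed = TRUE) {
  points <- matrix(as.integer(points), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  structure(list(points = points, closed = closed), class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour: %d points, %s>\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Ordered boundary walk of a single-component mask
#'
#' Moore-neighbour tracing of the outer boundary, stored counter-clockwise
#' (as displayed, with the row axis pointing down).
#'
#' @param mask logical matrix with exactly one 8-connected component.
#' @return A closed [leaf_contour()].
#' @export
mask_to_contour <- function(mask) {
  lab <- cpp_label_components(mask, 8L)
  if (lab$count == 0) abort("mask is empty")
  if (lab$count > 1) {
    abort(paste0("mask has ", lab$count,
                 " components; select one (e.g. the largest) before tracing"))
  }
  leaf_contour(cpp_moore_boundary(mask), closed = TRUE)
}

#' Fill a closed contour into a binary mask
#'
#' Polygon scan fill: boundary pixels and all interior pixels are foreground.
#'
#' @param contour a closed [leaf_contour()].
#' @param shape `(H, W)` of the output mask.
#' @return Logical matrix.
#' @export
fill_contour <- function(contour, shape) {
  if (!inherits(contour, "leaf_contour")) abort("`contour` must be a leaf_contour")
  if (!contour$closed) abort("contour must be closed")
  cpp_fill_contour(contour$points, as.integer(shape[1]), as.integer(shape[2]))
}

#' Arc length of a pixel contour
#'
#' Sum of inter-pixel steps, counting diagonal steps as `sqrt(2)`.
#'
#' @param contour a [leaf_contour()] or an `n x 2` coordinate matrix.
#' @return Length in pixels.
#' @export
contour_arc_length <- function(contour) {
  pts <- if (inherits(contour, "leaf_contour")) contour$points else contour
  closed <- if (inherits(contour, "leaf_contour")) contour$closed else TRUE
  n <- nrow(pts)
  if (n < 2) return(0)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  d <- sqrt(rowSums((pts[idx[-1], , drop = FALSE] -
                       pts[idx[-length(idx)], , drop = FALSE])^2))
  sum(d)
}

# Largest connected component of a mask (8-connectivity); empty mask allowed.
largest_component <- function(mask, connectivity = 8) {
  lab <- cpp_label_components(mask, as.integer(connectivity))
  if (lab$count == 0) return(mask & FALSE)
  sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$count)
  lab$labels == which.max(sizes)
}

#' Read and write binary mask PNGs
#'
#' Masks are stored as single-channel PNGs with 0 = background and
#' 255 = foreground.
#'
#' @param path file path.
#' @param mask logical matrix.
#' @return `read_mask_png` returns a logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname read_mask_png
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname read_mask_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
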