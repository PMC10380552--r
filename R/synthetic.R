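# Seedable synthetic leaf-scan generator with exact ground-truth masks.
# Emulates the relevant properties of flatbed leaf-bottom scans: near-white
# background, one serrated green lamina with heterogeneous color, a single
# connected branching vein tree with tapering diameters, a petiole protruding
# below the blade, and optional scan artifacts (fold line, vertical white
# stripe, dust specks, blur patch). Artifacts perturb only the image, never
# the masks.

#' Parameters of the synthetic leaf generator
#'
#' Defaults mirror the flatbed scan format the segmentation methods target
#' (3510 x 2550 px at 300 DPI) with a leaf of realistic proportion. Tests and
#' the worked examples use scaled-down canvases for speed; all sizes are in
#' pixels so the geometry scales together.
#'
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   samples.
#' @param canvas_size `(height, width)` in pixels.
#' @param dpi scan resolution used to derive physical-unit ground truth.
#' @param lamina_scale mean lamina radius in pixels.
#' @param aspect horizontal/vertical semi-axis ratio of the blade.
#' @param serration_amplitude radial amplitude of marginal serration in px
#'   (0 gives a smooth margin).
#' @param serration_count number of serration teeth around the margin.
#' @param vein_branch_depth recursion depth of the vein tree (0 = midrib only).
#' @param vein_base_width midrib width at its base in px.
#' @param petiole_length,petiole_width petiole size in px.
#' @param artifact_flags character subset of
#'   `c("fold", "white_stripe", "dust", "blur")`.
#' @param genotype_effect dimensionless additive shift of the latent
#'   vein-density driver (scales branch lengths); used by
#'   [generate_population()].
#' @param vein_contrast brightness contrast of veins against the lamina.
#' @param margin minimum gap between the lamina extent and the canvas edge,
#'   in pixels (must be at least the tile radius used downstream).
#' @return A `leaf_gen_params` list.
#' @export
leaf_gen_params <- function(seed = 1L,
                            canvas_size = c(3510L, 2550L),
                            dpi = 300,
                            lamina_scale = 900,
                            aspect = 0.75,
                            serration_amplitude = 12,
                            serration_count = 40,
                            vein_branch_depth = 3L,
                            vein_base_width = 10,
                            petiole_length = 470,
                            petiole_width = 30,
                            artifact_flags = character(),
                            genotype_effect = 0,
                            vein_contrast = 0.35,
                            margin = 32) {
  p <- list(seed = as.integer(seed), canvas_size = as.integer(canvas_size),
            dpi = dpi, lamina_scale = lamina_scale, aspect = aspect,
            serration_amplitude = serration_amplitude,
            serration_count = as.integer(serration_count),
            vein_branch_depth = as.integer(vein_branch_depth),
            vein_base_width = vein_base_width,
            petiole_length = petiole_length, petiole_width = petiole_width,
            artifact_flags = artifact_flags,
            genotype_effect = genotype_effect,
            vein_contrast = vein_contrast, margin = margin)
  class(p) <- "leaf_gen_params"
  validate_gen_params(p)
  p
}

validate_gen_params <- function(p) {
  bad <- setdiff(p$artifact_flags, c("fold", "white_stripe", "dust", "blur"))
  if (length(bad)) abort(paste("unknown artifact flags:", paste(bad, collapse = ", ")))
  H <- p$canvas_size[1]; W <- p$canvas_size[2]
  # maximal lamina extent: ellipse + low-order perturbation (<= 12%) + serration
  ext_r <- p$lamina_scale * 1.15 + p$serration_amplitude
  ext_c <- p$lamina_scale * p$aspect * 1.15 + p$serration_amplitude
  need_h <- 2 * ext_r + p$petiole_length + 2 * p$margin
  need_w <- 2 * ext_c + 2 * p$margin
  if (need_h > H || need_w > W) {
    abort(sprintf(
      "canvas %d x %d too small for lamina_scale %g (needs >= %.0f x %.0f)",
      H, W, p$lamina_scale, need_h, need_w), class = "leaftrace_param_error")
  }
  invisible(p)
}

#' Scaled-down generator preset
#'
#' A small canvas with the same leaf proportions, used throughout the tests,
#' examples and the demo pipeline so training and inference run in seconds.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [leaf_gen_params()].
#' @export
small_leaf_params <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, canvas_size = c(288L, 224L), dpi = 300,
                   lamina_scale = 70, serration_amplitude = 3,
                   serration_count = 24, vein_branch_depth = 3L,
                   vein_base_width = 5, petiole_length = 30,
                   petiole_width = 5, margin = 32)
  args <- utils::modifyList(defaults, list(...))
  do.call(leaf_gen_params, args)
}

# triangle wave with period 1, range [-1, 1]
tri_wave <- function(x) 4 * abs(x - floor(x + 0.5)) - 1

# smooth value noise: bilinear upsample of a coarse gaussian grid
value_noise <- function(H, W, cell) {
  gh <- ceiling(H / cell) + 2L
  gw <- ceiling(W / cell) + 2L
  g <- matrix(rnorm(gh * gw), gh, gw)
  r <- (seq_len(H) - 1) / cell + 1
  c <- (seq_len(W) - 1) / cell + 1
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  a <- g[cbind(rep(r0, W), rep(c0, each = H))]
  b <- g[cbind(rep(r0 + 1, W), rep(c0, each = H))]
  d <- g[cbind(rep(r0, W), rep(c0 + 1, each = H))]
  e <- g[cbind(rep(r0 + 1, W), rep(c0 + 1, each = H))]
  frm <- matrix(rep(fr, W), H, W)
  fcm <- matrix(rep(fc, each = H), H, W)
  m <- matrix(a, H, W) * (1 - frm) * (1 - fcm) +
    matrix(b, H, W) * frm * (1 - fcm) +
    matrix(d, H, W) * (1 - frm) * fcm +
    matrix(e, H, W) * frm * fcm
  m / max(1e-9, sd(m))
}

# boundary radius of the lamina at polar angle theta (theta = 0 points down
# towards the petiole, pi points to the apex), given fourier coefficients
lamina_radius <- function(theta, p, four) {
  re <- 1 / sqrt((cos(theta) / p$lamina_scale)^2 +
                   (sin(theta) / (p$lamina_scale * p$aspect))^2)
  pert <- rep(0, length(theta))
  for (k in seq_along(four$amp)) {
    pert <- pert + four$amp[k] * cos((k + 1) * theta + four$phase[k])
  }
  serr <- p$serration_amplitude * tri_wave(p$serration_count * theta / (2 * pi))
  re * (1 + pert) + serr
}

# recursive vein tree as a table of tapered segments
# returns data.frame(r0, c0, r1, c1, w0, w1, depth)
vein_tree <- function(p, center, attach, apex, len_scale) {
  segs <- list()
  add_branch <- function(r0, c0, angle, len, w0, depth) {
    # two sub-segments with a slight random kink
    kink <- rnorm(1, 0, 0.12)
    mid_r <- r0 + cos(angle) * len * 0.5
    mid_c <- c0 + sin(angle) * len * 0.5
    end_r <- mid_r + cos(angle + kink) * len * 0.5
    end_c <- mid_c + sin(angle + kink) * len * 0.5
    wm <- max(1, w0 * 0.6)
    w1 <- 1
    segs[[length(segs) + 1]] <<- data.frame(
      r0 = c(r0, mid_r), c0 = c(c0, mid_c), r1 = c(mid_r, end_r),
      c1 = c(mid_c, end_c), w0 = c(w0, wm), w1 = c(wm, w1), depth = depth)
    if (depth < p$vein_branch_depth) {
      nk <- if (depth == 0) 5L else 2L
      side <- 1
      for (i in seq_len(nk)) {
        t <- 0.15 + 0.75 * (i - 0.5) / nk
        br <- r0 + cos(angle) * len * t
        bc <- c0 + sin(angle) * len * t
        child_angle <- angle + side * (0.9 + rnorm(1, 0, 0.1))
        child_len <- len * (if (depth == 0) 0.45 else 0.5) *
          (1 - 0.35 * t) * len_scale
        add_branch(br, bc, child_angle, child_len, max(1, w0 * 0.5), depth + 1)
        side <- -side
      }
    }
  }
  # midrib from apex to attachment point
  mid_len <- sqrt(sum((attach - apex)^2))
  mid_angle <- atan2(attach[2] - apex[2], attach[1] - apex[1])
  segs[[length(segs) + 1]] <- data.frame(
    r0 = apex[1], c0 = apex[2], r1 = attach[1], c1 = attach[2],
    w0 = 1, w1 = p$vein_base_width, depth = 0)
  if (p$vein_branch_depth > 0) {
    # secondary veins branch off the midrib
    nk <- 6L
    side <- 1
    for (i in seq_len(nk)) {
      t <- 0.1 + 0.8 * (i - 0.5) / nk
      br <- apex[1] + cos(mid_angle) * mid_len * t
      bc <- apex[2] + sin(mid_angle) * mid_len * t
      child_angle <- mid_angle + side * (1.0 + rnorm(1, 0, 0.1))
      child_len <- mid_len * 0.42 * (1 - 0.4 * abs(t - 0.45)) * len_scale
      wb <- max(1, p$vein_base_width * (1 - 0.5 * t) * 0.55)
      add_branch(br, bc, child_angle, child_len, wb, 1L)
      side <- -side
    }
  }
  do.call(rbind, segs)
}

# rasterize tapered segments into a mask restricted to `inside`
rasterize_veins <- function(segs, H, W, inside) {
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    wmax <- max(s$w0, s$w1) / 2 + 1
    r_lo <- max(1L, floor(min(s$r0, s$r1) - wmax))
    r_hi <- min(H, ceiling(max(s$r0, s$r1) + wmax))
    c_lo <- max(1L, floor(min(s$c0, s$c1) - wmax))
    c_hi <- min(W, ceiling(max(s$c0, s$c1) + wmax))
    if (r_hi < r_lo || c_hi < c_lo) next
    rr <- r_lo:r_hi; cc <- c_lo:c_hi
    rm <- matrix(rr, length(rr), length(cc))
    cm <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    dr <- s$r1 - s$r0; dc <- s$c1 - s$c0
    len2 <- dr * dr + dc * dc
    t <- if (len2 < 1e-9) 0 else
      pmin(1, pmax(0, ((rm - s$r0) * dr + (cm - s$c0) * dc) / len2))
    px <- s$r0 + t * dr; py <- s$c0 + t * dc
    dist <- sqrt((rm - px)^2 + (cm - py)^2)
    wloc <- (s$w0 + t * (s$w1 - s$w0)) / 2
    sel <- dist <= pmax(0.5, wloc)
    mask[rr, cc] <- mask[rr, cc] | sel
  }
  mask <- mask & inside
  # clipping at the margin can sever branch tips that strayed outside the
  # blade; keep the component attached to the midrib so the network is a
  # single connected tree
  if (any(mask)) mask <- largest_component(mask, 8) else mask
}

#' Generate one synthetic leaf scan with ground truth
#'
#' Deterministic given `params$seed`. The image is rendered from the masks,
#' so ground truth is exact; artifacts (if any) perturb only the image.
#'
#' @param params a [leaf_gen_params()].
#' @return A `synthetic_sample`: list with `image` (H x W x 3 in `[0,1]`),
#'   `leaf_mask`, `vein_mask` (veins inside the blade), `petiole_mask`,
#'   `params`, and `true_traits` (a one-row tibble computed analytically from
#'   the generative geometry, not from the rasters).
#' @export
generate_leaf <- function(params) {
  validate_gen_params(params)
  withr::with_seed(params$seed, generate_leaf_impl(params))
}

generate_leaf_impl <- function(p) {
  H <- p$canvas_size[1]; W <- p$canvas_size[2]
  # lamina centre: leave room for the petiole below
  cr <- (H - p$petiole_length) / 2
  cc <- W / 2
  four <- list(amp = runif(3, 0.015, 0.05), phase = runif(3, 0, 2 * pi))

  # masks are computed on the lamina bounding box only
  ext <- p$lamina_scale * 1.15 + p$serration_amplitude + 2
  r_lo <- max(1L, floor(cr - ext)); r_hi <- min(H, ceiling(cr + ext))
  c_lo <- max(1L, floor(cc - ext)); c_hi <- min(W, ceiling(cc + ext))
  rr <- r_lo:r_hi; cc_idx <- c_lo:c_hi
  rm <- matrix(rr - cr, length(rr), length(cc_idx))
  cm <- matrix(cc_idx - cc, length(rr), length(cc_idx), byrow = TRUE)
  theta <- atan2(cm, rm)
  dist <- sqrt(rm^2 + cm^2)
  leaf_mask <- matrix(FALSE, H, W)
  leaf_mask[rr, cc_idx] <- dist <= lamina_radius(theta, p, four)

  # attachment (bottom of blade) and apex (top)
  attach <- c(cr + lamina_radius(0, p, four), cc)
  apex <- c(cr - lamina_radius(pi, p, four) * 0.92, cc)

  # vein tree, restricted to the blade
  len_scale <- max(0.2, 1 + p$genotype_effect)
  segs <- vein_tree(p, c(cr, cc), attach, apex, len_scale)
  vein_mask <- rasterize_veins(segs, H, W, leaf_mask)

  # petiole: vertical bar from the attachment downwards
  petiole_mask <- matrix(FALSE, H, W)
  pr0 <- floor(attach[1]); pr1 <- min(H, ceiling(attach[1] + p$petiole_length))
  pc0 <- max(1L, floor(cc - p$petiole_width / 2))
  pc1 <- min(W, ceiling(cc + p$petiole_width / 2) - 1L)
  petiole_mask[pr0:pr1, pc0:pc1] <- TRUE
  petiole_mask <- petiole_mask & !leaf_mask

  img <- render_leaf_image(p, leaf_mask, vein_mask, petiole_mask)
  img_clean <- img
  if (length(p$artifact_flags)) {
    img <- apply_artifacts(img, p, leaf_mask)
  }

  structure(list(image = img, image_clean = img_clean,
                 leaf_mask = leaf_mask, vein_mask = vein_mask,
                 petiole_mask = petiole_mask, params = p,
                 true_traits = analytic_traits(p, four, segs)),
            class = "synthetic_sample")
}

render_leaf_image <- function(p, leaf_mask, vein_mask, petiole_mask) {
  H <- p$canvas_size[1]; W <- p$canvas_size[2]
  bgn <- value_noise(H, W, max(8, round(min(H, W) / 24)))
  lamn <- value_noise(H, W, max(4, round(p$lamina_scale / 10)))
  fine <- matrix(rnorm(H * W), H, W)
  base <- c(0.34, 0.52, 0.28)         # lamina green (leaf-bottom)
  veinc <- base + p$vein_contrast * c(0.95, 0.75, 0.95)  # veins lighter
  petc <- c(0.58, 0.56, 0.38)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    # scanner background: near-white with mild texture, floor keeps every
    # background pixel at >= 0.9 of full scale
    plane <- pmax(0.905, 0.955 + 0.015 * bgn + 0.006 * fine)
    lam <- base[ch] * (1 + 0.10 * lamn + 0.03 * fine)
    plane[leaf_mask] <- lam[leaf_mask]
    vv <- pmin(1, veinc[ch] * (1 + 0.04 * lamn + 0.02 * fine))
    plane[vein_mask] <- vv[vein_mask]
    pp <- petc[ch] * (1 + 0.05 * fine)
    plane[petiole_mask] <- pp[petiole_mask]
    img[, , ch] <- pmin(1, pmax(0, plane))
  }
  img
}

apply_artifacts <- function(img, p, leaf_mask) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if ("fold" %in% p$artifact_flags) {
    # dark fold line across the blade
    idx <- which(leaf_mask, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- idx[sample.int(nrow(idx), 1), ]
      ang <- runif(1, 0, pi)
      len <- p$lamina_scale * 1.2
      b <- pmin(c(H, W), pmax(c(1, 1), round(a + len * c(cos(ang), sin(ang)))))
      a2 <- pmin(c(H, W), pmax(c(1, 1), round(a - len * c(cos(ang), sin(ang)))))
      line <- cpp_bresenham(a2[1], a2[2], b[1], b[2]) + 1L
      keep <- line[, 1] >= 1 & line[, 1] <= H & line[, 2] >= 1 & line[, 2] <= W
      line <- line[keep, , drop = FALSE]
      for (d in -1:1) {
        rs <- pmin(H, pmax(1, line[, 1] + d))
        for (ch in 1:3) {
          pl <- img[, , ch]
          sel <- cbind(rs, line[, 2])
          pl[sel] <- pl[sel] * 0.55
          img[, , ch] <- pl
        }
      }
    }
  }
  if ("white_stripe" %in% p$artifact_flags) {
    w <- max(2L, round(W / 200))
    c0 <- sample.int(W - w, 1)
    img[, c0:(c0 + w - 1), ] <- 0.97
  }
  if ("dust" %in% p$artifact_flags) {
    n <- 20L
    rs <- sample.int(H, n); cs <- sample.int(W, n)
    for (i in seq_len(n)) {
      rad <- sample(1:2, 1)
      rr <- max(1, rs[i] - rad):min(H, rs[i] + rad)
      cc <- max(1, cs[i] - rad):min(W, cs[i] + rad)
      img[rr, cc, ] <- img[rr, cc, ] * 0.35
    }
  }
  if ("blur" %in% p$artifact_flags) {
    sz <- round(min(H, W) / 4)
    r0 <- sample.int(H - sz, 1); c0 <- sample.int(W - sz, 1)
    patch <- img[r0:(r0 + sz - 1), c0:(c0 + sz - 1), , drop = FALSE]
    for (ch in 1:3) {
      patch[, , ch] <- as.matrix(EBImage::gblur(EBImage::Image(patch[, , ch]),
                                                sigma = 2))
    }
    img[r0:(r0 + sz - 1), c0:(c0 + sz - 1), ] <- patch
  }
  img
}

# ground truth traits from the generative geometry (not from rasters)
analytic_traits <- function(p, four, segs) {
  th <- seq(0, 2 * pi, length.out = 2048L)
  rad <- lamina_radius(th, p, four)
  x <- rad * sin(th); y <- rad * cos(th)
  area_px <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per_px <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  seg_len <- sqrt((segs$r1 - segs$r0)^2 + (segs$c1 - segs$c0)^2)
  seg_area <- seg_len * (segs$w0 + segs$w1) / 2
  mm <- 25.4 / p$dpi
  tibble(
    leaf_area = area_px * mm^2 / 100,              # cm^2
    leaf_perimeter = per_px * mm / 10,             # cm
    circularity = 4 * pi * area_px / per_px^2,
    vein_total_length = sum(seg_len) * mm,         # mm
    vein_area = sum(seg_area) * mm^2,              # mm^2
    vein_density = sum(seg_area) / area_px,
    petiole_length = p$petiole_length * mm,
    petiole_width = p$petiole_width * mm,
    density_target = sum(seg_area) / area_px
  )
}

#' Generate a clonally replicated synthetic population
#'
#' Genotype effects on the latent vein-density driver are drawn from
#' `Normal(0, sigma_G^2)` and clone-level noise from `Normal(0, sigma_E^2)`,
#' so broad-sense heritability of the true trait values is
#' `sigma_G^2 / (sigma_G^2 + sigma_E^2)` in expectation.
#'
#' @param n number of samples; must equal `n_genotypes * clones_per_genotype`.
#' @param base a [leaf_gen_params()] used for every sample (seed is re-drawn).
#' @param n_genotypes,clones_per_genotype population structure.
#' @param sigma_G,sigma_E genotype and clone (environmental) standard
#'   deviations of the trait shift; non-negative.
#' @param seed master seed.
#' @param render if `FALSE`, skip image rendering and return only parameters,
#'   genotype assignments and true trait values (fast path for
#'   variance-component studies).
#' @return list with `assignments` (tibble: sample_id, genotype, clone,
#'   trait_value, genotype_effect) and `samples` (list of
#'   `synthetic_sample`, or of `leaf_gen_params` when `render = FALSE`).
#' @export
generate_population <- function(n, base, n_genotypes, clones_per_genotype,
                                sigma_G, sigma_E, seed = 1L, render = TRUE) {
  if (n != n_genotypes * clones_per_genotype) {
    abort("n must equal n_genotypes * clones_per_genotype",
          class = "leaftrace_param_error")
  }
  if (sigma_G < 0 || sigma_E < 0) {
    abort("variances must be non-negative", class = "leaftrace_param_error")
  }
  withr::with_seed(seed, {
    g_eff <- rnorm(n_genotypes, 0, sigma_G)
    e_eff <- rnorm(n, 0, sigma_E)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  genotype <- rep(seq_len(n_genotypes), each = clones_per_genotype)
  clone <- rep(seq_len(clones_per_genotype), times = n_genotypes)
  shift <- g_eff[genotype] + e_eff
  base_density <- 0.08   # latent density scale before genotype shifts
  samples <- vector("list", n)
  trait <- numeric(n)
  for (i in seq_len(n)) {
    p_i <- base
    p_i$seed <- seeds[i]
    p_i$genotype_effect <- shift[i]
    trait[i] <- base_density * (1 + shift[i])
    samples[[i]] <- if (render) generate_leaf(p_i) else p_i
    if (render) {
      samples[[i]]$true_traits$density_target <- trait[i]
    }
  }
  list(assignments = tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    genotype = factor(genotype), clone = clone,
    genotype_effect = g_eff[genotype], trait_value = trait),
    samples = samples)
}
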