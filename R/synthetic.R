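#' Specification for synthetic weed field images
#'
#' Describes the seeded generator that emulates inter-row field imagery:
#' green-dominant weed seedlings on brownish soil, monocots as long thin
#' slightly curved ribbons, dicots as compact multi-lobed blobs, with
#' global illumination gain, Gaussian channel noise and salt specks.
#'
#' Monocot ribbons are stamped from disks of radius `monocot_radius`
#' (width about 8-12 px) swept along a quadratic arc, so a leaf is wider
#' than the 5x5 noise-removal structuring element and survives the opening
#' essentially unchanged; lengths and the axis-ratio validation
#' (`monocot_d5_max`, `dicot_d5_min`) keep the two classes' elongation
#' disjoint by construction. Foreground colours are drawn from the stated
#' RGB ranges but rejection-validated so the greenness index stays >= 10
#' with high probability after the worst-case illumination gain and noise;
#' soil colours are constructed to stay well below the threshold.
#'
#' @param n_monocots,n_dicots Number of plants of each class.
#' @param width,height Canvas size in pixels.
#' @param monocot_length Length range (px) of the ribbon midline.
#' @param monocot_radius Stamp-disk radius range (px).
#' @param monocot_curv Arc deflection range as a fraction of length.
#' @param dicot_diameter Overall blob diameter range (px).
#' @param dicot_lobes Range of lobe counts.
#' @param monocot_d5_max,dicot_d5_min Axis-ratio validation bounds.
#' @param fg_R,fg_G,fg_B Foreground colour ranges (0-255).
#' @param fg_min_gi Minimum pre-gain greenness index accepted for a plant
#'   colour.
#' @param soil_R Soil red-channel range; green and blue follow as the
#'   fractions `soil_G_frac`, `soil_B_frac` of red.
#' @param soil_G_frac,soil_B_frac Soil G/R and B/R fraction ranges.
#' @param noise_sd Gaussian channel noise standard deviation.
#' @param gain Fixed illumination gain, or `NULL` to draw from
#'   `gain_range`.
#' @param gain_range Illumination gain range.
#' @param salt_density Fraction of pixels turned into white salt specks.
#' @param min_gap Minimum separation (px) enforced between plants.
#' @param seed Optional integer seed used by [render_field()].
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_monocots = 5, n_dicots = 5,
                         width = 512, height = 512,
                         monocot_length = c(80, 300),
                         monocot_radius = c(4, 6),
                         monocot_curv = c(0, 0.08),
                         dicot_diameter = c(30, 120),
                         dicot_lobes = c(2, 6),
                         monocot_d5_max = 0.2,
                         dicot_d5_min = 0.4,
                         fg_R = c(20, 90), fg_G = c(100, 200),
                         fg_B = c(10, 80), fg_min_gi = 80,
                         soil_R = c(110, 150),
                         soil_G_frac = c(0.70, 0.82),
                         soil_B_frac = c(0.55, 0.75),
                         noise_sd = 10, gain = NULL,
                         gain_range = c(0.7, 1.3),
                         salt_density = 0.002, min_gap = 5,
                         seed = NULL) {
  spec <- as.list(environment())
  stopifnot(width >= 64, height >= 64, n_monocots >= 0, n_dicots >= 0)
  structure(spec, class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("<fixture_spec> %dx%d canvas, %d monocot(s) + %d dicot(s)\n",
              x$width, x$height, x$n_monocots, x$n_dicots))
  invisible(x)
}

# disk stamp offsets for a given radius
.disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Generate one synthetic plant region mask
#'
#' Draws a single monocot (curved ribbon) or dicot (multi-lobed blob) at a
#' random position, using the session RNG. The shape is re-drawn (up to
#' `max_attempts`) until its equal-moments axis ratio d5 falls on the
#' correct side of the class's validation bound, so the two classes stay
#' separable by elongation by construction.
#'
#' @param kind `"monocot"` or `"dicot"`.
#' @param spec A [fixture_spec()].
#' @param max_attempts Resampling budget before erroring.
#' @return Logical `height x width` mask.
#' @export
generate_region <- function(kind = c("monocot", "dicot"),
                            spec = fixture_spec(), max_attempts = 100) {
  kind <- match.arg(kind)
  for (attempt in seq_len(max_attempts)) {
    mask <- if (kind == "monocot") .draw_monocot(spec) else .draw_dicot(spec)
    if (is.null(mask)) next
    coords <- which(mask, arr.ind = TRUE)
    d <- geometric_descriptors(coords)
    ok <- if (kind == "monocot") d["d5"] <= spec$monocot_d5_max
          else d["d5"] >= spec$dicot_d5_min
    if (!ok) next
    # opening stability, validated at generation: the shape must come
    # through the 5x5 noise-removal opening essentially unchanged
    rows <- max(1, min(coords[, 1]) - 3):min(spec$height, max(coords[, 1]) + 3)
    cols <- max(1, min(coords[, 2]) - 3):min(spec$width, max(coords[, 2]) + 3)
    sub <- mask[rows, cols, drop = FALSE]
    if (sum(sub & !open_mask(sub, 5)) / sum(sub) <= 0.02) return(mask)
  }
  stop("failed to generate a valid ", kind, " region in ", max_attempts,
       " attempts", call. = FALSE)
}

.draw_monocot <- function(spec) {
  H <- spec$height; W <- spec$width
  L <- stats::runif(1, spec$monocot_length[1],
                    min(spec$monocot_length[2], 0.8 * min(H, W)))
  r <- stats::runif(1, spec$monocot_radius[1], spec$monocot_radius[2])
  curv <- stats::runif(1, spec$monocot_curv[1], spec$monocot_curv[2]) *
    sample(c(-1, 1), 1)
  theta <- stats::runif(1, 0, pi)
  u <- c(cos(theta), sin(theta))
  nv <- c(-u[2], u[1])
  t <- seq(0, 1, length.out = max(64L, ceiling(2 * L)))
  # midline: straight sweep plus a mid-arc perpendicular bulge
  pr <- t * L * u[1] + curv * L * 4 * t * (1 - t) * nv[1]
  pc <- t * L * u[2] + curv * L * 4 * t * (1 - t) * nv[2]
  .stamp_shape(pr, pc, r, H, W)
}

.draw_dicot <- function(spec) {
  H <- spec$height; W <- spec$width
  D <- stats::runif(1, spec$dicot_diameter[1], spec$dicot_diameter[2])
  R0 <- max(D * 0.3, 6)
  k <- sample(spec$dicot_lobes[1]:spec$dicot_lobes[2], 1)
  # central disk plus k elliptical lobes with bounded offsets keeps the
  # blob compact (aspect well under 2.5) and every lobe thick enough to
  # survive the 5x5 opening
  lob_a <- pmax(R0 * stats::runif(k, 0.65, 1.0), 6)
  lob_b <- pmax(lob_a * stats::runif(k, 0.75, 1.0), 6)
  lob_d <- stats::runif(k, 0, 0.6 * R0)
  lob_t <- stats::runif(k, 0, 2 * pi)
  lob_o <- stats::runif(k, 0, pi)
  ext <- ceiling(max(R0 * 0.85, lob_d + pmax(lob_a, lob_b))) + 1L
  if (2 * ext + 2 >= min(H, W)) return(NULL)
  cr <- stats::runif(1, ext + 1, H - ext)
  cc <- stats::runif(1, ext + 1, W - ext)
  rows <- max(1L, floor(cr - ext)):min(H, ceiling(cr + ext))
  cols <- max(1L, floor(cc - ext)):min(W, ceiling(cc + ext))
  g <- expand.grid(row = rows, col = cols)
  dr <- g$row - cr; dc <- g$col - cc
  inside <- dr^2 + dc^2 <= (R0 * 0.85)^2
  for (i in seq_len(k)) {
    ocr <- lob_d[i] * cos(lob_t[i]); occ <- lob_d[i] * sin(lob_t[i])
    x <- dc - occ; y <- dr - ocr
    xr <- x * cos(lob_o[i]) + y * sin(lob_o[i])
    yr <- -x * sin(lob_o[i]) + y * cos(lob_o[i])
    inside <- inside | (xr^2 / lob_a[i]^2 + yr^2 / lob_b[i]^2 <= 1)
  }
  mask <- matrix(FALSE, H, W)
  mask[cbind(g$row[inside], g$col[inside])] <- TRUE
  mask
}

# stamp disks of radius r along midline points (pr, pc), placing the whole
# shape uniformly at random inside the canvas; NULL if it cannot fit
.stamp_shape <- function(pr, pc, r, H, W) {
  off <- .disk_offsets(r)
  rmin <- floor(min(pr) - r); rmax <- ceiling(max(pr) + r)
  cmin <- floor(min(pc) - r); cmax <- ceiling(max(pc) + r)
  if (rmax - rmin + 3 >= H || cmax - cmin + 3 >= W) return(NULL)
  r0 <- stats::runif(1, 2 - rmin, H - 1 - rmax)
  c0 <- stats::runif(1, 2 - cmin, W - 1 - cmax)
  pts_r <- rep(round(pr + r0), each = nrow(off)) + off$dr
  pts_c <- rep(round(pc + c0), each = nrow(off)) + off$dc
  keep <- pts_r >= 1 & pts_r <= H & pts_c >= 1 & pts_c <= W
  mask <- matrix(FALSE, H, W)
  mask[cbind(pts_r[keep], pts_c[keep])] <- TRUE
  mask
}

# draw a plant colour from the configured ranges, rejecting colours whose
# greenness index is below spec$fg_min_gi (generation-time validation)
.fg_colour <- function(spec, max_attempts = 100) {
  for (i in seq_len(max_attempts)) {
    col <- c(stats::runif(1, spec$fg_R[1], spec$fg_R[2]),
             stats::runif(1, spec$fg_G[1], spec$fg_G[2]),
             stats::runif(1, spec$fg_B[1], spec$fg_B[2]))
    gi <- -0.884 * col[1] + 1.262 * col[2] - 0.311 * col[3]
    if (gi >= spec$fg_min_gi) return(col)
  }
  stop("could not draw a sufficiently green foreground colour",
       call. = FALSE)
}

#' Render a synthetic field image with ground truth
#'
#' Places the requested monocots and dicots without overlap (rejection
#' sampling with a `min_gap` separation), colours foreground and soil,
#' applies a global illumination gain, then Gaussian channel noise and
#' salt specks. The returned label map and region table are the ground
#' truth captured \emph{before} noise, so downstream segmentation error is
#' measurable rather than baked in.
#'
#' @param spec A [fixture_spec()]. If `spec$seed` is set the RNG is seeded
#'   first, making the render fully reproducible.
#' @return List with `image` (`H x W x 3`, 0-255), `truth`
#'   (a `weed_labels` ground-truth map), `regions` (data frame: `label`,
#'   `class`, `area`) and `gain`.
#' @export
render_field <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  kinds <- c(rep("monocot", spec$n_monocots), rep("dicot", spec$n_dicots))
  truth <- matrix(0L, H, W)
  occupied <- matrix(FALSE, H, W)
  gap_brush <- EBImage::makeBrush(2L * spec$min_gap + 1L, shape = "box")
  img <- .soil_background(spec)
  info <- list()
  for (i in seq_along(kinds)) {
    placed <- FALSE
    for (attempt in 1:100) {
      mask <- generate_region(kinds[i], spec)
      dil <- EBImage::dilate(mask * 1L, gap_brush) > 0.5
      if (!any(dil & occupied)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place region ", i, " without overlap; ",
           "canvas too small for the requested shapes", call. = FALSE)
    }
    occupied <- occupied | dil
    truth[mask] <- i
    col <- .fg_colour(spec)
    jitter <- matrix(stats::rnorm(sum(mask) * 3, 0, 4), ncol = 3)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch] + jitter[, ch]
      img[, , ch] <- plane
    }
    info[[i]] <- data.frame(label = i, class = kinds[i], area = sum(mask))
  }
  gain <- if (is.null(spec$gain)) {
    stats::runif(1, spec$gain_range[1], spec$gain_range[2])
  } else {
    spec$gain
  }
  img <- img * gain
  img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  if (spec$salt_density > 0) {
    salt <- which(stats::runif(H * W) < spec$salt_density)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[salt] <- 255
      img[, , ch] <- plane
    }
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  regions <- if (length(info)) do.call(rbind, info) else
    data.frame(label = integer(), class = character(), area = integer())
  list(image = round(img),
       truth = structure(list(labels = truth,
                              n_regions = length(kinds),
                              connectivity = 8L),
                         class = "weed_labels"),
       regions = regions,
       gain = gain)
}

.soil_background <- function(spec) {
  H <- spec$height; W <- spec$width
  R <- matrix(stats::runif(H * W, spec$soil_R[1], spec$soil_R[2]), H, W)
  G <- R * matrix(stats::runif(H * W, spec$soil_G_frac[1],
                               spec$soil_G_frac[2]), H, W)
  B <- R * matrix(stats::runif(H * W, spec$soil_B_frac[1],
                               spec$soil_B_frac[2]), H, W)
  array(c(R, G, B), dim = c(H, W, 3))
}

#' Write a rendered field to disk
#'
#' Writes the image as PNG, the ground-truth label map as 16-bit PNG and
#' the region table as CSV.
#'
#' @param field A [render_field()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the named vector of paths written.
#' @export
write_field <- function(field, dir, stem = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  lab_path <- file.path(dir, paste0(stem, "_truth.png"))
  csv_path <- file.path(dir, paste0(stem, "_regions.csv"))
  png::writePNG(field$image / 255, img_path)
  png::writePNG(field$truth$labels / max(1L, field$truth$n_regions),
                lab_path)
  utils::write.csv(field$regions, csv_path, row.names = FALSE)
  invisible(c(image = img_path, truth = lab_path, regions = csv_path))
}
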