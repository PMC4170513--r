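#' Hu invariant moments of a binary region
#'
#' The seven Hu moments are computed from the normalised central moments
#' eta_pq of the region treated as a set of unit point masses at the pixel
#' centres. phi1..phi6 are invariant to translation, rotation and scale;
#' phi7 is additionally mirror-sensitive (its sign flips under reflection),
#' so the sign is preserved.
#'
#' A single-pixel region has all central moments zero; the function then
#' returns seven zeros with attribute `degenerate = TRUE`.
#'
#' @param coords Two-column matrix of (row, col) pixel coordinates.
#' @return Named numeric vector `phi1..phi7`.
#' @export
#' @examples
#' sq <- as.matrix(expand.grid(row = 1:10, col = 1:10))
#' hu_moments(sq)["phi1"]
hu_moments <- function(coords) {
  coords <- .as_coords(coords)
  n <- nrow(coords)
  x <- coords[, 2]; y <- coords[, 1]
  dx <- x - mean(x); dy <- y - mean(y)
  phi <- stats::setNames(numeric(7), paste0("phi", 1:7))
  mu20 <- sum(dx^2); mu02 <- sum(dy^2)
  if (mu20 + mu02 == 0) {
    attr(phi, "degenerate") <- TRUE
    return(phi)
  }
  mu11 <- sum(dx * dy)
  mu30 <- sum(dx^3); mu03 <- sum(dy^3)
  mu21 <- sum(dx^2 * dy); mu12 <- sum(dx * dy^2)
  n2 <- n^2; n25 <- n^2.5
  e20 <- mu20 / n2; e02 <- mu02 / n2; e11 <- mu11 / n2
  e30 <- mu30 / n25; e03 <- mu03 / n25
  e21 <- mu21 / n25; e12 <- mu12 / n25

  a <- e30 + e12; b <- e21 + e03   # recurring third-order sums
  phi[1] <- e20 + e02
  phi[2] <- (e20 - e02)^2 + 4 * e11^2
  phi[3] <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  phi[4] <- a^2 + b^2
  phi[5] <- (e30 - 3 * e12) * a * (a^2 - 3 * b^2) +
            (3 * e21 - e03) * b * (3 * a^2 - b^2)
  phi[6] <- (e20 - e02) * (a^2 - b^2) + 4 * e11 * a * b
  phi[7] <- (3 * e21 - e03) * a * (a^2 - 3 * b^2) -
            (e30 - 3 * e12) * b * (3 * a^2 - b^2)
  phi
}

.as_coords <- function(coords) {
  if (is.list(coords) && !is.null(coords$coords)) coords <- coords$coords
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 1L) {
    stop("coords must be a non-empty two-column (row, col) matrix",
         call. = FALSE)
  }
  coords
}

# Moore-neighbour tracing of the outer 8-contour; returns the contour
# length with diagonal steps weighted sqrt(2). Inner holes are not traced:
# the descriptor follows the pixels on the inside of the object's outer
# boundary. Single pixels have no contour (length 0).
.trace_perimeter <- function(coords) {
  coords <- .as_coords(coords)
  if (nrow(coords) == 1L) return(0)
  rmin <- min(coords[, 1]); cmin <- min(coords[, 2])
  h <- max(coords[, 1]) - rmin + 1L
  w <- max(coords[, 2]) - cmin + 1L
  m <- matrix(FALSE, h + 2L, w + 2L)  # 1-pixel background frame
  m[cbind(coords[, 1] - rmin + 2L, coords[, 2] - cmin + 2L)] <- TRUE

  # clockwise ring (image coords, row grows downward): W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  ring_idx <- function(orow, ocol) which(dr == orow & dc == ocol)

  # start at the first foreground pixel in row-major order: its west
  # neighbour is guaranteed background
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  cr <- start[1]; cc <- start[2]
  br <- cr; bc <- cc - 1L  # backtrack cell (background)
  per <- 0
  first_move <- NULL
  max_steps <- 4L * sum(m) + 8L
  for (step in seq_len(max_steps)) {
    bi <- ring_idx(br - cr, bc - cc)
    lr <- br; lc <- bc  # last background cell examined
    found <- 0L
    for (k in seq_len(8L)) {
      di <- (bi - 1L + k) %% 8L + 1L
      nr <- cr + dr[di]; nc <- cc + dc[di]
      if (m[nr, nc]) { found <- di; break }
      lr <- nr; lc <- nc
    }
    if (found == 0L) return(0)  # isolated pixel
    mv <- c(cr, cc, found)
    if (!is.null(first_move) && all(mv == first_move)) break
    if (is.null(first_move)) first_move <- mv
    per <- per + sqrt(dr[found]^2 + dc[found]^2)
    br <- lr; bc <- lc
    cr <- cr + dr[found]; cc <- cc + dc[found]
  }
  per
}

# --- minimal enclosing circle (Welzl) ---------------------------------

.circle2 <- function(p, q) {
  c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
}

.circle3 <- function(p, q, r) {
  # circumcircle; NULL if (nearly) collinear
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-9) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

.circle_trivial <- function(R) {
  k <- nrow(R)
  if (k == 0L) return(c(0, 0, -1))
  if (k == 1L) return(c(R[1, ], 0))
  if (k == 2L) return(.circle2(R[1, ], R[2, ]))
  circ <- .circle3(R[1, ], R[2, ], R[3, ])
  if (is.null(circ)) {
    # collinear boundary points: widest pair defines the circle
    cands <- list(.circle2(R[1, ], R[2, ]), .circle2(R[1, ], R[3, ]),
                  .circle2(R[2, ], R[3, ]))
    circ <- cands[[which.max(vapply(cands, `[`, numeric(1), 3))]]
  }
  circ
}

.in_circle <- function(circ, p) {
  sqrt(sum((p - circ[1:2])^2)) <= circ[3] * (1 + 1e-10) + 1e-10
}

.welzl <- function(P, R) {
  if (nrow(P) == 0L || nrow(R) == 3L) return(.circle_trivial(R))
  p <- P[1, ]
  circ <- .welzl(P[-1, , drop = FALSE], R)
  if (circ[3] >= 0 && .in_circle(circ, p)) return(circ)
  .welzl(P[-1, , drop = FALSE], rbind(R, p))
}

#' Minimal enclosing circle of a point set
#'
#' Welzl's move-to-front algorithm applied to the convex hull of the
#' points. Used for the region "diameter" descriptor (the circle that
#' circumscribes the region's pixel centres).
#'
#' @param points Two-column numeric matrix (x, y).
#' @return Numeric vector `c(x, y, radius)`.
#' @export
min_enclosing_circle <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 1L)
  if (nrow(points) == 1L) return(c(points[1, ], 0))
  dimnames(points) <- NULL
  hull <- grDevices::chull(points)
  P <- points[hull, , drop = FALSE]
  n <- nrow(P)
  # deterministic pseudo-random order keeps Welzl's expected-linear
  # behaviour without touching the user's RNG stream
  perm <- order((seq_len(n) * 2654435761) %% 1000003)
  unname(.welzl(P[perm, , drop = FALSE], matrix(numeric(0), 0, 2)))
}

#' Geometric shape descriptors of a region
#'
#' The six geometric descriptors, in pixel units:
#' \describe{
#'   \item{d1 perimeter}{length of the outer 8-connected boundary contour
#'     traced along the pixels just inside the region edge, diagonal steps
#'     weighted sqrt(2).}
#'   \item{d2 diameter}{diameter of the minimal circle enclosing the pixel
#'     centres (the circle that circumscribes the region). With
#'     `diameter = "equivalent"`, the diameter of the circle with the same
#'     area instead.}
#'   \item{d3, d4 minor/major axis length}{axis lengths of the ellipse with
#'     the same normalised second central moments as the region:
#'     `4 * sqrt(eigenvalue)` of the pixel-coordinate covariance with the
#'     +1/12 per-pixel variance term, so a 1-pixel-wide line keeps a
#'     nonzero minor axis.}
#'   \item{d5 eccentricity}{the ratio d3/d4 (minor over major axis). Note
#'     this is the axis ratio, \emph{not} the classical conic eccentricity
#'     `sqrt(1 - (b/a)^2)`: a circle has d5 = 1, a line d5 = 0.}
#'   \item{d6 area}{pixel count.}
#' }
#'
#' @param coords Two-column matrix of (row, col) pixel coordinates.
#' @param diameter `"enclosing"` (default) or `"equivalent"`.
#' @return Named numeric vector `d1..d6`.
#' @export
geometric_descriptors <- function(coords, diameter = c("enclosing", "equivalent")) {
  diameter <- match.arg(diameter)
  coords <- .as_coords(coords)
  n <- nrow(coords)
  x <- coords[, 2]; y <- coords[, 1]
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- mean(dx^2) + 1 / 12
  vy <- mean(dy^2) + 1 / 12
  vxy <- mean(dx * dy)
  disc <- sqrt((vx - vy)^2 + 4 * vxy^2)
  lam1 <- (vx + vy + disc) / 2
  lam2 <- max((vx + vy - disc) / 2, 0)
  d4 <- 4 * sqrt(lam1)
  d3 <- 4 * sqrt(lam2)
  d2 <- if (diameter == "enclosing") {
    2 * min_enclosing_circle(cbind(x, y))[3]
  } else {
    2 * sqrt(n / pi)
  }
  c(d1 = .trace_perimeter(coords),
    d2 = d2, d3 = d3, d4 = d4,
    d5 = if (d4 > 0) d3 / d4 else 0,
    d6 = n)
}

#' All thirteen shape attributes of a region
#'
#' Concatenates the seven Hu moments and the six geometric descriptors.
#'
#' @inheritParams geometric_descriptors
#' @return Named numeric vector `phi1..phi7, d1..d6`.
#' @export
region_descriptors <- function(coords, diameter = "enclosing") {
  c(hu_moments(coords), geometric_descriptors(coords, diameter))
}

#' Descriptor table for a list of regions
#'
#' @param regions A `weed_regions` list from [extract_regions()].
#' @param diameter Passed to [geometric_descriptors()].
#' @return Data frame with columns `label`, `phi1..phi7`, `d1..d6`.
#' @export
describe_regions <- function(regions, diameter = "enclosing") {
  if (length(regions) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, 14))
    names(out) <- c("label", attribute_names())
    return(out)
  }
  rows <- lapply(regions, function(r) {
    c(label = r$label, region_descriptors(r$coords, diameter))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Names of the thirteen shape attributes
#'
#' @return Character vector `phi1..phi7, d1..d6` in canonical order.
#' @export
attribute_names <- function() {
  c(paste0("phi", 1:7), paste0("d", 1:6))
}

#' Fit min-max normalisation statistics for the thirteen attributes
#'
#' Componentwise minima and maxima over a reference (training) population
#' of descriptor vectors. The statistics are frozen into the trained model
#' and reused at test time.
#'
#' @param X Numeric matrix or data frame with the 13 attribute columns
#'   (rows = regions).
#' @return Object of class `attribute_stats` with `min` and `max`.
#' @export
fit_attribute_stats <- function(X) {
  X <- .attribute_matrix(X)
  if (nrow(X) < 2L) stop("need at least two descriptor vectors", call. = FALSE)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "attribute_stats")
}

.attribute_matrix <- function(X) {
  nm <- attribute_names()
  if (is.data.frame(X)) {
    missing <- setdiff(nm, names(X))
    if (length(missing)) {
      stop("missing attribute columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(X[, nm, drop = FALSE])
  } else {
    X <- as.matrix(X)
    if (ncol(X) != 13L) stop("expected 13 attribute columns", call. = FALSE)
    colnames(X) <- nm
  }
  if (nrow(X) == 0L) stop("empty descriptor input", call. = FALSE)
  X
}

#' Min-max normalise descriptor vectors to \[0,1\]
#'
#' `(x - min) / (max - min)` per attribute, using statistics from
#' [fit_attribute_stats()]; values outside the training range are clipped
#' to \[0,1\]. Degenerate attributes (min equal to max in training)
#' normalise to 0 by convention, with a warning.
#'
#' All thirteen attributes are normalised, Hu moments included, so every
#' attribute feeds the decision engines on a common \[0,1\] scale.
#'
#' @param X Matrix/data frame of raw descriptors (13 attribute columns) or
#'   a single named 13-vector.
#' @param stats An `attribute_stats` object.
#' @return Numeric matrix of normalised descriptors (rows preserved).
#' @export
normalise_descriptors <- function(X, stats) {
  stopifnot(inherits(stats, "attribute_stats"))
  single <- is.null(dim(X)) && length(X) == 13L
  if (single) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  X <- .attribute_matrix(X)
  rng <- stats$max - stats$min
  flat <- rng <= 0
  if (any(flat)) {
    warning("attribute(s) with min = max normalise to 0: ",
            paste(attribute_names()[flat], collapse = ", "), call. = FALSE)
    rng[flat] <- 1
  }
  Z <- sweep(sweep(X, 2, stats$min), 2, rng, "/")
  Z[, flat] <- 0
  Z[Z < 0] <- 0
  Z[Z > 1] <- 1
  Z
}
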