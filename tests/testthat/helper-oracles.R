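# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own algorithms: labelling is
# checked against a breadth-first flood fill, the Choquet integral against
# exhaustive subset enumeration, the enclosing circle against brute force
# over point pairs/triples.

# flood-fill (BFS) connected-component labelling; labels assigned in
# row-major first-encounter order, like the run-length labeller's contract
flood_fill_labels <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    ndr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    ndc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    ndr <- c(-1L, 0L, 0L, 1L)
    ndc <- c(0L, -1L, 1L, 0L)
  }
  stack_r <- integer(h * w); stack_c <- integer(h * w)
  nxt <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    top <- 1L; stack_r[1] <- i; stack_c[1] <- j
    lab[i, j] <- nxt
    while (top > 0L) {
      cr <- stack_r[top]; cc <- stack_c[top]; top <- top - 1L
      for (k in seq_along(ndr)) {
        r <- cr + ndr[k]; c <- cc + ndc[k]
        if (r >= 1L && r <= h && c >= 1L && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          top <- top + 1L
          stack_r[top] <- r; stack_c[top] <- c
        }
      }
    }
  }
  lab
}

# standard Choquet integral by exhaustive subset measures:
# sum_h a_(h) * (g(A_h) - g(A_{h-1})) with A_h the h largest supports
choquet_bruteforce <- function(a, densities, lambda) {
  gA <- function(idx) {
    if (length(idx) == 0) return(0)
    if (lambda == 0) return(sum(densities[idx]))
    (prod(1 + lambda * densities[idx]) - 1) / lambda
  }
  ord <- order(a, decreasing = TRUE)
  s <- 0
  for (h in seq_along(a)) {
    s <- s + a[ord[h]] * (gA(ord[seq_len(h)]) - gA(ord[seq_len(h - 1)]))
  }
  s
}

# smallest circle containing all points, by brute force over pairs and
# triples (only usable for small point sets)
mec_bruteforce <- function(pts) {
  n <- nrow(pts)
  contains_all <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + 1e-9)
  }
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cx <- (pts[i, 1] + pts[j, 1]) / 2; cy <- (pts[i, 2] + pts[j, 2]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best && contains_all(cx, cy, r)) best <- r
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
      d <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) +
                s[1] * (p[2] - q[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(p^2) * (q[2] - s[2]) + sum(q^2) * (s[2] - p[2]) +
             sum(s^2) * (p[2] - q[2])) / d
      uy <- (sum(p^2) * (s[1] - q[1]) + sum(q^2) * (p[1] - s[1]) +
             sum(s^2) * (q[1] - p[1])) / d
      r <- sqrt((p[1] - ux)^2 + (p[2] - uy)^2)
      if (r < best && contains_all(ux, uy, r)) best <- r
    }
  }
  best
}

# --- small raster shapes -------------------------------------------------

raster_disk <- function(radius, centre = c(0, 0)) {
  r <- ceiling(radius)
  g <- expand.grid(row = -r:r, col = -r:r)
  g <- g[g$row^2 + g$col^2 <= radius^2, ]
  cbind(row = g$row + centre[1], col = g$col + centre[2])
}

raster_rect <- function(h, w, origin = c(1, 1)) {
  as.matrix(expand.grid(row = origin[1]:(origin[1] + h - 1),
                        col = origin[2]:(origin[2] + w - 1)))
}

# nearest-neighbour x2 upsampling of a coordinate set (each pixel becomes
# a 2x2 block)
scale_coords_2x <- function(coords) {
  out <- rbind(cbind(2 * coords[, 1] - 1, 2 * coords[, 2] - 1),
               cbind(2 * coords[, 1] - 1, 2 * coords[, 2]),
               cbind(2 * coords[, 1], 2 * coords[, 2] - 1),
               cbind(2 * coords[, 1], 2 * coords[, 2]))
  colnames(out) <- c("row", "col")
  out
}

rotate_coords_90 <- function(coords) {
  out <- cbind(coords[, 2], -coords[, 1] + max(coords[, 1]) + 1)
  colnames(out) <- c("row", "col")
  out
}

mirror_coords <- function(coords) {
  out <- cbind(coords[, 1], -coords[, 2] + max(coords[, 2]) + 1)
  colnames(out) <- c("row", "col")
  out
}

# random synthetic-ish blob mask for property tests
random_mask <- function(h, w, density = 0.4) {
  matrix(stats::runif(h * w) < density, h, w)
}

# a small labelled descriptor population with one informative attribute
# (attribute `informative`) and noise elsewhere
toy_population <- function(n_per_class, informative = 11, sep = 0.6) {
  n <- 2 * n_per_class
  X <- matrix(stats::runif(n * 13), n, 13)
  colnames(X) <- attribute_names()
  y <- rep(1:2, each = n_per_class)
  X[, informative] <- ifelse(y == 1, 0.2, 0.2 + sep) +
    stats::rnorm(n, 0, 0.05)
  list(X = X, y = y)
}
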