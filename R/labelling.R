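#' Label connected vegetation regions
#'
#' Run-length-based connected-component labelling: each row of the mask is
#' run-length encoded; runs are scanned in row-major order, receiving
#' preliminary labels while label equivalences induced by runs touching in
#' the previous row are recorded in a union-find table; equivalence classes
#' are then resolved and the runs relabelled. Labels are assigned in order
#' of first encounter in a top-to-bottom, left-to-right scan, so region 1 is
#' the component whose topmost-leftmost pixel comes first.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param connectivity 8 (default) or 4. Under 8-connectivity diagonal
#'   neighbours belong to the same region.
#' @return An object of class `weed_labels`: a list with `labels` (integer
#'   matrix, 0 = background) and `n_regions`.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' label_components(m, 8)$n_regions  # 1: touching diagonally
#' label_components(m, 4)$n_regions  # 2
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  h <- nrow(mask); w <- ncol(mask)
  storage.mode(mask) <- "logical"

  # --- step 1: run-length encode each row ------------------------------
  row_runs <- vector("list", h)
  for (i in seq_len(h)) {
    r <- rle(as.vector(mask[i, ]))
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    row_runs[[i]] <- cbind(row = i, s = starts[keep], e = ends[keep])
  }
  runs <- do.call(rbind, row_runs)
  labels <- matrix(0L, h, w)
  if (is.null(runs)) {
    return(structure(list(labels = labels, n_regions = 0L,
                          connectivity = connectivity),
                     class = "weed_labels"))
  }
  nrun <- nrow(runs)
  rrow <- runs[, 1]; rs <- runs[, 2]; re <- runs[, 3]

  # --- steps 2-3: preliminary labels + equivalence resolution ----------
  # union-find over runs; a run overlapping a run of the previous row is
  # merged with it (reach = 1 extends overlap to diagonals)
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  reach <- if (connectivity == 8L) 1L else 0L
  prev_first <- 0L; prev_last <- 0L  # run index range of previous row
  row_start <- 1L
  k <- 1L
  while (k <= nrun) {
    row_start <- k
    this_row <- rrow[k]
    while (k <= nrun && rrow[k] == this_row) k <- k + 1L
    row_end <- k - 1L
    if (prev_first > 0L && rrow[prev_first] == this_row - 1L) {
      p <- prev_first
      for (j in row_start:row_end) {
        while (p <= prev_last && re[p] < rs[j] - reach) p <- p + 1L
        q <- p
        while (q <= prev_last && rs[q] <= re[j] + reach) {
          ra <- find(j); rb <- find(q)
          if (ra != rb) parent[ra] <- rb
          q <- q + 1L
        }
      }
    }
    prev_first <- row_start; prev_last <- row_end
  }

  # --- step 4: relabel in first-encounter scan order -------------------
  roots <- vapply(seq_len(nrun), find, integer(1))
  final <- match(roots, unique(roots))  # unique() keeps scan order
  for (j in seq_len(nrun)) {
    labels[rrow[j], rs[j]:re[j]] <- final[j]
  }
  structure(list(labels = labels, n_regions = max(final),
                 connectivity = connectivity),
            class = "weed_labels")
}

#' @export
print.weed_labels <- function(x, ...) {
  cat(sprintf("<weed_labels> %d x %d map, %d region(s), %d-connectivity\n",
              nrow(x$labels), ncol(x$labels), x$n_regions, x$connectivity))
  invisible(x)
}

#' Extract region objects from a label map
#'
#' Builds one region record per label, dropping (with a message) regions
#' smaller than `min_area`. The default of 25 px equals the area of the 5x5
#' structuring element, so after the standard opening the filter is a
#' no-op; it only guards degenerate inputs that skipped the opening.
#'
#' @param lmap A `weed_labels` object from [label_components()].
#' @param min_area Minimum region area in pixels (default 25).
#' @return List of class `weed_regions`; each element has `label`, `coords`
#'   (two-column matrix of row, col pixel coordinates), `bbox`
#'   (`row_min, col_min, row_max, col_max`, inclusive) and `area`.
#' @export
extract_regions <- function(lmap, min_area = 25) {
  stopifnot(inherits(lmap, "weed_labels"), min_area >= 0)
  labels <- lmap$labels
  h <- nrow(labels)
  idx <- which(labels > 0L)
  out <- list()
  if (length(idx)) {
    lab <- labels[idx]
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    dropped <- 0L
    for (l in sort(unique(lab))) {
      sel <- lab == l
      if (sum(sel) < min_area) {
        dropped <- dropped + 1L
        next
      }
      cr <- rows[sel]; cc <- cols[sel]
      out[[length(out) + 1L]] <- list(
        label = l,
        coords = cbind(row = cr, col = cc),
        bbox = c(row_min = min(cr), col_min = min(cc),
                 row_max = max(cr), col_max = max(cc)),
        area = sum(sel))
    }
    if (dropped > 0L) {
      message(dropped, " region(s) below min_area = ", min_area, " dropped")
    }
  }
  structure(out, class = "weed_regions")
}

#' @export
print.weed_regions <- function(x, ...) {
  cat(sprintf("<weed_regions> %d region(s)\n", length(x)))
  if (length(x)) {
    a <- vapply(x, `[[`, numeric(1), "area")
    cat(sprintf("  areas: min %d, median %d, max %d px\n",
                as.integer(min(a)), as.integer(stats::median(a)),
                as.integer(max(a))))
  }
  invisible(x)
}

#' Write a label map as 16-bit PNG and the region table as CSV
#'
#' @param lmap A `weed_labels` object.
#' @param regions A `weed_regions` list (for the CSV; optional).
#' @param labels_path,regions_path Output paths (`NULL` to skip either).
#' @return Invisibly, a list of the paths written.
#' @export
write_label_outputs <- function(lmap, regions = NULL,
                                labels_path = NULL, regions_path = NULL) {
  written <- list()
  if (!is.null(labels_path)) {
    m <- lmap$labels / max(1L, lmap$n_regions)
    png::writePNG(m, labels_path)  # 16-bit depth preserves many labels
    written$labels <- labels_path
  }
  if (!is.null(regions_path) && !is.null(regions)) {
    df <- do.call(rbind, lapply(regions, function(r) {
      data.frame(label = r$label, area = r$area,
                 row_min = r$bbox[1], col_min = r$bbox[2],
                 row_max = r$bbox[3], col_max = r$bbox[4])
    }))
    if (is.null(df)) {
      df <- data.frame(label = integer(), area = integer(),
                       row_min = integer(), col_min = integer(),
                       row_max = integer(), col_max = integer())
    }
    utils::write.csv(df, regions_path, row.names = FALSE)
    written$regions <- regions_path
  }
  invisible(written)
}
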