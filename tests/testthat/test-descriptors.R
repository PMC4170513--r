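test_that("Hu moments match the closed form for a disk", {
  disk <- raster_disk(50)
  phi <- hu_moments(disk)
  expect_lt(abs(phi["phi1"] - 1 / (2 * pi)) / (1 / (2 * pi)), 0.01)
})

test_that("Hu moments are translation- and 90-degree-rotation invariant", {
  set.seed(21)
  blob <- which(generate_region("dicot",
                                fixture_spec(width = 256, height = 256)),
                arr.ind = TRUE)
  phi <- hu_moments(blob)
  shifted <- blob + rep(c(10, 17), each = nrow(blob))
  expect_equal(hu_moments(shifted), phi, tolerance = 1e-12)
  expect_equal(hu_moments(rotate_coords_90(blob)), phi, tolerance = 1e-10)
})

test_that("phi7 flips sign under mirroring, magnitude preserved", {
  set.seed(31)
  ribbon <- which(generate_region("monocot",
                                  fixture_spec(width = 320, height = 320)),
                  arr.ind = TRUE)
  phi <- hu_moments(ribbon)
  phim <- hu_moments(mirror_coords(ribbon))
  expect_equal(phim["phi7"], -phi["phi7"], tolerance = 1e-10)
  expect_equal(abs(phim), abs(phi), tolerance = 1e-10)
})

test_that("single-pixel regions degrade to zeros with a flag", {
  phi <- hu_moments(cbind(5, 5))
  expect_equal(as.numeric(phi), rep(0, 7))
  expect_true(attr(phi, "degenerate"))
})

test_that("geometric descriptors match closed forms on canonical shapes", {
  # 1 x 100 horizontal line: variance formula gives exactly 4L/sqrt(12)
  line <- cbind(row = rep(1, 100), col = 1:100)
  g <- geometric_descriptors(line)
  expect_equal(g[["d4"]], 4 * 100 / sqrt(12), tolerance = 1e-12)
  expect_equal(g[["d3"]], 4 / sqrt(12), tolerance = 1e-12)
  expect_lte(g[["d5"]], 0.05)
  expect_equal(g[["d6"]], 100)

  # 10 x 10 square: enclosing circle spans the corner pixel centres
  sq <- raster_rect(10, 10)
  gs <- geometric_descriptors(sq)
  expect_equal(gs[["d2"]], 9 * sqrt(2), tolerance = 1e-9)
  expect_equal(gs[["d1"]], 36, tolerance = 1e-9)
  expect_equal(gs[["d6"]], 100)

  # disk: near-unit axis ratio
  gd <- geometric_descriptors(raster_disk(50))
  expect_gt(gd[["d5"]], 0.98)
  expect_equal(gd[["d2"]], 2 * sqrt(50^2), tolerance = 2)

  # equal-area convention
  ge <- geometric_descriptors(sq, diameter = "equivalent")
  expect_equal(ge[["d2"]], 2 * sqrt(100 / pi), tolerance = 1e-12)
})

test_that("d3 <= d4 and d5 in [0,1] on random regions", {
  set.seed(12)
  for (i in 1:25) {
    m <- open_mask(random_mask(32, 32, 0.55), 3)
    if (!any(m)) next
    lm <- label_components(m)
    for (r in extract_regions(lm, min_area = 2)) {
      g <- geometric_descriptors(r$coords)
      expect_lte(g[["d3"]], g[["d4"]] + 1e-12)
      expect_gte(g[["d5"]], 0); expect_lte(g[["d5"]], 1)
      expect_true(all(g >= 0))
    }
  }
})

test_that("minimal enclosing circle agrees with brute force", {
  set.seed(8)
  for (i in 1:30) {
    pts <- matrix(runif(2 * sample(3:12, 1), 0, 20), ncol = 2)
    expect_equal(min_enclosing_circle(pts)[3], mec_bruteforce(pts),
                 tolerance = 1e-7)
  }
})

test_that("scaling a blob x2 changes each |phi| by at most 5 percent", {
  set.seed(77)
  for (kind in c("monocot", "dicot")) {
    coords <- which(generate_region(kind,
                                    fixture_spec(width = 200, height = 200)),
                    arr.ind = TRUE)
    p1 <- hu_moments(coords)
    p2 <- hu_moments(scale_coords_2x(coords))
    rel <- abs(p2 - p1) / pmax(abs(p1), 1e-12)
    # sign-bearing higher moments can be tiny; compare where meaningful
    meaningful <- abs(p1) > 1e-10
    expect_true(all(rel[meaningful] <= 0.05))
  }
})

test_that("min-max statistics and normalisation behave per contract", {
  X <- rbind(a = c(1:7, 1:6), b = c(3 * (1:7), 2 * (1:6)))
  colnames(X) <- attribute_names()
  st <- fit_attribute_stats(X)
  expect_equal(unname(st$min), pmin(X[1, ], X[2, ]), ignore_attr = TRUE)
  expect_equal(unname(st$max), pmax(X[1, ], X[2, ]), ignore_attr = TRUE)
  expect_error(fit_attribute_stats(X[1, , drop = FALSE]), "two")

  Z <- normalise_descriptors(X, st)
  expect_true(all(Z >= 0 & Z <= 1))
  expect_equal(unname(Z[1, ]), rep(0, 13))
  expect_equal(unname(Z[2, ]), rep(1, 13))
  mid <- normalise_descriptors((X[1, ] + X[2, ]) / 2, st)
  expect_equal(unname(mid[1, ]), rep(0.5, 13))

  # degenerate attribute: min = max -> 0 with warning; out-of-range clipped
  X2 <- X; X2[, 5] <- 1
  st2 <- fit_attribute_stats(X2)
  expect_warning(Z2 <- normalise_descriptors(X2, st2), "min = max")
  expect_equal(unname(Z2[, 5]), c(0, 0))
  far <- X[2, ] * 10
  expect_true(all(normalise_descriptors(far, st) <= 1))
})

test_that("generator classes are separated in d5 and d4", {
  set.seed(55)
  sp <- fixture_spec(width = 320, height = 320)
  d5m <- d5d <- d4m <- d4d <- numeric(12)
  for (i in 1:12) {
    gm <- geometric_descriptors(which(generate_region("monocot", sp),
                                      arr.ind = TRUE))
    gd <- geometric_descriptors(which(generate_region("dicot", sp),
                                      arr.ind = TRUE))
    d5m[i] <- gm[["d5"]]; d5d[i] <- gd[["d5"]]
    d4m[i] <- gm[["d4"]]; d4d[i] <- gd[["d4"]]
  }
  expect_lt(max(d5m), min(d5d))   # disjoint axis-ratio distributions
})
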