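# shared toy prototypes: class 1 at the origin, class 2 one unit away on
# each attribute
proto_unit <- structure(
  list(v1 = stats::setNames(rep(0, 13), attribute_names()),
       v2 = stats::setNames(rep(1, 13), attribute_names()),
       class_names = c("monocot", "dicot")),
  class = "class_prototypes")

test_that("attribute supports follow the proximity formula", {
  # on the class-1 prototype with the other prototype at distance 1:
  # (1)/(1 + 1/2) = 2/3
  a <- attribute_supports(rep(0, 13), proto_unit, 1, subset = 1:13)
  expect_equal(unname(a), rep(2 / 3, 13), tolerance = 1e-12)
  expect_equal(unname(attribute_supports(rep(0, 13), proto_unit, 2, 1:13)),
               rep(1 / 3, 13), tolerance = 1e-12)
  # midway between prototypes: symmetric support
  expect_equal(unname(attribute_supports(rep(0.5, 13), proto_unit, 1, 1:13)),
               rep(0.5, 13))
  # identical prototypes: support 0.5 regardless of x
  pe <- proto_unit; pe$v2 <- pe$v1
  expect_equal(unname(attribute_supports(runif(13), pe, 1, 1:13)),
               rep(0.5, 13))
})

test_that("Choquet integral: worked example, modes, and brute-force match", {
  m0 <- fuzzy_measure(c(0.5, 0.5))
  expect_equal(choquet_support(c(0.8, 0.4), m0), 0.6)
  expect_equal(choquet_support(c(0.8, 0.4), m0, "verbatim"), 1.0)
  expect_error(choquet_support(c(0.4, 0.8), m0), "sorted")

  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:5, 1)
    g <- runif(n, 0.05, 0.7)
    lam <- solve_lambda(g)
    a <- runif(n)
    ord <- order(a, decreasing = TRUE)
    S <- choquet_support(a[ord], fuzzy_measure(g[ord], lambda = lam))
    expect_lt(abs(S - choquet_bruteforce(a, g, lam)), 1e-10)
  }
})

test_that("integrals are idempotent, bounded and monotone", {
  set.seed(67)
  for (i in 1:150) {
    n <- sample(2:13, 1)
    g <- runif(n, 0.05, 0.8 / sqrt(n))
    lam <- solve_lambda(g)
    meas <- function(ord) fuzzy_measure(g[ord], lambda = lam)
    a <- runif(n)
    ord <- order(a, decreasing = TRUE)
    Sc <- choquet_support(a[ord], meas(ord))
    Ss <- sugeno_support(a[ord], meas(ord))
    expect_gte(Sc, min(a) - 1e-10); expect_lte(Sc, max(a) + 1e-10)
    expect_gte(Ss, min(a) - 1e-10); expect_lte(Ss, max(a) + 1e-10)

    # idempotence at a constant support level
    cst <- rep(runif(1), n)
    expect_equal(choquet_support(cst, meas(seq_len(n))), cst[1],
                 tolerance = 1e-9)
    expect_equal(sugeno_support(cst, meas(seq_len(n))), cst[1],
                 tolerance = 1e-6)

    # raising one support never lowers either integral
    j <- sample(n, 1)
    b <- a; b[j] <- min(1, b[j] + runif(1, 0, 1 - b[j]))
    ordb <- order(b, decreasing = TRUE)
    expect_gte(choquet_support(b[ordb], meas(ordb)) - Sc, -1e-10)
    expect_gte(sugeno_support(b[ordb], meas(ordb)) - Ss, -1e-10)
  }
})

test_that("additive measure turns the Choquet integral into a weighted mean", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(2:13, 1)
    g <- runif(n); g <- g / sum(g)
    a <- runif(n)
    ord <- order(a, decreasing = TRUE)
    S <- choquet_support(a[ord], fuzzy_measure(g[ord], lambda = 0))
    expect_equal(S, sum(g * a), tolerance = 1e-10)
  }
})

test_that("Sugeno integral: hand example and zero supports", {
  m0 <- fuzzy_measure(c(0.5, 0.5))
  expect_equal(sugeno_support(c(0.8, 0.4), m0), 0.5)
  expect_equal(sugeno_support(c(0, 0), m0), 0)
})

test_that("Dempster-Shafer: hand-worked values and label symmetry", {
  # x on v1 with v2 at unit distance: Phi = (2/3, 1/3); b1 = 4/7
  x <- rep(0, 13)
  mu <- des_supports(x, proto_unit, subset = 1)
  phi1 <- 2 / 3; phi2 <- 1 / 3
  b1 <- phi1 * (1 - phi2) / (1 - phi1 * (1 - (1 - phi2)))
  b2 <- phi2 * (1 - phi1) / (1 - phi2 * (1 - (1 - phi1)))
  expect_equal(b1, 4 / 7, tolerance = 1e-12)
  expect_equal(mu, c(b1, b2), tolerance = 1e-12)

  # swapping prototypes swaps the class supports
  set.seed(73)
  for (i in 1:20) {
    pr <- proto_unit
    pr$v1 <- stats::setNames(runif(13), attribute_names())
    pr$v2 <- stats::setNames(runif(13), attribute_names())
    xr <- runif(13)
    sub <- sort(sample(13, 4))
    mu1 <- des_supports(xr, pr, sub)
    prs <- pr; prs$v1 <- pr$v2; prs$v2 <- pr$v1
    mu2 <- des_supports(xr, prs, sub)
    expect_equal(mu1, rev(mu2), tolerance = 1e-12)
    expect_true(all(mu1 >= 0 & mu1 <= 1))
  }

  # equal prototypes: perfect tie
  pe <- proto_unit; pe$v2 <- pe$v1
  mue <- des_supports(runif(13), pe, 1:13)
  expect_equal(mue[1], mue[2], tolerance = 1e-12)
})

test_that("triangular fuzzy number distance and ideal solutions", {
  expect_equal(tfn_distance(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(tfn_distance(c(0.2, 0.4, 0.9), c(0.2, 0.4, 0.9)), 0)
})

test_that("fuzzy TOPSIS ranks the dominant alternative first", {
  # two alternatives, one criterion, ratings (0.4,0.5,0.6) vs (0.2,0.3,0.4):
  # normalising by a3* = 0.6 gives r1 = (2/3, 5/6, 1), r2 = (1/3, 1/2, 2/3)
  r1 <- c(2 / 3, 5 / 6, 1); r2 <- c(1 / 3, 1 / 2, 2 / 3)
  cc <- vapply(list(r1, r2), function(r) {
    dp <- tfn_distance(r, c(1, 1, 1)); dn <- tfn_distance(r, c(0, 0, 0))
    dn / (dp + dn)
  }, numeric(1))
  expect_gt(cc[1], cc[2])
  expect_equal(cc[2], 0.5, tolerance = 1e-12)  # symmetric triplet

  # engine-level: CC in [0,1]; near-prototype region wins for its class
  set.seed(79)
  for (i in 1:50) {
    pr <- proto_unit
    pr$v1 <- stats::setNames(runif(13, 0, 0.3), attribute_names())
    pr$v2 <- stats::setNames(runif(13, 0.7, 1), attribute_names())
    cc <- fmcdm_supports(pr$v1, pr, weights = rep(1 / 4, 4), subset = 1:4)
    expect_true(all(cc >= 0 & cc <= 1))
    expect_gt(cc[1], cc[2])
  }
})

test_that("fuzzy TOPSIS decisions are stable across seeds on separated regions", {
  pr <- proto_unit
  x <- rep(0.1, 13)  # close to v1, far from v2
  flips <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    cc <- fmcdm_supports(x, pr, weights = rep(1 / 4, 4), subset = c(1, 2, 7, 11))
    if (cc[2] >= cc[1]) flips <- flips + 1
  }
  expect_lt(flips / 100, 0.05)
})

test_that("classify_region dispatches and resolves ties to monocot", {
  set.seed(83)
  pop <- toy_population(40, informative = 11)
  model <- train_weed_model(pop$X, pop$y, subset = NULL, k = 4)
  xm <- model$prototypes$v1  # exactly the monocot prototype
  for (meth in c("cfi", "sfi", "des", "fmcdm")) {
    set.seed(7)
    expect_equal(classify_region(xm, model, meth)$class, 1L)
  }
  expect_error(classify_region(xm, model, "svm"), "should be one of")

  # symmetric degenerate model: everything ties, class 1 wins with warning
  pe <- model
  pe$prototypes$v2 <- pe$prototypes$v1
  expect_warning(res <- classify_region(runif(13), pe, "des"), "tied")
  expect_equal(res$class, 1L)
})

test_that("generated ribbon and blob regions classify correctly", {
  set.seed(89)
  sp <- fixture_spec(width = 320, height = 320)
  build <- function(kind, n) {
    t(vapply(seq_len(n), function(i) {
      region_descriptors(which(generate_region(kind, sp), arr.ind = TRUE))
    }, numeric(13)))
  }
  Xtr <- rbind(build("monocot", 15), build("dicot", 15))
  ytr <- rep(1:2, each = 15)
  model <- train_weed_model(Xtr, ytr, subset = NULL, k = 4)
  Xte <- rbind(build("monocot", 5), build("dicot", 5))
  yte <- rep(1:2, each = 5)
  for (meth in c("cfi", "sfi", "des", "fmcdm")) {
    pred <- classify_regions(Xte, model, meth, seed = 11)
    expect_gte(mean(pred$class == yte), 0.9)
  }
})

test_that("evaluate_predictions reports accuracy and per-image spread", {
  pred <- data.frame(class = c(1, 1, 2, 2, 1), image = c(1, 1, 1, 2, 2))
  ev <- evaluate_predictions(pred, c(1, 2, 2, 2, 1))
  expect_equal(ev$accuracy, 80)
  expect_equal(unname(ev$per_image), c(200 / 3, 100))
  expect_equal(ev$confusion["monocot", "dicot"], 1)
})
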