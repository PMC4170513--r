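p_printed <- c(18, 20, 30, 28, 24, 23, 21, 27.5, 27.5, 27.5, 15, 40, 40)

test_that("densities reproduce the error-proportional formula", {
  rel <- compute_densities(p_printed)
  expect_equal(sum(rel$g), 1)
  expect_equal(rel$g[11], 15 / 341.5, tolerance = 1e-12)
  # accuracy reading flips the ranking
  rela <- compute_densities(p_printed, "accuracy")
  expect_equal(sum(rela$g), 1)
  expect_equal(rela$g[11], 85 / (1300 - 341.5), tolerance = 1e-12)
  expect_gt(rela$g[11], rela$g[12])
  expect_lt(rel$g[11], rel$g[12])
  # uniform errors -> uniform densities; scale invariance
  expect_equal(compute_densities(rep(20, 13))$g, rep(1 / 13, 13))
  expect_equal(compute_densities(p_printed / 2)$g, compute_densities(p_printed)$g)
  expect_error(compute_densities(rep(0, 13)), "zero")
  expect_error(compute_densities(rep(100, 13), "accuracy"), "zero")
})

test_that("subset selection honours fixed sets and error ranking", {
  expect_equal(select_subset(p_printed), c(1L, 2L, 7L, 11L))
  expect_equal(select_subset(p_printed, k = 4, fixed = NULL),
               c(11L, 1L, 2L, 7L))
  expect_equal(sort(select_subset(p_printed, k = 13, fixed = NULL)), 1:13)
  expect_error(select_subset(p_printed, fixed = c(1, 1, 2)), "distinct")
})

test_that("prototypes are class means; duplication leaves them unchanged", {
  x1 <- seq(0.1, 0.9, length.out = 13)
  x2 <- rev(x1)
  X <- rbind(x1, x2); colnames(X) <- attribute_names()
  pr <- fit_prototypes(X, c("monocot", "dicot"))
  expect_equal(unname(pr$v1), x1)
  expect_equal(unname(pr$v2), x2)
  Xd <- rbind(X, X)
  prd <- fit_prototypes(Xd, rep(c(1, 2), 2))
  expect_equal(prd$v1, pr$v1)
  expect_error(fit_prototypes(X, c(1, 1)), "both classes")
})

test_that("single-attribute error finds separation and coin flips", {
  set.seed(41)
  pop <- toy_population(50, informative = 11, sep = 0.6)
  st <- fit_attribute_stats(pop$X)
  Xn <- normalise_descriptors(pop$X, st)
  expect_equal(single_attribute_error(Xn, pop$y, 11), 0)
  # a constant attribute cannot separate: ties all go to class 1
  Xc <- Xn; Xc[, 4] <- 0.5
  expect_equal(single_attribute_error(Xc, pop$y, 4), 50)
  # pure-noise attributes hover near chance
  errs <- vapply(1:13, function(h) single_attribute_error(Xn, pop$y, h),
                 numeric(1))
  expect_equal(which.min(errs), 11L)
  expect_true(all(errs[-11] > 25))
})

test_that("trained model is coherent and round-trips through JSON", {
  set.seed(43)
  pop <- toy_population(60, informative = 11)
  model <- train_weed_model(pop$X, pop$y, subset = NULL, k = 4)
  expect_s3_class(model, "weed_model")
  expect_equal(sum(model$relevance$g), 1)
  expect_equal(sum(model$g_subset), 1)
  expect_true(11 %in% model$subset)
  expect_lt(abs(prod(1 + model$lambda_subset * model$g_subset) -
                (1 + model$lambda_subset)), 1e-10)

  tmp <- tempfile(fileext = ".json")
  write_weed_model(model, tmp)
  m2 <- read_weed_model(tmp)
  expect_equal(m2$prototypes$v1, model$prototypes$v1, tolerance = 1e-12)
  expect_equal(m2$g_subset, model$g_subset, tolerance = 1e-12)
  expect_equal(m2$subset, model$subset)
  expect_equal(m2$relevance$mode, model$relevance$mode)
  # restored model classifies identically
  x <- normalise_descriptors(pop$X, model$stats)[1, ]
  expect_equal(classify_region(x, m2, "des")$scores,
               classify_region(x, model, "des")$scores, tolerance = 1e-12)
})

test_that("prototype recovery approaches generator class means", {
  set.seed(47)
  n <- 200
  mu1 <- runif(13, 0.2, 0.4); mu2 <- runif(13, 0.6, 0.8)
  X <- rbind(matrix(rep(mu1, each = n / 2), n / 2) + rnorm(13 * n / 2, 0, 0.05),
             matrix(rep(mu2, each = n / 2), n / 2) + rnorm(13 * n / 2, 0, 0.05))
  colnames(X) <- attribute_names()
  y <- rep(1:2, each = n / 2)
  pr <- fit_prototypes(X, y)
  expect_lt(max(abs(pr$v1 - mu1)), 0.05)
  expect_lt(max(abs(pr$v2 - mu2)), 0.05)
})
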