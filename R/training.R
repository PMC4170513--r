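#' Canonical class labels
#'
#' Internal coercion of class labels to indices 1 (monocot) / 2 (dicot).
#' @noRd
.class_index <- function(y) {
  if (is.numeric(y)) {
    y <- as.integer(y)
    if (!all(y %in% c(1L, 2L))) stop("numeric labels must be 1 or 2",
                                     call. = FALSE)
    return(y)
  }
  idx <- match(tolower(as.character(y)), c("monocot", "dicot"))
  if (anyNA(idx)) stop("labels must be 'monocot' or 'dicot'", call. = FALSE)
  idx
}

.check_two_classes <- function(cls) {
  if (length(unique(cls)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
}

#' Class prototype vectors
#'
#' Componentwise mean of the normalised 13-attribute vectors per class:
#' `v1` for monocots, `v2` for dicots. These prototypes drive the
#' Dempster-Shafer proximities and, through them, the per-attribute grades
#' of support used by all four decision engines.
#'
#' @param X Matrix/data frame of normalised descriptors (13 attribute
#'   columns, values in \[0,1\]).
#' @param y Class labels: `"monocot"`/`"dicot"` or 1/2.
#' @return Object of class `class_prototypes` with `v1`, `v2`,
#'   `class_names`.
#' @export
fit_prototypes <- function(X, y) {
  X <- .attribute_matrix(X)
  cls <- .class_index(y)
  stopifnot(nrow(X) == length(cls))
  .check_two_classes(cls)
  structure(list(v1 = colMeans(X[cls == 1L, , drop = FALSE]),
                 v2 = colMeans(X[cls == 2L, , drop = FALSE]),
                 class_names = c("monocot", "dicot")),
            class = "class_prototypes")
}

#' Training-set error of a single attribute
#'
#' The error rate (in percent) of the one-attribute nearest-prototype rule:
#' a region is assigned the class whose prototype component gives the
#' larger proximity `(1 + (x_h - v_h)^2)^-1` (equivalently, whose prototype
#' is closer) on attribute `h` alone; ties go to class 1. Estimated on the
#' training regions themselves, mirroring a fixed training split without
#' cross-validation.
#'
#' @param X Normalised descriptor matrix.
#' @param y Class labels.
#' @param attribute Attribute index in 1..13.
#' @param prototypes Optional precomputed [fit_prototypes()] result.
#' @return Error percentage in \[0, 100\].
#' @export
single_attribute_error <- function(X, y, attribute, prototypes = NULL) {
  X <- .attribute_matrix(X)
  cls <- .class_index(y)
  .check_two_classes(cls)
  stopifnot(length(attribute) == 1L, attribute %in% 1:13)
  if (is.null(prototypes)) prototypes <- fit_prototypes(X, y)
  xh <- X[, attribute]
  p1 <- 1 / (1 + (xh - prototypes$v1[attribute])^2)
  p2 <- 1 / (1 + (xh - prototypes$v2[attribute])^2)
  pred <- ifelse(p1 >= p2, 1L, 2L)  # ties -> class 1
  100 * mean(pred != cls)
}

#' Fuzzy densities / criterion weights from per-attribute error rates
#'
#' Normalises the thirteen per-attribute error percentages `p_1..p_13`
#' into densities summing to one. Two readings are supported:
#' \describe{
#'   \item{`"verbatim-error"` (default)}{`g_i = p_i / sum(p)`, the relevance
#'     formula exactly as stated; note it makes relevance
#'     \emph{proportional to error}, i.e. worse attributes get larger
#'     densities. Kept as the default for fidelity to the published
#'     procedure.}
#'   \item{`"accuracy"`}{`g_i = (100 - p_i) / sum(100 - p)`, the reading
#'     under which the lowest-error attributes carry the most weight,
#'     consistent with calling them the "best" attributes.}
#' }
#' Numerators are floored at 0.5 percentage points so that a perfectly
#' separating (or perfectly failing) attribute still yields a density
#' strictly inside (0, 1), as the lambda-measure requires.
#'
#' @param p Numeric vector of 13 error percentages in \[0, 100\].
#' @param mode `"verbatim-error"` or `"accuracy"`.
#' @return Object of class `relevance_estimate` with `p`, `g`, `mode`.
#' @export
#' @examples
#' p <- c(18, 20, 30, 28, 24, 23, 21, 27.5, 27.5, 27.5, 15, 40, 40)
#' compute_densities(p)$g[11]  # 15 / 341.5
compute_densities <- function(p, mode = c("verbatim-error", "accuracy")) {
  mode <- match.arg(mode)
  p <- as.numeric(p)
  if (length(p) != 13L) stop("expected 13 error percentages", call. = FALSE)
  if (any(p < 0 | p > 100)) stop("error percentages must be in [0, 100]",
                                 call. = FALSE)
  num <- if (mode == "verbatim-error") p else 100 - p
  if (sum(num) == 0) stop("all relevance numerators are zero", call. = FALSE)
  num <- pmax(num, 0.5)
  structure(list(p = p, g = num / sum(num), mode = mode),
            class = "relevance_estimate")
}

#' Select the attribute subset used for classification
#'
#' Either a fixed subset (the published best-performing set
#' `{phi1, phi2, phi7, d4}`, i.e. indices 1, 2, 7, 11, by default) or the
#' `k` attributes with the lowest single-attribute error.
#'
#' @param p Numeric vector of 13 per-attribute error percentages.
#' @param k Number of attributes to keep when selecting by error.
#' @param fixed Optional integer indices to return as-is; set `NULL` to
#'   rank by `p` instead.
#' @return Integer vector of attribute indices.
#' @export
#' @examples
#' p <- c(18, 20, 30, 28, 24, 23, 21, 27.5, 27.5, 27.5, 15, 40, 40)
#' select_subset(p, fixed = NULL, k = 4)  # 11 1 2 7 by increasing error
select_subset <- function(p, k = 4, fixed = c(1L, 2L, 7L, 11L)) {
  if (!is.null(fixed)) {
    fixed <- as.integer(fixed)
    if (anyDuplicated(fixed) || !all(fixed %in% 1:13) || !length(fixed)) {
      stop("`fixed` must be distinct indices in 1..13", call. = FALSE)
    }
    return(fixed)
  }
  stopifnot(length(p) == 13L, k >= 1, k <= 13)
  order(p)[seq_len(k)]
}

#' Train the weed classification model
#'
#' Fits everything the four decision engines need, from raw descriptor
#' vectors and expert labels:
#' min-max attribute statistics (frozen for test time), per-class prototype
#' vectors in normalised space, the thirteen single-attribute error rates,
#' fuzzy densities / criterion weights, the attribute subset, and the
#' lambda-measure parameters for the full set and the subset (densities
#' renormalised over the subset so the measure of the full coalition stays
#' 1).
#'
#' @param X Matrix/data frame of \emph{raw} descriptors (13 attribute
#'   columns).
#' @param y Class labels (`"monocot"`/`"dicot"` or 1/2).
#' @param relevance_mode Passed to [compute_densities()].
#' @param subset Fixed attribute subset (default the published best four,
#'   indices 1, 2, 7, 11); `NULL` to select the `k` lowest-error
#'   attributes from this training set.
#' @param k Subset size when `subset = NULL`.
#' @param fmcdm_T Fuzziness threshold for the FMCDM engine (default 0.1).
#' @return Object of class `weed_model`.
#' @export
train_weed_model <- function(X, y,
                             relevance_mode = c("verbatim-error", "accuracy"),
                             subset = c(1L, 2L, 7L, 11L), k = 4,
                             fmcdm_T = 0.1) {
  relevance_mode <- match.arg(relevance_mode)
  X <- .attribute_matrix(X)
  cls <- .class_index(y)
  .check_two_classes(cls)
  stats <- fit_attribute_stats(X)
  Xn <- normalise_descriptors(X, stats)
  prototypes <- fit_prototypes(Xn, cls)
  p <- vapply(1:13, function(h) {
    single_attribute_error(Xn, cls, h, prototypes)
  }, numeric(1))
  relevance <- compute_densities(p, relevance_mode)
  subset <- select_subset(p, k = k, fixed = subset)
  g_sub <- relevance$g[subset] / sum(relevance$g[subset])
  model <- structure(list(
    prototypes = prototypes,
    stats = stats,
    relevance = relevance,
    subset = subset,
    g_subset = g_sub,
    lambda_full = solve_lambda(relevance$g),
    lambda_subset = solve_lambda(g_sub),
    fmcdm_T = fmcdm_T,
    n_train = nrow(X)
  ), class = "weed_model")
  model
}

#' @export
print.weed_model <- function(x, ...) {
  cat("<weed_model>\n")
  cat("  trained on", x$n_train, "regions;",
      "relevance mode:", x$relevance$mode, "\n")
  cat("  subset:", paste(attribute_names()[x$subset], collapse = ", "), "\n")
  cat(sprintf("  lambda (full / subset): %.4g / %.4g\n",
              x$lambda_full, x$lambda_subset))
  invisible(x)
}

#' Serialise / restore a trained model as JSON
#'
#' The whole model (prototypes, attribute statistics, error rates,
#' densities, subset, lambdas, configuration) round-trips through a single
#' human-readable JSON document.
#'
#' @param model A `weed_model`.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_weed_model()` returns the model.
#' @export
write_weed_model <- function(model, path) {
  stopifnot(inherits(model, "weed_model"))
  doc <- list(
    prototypes = list(v1 = model$prototypes$v1, v2 = model$prototypes$v2,
                      class_names = model$prototypes$class_names),
    stats = list(min = model$stats$min, max = model$stats$max),
    relevance = list(p = model$relevance$p, g = model$relevance$g,
                     mode = model$relevance$mode),
    subset = model$subset,
    g_subset = model$g_subset,
    lambda_full = model$lambda_full,
    lambda_subset = model$lambda_subset,
    fmcdm_T = model$fmcdm_T,
    n_train = model$n_train
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_weed_model
#' @export
read_weed_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- attribute_names()
  structure(list(
    prototypes = structure(list(
      v1 = stats::setNames(as.numeric(doc$prototypes$v1), nm),
      v2 = stats::setNames(as.numeric(doc$prototypes$v2), nm),
      class_names = doc$prototypes$class_names), class = "class_prototypes"),
    stats = structure(list(min = stats::setNames(as.numeric(doc$stats$min), nm),
                           max = stats::setNames(as.numeric(doc$stats$max), nm)),
                      class = "attribute_stats"),
    relevance = structure(list(p = as.numeric(doc$relevance$p),
                               g = as.numeric(doc$relevance$g),
                               mode = doc$relevance$mode),
                          class = "relevance_estimate"),
    subset = as.integer(doc$subset),
    g_subset = as.numeric(doc$g_subset),
    lambda_full = doc$lambda_full,
    lambda_subset = doc$lambda_subset,
    fmcdm_T = doc$fmcdm_T,
    n_train = doc$n_train
  ), class = "weed_model")
}
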