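#' Per-attribute grades of support for one class
#'
#' Converts a region's normalised attribute values into class-conditional
#' supports in (0, 1) via the Dempster-Shafer proximity restricted to one
#' attribute at a time:
#' `a_h = (1 + (x_h - v_class,h)^2)^-1 / sum_k (1 + (x_h - v_k,h)^2)^-1`.
#' With two classes the supports of a given attribute for the two classes
#' sum to 1, and a region equidistant from both prototypes scores 0.5.
#'
#' The fuzzy-integral and MCDM engines need class-specific supports rather
#' than raw attribute values; this proximity supplies them consistently
#' with the evidence-combination engine.
#'
#' @param x Named (or canonically ordered) numeric 13-vector of normalised
#'   attributes, or a vector covering at least `subset`.
#' @param prototypes A [fit_prototypes()] result.
#' @param class Class index, 1 (monocot) or 2 (dicot).
#' @param subset Integer attribute indices to use.
#' @return Numeric vector of supports, one per attribute in `subset`.
#' @export
attribute_supports <- function(x, prototypes, class, subset = 1:13) {
  stopifnot(inherits(prototypes, "class_prototypes"), class %in% c(1L, 2L))
  x <- as.numeric(x)[subset]
  d1 <- 1 / (1 + (x - prototypes$v1[subset])^2)
  d2 <- 1 / (1 + (x - prototypes$v2[subset])^2)
  if (class == 1L) d1 / (d1 + d2) else d2 / (d1 + d2)
}

#' Choquet fuzzy integral of a sorted support vector
#'
#' Aggregates per-attribute supports `a_1 >= a_2 >= ... >= a_n` against the
#' cumulative lambda-measure `g(1)..g(n)` computed over that order.
#'
#' Two modes:
#' \describe{
#'   \item{`"canonical"` (default)}{`S = a_n + sum_{h=2..n}(a_{h-1} - a_h)
#'     g(h-1)`, which given `g(n) = 1` is algebraically the standard
#'     Choquet integral `sum_h a_h (g(h) - g(h-1))`; output lies in
#'     `[min a, max a]`.}
#'   \item{`"verbatim"`}{starts the telescoped sum at `a_1` instead of
#'     `a_n`, reproducing the published expression literally; the result
#'     then always exceeds `a_1` and can leave \[0,1\]. Retained for
#'     fidelity; see the methods vignette.}
#' }
#'
#' @param a Numeric support vector sorted in non-increasing order (sorting
#'   and co-sorting of the densities is the caller's step).
#' @param measure A [fuzzy_measure()] whose densities are aligned with `a`.
#' @param mode `"canonical"` or `"verbatim"`.
#' @return Scalar degree of support.
#' @export
choquet_support <- function(a, measure, mode = c("canonical", "verbatim")) {
  mode <- match.arg(mode)
  stopifnot(inherits(measure, "fuzzy_measure"), length(a) == measure$n)
  if (any(diff(a) > 1e-12)) {
    stop("internal error: supports must be sorted in non-increasing order",
         call. = FALSE)
  }
  n <- length(a)
  if (n == 1L) return(a)
  gcum <- cumulative_measures(measure)
  head_term <- if (mode == "canonical") a[n] else a[1]
  head_term + sum((a[-n] - a[-1]) * gcum[-n])
}

#' Sugeno fuzzy integral of a sorted support vector
#'
#' `S = max_h min(a_h, g(h))` with the cumulative measures over the
#' non-increasing order of `a`. Like the canonical Choquet integral it is
#' idempotent and bounded by `[min a, max a]`.
#'
#' @inheritParams choquet_support
#' @return Scalar degree of support.
#' @export
sugeno_support <- function(a, measure) {
  stopifnot(inherits(measure, "fuzzy_measure"), length(a) == measure$n)
  if (any(diff(a) > 1e-12)) {
    stop("internal error: supports must be sorted in non-increasing order",
         call. = FALSE)
  }
  gcum <- cumulative_measures(measure)
  max(pmin(a, gcum))
}

# fuzzy-integral class supports for one region
.integral_supports <- function(x, model, engine, mode = "canonical") {
  vapply(1:2, function(l) {
    a <- attribute_supports(x, model$prototypes, l, model$subset)
    ord <- order(a, decreasing = TRUE)
    meas <- fuzzy_measure(model$g_subset[ord], lambda = model$lambda_subset)
    if (engine == "cfi") {
      choquet_support(a[ord], meas, mode)
    } else {
      sugeno_support(a[ord], meas)
    }
  }, numeric(1))
}

#' Dempster-Shafer class supports for one region
#'
#' Per attribute `A`, the proximities `Phi_jA` of the region to the two
#' class prototypes are turned into membership degrees
#' `b_j(A) = Phi_jA prod_{k != j}(1 - Phi_kA) /
#' (1 - Phi_jA (1 - prod_{k != j}(1 - Phi_kA)))`, and the evidence is
#' combined across attributes as `mu_j = prod_A b_j(A)`. Swapping the two
#' prototypes swaps `mu_1` and `mu_2`.
#'
#' @param x Normalised attribute vector.
#' @param prototypes A [fit_prototypes()] result.
#' @param subset Attribute indices to combine.
#' @return Numeric vector `c(mu_1, mu_2)`.
#' @export
des_supports <- function(x, prototypes, subset = 1:13) {
  phi1 <- attribute_supports(x, prototypes, 1L, subset)
  phi2 <- 1 - phi1
  eps <- 1e-12  # denominator cannot vanish for finite input; guard anyway
  b1 <- phi1 * (1 - phi2) / pmax(1 - phi1 * (1 - (1 - phi2)), eps)
  b2 <- phi2 * (1 - phi1) / pmax(1 - phi2 * (1 - (1 - phi1)), eps)
  c(prod(b1), prod(b2))
}

#' Distance between two triangular fuzzy numbers
#'
#' `d(u, z) = sqrt(((u1-z1)^2 + (u2-z2)^2 + (u3-z3)^2) / 3)` for triplets
#' `(u1, u2, u3)` with `u1 <= u2 <= u3`.
#'
#' @param u,z Numeric triplets.
#' @return Scalar distance.
#' @export
tfn_distance <- function(u, z) {
  sqrt(sum((u - z)^2) / 3)
}

#' Fuzzy multicriteria (fuzzy TOPSIS) class closeness coefficients
#'
#' Each class (alternative) is rated under each attribute (criterion) by
#' its class-conditional support, fuzzified into a triangular fuzzy number
#' `(x - eps1, x, x + eps2)` with `eps1 != eps2` drawn uniformly from
#' (0, T] once per region, clipped to \[0,1\] and sorted ascending. The
#' matrix is normalised per criterion by the largest upper bound, weighted
#' by the criterion weights, and each class is scored by its closeness
#' coefficient `CC = d- / (d+ + d-)` to the fuzzy ideal solutions
#' `p+ = (1,1,1)` and `p- = (0,0,0)`.
#'
#' Uses the current RNG stream; seed the session (or use the `seed`
#' argument of [classify_regions()]) for reproducibility.
#'
#' @param x Normalised attribute vector.
#' @param prototypes A [fit_prototypes()] result.
#' @param weights Criterion weights for the attributes in `subset`
#'   (renormalised to sum 1 internally).
#' @param subset Attribute indices used as criteria.
#' @param T Fuzziness threshold in (0, 1], default 0.1.
#' @return Numeric vector `c(CC_1, CC_2)` of closeness coefficients in
#'   \[0, 1\].
#' @export
fmcdm_supports <- function(x, prototypes, weights, subset = 1:13, T = 0.1) {
  stopifnot(T > 0, T <= 1, length(weights) == length(subset))
  w <- weights / sum(weights)
  eps1 <- stats::runif(1, 0, T)
  eps2 <- stats::runif(1, 0, T)
  while (eps2 == eps1) eps2 <- stats::runif(1, 0, T)
  rate <- rbind(attribute_supports(x, prototypes, 1L, subset),
                attribute_supports(x, prototypes, 2L, subset))
  n <- length(subset)
  dpos <- numeric(2); dneg <- numeric(2)
  tfn <- array(0, dim = c(2, n, 3))
  for (i in 1:2) for (j in seq_len(n)) {
    tfn[i, j, ] <- sort(pmin(pmax(
      c(rate[i, j] - eps1, rate[i, j], rate[i, j] + eps2), 0), 1))
  }
  for (j in seq_len(n)) {
    a3_star <- max(tfn[, j, 3])
    for (i in 1:2) {
      v <- (tfn[i, j, ] / a3_star) * w[j]
      dpos[i] <- dpos[i] + tfn_distance(v, c(1, 1, 1))
      dneg[i] <- dneg[i] + tfn_distance(v, c(0, 0, 0))
    }
  }
  dneg / (dpos + dneg)
}

#' Classify one region
#'
#' Dispatches the region's normalised attribute vector to one of the four
#' decision engines over the model's attribute subset and picks the class
#' with maximal support. Exact ties resolve to class 1 (monocot) with a
#' warning.
#'
#' @param x Normalised 13-attribute vector (e.g. a row of
#'   [normalise_descriptors()] output).
#' @param model A [train_weed_model()] result.
#' @param method One of `"cfi"`, `"sfi"`, `"des"`, `"fmcdm"`.
#' @param choquet_mode Passed to [choquet_support()] when `method = "cfi"`.
#' @return List with `class` (1/2), `class_name`, `scores` (named
#'   per-class supports) and `method`.
#' @export
classify_region <- function(x, model,
                            method = c("cfi", "sfi", "des", "fmcdm"),
                            choquet_mode = "canonical") {
  method <- match.arg(method)
  stopifnot(inherits(model, "weed_model"))
  scores <- switch(method,
    cfi = .integral_supports(x, model, "cfi", choquet_mode),
    sfi = .integral_supports(x, model, "sfi"),
    des = des_supports(x, model$prototypes, model$subset),
    fmcdm = fmcdm_supports(x, model$prototypes,
                           model$g_subset, model$subset, model$fmcdm_T)
  )
  if (scores[1] == scores[2]) {
    warning("tied class supports; resolving to class 1 (monocot)",
            call. = FALSE)
  }
  cls <- if (scores[2] > scores[1]) 2L else 1L
  list(class = cls,
       class_name = model$prototypes$class_names[cls],
       scores = stats::setNames(scores, model$prototypes$class_names),
       method = method)
}

#' Classify a table of regions
#'
#' @param X Matrix/data frame of \emph{raw} descriptors (13 attribute
#'   columns; normalised internally with the model's frozen statistics),
#'   optionally with a `label` column carried through.
#' @param model A `weed_model`.
#' @param method Decision engine, as in [classify_region()].
#' @param seed Optional integer seed applied before the (FMCDM) random
#'   draws so predictions are reproducible.
#' @return Data frame with columns `label`, `class`, `class_name`,
#'   `score_monocot`, `score_dicot`, `method`.
#' @export
classify_regions <- function(X, model, method = "fmcdm", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- if (is.data.frame(X) && "label" %in% names(X)) {
    X$label
  } else {
    seq_len(nrow(as.matrix(X)))
  }
  Xn <- normalise_descriptors(.attribute_matrix(X), model$stats)
  rows <- lapply(seq_len(nrow(Xn)), function(i) {
    res <- classify_region(Xn[i, ], model, method)
    data.frame(label = labels[i], class = res$class,
               class_name = res$class_name,
               score_monocot = res$scores[1], score_dicot = res$scores[2],
               method = method, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Evaluate predictions against expert labels
#'
#' @param pred Data frame from [classify_regions()] (needs `class`), with
#'   an optional `image` column for per-image statistics.
#' @param truth Vector of true classes (`"monocot"`/`"dicot"` or 1/2)
#'   aligned with `pred` rows.
#' @return List with overall `accuracy` (percent), the 2x2 `confusion`
#'   table, and when `image` is present, `per_image` accuracies with their
#'   `mean` and `sd`.
#' @export
evaluate_predictions <- function(pred, truth) {
  truth <- .class_index(truth)
  stopifnot(nrow(pred) == length(truth))
  hit <- pred$class == truth
  out <- list(
    accuracy = 100 * mean(hit),
    confusion = table(predicted = factor(pred$class, 1:2,
                                         c("monocot", "dicot")),
                      truth = factor(truth, 1:2, c("monocot", "dicot")))
  )
  if ("image" %in% names(pred)) {
    per <- c(tapply(hit, pred$image, function(z) 100 * mean(z)))
    out$per_image <- per
    out$mean_per_image <- mean(per)
    out$sd_per_image <- stats::sd(per)
  }
  out
}
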