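#' Solve for the lambda parameter of a Sugeno lambda-fuzzy measure
#'
#' Given attribute densities `g_1..g_n` in (0,1), the measure's lambda is
#' the unique real root greater than -1 (excluding the trivial root 0) of
#' `1 + lambda = prod_i(1 + lambda * g_i)`.
#'
#' If the densities sum to 1 the measure is additive and lambda = 0; a sum
#' below 1 gives lambda > 0 (superadditive), above 1 gives
#' lambda in (-1, 0) (subadditive). The root is isolated by dividing out
#' the trivial zero root (so no bracketing trouble arises when the sum is
#' close to 1), bracketed, solved with [stats::uniroot()], and polished
#' with Newton steps to `|f(lambda)| < 1e-12`.
#'
#' @param densities Numeric vector, each in the open interval (0, 1),
#'   length >= 2.
#' @return The scalar lambda.
#' @export
#' @examples
#' solve_lambda(c(0.3, 0.3))  # 40/9
#' solve_lambda(c(0.6, 0.6))  # -5/9
solve_lambda <- function(densities) {
  g <- as.numeric(densities)
  if (length(g) < 2L) stop("need at least two densities", call. = FALSE)
  if (any(g <= 0 | g >= 1)) {
    stop("densities must lie strictly inside (0, 1)", call. = FALSE)
  }
  s <- sum(g)
  if (abs(s - 1) < 1e-9) return(0)
  f <- function(l) prod(1 + l * g) - (1 + l)
  # h = f(lambda) / lambda removes the trivial root at 0; h(0) = sum(g) - 1
  h <- function(l) if (l == 0) s - 1 else f(l) / l
  if (s > 1) {
    lo <- -1 + 1e-9; hi <- 0           # h(lo) < 0 < h(0)
  } else {
    lo <- 0; hi <- 1
    while (h(hi) <= 0) {
      hi <- hi * 2
      if (hi > 1e12) stop("failed to bracket lambda", call. = FALSE)
    }
  }
  lam <- stats::uniroot(h, c(lo, hi), tol = 1e-15)$root
  # Newton polish on f itself
  for (i in 1:50) {
    fv <- f(lam)
    if (abs(fv) < 1e-12) break
    dfv <- sum(vapply(seq_along(g), function(j) {
      g[j] * prod(1 + lam * g[-j])
    }, numeric(1))) - 1
    if (dfv == 0) break
    step <- fv / dfv
    lam2 <- lam - step
    if (lam2 <= -1) lam2 <- (lam - 1) / 2
    lam <- lam2
  }
  lam
}

#' Construct a lambda-fuzzy measure from densities
#'
#' @param densities Numeric vector of densities in (0, 1).
#' @param lambda Optional precomputed lambda; solved from the densities
#'   when `NULL`.
#' @return Object of class `fuzzy_measure` with `densities`, `lambda`, `n`.
#' @export
fuzzy_measure <- function(densities, lambda = NULL) {
  if (is.null(lambda)) lambda <- solve_lambda(densities)
  structure(list(densities = as.numeric(densities), lambda = lambda,
                 n = length(densities)),
            class = "fuzzy_measure")
}

#' @export
print.fuzzy_measure <- function(x, ...) {
  cat(sprintf("<fuzzy_measure> n = %d, lambda = %.6g, sum(g) = %.6g\n",
              x$n, x$lambda, sum(x$densities)))
  invisible(x)
}

#' Cumulative measures over an ordered attribute sequence
#'
#' The recursion `g(1) = g_{o(1)}`,
#' `g(t) = g_{o(t)} + g(t-1) + lambda * g_{o(t)} * g(t-1)` evaluated along a
#' permutation `o` of the attributes. For a valid measure the sequence is
#' strictly increasing and reaches `g(n) = 1` (within 1e-6); with
#' lambda = 0 it is simply the running sum of the densities.
#'
#' @param measure A [fuzzy_measure()].
#' @param order Integer permutation of `1:n` (default identity).
#' @return Numeric vector `g(1)..g(n)`.
#' @export
cumulative_measures <- function(measure, order = seq_len(measure$n)) {
  stopifnot(inherits(measure, "fuzzy_measure"))
  if (length(order) != measure$n || !setequal(order, seq_len(measure$n))) {
    stop("`order` must be a permutation of 1..n", call. = FALSE)
  }
  g <- measure$densities[order]
  lam <- measure$lambda
  out <- numeric(length(g))
  out[1] <- g[1]
  for (t in seq_along(g)[-1]) {
    out[t] <- g[t] + out[t - 1] + lam * g[t] * out[t - 1]
  }
  out
}

#' Measure of an arbitrary attribute subset
#'
#' Closed form `g(A) = (prod_{i in A}(1 + lambda g_i) - 1) / lambda`
#' (the running sum when lambda = 0). Mainly a convenience for inspecting
#' coalition worths; the classifiers use [cumulative_measures()].
#'
#' @param measure A [fuzzy_measure()].
#' @param subset Integer indices of the attributes in the coalition.
#' @return Scalar measure of the subset.
#' @export
subset_measure <- function(measure, subset) {
  stopifnot(inherits(measure, "fuzzy_measure"))
  if (length(subset) == 0L) return(0)
  g <- measure$densities[subset]
  lam <- measure$lambda
  if (lam == 0) sum(g) else (prod(1 + lam * g) - 1) / lam
}
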