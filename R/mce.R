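#' Saaty random consistency index
#'
#' Classical random-index values used to turn the consistency index of a
#' pairwise comparison matrix into a consistency ratio.
#'
#' @param n matrix order (1..9 supported; larger orders use the n = 9
#'   value, adequate for suitability hierarchies which stay small).
#' @return The random index.
#' @export
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  ri[min(n, 9L)]
}

validate_pairwise <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("pairwise matrix must be square", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("pairwise matrix entries must be positive and finite", call. = FALSE)
  if (any(abs(diag(m) - 1) > tol))
    stop("pairwise matrix must have a unit diagonal", call. = FALSE)
  if (any(abs(m * t(m) - 1) > 1e-6))
    stop("pairwise matrix is not reciprocal (a_ji must equal 1/a_ij)",
         call. = FALSE)
  invisible(m)
}

#' AHP weights from a pairwise comparison matrix
#'
#' Computes the principal right eigenvector of a reciprocal pairwise
#' comparison matrix by power iteration (tolerance 1e-10, at most 1e4
#' iterations), normalized to sum to one, together with the standard
#' consistency diagnostics: lambda_max, consistency index
#' CI = (lambda_max - n)/(n - 1) and consistency ratio CR = CI / RI using
#' Saaty's random-index table. For n <= 2 a reciprocal matrix is always
#' consistent and CR is defined as 0. A CR above 0.1 flags the judgments
#' as inconsistent (result still returned).
#'
#' @param m square reciprocal matrix of positive comparison ratios.
#' @return A list of class `ahp_result`: `weights`, `lambda_max`,
#'   `consistency_index`, `consistency_ratio`, `is_consistent`.
#' @export
ahp_weights <- function(m) {
  validate_pairwise(m)
  n <- nrow(m)
  w <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(10000L)) {
    wn <- as.numeric(m %*% w)
    lambda_new <- sum(wn)      # since sum(w) == 1
    wn <- wn / lambda_new
    if (max(abs(wn - w)) < 1e-10) { w <- wn; lambda <- lambda_new; break }
    w <- wn; lambda <- lambda_new
  }
  ci <- if (n <= 2L) 0 else (lambda - n) / (n - 1)
  ri <- saaty_ri(n)
  cr <- if (n <= 2L || ri == 0) 0 else ci / ri
  if (cr > 0.1)
    warning(sprintf("consistency ratio %.3f exceeds 0.1: judgments are inconsistent", cr))
  structure(list(weights = w, lambda_max = lambda,
                 consistency_index = ci, consistency_ratio = cr,
                 is_consistent = cr <= 0.1),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat("<ahp_result>\n  weights:", paste(sprintf("%.4f", x$weights),
                                        collapse = " "), "\n")
  cat(sprintf("  lambda_max %.6f  CI %.6f  CR %.6f  (%s)\n",
              x$lambda_max, x$consistency_index, x$consistency_ratio,
              if (x$is_consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Build a perfectly consistent pairwise matrix from a weight vector
#'
#' Useful for weight entry by direct assignment and for testing: the matrix
#' `w_i / w_j` has the given weights as its principal eigenvector and CR 0.
#'
#' @param w positive weight vector (any scale).
#' @return Reciprocal matrix.
#' @export
consistent_matrix <- function(w) {
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  outer(w, w, "/")
}

check_weights <- function(weights, tol = 0.01) {
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights > 1))
    stop("weights must lie in (0, 1]", call. = FALSE)
  if (abs(sum(weights) - 1) > tol)
    stop(sprintf("weights sum to %.4f, outside 1 +/- %.2f", sum(weights), tol),
         call. = FALSE)
  invisible(weights)
}

#' Weighted linear combination
#'
#' Aggregates standardized criterion scores as a weighted sum. Weights must
#' sum to one within a tolerance of 0.01 (printed weight tables are often
#' rounded, e.g. 0.33/0.34/0.33). `NA` in any score propagates to `NA`.
#' `scores` may be a matrix (units x criteria); then a vector of per-row
#' combinations is returned.
#'
#' @param scores numeric vector (one value per criterion) or matrix with
#'   one column per criterion.
#' @param weights weight vector, same length as the number of criteria.
#' @return Single value or per-row vector.
#' @export
wlc_aggregate <- function(scores, weights) {
  check_weights(weights)
  if (is.matrix(scores)) {
    if (ncol(scores) != length(weights))
      stop("scores and weights length mismatch", call. = FALSE)
    return(as.numeric(scores %*% weights))
  }
  if (length(scores) != length(weights))
    stop("scores and weights length mismatch", call. = FALSE)
  sum(scores * weights)
}

#' Rescale values linearly to the 1-9 suitability scale
#'
#' The observed minimum maps to 1 and the maximum to 9 (benefit criteria);
#' with `invert = TRUE` the mapping is reversed so that small input values
#' (e.g. distances to a road) score high. Scores are kept continuous;
#' integer rounding would discard information before classification. A
#' constant input cannot be anchored at both ends and maps to the midpoint
#' 5 with a warning. `NA` is preserved.
#'
#' @param x numeric vector or `lucis_raster`.
#' @param invert logical; reverse the scale for cost-like criteria.
#' @return Same shape as `x`, values in `[1, 9]`.
#' @export
rescale_linear_1_9 <- function(x, invert = FALSE) {
  if (inherits(x, "lucis_raster")) {
    x$values[] <- rescale_linear_1_9(as.vector(x$values), invert = invert)
    return(x)
  }
  fin <- x[is.finite(x)]
  if (!length(fin)) stop("cannot rescale an all-NA input", call. = FALSE)
  lo <- min(fin); hi <- max(fin)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    warning("constant input: rescaled to midpoint 5")
    out <- ifelse(is.na(x), NA_real_, 5)
    return(out)
  }
  s <- 1 + 8 * (x - lo) / (hi - lo)
  if (invert) s <- 10 - s
  s
}

# ---- Jenks natural breaks (exact Fisher dynamic program) ----------------

# Interval cost: within-class sum of squared deviations of sorted x[j..i],
# from prefix sums. j, i may be vectors of equal length.
.jenks_cost <- function(S, Q, j, i) {
  n <- i - j + 1
  s <- S[i + 1L] - S[j]
  Q[i + 1L] - Q[j] - s * s / n
}

# One DP layer by divide and conquer over the monotone argmin (the SSE
# interval cost satisfies the concave quadrangle inequality). Fills, in the
# environment `env`, env$D[i] = min_j prev[j-1] + cost(j, i) and env$J[i] =
# the smallest optimal j, for i in [m, n]. Iterative stack avoids deep
# recursion and vector copying.
.jenks_layer <- function(prev, S, Q, m, n, env) {
  stack <- list(c(m, n, m, n))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo_i <- fr[1]; hi_i <- fr[2]; lo_j <- fr[3]; hi_j <- fr[4]
    if (lo_i > hi_i) next
    mid <- (lo_i + hi_i) %/% 2L
    js <- lo_j:min(hi_j, mid)
    cand <- prev[js - 1L] + .jenks_cost(S, Q, js, rep(mid, length(js)))
    best <- which.min(cand)               # first minimum = smallest j
    env$D[mid] <- cand[best]
    env$J[mid] <- js[best]
    stack[[length(stack) + 1L]] <- c(lo_i, mid - 1L, lo_j, js[best])
    stack[[length(stack) + 1L]] <- c(mid + 1L, hi_i, js[best], hi_j)
  }
  invisible(NULL)
}

#' Jenks natural-breaks classification
#'
#' Exact optimal 1-D classification: partitions the sorted data into `k`
#' contiguous classes minimizing the within-class sum of squared
#' deviations (SDCM), via the Fisher dynamic program (argmin monotonicity
#' makes each layer O(n log n)). Ties between equally good partitions are
#' broken toward the lowest break values. For very large inputs
#' (> `sample_threshold` values) the breaks are fit on a deterministic
#' evenly spaced subsample of the sorted values and applied to all data.
#'
#' @param values numeric vector (NA dropped for fitting; assignments for
#'   `NA` are `NA`).
#' @param k number of classes, `1 <= k <=` number of distinct values.
#' @param sample_threshold fit on a subsample above this size (default
#'   50000).
#' @return A list of class `jenks_result`: `breaks` (the k-1 interior
#'   class maxima, ascending), `assignments` (class 1..k per input datum),
#'   `gvf` (goodness of variance fit, 1 - SDCM/SDAM), `sdcm`, `sdam`.
#' @export
jenks_breaks <- function(values, k, sample_threshold = 50000L) {
  xin <- as.numeric(values)
  x <- xin[!is.na(xin)]
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ndist <- length(unique(x))
  if (ndist < k)
    stop(sprintf("need at least k = %d distinct values, got %d", k, ndist),
         call. = FALSE)
  xfit <- sort(x)
  if (length(xfit) > sample_threshold) {
    idx <- unique(round(seq(1L, length(xfit), length.out = sample_threshold)))
    xfit <- xfit[idx]
  }
  n <- length(xfit)
  S <- c(0, cumsum(xfit))
  Q <- c(0, cumsum(xfit * xfit))

  ii <- seq_len(n)
  D <- .jenks_cost(S, Q, rep(1L, n), ii)      # one class
  Jlayers <- vector("list", k)
  if (k > 1L) {
    env <- new.env(parent = emptyenv())
    for (m in 2:k) {
      env$D <- rep(NA_real_, n); env$J <- rep(NA_integer_, n)
      .jenks_layer(D, S, Q, m, n, env)
      D <- env$D; Jlayers[[m]] <- env$J
    }
  }
  # reconstruct class start indices
  starts <- integer(k)
  i <- n
  if (k > 1L) {
    for (m in k:2) {
      starts[m] <- Jlayers[[m]][i]
      i <- starts[m] - 1L
    }
  }
  starts[1] <- 1L
  breaks <- if (k > 1L) xfit[starts[2:k] - 1L] else numeric(0)

  assign_cls <- function(v) {
    cls <- rep(1L, length(v))
    for (b in breaks) cls <- cls + as.integer(v > b)
    cls
  }
  assignments <- rep(NA_integer_, length(xin))
  assignments[!is.na(xin)] <- assign_cls(x)
  sdam <- sum((x - mean(x))^2)
  sdcm <- sum(vapply(split(x, assign_cls(x)),
                     function(g) sum((g - mean(g))^2), 0))
  gvf <- if (sdam > 0) 1 - sdcm / sdam else 1
  if (k == 1L) gvf <- 0
  structure(list(breaks = breaks, assignments = assignments,
                 gvf = gvf, sdcm = sdcm, sdam = sdam, k = k),
            class = "jenks_result")
}

#' @export
print.jenks_result <- function(x, ...) {
  cat(sprintf("<jenks_result> k = %d  GVF = %.4f\n", x$k, x$gvf))
  if (length(x$breaks))
    cat("  breaks:", paste(signif(x$breaks, 6), collapse = ", "), "\n")
  cat("  class sizes:", paste(table(x$assignments), collapse = ", "), "\n")
  invisible(x)
}
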