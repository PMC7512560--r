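#' Validate a univariate signal
#'
#' All estimators in the package operate on plain numeric vectors. A valid
#' signal is finite everywhere (no NA/NaN/Inf) and non-empty.
#'
#' @param x numeric vector.
#' @param n_min minimum admissible length.
#' @param arg name used in error messages.
#' @return the signal, invisibly, as a plain double vector.
#' @keywords internal
check_signal <- function(x, n_min = 1L, arg = "x") {
  if (!is.numeric(x) || length(x) < n_min) {
    stop(sprintf("`%s` must be a numeric vector of length >= %d (got length %d)",
                 arg, n_min, length(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values (NA/NaN/Inf are not allowed)", arg),
         call. = FALSE)
  }
  as.double(x)
}

#' Delay-1 phase-space embedding
#'
#' Slices a signal of length `N` into its `N - m + 1` overlapping templates
#' (state vectors) of length `m`, the delay-1 reconstructed phase space on
#' which all four entropy estimators operate. Template `i` is the half-open
#' window `x[i], ..., x[i + m - 1]`; consecutive templates overlap in `m - 1`
#' samples.
#'
#' @param x numeric signal of length at least `m + 1`.
#' @param m embedding dimension (template length), integer >= 1.
#' @return a numeric matrix with `N - m + 1` rows (templates) and `m` columns,
#'   with attribute `m` set; row `i` holds the template starting at sample `i`.
#' @examples
#' embed_templates(c(1, 2, 3, 4), m = 2)
#' @export
embed_templates <- function(x, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be an integer >= 1", call. = FALSE)
  x <- check_signal(x)
  N <- length(x)
  if (N < m + 1L) {
    stop(sprintf("signal too short for embedding: N = %d but m = %d requires N >= m + 1",
                 N, m), call. = FALSE)
  }
  nt <- N - m + 1L
  tmpl <- vapply(seq_len(m), function(k) x[k:(nt + k - 1L)], numeric(nt))
  tmpl <- matrix(tmpl, nrow = nt, ncol = m)
  attr(tmpl, "m") <- m
  attr(tmpl, "source_length") <- N
  tmpl
}

#' Chebyshev distance between two templates
#'
#' The maximum absolute element-wise difference, the classical template
#' distance of approximate and sample entropy.
#'
#' @param a,b numeric vectors of equal length.
#' @return a non-negative scalar.
#' @examples
#' chebyshev_distance(c(0, 0), c(1, 3)) # 3
#' @export
chebyshev_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("template length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  max(abs(a - b))
}

#' Normalised range distance between two templates
#'
#' The stretch-sensitive distance at the heart of range entropy:
#' \deqn{d = \frac{\max_k |a_k - b_k| - \min_k |a_k - b_k|}
#'            {\max_k |a_k - b_k| + \min_k |a_k - b_k|}.}
#' It lies in \[0, 1\] whenever defined, is symmetric, and is exactly
#' invariant to a common additive offset of both templates and to joint
#' rescaling by any nonzero scalar. For element-wise identical templates the
#' denominator vanishes and the distance is undefined; this is returned as
#' `NA` and must never be silently treated as 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return a scalar in \[0, 1\], or `NA` when `a` and `b` are identical.
#' @examples
#' range_distance(c(0, 0), c(1, 3)) # (3 - 1) / (3 + 1) = 0.5
#' range_distance(c(0, 0), c(2, 2)) # 0
#' range_distance(c(1, 2), c(1, 2)) # NA: undefined for equal templates
#' @export
range_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("template length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  d <- abs(a - b)
  hi <- max(d)
  lo <- min(d)
  den <- hi + lo
  if (den == 0) return(NA_real_)
  (hi - lo) / den
}

#' Per-template match counts
#'
#' For each template `i` in a template set, counts the templates `j` whose
#' distance to `i` is within tolerance `r` (inclusive, Heaviside convention).
#' Two counting modes mirror the two entropy families: `include_self` (the
#' approximate-entropy convention, `j` ranges over all templates) and
#' `exclude_self` (the sample-entropy convention, `j != i`). Under the range
#' distance the self-pair is undefined, so it is never a match even in
#' `include_self` mode; undefined pairs (identical templates) count as
#' non-matches and are tallied in `n_excluded_pairs`.
#'
#' @param templates template matrix from [embed_templates()].
#' @param r tolerance, `>= 0`.
#' @param distance `"chebyshev"` or `"range"`.
#' @param mode `"include_self"` or `"exclude_self"`.
#' @return an integer vector of counts with attribute `n_excluded_pairs`
#'   (undefined off-diagonal pairs counted as non-matches).
#' @export
match_counts <- function(templates, r,
                         distance = c("chebyshev", "range"),
                         mode = c("include_self", "exclude_self")) {
  distance <- match.arg(distance)
  mode <- match.arg(mode)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop("`r` must be a single non-negative number", call. = FALSE)
  }
  if (!is.matrix(templates)) templates <- matrix(templates, ncol = 1L)
  D <- pairwise_distance_matrix(templates, distance)
  undef <- is.na(D)
  hit <- !undef & D <= r
  if (mode == "exclude_self") diag(hit) <- FALSE
  counts <- as.integer(rowSums(hit))
  # undefined off-diagonal pairs only: the self-pair is undefined by
  # construction under the range distance and is not an exclusion
  attr(counts, "n_excluded_pairs") <- sum(undef) - sum(diag(undef))
  attr(counts, "mode") <- mode
  attr(counts, "distance") <- distance
  counts
}

# Full pairwise distance matrix for a template set (small-n reference path;
# the estimators use the running-extrema engine in entropy.R instead).
pairwise_distance_matrix <- function(templates, distance = c("chebyshev", "range")) {
  distance <- match.arg(distance)
  m <- ncol(templates)
  M <- mu <- NULL
  for (k in seq_len(m)) {
    d <- abs(outer(templates[, k], templates[, k], "-"))
    if (is.null(M)) {
      M <- d
      mu <- d
    } else {
      M <- pmax(M, d)
      mu <- pmin(mu, d)
    }
  }
  if (distance == "chebyshev") return(M)
  den <- M + mu
  out <- (M - mu) / den
  out[den == 0] <- NA_real_
  out
}
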