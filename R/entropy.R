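#' @title Entropy estimators
#' @description Shared engine for ApEn, SampEn, RangeEnA and RangeEnB.
#' @details
#' All four estimators compare length-`m` templates against length-`m + 1`
#' templates in the delay-1 phase space. The engine materialises, once per
#' `(signal, m)`, the pairwise running maxima and minima of element-wise
#' absolute differences; both the Chebyshev distance (the max) and the range
#' distance ((max - min)/(max + min)) fall out of those two matrices, and a
#' whole tolerance grid can then be thresholded against them without
#' recomputing distances. Results are identical to independent per-point
#' evaluation because the counting arithmetic is the same.
#' @name entropy-engine
#' @keywords internal
NULL

# Pairwise extrema tables at dimensions m and m + 1.
# Returns nt x nt matrices at dimension m and t1 x t1 at m + 1, where
# nt = N - m + 1 and t1 = N - m. Range-distance matrices carry NA where the
# denominator vanishes (identical templates, including the diagonal).
distance_tables <- function(x, m, distances = c("chebyshev", "range")) {
  N <- length(x)
  nt <- N - m + 1L
  t1 <- N - m
  M <- mu <- NULL
  for (k in 0:(m - 1L)) {
    xs <- x[(1L + k):(nt + k)]
    d <- abs(outer(xs, xs, "-"))
    if (is.null(M)) {
      M <- d
      mu <- d
    } else {
      M <- pmax(M, d)
      mu <- pmin(mu, d)
    }
  }
  idx <- seq_len(t1)
  dm <- abs(outer(x[(m + 1L):N], x[(m + 1L):N], "-"))
  M1 <- pmax(M[idx, idx], dm)
  mu1 <- pmin(mu[idx, idx], dm)
  tab <- list(nt = nt, t1 = t1, m = m)
  if ("chebyshev" %in% distances) {
    tab$cheb_m <- M
    tab$cheb_m_sub <- M[idx, idx]
    tab$cheb_m1 <- M1
  }
  if ("range" %in% distances) {
    tab$range_m <- range_from_extrema(M, mu)
    tab$range_m_sub <- tab$range_m[idx, idx]
    tab$range_m1 <- range_from_extrema(M1, mu1)
  }
  tab
}

range_from_extrema <- function(M, mu) {
  den <- M + mu
  out <- (M - mu) / den
  out[den == 0] <- NA_real_
  out
}

# One estimator at one tolerance, from precomputed tables.
# Returns list(value, undefined, n_m, n_m1, n_excluded_pairs).
entropy_from_tables <- function(tab, measure, r) {
  t1 <- tab$t1
  nt <- tab$nt
  switch(measure,
    ApEn = {
      Ci <- rowSums(tab$cheb_m <= r) / nt
      Ci1 <- rowSums(tab$cheb_m1 <= r) / t1
      list(value = mean(log(Ci)) - mean(log(Ci1)), undefined = FALSE,
           n_m = nt, n_m1 = t1, n_excluded_pairs = 0L)
    },
    SampEn = {
      Bi <- rowSums(tab$cheb_m_sub <= r) - 1L
      Ai <- rowSums(tab$cheb_m1 <= r) - 1L
      B <- sum(Bi)
      A <- sum(Ai)
      if (A == 0 || B == 0) {
        list(value = NA_real_, undefined = TRUE, n_m = t1, n_m1 = t1,
             n_excluded_pairs = 0L)
      } else {
        # + 0 canonicalises the -0 that -log(1) produces when A == B
        list(value = -log(A / B) + 0, undefined = FALSE, n_m = t1, n_m1 = t1,
             n_excluded_pairs = 0L)
      }
    },
    RangeEnA = {
      # self-pair undefined -> never a match; probabilities normalised by the
      # number of admissible comparisons (t1 at dim m, t1 - 1 at dim m + 1) so
      # that the terminal-zero property at r >= 1 holds exactly
      Bi <- rowSums(tab$range_m <= r, na.rm = TRUE)
      Ai <- rowSums(tab$range_m1 <= r, na.rm = TRUE)
      nx <- count_excluded(tab$range_m, nt) + count_excluded(tab$range_m1, t1)
      if (any(Bi == 0) || any(Ai == 0)) {
        list(value = NA_real_, undefined = TRUE, n_m = nt, n_m1 = t1,
             n_excluded_pairs = nx)
      } else {
        val <- mean(log(Bi / t1)) - mean(log(Ai / (t1 - 1L)))
        list(value = val, undefined = FALSE, n_m = nt, n_m1 = t1,
             n_excluded_pairs = nx)
      }
    },
    RangeEnB = {
      Bi <- rowSums(tab$range_m_sub <= r, na.rm = TRUE)
      Ai <- rowSums(tab$range_m1 <= r, na.rm = TRUE)
      nx <- count_excluded(tab$range_m_sub, t1) + count_excluded(tab$range_m1, t1)
      B <- sum(Bi)
      A <- sum(Ai)
      if (A == 0 || B == 0) {
        list(value = NA_real_, undefined = TRUE, n_m = t1, n_m1 = t1,
             n_excluded_pairs = nx)
      } else {
        # + 0 canonicalises the -0 that -log(1) produces when A == B
        list(value = -log(A / B) + 0, undefined = FALSE, n_m = t1, n_m1 = t1,
             n_excluded_pairs = nx)
      }
    },
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
  )
}

# off-diagonal undefined pairs (duplicate templates); the diagonal is
# undefined by construction and not an exclusion
count_excluded <- function(D, n_diag) {
  sum(is.na(D)) - n_diag
}

prepare_signal <- function(x, m, sd_correction) {
  x <- check_signal(x)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be an integer >= 1", call. = FALSE)
  if (length(x) < m + 2L) {
    stop(sprintf(
      "signal too short: N = %d but templates are needed at dimensions %d and %d (N >= m + 2)",
      length(x), m, m + 1L), call. = FALSE)
  }
  if (sd_correction) {
    s <- pop_sd(x)
    if (s == 0) {
      stop("sd_correction requested but the signal has zero standard deviation",
           call. = FALSE)
    }
    x <- x / s
  }
  x
}

# population standard deviation (denominator N)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

new_entropy_value <- function(measure, res, m, r, sd_correction) {
  structure(
    list(measure = measure, value = res$value, undefined = res$undefined,
         m = m, r = r, sd_correction = sd_correction,
         n_templates_m = res$n_m, n_templates_m1 = res$n_m1,
         n_excluded_pairs = res$n_excluded_pairs),
    class = "entropy_value")
}

#' @export
print.entropy_value <- function(x, ...) {
  val <- if (x$undefined) "undefined" else format(x$value, digits = 6)
  cat(sprintf("%s(m = %d, r = %g%s) = %s\n", x$measure, x$m, x$r,
              if (isTRUE(x$sd_correction)) ", SD-corrected" else "", val))
  if (x$n_excluded_pairs > 0) {
    cat(sprintf("  (%d duplicate template pair(s) excluded)\n", x$n_excluded_pairs))
  }
  invisible(x)
}

#' @export
as.double.entropy_value <- function(x, ...) {
  if (x$undefined) NA_real_ else x$value
}

entropy_single <- function(x, m, r, measure, sd_correction = FALSE) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop("`r` must be a single non-negative number", call. = FALSE)
  }
  x <- prepare_signal(x, m, sd_correction)
  dist <- if (measure %in% c("ApEn", "SampEn")) "chebyshev" else "range"
  tab <- distance_tables(x, as.integer(m), dist)
  res <- entropy_from_tables(tab, measure, r)
  new_entropy_value(measure, res, as.integer(m), r, sd_correction)
}

#' Approximate entropy
#'
#' The mean negative log conditional probability that templates matching
#' within Chebyshev tolerance `r` at embedding dimension `m` still match at
#' dimension `m + 1`, with self-matching allowed. Self-matching guarantees a
#' defined value on every finite signal, at the price of a bias toward
#' regularity for short signals.
#'
#' @param x numeric signal, length at least `m + 2`.
#' @param m embedding dimension (default 2, the conventional choice).
#' @param r tolerance (default 0.2). With `sd_correction = TRUE` the signal is
#'   first divided by its population standard deviation, equivalent to the
#'   common "r times SD" tolerance correction.
#' @param sd_correction divide the signal by its standard deviation first?
#' @return an `entropy_value` object; use `as.double()` to extract the number.
#' @seealso [sampen()], [rangeen_a()], [rangeen_b()], [entropy_profile()]
#' @examples
#' x <- gen_noise(200, "white", seed = 1)
#' apen(x, m = 2, r = 0.2)
#' @export
apen <- function(x, m = 2, r = 0.2, sd_correction = FALSE) {
  entropy_single(x, m, r, "ApEn", sd_correction)
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` and `A` aggregate, over templates `i = 1..N-m`, the
#' numbers of Chebyshev matches at dimensions `m` and `m + 1` with the
#' self-pair excluded. Undefined (returned as such, never as 0) when either
#' aggregate count is zero. Always non-negative when defined, because
#' extending templates can only lose matches.
#'
#' @inheritParams apen
#' @return an `entropy_value` object.
#' @examples
#' x <- gen_noise(200, "white", seed = 1)
#' sampen(x, m = 2, r = 0.2)
#' @export
sampen <- function(x, m = 2, r = 0.2, sd_correction = FALSE) {
  entropy_single(x, m, r, "SampEn", sd_correction)
}

#' Range entropy A (ApEn-style)
#'
#' Approximate entropy with the Chebyshev distance replaced by the normalised
#' range distance of [range_distance()]. Because that distance is bounded in
#' \[0, 1\], the tolerance axis is bounded too: on a signal without duplicate
#' templates the estimate is exactly 0 for every `r >= 1`. The self-pair has
#' an undefined distance and is not a match, so per-template probabilities are
#' normalised by the number of admissible comparisons and a template with no
#' match at all makes the whole estimate undefined - at small `r` this happens
#' more often than for any of the other three measures. The range distance is
#' self-normalising, so no SD correction is ever applied.
#'
#' @inheritParams apen
#' @return an `entropy_value` object.
#' @examples
#' x <- gen_noise(200, "white", seed = 1)
#' rangeen_a(x, m = 2, r = 0.5)
#' as.double(rangeen_a(x, m = 2, r = 1)) # exactly 0
#' @export
rangeen_a <- function(x, m = 2, r = 0.2) {
  entropy_single(x, m, r, "RangeEnA", sd_correction = FALSE)
}

#' Range entropy B (SampEn-style)
#'
#' Sample entropy with the Chebyshev distance replaced by the normalised range
#' distance. Defined values are non-negative, exactly invariant to global
#' rescaling and offset of the input, and exactly 0 at `r >= 1` on
#' duplicate-free signals. Undefined when either aggregated match count is
#' zero. No SD correction is ever applied.
#'
#' @inheritParams apen
#' @return an `entropy_value` object.
#' @examples
#' x <- gen_noise(200, "white", seed = 1)
#' rangeen_b(x, m = 2, r = 0.5)
#' identical(as.double(rangeen_b(5 * x)), as.double(rangeen_b(x)))
#' @export
rangeen_b <- function(x, m = 2, r = 0.2) {
  entropy_single(x, m, r, "RangeEnB", sd_correction = FALSE)
}

#' All four entropy measures at once
#'
#' Convenience wrapper computing any subset of `ApEn`, `SampEn`, `RangeEnA`
#' and `RangeEnB` at a single `(m, r)`, sharing the pairwise-distance work.
#'
#' @inheritParams apen
#' @param measures character vector of measures to compute.
#' @return a data frame with one row per measure: `measure`, `value`
#'   (`NA` when undefined), `undefined`, `m`, `r`, `sd_correction`,
#'   `n_excluded_pairs`.
#' @export
entropy_all <- function(x, m = 2, r = 0.2,
                        measures = c("ApEn", "SampEn", "RangeEnA", "RangeEnB"),
                        sd_correction = FALSE) {
  measures <- match.arg(measures, several.ok = TRUE)
  rows <- lapply(measures, function(msr) {
    ev <- if (msr %in% c("ApEn", "SampEn")) {
      entropy_single(x, m, r, msr, sd_correction)
    } else {
      entropy_single(x, m, r, msr, FALSE)
    }
    data.frame(measure = msr, value = if (ev$undefined) NA_real_ else ev$value,
               undefined = ev$undefined, m = ev$m, r = ev$r,
               sd_correction = ev$sd_correction,
               n_excluded_pairs = ev$n_excluded_pairs)
  })
  do.call(rbind, rows)
}
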