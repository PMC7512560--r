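#' Entropy profile over a tolerance or embedding-dimension grid
#'
#' Sweeps one entropy measure across a grid of tolerances `r` (holding `m`
#' fixed) or embedding dimensions `m` (holding `r` fixed), preserving
#' undefined estimates as `NA` rows rather than dropping or zeroing them.
#' For an `r`-sweep the pairwise distances are computed once per
#' `(signal, m)` and thresholded across the whole grid; this is arithmetic
#' identical to evaluating each grid point independently.
#'
#' Defaults follow the common protocol for these measures: `r` from 0.01 to 1
#' in steps of 0.01 at `m = 2`, and `m` from 2 to 10 at `r = 0.2`.
#'
#' @inheritParams apen
#' @param measure one of `"ApEn"`, `"SampEn"`, `"RangeEnA"`, `"RangeEnB"`.
#' @param sweep `"r"` or `"m"`.
#' @param grid strictly increasing numeric grid for the swept parameter;
#'   defaults to `seq(0.01, 1, 0.01)` for `r`-sweeps and `2:10` for `m`-sweeps.
#' @param sd_correction applied to `ApEn`/`SampEn` only; the range-entropy
#'   measures are amplitude-invariant by construction and never corrected.
#' @return a data frame of class `entropy_profile` with columns `measure`,
#'   `sweep`, `grid`, `value` (`NA` where undefined), `undefined`, `m`, `r`,
#'   `n_excluded_pairs`.
#' @examples
#' x <- gen_noise(300, "white", seed = 7)
#' p <- entropy_profile(x, "RangeEnB", sweep = "r", grid = seq(0.1, 1, 0.1))
#' p$value[p$grid == 1] # exactly 0
#' @export
entropy_profile <- function(x, measure = c("RangeEnB", "RangeEnA", "ApEn", "SampEn"),
                            sweep = c("r", "m"), grid = NULL,
                            m = 2, r = 0.2, sd_correction = FALSE) {
  measure <- match.arg(measure)
  sweep <- match.arg(sweep)
  if (is.null(grid)) {
    grid <- if (sweep == "r") seq(0.01, 1, by = 0.01) else 2:10
  }
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be non-empty and strictly increasing", call. = FALSE)
  }
  use_sd <- sd_correction && measure %in% c("ApEn", "SampEn")
  dist <- if (measure %in% c("ApEn", "SampEn")) "chebyshev" else "range"

  if (sweep == "r") {
    xs <- prepare_signal(x, m, use_sd)
    tab <- distance_tables(xs, as.integer(m), dist)
    res <- lapply(grid, function(ri) entropy_from_tables(tab, measure, ri))
    mm <- rep(as.integer(m), length(grid))
    rr <- grid
  } else {
    if (any(grid < 1) || any(grid != floor(grid))) {
      stop("an m-sweep grid must consist of integers >= 1", call. = FALSE)
    }
    res <- lapply(grid, function(mi) {
      xs <- prepare_signal(x, mi, use_sd)
      tab <- distance_tables(xs, as.integer(mi), dist)
      entropy_from_tables(tab, measure, r)
    })
    mm <- as.integer(grid)
    rr <- rep(r, length(grid))
  }

  out <- data.frame(
    measure = measure,
    sweep = sweep,
    grid = as.double(grid),
    value = vapply(res, function(z) if (z$undefined) NA_real_ else z$value, 0),
    undefined = vapply(res, function(z) z$undefined, TRUE),
    m = mm,
    r = rr,
    n_excluded_pairs = vapply(res, function(z) as.integer(z$n_excluded_pairs), 0L)
  )
  attr(out, "sd_correction") <- use_sd
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Fit an r-exponent or m-exponent to an entropy profile
#'
#' Ordinary least-squares slope of the entropy values against the natural log
#' of the swept parameter. Following the exclusion rule used when relating
#' these exponents to the Hurst exponent, a profile containing any undefined
#' grid point is not fitted at all (`skipped = TRUE`); so is a profile with
#' fewer than two points.
#'
#' @param profile an `entropy_profile` from [entropy_profile()].
#' @return a list of class `exponent_fit`: `slope` (the r- or m-exponent),
#'   `intercept`, `n_points`, `skipped`, `measure`, `sweep`.
#' @examples
#' x <- gen_noise(300, "white", seed = 7)
#' p <- entropy_profile(x, "RangeEnB", grid = seq(0.2, 1, 0.2))
#' fit_exponent(p)
#' @export
fit_exponent <- function(profile) {
  if (!inherits(profile, "entropy_profile")) {
    stop("`profile` must be an entropy_profile", call. = FALSE)
  }
  skipped <- any(profile$undefined) || nrow(profile) < 2L
  if (skipped) {
    fit <- list(slope = NA_real_, intercept = NA_real_,
                n_points = sum(!profile$undefined), skipped = TRUE)
  } else {
    co <- stats::coef(stats::lm(value ~ log(grid), data = profile))
    fit <- list(slope = unname(co[2L]), intercept = unname(co[1L]),
                n_points = nrow(profile), skipped = FALSE)
  }
  fit$measure <- profile$measure[1L]
  fit$sweep <- profile$sweep[1L]
  class(fit) <- "exponent_fit"
  fit
}

#' @export
print.exponent_fit <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("%s %s-exponent: skipped (undefined grid points or too few points; %d defined)\n",
                x$measure, x$sweep, x$n_points))
  } else {
    cat(sprintf("%s %s-exponent: slope = %.6g (intercept %.6g, %d points)\n",
                x$measure, x$sweep, x$slope, x$intercept, x$n_points))
  }
  invisible(x)
}

#' @export
plot.entropy_profile <- function(x, ...) {
  log_axis <- if (x$sweep[1L] == "r") "x" else ""
  graphics::plot(x$grid, x$value, type = "b", log = log_axis,
                 xlab = x$sweep[1L], ylab = paste(x$measure[1L], "(nats)"), ...)
  invisible(x)
}
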