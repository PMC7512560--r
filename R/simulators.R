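#' @title Seeded simulators for the validation processes
#' @description White/pink/brown noise, fractional Brownian motion (exact
#'   Cholesky method), fractional Levy motion, and piecewise amplitude gains.
#'   Every generator is bit-reproducible given its parameters and `seed`.
#' @name simulators
NULL

run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Coloured-noise generator
#'
#' `white` draws iid standard Gaussian samples. `pink` (power spectral density
#' proportional to 1/f) and `brown` (1/f^2) are produced by spectral shaping:
#' a white draw is Fourier-transformed, each bin's amplitude is multiplied by
#' `f^(-beta/2)` (`beta` = 1 for pink, 2 for brown) with the zero-frequency
#' bin set to 0, and the inverse transform is standardised to zero mean and
#' unit (population) variance. Shaping is exact in expectation, so the
#' log-log periodogram slope is `-beta`.
#'
#' @param n signal length, at least 8.
#' @param kind `"white"`, `"pink"` or `"brown"`.
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return a numeric vector of length `n`.
#' @examples
#' w <- gen_noise(1000, "white", seed = 42)
#' @export
gen_noise <- function(n, kind = c("white", "pink", "brown"), seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 8L) stop("`n` must be an integer >= 8", call. = FALSE)
  run_seeded(seed, {
    w <- stats::rnorm(n)
    if (kind == "white") {
      w
    } else {
      beta <- if (kind == "pink") 1 else 2
      # symmetric frequency index: bin j (0-based) has frequency min(j, n - j)
      j <- 0:(n - 1L)
      f <- pmin(j, n - j)
      amp <- c(0, f[-1L]^(-beta / 2))
      shaped <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
      (shaped - mean(shaped)) / pop_sd(shaped)
    }
  })
}

#' Fractional Brownian motion (exact Cholesky method)
#'
#' Draws a zero-mean Gaussian vector on integer times `t = 1..n` with
#' covariance `D * (t^{2H} + s^{2H} - |t - s|^{2H}) / 2`, the fBm covariance
#' scaled by `D`. The path is implicitly anchored at `B(0) = 0`. The
#' covariance matrix is factorised once at `D = 1` and the draw is multiplied
#' by `sqrt(D)`, so paths with matched seeds and different `D` differ by an
#' exact scalar factor. The exact factorisation is `O(n^3)`, so `n` is capped
#' at 4096.
#'
#' @param n path length (`<= 4096`).
#' @param H Hurst exponent, strictly inside (0, 1).
#' @param D covariance scale, `> 0` (default 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric vector of length `n`, the path values at `t = 1..n`.
#' @examples
#' b <- gen_fbm(500, H = 0.8, seed = 3)
#' @export
gen_fbm <- function(n, H, D = 1, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (n > 4096L) {
    stop("`n` exceeds the 4096 cap for exact Cholesky fBm (O(n^3) factorisation)",
         call. = FALSE)
  }
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0 || H >= 1) {
    stop("`H` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D <= 0) {
    stop("`D` must be > 0", call. = FALSE)
  }
  t <- seq_len(n)
  h2 <- 2 * H
  Sigma <- 0.5 * (outer(t^h2, t^h2, "+") - abs(outer(t, t, "-"))^h2)
  R <- tryCatch(chol(Sigma), error = function(e) {
    stop(paste0("Cholesky factorisation of the fBm covariance failed (",
                conditionMessage(e),
                "); try a smaller n or add a small diagonal jitter"),
         call. = FALSE)
  })
  z <- run_seeded(seed, stats::rnorm(n))
  sqrt(D) * as.vector(crossprod(R, z))
}

#' Symmetric alpha-stable random numbers
#'
#' Chambers-Mallows-Stuck sampling of the symmetric alpha-stable law with
#' stability index `alpha` in (0, 2] and scale `scale`. `alpha = 1` is the
#' Cauchy law; `alpha = 2` is Gaussian with variance `2 * scale^2` (the stable
#' scale convention).
#'
#' @param n number of draws.
#' @param alpha stability index in (0, 2].
#' @param scale scale parameter, `> 0`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric vector of length `n`.
#' @export
rstable_sym <- function(n, alpha, scale = 1, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 2) {
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  }
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  run_seeded(seed, {
    U <- stats::runif(n, -pi / 2, pi / 2)
    if (alpha == 1) {
      scale * tan(U)
    } else {
      W <- stats::rexp(n)
      scale * (sin(alpha * U) / cos(U)^(1 / alpha)) *
        (cos((1 - alpha) * U) / W)^((1 - alpha) / alpha)
    }
  })
}

#' Fractional Levy motion
#'
#' Discretised moving-average construction of fractional Levy motion:
#' symmetric alpha-stable innovations (scale `C`) are convolved with the
#' memory kernel `a(k) = (k + 1)^d - k^d`, `k = 0..M-1`, `a(0) = 1`, where
#' `d = H - 1/alpha`, and the resulting increments are cumulated into a
#' motion. The kernel is proportional to the continuous-time moving-average
#' kernel; the implicit normalisation constant is immaterial for the
#' scale-invariant range-entropy measures and for SD-corrected ApEn/SampEn.
#' With `alpha = 2` the innovations are Gaussian and the output is a
#' (non-exact, moving-average) fractional Brownian motion; `d = 0` degenerates
#' to an ordinary alpha-stable Levy motion.
#'
#' @param n path length.
#' @param H Hurst exponent in (0, 1).
#' @param alpha stability index in (0, 2] (default 1, the Cauchy-driven case).
#' @param C innovation scale, `> 0`.
#' @param M kernel cutoff (memory horizon) in samples, default 600.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric vector of length `n`.
#' @examples
#' z <- gen_flm(1000, H = 0.3, alpha = 1, seed = 9)
#' @export
gen_flm <- function(n, H, alpha = 1, C = 1, M = 600L, seed = NULL) {
  n <- as.integer(n)
  M <- as.integer(M)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (is.na(M) || M < 1L) stop("`M` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0 || H >= 1) {
    stop("`H` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 2) {
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  }
  d <- H - 1 / alpha
  k <- seq_len(M) - 1L
  kern <- c(1, (k[-1L] + 1)^d - k[-1L]^d)
  innov <- rstable_sym(n + M - 1L, alpha = alpha, scale = C, seed = seed)
  inc <- stats::filter(innov, kern, method = "convolution", sides = 1)
  inc <- as.numeric(inc)[M:(M + n - 1L)]
  out <- cumsum(inc)
  attr(out, "spec") <- list(alpha = alpha, H = H, d = d, C = C, M = M, seed = seed)
  out
}

#' Piecewise-constant gain profile
#'
#' Describes a time-varying amplitude gain as consecutive blocks, each with a
#' positive multiplier. The default is the nonstationary test profile used to
#' probe amplitude robustness: five 200-sample blocks with gains
#' 1, 3, 10, 4, 1 (block boundaries after samples 200/400/600/800 of a
#' 1000-sample signal).
#'
#' @param gains positive multipliers, one per block.
#' @param lengths block lengths in samples, same length as `gains`.
#' @return a data frame of class `gain_profile` with columns `start`, `end`,
#'   `gain`.
#' @examples
#' gain_profile() # the default 5-block profile
#' gain_profile(gains = 5, lengths = 1000) # constant gain 5
#' @export
gain_profile <- function(gains = c(1, 3, 10, 4, 1), lengths = rep(200L, 5L)) {
  if (length(gains) != length(lengths) || length(gains) < 1L) {
    stop("`gains` and `lengths` must have equal positive length", call. = FALSE)
  }
  if (any(gains <= 0)) stop("all gains must be > 0", call. = FALSE)
  if (any(lengths < 1L) || any(lengths != floor(lengths))) {
    stop("all block lengths must be positive integers", call. = FALSE)
  }
  end <- cumsum(as.integer(lengths))
  start <- c(1L, utils::head(end, -1L) + 1L)
  structure(data.frame(start = start, end = end, gain = as.double(gains)),
            class = c("gain_profile", "data.frame"))
}

#' Apply a piecewise gain to a signal
#'
#' Element-wise multiplication by the block gains of a [gain_profile()]. The
#' profile must cover the whole signal (`sum(lengths) == length(x)`).
#'
#' @param x numeric signal.
#' @param profile a [gain_profile()]; the default reproduces the 1/3/10/4/1
#'   nonstationary test gain for a 1000-sample signal.
#' @return the scaled signal.
#' @examples
#' x1 <- gen_noise(1000, "white", seed = 1)
#' x3 <- apply_gain(x1, gain_profile())
#' @export
apply_gain <- function(x, profile = gain_profile()) {
  x <- check_signal(x)
  if (!inherits(profile, "gain_profile")) {
    stop("`profile` must be a gain_profile", call. = FALSE)
  }
  if (profile$end[nrow(profile)] != length(x)) {
    stop(sprintf("gain profile covers samples 1..%d but the signal has length %d",
                 profile$end[nrow(profile)], length(x)), call. = FALSE)
  }
  g <- rep(profile$gain, times = profile$end - profile$start + 1L)
  x * g
}
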