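#' Loess detrending
#'
#' Removes slow trends (long multigeneration fluctuations whose wavelength
#' approaches the series length) by local polynomial regression on the time
#' index with tricube weights, returning the fitted trend and the residual.
#' The residual is the input for wavelet analysis.
#'
#' @param y Numeric vector.
#' @param span Fraction of points in each local window (default 0.4).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @return A tibble of class `gc_loess` with columns `t`, `y`, `fitted`,
#'   `residual` (`fitted + residual == y` to numerical precision).
#' @export
loess_detrend <- function(y, span = 0.4, degree = 2) {
  n <- length(y)
  if (anyNA(y)) stop("loess_detrend input may not contain NA", call. = FALSE)
  if (n * span < degree + 1) {
    stop("span too small: window of ", floor(n * span),
         " points cannot fit a degree-", degree, " polynomial", call. = FALSE)
  }
  t <- seq_len(n)
  fit <- stats::loess(y ~ t, span = span, degree = degree,
                      family = "gaussian", surface = "direct")
  fitted <- as.numeric(stats::predict(fit, newdata = data.frame(t = t)))
  out <- tibble::tibble(t = t, y = y, fitted = fitted, residual = y - fitted)
  class(out) <- c("gc_loess", class(out))
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  out
}

morlet_fourier_factor <- function(omega0 = 6) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Morlet continuous wavelet transform
#'
#' Continuous wavelet transform with the Morlet mother wavelet
#' \eqn{\psi(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}},
#' \eqn{\omega_0 = 6}, computed in the frequency domain with zero padding.
#' Scales lie on a geometric grid with `dj` sub-octaves per octave, indexed
#' by Fourier period via `period = (4 pi / (omega0 + sqrt(2 + omega0^2))) *
#' scale` (about 1.033 scale for `omega0 = 6`). The cone of influence is the
#' e-folding time `sqrt(2) * scale` of the wavelet envelope, mapped to period
#' units: power at periods above the cone is contaminated by the series
#' edges.
#'
#' @param y Numeric vector (detrended and mean-centred), length at least 16.
#' @param dt Sampling interval in weeks (default 1).
#' @param dj Sub-octave resolution (default 1/20).
#' @param period_range Smallest and largest period analysed, in time units;
#'   default `c(2 * dt, floor(n/3) * dt)`.
#' @param omega0 Morlet angular frequency (default 6, the standard
#'   admissibility choice).
#' @param pad_factor Zero-pad to the next power of two at least `pad_factor`
#'   times the series length (default 4; generous padding keeps the circular
#'   FFT convolution equal to the linear one well below working precision).
#' @return Object of class `wavelet_spectrum`: list with `times`, `periods`,
#'   `scales`, `wave` (complex `n x n_periods` matrix), `power` (`|wave|^2`),
#'   `coi` (per-time maximum trustworthy period), `dt`, `dj`, `omega0`,
#'   `series_sd`.
#' @export
morlet_cwt <- function(y, dt = 1, dj = 1 / 20, period_range = NULL,
                       omega0 = 6, pad_factor = 4) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 16) stop("wavelet analysis needs a series of length >= 16", call. = FALSE)
  if (anyNA(y)) stop("morlet_cwt input may not contain NA", call. = FALSE)
  if (is.null(period_range)) period_range <- c(2 * dt, floor(n / 3) * dt)
  if (period_range[1] < 2 * dt || period_range[2] > n * dt) {
    stop("period_range must lie within [2*dt, n*dt]", call. = FALSE)
  }
  series_sd <- stats::sd(y)
  y <- y - mean(y)

  ff <- morlet_fourier_factor(omega0)
  n_oct <- log2(period_range[2] / period_range[1])
  periods <- period_range[1] * 2^(seq(0, n_oct, by = dj))
  scales <- periods / ff

  npad <- 2^ceiling(log2(pad_factor * n))
  ypad <- c(y, rep(0, npad - n))
  yhat <- stats::fft(ypad)
  # angular frequencies of the padded DFT grid
  k <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1))
  omega <- 2 * pi * k / (npad * dt)

  wave <- matrix(0 + 0i, nrow = n, ncol = length(scales))
  norm_const <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    # analytic Morlet daughter in frequency space (support on omega > 0)
    psi_hat <- norm_const * sqrt(2 * pi * s / dt) * (omega > 0) *
      exp(-((s * omega - omega0)^2) / 2)
    w <- stats::fft(yhat * psi_hat, inverse = TRUE) / npad
    wave[, j] <- w[seq_len(n)]
  }

  d <- pmax(pmin(seq_len(n) - 1, n - seq_len(n)), 1e-8)
  coi <- ff / sqrt(2) * dt * d

  structure(
    list(times = seq_len(n) * dt, periods = periods, scales = scales,
         wave = wave, power = Mod(wave)^2, coi = coi,
         dt = dt, dj = dj, omega0 = omega0, series_sd = series_sd,
         signif_mask = NULL, alpha = NULL),
    class = "wavelet_spectrum"
  )
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat("Morlet wavelet spectrum:", length(x$times), "times x",
      length(x$periods), "periods (", signif(min(x$periods), 3), "-",
      signif(max(x$periods), 3), "weeks ), omega0 =", x$omega0, "\n")
  if (!is.null(x$signif_mask)) {
    cat("  significance mask at alpha =", x$alpha, ":",
        sum(x$signif_mask), "significant pixels\n")
  }
  invisible(x)
}

#' Pointwise white-noise significance for a wavelet spectrum
#'
#' Simulates `nsim` Gaussian white-noise series with the standard deviation
#' of the analysed series, transforms each with the same wavelet settings,
#' and marks a pixel significant when its power exceeds the empirical
#' `1 - alpha` quantile of the surrogate power at that pixel.
#'
#' @param ws A `wavelet_spectrum` from [morlet_cwt()].
#' @param nsim Number of surrogate series (default 100; use 1000 or more for
#'   final figures).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed.
#' @return `ws` with `signif_mask` (logical matrix) and `alpha` filled in.
#' @export
wavelet_significance <- function(ws, nsim = 100, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(ws, "wavelet_spectrum"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (nsim < 20) warning("nsim < 20: surrogate quantile will be unstable")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ws$times)
  pr <- range(ws$periods)
  sims <- array(0, dim = c(nsim, n, length(ws$periods)))
  for (i in seq_len(nsim)) {
    z <- stats::rnorm(n, sd = ws$series_sd)
    sims[i, , ] <- morlet_cwt(z, dt = ws$dt, dj = ws$dj, period_range = pr,
                              omega0 = ws$omega0)$power
  }
  thr <- apply(sims, c(2, 3), stats::quantile, probs = 1 - alpha, names = FALSE)
  ws$signif_mask <- ws$power > thr
  ws$alpha <- alpha
  ws
}

# logical matrix: TRUE where the pixel's period is inside the cone of influence
coi_mask <- function(ws) {
  outer(ws$coi, ws$periods, FUN = ">=")
}

#' Summarise the significant ridge of a wavelet spectrum
#'
#' For each time point inside the cone of influence, reports the in-band
#' period with maximal significant power (NA when none is significant), and
#' the fraction of in-cone time points carrying a significant in-band period
#' (the "ridge coverage": a sustained generation cycle shows up as coverage
#' close to 1).
#'
#' @param ws A `wavelet_spectrum` with a significance mask.
#' @param band Period band in weeks (default `c(5, 7)`).
#' @return List of class `ridge_summary`: `ridge` (tibble `time`,
#'   `dominant_period`, `in_coi`), `coverage` (scalar in `[0, 1]`), `band`.
#' @export
summarize_ridge <- function(ws, band = c(5, 7)) {
  stopifnot(inherits(ws, "wavelet_spectrum"))
  if (is.null(ws$signif_mask)) {
    stop("run wavelet_significance() before summarising the ridge", call. = FALSE)
  }
  band <- sort(band)
  in_band <- ws$periods >= band[1] & ws$periods <= band[2]
  if (!any(in_band)) stop("no period grid points in band", call. = FALSE)
  in_coi_t <- ws$coi >= band[2]
  dom <- rep(NA_real_, length(ws$times))
  for (i in seq_along(ws$times)) {
    sig <- in_band & ws$signif_mask[i, ]
    if (any(sig)) {
      pw <- ws$power[i, ]
      pw[!sig] <- -Inf
      dom[i] <- ws$periods[which.max(pw)]
    }
  }
  coverage <- if (any(in_coi_t)) mean(!is.na(dom[in_coi_t])) else NA_real_
  structure(list(
    ridge = tibble::tibble(time = ws$times, dominant_period = dom,
                           in_coi = in_coi_t),
    coverage = coverage, band = band
  ), class = "ridge_summary")
}

#' @export
print.ridge_summary <- function(x, ...) {
  cat("Ridge summary, band [", x$band[1], ",", x$band[2], "] weeks: ",
      "coverage ", signif(x$coverage, 3), " of in-cone time points\n", sep = "")
  invisible(x)
}

#' Full wavelet analysis of a count series
#'
#' Square-root transforms the counts, removes slow trends by loess, computes
#' the Morlet wavelet spectrum and its pointwise white-noise significance
#' mask.
#'
#' @param x Non-negative count vector (already truncated).
#' @param span,degree Loess settings, see [loess_detrend()].
#' @param sqrt_first Apply the square-root transform before detrending
#'   (default `TRUE`, matching the variance stabilisation used in the
#'   spectral path)? `FALSE` detrends the raw counts instead.
#' @param dj,period_range,omega0 Wavelet settings, see [morlet_cwt()].
#' @param nsim,alpha,seed Significance settings, see
#'   [wavelet_significance()].
#' @return A `wavelet_spectrum` with significance mask; the detrending fit is
#'   attached as attribute `loess`.
#' @export
wavelet_analysis <- function(x, span = 0.4, degree = 2, sqrt_first = TRUE,
                             dj = 1 / 20, period_range = NULL, omega0 = 6,
                             nsim = 100, alpha = 0.05, seed = NULL) {
  y <- if (sqrt_first) sqrt_transform(x) else as.numeric(x)
  lf <- loess_detrend(y, span = span, degree = degree)
  ws <- morlet_cwt(lf$residual, dj = dj, period_range = period_range,
                   omega0 = omega0)
  ws <- wavelet_significance(ws, nsim = nsim, alpha = alpha, seed = seed)
  attr(ws, "loess") <- lf
  ws
}

#' Heat-map plot of a wavelet spectrum
#'
#' @param object A `wavelet_spectrum`.
#' @param ... Ignored.
#' @return A ggplot: power heat map with the cone of influence shaded and
#'   significance contours when a mask is present.
#' @method autoplot wavelet_spectrum
#' @export
autoplot.wavelet_spectrum <- function(object, ...) {
  df <- tidy.wavelet_spectrum(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$power)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::geom_line(
      data = tibble::tibble(time = object$times,
                            period = pmin(object$coi, max(object$periods))),
      colour = "white", linetype = "dashed"
    ) +
    ggplot2::labs(x = "time (weeks)", y = "period (weeks)", fill = "power")
  if (!is.null(object$signif_mask)) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$significant)),
                                   breaks = 0.5, colour = "black")
  }
  p
}

#' Tidy a wavelet spectrum into a pixel tibble
#'
#' @param x A `wavelet_spectrum`.
#' @param ... Ignored.
#' @return Tibble with one row per (time, period) pixel: `time`, `period`,
#'   `power`, `in_coi`, and `significant` when a mask is present.
#' @method tidy wavelet_spectrum
#' @export
tidy.wavelet_spectrum <- function(x, ...) {
  grid <- expand.grid(time = x$times, period = x$periods)
  out <- tibble::tibble(
    time = grid$time, period = grid$period,
    power = as.vector(x$power),
    in_coi = as.vector(coi_mask(x))
  )
  if (!is.null(x$signif_mask)) out$significant <- as.vector(x$signif_mask)
  out
}

#' One-line summary of a wavelet spectrum
#'
#' @param x A `wavelet_spectrum`.
#' @param ... Ignored.
#' @return One-row tibble: grid dimensions, fraction of in-cone pixels
#'   significant (NA without a mask), and the period maximising time-averaged
#'   in-cone power.
#' @method glance wavelet_spectrum
#' @export
glance.wavelet_spectrum <- function(x, ...) {
  cm <- coi_mask(x)
  avg <- colSums(x$power * cm) / pmax(colSums(cm), 1)
  tibble::tibble(
    n_times = length(x$times),
    n_periods = length(x$periods),
    dominant_period = x$periods[which.max(avg)],
    frac_significant = if (is.null(x$signif_mask)) NA_real_ else
      mean(x$signif_mask[cm]),
    alpha = if (is.null(x$alpha)) NA_real_ else x$alpha
  )
}
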