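#' Square-root transform of count data
#'
#' Counts from overdispersed censuses have variance growing with the mean;
#' the square root is the conventional variance-stabilising transform applied
#' before spectral analysis so that errors are closer to homoscedastic.
#'
#' @param x Non-negative numeric vector.
#' @return `sqrt(x)`.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  sqrt(x)
}

#' Raw periodogram
#'
#' Mean-centres `y` and computes the raw (untapered, unpadded, unsmoothed)
#' periodogram \eqn{I(f_j) = |\sum_t y_t e^{-2\pi i f_j t}|^2 / n} on the
#' Fourier grid \eqn{f_j = j/n}, \eqn{j = 1..\lfloor n/2 \rfloor}. The zero
#' frequency is excluded (the mean is removed); the Nyquist ordinate is
#' included only for even `n`. With this scaling a unit-amplitude cosine at a
#' Fourier frequency yields an ordinate of `n/4`, and the ordinates sum to
#' approximately `n * var(y) / 2`.
#'
#' @param y Numeric vector, length at least 8.
#' @param taper Split-cosine taper proportion passed to the data before
#'   transforming (default 0, i.e. no taper). Provided for parity experiments
#'   with tapered spectral estimates; the Monte-Carlo null in
#'   [mc_threshold()] applies the same taper, so significance logic is
#'   unaffected.
#' @return A tibble of class `gc_periodogram` with columns `frequency`
#'   (cycles/week), `period` (weeks) and `density`, plus attributes `n` and
#'   `taper`.
#' @export
periodogram <- function(y, taper = 0) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 8) stop("periodogram needs a series of length >= 8", call. = FALSE)
  if (anyNA(y)) stop("periodogram input may not contain NA", call. = FALSE)
  y <- y - mean(y)
  if (taper > 0) y <- spec_taper_vec(y, taper)
  j <- seq_len(n %/% 2)
  dens <- Mod(stats::fft(y)[j + 1])^2 / n
  out <- tibble::tibble(frequency = j / n, period = n / j, density = dens)
  class(out) <- c("gc_periodogram", class(out))
  attr(out, "n") <- n
  attr(out, "taper") <- taper
  out
}

# split-cosine-bell taper on a mean-centred series (p = total proportion tapered)
spec_taper_vec <- function(y, p) {
  n <- length(y)
  m <- floor(n * p / 2)
  if (m == 0) return(y)
  w <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
  y * c(w, rep(1, n - 2 * m), rev(w))
}

#' Fit a negative-binomial white-noise null by moments
#'
#' Matches a negative-binomial distribution to a count series by the method
#' of moments: mean `m` = sample mean, shape `k = m^2 / (s^2 - m)` with `s^2`
#' the n-1 sample variance (so variance = m + m^2/k). Underdispersed samples
#' (`s^2 <= m`) fall back to the Poisson limit (`k = Inf`), in which case
#' surrogate draws are Poisson.
#'
#' @param x Non-negative count vector with positive mean.
#' @return List of class `nb_null` with elements `mean`, `k`, `poisson`
#'   (logical), `n`.
#' @export
fit_nb_moments <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("NB null needs a positive mean", call. = FALSE)
  s2 <- stats::var(x)
  poisson <- s2 <= m
  k <- if (poisson) Inf else m^2 / (s2 - m)
  structure(list(mean = m, k = k, poisson = poisson, n = length(x)),
            class = "nb_null")
}

#' @export
print.nb_null <- function(x, ...) {
  cat("Negative-binomial white-noise null: mean =", signif(x$mean, 4),
      if (x$poisson) "(Poisson limit)" else paste("shape k =", signif(x$k, 4)),
      "n =", x$n, "\n")
  invisible(x)
}

# draw `reps` surrogate white-noise series as an n x reps matrix
draw_null_matrix <- function(null, reps) {
  n <- null$n
  if (isTRUE(null$poisson)) {
    matrix(stats::rpois(n * reps, lambda = null$mean), nrow = n)
  } else {
    matrix(stats::rnbinom(n * reps, mu = null$mean, size = null$k), nrow = n)
  }
}

# periodograms of the columns of a matrix, sharing the sqrt -> centre ->
# periodogram path with the data route (single code path for data and null)
periodogram_matrix <- function(m, taper = 0) {
  n <- nrow(m)
  y <- sqrt_transform(m)
  y <- sweep(y, 2, colMeans(y))
  if (taper > 0) y <- apply(y, 2, spec_taper_vec, p = taper)
  j <- seq_len(n %/% 2)
  Mod(stats::mvfft(y)[j + 1, , drop = FALSE])^2 / n
}

#' Monte-Carlo significance threshold from a white-noise null
#'
#' Simulates `reps` independent white-noise count series from the fitted
#' null, passes each through the identical square-root / mean-centre /
#' periodogram path used for the data, and returns the empirical `q` quantile
#' of the surrogate spectral ordinates. By default the quantile is taken per
#' frequency (the threshold is frequency-local); `pooled = TRUE` instead
#' pools ordinates across all frequencies into a single level.
#'
#' @param null An `nb_null` from [fit_nb_moments()].
#' @param reps Number of surrogate series (default 10000).
#' @param q Quantile (default 0.95).
#' @param seed Optional integer seed for the surrogate draws.
#' @param pooled Pool ordinates across frequencies? Default `FALSE`.
#' @param taper Taper proportion, matched to the data periodogram.
#' @return Numeric vector of thresholds, one per frequency of the
#'   `floor(n/2)`-point grid (constant if `pooled`).
#' @export
mc_threshold <- function(null, reps = 10000, q = 0.95, seed = NULL,
                         pooled = FALSE, taper = 0) {
  stopifnot(inherits(null, "nb_null"), reps >= 1, q > 0, q < 1)
  if (!is.null(seed)) set.seed(seed)
  dens <- periodogram_matrix(draw_null_matrix(null, reps), taper = taper)
  if (pooled) {
    rep(stats::quantile(dens, probs = q, names = FALSE), nrow(dens))
  } else {
    apply(dens, 1, stats::quantile, probs = q, names = FALSE)
  }
}

#' Periodogram with Monte-Carlo white-noise significance threshold
#'
#' Convenience wrapper: fits the negative-binomial null to the raw counts,
#' square-root transforms, computes the raw periodogram, and attaches the
#' per-frequency Monte-Carlo threshold.
#'
#' @param x Non-negative count vector (raw counts, already truncated).
#' @param reps,q,seed,pooled,taper Passed to [mc_threshold()].
#' @return A `gc_periodogram` tibble with additional columns `threshold` and
#'   `significant`, and attribute `null` (the fitted `nb_null`).
#' @export
cycle_spectrum <- function(x, reps = 10000, q = 0.95, seed = NULL,
                           pooled = FALSE, taper = 0) {
  null <- fit_nb_moments(x)
  pg <- periodogram(sqrt_transform(x), taper = taper)
  thr <- mc_threshold(null, reps = reps, q = q, seed = seed, pooled = pooled,
                      taper = taper)
  pg$threshold <- thr
  pg$significant <- pg$density > pg$threshold
  attr(pg, "null") <- null
  pg
}

#' Classify a generation cycle from a thresholded periodogram
#'
#' Restricts to frequencies whose period lies in `band` (default 5-7 weeks,
#' bracketing the one-generation period of 6 weeks) and calls a cycle present
#' when any ordinate in the band exceeds its Monte-Carlo threshold. The peak
#' is the band frequency maximising `density - threshold`; ties are broken
#' toward the frequency nearest 1/6 cycles per week.
#'
#' @param pg A `gc_periodogram` with a `threshold` column (see
#'   [cycle_spectrum()]).
#' @param band Closed period window in weeks (default `c(5, 7)`).
#' @return One-row tibble: `present`, `peak_period`, `peak_density`,
#'   `peak_threshold`.
#' @export
classify_cycle <- function(pg, band = c(5, 7)) {
  stopifnot(inherits(pg, "gc_periodogram"))
  if (is.null(pg$threshold)) stop("periodogram has no threshold; run cycle_spectrum()",
                                  call. = FALSE)
  band <- sort(band)
  in_band <- pg$period >= band[1] & pg$period <= band[2]
  if (!any(in_band)) {
    stop("no periodogram frequencies fall in the period band [",
         band[1], ", ", band[2], "] weeks", call. = FALSE)
  }
  sub <- pg[in_band, ]
  excess <- sub$density - sub$threshold
  best <- which(excess == max(excess))
  if (length(best) > 1) best <- best[which.min(abs(sub$frequency[best] - 1 / 6))]
  tibble::tibble(
    present = excess[best] > 0,
    peak_period = sub$period[best],
    peak_density = sub$density[best],
    peak_threshold = sub$threshold[best]
  )
}

#' Spectral cycle calls for every population in a census
#'
#' Runs [cycle_spectrum()] + [classify_cycle()] on the weekly total
#' dead-adult counts of each persisting population.
#'
#' @param census A census tibble (already truncated).
#' @param band Period band in weeks for the cycle call.
#' @param reps,q,seed Monte-Carlo settings, see [mc_threshold()]. Each
#'   population gets an independent surrogate stream derived from `seed`.
#' @param exclude_extinct Drop populations flagged by [detect_extinctions()]?
#'   Default `TRUE` (the analysis addresses populations that persisted).
#' @return Tibble with one row per analysed population: treatment columns
#'   plus the [classify_cycle()] fields.
#' @export
classify_study <- function(census, band = c(5, 7), reps = 10000, q = 0.95,
                           seed = NULL, exclude_extinct = TRUE) {
  pops <- split_populations(census)
  if (exclude_extinct) {
    ext <- detect_extinctions(census)
    keep <- !ext$extinct[match(names(pops), pop_label(ext))]
    pops <- pops[keep]
  }
  purrr::imap_dfr(pops, function(p, label) {
    x <- p$adults_female + p$adults_male
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, label)
    pg <- cycle_spectrum(x, reps = reps, q = q, seed = sub_seed)
    dplyr::bind_cols(p[1, treatment_cols], classify_cycle(pg, band = band))
  })
}

# deterministic per-stage/per-population seed from a master seed (kept < 2^31)
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.integer(seed) + 7919L * (h %% 100000L)) %% 2147483647L
}

#' Cross-tabulate cycle presence by treatment
#'
#' @param calls Output of [classify_study()] (or any tibble with
#'   `temperature_C`, `diet` and logical `present`).
#' @return An r x 2 integer matrix, rows = temperature-diet combinations,
#'   columns `cycling` / `not_cycling`; input for [fisher_exact()].
#' @export
cycling_pattern <- function(calls) {
  grp <- paste0(calls$temperature_C, "C_", calls$diet)
  tab <- table(factor(grp, levels = unique(grp)),
               factor(ifelse(calls$present, "cycling", "not_cycling"),
                      levels = c("cycling", "not_cycling")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' @rdname periodogram
#' @param object A `gc_periodogram`.
#' @param ... Ignored.
#' @method autoplot gc_periodogram
#' @export
autoplot.gc_periodogram <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1 / 6, linetype = "dotted") +
    ggplot2::labs(x = "frequency (cycles/week)", y = "spectral density")
  if (!is.null(object$threshold)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$threshold),
                                linetype = "dashed", colour = "red")
  }
  p
}
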