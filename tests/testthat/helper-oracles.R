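# Independent oracles and small fixture builders used across the suite.

# O(n^2) direct DFT periodogram, kept deliberately naive and separate from
# the package's FFT path.
direct_periodogram <- function(y) {
  n <- length(y)
  yc <- y - mean(y)
  t <- seq_len(n)
  vapply(seq_len(n %/% 2), function(j) {
    Mod(sum(yc * exp(-2i * pi * j * t / n)))^2 / n
  }, numeric(1))
}

# Direct time-domain Morlet convolution: W(t,s) = sqrt(dt/s) *
# sum_t' y(t') conj(psi0((t'-t) dt / s)), psi0 the time-sampled mother wavelet.
direct_morlet_cwt <- function(y, periods, dt = 1, omega0 = 6) {
  n <- length(y)
  y <- y - mean(y)
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / ff
  W <- matrix(0 + 0i, n, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    for (t in seq_len(n)) {
      eta <- (seq_len(n) - t) * dt / s
      psi <- pi^(-1 / 4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
      W[t, j] <- sum(y * Conj(psi)) * sqrt(dt / s)
    }
  }
  W
}

# hand-built census tibble for a single population
toy_census <- function(weeks = 1:12, temperature = 27, diet = "standard",
                       replicate = 1, f = NULL, m = NULL) {
  n <- length(weeks)
  if (is.null(f)) f <- rep(2L, n)
  if (is.null(m)) m <- rep(3L, n)
  tibble::tibble(
    week = weeks, temperature_C = temperature, diet = diet,
    replicate = as.integer(replicate),
    adults_female = as.integer(f), adults_male = as.integer(m),
    larvae_L3 = 1L, larvae_L4 = 1L, larvae_L5 = 2L
  )
}

# random schema-valid census table for round-trip properties
random_census <- function(seed, n_pops = 2, n_weeks = 8) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_pops), function(i) {
    tibble::tibble(
      week = seq_len(n_weeks),
      temperature_C = sample(c(27, 30, 33), 1),
      diet = sample(c("standard", "poor"), 1),
      replicate = i,
      adults_female = rpois(n_weeks, 5),
      adults_male = rpois(n_weeks, 5),
      larvae_L3 = rpois(n_weeks, 3),
      larvae_L4 = rpois(n_weeks, 3),
      larvae_L5 = rpois(n_weeks, 3)
    )
  })
}
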