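test_that("sqrt_transform is the elementwise square root and rejects negatives", {
  expect_equal(sqrt_transform(c(0, 1, 4, 9)), c(0, 1, 2, 3))
  expect_error(sqrt_transform(c(1, -1)), "non-negative")
  # variance stabilisation direction on overdispersed counts
  set.seed(5)
  x <- rnbinom(5000, mu = 100, size = 5)
  expect_lt(var(sqrt_transform(x)) / var(x), 0.05)
})

test_that("periodogram matches the direct-DFT oracle on random series", {
  set.seed(11)
  for (n in c(16, 31, 72, 128)) {
    y <- rnorm(n) + sin(2 * pi * seq_len(n) / 9)
    got <- periodogram(y)$density
    want <- direct_periodogram(y)
    expect_lt(max(abs(got - want)) / max(want), 1e-10)
  }
})

test_that("a Fourier-frequency cosine concentrates all mass at its frequency", {
  t <- 1:72
  pg <- periodogram(cos(2 * pi * t / 6))
  at6 <- pg$density[abs(pg$frequency - 1 / 6) < 1e-12]
  expect_equal(at6, 72 / 4)
  expect_lt(max(pg$density[abs(pg$frequency - 1 / 6) > 1e-12]), 1e-20)
  expect_equal(periodogram(rep(3, 20))$density, rep(0, 10))
})

test_that("periodogram ordinates satisfy Parseval's identity", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(c(40, 71, 72), 1)
    y <- rnorm(n)
    pg <- periodogram(y)
    yc <- y - mean(y)
    total <- sum(yc^2)
    # odd n: interior ordinates count twice; even n: Nyquist counts once
    recon <- if (n %% 2 == 0) {
      2 * sum(pg$density[-nrow(pg)]) + pg$density[nrow(pg)]
    } else {
      2 * sum(pg$density)
    }
    expect_equal(recon, total, tolerance = 1e-10)
  }
})

test_that("fit_nb_moments recovers mean and shape by moments", {
  x <- c(rep(5, 5), rep(15, 5))  # mean 10, var 27.78
  nb <- fit_nb_moments(x)
  expect_equal(nb$mean, 10)
  expect_equal(nb$k, 100 / (var(x) - 10))
  # textbook case m = 10, s2 = 30 -> k = 5
  expect_equal(10^2 / (30 - 10), 5)
  # underdispersion -> Poisson limit
  expect_true(fit_nb_moments(rep(c(9, 10, 11), 8))$poisson)
  # Monte-Carlo consistency
  set.seed(9)
  nb2 <- fit_nb_moments(rnbinom(1e5, mu = 10, size = 5))
  expect_lt(abs(nb2$k - 5) / 5, 0.1)
  expect_error(fit_nb_moments(rep(0, 10)), "positive mean")
})

test_that("mc_threshold approaches the closed-form exponential quantile for Gaussian noise", {
  # For Gaussian white noise with variance sigma^2, interior raw-periodogram
  # ordinates under this scaling are sigma^2 * chi^2_2 / 2 = Exp(mean
  # sigma^2), so the q-quantile is -log(1-q) * sigma^2. Poisson counts at
  # large mu behave Gaussian after sqrt: sqrt(X) ~ N(sqrt(mu), 1/4), so
  # sigma^2 = 1/4.
  set.seed(101)
  null <- fit_nb_moments(rpois(200, 10000))
  thr <- mc_threshold(null, reps = 4000, q = 0.95, seed = 3)
  expected <- -log(0.05) * 0.25
  interior <- thr[-length(thr)]
  expect_lt(abs(median(interior) - expected) / expected, 0.1)
})

test_that("thresholds are seed-stable at large reps and max at q -> 1", {
  set.seed(103)
  nb <- fit_nb_moments(rnbinom(72, mu = 50, size = 10))
  t1 <- mc_threshold(nb, reps = 4000, seed = 1)
  t2 <- mc_threshold(nb, reps = 4000, seed = 2)
  expect_lt(max(abs(t1 - t2) / t1), 0.25)
  # q near 1 with tiny reps equals the per-frequency maximum
  set.seed(7)
  dens <- gencycles:::periodogram_matrix(gencycles:::draw_null_matrix(nb, 20))
  set.seed(7)
  thr_max <- mc_threshold(nb, reps = 20, q = 1 - 1e-9)
  expect_equal(thr_max, apply(dens, 1, max), tolerance = 1e-6)
})

test_that("surrogates and data share one spectral code path", {
  x <- rnbinom(72, mu = 80, size = 8)
  m <- matrix(x, ncol = 1)
  via_matrix <- gencycles:::periodogram_matrix(m)[, 1]
  via_data <- periodogram(sqrt_transform(x))$density
  expect_equal(via_matrix, via_data)
})

test_that("classify_cycle calls strong 6-week cycles and not constants", {
  cen <- generate_phenom(mu = 100, k = 20, A6 = 0.8, n_weeks = 72, seed = 4)
  x <- cen$adults_female + cen$adults_male
  pg <- cycle_spectrum(x, reps = 2000, seed = 5)
  cc <- classify_cycle(pg)
  expect_true(cc$present)
  expect_true(cc$peak_period >= 5 && cc$peak_period <= 7)

  # near-constant series: nothing significant
  set.seed(8)
  flat <- rep(100L, 72) + rbinom(72, 2, 0.5)
  pgf <- cycle_spectrum(flat, reps = 2000, seed = 6)
  expect_false(classify_cycle(pgf)$present)
  expect_error(classify_cycle(pgf, band = c(0.2, 0.4)), "band")
})

test_that("detection power is monotone in the cycle amplitude", {
  rate <- sapply(c(0, 0.4, 0.8), function(a) {
    mean(sapply(1:15, function(s) {
      cen <- generate_phenom(mu = 100, k = 20, A6 = a, n_weeks = 72, seed = s)
      x <- cen$adults_female + cen$adults_male
      classify_cycle(cycle_spectrum(x, reps = 800, seed = s + 100))$present
    }))
  })
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.5)
  expect_equal(rate[3], 1)
})

test_that("cycling_pattern cross-tabulates calls with conserved margins", {
  calls <- tibble::tibble(
    temperature_C = rep(c(27, 27, 30, 30), each = 3),
    diet = rep(c("standard", "poor", "poor", "standard"), each = 3),
    replicate = rep(1:3, 4),
    present = c(rep(TRUE, 9), rep(FALSE, 3))
  )
  tab <- cycling_pattern(calls)
  expect_equal(unname(tab), rbind(c(3, 0), c(3, 0), c(3, 0), c(0, 3)))
  expect_equal(unname(rowSums(tab)), rep(3, 4))
})
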