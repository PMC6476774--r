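test_that("factorial_lm reproduces hand-computed one-way ANOVA", {
  d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
  res <- factorial_lm(d, "y", factors = "g")
  expect_equal(res$F, 8)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 2)
  expect_equal(res$p, pf(8, 1, 2, lower.tail = FALSE))
  expect_false(res$retained)  # p ~ 0.106 >= 0.05
})

test_that("factorial_lm matches stats::anova for the full factorial and keeps significant terms", {
  set.seed(13)
  d <- expand.grid(temperature_C = c(27, 30, 33), diet = c("standard", "poor"),
                   rep = 1:3)
  d$y <- 10 + 5 * (d$temperature_C == 30) + rnorm(nrow(d), sd = 0.5)
  res <- factorial_lm(d, "y")
  ref <- anova(lm(y ~ factor(temperature_C) * factor(diet), data = d))
  # temperature is hugely significant and retained with the reference F
  trow <- res[res$term == "temperature_C", ]
  expect_true(trow$retained)
  # interaction and diet are noise: dropped; temperature refit F comes from
  # the reduced model
  expect_false(res$retained[res$term == "diet"])
  expect_false(res$retained[res$term == "temperature_C:diet"])
  red <- anova(lm(y ~ factor(temperature_C), data = d))
  expect_equal(trow$F, red["factor(temperature_C)", "F value"])
  expect_equal(trow$df_den, red["Residuals", "Df"])
  # interaction tested against the full model
  irow <- res[res$term == "temperature_C:diet", ]
  expect_equal(irow$F, ref["factor(temperature_C):factor(diet)", "F value"])
})

test_that("marginality is respected when the interaction is significant", {
  d <- expand.grid(temperature_C = c(27, 30), diet = c("standard", "poor"),
                   rep = 1:4)
  set.seed(17)
  d$y <- ifelse(d$temperature_C == 30 & d$diet == "poor", 20, 10) +
    rnorm(nrow(d), sd = 0.5)
  res <- factorial_lm(d, "y")
  expect_true(res$retained[res$term == "temperature_C:diet"])
  # main effects stay whatever their own p, because the interaction stays
  expect_true(all(res$retained))
})

test_that("constant response degenerates to F = 0, p = 1", {
  d <- expand.grid(temperature_C = c(27, 30), diet = c("standard", "poor"),
                   rep = 1:2)
  d$y <- 7
  res <- factorial_lm(d, "y")
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
})

test_that("fisher_exact reproduces the all-but-one-treatment cycling pattern", {
  tab <- rbind(c(3, 0), c(3, 0), c(3, 0), c(0, 3))
  fe <- fisher_exact(tab)
  expect_equal(fe$p, 4 * 6 / 1320, tolerance = 1e-12)
  expect_equal(signif(fe$p, 2), 0.018)
  expect_equal(fe$total_prob, 1, tolerance = 1e-10)
  expect_equal(fe$observed_prob, 6 / 1320, tolerance = 1e-12)
})

test_that("fisher_exact agrees with stats::fisher.test across table shapes", {
  tabs <- list(
    rbind(c(3, 0), c(3, 0), c(3, 0), c(0, 3)),
    rbind(c(1, 0), c(0, 1)),
    rbind(c(2, 3), c(4, 1)),
    rbind(c(1, 2, 3), c(3, 2, 1)),
    rbind(c(5, 1), c(2, 4), c(3, 3))
  )
  for (tab in tabs) {
    expect_equal(fisher_exact(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1)))$p, 1)
})

test_that("fisher_exact enumerates a distribution that sums to one", {
  set.seed(19)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 3) + 1, nrow = 3)
    fe <- fisher_exact(tab)
    expect_equal(fe$total_prob, 1, tolerance = 1e-10)
    expect_lte(fe$observed_prob, fe$p + 1e-12)
    expect_lte(fe$p, 1 + 1e-12)
  }
  expect_error(fisher_exact(matrix(20, 2, 2)), "guard")
  expect_error(fisher_exact(rbind(c(1, -1), c(2, 2))), "non-negative")
})

test_that("Monte-Carlo exact test agrees with enumeration and is reproducible", {
  tab <- rbind(c(3, 0), c(3, 0), c(3, 0), c(0, 3))
  mc1 <- fisher_exact_mc(tab, reps = 4000, seed = 23)
  expect_lt(abs(mc1$p - 0.018182), 3 * mc1$se)
  mc2 <- fisher_exact_mc(tab, reps = 4000, seed = 23)
  expect_equal(mc1$p, mc2$p)
  expect_warning(fisher_exact_mc(tab, reps = 500, seed = 1), "reps")
})

test_that("summarize_study assembles means, models and the cycling test", {
  set.seed(29)
  cen <- purrr::pmap_dfr(
    expand.grid(tt = c(27, 30), dd = c("standard", "poor"), r = 1:3,
                stringsAsFactors = FALSE),
    function(tt, dd, r) {
      mu <- if (tt == 30) 140 else 90
      generate_phenom(mu = mu, k = 20, A6 = 0.5, n_weeks = 40,
                      seed = tt * 100 + r + (dd == "poor") * 7,
                      temperature_C = tt, diet = dd, replicate = r)
    })
  # phenom series carry no larvae; splice constant larval counts in
  cen$larvae_L3 <- 3L; cen$larvae_L4 <- 2L; cen$larvae_L5 <- 1L
  calls <- tibble::tibble(
    temperature_C = rep(c(27, 27, 30, 30), each = 3),
    diet = rep(c("standard", "poor", "poor", "standard"), each = 3),
    present = c(rep(TRUE, 9), rep(FALSE, 3))
  )
  rep_ <- summarize_study(cen, calls)
  expect_s3_class(rep_, "study_report")
  expect_equal(nrow(rep_$populations), 12)
  expect_equal(rep_$fisher$p, 4 * 6 / 1320, tolerance = 1e-10)
  # adult-mean model must pick up the big temperature effect
  am <- rep_$anova$mean_adults
  expect_true(am$retained[am$term == "temperature_C"])
  expect_lt(am$p[am$term == "temperature_C"], 0.001)
  # treatment means cover 4 cells x 4 measures
  expect_equal(nrow(rep_$treatment_means), 16)
  expect_true(all(rep_$treatment_means$ci_lo <= rep_$treatment_means$mean,
                  na.rm = TRUE))
})
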