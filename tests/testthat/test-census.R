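test_that("read_census round-trips schema-valid tables", {
  for (seed in 1:5) {
    cen <- random_census(seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_census(cen, path)
    back <- read_census(path)
    expect_equal(
      dplyr::arrange(back, temperature_C, diet, replicate, week),
      dplyr::arrange(cen, temperature_C, diet, replicate, week),
      ignore_attr = TRUE
    )
  }
})

test_that("read_census reports schema and validation problems precisely", {
  cen <- toy_census(weeks = 1:3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_census(cen, path)
  one <- read_census(path)
  expect_equal(nrow(one), 3)
  expect_equal(one$week, 1:3)

  # missing column
  broken <- utils::read.csv(path, comment.char = "#")
  broken$adults_male <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_census(p2), "adults_male")

  # negative count with row number
  bad <- cen
  bad$adults_female[2] <- -2L
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  expect_error(read_census(p3), "row 2")
})

test_that("alternate column dialects map onto the canonical schema", {
  cen <- toy_census(weeks = 1:4)
  path <- withr::local_tempfile(fileext = ".csv")
  renamed <- dplyr::rename(cen, females = adults_female, males = adults_male)
  utils::write.csv(renamed, path, row.names = FALSE)
  dia <- census_dialect(adults_female = "females", adults_male = "males")
  expect_equal(read_census(path, dialect = dia)$adults_female,
               cen$adults_female)
  expect_error(census_dialect(not_a_column = "x"), "unknown canonical")
})

test_that("truncate_transients drops initial weeks and composes", {
  cen <- toy_census(weeks = 1:82)
  tr <- truncate_transients(cen, 10)
  expect_equal(nrow(tr), 72)
  expect_equal(min(tr$week), 11)
  expect_equal(truncate_transients(cen, 0), cen)
  expect_equal(
    truncate_transients(truncate_transients(cen, 5), 5)$week,
    truncate_transients(cen, 10)$week
  )
  expect_error(truncate_transients(toy_census(weeks = 1:10), 10), "n_drop")
})

test_that("total_adults sums the sexes and conserves totals", {
  cen <- toy_census(weeks = 1:2, f = c(1, 2), m = c(0, 3))
  expect_equal(total_adults(cen)$adults_total, c(1, 5))
  for (seed in 1:5) {
    cen <- random_census(seed, n_pops = 1)
    expect_equal(sum(total_adults(cen)$adults_total),
                 sum(cen$adults_female) + sum(cen$adults_male))
  }
})

test_that("coefficient_of_variation matches the hand formula and is scale invariant", {
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  set.seed(1)
  x <- rpois(50, 20) + 1
  for (c_ in c(0.5, 3, 100)) {
    expect_equal(coefficient_of_variation(c_ * x), coefficient_of_variation(x))
  }
  expect_error(coefficient_of_variation(rep(0, 5)), "mean")
})

test_that("age_structure averages weekly proportions and sums to one", {
  cen <- toy_census(weeks = 1)
  cen$larvae_L3 <- 1L; cen$larvae_L4 <- 1L; cen$larvae_L5 <- 2L
  as1 <- age_structure(cen)
  expect_equal(c(as1$p3, as1$p4, as1$p5), c(0.25, 0.25, 0.5))

  # pooled and weekly agree when weekly totals are constant
  cen2 <- toy_census(weeks = 1:6)
  w <- age_structure(cen2, "weekly")
  p <- age_structure(cen2, "pooled")
  expect_equal(w[c("p3", "p4", "p5")], p[c("p3", "p4", "p5")])

  for (seed in 1:5) {
    as_ <- age_structure(random_census(seed))
    expect_true(all(abs(as_$p3 + as_$p4 + as_$p5 - 1) < 1e-12))
  }
  zero <- toy_census(weeks = 1:3)
  zero$larvae_L3 <- 0L; zero$larvae_L4 <- 0L; zero$larvae_L5 <- 0L
  expect_error(age_structure(zero), "no week")
})

test_that("extinction flagging requires a long terminal zero run", {
  gone <- toy_census(weeks = 1:30, f = c(rep(5L, 18), rep(0L, 12)),
                     m = c(rep(5L, 18), rep(0L, 12)))
  ext <- detect_extinctions(gone)
  expect_true(ext$extinct)
  expect_equal(ext$extinct_week, 19)

  # short terminal gap is not extinction
  gap <- toy_census(weeks = 1:30, f = c(rep(5L, 27), 0L, 0L, 0L),
                    m = rep(5L, 30))
  expect_false(detect_extinctions(gap)$extinct)
})
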