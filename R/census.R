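#' @importFrom rlang .data
#' @importFrom stats sd quantile var fft rnbinom rpois rbinom runif complete.cases
NULL

# Canonical census schema. One row per population-week; larval columns may be
# NA once the (shorter) larval sampling span has ended.
census_cols <- c(
  "week", "temperature_C", "diet", "replicate",
  "adults_female", "adults_male", "larvae_L3", "larvae_L4", "larvae_L5"
)
count_cols <- census_cols[5:9]
treatment_cols <- c("temperature_C", "diet", "replicate")

#' Column mapping for alternate census file dialects
#'
#' A dialect is a named character vector mapping the canonical column names
#' (`week`, `temperature_C`, `diet`, `replicate`, `adults_female`,
#' `adults_male`, `larvae_L3`, `larvae_L4`, `larvae_L5`) onto the column
#' names used in a particular file. Unmentioned columns keep their canonical
#' name. A mapping can also be kept in a two-column `canonical,file` CSV and
#' loaded with this helper, so archived deposits with different headers can
#' be read without editing code.
#'
#' @param ... Named character entries, `canonical = "file_column"`.
#' @param file Optional path to a two-column CSV (`canonical,file`) holding
#'   the mapping; entries in `...` take precedence.
#' @return Named character vector usable as the `dialect` argument of
#'   [read_census()].
#' @examples
#' census_dialect(adults_female = "females", adults_male = "males")
#' @export
census_dialect <- function(..., file = NULL) {
  m <- c(...)
  if (!is.null(file)) {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("canonical", "file") %in% names(tab))) {
      stop("dialect mapping file needs columns 'canonical' and 'file'", call. = FALSE)
    }
    fm <- stats::setNames(tab$file, tab$canonical)
    m <- c(m, fm[setdiff(names(fm), names(m))])
  }
  bad <- setdiff(names(m), census_cols)
  if (length(bad)) {
    stop("unknown canonical column(s) in dialect: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(census_cols, census_cols)
  full[names(m)] <- unname(m)
  full
}

#' Read a weekly census table
#'
#' Reads a delimited census file into the canonical long format: one row per
#' population-week with treatment metadata (`temperature_C`, `diet`,
#' `replicate`), dead-adult counts by sex, and counts of 3rd-5th instar
#' larvae. Larval cells may be empty after the larval sampling span ends
#' (larvae are typically censused for fewer weeks than adults).
#'
#' @param path Path to a delimited text file with a header row. Lines
#'   starting with `#` are treated as comments (the simulator writes scenario
#'   metadata that way).
#' @param dialect Column mapping from [census_dialect()]; defaults to the
#'   canonical names.
#' @return A tibble with the canonical columns, weeks sorted within each
#'   population.
#' @seealso [write_census()], [validate_census()]
#' @export
read_census <- function(path, dialect = census_dialect()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- dialect[!unname(dialect) %in% names(df)]
  if (length(missing)) {
    stop("census file is missing column(s): ",
         paste(unname(missing), collapse = ", "),
         " (expected for: ", paste(names(missing), collapse = ", "), ")",
         call. = FALSE)
  }
  df <- df[, unname(dialect)]
  names(df) <- names(dialect)
  out <- tibble::as_tibble(df)
  out$diet <- as.character(out$diet)
  for (cc in count_cols) {
    # an all-empty larval column reads back as logical NA
    if (is.logical(out[[cc]])) out[[cc]] <- as.integer(out[[cc]])
  }
  validate_census(out)
  dplyr::arrange(out, .data$temperature_C, .data$diet, .data$replicate, .data$week)
}

#' Validate a census tibble against the schema
#'
#' Checks column presence, non-negative integer counts (row numbers are
#' reported for offending cells), strictly increasing unit-spaced weeks per
#' population, and that the adult span covers the larval span.
#'
#' @param census A census tibble.
#' @return `census`, invisibly, if valid; otherwise an error.
#' @export
validate_census <- function(census) {
  missing <- setdiff(census_cols, names(census))
  if (length(missing)) {
    stop("census is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(census$diet %in% c("standard", "poor"))) {
    stop("diet must be 'standard' or 'poor'", call. = FALSE)
  }
  for (cc in c("week", count_cols)) {
    x <- census[[cc]]
    if (!is.numeric(x)) stop("column ", cc, " must be numeric", call. = FALSE)
    bad <- which(!is.na(x) & (x < 0 | x != round(x)))
    if (length(bad)) {
      stop("column ", cc, " has negative or non-integer value at row ", bad[1],
           call. = FALSE)
    }
  }
  adult_na <- which(is.na(census$adults_female) | is.na(census$adults_male))
  if (length(adult_na)) {
    stop("adult counts may not be missing (row ", adult_na[1], ")", call. = FALSE)
  }
  by_pop <- dplyr::group_split(dplyr::group_by(
    census, dplyr::across(dplyr::all_of(treatment_cols))))
  for (p in by_pop) {
    w <- sort(p$week)
    if (any(diff(w) != 1)) {
      stop("weeks must be strictly increasing with unit spacing within a ",
           "population (", p$temperature_C[1], "C/", p$diet[1],
           "/rep ", p$replicate[1], ")", call. = FALSE)
    }
    lar <- !is.na(p$larvae_L3) | !is.na(p$larvae_L4) | !is.na(p$larvae_L5)
    if (any(lar) && any(diff(which(lar[order(p$week)])) != 1)) {
      stop("larval weeks must form a contiguous block within the adult span",
           call. = FALSE)
    }
  }
  invisible(census)
}

#' Write a census tibble to a delimited file
#'
#' @param census A census tibble (canonical columns).
#' @param path Output path.
#' @param comment Optional character vector written as `#`-prefixed header
#'   lines (used by the simulator to record scenario and seed).
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path, comment = NULL) {
  validate_census(census)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(census[, census_cols], con, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Split a census into one tibble per population
#'
#' @param census A census tibble.
#' @return Named list of single-population tibbles; names are
#'   `"<temperature>C_<diet>_r<replicate>"`.
#' @export
split_populations <- function(census) {
  g <- dplyr::group_by(census, dplyr::across(dplyr::all_of(treatment_cols)))
  keys <- dplyr::group_keys(g)
  out <- dplyr::group_split(g)
  names(out) <- pop_label(keys)
  out
}

pop_label <- function(df) {
  paste0(df$temperature_C, "C_", df$diet, "_r", df$replicate)
}

#' Drop initial transient weeks from a census
#'
#' Census series from newly founded populations carry transients from the
#' initial cohort; analyses conventionally drop the first weeks. The first
#' `n_drop` observed weeks are removed from every channel of every
#' population; treatment metadata is untouched.
#'
#' @param census A census tibble.
#' @param n_drop Number of initial weeks to drop (default 10).
#' @return The truncated census tibble.
#' @export
truncate_transients <- function(census, n_drop = 10) {
  stopifnot(n_drop >= 0, n_drop == round(n_drop))
  if (n_drop == 0) return(census)
  g <- dplyr::group_by(census, dplyr::across(dplyr::all_of(treatment_cols)))
  lens <- dplyr::summarise(g, n = dplyr::n(), .groups = "drop")
  if (any(lens$n <= n_drop)) {
    stop("n_drop (", n_drop, ") must be smaller than every population's ",
         "series length (min ", min(lens$n), ")", call. = FALSE)
  }
  dplyr::ungroup(dplyr::filter(g, dplyr::row_number(.data$week) > n_drop))
}

#' Weekly total dead-adult counts
#'
#' @param census A census tibble.
#' @return Tibble with treatment columns, `week`, and `adults_total`
#'   (female + male).
#' @export
total_adults <- function(census) {
  dplyr::select(
    dplyr::mutate(census, adults_total = .data$adults_female + .data$adults_male),
    dplyr::all_of(treatment_cols), "week", "adults_total"
  )
}

#' Coefficient of variation
#'
#' Sample standard deviation (denominator n - 1) divided by the mean; a
#' scale-free measure of population variability.
#'
#' @param x Numeric vector with positive mean.
#' @return The CV as a single number.
#' @examples
#' coefficient_of_variation(c(1, 3)) # sqrt(2)/2
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined: mean must be positive", call. = FALSE)
  }
  stats::sd(x) / m
}

#' Time-averaged larval age structure
#'
#' Proportions of counted larvae in instars 3, 4 and 5, averaged over weeks.
#' Two readings of "time-averaged" are offered: the mean of weekly proportions
#' over weeks with at least one counted larva (default; robust to varying
#' weekly sampling effort), or proportions of the pooled counts. The two
#' agree exactly when every week has the same larval total.
#'
#' @param census A census tibble.
#' @param method `"weekly"` (mean of weekly proportions) or `"pooled"`
#'   (proportions of pooled counts).
#' @return Tibble with treatment columns and `p3`, `p4`, `p5`
#'   (each population's proportions sum to 1).
#' @export
age_structure <- function(census, method = c("weekly", "pooled")) {
  method <- match.arg(method)
  d <- dplyr::filter(census, !is.na(.data$larvae_L3))
  d <- dplyr::mutate(d, lar_tot = .data$larvae_L3 + .data$larvae_L4 + .data$larvae_L5)
  d <- dplyr::filter(d, .data$lar_tot > 0)
  if (nrow(d) == 0) {
    stop("age structure undefined: no week with counted larvae", call. = FALSE)
  }
  g <- dplyr::group_by(d, dplyr::across(dplyr::all_of(treatment_cols)))
  if (method == "weekly") {
    out <- dplyr::summarise(
      g,
      p3 = mean(.data$larvae_L3 / .data$lar_tot),
      p4 = mean(.data$larvae_L4 / .data$lar_tot),
      p5 = mean(.data$larvae_L5 / .data$lar_tot),
      .groups = "drop"
    )
  } else {
    out <- dplyr::summarise(
      g,
      p3 = sum(.data$larvae_L3) / sum(.data$lar_tot),
      p4 = sum(.data$larvae_L4) / sum(.data$lar_tot),
      p5 = sum(.data$larvae_L5) / sum(.data$lar_tot),
      .groups = "drop"
    )
  }
  out
}

#' Flag extinct populations
#'
#' A population is flagged extinct at the first week of a terminal run of
#' all-zero adult counts at least `min_zero_run` weeks long. Extinct
#' populations are conventionally excluded from spectral, wavelet and
#' linear-model analyses, which address populations that persisted.
#'
#' @param census A census tibble.
#' @param min_zero_run Minimum length of the terminal zero run (default 8
#'   weeks, longer than one generation).
#' @return Tibble with treatment columns, `extinct` (logical) and
#'   `extinct_week` (NA when persisting).
#' @export
detect_extinctions <- function(census, min_zero_run = 8) {
  tot <- total_adults(census)
  g <- dplyr::group_by(tot, dplyr::across(dplyr::all_of(treatment_cols)))
  dplyr::summarise(g, {
    x <- .data$adults_total[order(.data$week)]
    w <- sort(.data$week)
    nz <- which(x > 0)
    run_start <- if (length(nz) == 0) 1L else if (max(nz) == length(x)) NA_integer_ else max(nz) + 1L
    ext <- !is.na(run_start) && (length(x) - run_start + 1L) >= min_zero_run
    tibble::tibble(
      extinct = ext,
      extinct_week = if (ext) w[run_start] else NA_integer_
    )
  }, .groups = "drop")
}

#' Per-population descriptive summary
#'
#' Mean weekly dead-adult and larval counts, the adult-count coefficient of
#' variation, time-averaged age structure, and extinction status, one row per
#' population.
#'
#' @param census A census tibble (typically already passed through
#'   [truncate_transients()]).
#' @param age_method Passed to [age_structure()].
#' @return One-row-per-population tibble.
#' @export
population_summary <- function(census, age_method = "weekly") {
  tot <- total_adults(census)
  g <- dplyr::group_by(tot, dplyr::across(dplyr::all_of(treatment_cols)))
  adults <- dplyr::summarise(
    g,
    mean_adults = mean(.data$adults_total),
    cv_adults = if (mean(.data$adults_total) > 0)
      stats::sd(.data$adults_total) / mean(.data$adults_total) else NA_real_,
    .groups = "drop"
  )
  lar <- dplyr::filter(census, !is.na(.data$larvae_L3))
  lg <- dplyr::group_by(lar, dplyr::across(dplyr::all_of(treatment_cols)))
  larvae <- dplyr::summarise(
    lg,
    mean_larvae = mean(.data$larvae_L3 + .data$larvae_L4 + .data$larvae_L5),
    .groups = "drop"
  )
  age <- tryCatch(age_structure(census, method = age_method), error = function(e) NULL)
  ext <- detect_extinctions(census)
  out <- dplyr::left_join(adults, larvae, by = treatment_cols)
  if (!is.null(age)) out <- dplyr::left_join(out, age, by = treatment_cols)
  dplyr::left_join(out, ext, by = treatment_cols)
}
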