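#' Factorial linear model with backward simplification
#'
#' Fits a least-squares model of a per-population measure on temperature and
#' diet (both treated as factors) with their interaction, then simplifies
#' backwards to a minimal adequate model: the interaction is dropped if its
#' F-test p-value is at least `alpha`, then any non-significant main effect,
#' always respecting marginality (a main effect is never removed while its
#' interaction is retained). F tests use sequential (type I) sums of squares
#' with factors entered in the order given; for a balanced design this equals
#' the orthogonal decomposition, so the order is immaterial there.
#'
#' @param data Data frame with one row per population.
#' @param response Name of the response column (string).
#' @param factors Character vector of factor column names, first entered
#'   first (default `c("temperature_C", "diet")`).
#' @param alpha Removal threshold (default 0.05).
#' @return Tibble of class `gc_anova` with one row per term ever tested:
#'   `term`, `F`, `df_num`, `df_den`, `p`, `retained`. The `F`, `df` and `p`
#'   shown for retained terms come from the minimal adequate model; for
#'   dropped terms they are the values at the step the term was removed.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
#' factorial_lm(d, "y", factors = "g")  # F(1,2) = 8, p ~ 0.106
#' @export
factorial_lm <- function(data, response, factors = c("temperature_C", "diet"),
                         alpha = 0.05) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("no column '", response, "'", call. = FALSE)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  data <- data[stats::complete.cases(data[, c(response, factors)]), ]

  terms_all <- if (length(factors) >= 2) {
    c(factors, paste(factors, collapse = ":"))
  } else {
    factors
  }
  current <- terms_all
  record <- list()

  # essentially constant response: every F is 0/0; report F = 0, p = 1
  yv <- data[[response]]
  if (stats::sd(yv) < 1e-10 * (abs(mean(yv)) + 1)) {
    fml <- stats::reformulate(terms_all, response = response)
    at <- suppressWarnings(stats::anova(stats::lm(fml, data = data)))
    tms <- setdiff(rownames(at), "Residuals")
    out <- tibble::tibble(term = tms, F = 0, df_num = at[tms, "Df"],
                          df_den = at["Residuals", "Df"], p = 1,
                          retained = FALSE)
    class(out) <- c("gc_anova", class(out))
    attr(out, "response") <- response
    return(out)
  }

  fit_terms <- function(trms) {
    fml <- stats::reformulate(trms, response = response)
    fit <- stats::lm(fml, data = data)
    if (stats::df.residual(fit) == 0) {
      stop("zero residual degrees of freedom; too few replicates", call. = FALSE)
    }
    fit
  }

  anova_rows <- function(fit) {
    at <- stats::anova(fit)
    terms <- rownames(at)
    terms <- terms[terms != "Residuals"]
    df_den <- at["Residuals", "Df"]
    purrr::map_dfr(terms, function(tm) {
      Fv <- at[tm, "F value"]
      pv <- at[tm, "Pr(>F)"]
      # constant response: SS are all ~0 and F is NaN; report F = 0, p = 1
      if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }
      tibble::tibble(term = tm, F = Fv, df_num = at[tm, "Df"],
                     df_den = df_den, p = pv)
    })
  }

  is_marginal_to <- function(tm, others) {
    # TRUE if tm appears inside a retained higher-order term
    any(vapply(others, function(o) {
      o != tm && all(strsplit(tm, ":")[[1]] %in% strsplit(o, ":")[[1]])
    }, logical(1)))
  }

  repeat {
    fit <- fit_terms(current)
    rows <- anova_rows(fit)
    droppable <- rows$term[rows$p >= alpha &
                             !vapply(rows$term, is_marginal_to,
                                     logical(1), others = current)]
    if (length(droppable) == 0) break
    worst <- droppable[which.max(rows$p[match(droppable, rows$term)])]
    record[[worst]] <- rows[rows$term == worst, ]
    current <- setdiff(current, worst)
    if (length(current) == 0) break
  }

  retained_rows <- if (length(current)) {
    dplyr::mutate(anova_rows(fit_terms(current)), retained = TRUE)
  } else {
    tibble::tibble(term = character(), F = double(), df_num = integer(),
                   df_den = integer(), p = double(), retained = logical())
  }
  dropped_rows <- if (length(record)) {
    dplyr::mutate(dplyr::bind_rows(record), retained = FALSE)
  } else {
    NULL
  }
  out <- dplyr::bind_rows(retained_rows, dropped_rows)
  out <- out[order(match(out$term, terms_all)), ]
  class(out) <- c("gc_anova", class(out))
  attr(out, "response") <- response
  out
}

# log multivariate hypergeometric probability of a table with fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, calling fun(tab) on each
enumerate_tables <- function(row_margins, col_margins, fun) {
  r <- length(row_margins)
  tab <- matrix(0L, nrow = r, ncol = length(col_margins))
  recurse_row <- function(i, col_rem) {
    if (i == r) {
      tab[r, ] <<- col_rem
      fun(tab)
      return(invisible())
    }
    fill_row <- function(j, left) {
      if (j == length(col_rem)) {
        tab[i, j] <<- left
        if (left <= col_rem[j]) recurse_row(i + 1, col_rem - tab[i, ])
        return(invisible())
      }
      lo <- max(0L, left - sum(col_rem[(j + 1):length(col_rem)]))
      hi <- min(left, col_rem[j])
      if (hi < lo) return(invisible())
      for (v in lo:hi) {
        tab[i, j] <<- v
        fill_row(j + 1, left - v)
      }
    }
    fill_row(1L, row_margins[i])
  }
  recurse_row(1L, as.integer(col_margins))
}

#' Exact test of independence for an r x c contingency table
#'
#' Full enumeration of every table sharing the observed row and column
#' margins; each table's null probability is the multivariate hypergeometric
#' \eqn{P = \prod_i r_i! \prod_j c_j! / (N! \prod_{ij} n_{ij}!)}, and the
#' two-sided p-value sums the probabilities of all tables no more probable
#' than the observed one (probability-ordering rule, with a relative
#' tolerance of 1e-12 on the comparison).
#'
#' @param table Non-negative integer matrix (e.g. from [cycling_pattern()]).
#' @param max_total Guard on the grand total for full enumeration (default
#'   60); larger tables should use [fisher_exact_mc()].
#' @return Object of class `fisher_exact`: `p`, `n_tables` (tables
#'   enumerated), `observed_prob`, `total_prob` (sum over all tables, a
#'   self-check equal to 1), `table`, `method`.
#' @examples
#' cyc <- rbind(c(3, 0), c(3, 0), c(3, 0), c(0, 3))
#' fisher_exact(cyc)$p  # 0.01818...
#' @export
fisher_exact <- function(table, max_total = 60) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers", call. = FALSE)
  }
  storage.mode(table) <- "integer"
  N <- sum(table)
  if (N > max_total) {
    stop("total count ", N, " exceeds the enumeration guard (", max_total,
         "); use fisher_exact_mc()", call. = FALSE)
  }
  rm_ <- rowSums(table); cm_ <- colSums(table)
  if (any(rm_ == 0) || any(cm_ == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  lp_obs <- log_table_prob(table)
  tol <- 1e-12
  p_sum <- 0; total <- 0; n_tab <- 0L
  enumerate_tables(rm_, cm_, function(tab) {
    lp <- log_table_prob(tab)
    pr <- exp(lp)
    total <<- total + pr
    n_tab <<- n_tab + 1L
    if (lp <= lp_obs + tol) p_sum <<- p_sum + pr
  })
  structure(list(p = p_sum, n_tables = n_tab, observed_prob = exp(lp_obs),
                 total_prob = total, table = table,
                 method = "full enumeration"),
            class = "fisher_exact")
}

#' Monte-Carlo exact test for large contingency tables
#'
#' Estimates the two-sided probability-ordering p-value by sampling tables
#' with the observed margins from the null (via [stats::r2dtable()]).
#'
#' @param table Non-negative integer matrix.
#' @param reps Number of sampled tables (default 10000; fewer than 1000
#'   triggers a warning).
#' @param seed Optional integer seed.
#' @return A `fisher_exact` object with `p` (the estimate, using the add-one
#'   rule so `p > 0`), `se` (binomial standard error), `reps`.
#' @export
fisher_exact_mc <- function(table, reps = 10000, seed = NULL) {
  table <- as.matrix(table)
  storage.mode(table) <- "integer"
  rm_ <- rowSums(table); cm_ <- colSums(table)
  if (any(rm_ == 0) || any(cm_ == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  if (reps < 1000) warning("reps < 1000: Monte-Carlo p-value will be imprecise")
  if (!is.null(seed)) set.seed(seed)
  lp_obs <- log_table_prob(table)
  tol <- 1e-12
  sims <- stats::r2dtable(reps, rm_, cm_)
  hits <- vapply(sims, function(tab) log_table_prob(tab) <= lp_obs + tol,
                 logical(1))
  p_hat <- (sum(hits) + 1) / (reps + 1)
  structure(list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / reps),
                 reps = reps, observed_prob = exp(lp_obs), table = table,
                 method = "Monte-Carlo (fixed margins)"),
            class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("Exact contingency test (", x$method, "): p =", signif(x$p, 4))
  if (!is.null(x$se)) cat(" (se", signif(x$se, 2), ")")
  cat("\n")
  invisible(x)
}

#' @rdname fisher_exact
#' @param x A `fisher_exact` object.
#' @param ... Ignored.
#' @method tidy fisher_exact
#' @export
tidy.fisher_exact <- function(x, ...) {
  tibble::tibble(p.value = x$p, observed_prob = x$observed_prob,
                 n_tables = if (is.null(x$n_tables)) NA_integer_ else x$n_tables,
                 method = x$method)
}

#' @rdname factorial_lm
#' @param x A `gc_anova` tibble.
#' @param ... Ignored.
#' @method tidy gc_anova
#' @export
tidy.gc_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Treatment-level mean with a 95\% t confidence interval
#' @noRd
mean_ci <- function(x, level = 0.95) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x, na.rm = TRUE) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Study-level statistical report
#'
#' Assembles the treatment-level battery for a study: per-treatment means of
#' the descriptive measures with 95% t confidence intervals, minimal
#' adequate factorial models for adult mean, larval mean, adult CV and the
#' 5th-instar proportion (persisting populations only), and the exact test
#' of the cycling-by-treatment pattern.
#'
#' @param census A census tibble (already truncated).
#' @param calls Cycle calls from [classify_study()]; when `NULL` the
#'   contingency part is omitted.
#' @param alpha Simplification threshold for [factorial_lm()].
#' @return Object of class `study_report`: `populations` (per-population
#'   measures), `treatment_means`, `anova` (named list of `gc_anova`),
#'   `cycling_table`, `fisher` (`fisher_exact` or NULL).
#' @export
summarize_study <- function(census, calls = NULL, alpha = 0.05) {
  pops <- population_summary(census)
  persist <- dplyr::filter(pops, !.data$extinct)

  measures <- intersect(c("mean_adults", "mean_larvae", "cv_adults", "p5"),
                        names(persist))
  measures <- measures[vapply(measures,
                              function(m) any(is.finite(persist[[m]])),
                              logical(1))]
  names(measures) <- measures
  anovas <- purrr::map(measures, function(m) {
    tryCatch(factorial_lm(persist, m, alpha = alpha), error = function(e) NULL)
  })

  long <- tidyr::pivot_longer(persist, dplyr::all_of(unname(measures)),
                              names_to = "measure", values_to = "value")
  tmeans <- dplyr::summarise(
    dplyr::group_by(long, .data$temperature_C, .data$diet, .data$measure),
    n = sum(!is.na(.data$value)),
    mean = mean_ci(.data$value)[["mean"]],
    ci_lo = mean_ci(.data$value)[["lo"]],
    ci_hi = mean_ci(.data$value)[["hi"]],
    .groups = "drop"
  )

  cyc_tab <- NULL; fe <- NULL
  if (!is.null(calls) && nrow(calls) > 0) {
    cyc_tab <- cycling_pattern(calls)
    if (all(rowSums(cyc_tab) > 0) && all(colSums(cyc_tab) > 0)) {
      fe <- fisher_exact(cyc_tab)
    }
  }

  structure(list(populations = pops, treatment_means = tmeans,
                 anova = anovas, cycling_table = cyc_tab, fisher = fe),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", nrow(x$populations), "populations,",
      sum(!x$populations$extinct), "persisting\n\n")
  cat("Treatment means (95% CI):\n")
  print(as.data.frame(x$treatment_means), digits = 3)
  for (m in names(x$anova)) {
    if (is.null(x$anova[[m]])) next
    cat("\nMinimal adequate model for", m, ":\n")
    print(as.data.frame(x$anova[[m]]), digits = 3)
  }
  if (!is.null(x$fisher)) {
    cat("\nCycling pattern:\n")
    print(x$cycling_table)
    print(x$fisher)
  }
  invisible(x)
}
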