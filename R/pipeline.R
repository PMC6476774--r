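#' Pipeline configuration
#'
#' Builds the configuration object for [run_pipeline()]. All analysis
#' settings are gathered here; per-stage seeds are derived deterministically
#' from `seed`, so stages can be rerun independently yet reproducibly.
#'
#' @param input Path to a census CSV, or `NULL` to simulate a full study.
#' @param seed Master integer seed.
#' @param weeks,larval_weeks Spans used when simulating (defaults 82 / 62).
#' @param n_drop Initial transient weeks removed before analysis (default 10).
#' @param reps,quantile,band,taper Spectral settings (see [mc_threshold()]
#'   and [classify_cycle()]).
#' @param span,dj,nsim,alpha_wavelet Wavelet settings (see
#'   [wavelet_analysis()]).
#' @param alpha Simplification threshold for the treatment models.
#' @param run_wavelet Compute wavelet spectra (default `TRUE`; the slowest
#'   stage)?
#' @return A named list of class `gc_config`.
#' @export
pipeline_config <- function(input = NULL, seed = 1, weeks = 82,
                            larval_weeks = 62, n_drop = 10, reps = 10000,
                            quantile = 0.95, band = c(5, 7), taper = 0,
                            span = 0.4, dj = 1 / 20, nsim = 100,
                            alpha_wavelet = 0.05, alpha = 0.05,
                            run_wavelet = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "gc_config"
  cfg
}

#' Read / write a pipeline configuration as plain text
#'
#' Configurations serialise to YAML so runs can be driven from a
#' version-controlled text file.
#'
#' @param path File path.
#' @param cfg A `gc_config`.
#' @return `read_config()` returns a `gc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: load or simulate a study, drop initial
#' transients, run the spectral cycle classification and (optionally) the
#' wavelet analysis per persisting population, fit the treatment-level
#' models, and write all artifacts plus a machine-readable manifest to
#' `out_dir`. Identical configuration and seed give byte-identical outputs.
#'
#' @param cfg A `gc_config` from [pipeline_config()] (or a path to a YAML
#'   config).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress lines?
#' @return Invisibly, a list with the in-memory results: `census`,
#'   `truncated`, `calls`, `ridges`, `report`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "gc_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[gencycles] ", ...)
  t0 <- Sys.time()

  if (is.null(cfg$input)) {
    say("simulating full factorial study (seed ", cfg$seed, ")")
    census <- generate_study(seed = cfg$seed, weeks = cfg$weeks,
                             larval_weeks = cfg$larval_weeks)
  } else {
    say("reading census from ", cfg$input)
    census <- read_census(cfg$input)
  }
  write_census(census, file.path(out_dir, "census.csv"))

  trunc <- truncate_transients(census, n_drop = cfg$n_drop)
  ext <- detect_extinctions(trunc)
  say(sum(ext$extinct), " extinct population(s) excluded from dynamics analyses")

  pops <- split_populations(trunc)
  persisting <- names(pops)[!ext$extinct[match(names(pops), pop_label(ext))]]

  spec_dir <- file.path(out_dir, "periodograms")
  dir.create(spec_dir, showWarnings = FALSE)
  calls <- list()
  ridges <- list()
  for (label in persisting) {
    p <- pops[[label]]
    x <- p$adults_female + p$adults_male
    s_seed <- derive_seed(cfg$seed, paste0("spec_", label))
    pg <- cycle_spectrum(x, reps = cfg$reps, q = cfg$quantile, seed = s_seed,
                         taper = cfg$taper)
    readr::write_csv(tibble::as_tibble(pg), file.path(spec_dir, paste0(label, ".csv")))
    calls[[label]] <- dplyr::bind_cols(p[1, treatment_cols],
                                       classify_cycle(pg, band = cfg$band))
    if (isTRUE(cfg$run_wavelet)) {
      w_seed <- derive_seed(cfg$seed, paste0("wav_", label))
      ws <- wavelet_analysis(x, span = cfg$span, dj = cfg$dj,
                             nsim = cfg$nsim, alpha = cfg$alpha_wavelet,
                             seed = w_seed)
      write_wavelet(ws, file.path(out_dir, "wavelets"), label)
      ridges[[label]] <- summarize_ridge(ws, band = cfg$band)
    }
    say("analysed ", label, " (", signif(difftime(Sys.time(), t0, units = "secs"), 3),
        "s elapsed)")
  }
  calls <- dplyr::bind_rows(calls)
  readr::write_csv(calls, file.path(out_dir, "cycle_calls.csv"))

  report <- summarize_study(trunc, calls, alpha = cfg$alpha)
  readr::write_csv(report$populations, file.path(out_dir, "population_summary.csv"))
  readr::write_csv(report$treatment_means, file.path(out_dir, "treatment_means.csv"))
  sink(file.path(out_dir, "report.txt")); print(report); sink()

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "input")],
    n_populations = length(pops),
    n_persisting = length(persisting),
    files = lapply(stats::setNames(files, sub(paste0("^", out_dir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", length(files), " artifact(s) in ", out_dir)
  invisible(list(census = census, truncated = trunc, calls = calls,
                 ridges = ridges, report = report, manifest = manifest))
}

# wavelet power + mask as delimited text (rows = periods, cols = weeks) with
# a JSON sidecar holding the grids
write_wavelet <- function(ws, dir, label) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(ws$power), file.path(dir, paste0(label, "_power.tsv")),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(ws$signif_mask)) {
    utils::write.table(t(ws$signif_mask) * 1L,
                       file.path(dir, paste0(label, "_mask.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(times = ws$times, periods = ws$periods, coi = ws$coi,
         dt = ws$dt, dj = ws$dj, omega0 = ws$omega0, alpha = ws$alpha),
    file.path(dir, paste0(label, "_grid.json")), auto_unbox = TRUE, digits = NA
  )
  invisible(NULL)
}

#' Write small deterministic census fixtures
#'
#' Generates the miniature census files used by the test suite and examples:
#' negative-binomial white noise, a strong 6-week cycle, and a mixed series
#' with both a generation cycle and a slow component. Byte-identical for a
#' given seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed (default 42).
#' @return Named character vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    white_noise = list(A6 = 0, A_long = 0),
    pure_cycle = list(A6 = 0.8, A_long = 0),
    mixed = list(A6 = 0.6, A_long = 0.3)
  )
  paths <- purrr::imap_chr(specs, function(sp, nm) {
    cen <- generate_phenom(mu = 100, k = 20, A6 = sp$A6, A_long = sp$A_long,
                           n_weeks = 72, seed = derive_seed(seed, nm))
    path <- file.path(dir, paste0(nm, ".csv"))
    write_census(cen, path, comment = paste0("fixture ", nm, " seed ", seed))
    path
  })
  paths
}
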