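# Evaluate a pipeline stage; any failure aborts with the stage name.
#' @keywords internal
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Write a simulated registry bundle to disk
#'
#' Writes the counts, population and life-table CSVs in exactly the
#' schemas the readers expect, plus the truth report, so a synthetic run
#' can exercise the full file-based pipeline.
#'
#' @param sim A `registry_sim` from [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_registry_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "registry_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             population = file.path(dir, "population.csv"),
             life_table = file.path(dir, "life_table.csv"),
             truth = file.path(dir, "truth.csv"))
  write_counts(sim$counts, paths["counts"])
  write_population(sim$population, paths["population"])
  write_life_table(sim$life_table, paths["life_table"])
  utils::write.csv(sim$truth_report, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Run the full prevalence-modelling pipeline
#'
#' Orchestrates every stage on file inputs: reads the counts, population
#' and life-table CSVs, fits the hospital prevalence model
#' ([dcm_prevalence()]), reformats it onto the coarse comparison scheme,
#' extrapolates the SCC-derived estimate when the config carries an SCC
#' curve and conversion rates, compares the two, builds the cohort table,
#' and writes every result as CSV together with age-profile plots and a
#' reproducibility manifest. Any stage failure aborts with a stage-named
#' error. Plotting failures degrade to CSV-only output with a warning:
#' the tables are the results, the figures a convenience.
#'
#' @param config A `run_config` (from [read_run_config()]) or a YAML path.
#' @param counts_path,population_path,life_table_path Input CSVs
#'   ([read_counts()] / [read_population()] / [read_life_table()]
#'   schemas).
#' @param out_dir Output directory, created if needed.
#' @param setting Care-setting tag of the counts file.
#' @param bands Fine band scheme; default [fine_bands()].
#' @param coarse Coarse comparison scheme; default [coarse_bands()].
#' @return Invisibly, a list with the fitted model (`fit`), the coarse
#'   tables, the comparison (or `NULL` without SCC config), the cohort
#'   table and the manifest. Output files: `incidence.csv`,
#'   `prevalence_fine.csv`, `prevalence_coarse.csv`, `scc_prevalence.csv`,
#'   `comparison.csv`, `cohort.csv`, `manifest.json`, and
#'   `prevalence_age_profile.png` / `comparison.png` plots.
#' @export
run_pipeline <- function(config, counts_path, population_path,
                         life_table_path, out_dir,
                         setting = c("fce", "admission", "outpatient"),
                         bands = fine_bands(), coarse = coarse_bands()) {
  setting <- match.arg(setting)
  if (is.character(config))
    config <- stage("config", read_run_config(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in c(counts_path, population_path, life_table_path))
    if (!file.exists(p)) stop("stage [inputs]: input file not found: ", p,
                              call. = FALSE)

  counts <- stage("read counts",
                  read_counts(counts_path, setting, years = config$years,
                              bands = bands,
                              fill_missing = config$fill_missing))
  population <- stage("read population",
                      read_population(population_path,
                                      years = config$years, bands = bands))
  schedule <- stage("read life table", read_life_table(life_table_path))

  fit <- stage("prevalence model",
               dcm_prevalence(counts, population, schedule,
                              smr = config$smr, bands = bands,
                              ci_method = config$ci_method))
  fine_tab <- as.data.frame(fit)
  coarse_tab <- stage("rebin",
                      rebin_prevalence(fit$prevalence, bands, coarse))

  scc <- comparison <- NULL
  if (!is.null(config$scc_curve) && !is.null(config$conversion)) {
    rates <- conversion_rates(config$conversion$pooled,
                              config$conversion$lower,
                              config$conversion$upper)
    scc_native <- stage("scc extrapolation",
                        extrapolate_scc(config$scc_curve, rates))
    scc <- stage("scc rebin", {
      if (identical(names(config$scc_curve), band_labels(coarse)))
        scc_native$pooled
      else {
        native <- lapply(names(config$scc_curve), parse_band_label)
        rebin_prevalence(scc_native$pooled, native, coarse)
      }
    })
    comparison <- stage("comparison", compare_prevalence(coarse_tab, scc))
  }

  per_year <- attr(fit$incidence, "per_year")
  dur <- fit$duration[match(per_year$age_band, fit$incidence$age_band)]
  cohort <- stage("cohort table", cohort_table(
    data.frame(year = per_year$year, age_band = per_year$age_band,
               prevalence = extrapolate_prevalence(per_year$rate, dur)),
    bands))

  out <- function(f) file.path(out_dir, f)
  utils::write.csv(as.data.frame(fit$incidence), out("incidence.csv"),
                   row.names = FALSE)
  utils::write.csv(fine_tab, out("prevalence_fine.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(coarse_tab), out("prevalence_coarse.csv"),
                   row.names = FALSE)
  if (!is.null(scc))
    utils::write.csv(as.data.frame(scc), out("scc_prevalence.csv"),
                     row.names = FALSE)
  if (!is.null(comparison))
    utils::write.csv(as.data.frame(comparison), out("comparison.csv"),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(cohort), out("cohort.csv"),
                   row.names = FALSE)

  tryCatch({
    grDevices::png(out("prevalence_age_profile.png"), width = 900,
                   height = 600)
    plot(fit)
    grDevices::dev.off()
    if (!is.null(comparison)) {
      grDevices::png(out("comparison.png"), width = 900, height = 600)
      plot_comparison(comparison)
      grDevices::dev.off()
    }
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warning("plotting failed (", conditionMessage(e),
            "); tables written without figures")
  })

  manifest <- list(
    package = "dcmprev",
    version = as.character(utils::packageVersion("dcmprev")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    setting = setting,
    config = config[setdiff(names(config), NULL)],
    inputs = list(counts = unname(tools::md5sum(counts_path)),
                  population = unname(tools::md5sum(population_path)),
                  life_table = unname(tools::md5sum(life_table_path))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)

  invisible(list(fit = fit, coarse = coarse_tab, scc = scc,
                 comparison = comparison, cohort = cohort,
                 manifest = manifest))
}

#' Grouped-bar comparison of the two prevalence estimates
#'
#' @param comparison A `prevalence_comparison` from [compare_prevalence()].
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_comparison <- function(comparison, ...) {
  h <- 100 * comparison$hospital
  s <- 100 * comparison$scc
  m <- rbind(hospital = h, scc = s)
  mids <- graphics::barplot(m, beside = TRUE,
                            names.arg = comparison$age_band,
                            ylab = "Prevalence (% of population)",
                            xlab = "Age group",
                            ylim = c(0, 1.1 * max(100 * comparison$scc_high)),
                            legend.text = c("Hospital-derived",
                                            "SCC-derived"), ...)
  graphics::arrows(mids[1, ], 100 * comparison$hospital_low,
                   mids[1, ], 100 * comparison$hospital_high,
                   angle = 90, code = 3, length = 0.03)
  graphics::arrows(mids[2, ], 100 * comparison$scc_low,
                   mids[2, ], 100 * comparison$scc_high,
                   angle = 90, code = 3, length = 0.03)
  invisible(mids)
}
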