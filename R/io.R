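#' Read a cohort table from CSV
#'
#' Documented dialect: header row, UTF-8, dot decimal separator. Required
#' columns: `individual_id`, `population_id`, `sex` (male/female),
#' `svl_mm`, `latitude_utm`, either `capture_day` (1-365) or `capture_date`
#' (ISO-8601, converted through [julian_day]), `wbc_cells_per_ul`, and the
#' differential either as fractions in the [leukocyte_classes] columns or as
#' percentages in `pct_<class>` columns (converted to fractions internally —
#' percentages only reappear at reporting).
#'
#' @param path CSV file path.
#' @return Cohort data frame ready for [cosinor_lmm].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (file.size(path) == 0) stop("cohort file is empty: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("cohort file has a header but no rows: ", path)
  need <- c("individual_id", "population_id", "sex", "svl_mm", "latitude_utm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"capture_day" %in% names(d)) {
    if (!"capture_date" %in% names(d))
      stop("cohort file is missing required column(s): capture_day (or capture_date)")
    d$capture_day <- julian_day(d$capture_date)
  }
  pct <- paste0("pct_", leukocyte_classes)
  if (all(pct %in% names(d))) {
    d[leukocyte_classes] <- d[pct] / 100
    d[pct] <- NULL
  }
  num_cols <- intersect(c("svl_mm", "capture_day", "latitude_utm",
                          "wbc_cells_per_ul", leukocyte_classes), names(d))
  for (cl in num_cols) {
    bad <- which(is.na(suppressWarnings(as.numeric(d[[cl]]))))
    if (length(bad))
      stop("malformed numeric values in column '", cl, "', data row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    d[[cl]] <- as.numeric(d[[cl]])
  }
  d$capture_day <- as.integer(d$capture_day)
  d
}

#' Write a cohort table to CSV at full precision
#'
#' Numeric fields are serialized with enough digits for a lossless
#' write-then-read round trip.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- cohort
  for (cl in names(d)) {
    if (is.numeric(d[[cl]]) && !is.integer(d[[cl]]))
      d[[cl]] <- sprintf("%.17g", d[[cl]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a reference-interval table
#'
#' One row per variable x sex: mode, lower and upper 95% bounds, units.
#'
#' @param ri_list List of [reference_interval] objects.
#' @return Data frame mirroring the standard blood-values table layout.
#' @export
ri_table <- function(ri_list) {
  do.call(rbind, lapply(ri_list, function(r) {
    data.frame(variable = r$variable %||% NA, sex = r$sex %||% NA,
               mode = r$mode, lower = r$lower, upper = r$upper,
               level = r$level, units = r$units %||% NA,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reference-interval table
#'
#' The machine table keeps full precision; [format_ri_table] renders the
#' human-readable one-decimal display (`mode (lower-upper)`).
#'
#' @param tab Data frame from [ri_table].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ri_table <- function(tab, path) {
  out <- tab
  for (cl in c("mode", "lower", "upper"))
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ri_table
#' @param digits Decimals for the display table (default 1, matching how
#'   percentages are conventionally reported).
#' @export
format_ri_table <- function(tab, digits = 1) {
  data.frame(variable = tab$variable, sex = tab$sex,
             value = sprintf(paste0("%.", digits, "f (%.", digits,
                                    "f-%.", digits, "f)"),
                             tab$mode, tab$lower, tab$upper),
             units = tab$units, stringsAsFactors = FALSE)
}

#' Write a contrasts table
#'
#' @param contrasts Named list of `posterior_contrast` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_contrasts <- function(contrasts, path) {
  tab <- do.call(rbind, lapply(contrasts, function(ct) {
    data.frame(contrast = ct$label %||% NA, mean = sprintf("%.17g", ct$mean),
               sd = sprintf("%.17g", ct$sd),
               prob_positive = sprintf("%.17g", ct$prob_positive),
               prob_negative = sprintf("%.17g", ct$prob_negative),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate the default
#'   study design.
#' @param responses Responses to model (default all five).
#' @param prior A [prior_spec].
#' @param mcmc An [mcmc_config].
#' @param ri_level Reference-interval coverage level in (0, 1).
#' @param new_population Include a fresh population effect in predictive
#'   draws (default `TRUE`).
#' @param output_dir Directory for the output bundle.
#' @param seed Run seed, recorded in the manifest and every derived seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, responses = .responses,
                            prior = prior_spec(), mcmc = mcmc_config(),
                            ri_level = 0.95, new_population = TRUE,
                            output_dir = "leukoRI-run", seed = 1) {
  responses <- match.arg(responses, .responses, several.ok = TRUE)
  if (ri_level <= 0 || ri_level >= 1) stop("'ri_level' must be in (0, 1)")
  structure(list(input = input, responses = responses, prior = prior,
                 mcmc = mcmc, ri_level = ri_level,
                 new_population = new_population,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config] arguments; `prior` and
#' `mcmc` may be nested maps of their respective hyperparameters.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    input = x$input,
    responses = x$responses %||% .responses,
    prior = do.call(prior_spec, x$prior %||% list()),
    mcmc = do.call(mcmc_config, x$mcmc %||% list()),
    ri_level = x$ri_level %||% 0.95,
    new_population = x$new_population %||% TRUE,
    output_dir = x$output_dir %||% "leukoRI-run",
    seed = x$seed %||% 1)
}
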