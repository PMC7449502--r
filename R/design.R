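#' Standardize a covariate, keeping center and scale
#'
#' z-scores `(x - mean(x)) / sd(x)`, returning the center and scale so that
#' prediction-time inputs can be placed on the same scale as the training
#' sample. Standardization is computed on the pooled modeled sample (both
#' sexes together).
#'
#' @param values Numeric vector with at least two distinct values.
#' @param center,scale Optional pre-computed center/scale to reuse.
#' @return List with `z`, `center`, `scale`.
#' @export
standardize <- function(values, center = NULL, scale = NULL) {
  if (anyNA(values)) stop("'values' contains missing data")
  if (is.null(center) || is.null(scale)) {
    if (length(unique(values)) < 2L)
      stop("cannot standardize: fewer than 2 distinct values (zero variance)")
    center <- mean(values)
    scale <- stats::sd(values)
  }
  if (scale <= 0) stop("cannot standardize: zero variance")
  list(z = (values - center) / scale, center = center, scale = scale)
}

.design_cols <- c("intercept", "cos_t", "sin_t", "sex_f", "std_svl", "std_lat",
                  "cos_t_sex", "sin_t_sex", "cos_t_svl", "sin_t_svl",
                  "cos_t_lat", "sin_t_lat")

.responses <- c("log_wbc", "ilr1", "ilr2", "ilr3", "ilr4")

#' Build the cosinor mixed-model design matrix
#'
#' Assembles the fixed-effect design for one hematological response: an
#' intercept (the MESOR), cosine and sine terms of the circannual cosinor,
#' a female indicator (male is the reference level, so the sex coefficient is
#' the female-minus-male contrast), standardized snout-vent length,
#' standardized latitude (UTM northing), and the cosinor-by-sex, -size and
#' -latitude interactions. The response is log(WBC) or one of the four ilr
#' coordinates of the leukocyte differential (zeros replaced multiplicatively
#' before the transform). Rows are grouped by population for the random
#' intercept.
#'
#' @param cohort Cohort data frame; see [read_cohort] for the expected
#'   columns.
#' @param response One of `"log_wbc"`, `"ilr1"`..`"ilr4"`.
#' @param period_days Cosinor period (default 365).
#' @param basis ilr contrast basis (default [ilr_basis] on 5 parts).
#' @param delta Zero-replacement fraction passed to [replace_zeros].
#' @param standardization Optional list with `svl`/`lat` center+scale to
#'   reuse (for fitting several responses on identical covariates).
#' @param check_rank Verify full column rank (default `TRUE`; prediction-time
#'   designs for a handful of rows skip the check).
#' @return List with the design matrix `X` (columns in the fixed documented
#'   order), response vector `y`, `group` factor of populations,
#'   `standardization` (centers/scales and observed ranges), `basis`,
#'   `period_days` and `response`.
#' @export
build_design <- function(cohort, response = "log_wbc", period_days = 365,
                         basis = ilr_basis(5), delta = 0.65 / 150,
                         standardization = NULL, check_rank = TRUE) {
  response <- match.arg(response, .responses)
  need <- c("individual_id", "population_id", "sex", "svl_mm", "capture_day",
            "latitude_utm")
  need <- c(need, if (response == "log_wbc") "wbc_cells_per_ul" else leukocyte_classes)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(cohort[need]))
  if (length(bad))
    stop("missing covariate values in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  if (!all(cohort$sex %in% c("male", "female")))
    stop("'sex' must be coded \"male\"/\"female\"")
  if (any(cohort$svl_mm <= 0)) stop("'svl_mm' must be positive")

  if (is.null(standardization)) {
    s_svl <- standardize(cohort$svl_mm)
    s_lat <- standardize(cohort$latitude_utm)
    standardization <- list(
      svl = list(center = s_svl$center, scale = s_svl$scale,
                 range = range(cohort$svl_mm)),
      lat = list(center = s_lat$center, scale = s_lat$scale,
                 range = range(cohort$latitude_utm)))
  } else {
    s_svl <- standardize(cohort$svl_mm, standardization$svl$center,
                         standardization$svl$scale)
    s_lat <- standardize(cohort$latitude_utm, standardization$lat$center,
                         standardization$lat$scale)
  }

  cs <- cosinor_regressors(cohort$capture_day, period_days)
  sex_f <- as.numeric(cohort$sex == "female")
  X <- cbind(intercept = 1, cos_t = cs[, "cos_t"], sin_t = cs[, "sin_t"],
             sex_f = sex_f, std_svl = s_svl$z, std_lat = s_lat$z,
             cos_t_sex = cs[, "cos_t"] * sex_f,
             sin_t_sex = cs[, "sin_t"] * sex_f,
             cos_t_svl = cs[, "cos_t"] * s_svl$z,
             sin_t_svl = cs[, "sin_t"] * s_svl$z,
             cos_t_lat = cs[, "cos_t"] * s_lat$z,
             sin_t_lat = cs[, "sin_t"] * s_lat$z)

  if (check_rank && qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient on the supplied data")

  if (response == "log_wbc") {
    if (any(cohort$wbc_cells_per_ul <= 0))
      stop("'wbc_cells_per_ul' must be positive for log transformation")
    y <- log(cohort$wbc_cells_per_ul)
  } else {
    parts <- as.matrix(cohort[leukocyte_classes])
    parts <- close_composition(parts)
    if (any(parts == 0)) parts <- replace_zeros(parts, delta)
    k <- as.integer(substring(response, 4))
    y <- ilr(parts, basis)[, k]
  }

  list(X = X, y = as.numeric(y),
       group = factor(cohort$population_id),
       standardization = standardization,
       basis = basis, period_days = period_days, response = response)
}
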