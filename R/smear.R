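#' Leukocyte class order
#'
#' Fixed class order used throughout the package for the five-part leukocyte
#' differential: lymphocytes, monocytes, eosinophils, heterophils, basophils.
#' Heterophils are the reptilian/avian analogue of mammalian neutrophils.
#'
#' @format Character vector of length 5.
#' @export
leukocyte_classes <- c("lymphocytes", "monocytes", "eosinophils",
                       "heterophils", "basophils")

#' Construct a blood-smear count record
#'
#' A smear record holds per-individual leukocyte tallies from light-microscopy
#' scanning of a stained blood film: the number of microscope fields examined,
#' the per-class cell counts, and the objective power of the lens.
#'
#' @param individual_id Identifier for the sampled individual.
#' @param n_fields Number of microscope fields examined (integer >= 0).
#' @param class_counts Numeric vector of 5 non-negative integer counts in the
#'   order given by [leukocyte_classes].
#' @param objective_power Magnification of the objective lens (default 60).
#' @return An object of class `smear_record`.
#' @examples
#' rec <- smear_record("L001", 50, c(120, 10, 10, 5, 5))
#' estimate_wbc(rec)
#' @export
smear_record <- function(individual_id, n_fields, class_counts,
                         objective_power = 60) {
  n_fields <- as.integer(n_fields)
  if (length(n_fields) != 1L || is.na(n_fields) || n_fields < 0L)
    stop("'n_fields' must be a single non-negative integer")
  if (length(class_counts) != 5L)
    stop("'class_counts' must have length 5 (", paste(leukocyte_classes, collapse = ", "), ")")
  if (anyNA(class_counts) || any(class_counts < 0))
    stop("'class_counts' must be non-negative")
  if (any(abs(class_counts - round(class_counts)) > 1e-8))
    stop("'class_counts' must be whole numbers")
  if (length(objective_power) != 1L || is.na(objective_power) || objective_power <= 0)
    stop("'objective_power' must be a single positive number")
  class_counts <- as.numeric(round(class_counts))
  names(class_counts) <- leukocyte_classes
  structure(
    list(individual_id = individual_id,
         n_fields = n_fields,
         class_counts = class_counts,
         total_leukocytes = sum(class_counts),
         objective_power = as.numeric(objective_power)),
    class = "smear_record")
}

#' @export
print.smear_record <- function(x, ...) {
  cat("Blood-smear record:", x$individual_id, "\n")
  cat("  fields examined:", x$n_fields,
      " total leukocytes:", x$total_leukocytes,
      " objective:", paste0(x$objective_power, "x"), "\n")
  print(x$class_counts)
  invisible(x)
}

#' Estimate total white blood cell concentration from a smear
#'
#' WBC (cells/microliter) is estimated as the mean number of leukocytes per
#' microscope field multiplied by the square of the objective power.
#'
#' @param record A [smear_record].
#' @return Estimated WBC in cells/microliter.
#' @examples
#' estimate_wbc(smear_record("a", 50, c(40, 5, 2, 2, 1)))
#' @export
estimate_wbc <- function(record) {
  stopifnot(inherits(record, "smear_record"))
  if (record$n_fields == 0L)
    stop("cannot estimate WBC: zero fields examined (mean per field undefined)")
  (record$total_leukocytes / record$n_fields) * record$objective_power^2
}

#' Check the smear counting stopping rule
#'
#' Counting continues until at least `min_fields` microscope fields have been
#' examined and at least `min_total` leukocytes tallied; records below either
#' floor represent incomplete counting.
#'
#' @param n_fields Number of fields examined.
#' @param total_leukocytes Total leukocytes tallied.
#' @param min_fields Minimum fields required (default 50).
#' @param min_total Minimum leukocytes required (default 150).
#' @return Logical: `TRUE` iff both floors are met. Vectorized.
#' @export
counting_rule_satisfied <- function(n_fields, total_leukocytes,
                                    min_fields = 50, min_total = 150) {
  if (any(n_fields < 0) || any(total_leukocytes < 0))
    stop("counts must be non-negative")
  n_fields >= min_fields & total_leukocytes >= min_total
}

#' Minimum detectable class frequency under a counting floor
#'
#' The smallest relative frequency representable by a single cell among
#' `min_total` counted leukocytes, as a percentage rounded to one decimal.
#' With the default 150-cell floor this is 0.7%.
#'
#' @param min_total Minimum total leukocyte count mandated by the counting
#'   rule (default 150).
#' @return Percentage, rounded to one decimal place.
#' @examples
#' min_detectable_frequency(150)
#' @export
min_detectable_frequency <- function(min_total = 150) {
  if (length(min_total) != 1L || is.na(min_total) || min_total <= 0)
    stop("'min_total' must be a single positive count")
  round(100 / min_total, 1)
}

#' Leukocyte differential composition from smear counts
#'
#' Divides the class tallies by the total leukocyte count, giving the five
#' relative abundances (closed composition, before any zero replacement).
#'
#' @param record A [smear_record].
#' @return Named numeric vector of 5 fractions summing to 1, with attribute
#'   `has_zeros` flagging classes not observed on the smear.
#' @export
differential_from_counts <- function(record) {
  stopifnot(inherits(record, "smear_record"))
  if (record$total_leukocytes <= 0)
    stop("cannot form a differential: zero leukocytes counted")
  parts <- record$class_counts / record$total_leukocytes
  attr(parts, "has_zeros") <- any(parts == 0)
  parts
}

#' Read smear records from a CSV file
#'
#' Expects columns `individual_id`, `n_fields`, the five class-count columns
#' named as in [leukocyte_classes], and optionally `objective_power`
#' (defaulting to 60 when absent).
#'
#' @param path Path to a CSV file, one row per smear.
#' @param strict If `TRUE`, rows failing the counting rule are dropped with a
#'   warning; otherwise they are kept and flagged in the `rule_ok` column.
#' @return A data frame with one row per smear and a logical `rule_ok` column.
#' @export
read_smears <- function(path, strict = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "n_fields", leukocyte_classes)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("smear file is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"objective_power" %in% names(d)) d$objective_power <- 60
  d$total_leukocytes <- rowSums(d[leukocyte_classes])
  d$rule_ok <- counting_rule_satisfied(d$n_fields, d$total_leukocytes)
  if (strict && any(!d$rule_ok)) {
    warning(sum(!d$rule_ok), " smear(s) failing the counting rule dropped (strict mode)")
    d <- d[d$rule_ok, , drop = FALSE]
  }
  d
}
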