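#' Total sequencing depth needed for a target number of microbial reads
#'
#' If a fraction `percent/100` of a library's reads is microbial, reaching
#' `target_microbial_reads` microbial reads needs
#' `ceiling(target / (percent/100))` total reads. The ceiling guarantees the
#' target is met rather than approximated.
#'
#' @param percent_microbial Predicted percent microbial reads, in `(0, 100]`.
#' @param target_microbial_reads Desired microbial read count (default 1e6,
#'   a depth adequate for common alpha-diversity analyses).
#' @return Required total read count(s).
#' @export
required_total_reads <- function(percent_microbial,
                                 target_microbial_reads = 1e6) {
  if (any(!is.finite(percent_microbial)) || any(percent_microbial <= 0)) {
    stop("sample predicted to contain no microbial DNA at detectable level ",
         "(percent_microbial must be > 0)", call. = FALSE)
  }
  if (any(percent_microbial > 100)) {
    stop("percent_microbial must be <= 100", call. = FALSE)
  }
  if (any(target_microbial_reads < 1)) {
    stop("target_microbial_reads must be >= 1", call. = FALSE)
  }
  ceiling(target_microbial_reads / (percent_microbial / 100))
}

.plan_one <- function(record, model, target, budget, level) {
  pred <- predict_percent_microbial(model, record, level = level)
  warnings <- character()
  if (!pred$in_validity_range) warnings <- c(warnings, "low_validity")
  if (pred$extrapolated) warnings <- c(warnings, "extrapolated")
  required <- required_total_reads(pred$percent_microbial, target)
  feasible <- if (is.null(budget)) NA else required <= budget
  data.frame(sample_id = record$sample_id,
             percent_microbial = pred$percent_microbial,
             lower_bound_95 = pred$lower_bound_95,
             required_total_reads = required,
             feasible_within_budget = feasible,
             warnings = paste(warnings, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Plan sequencing depth for one sample
#'
#' Chains composition prediction and [required_total_reads()], carrying the
#' prediction's validity and extrapolation flags into the plan's warnings.
#'
#' @param record A one-row `sample_records` data frame.
#' @param model A `calibration_model`.
#' @param target_microbial_reads Target microbial read count (default 1e6).
#' @param read_budget Optional available total reads for this sample; when
#'   given, `feasible_within_budget` reports whether the requirement fits.
#' @param level One-tailed bound level passed to prediction.
#' @return One-row data frame: `sample_id`, `percent_microbial`,
#'   `lower_bound_95`, `required_total_reads`, `feasible_within_budget`,
#'   `warnings`.
#' @export
plan_sample <- function(record, model, target_microbial_reads = 1e6,
                        read_budget = NULL, level = 0.95) {
  if (target_microbial_reads < 1) {
    stop("target_microbial_reads must be >= 1", call. = FALSE)
  }
  stopifnot(nrow(record) == 1)
  .plan_one(record, model, target_microbial_reads, read_budget, level)
}

#' Plan sequencing depth for a batch of samples
#'
#' One plan row per record, in input order. A record whose prediction fails
#' (censored or missing Cts) produces an error row — `NA` estimates with a
#' `censored_input` warning and the failure message — instead of aborting
#' the rest of the batch.
#'
#' @inheritParams plan_sample
#' @param records A `sample_records` data frame.
#' @return Data frame with the [plan_sample()] columns plus `error`.
#' @export
batch_plan <- function(records, model, target_microbial_reads = 1e6,
                       read_budget = NULL, level = 0.95) {
  if (target_microbial_reads < 1) {
    stop("target_microbial_reads must be >= 1", call. = FALSE)
  }
  empty <- data.frame(sample_id = character(), percent_microbial = numeric(),
                      lower_bound_95 = numeric(),
                      required_total_reads = numeric(),
                      feasible_within_budget = logical(),
                      warnings = character(), error = character(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    tryCatch({
      row <- .plan_one(rec, model, target_microbial_reads, read_budget, level)
      row$error <- ""
      row
    }, error = function(e) {
      data.frame(sample_id = rec$sample_id, percent_microbial = NA_real_,
                 lower_bound_95 = NA_real_, required_total_reads = NA_real_,
                 feasible_within_budget = NA,
                 warnings = "censored_input",
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
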