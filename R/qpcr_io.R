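#' Default column mapping for qPCR Ct tables
#'
#' Plate-export dialects differ in column naming; a dialect maps the exporter's
#' column names onto the fields `read_ct_table()` needs, and lists the tokens
#' that mark an undetermined (censored-at-maximum) well.
#'
#' @param sample_id,sample_type,target,replicate,ct Column names in the input
#'   file holding each field.
#' @param undetermined_tokens Character vector of Ct cell values that denote a
#'   well which never crossed the fluorescence threshold.
#' @return A named list usable as the `dialect` argument of [read_ct_table()].
#' @export
ct_dialect <- function(sample_id = "sample_id", sample_type = "sample_type",
                       target = "target", replicate = "replicate", ct = "ct",
                       undetermined_tokens = c("Undetermined", "undetermined",
                                               "NA", "N/A", "")) {
  list(sample_id = sample_id, sample_type = sample_type, target = target,
       replicate = replicate, ct = ct,
       undetermined_tokens = undetermined_tokens)
}

.valid_targets <- c("16S", "18S", "ACTB")

#' Read a long-format qPCR cycle-threshold table
#'
#' Reads a CSV/TSV with one row per well (sample x target x replicate).
#' Undetermined wells are kept as censored-at-maximum measurements (`ct = NA`,
#' `censored = TRUE`) rather than dropped: a well that never amplified carries
#' information (no detectable target at `ct_max` cycles) and downstream models
#' refuse censored inputs explicitly instead of silently losing samples.
#'
#' @param source Path to a CSV or TSV file with a header row.
#' @param dialect Column mapping from [ct_dialect()].
#' @param ct_max Run-level maximum cycle number; the default 45 matches a
#'   45-cycle protocol. Numeric Cts must lie in `(0, ct_max]`.
#' @param sep Field separator; `NULL` (default) guesses from the file
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @return A data frame of class `ct_measurements` with columns `sample_id`,
#'   `sample_type`, `target` (one of `16S`, `18S`, `ACTB`), `replicate`,
#'   `ct` (numeric, `NA` when censored) and `censored` (logical); `ct_max`
#'   is stored as an attribute. Row order follows the file.
#' @export
read_ct_table <- function(source, dialect = ct_dialect(), ct_max = 45,
                          sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", source, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  needed <- c("sample_id", "sample_type", "target", "replicate", "ct")
  for (field in needed) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("ct table is missing mandatory column '", col %||% field,
           "' (field: ", field, ")", call. = FALSE)
    }
  }
  target <- toupper(raw[[dialect$target]])
  bad_target <- which(!target %in% .valid_targets)
  if (length(bad_target) > 0) {
    stop("unrecognized target '", raw[[dialect$target]][bad_target[1]],
         "' at row ", bad_target[1], "; expected one of ",
         paste(.valid_targets, collapse = ", "), call. = FALSE)
  }
  ct_chr <- raw[[dialect$ct]]
  censored <- ct_chr %in% dialect$undetermined_tokens | is.na(ct_chr)
  ct <- suppressWarnings(as.numeric(ct_chr))
  bad_ct <- which(!censored & is.na(ct))
  if (length(bad_ct) > 0) {
    stop("non-numeric Ct value '", ct_chr[bad_ct[1]], "' at row ", bad_ct[1],
         call. = FALSE)
  }
  out_of_range <- which(!censored & (ct <= 0 | ct > ct_max))
  if (length(out_of_range) > 0) {
    stop("Ct value ", ct[out_of_range[1]], " at row ", out_of_range[1],
         " outside (0, ", ct_max, "]", call. = FALSE)
  }
  ct[censored] <- NA_real_
  replicate <- suppressWarnings(as.integer(raw[[dialect$replicate]]))
  if (anyNA(replicate) || any(replicate < 1)) {
    stop("replicate indices must be positive integers", call. = FALSE)
  }
  out <- data.frame(sample_id = raw[[dialect$sample_id]],
                    sample_type = raw[[dialect$sample_type]],
                    target = target, replicate = replicate,
                    ct = ct, censored = censored,
                    stringsAsFactors = FALSE)
  attr(out, "ct_max") <- ct_max
  class(out) <- c("ct_measurements", class(out))
  out
}

#' Aggregate replicate wells into one Ct per sample and target
#'
#' Replicate Cts for the same (sample, target) pair are combined by the
#' arithmetic mean of the numeric replicates. Groups whose replicates disagree
#' by more than `discordance_limit` cycles are flagged `discordant_replicates`;
#' groups with no numeric replicate yield a censored aggregate flagged
#' `all_censored`.
#'
#' @param measurements A `ct_measurements` data frame from [read_ct_table()].
#' @param discordance_limit Maximum tolerated max-minus-min replicate spread,
#'   in cycles (default 1.0).
#' @return Data frame with one row per (sample_id, target): columns
#'   `sample_id`, `sample_type`, `target`, `ct`, `n_replicates`, `censored`,
#'   `flags` (semicolon-separated, empty when clean).
#' @export
aggregate_replicates <- function(measurements, discordance_limit = 1.0) {
  if (!is.numeric(discordance_limit) || length(discordance_limit) != 1 ||
      is.na(discordance_limit) || discordance_limit < 0) {
    stop("discordance_limit must be a single non-negative number",
         call. = FALSE)
  }
  if (nrow(measurements) == 0) {
    out <- data.frame(sample_id = character(), sample_type = character(),
                      target = character(), ct = numeric(),
                      n_replicates = integer(), censored = logical(),
                      flags = character(), stringsAsFactors = FALSE)
    attr(out, "ct_max") <- attr(measurements, "ct_max")
    return(out)
  }
  key <- paste(measurements$sample_id, measurements$target, sep = "\r")
  groups <- split(seq_len(nrow(measurements)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    m <- measurements[idx, , drop = FALSE]
    numeric_ct <- m$ct[!m$censored]
    flags <- character()
    if (length(numeric_ct) == 0) {
      ct <- NA_real_
      flags <- c(flags, "all_censored")
    } else {
      ct <- mean(numeric_ct)
      if (length(numeric_ct) > 1 &&
          max(numeric_ct) - min(numeric_ct) > discordance_limit) {
        flags <- c(flags, "discordant_replicates")
      }
    }
    data.frame(sample_id = m$sample_id[1], sample_type = m$sample_type[1],
               target = m$target[1], ct = ct, n_replicates = nrow(m),
               censored = length(numeric_ct) == 0,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "ct_max") <- attr(measurements, "ct_max")
  out
}

.empty_sample_records <- function() {
  out <- data.frame(sample_id = character(), sample_type = character(),
                    ct_16s = numeric(), ct_actb = numeric(),
                    ct_18s = numeric(), delta_ct = numeric(),
                    observed_percent_microbial = numeric(),
                    flags = character(), stringsAsFactors = FALSE)
  class(out) <- c("sample_records", class(out))
  out
}

#' Assemble per-sample records with delta-Ct
#'
#' Pivots aggregated Cts into one row per sample and computes
#' `delta_ct = ct_actb - ct_16s`, the quantity the composition models use
#' (large positive values mean much more bacterial than human template).
#' Censored Cts propagate a `censored_ct` flag and leave `delta_ct` absent;
#' samples missing the 16S or ACTB assay are flagged `incomplete_targets`.
#'
#' @param aggregates Output of [aggregate_replicates()].
#' @param observed Optional data frame (`sample_id`,
#'   `observed_percent_microbial`) with the percent of shotgun reads not
#'   matching a human reference, as produced by host-read filtering. Values
#'   must lie in `[0, 100]`.
#' @return A `sample_records` data frame with columns `sample_id`,
#'   `sample_type`, `ct_16s`, `ct_actb`, `ct_18s`, `delta_ct`,
#'   `observed_percent_microbial`, `flags`.
#' @export
build_sample_records <- function(aggregates, observed = NULL) {
  if (!is.null(observed)) {
    if (!all(c("sample_id", "observed_percent_microbial") %in% names(observed))) {
      stop("observed table needs columns sample_id, observed_percent_microbial",
           call. = FALSE)
    }
    obs_p <- observed$observed_percent_microbial
    if (any(!is.na(obs_p) & (obs_p < 0 | obs_p > 100))) {
      stop("observed_percent_microbial outside [0, 100] for sample ",
           observed$sample_id[which(obs_p < 0 | obs_p > 100)[1]],
           call. = FALSE)
    }
  }
  if (nrow(aggregates) == 0) return(.empty_sample_records())
  ids <- unique(aggregates$sample_id)
  rows <- lapply(ids, function(id) {
    a <- aggregates[aggregates$sample_id == id, , drop = FALSE]
    pick <- function(tgt) {
      i <- which(a$target == tgt)
      if (length(i) == 0) NULL else a[i[1], , drop = FALSE]
    }
    r16 <- pick("16S"); ractb <- pick("ACTB"); r18 <- pick("18S")
    flags <- character()
    for (r in list(r16, ractb, r18)) {
      if (!is.null(r) && nzchar(r$flags)) {
        flags <- c(flags, strsplit(r$flags, ";", fixed = TRUE)[[1]])
      }
    }
    ct_16s <- if (is.null(r16)) NA_real_ else r16$ct
    ct_actb <- if (is.null(ractb)) NA_real_ else ractb$ct
    ct_18s <- if (is.null(r18)) NA_real_ else r18$ct
    if (is.null(r16) || is.null(ractb)) flags <- c(flags, "incomplete_targets")
    censored <- (!is.null(r16) && r16$censored) ||
      (!is.null(ractb) && ractb$censored) || (!is.null(r18) && r18$censored)
    if (censored) flags <- c(flags, "censored_ct")
    delta_ct <- if (!is.na(ct_actb) && !is.na(ct_16s)) ct_actb - ct_16s else NA_real_
    data.frame(sample_id = id, sample_type = a$sample_type[1],
               ct_16s = ct_16s, ct_actb = ct_actb, ct_18s = ct_18s,
               delta_ct = delta_ct,
               observed_percent_microbial = NA_real_,
               flags = paste(unique(flags), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(observed)) {
    idx <- match(out$sample_id, observed$sample_id)
    out$observed_percent_microbial <- observed$observed_percent_microbial[idx]
  }
  class(out) <- c("sample_records", class(out))
  out
}

#' Quality-control report for a qPCR run
#'
#' Checks the no-template (water) controls: a control is contaminated for a
#' target when it produced a numeric Ct more than `margin` cycles below
#' `ct_max`, i.e. genuine late-cycle amplification rather than threshold
#' noise. Also counts censored wells and discordant replicate groups.
#'
#' @param measurements A `ct_measurements` data frame.
#' @param negative_control_ids Sample ids of the no-template controls.
#' @param margin Cycles below `ct_max` a control Ct must fall to be called
#'   contamination (default 5).
#' @param discordance_limit Passed to [aggregate_replicates()] for the
#'   discordance count.
#' @return A list of class `ct_qc_report`: per-target control status,
#'   `contaminated_targets`, counts of censored wells and discordant groups,
#'   and `notes`.
#' @export
validate_run <- function(measurements, negative_control_ids = character(),
                         margin = 5, discordance_limit = 1.0) {
  ct_max <- attr(measurements, "ct_max") %||% 45
  notes <- character()
  if (length(negative_control_ids) == 0) {
    notes <- c(notes, "no controls declared")
  }
  ctrl <- measurements[measurements$sample_id %in% negative_control_ids, ,
                       drop = FALSE]
  per_target <- lapply(.valid_targets, function(tgt) {
    tc <- ctrl[ctrl$target == tgt, , drop = FALSE]
    hot <- !tc$censored & tc$ct < ct_max - margin
    list(target = tgt, n_control_wells = nrow(tc),
         contaminated = any(hot),
         min_control_ct = if (any(!tc$censored)) min(tc$ct, na.rm = TRUE) else NA_real_)
  })
  names(per_target) <- .valid_targets
  contaminated <- .valid_targets[vapply(per_target, `[[`, TRUE, "contaminated")]
  agg <- aggregate_replicates(measurements, discordance_limit)
  report <- list(targets = per_target,
                 contaminated_targets = contaminated,
                 n_censored_wells = sum(measurements$censored),
                 n_censored_groups = sum(agg$censored),
                 n_discordant_groups = sum(grepl("discordant_replicates", agg$flags)),
                 notes = notes, ct_max = ct_max, margin = margin)
  class(report) <- "ct_qc_report"
  report
}

#' @export
print.ct_qc_report <- function(x, ...) {
  cat("qPCR run QC report (ct_max =", x$ct_max, ")\n")
  if (length(x$contaminated_targets) > 0) {
    cat("  contaminated_control:", paste(x$contaminated_targets, collapse = ", "),
        sprintf("(control Ct < %g)\n", x$ct_max - x$margin))
  } else {
    cat("  negative controls: clean\n")
  }
  cat("  censored wells:", x$n_censored_wells,
      "| censored groups:", x$n_censored_groups,
      "| discordant groups:", x$n_discordant_groups, "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write sample records to CSV
#'
#' @param records A `sample_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read sample records written by [write_sample_records()]
#'
#' @param path CSV path.
#' @return A `sample_records` data frame.
#' @export
read_sample_records <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        sample_type = "character",
                                        flags = "character"))
  out$flags[is.na(out$flags)] <- ""
  for (col in c("ct_16s", "ct_actb", "ct_18s", "delta_ct",
                "observed_percent_microbial")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  class(out) <- c("sample_records", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
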