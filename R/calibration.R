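#' Logit of a percentage
#'
#' Maps a percentage to the real line via `ln(q/(1-q))` with `q = p/100`
#' clamped to `[eps, 1-eps]`. The clamp makes 0% and 100% observations usable
#' in logit-linear fits: a shotgun library can legitimately yield 0 observed
#' microbial reads, but the logit is only defined on the open interval.
#'
#' @param p Percentage(s) in `[0, 100]`.
#' @param eps Clamp width on the fraction scale, in `(0, 0.5)`; default 1e-4.
#' @return Logit value(s).
#' @seealso [inv_logit_percent()]
#' @export
logit_percent <- function(p, eps = 1e-4) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5) {
    stop("eps must be in (0, 0.5)", call. = FALSE)
  }
  if (any(!is.na(p) & (p < 0 | p > 100))) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  q <- pmin(pmax(p / 100, eps), 1 - eps)
  stats::qlogis(q)
}

#' Inverse logit, returning a percentage
#'
#' @param x Real value(s) on the logit scale.
#' @return `100 / (1 + exp(-x))`, a percentage in `(0, 100)`.
#' @export
inv_logit_percent <- function(x) 100 * stats::plogis(x)

# Family definitions: predictors and response transform.
.family_table <- list(
  A = list(predictors = c("ct_16s", "ct_actb"), transform = "none"),
  B = list(predictors = c("ct_16s", "ct_18s", "ct_actb"), transform = "none"),
  C = list(predictors = c("ct_16s", "ct_actb"), transform = "logit"),
  D = list(predictors = c("ct_16s", "ct_18s", "ct_actb"), transform = "logit"),
  E = list(predictors = "delta_ct", transform = "none")
)

#' Describe a calibration model family
#'
#' Five families relate qPCR cycle thresholds to percent microbial reads:
#' A (linear in 16S and ACTB Cts), B (linear, adding 18S), C and D (the same
#' predictors fitted to logit-transformed percentages), and E (logistic
#' growth in the single predictor delta-Ct = ACTB - 16S).
#'
#' @param family One of `"A".."E"`.
#' @return List with `family`, `predictors`, `transform`.
#' @export
model_spec <- function(family) {
  family <- toupper(as.character(family))
  if (length(family) != 1 || !family %in% names(.family_table)) {
    stop("family must be one of A, B, C, D, E", call. = FALSE)
  }
  c(list(family = family), .family_table[[family]])
}

.new_calibration_model <- function(family, coefficients = NULL, params = NULL,
                                   shift_offset = 0, n_train = NA_integer_,
                                   residual_sd = NA_real_,
                                   training_range = NULL, eps = 1e-4,
                                   r_squared = NA_real_, source = "fitted") {
  spec <- model_spec(family)
  m <- list(family = spec$family, predictors = spec$predictors,
            transform = spec$transform, coefficients = coefficients,
            params = params, shift_offset = shift_offset,
            n_train = n_train, residual_sd = residual_sd,
            training_range = training_range, eps = eps,
            r_squared = r_squared, source = source)
  class(m) <- "calibration_model"
  m
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model", x$family,
      switch(x$transform, logit = "(logit-linear)", "none" = "", ""), "\n")
  if (x$family == "E") {
    cat(sprintf("  percent = YM*Y0 / ((YM-Y0) * exp(-k * delta_ct) + Y0)\n"))
    cat(sprintf("  YM = %.5f  Y0 = %.5f  k = %.4f\n",
                x$params[["YM"]], x$params[["Y0"]], x$params[["k"]]))
  } else {
    cat("  coefficients:\n")
    print(x$coefficients)
  }
  if (x$shift_offset != 0) cat(sprintf("  shift_offset: %+.4f%%\n", x$shift_offset))
  if (!is.na(x$n_train)) cat("  n_train:", x$n_train, "\n")
  if (!is.na(x$residual_sd)) cat(sprintf("  residual_sd: %.3f%%\n", x$residual_sd))
  invisible(x)
}

.check_records_fields <- function(records, fields, need_observed = TRUE) {
  if (need_observed) fields <- c(fields, "observed_percent_microbial")
  for (f in fields) {
    bad <- which(is.na(records[[f]]))
    if (length(bad) > 0) {
      stop("record for sample '", records$sample_id[bad[1]],
           "' is missing required field '", f, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.training_range <- function(records, predictors) {
  rng <- lapply(predictors, function(f) range(records[[f]]))
  names(rng) <- predictors
  rng
}

#' Fit a linear or logit-linear calibration model (families A-D)
#'
#' Ordinary least squares of the observed percent microbial reads (A, B) or
#' its logit (C, D) on the family's Ct predictors. Residual diagnostics are
#' always computed on the percent scale after back-transformation, so that
#' residual ranges are comparable across families.
#'
#' @param records A `sample_records` data frame; every record must carry the
#'   family's predictor Cts and `observed_percent_microbial`.
#' @param family `"A"`, `"B"`, `"C"` or `"D"`.
#' @param eps Logit clamp width for C/D (see [logit_percent()]).
#' @return A `calibration_model`.
#' @export
fit_linear_calibration <- function(records, family, eps = 1e-4) {
  spec <- model_spec(family)
  if (spec$family == "E") {
    stop("family E is nonlinear; use fit_logistic_growth()", call. = FALSE)
  }
  .check_records_fields(records, spec$predictors)
  n <- nrow(records)
  p <- length(spec$predictors) + 1
  if (n <= p) {
    stop("rank error: ", n, " samples cannot identify ", p, " coefficients",
         call. = FALSE)
  }
  for (f in spec$predictors) {
    if (length(unique(records[[f]])) == 1) {
      stop("collinearity error: predictor '", f,
           "' is constant across all records", call. = FALSE)
    }
  }
  y <- if (spec$transform == "logit") {
    logit_percent(records$observed_percent_microbial, eps)
  } else {
    records$observed_percent_microbial
  }
  X <- as.data.frame(records[, spec$predictors, drop = FALSE])
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  if (fit$rank < p) {
    stop("collinearity error: predictors are linearly dependent", call. = FALSE)
  }
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", spec$predictors)
  m <- .new_calibration_model(spec$family, coefficients = coefs,
                              n_train = n,
                              training_range = .training_range(records, spec$predictors),
                              eps = eps)
  d <- diagnostics(m, records)
  m$residual_sd <- d$residual_sd
  m$r_squared <- d$r_squared
  m
}

#' Fit the logistic-growth composition model (family E)
#'
#' Least-squares fit, on the percent scale, of
#' `p(delta) = YM * Y0 / ((YM - Y0) * exp(-k * delta) + Y0)`
#' where `delta = ct_actb - ct_16s`, `Y0` is the baseline percent at
#' `delta = 0`, `YM` the upper plateau and `k` the per-cycle growth rate.
#' Uses Levenberg-Marquardt least squares with box bounds.
#'
#' @param records A `sample_records` data frame with `delta_ct` and
#'   `observed_percent_microbial` on every row; at least 4 rows.
#' @param init Optional named start values `c(YM=, Y0=, k=)`. Default:
#'   `Y0 = max(min(observed), 0.01)`, `YM = min(1.05 * max(observed), 100)`,
#'   `k = 0.5`.
#' @param bounds Optional list with named vectors `lower` and `upper`.
#'   Defaults: `Y0` in (1e-6, 10), `YM` in (10, 100], `k` in (0, 10].
#' @return A `calibration_model` with `params = c(YM, Y0, k)` satisfying
#'   `0 < Y0 < YM <= 100`, `k > 0`.
#' @export
fit_logistic_growth <- function(records, init = NULL, bounds = NULL) {
  .check_records_fields(records, "delta_ct")
  n <- nrow(records)
  if (n < 4) {
    stop("rank error: need at least 4 records to fit 3 parameters",
         call. = FALSE)
  }
  delta <- records$delta_ct
  obs <- records$observed_percent_microbial
  if (length(unique(delta)) == 1) {
    stop("identifiability error: delta_ct has zero variance", call. = FALSE)
  }
  if (is.null(init)) {
    # Self-starting values from the model's own linearization:
    # ln(p / (YM - p)) = k * delta + ln(Y0 / (YM - Y0)) at a plateau guess YM0.
    # A naive start (YM at the box ceiling) can stall the bounded fit there.
    YM0 <- min(max(obs) * 1.02, 99.9)
    p_cl <- pmin(pmax(obs, YM0 * 1e-6), YM0 * (1 - 1e-6))
    z <- log(p_cl / (YM0 - p_cl))
    lin <- stats::lm(z ~ delta)
    k0 <- max(unname(stats::coef(lin)[2]), 1e-3)
    b0 <- unname(stats::coef(lin)[1])
    Y00 <- YM0 * exp(b0) / (1 + exp(b0))
    init <- c(YM = YM0, Y0 = min(max(Y00, 1e-5), 9.99), k = min(k0, 9.99))
  }
  lower <- c(YM = 10, Y0 = 1e-6, k = 1e-9)
  upper <- c(YM = 100, Y0 = 10, k = 10)
  if (!is.null(bounds)) {
    lower[names(bounds$lower)] <- bounds$lower
    upper[names(bounds$upper)] <- bounds$upper
  }
  # Keep the start strictly inside the box: the bounded Levenberg-Marquardt
  # step is clamped at the boundary, and a start on the boundary can satisfy
  # the relative-SSR stopping rule before the fit has moved anywhere.
  margin <- 1e-3 * (upper - lower)
  init <- pmin(pmax(init[c("YM", "Y0", "k")], lower + margin), upper - margin)
  dat <- data.frame(delta = delta, obs = obs)
  run_fit <- function(start) {
    minpack.lm::nlsLM(
      obs ~ (YM * Y0) / ((YM - Y0) * exp(-k * delta) + Y0),
      data = dat, start = as.list(start),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxiter = 1000, maxfev = 10000))
  }
  fit <- tryCatch(run_fit(init),
                  error = function(e) stop("logistic-growth fit failed: ",
                                           conditionMessage(e), call. = FALSE))
  params <- stats::coef(fit)[c("YM", "Y0", "k")]
  # A solution pinned to the box is suspect: restart from mid-box and keep
  # the fit with the smaller residual sum of squares.
  on_bound <- any(params <= lower + margin / 2 | params >= upper - margin / 2)
  if (on_bound) {
    restart <- (lower + upper) / 2
    restart[["Y0"]] <- max(min(obs), 0.01)
    refit <- tryCatch(run_fit(pmin(pmax(restart, lower + margin),
                                   upper - margin)),
                      error = function(e) NULL)
    if (!is.null(refit) &&
        sum(stats::residuals(refit)^2) < sum(stats::residuals(fit)^2)) {
      fit <- refit
      params <- stats::coef(fit)[c("YM", "Y0", "k")]
    }
  }
  info <- fit$convInfo
  if (!is.null(info) && !isTRUE(info$isConv)) {
    stop("logistic-growth fit did not converge (best so far: YM=",
         signif(params[["YM"]], 6), ", Y0=", signif(params[["Y0"]], 6),
         ", k=", signif(params[["k"]], 6), ")", call. = FALSE)
  }
  if (!(params[["Y0"]] > 0 && params[["Y0"]] < params[["YM"]] &&
        params[["YM"]] <= 100 && params[["k"]] > 0)) {
    stop("fitted parameters violate 0 < Y0 < YM <= 100, k > 0", call. = FALSE)
  }
  m <- .new_calibration_model("E", params = params, n_train = n,
                              training_range = list(delta_ct = range(delta)))
  d <- diagnostics(m, records)
  m$residual_sd <- d$residual_sd
  m$r_squared <- d$r_squared
  m
}

#' Published logistic-growth composition curve
#'
#' Evaluates the published two-target calibration curve
#' `percent = 2.7201549 / (99.50267 * exp(-0.7218 * delta_ct) + 0.02733)`,
#' where `delta_ct = Ct(ACTB) - Ct(16S)`. The curve is strictly increasing
#' and bounded in `(0.02733, 99.53)`: the numerator equals `YM * Y0` with
#' `YM = 99.53`, `Y0 = 0.02733` and `YM - Y0 = 99.50267`.
#'
#' @param delta_ct Finite delta-Ct value(s), in cycles.
#' @return Predicted percent microbial reads.
#' @export
published_model_e <- function(delta_ct) {
  if (any(!is.finite(delta_ct))) {
    stop("delta_ct must be finite", call. = FALSE)
  }
  2.7201549 / (99.50267 * exp(-0.7218 * delta_ct) + 0.02733)
}

#' The published model E as a calibration_model object
#'
#' Loads the packaged constants of the published curve (see
#' [published_model_e()]) together with its derivation-set metadata: 89
#' training samples (oropharyngeal swabs and stool), percent-scale residual
#' standard deviation 4.35, and the observed delta-Ct range
#' `[-8.16, 34.45]` used for extrapolation flagging.
#'
#' @return A `calibration_model` of family E.
#' @export
published_model <- function() {
  path <- system.file("extdata", "model_e_published.json",
                      package = "shallowplan", mustWork = TRUE)
  read_model(path)
}

# Raw model-scale predictions (before shift and clamping), percent scale.
.predict_percent_raw <- function(model, records) {
  if (model$family == "E") {
    YM <- model$params[["YM"]]; Y0 <- model$params[["Y0"]]
    k <- model$params[["k"]]
    (YM * Y0) / ((YM - Y0) * exp(-k * records$delta_ct) + Y0)
  } else {
    co <- model$coefficients
    eta <- co[["(Intercept)"]]
    for (f in model$predictors) eta <- eta + co[[f]] * records[[f]]
    if (model$transform == "logit") inv_logit_percent(eta) else eta
  }
}

#' Predict percent microbial reads for samples
#'
#' Applies a calibration model to sample records, returning per-sample point
#' estimates with a one-tailed lower prediction bound and two validity flags:
#' `in_validity_range` is `FALSE` when the estimate falls below 4% or above
#' 98% (where the sigmoid's asymptotes make the calibration unreliable), and
#' `extrapolated` is `TRUE` when the sample's predictors fall outside the
#' model's training range (for family E, delta-Ct outside the calibration
#' range).
#'
#' @param model A `calibration_model`.
#' @param records A `sample_records` data frame. Records must carry the
#'   model's required Ct fields, uncensored.
#' @param level One-tailed coverage for the lower bound (default 0.95);
#'   `NULL` suppresses the bound.
#' @return Data frame with columns `sample_id`, `percent_microbial`,
#'   `lower_bound_95`, `in_validity_range`, `extrapolated`, `flags`.
#' @export
predict_percent_microbial <- function(model, records, level = 0.95) {
  required <- model$predictors
  if (model$family == "E" && !"delta_ct" %in% names(records)) {
    stop("records lack delta_ct", call. = FALSE)
  }
  .check_records_fields(records, required, need_observed = FALSE)
  if ("flags" %in% names(records)) {
    cen <- grepl("censored_ct", records$flags)
    if (any(cen)) {
      stop("sample '", records$sample_id[which(cen)[1]],
           "' has censored Ct values; refusing to predict", call. = FALSE)
    }
  }
  raw <- .predict_percent_raw(model, records) + model$shift_offset
  clamped <- raw <= 0 | raw >= 100
  est <- pmin(pmax(raw, 1e-6), 100 - 1e-6)
  extrapolated <- rep(FALSE, nrow(records))
  if (!is.null(model$training_range)) {
    for (f in names(model$training_range)) {
      rng <- model$training_range[[f]]
      extrapolated <- extrapolated | records[[f]] < rng[1] | records[[f]] > rng[2]
    }
  }
  lb <- if (!is.null(level) && !is.na(model$residual_sd)) {
    one_tailed_prediction_bound(model, est, level = level)
  } else {
    rep(NA_real_, length(est))
  }
  flags <- ifelse(clamped, "clamped", "")
  data.frame(sample_id = records$sample_id,
             percent_microbial = est,
             lower_bound_95 = lb,
             in_validity_range = est >= 4 & est <= 98,
             extrapolated = extrapolated,
             flags = flags, stringsAsFactors = FALSE)
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  predict_percent_microbial(object, newdata, ...)$percent_microbial
}

#' Goodness-of-fit diagnostics on the percent scale
#'
#' Residuals are `observed - predicted` percent for every family, including
#' the logit-linear ones after back-transformation, so residual ranges and
#' standard deviations are directly comparable across families.
#' `r_squared = 1 - SS_res / SS_tot` computed on the percent scale (the
#' convention of common curve-fitting software, also for nonlinear fits).
#'
#' @param model A `calibration_model`.
#' @param records Records with observations and the model's predictors.
#' @return List of class `calibration_diagnostics`: `r_squared`, `residuals`,
#'   `residual_range`, `residual_sd` (n-1 denominator), `residual_median`,
#'   `residual_mean`, `n`.
#' @export
diagnostics <- function(model, records) {
  if (nrow(records) == 0) stop("no records to diagnose", call. = FALSE)
  .check_records_fields(records, model$predictors)
  obs <- records$observed_percent_microbial
  pred <- .predict_percent_raw(model, records) + model$shift_offset
  res <- obs - pred
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) {
    warning("observed values have zero variance; r_squared undefined")
    NA_real_
  } else {
    1 - sum(res^2) / ss_tot
  }
  out <- list(r_squared = r2, residuals = res,
              residual_range = max(res) - min(res),
              residual_sd = stats::sd(res),
              residual_median = stats::median(res),
              residual_mean = mean(res), n = length(res))
  class(out) <- "calibration_diagnostics"
  out
}

#' @export
print.calibration_diagnostics <- function(x, ...) {
  cat(sprintf("n = %d  R^2 = %.4f\n", x$n, x$r_squared))
  cat(sprintf("residuals (%%): mean %+.3f  median %+.3f  sd %.3f  range %.2f\n",
              x$residual_mean, x$residual_median, x$residual_sd,
              x$residual_range))
  invisible(x)
}

#' Shift a model so its mean residual is zero
#'
#' Adds the mean residual on `records` to the model's percent-scale shift
#' offset. Re-running diagnostics on the same records then gives a zero mean
#' residual with unchanged residual standard deviation; applying the shift
#' twice to the same records is a no-op (idempotent). Shifting trades a
#' little of the logit-linear families' bias for none of their spread, which
#' is why it is offered for families C and D in particular.
#'
#' @param model A `calibration_model`.
#' @param records Records to center the residuals on.
#' @return The shifted `calibration_model`.
#' @export
shift_to_zero_mean_residual <- function(model, records) {
  d <- diagnostics(model, records)
  model$shift_offset <- model$shift_offset + d$residual_mean
  model
}

#' One-tailed lower prediction bound
#'
#' Normal-approximation bound
#' `point - z(level) * residual_sd * sqrt(1 + 1/n_train)`, clamped at 0.
#' This is the conservative quantity a sequencing planner needs: the
#' composition the sample is unlikely (at `level`) to fall below. The paper
#' trail of the bound's construction is recorded in the `method` attribute;
#' `method = "empirical"` instead uses the empirical residual quantile when
#' residuals are supplied.
#'
#' @param model A `calibration_model` with `residual_sd` and `n_train`.
#' @param point Point estimate(s), percent.
#' @param level One-tailed coverage in `(0.5, 1)`; default 0.95.
#' @param method `"normal"` (default) or `"empirical"`.
#' @param residuals Percent-scale residuals, required for
#'   `method = "empirical"`.
#' @return Lower bound(s), percent, with attribute `method`.
#' @export
one_tailed_prediction_bound <- function(model, point, level = 0.95,
                                        method = c("normal", "empirical"),
                                        residuals = NULL) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1 || level <= 0.5 || level >= 1) {
    stop("level must be in (0.5, 1)", call. = FALSE)
  }
  lb <- if (method == "normal") {
    if (is.na(model$residual_sd) || is.na(model$n_train)) {
      stop("model lacks residual_sd/n_train; cannot form a bound", call. = FALSE)
    }
    point - stats::qnorm(level) * model$residual_sd * sqrt(1 + 1 / model$n_train)
  } else {
    if (is.null(residuals)) {
      stop("method = 'empirical' needs residuals", call. = FALSE)
    }
    point + stats::quantile(residuals, 1 - level, names = FALSE, type = 7)
  }
  lb <- pmax(lb, 0)
  attr(lb, "method") <- method
  lb
}

#' Serialize a calibration model to JSON
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  x <- list(family = model$family, transform = model$transform,
            shift_offset = model$shift_offset, n_train = model$n_train,
            residual_sd = model$residual_sd, r_squared = model$r_squared,
            eps = model$eps, training_range = model$training_range,
            source = model$source)
  if (model$family == "E") {
    x$params <- as.list(model$params)
  } else {
    x$coefficients <- as.list(model$coefficients)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path Path to a JSON file written by [write_model()] or the
#'   packaged published-model asset.
#' @return A `calibration_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (!is.null(x$params)) unlist(x$params)[c("YM", "Y0", "k")] else NULL
  coefs <- if (!is.null(x$coefficients)) unlist(x$coefficients) else NULL
  tr <- if (!is.null(x$training_range)) {
    lapply(x$training_range, as.numeric)
  } else NULL
  .new_calibration_model(x$family, coefficients = coefs, params = params,
                         shift_offset = x$shift_offset %||% 0,
                         n_train = x$n_train %||% NA_integer_,
                         residual_sd = x$residual_sd %||% NA_real_,
                         training_range = tr, eps = x$eps %||% 1e-4,
                         r_squared = x$r_squared %||% NA_real_,
                         source = x$source %||% "file")
}
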