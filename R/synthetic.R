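#' Simulate a qPCR calibration data set
#'
#' Generates sample records with the joint structure the calibration models
#' assume: delta-Ct values drawn uniformly over the calibration range, true
#' percent microbial reads placed on the logistic-growth curve, and observed
#' percents obtained by perturbing the truth on the logit scale — noise there
#' keeps every observation inside (0, 100), mimicking how compositional
#' error behaves near the asymptotes. Absolute 16S Cts are drawn uniformly
#' and `ct_actb = ct_16s + delta`, so the absolute-Ct families (A-D) are
#' exercised as well; `ct_18s` is generated as an uninformative target
#' (noise around a constant), matching its published lack of predictive
#' value.
#'
#' @param n_samples Number of samples (default 89, the size of a two-site
#'   derivation cohort).
#' @param delta_range Range of delta-Ct, cycles (default `c(-8.16, 34.45)`,
#'   the published calibration range).
#' @param params Generating curve `c(YM=, Y0=, k=)`; defaults to the
#'   published constants.
#' @param noise_sd_logit Logit-scale noise SD (default 0.59, which yields a
#'   percent-scale residual SD of about 4.35 over the default delta range).
#' @param ct_16s_range Range for absolute 16S Cts (default `c(15, 35)`).
#' @param sample_types Labels cycled over the samples.
#' @param seed Integer seed; identical configs and seeds yield identical
#'   records.
#' @return A `sample_records` data frame with observed percents attached and
#'   the generating truth in column `true_percent_microbial`.
#' @export
simulate_calibration_records <- function(n_samples = 89,
                                         delta_range = c(-8.16, 34.45),
                                         params = c(YM = 99.53, Y0 = 0.02733,
                                                    k = 0.7218),
                                         noise_sd_logit = 0.59,
                                         ct_16s_range = c(15, 35),
                                         sample_types = c("oropharyngeal",
                                                          "stool"),
                                         seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (noise_sd_logit < 0) stop("noise_sd_logit must be >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    delta <- stats::runif(n_samples, delta_range[1], delta_range[2])
    truth <- (params[["YM"]] * params[["Y0"]]) /
      ((params[["YM"]] - params[["Y0"]]) * exp(-params[["k"]] * delta) +
         params[["Y0"]])
    observed <- if (noise_sd_logit == 0) {
      truth
    } else {
      inv_logit_percent(stats::qlogis(truth / 100) +
                          stats::rnorm(n_samples, 0, noise_sd_logit))
    }
    ct_16s <- stats::runif(n_samples, ct_16s_range[1], ct_16s_range[2])
    ct_18s <- stats::rnorm(n_samples, 30, 1.5)
    out <- data.frame(
      sample_id = sprintf("sim%03d", seq_len(n_samples)),
      sample_type = rep_len(sample_types, n_samples),
      ct_16s = ct_16s, ct_actb = ct_16s + delta, ct_18s = ct_18s,
      delta_ct = delta,
      observed_percent_microbial = observed,
      flags = "", true_percent_microbial = truth,
      stringsAsFactors = FALSE)
    class(out) <- c("sample_records", class(out))
    out
  })
}

#' Simulate a taxonomic community profile
#'
#' Taxon relative abundances are drawn from a lognormal rank-abundance
#' model — abundances proportional to `exp(Normal(0, lognormal_sigma))` —
#' and read counts are a single multinomial draw at the requested depth, so
#' the total is exact. Larger `lognormal_sigma` gives a more uneven, more
#' dominated community.
#'
#' @param n_taxa Number of taxa in the species pool.
#' @param lognormal_sigma Spread of the rank-abundance distribution
#'   (default 2, a typical value for human-associated communities).
#' @param depth Total read count.
#' @param seed Integer seed.
#' @param sample_id,group Labels for the resulting profile.
#' @return A `taxon_profile` (taxa that drew zero reads are kept with count
#'   zero in the abundance model but dropped from the profile).
#' @export
simulate_community <- function(n_taxa, lognormal_sigma = 2, depth = 1e6,
                               seed = 1, sample_id = "simulated_community",
                               group = NA_character_) {
  if (n_taxa < 1) stop("n_taxa must be >= 1", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be > 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    ab <- exp(stats::rnorm(n_taxa, 0, lognormal_sigma))
    prob <- ab / sum(ab)
    counts <- as.numeric(stats::rmultinom(1, size = depth, prob = prob))
    names(counts) <- sprintf("s__taxon_%03d", seq_len(n_taxa))
    taxon_profile(counts[counts > 0], sample_id = sample_id, group = group)
  })
}

.write_profile_tsv <- function(profile, path) {
  lines <- c("#taxon\tcount",
             sprintf("%s\t%d", names(profile$counts),
                     as.integer(profile$counts)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a self-contained synthetic fixture suite
#'
#' Generates a small, deterministic set of files exercising every reader in
#' the package: a long-format Ct table (12 samples over 4 sample types, all
#' assays in duplicate, one undetermined well, one water negative control),
#' the matching observed-percent table, and four community profiles crossing
#' high/low richness with high/low dominance at totals of at least one
#' million reads. All files are labelled synthetic by name; regenerating
#' with the same seed reproduces them byte for byte.
#'
#' @param out_dir Writable output directory (created if absent).
#' @param seed Integer seed (default 2021).
#' @return Data frame manifest (`file`, `kind`, `path`), also written to
#'   `manifest.csv` in `out_dir`.
#' @export
make_fixture_suite <- function(out_dir, seed = 2021) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  types <- rep(c("oropharyngeal", "stool", "rectal", "vaginal"), each = 3)
  n <- length(types)
  recs <- withr::with_seed(as.integer(seed), {
    delta <- stats::runif(n, -8, 34)
    # keep both absolute Cts inside (0, 45] after adding delta and jitter
    ct_16s <- round(stats::runif(n, pmax(9, 1 - delta), pmin(32, 44.5 - delta)), 3)
    ct_18s <- round(stats::rnorm(n, 30, 1.5), 3)
    truth <- published_model_e(delta)
    observed <- round(inv_logit_percent(stats::qlogis(truth / 100) +
                                          stats::rnorm(n, 0, 0.59)), 3)
    list(ct_16s = ct_16s, ct_actb = round(ct_16s + delta, 3),
         ct_18s = ct_18s, observed = observed)
  })
  ids <- sprintf("syn_%s_%02d", substr(types, 1, 4), seq_len(n))
  rows <- list()
  add_row <- function(id, type, target, rep_i, ct) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, sample_type = type, target = target,
      replicate = rep_i, ct = ct, stringsAsFactors = FALSE)
  }
  jitter_rep <- c(-0.05, 0.05)  # fixed replicate offsets keep files reproducible
  for (i in seq_len(n)) {
    for (tgt in c("16S", "18S", "ACTB")) {
      base <- switch(tgt, "16S" = recs$ct_16s[i], "18S" = recs$ct_18s[i],
                     "ACTB" = recs$ct_actb[i])
      for (r in 1:2) {
        ct <- format(round(base + jitter_rep[r], 3), nsmall = 3)
        if (i == 1 && tgt == "18S" && r == 2) ct <- "Undetermined"
        add_row(ids[i], types[i], tgt, r, ct)
      }
    }
  }
  for (tgt in c("16S", "18S", "ACTB")) {
    for (r in 1:2) add_row("NTC_water", "control", tgt, r, "Undetermined")
  }
  ct_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ct_path <- file.path(out_dir, "synthetic_ct_table.csv")
  utils::write.csv(ct_tab, ct_path, row.names = FALSE, quote = FALSE)
  obs_path <- file.path(out_dir, "synthetic_observed_percent.csv")
  utils::write.csv(data.frame(sample_id = ids,
                              observed_percent_microbial = recs$observed),
                   obs_path, row.names = FALSE, quote = FALSE)
  comm_cfg <- list(
    synthetic_community_rich_even = list(n_taxa = 150, sigma = 1),
    synthetic_community_rich_dominated = list(n_taxa = 150, sigma = 3),
    synthetic_community_poor_even = list(n_taxa = 12, sigma = 0.5),
    synthetic_community_poor_dominated = list(n_taxa = 12, sigma = 3))
  comm_paths <- character()
  for (j in seq_along(comm_cfg)) {
    nm <- names(comm_cfg)[j]
    cfg <- comm_cfg[[j]]
    prof <- simulate_community(cfg$n_taxa, cfg$sigma, depth = 1.2e6,
                               seed = seed + j, sample_id = nm)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_profile_tsv(prof, p)
    comm_paths <- c(comm_paths, p)
  }
  manifest <- data.frame(
    file = basename(c(ct_path, obs_path, comm_paths)),
    kind = c("ct_table", "observed_percent", rep("taxon_counts", 4)),
    path = c(ct_path, obs_path, comm_paths), stringsAsFactors = FALSE)
  utils::write.csv(manifest[, c("file", "kind")],
                   file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}
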