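#' Construct a taxon count profile
#'
#' @param counts Named non-negative integer vector, taxon -> read count.
#'   Taxon names must be unique.
#' @param sample_id Sample identifier.
#' @param group Group label (e.g. sample type), default `NA`.
#' @return A list of class `taxon_profile` with `sample_id`, `group`,
#'   `counts`, `total`.
#' @export
taxon_profile <- function(counts, sample_id, group = NA_character_) {
  if (length(counts) == 0 || is.null(names(counts)) ||
      anyDuplicated(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector with unique non-empty taxon names",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  p <- list(sample_id = sample_id, group = group, counts = counts,
            total = sum(counts))
  class(p) <- "taxon_profile"
  p
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat("Taxon profile '", x$sample_id, "'",
      if (!is.na(x$group)) paste0(" (", x$group, ")"), ": ",
      length(x$counts), " taxa, ", format(x$total, big.mark = ","),
      " reads\n", sep = "")
  invisible(x)
}

# Largest-remainder rounding: integer counts summing exactly to total.
.largest_remainder <- function(weights, total) {
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  base
}

#' Read a taxonomic profile from a TSV file
#'
#' Two dialects are supported. `taxon_counts`: two tab-separated columns,
#' taxon name and integer read count. `metaphlan_relab`: a MetaPhlAn-2-style
#' table (`#clade_name<TAB>relative_abundance`) from which only species-level
#' clades are kept (deepest rank `s__`, no strain `t__` suffix); relative
#' abundances are converted to integer counts at `assumed_depth` using
#' largest-remainder rounding so the counts sum to the depth exactly.
#'
#' @param source Path to the TSV file.
#' @param format `"taxon_counts"` or `"metaphlan_relab"`.
#' @param assumed_depth Total read count to distribute over the relative
#'   abundances; required for `metaphlan_relab`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param group Optional group label.
#' @return A `taxon_profile`.
#' @export
read_profile <- function(source, format = c("taxon_counts", "metaphlan_relab"),
                         assumed_depth = NULL,
                         sample_id = sub("\\.[^.]*$", "", basename(source)),
                         group = NA_character_) {
  format <- match.arg(format)
  lines <- readLines(source)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  if (length(body) == 0) stop("profile file has no data rows", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("profile rows must have at least two tab-separated columns",
         call. = FALSE)
  }
  name <- vapply(parts, `[[`, "", 1)
  value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(value)) stop("non-numeric abundance value in profile", call. = FALSE)
  if (any(value < 0)) stop("negative abundance/count in profile", call. = FALSE)
  if (format == "taxon_counts") {
    if (any(value != round(value))) {
      stop("taxon_counts values must be integers", call. = FALSE)
    }
    counts <- stats::setNames(value, name)
  } else {
    if (is.null(assumed_depth)) {
      stop("metaphlan_relab input needs assumed_depth", call. = FALSE)
    }
    species <- grepl("s__", name, fixed = TRUE) &
      !grepl("t__", name, fixed = TRUE)
    if (!any(species)) {
      stop("no species-level (s__) rows in MetaPhlAn profile", call. = FALSE)
    }
    name <- name[species]
    value <- value[species]
    short <- vapply(strsplit(name, "|", fixed = TRUE),
                    function(x) x[length(x)], "")
    counts <- stats::setNames(.largest_remainder(value, assumed_depth), short)
  }
  counts <- counts[counts > 0]
  taxon_profile(counts, sample_id = sample_id, group = group)
}

#' Subsample a profile without replacement
#'
#' Draws `depth` reads from the profile's count bins without replacement
#' (multivariate hypergeometric), emulating read-level subsampling of the
#' taxon-assigned reads. The draw is made by sequential conditional
#' hypergeometric sampling, so it runs in time proportional to the number of
#' taxa regardless of depth, and is fully determined by `seed`.
#'
#' @param profile A `taxon_profile`.
#' @param depth Number of reads to draw, in `[1, profile$total]`.
#' @param seed Integer seed; identical (profile, depth, seed) triples yield
#'   identical subsamples. The caller's RNG state is untouched.
#' @return A `taxon_profile` with total exactly `depth` (zero-count taxa
#'   dropped).
#' @export
subsample_counts <- function(profile, depth, seed) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (depth > profile$total) {
    stop("depth ", depth, " exceeds profile total ", profile$total,
         call. = FALSE)
  }
  counts <- profile$counts
  if (depth == profile$total) {
    return(taxon_profile(counts[counts > 0], profile$sample_id, profile$group))
  }
  drawn <- withr::with_seed(as.integer(seed), {
    remaining <- profile$total
    to_draw <- depth
    out <- numeric(length(counts))
    for (i in seq_along(counts)) {
      if (to_draw == 0) break
      ci <- counts[[i]]
      if (i == length(counts)) {
        out[i] <- to_draw
        to_draw <- 0
        break
      }
      x <- stats::rhyper(1, m = ci, n = remaining - ci, k = to_draw)
      out[i] <- x
      to_draw <- to_draw - x
      remaining <- remaining - ci
    }
    out
  })
  names(drawn) <- names(counts)
  taxon_profile(drawn[drawn > 0], profile$sample_id, profile$group)
}

#' Alpha diversity of a taxon profile
#'
#' Computes three indices on the taxon proportions `q_i = count_i / total`:
#' richness (number of taxa with positive count), the Shannon index
#' `-sum(q_i * ln(q_i))` in natural-log units, and the Berger-Parker
#' dominance index `max(q_i)`.
#'
#' @param profile A `taxon_profile` with `total >= 1`.
#' @return List with `richness`, `shannon`, `berger_parker`.
#' @export
alpha_diversity <- function(profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  counts <- profile$counts[profile$counts > 0]
  if (length(counts) == 0 || profile$total < 1) {
    stop("profile has no reads", call. = FALSE)
  }
  q <- counts / sum(counts)
  list(richness = length(q),
       shannon = -sum(q * log(q)),
       berger_parker = max(q))
}

#' Seeded rarefaction over a depth grid
#'
#' For every sample and every depth in the grid, draws `n_replicates`
#' subsamples with seeds `base_seed + 0 .. base_seed + (n_replicates - 1)`,
#' computes the three alpha-diversity indices on each, and averages them over
#' replicates. Depths exceeding a sample's total are skipped and noted. The
#' default grid (one million down to one thousand reads, ten replicates)
#' spans the shallow-shotgun regime where depth starts to erode measured
#' diversity.
#'
#' @param profiles A `taxon_profile` or list of them.
#' @param depths Depth grid (reads); default
#'   `c(1e6, 5e5, 2.5e5, 1e5, 5e4, 1e4, 1e3)`.
#' @param n_replicates Subsamples per depth (default 10).
#' @param base_seed First replicate seed (default 1).
#' @return Data frame: `sample_id`, `group`, `depth`, `richness`, `shannon`,
#'   `berger_parker` (replicate means), `n_replicates`, `note`.
#' @export
rarefaction_grid <- function(profiles,
                             depths = c(1e6, 5e5, 2.5e5, 1e5, 5e4, 1e4, 1e3),
                             n_replicates = 10, base_seed = 1) {
  if (inherits(profiles, "taxon_profile")) profiles <- list(profiles)
  if (length(depths) == 0) stop("depth grid is empty", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  depths <- sort(unique(depths))
  rows <- list()
  for (p in profiles) {
    for (d in depths) {
      if (d > p$total) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = p$sample_id, group = p$group, depth = d,
          richness = NA_real_, shannon = NA_real_, berger_parker = NA_real_,
          n_replicates = 0L, note = "depth_exceeds_total",
          stringsAsFactors = FALSE)
        next
      }
      idx <- vapply(seq_len(n_replicates) - 1L, function(r) {
        a <- alpha_diversity(subsample_counts(p, d, base_seed + r))
        c(a$richness, a$shannon, a$berger_parker)
      }, numeric(3))
      m <- rowMeans(matrix(idx, nrow = 3))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = p$sample_id, group = p$group, depth = d,
        richness = m[1], shannon = m[2], berger_parker = m[3],
        n_replicates = as.integer(n_replicates), note = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize rarefaction results by group
#'
#' Median and interquartile range (linear-interpolation quartiles) of the
#' per-sample replicate means, per group, depth, and index — the summary
#' used to draw group-level rarefaction curves.
#'
#' @param results Output of [rarefaction_grid()].
#' @param grouping Optional named vector `sample_id -> group` overriding the
#'   groups stored in `results`. Every sample must be assigned a group.
#' @return Data frame: `group`, `depth`, `index`, `median`, `q1`, `q3`, `n`.
#' @export
group_summary <- function(results, grouping = NULL) {
  empty <- data.frame(group = character(), depth = numeric(),
                      index = character(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(results) == 0) return(empty)
  results <- results[results$note == "", , drop = FALSE]
  if (nrow(results) == 0) return(empty)
  group <- if (is.null(grouping)) {
    results$group
  } else {
    grouping[results$sample_id]
  }
  if (any(is.na(group))) {
    stop("sample '", results$sample_id[which(is.na(group))[1]],
         "' has no group assigned", call. = FALSE)
  }
  rows <- list()
  for (g in unique(group)) {
    for (d in sort(unique(results$depth[group == g]))) {
      sel <- results[group == g & results$depth == d, , drop = FALSE]
      for (index in c("richness", "shannon", "berger_parker")) {
        v <- sel[[index]]
        qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
        rows[[length(rows) + 1]] <- data.frame(
          group = g, depth = d, index = index,
          median = qs[2], q1 = qs[1], q3 = qs[3], n = length(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
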