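# Small in-code fixtures shared across test files.

write_ct_csv <- function(rows, path = tempfile(fileext = ".csv"),
                         header = "sample_id,sample_type,target,replicate,ct") {
  writeLines(c(header, rows), path)
  path
}

# Minimal well-formed Ct table: two samples, 16S + ACTB in duplicate.
tiny_ct_table <- function() {
  write_ct_csv(c(
    "s1,stool,16S,1,20.1",
    "s1,stool,16S,2,20.3",
    "s1,stool,ACTB,1,25.0",
    "s1,stool,ACTB,2,25.0",
    "s2,oropharyngeal,16S,1,28.0",
    "s2,oropharyngeal,16S,2,28.2",
    "s2,oropharyngeal,ACTB,1,24.1",
    "s2,oropharyngeal,ACTB,2,24.3"))
}

# Records lying exactly on a linear surface p = b0 + b1*ct_16s + b2*ct_actb.
linear_surface_records <- function(n = 10, b = c(10, 2, -1), seed = 42) {
  withr::with_seed(seed, {
    ct_16s <- runif(n, 18, 30)
    ct_actb <- runif(n, 20, 32)
    p <- b[1] + b[2] * ct_16s + b[3] * ct_actb
    data.frame(sample_id = sprintf("lin%02d", seq_len(n)),
               sample_type = "stool", ct_16s = ct_16s, ct_actb = ct_actb,
               ct_18s = runif(n, 28, 32), delta_ct = ct_actb - ct_16s,
               observed_percent_microbial = p, flags = "",
               stringsAsFactors = FALSE)
  })
}

# Records exactly on a logit-linear surface (family C, percent response).
logit_surface_records <- function(n = 12, b = c(4, 0.3, -0.45), seed = 7) {
  withr::with_seed(seed, {
    ct_16s <- runif(n, 18, 30)
    ct_actb <- runif(n, 20, 32)
    eta <- b[1] + b[2] * ct_16s + b[3] * ct_actb
    data.frame(sample_id = sprintf("lgt%02d", seq_len(n)),
               sample_type = "stool", ct_16s = ct_16s, ct_actb = ct_actb,
               ct_18s = runif(n, 28, 32), delta_ct = ct_actb - ct_16s,
               observed_percent_microbial = shallowplan::inv_logit_percent(eta),
               flags = "", stringsAsFactors = FALSE)
  })
}

# One record per delta value, no observations (prediction-only input).
delta_records <- function(delta) {
  n <- length(delta)
  data.frame(sample_id = sprintf("d%02d", seq_len(n)),
             sample_type = rep("stool", n), ct_16s = rep(25, n),
             ct_actb = 25 + delta, ct_18s = rep(30, n), delta_ct = delta,
             observed_percent_microbial = rep(NA_real_, n),
             flags = rep("", n), stringsAsFactors = FALSE)
}
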