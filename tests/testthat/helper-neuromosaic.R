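# Shared fixtures and independent oracles for the test suite.

# Brute-force copy-number caller: plain-loop interval scan, independent of
# the package's vectorized decision rule but using the same tie-breaks.
oracle_call_bin <- function(rcn, ci_low, ci_high, bounds, gt6_rule = "ci") {
  k_max <- max(bounds$k)
  hits <- integer(0)
  for (k in bounds$k) {
    lo <- bounds$lower[bounds$k == k]
    hi <- bounds$upper[bounds$k == k]
    if (ci_low <= hi && ci_high >= lo) hits <- c(hits, k)
  }
  if (length(hits) == 1) return(hits)
  if (length(hits) > 1) {
    d <- abs(log2(rcn) - log2(hits))
    return(hits[which.min(d)])
  }
  beyond <- if (gt6_rule == "ci") {
    ci_low > bounds$upper[bounds$k == k_max]
  } else {
    rcn > bounds$upper[bounds$k == k_max]
  }
  if (beyond) return(k_max + 1)
  d <- abs(log2(rcn) - log2(bounds$k))
  bounds$k[which.min(d)]
}

# Printed modeled-bounds table (copy numbers 1-6, lower/upper RCN).
published_bounds <- tibble::tibble(
  k = 1:6,
  lower = c(0.92156, 1.84312, 2.76468, 3.68624, 4.60780, 5.52936),
  upper = c(1.08512, 2.17023, 3.25535, 4.34047, 5.42559, 6.51070)
)

# Ct replicate table for one unit/assay built from a vector of Ct values.
make_ct_rows <- function(cts, unit_id = "u1", assay_id = "APP_ex3",
                         brain_id = "b1", region = "CTX", group = "AD") {
  tibble::tibble(
    unit_id = unit_id, brain_id = brain_id, region = region, group = group,
    assay_id = assay_id, replicate_index = seq_along(cts), ct = cts
  )
}

# Fresh scratch directory per use.
withr_tempdir_lite <- function() {
  d <- tempfile("nmtest")
  dir.create(d)
  d
}

# An rcn-estimate row with a stated CI, for exercising the caller directly.
est_row <- function(rcn, ci_low, ci_high) {
  tibble::tibble(rcn = rcn, ci_low = ci_low, ci_high = ci_high)
}
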