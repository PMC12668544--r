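# Independent oracles and shared fixtures for the test suite.

# O(n^2 w) brute-force maximum sliding-window Pearson correlation.
brute_best_window_pcc <- function(x, y, w) {
  best <- -Inf
  bl <- c(NA_integer_, NA_integer_)
  for (l1 in 0:(length(x) - w)) {
    for (l2 in 0:(length(y) - w)) {
      cc <- suppressWarnings(stats::cor(x[l1 + 1:w], y[l2 + 1:w]))
      if (is.finite(cc) && cc > best) {
        best <- cc
        bl <- c(l1, l2)
      }
    }
  }
  list(C = best, l1 = bl[1], l2 = bl[2])
}

# Pearson correlation over an explicit pair of index sets (1-based).
pcc_index_oracle <- function(x, y, ix, iy) {
  suppressWarnings(stats::cor(x[ix], y[iy]))
}

# Memoized fixtures, shared across test files within one run.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# Small overlap parameters for fast unit tests.
small_params <- function() overlap_params(w = 100L, r_grid = seq(0.95, 1.05, by = 0.01))

# Null model calibrated at reduced size for unit tests.
small_null <- function() {
  memo("small_null", calibrate_null(small_params(), barcode_len_1 = 400L,
                                    barcode_len_2 = 400L, psf_sigma_px = 1.5,
                                    calib_n = 250L, seed = 11L))
}

# Full-scale null model at the study conditions (850 px pairs, w = 300),
# shared by the acceptance tests.
study_null <- function() {
  memo("study_null", calibrate_null(overlap_params(), barcode_len_1 = 850L,
                                    barcode_len_2 = 850L, psf_sigma_px = 1.5,
                                    calib_n = 1000L, seed = 1L))
}

# Build an overlap-candidate data.frame row from a best_local_overlap result.
cand_row <- function(cand) {
  data.frame(query_id = cand$query_id, ref_id = cand$ref_id, d = cand$d,
             r = cand$r, l1 = cand$l1, l2 = cand$l2, C = cand$C,
             C_leftover = cand$C_leftover, n_leftover = cand$n_leftover,
             implied_offset = cand$implied_offset,
             single_score = cand$single_score, stringsAsFactors = FALSE)
}

# Island layout constructed directly from a simulator ground-truth table
# (theory coordinates), bypassing assembly.
layout_from_gt <- function(gt, set, island_id = "gt_island") {
  n_raw <- vapply(gt$barcode_id, function(id) n_px(set[[id]]), integer(1))
  tab <- data.frame(barcode_id = gt$barcode_id, start = gt$gt_start,
                    stop = gt$gt_start + as.integer(round(n_raw / gt$gt_rescale)),
                    orientation = gt$gt_orientation,
                    rescale = 1 / gt$gt_rescale, stringsAsFactors = FALSE)
  shift <- min(tab$start)
  tab$start <- as.integer(tab$start - shift)
  tab$stop <- as.integer(tab$stop - shift)
  class(tab) <- c("island_layout", "data.frame")
  attr(tab, "island_id") <- island_id
  tab
}

# Orientation-aware best full-length correlation of a consensus profile
# against a theory barcode, over a wide uniform-stretch grid.
consensus_truth_pcc <- function(cons_intensity, theory) {
  m <- length(cons_intensity)
  best <- -Inf
  for (ori in 1:2) {
    v <- if (ori == 1) cons_intensity else rev(cons_intensity)
    for (r in seq(0.9, 1.1, by = 0.005)) {
      mm <- as.integer(round(r * m))
      if (mm > n_px(theory) || mm < 50) next
      vv <- stats::approx(seq_len(m) - 1, v, xout = seq(0, m - 1, length.out = mm))$y
      hit <- window_pcc_profile(theory, barcode("cons", vv), mm)
      if (!is.na(hit$C) && hit$C > best) best <- hit$C
    }
  }
  best
}
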