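#' Overlap search parameters
#'
#' Controls the matrix-profile overlap search: window width `w` (a 150 kb
#' window, about 300 px for this setup), the grid of length-rescaling
#' factors applied to the reference, and the orientations searched.
#'
#' @param w Integer window width in pixels (>= 8).
#' @param r_grid Ordered positive rescaling factors; default 0.95 to 1.05 in
#'   steps of 0.01.
#' @param orientations Subset of `c("+", "-")`.
#' @param min_leftover Minimum leftover length (px) for the leftover score to
#'   be statistically meaningful; shorter leftovers trigger single-score mode.
#' @return A list of class `overlap_params`.
#' @export
overlap_params <- function(w = 300L, r_grid = seq(0.95, 1.05, by = 0.01),
                           orientations = c("+", "-"), min_leftover = 20L) {
  w <- as.integer(w)
  r_grid <- round(r_grid, 10)  # snap seq() float residue so r = 1 is exact
  stopifnot(w >= 8L, length(r_grid) >= 1L, all(r_grid > 0),
            all(orientations %in% c("+", "-")), min_leftover >= 2L)
  structure(list(w = w, r_grid = as.numeric(r_grid),
                 orientations = orientations,
                 min_leftover = as.integer(min_leftover)),
            class = "overlap_params")
}

#' Sliding window means and standard deviations
#'
#' Per-window mean and population (divide-by-w) standard deviation for every
#' window start, computed by running sums. These are the mu / sigma terms of
#' the local overlap score.
#'
#' @param b A `barcode`.
#' @param w Window width.
#' @return List with numeric vectors `mean` and `std`, one value per window
#'   start `0 ... n_px - w`.
#' @export
sliding_mean_std <- function(b, w) {
  w <- as.integer(w)
  if (n_px(b) < w) {
    stop("barcode '", b$id, "' (", n_px(b), " px) shorter than window w=", w,
         call. = FALSE)
  }
  cpp_sliding_mean_std(b$intensity, w)
}

#' Best sliding-window Pearson correlation between two barcodes
#'
#' The matrix-profile primitive: the maximum over all window placements
#' (l1 on the reference, l2 on the query) of the window-w Pearson
#' correlation, computed from streaming dot products along alignment
#' diagonals. Windows with near-zero variance (std < 1e-9) are excluded.
#'
#' @param ref,query `barcode` objects, both of length >= w.
#' @param w Window width.
#' @return List with `C` (best correlation), `l1`, `l2` (0-based window
#'   starts).
#' @export
window_pcc_profile <- function(ref, query, w) {
  w <- as.integer(w)
  if (n_px(ref) < w || n_px(query) < w) {
    stop("both barcodes must be at least w=", w, " px", call. = FALSE)
  }
  cpp_best_window_pcc(ref$intensity, query$intensity, w)
}

orient_and_rescale <- function(b, d, r) {
  if (d == "-") b <- reverse_barcode(b)
  if (r != 1) b <- rescale_barcode(b, r)
  b
}

#' Best local overlap between two barcodes
#'
#' Finds the arg-max of the local overlap score over orientation d, rescaling
#' factor r (applied to the reference; the query is fixed) and all window
#' placements. Ties break to the rescaling closest to 1, forward before
#' reverse, then smallest l2 and l1.
#'
#' @param ref,query `barcode` objects.
#' @param p An [overlap_params()].
#' @return An `overlap_candidate`: list with ref_id, query_id, d, r, l1, l2
#'   (0-based, on the transformed reference / the query), C, implied_offset
#'   (= l2 - l1, start of the transformed reference in query coordinates),
#'   and C_leftover / n_leftover / single_score filled by [leftover_score()].
#' @export
best_local_overlap <- function(ref, query, p = overlap_params()) {
  if (n_px(query) < p$w) {
    stop("query '", query$id, "' shorter than window w=", p$w, call. = FALSE)
  }
  ord <- order(abs(p$r_grid - 1), p$r_grid)
  best <- NULL
  for (r in p$r_grid[ord]) {
    if (round(r * n_px(ref)) < p$w) next
    for (d in p$orientations) {
      refT <- orient_and_rescale(ref, d, r)
      hit <- cpp_best_window_pcc(refT$intensity, query$intensity, p$w)
      if (is.na(hit$C)) next
      if (is.null(best) || hit$C > best$C + 1e-12) {
        best <- list(ref_id = ref$id, query_id = query$id, d = d, r = r,
                     l1 = hit$l1, l2 = hit$l2, C = hit$C,
                     implied_offset = hit$l2 - hit$l1)
      }
    }
  }
  if (is.null(best)) {
    stop("no valid placement: every rescaled reference shorter than w=", p$w,
         call. = FALSE)
  }
  lo <- leftover_score(ref, query, best, min_leftover = p$min_leftover, w = p$w)
  best$C_leftover <- lo$C_leftover
  best$n_leftover <- lo$n_leftover
  best$single_score <- lo$single_score
  class(best) <- "overlap_candidate"
  best
}

#' Leftover score of an overlap candidate
#'
#' Extends the candidate's implied alignment (same r, d and offset) to the
#' full mutual overlap of the two barcodes and computes the Pearson
#' correlation over the overlapping pixels *excluded* from the local window.
#' If fewer than `min_leftover` such pixels exist the leftover correlation is
#' statistically meaningless and the candidate is flagged single-score.
#'
#' @param ref,query `barcode` objects the candidate was computed from.
#' @param cand An overlap candidate (list with d, r, l1, l2).
#' @param min_leftover Minimum pixel count for a defined leftover score.
#' @param w Window width the candidate was scored with.
#' @return List with `C_leftover` (NA in single-score mode), `n_leftover`,
#'   `single_score`.
#' @export
leftover_score <- function(ref, query, cand, min_leftover = 20L, w = 300L) {
  refT <- orient_and_rescale(ref, cand$d, cand$r)
  n1 <- n_px(refT); n2 <- n_px(query)
  off <- cand$l2 - cand$l1
  if (cand$l1 < 0 || cand$l2 < 0 || cand$l1 + w > n1 || cand$l2 + w > n2) {
    stop("inconsistent candidate geometry for pair (", cand$query_id, ", ",
         cand$ref_id, ")", call. = FALSE)
  }
  t0 <- max(0L, -off)
  t1 <- min(n1, n2 - off)  # exclusive
  tt <- seq.int(t0, t1 - 1L)
  tt <- tt[tt < cand$l1 | tt >= cand$l1 + w]
  n_leftover <- length(tt)
  if (n_leftover < min_leftover) {
    return(list(C_leftover = NA_real_, n_leftover = n_leftover,
                single_score = TRUE))
  }
  cl <- cpp_pcc_at(refT$intensity, query$intensity,
                   as.integer(tt), as.integer(tt + off))
  list(C_leftover = cl, n_leftover = n_leftover, single_score = FALSE)
}

#' All-pairs overlap candidates
#'
#' Scores every unordered pair of barcodes once, with a fixed role
#' convention: the lexicographically lower id is the query (fixed), the
#' higher id the reference (rescaled / reversed). Pairs that cannot be
#' scored (e.g. too short) are recorded and skipped.
#'
#' @param set A `barcode_set`.
#' @param p An [overlap_params()].
#' @param verbose Log progress every 500 pairs.
#' @return A data.frame with one row per scored pair: query_id, ref_id, d,
#'   r, l1, l2, C, C_leftover, n_leftover, implied_offset, single_score.
#'   Attribute `skipped` lists unscorable pairs.
#' @export
all_pairs_overlaps <- function(set, p = overlap_params(), verbose = FALSE) {
  stopifnot(inherits(set, "barcode_set"))
  ids <- sort(names(set))
  if (length(ids) < 2L) stop("need at least 2 barcodes", call. = FALSE)
  pairs <- utils::combn(ids, 2L)
  npair <- ncol(pairs)
  rows <- vector("list", npair)
  skipped <- character(0)
  for (k in seq_len(npair)) {
    qid <- pairs[1, k]; rid <- pairs[2, k]
    cand <- tryCatch(best_local_overlap(set[[rid]], set[[qid]], p),
                     error = function(e) e)
    if (inherits(cand, "error")) {
      skipped <- c(skipped, paste0(qid, "|", rid, ": ", conditionMessage(cand)))
      next
    }
    rows[[k]] <- data.frame(query_id = qid, ref_id = rid, d = cand$d,
                            r = cand$r, l1 = cand$l1, l2 = cand$l2,
                            C = cand$C, C_leftover = cand$C_leftover,
                            n_leftover = cand$n_leftover,
                            implied_offset = cand$implied_offset,
                            single_score = cand$single_score,
                            stringsAsFactors = FALSE)
    if (verbose && k %% 500 == 0) {
      message(sprintf("scored %d / %d pairs", k, npair))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
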