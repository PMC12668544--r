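#' Circular distance between two reference positions
#' @param a,b Positions (px).
#' @param len Reference length (px).
#' @param circular If FALSE, plain absolute difference.
#' @return Non-negative distance, at most `len / 2` when circular.
#' @export
circular_distance <- function(a, b, len, circular = TRUE) {
  d <- abs(a - b)
  if (!circular) return(d)
  dm <- d %% len
  pmin(dm, len - dm)
}

#' Full-length alignment of a barcode against a theory barcode
#'
#' Places the whole barcode (window = its full length) on the reference by
#' maximizing the Pearson correlation over all offsets, the rescaling grid
#' (applied to the barcode) and both orientations, with wrap-around when
#' the reference is circular. The p-value uses the calibrated
#' max-statistics null with K equal to the number of tested placements.
#'
#' @param b A `barcode`.
#' @param theory A `theory_barcode` longer than `b`.
#' @param null A `null_model_params` (the alignment reuses its
#'   m_eff_factor and nu).
#' @param r_grid Rescaling factors tried for the barcode.
#' @param orientations Orientations tried.
#' @return A `gt_alignment`: list with barcode_id, ref_start (0-based px,
#'   mod reference length), orientation, rescale, C, p_value.
#' @export
align_full_length <- function(b, theory, null,
                              r_grid = seq(0.95, 1.05, by = 0.01),
                              orientations = c("+", "-")) {
  L <- n_px(theory)
  if (n_px(b) > L) stop("barcode longer than the reference", call. = FALSE)
  r_grid <- round(r_grid, 10)
  circ <- isTRUE(theory$circular)
  maxlen <- as.integer(ceiling(max(r_grid) * n_px(b)))
  ref_ext <- if (circ) c(theory$intensity, theory$intensity[seq_len(min(L, maxlen))])
             else theory$intensity
  best <- NULL
  K <- 0
  rg <- sort(r_grid)
  for (r in rg[order(abs(rg - 1), rg)]) {
    for (d in orientations) {
      bt <- orient_and_rescale(b, d, r)
      m <- n_px(bt)
      if (m > length(ref_ext)) next
      K <- K + (length(ref_ext) - m + 1)
      hit <- cpp_best_window_pcc(ref_ext, bt$intensity, m)
      if (is.na(hit$C)) next
      if (is.null(best) || hit$C > best$C + 1e-12) {
        best <- list(C = hit$C, start = hit$l1, d = d, r = r, m = m)
      }
    }
  }
  if (is.null(best)) stop("no valid placement for '", b$id, "'", call. = FALSE)
  p <- p_max_beta(best$C, best$m, K, null)
  structure(list(barcode_id = b$id, ref_start = best$start %% L,
                 orientation = best$d, rescale = best$r, C = best$C,
                 p_value = p),
            class = "gt_alignment")
}

#' Ground-truth alignment table for a barcode set
#'
#' Runs [align_full_length()] on every barcode and assembles the result as
#' a data.frame.
#'
#' @inheritParams align_full_length
#' @param set A `barcode_set`.
#' @return Data.frame with barcode_id, ref_start, orientation, rescale, C,
#'   p_value.
#' @export
gt_alignment_table <- function(set, theory, null,
                               r_grid = seq(0.95, 1.05, by = 0.01)) {
  rows <- lapply(set, function(b) {
    a <- align_full_length(b, theory, null, r_grid = r_grid)
    data.frame(barcode_id = a$barcode_id, ref_start = a$ref_start,
               orientation = a$orientation, rescale = a$rescale, C = a$C,
               p_value = a$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Ground-truth (or full-length-alignment) placement of a barcode in theory
# coordinates, in the same placement algebra the assembler uses: raw pixel u
# maps to gt_start + u / g ("+") or gt_start + (len - u) / g ("-") where g
# is the rescale that produced the observed barcode from the theory slice.
gt_placement <- function(gt_row) {
  list(p = gt_row$gt_start, o = gt_row$gt_orientation, r = 1 / gt_row$gt_rescale)
}

#' Pairwise ground-truth distance of an overlap
#'
#' For a scored overlap between two barcodes with known reference
#' placements, maps the reference barcode's implied position into theory
#' coordinates through the query's ground-truth placement and returns the
#' (circular) distance to the reference barcode's own ground-truth start.
#' An orientation mismatch is reported alongside: a flipped placement is a
#' false positive regardless of distance.
#'
#' @param o One row of an overlap data.frame (query_id, ref_id, d, r, l1,
#'   l2).
#' @param gt Ground-truth data.frame (from [sample_fragments()] or
#'   converted from [gt_alignment_table()] via [gt_from_alignments()]).
#' @param set The `barcode_set`.
#' @param theory_len Reference length (px).
#' @param circular Whether the reference is circular.
#' @return List with `distance` (px) and `orientation_match` (logical).
#' @export
pairwise_gt_distance <- function(o, gt, set, theory_len, circular = TRUE) {
  gq <- gt[gt$barcode_id == o$query_id, , drop = FALSE]
  gr <- gt[gt$barcode_id == o$ref_id, , drop = FALSE]
  if (nrow(gq) != 1L || nrow(gr) != 1L) {
    stop("missing ground-truth row for pair (", o$query_id, ", ", o$ref_id, ")",
         call. = FALSE)
  }
  pl_q <- gt_placement(gq)
  edge <- list(d = o$d, r = o$r, off = o$l2 - o$l1)
  impl <- compose_placement(pl_q, edge, n_px(set[[o$ref_id]]),
                            n_px(set[[o$query_id]]))
  list(distance = circular_distance(impl$p, gr$gt_start, theory_len, circular),
       orientation_match = impl$o == gr$gt_orientation)
}

#' Convert a full-length alignment table to ground-truth table form
#'
#' For experimental-style (indirect) validation the reference placements
#' come from [gt_alignment_table()] rather than a simulator; this maps the
#' columns into the gt table layout the distance functions expect.
#'
#' @param aln Data.frame from [gt_alignment_table()].
#' @param set The `barcode_set`.
#' @return Ground-truth style data.frame.
#' @export
gt_from_alignments <- function(aln, set) {
  n <- vapply(aln$barcode_id, function(id) n_px(set[[id]]), integer(1))
  data.frame(barcode_id = aln$barcode_id, gt_start = aln$ref_start,
             gt_orientation = aln$orientation,
             gt_rescale = 1 / aln$rescale,
             gt_length = as.integer(round(aln$rescale * n)),
             p_value = aln$p_value, stringsAsFactors = FALSE)
}

#' Anchor an island on the reference and measure per-row distances
#'
#' The island member with the lowest alignment p-value is the anchor; the
#' island frame is mapped rigidly onto theory coordinates through the
#' anchor's placement, and every row's mapped start is compared with its
#' own reference placement.
#'
#' @param layout An `island_layout`.
#' @param gt Ground-truth table carrying a `p_value` column (from
#'   [gt_from_alignments()]) or a simulator gt table (then the anchor is
#'   chosen by a `p_value` column if present, else the first row).
#' @param set The `barcode_set`.
#' @param theory_len Reference length (px).
#' @param circular Whether the reference is circular.
#' @return Data.frame with barcode_id, mapped_start, gt_start, distance,
#'   orientation_match; attribute `anchor` names the anchor barcode.
#' @export
anchor_island <- function(layout, gt, set, theory_len, circular = TRUE) {
  if (nrow(layout) == 0L) stop("empty island layout", call. = FALSE)
  gt <- gt[match(layout$barcode_id, gt$barcode_id), , drop = FALSE]
  if (anyNA(gt$barcode_id)) {
    stop("every island member needs a ground-truth alignment", call. = FALSE)
  }
  anchor_i <- if ("p_value" %in% names(gt)) which.min(gt$p_value) else 1L
  n_anchor <- n_px(set[[layout$barcode_id[anchor_i]]])
  pl_island <- list(p = layout$start[anchor_i], o = layout$orientation[anchor_i],
                    r = layout$rescale[anchor_i])
  pl_theory <- gt_placement(gt[anchor_i, ])
  m <- frame_map(pl_island, pl_theory, n_anchor)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    n <- n_px(set[[layout$barcode_id[i]]])
    pl <- apply_frame_map(m, list(p = layout$start[i], o = layout$orientation[i],
                                  r = layout$rescale[i]), n)
    data.frame(barcode_id = layout$barcode_id[i],
               mapped_start = pl$p %% theory_len,
               gt_start = gt$gt_start[i],
               distance = circular_distance(pl$p, gt$gt_start[i], theory_len,
                                            circular),
               orientation_match = pl$o == gt$gt_orientation[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "anchor") <- layout$barcode_id[anchor_i]
  out
}

#' Classify distances into true/false positives and summarize
#'
#' A placement is a false positive when its distance to the reference
#' placement is at least `threshold` pixels or its orientation is flipped.
#' Also returns the true-positive-rate curve over thresholds for dot plots.
#'
#' @param distances Numeric distances (px).
#' @param threshold False-positive distance threshold (px); the customary
#'   settings are 40 px for pairwise validation and 30 px for island
#'   validation (anchoring adds positional variance).
#' @param orientation_match Optional logical vector; mismatches count as
#'   false positives regardless of distance.
#' @param curve_thresholds Thresholds for the TPR curve.
#' @return List with n, fp_rate, tp_mean_px, tp_std_px and `tpr_curve`
#'   (data.frame threshold / tpr).
#' @export
classify_and_summarize <- function(distances, threshold = 40,
                                   orientation_match = NULL,
                                   curve_thresholds = seq(0, 100, by = 5)) {
  stopifnot(threshold > 0)
  if (length(distances) == 0L) stop("no distances to classify", call. = FALSE)
  fp <- distances >= threshold
  if (!is.null(orientation_match)) fp <- fp | !orientation_match
  tp <- distances[!fp]
  tpr <- vapply(curve_thresholds, function(th) {
    ok <- distances < th
    if (!is.null(orientation_match)) ok <- ok & orientation_match
    mean(ok)
  }, numeric(1))
  list(n = length(distances),
       fp_rate = mean(fp),
       tp_mean_px = if (length(tp)) mean(tp) else NA_real_,
       tp_std_px = if (length(tp)) stats::sd(tp) else NA_real_,
       tpr_curve = data.frame(threshold = curve_thresholds, tpr = tpr))
}
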