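#' Read a kymograph from a TSV matrix
#'
#' A kymograph is a time-by-position intensity matrix of one molecule
#' (frames as rows). The molecule extent of each frame is detected by
#' thresholding at half the frame's intensity range (a simplification of
#' full image segmentation, which is out of scope), unless explicit
#' extents are supplied.
#'
#' @param path TSV file of intensities, one frame per row.
#' @param extents Optional data.frame with columns `left`, `right`
#'   (1-based inclusive pixel bounds per frame).
#' @return A `kymograph`: list with `intensity` matrix and `extent`
#'   data.frame.
#' @export
read_kymograph <- function(path, extents = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  kymograph(m, extents)
}

#' @rdname read_kymograph
#' @param intensity Numeric matrix, frames x pixels.
#' @export
kymograph <- function(intensity, extents = NULL) {
  stopifnot(is.matrix(intensity), nrow(intensity) >= 2)
  if (is.null(extents)) {
    extents <- do.call(rbind, lapply(seq_len(nrow(intensity)), function(i) {
      v <- intensity[i, ]
      thr <- min(v) + 0.5 * (max(v) - min(v))
      idx <- which(v >= thr)
      data.frame(left = min(idx), right = max(idx))
    }))
  }
  stopifnot(nrow(extents) == nrow(intensity), all(extents$left < extents$right),
            all(extents$left >= 1), all(extents$right <= ncol(intensity)))
  structure(list(intensity = intensity, extent = extents), class = "kymograph")
}

#' Shrink filter for kymographs
#'
#' Molecules out of equilibrium shrink over the recording; such molecules
#' are rejected before barcode extraction. The per-frame molecule length is
#' regressed on frame index by ordinary least squares and the kymograph is
#' kept iff the relative slope (px/frame divided by mean length) is not
#' more negative than `-max_rel_slope`.
#'
#' @param k A `kymograph` with at least 10 frames.
#' @param max_rel_slope Threshold on the relative shrink rate per frame
#'   (default 5e-4).
#' @return Logical: keep the molecule?
#' @export
shrink_filter <- function(k, max_rel_slope = 5e-4) {
  stopifnot(inherits(k, "kymograph"))
  len <- k$extent$right - k$extent$left + 1
  if (length(len) < 10L) {
    stop("shrink filter needs at least 10 frames, got ", length(len),
         call. = FALSE)
  }
  t <- seq_along(len)
  slope <- stats::cov(t, len) / stats::var(t)
  (slope / mean(len)) >= -max_rel_slope
}

#' Convert a kymograph to a barcode
#'
#' Aligns each frame's in-extent trace to the running average by the
#' integer-pixel shift maximizing their Pearson correlation, then averages
#' all aligned frames per pixel. The output length is the median extent
#' length; time-averaging of F frames reduces uncorrelated noise variance
#' by about 1/F.
#'
#' @param k A `kymograph`.
#' @param max_shift Largest integer shift searched per frame.
#' @param id Barcode id for the result.
#' @return A `barcode`.
#' @export
kymo_to_barcode <- function(k, max_shift = 20L, id = "kymo") {
  stopifnot(inherits(k, "kymograph"))
  traces <- lapply(seq_len(nrow(k$intensity)), function(i) {
    k$intensity[i, k$extent$left[i]:k$extent$right[i]]
  })
  if (all(vapply(traces, function(v) all(v == 0), logical(1)))) {
    stop("all-zero kymograph frames", call. = FALSE)
  }
  L <- as.integer(round(stats::median(lengths(traces))))
  fit_len <- function(v) {
    if (length(v) == L) v
    else stats::approx(seq_along(v) - 1, v, xout = seq(0, length(v) - 1, length.out = L))$y
  }
  traces <- lapply(traces, fit_len)
  avg <- traces[[1]]
  aligned <- list(traces[[1]])
  for (i in seq_along(traces)[-1]) {
    v <- traces[[i]]
    best <- c(shift = 0L, pcc = -Inf)
    for (s in (-max_shift):max_shift) {
      i1 <- max(1L, 1L + s):min(L, L + s)
      i2 <- i1 - s
      if (length(i1) < 10L) next
      pcc <- suppressWarnings(stats::cor(avg[i1], v[i2]))
      if (is.finite(pcc) && pcc > best["pcc"]) best <- c(shift = s, pcc = pcc)
    }
    s <- as.integer(best["shift"])
    shifted <- rep(NA_real_, L)
    i1 <- max(1L, 1L + s):min(L, L + s)
    shifted[i1] <- v[i1 - s]
    aligned[[length(aligned) + 1L]] <- shifted
    stack <- do.call(rbind, aligned)
    avg <- colMeans(stack, na.rm = TRUE)
  }
  stack <- do.call(rbind, aligned)
  out <- colMeans(stack, na.rm = TRUE)
  barcode(id, out, source = "experimental")
}
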