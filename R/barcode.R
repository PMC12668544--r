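#' Construct a barcode
#'
#' A barcode is a one-dimensional fluorescence intensity profile along a
#' stretched single DNA molecule, one value per pixel. Barcodes are the atoms
#' of the assembler: everything downstream (overlap scoring, islands,
#' consensus) operates on them.
#'
#' @param id Character scalar, unique identifier.
#' @param intensity Numeric vector of per-pixel intensities (arbitrary
#'   fluorescence units). Must be finite and of length >= 2.
#' @param source One of `"experimental"`, `"synthetic"`, `"theoretical"`,
#'   `"consensus"`.
#' @return An object of class `barcode`: a list with elements `id`,
#'   `intensity` and `source`.
#' @export
barcode <- function(id, intensity, source = "experimental") {
  source <- match.arg(source, c("experimental", "synthetic", "theoretical", "consensus"))
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("barcode id must be a non-empty character scalar", call. = FALSE)
  }
  intensity <- as.numeric(intensity)
  if (length(intensity) < 2L) {
    stop("barcode '", id, "' must have at least 2 pixels", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("barcode '", id, "' contains non-finite intensities", call. = FALSE)
  }
  structure(list(id = id, intensity = intensity, source = source),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode '%s'> %d px, source=%s, mean=%.4g, sd=%.4g\n",
              x$id, n_px(x), x$source, mean(x$intensity), stats::sd(x$intensity)))
  invisible(x)
}

#' Number of pixels in a barcode
#' @param b A `barcode`.
#' @return Integer length of the intensity series.
#' @export
n_px <- function(b) length(b$intensity)

#' Construct a barcode set
#'
#' An ordered collection of barcodes with unique ids, plus the pixel size in
#' basepairs as carried metadata (it never enters the assembly itself).
#'
#' @param barcodes List of `barcode` objects.
#' @param pixel_to_bp Basepairs per pixel (metadata only).
#' @return An object of class `barcode_set`: a list of barcodes named by id,
#'   with attribute `pixel_to_bp`.
#' @export
barcode_set <- function(barcodes, pixel_to_bp = NA_real_) {
  if (length(barcodes) == 0L) stop("barcode set must be non-empty", call. = FALSE)
  ok <- vapply(barcodes, inherits, logical(1), what = "barcode")
  if (!all(ok)) stop("all elements must be barcode objects", call. = FALSE)
  ids <- vapply(barcodes, function(b) b$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate barcode ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(barcodes) <- ids
  structure(barcodes, pixel_to_bp = pixel_to_bp, class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  lens <- vapply(x, n_px, integer(1))
  cat(sprintf("<barcode_set> %d barcodes, lengths %d-%d px (median %.0f)\n",
              length(x), min(lens), max(lens), stats::median(lens)))
  invisible(x)
}

#' Z-normalize a barcode
#'
#' Centers to mean 0 and scales to standard deviation 1 (population
#' convention). All correlation machinery assumes z-normalized inputs; the
#' operation is idempotent.
#'
#' @param b A `barcode`.
#' @return The normalized `barcode`.
#' @export
znormalize <- function(b) {
  v <- b$intensity
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (!is.finite(s) || s <= 0) {
    stop("degenerate barcode '", b$id, "': zero variance, cannot z-normalize",
         call. = FALSE)
  }
  b$intensity <- (v - m) / s
  b
}

#' Length-rescale a barcode
#'
#' Resamples the intensity series to `round(r * n_px)` pixels by linear
#' interpolation on the uniform pixel grid. Used both for the reference-side
#' rescaling during overlap search and for simulating molecule-to-molecule
#' stretch variation.
#'
#' @param b A `barcode`.
#' @param r Positive rescaling factor.
#' @return The rescaled `barcode` (same id and source).
#' @export
rescale_barcode <- function(b, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("rescale factor r must be a positive finite number", call. = FALSE)
  }
  n <- n_px(b)
  m <- as.integer(round(r * n))
  if (m < 2L) stop("rescale of '", b$id, "' by r=", r, " leaves < 2 px", call. = FALSE)
  if (m == n && isTRUE(all.equal(r, 1))) return(b)
  b$intensity <- stats::approx(x = seq_len(n) - 1, y = b$intensity,
                               xout = seq(0, n - 1, length.out = m))$y
  b
}

#' Reverse a barcode
#'
#' Flips the pixel order (orientation change); an involution.
#'
#' @param b A `barcode`.
#' @return The reversed `barcode`.
#' @export
reverse_barcode <- function(b) {
  b$intensity <- rev(b$intensity)
  b
}

#' Read / write barcode sets as TSV
#'
#' The on-disk format is one row per barcode: `id<TAB>v1,v2,...` with
#' comma-joined full-precision floats. The round trip is lossless.
#'
#' @param path File path.
#' @param pixel_to_bp Basepairs per pixel recorded on the returned set.
#' @param source Source tag applied to all barcodes read.
#' @return `read_barcodes` returns a `barcode_set`; `write_barcodes`
#'   invisibly returns `path`.
#' @export
read_barcodes <- function(path, pixel_to_bp = NA_real_, source = "experimental") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty barcode file: ", path, call. = FALSE)
  bcs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("parse error at line ", i, " of ", path, ": expected id<TAB>values",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(strsplit(parts[[2]], ",", fixed = TRUE)[[1]]))
    if (length(vals) < 2L || anyNA(vals) || !all(is.finite(vals))) {
      stop("parse error at line ", i, " of ", path,
           ": non-numeric or non-finite intensity value", call. = FALSE)
    }
    bcs[[i]] <- barcode(parts[[1]], vals, source = source)
  }
  barcode_set(bcs, pixel_to_bp = pixel_to_bp)
}

#' @rdname read_barcodes
#' @param set A `barcode_set`.
#' @export
write_barcodes <- function(set, path) {
  stopifnot(inherits(set, "barcode_set"))
  lines <- vapply(set, function(b) {
    paste0(b$id, "\t", paste(format(b$intensity, digits = 17, trim = TRUE,
                                    scientific = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
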