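#' Simulation configuration for synthetic barcode datasets
#'
#' Defaults are the study conditions used throughout the package: fragments
#' of mean length 850 px (sd 100 px), random orientation, per-fragment
#' length-rescaling jitter with sd 0.02 (inside the +/-5% search grid), and
#' additive Gaussian noise controlled by the synthetic-noise variance ratio
#' SNVR = Var(signal) / Var(noise).
#'
#' @param n_barcodes Number of fragments to draw.
#' @param mean_len_px,sd_len_px Fragment length distribution (Normal,
#'   truncated below at `min_len_px` and above at the reference length).
#' @param snvr Synthetic-noise variance ratio (> 0); `Inf`-like large values
#'   give effectively noiseless fragments.
#' @param rescale_jitter_sd Standard deviation of the per-fragment
#'   length-rescaling factor around 1; 0 disables stretch jitter.
#' @param circular Whether fragments may wrap around the reference end.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param min_len_px Lower truncation for fragment lengths; defaults to the
#'   overlap window width (300 px) so every fragment can be scored.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_barcodes, mean_len_px = 850, sd_len_px = 100,
                       snvr = 1, rescale_jitter_sd = 0.02, circular = TRUE,
                       seed = 1L, min_len_px = 300L) {
  stopifnot(n_barcodes >= 1, mean_len_px >= min_len_px, sd_len_px >= 0,
            snvr > 0, rescale_jitter_sd >= 0, min_len_px >= 2)
  structure(list(n_barcodes = as.integer(n_barcodes), mean_len_px = mean_len_px,
                 sd_len_px = sd_len_px, snvr = snvr,
                 rescale_jitter_sd = rescale_jitter_sd, circular = circular,
                 seed = as.integer(seed), min_len_px = as.integer(min_len_px)),
            class = "sim_config")
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve x with kernel k; circular wrap or edge-renormalized linear.
convolve_kernel <- function(x, k, circular) {
  if (length(k) == 1L) return(x)
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (circular) {
    xp <- c(x[(n - half + 1L):n], x, x[1:half])
    out <- stats::filter(xp, k, method = "convolution", sides = 2)
    as.numeric(out[(half + 1L):(half + n)])
  } else {
    out <- stats::filter(c(rep(x[1], half), x, rep(x[n], half)), k,
                         method = "convolution", sides = 2)
    as.numeric(out[(half + 1L):(half + n)])
  }
}

#' Theoretical barcode from a DNA sequence
#'
#' Computes the expected intensity profile of a reference sequence under a
#' simplified generative model: the per-basepair GC indicator (N counts 0.5)
#' is averaged into pixels of `bp_per_px` basepairs and blurred with a
#' Gaussian point-spread function of width `psf_sigma_px` pixels (circular
#' convolution for circular genomes), then z-normalized. The model is
#' deliberately pluggable: any sequence-to-intensity map producing a smooth
#' pixel profile can replace it without touching the assembler.
#'
#' @param seq Character scalar DNA sequence over A, C, G, T, N.
#' @param bp_per_px Basepairs per pixel. The default 366.67 maps the
#'   4,641,652 bp E. coli K-12 reference to 12,659 px.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param circular Treat the sequence as circular.
#' @param id Barcode id.
#' @return A `theory_barcode`: a `barcode` with extra fields `bp_per_px`,
#'   `psf_sigma_px`, `circular`.
#' @export
theory_from_sequence <- function(seq, bp_per_px = 366.67, psf_sigma_px = 1.5,
                                 circular = TRUE, id = "theory") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len == 0L) stop("empty sequence", call. = FALSE)
  if (len < 2 * bp_per_px) {
    stop("sequence shorter than 2 pixels at ", bp_per_px, " bp/px", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) stop("sequence contains non-ACGTN characters", call. = FALSE)
  gc <- ifelse(chars %in% c("G", "C"), 1, ifelse(chars == "N", 0.5, 0))
  npx <- as.integer(round(len / bp_per_px))
  # bin bp -> px on a uniform grid
  idx <- pmin(npx, floor((seq_len(len) - 1) / len * npx) + 1L)
  sums <- rowsum(gc, idx)
  cnts <- tabulate(idx, nbins = npx)
  prof <- as.numeric(sums) / cnts
  prof <- convolve_kernel(prof, gaussian_kernel(psf_sigma_px), circular)
  b <- barcode(id, prof, source = "theoretical")
  b <- znormalize(b)
  b$bp_per_px <- bp_per_px
  b$psf_sigma_px <- psf_sigma_px
  b$circular <- circular
  class(b) <- c("theory_barcode", "barcode")
  b
}

#' Theoretical barcode from a FASTA file
#'
#' Reads the first record of a FASTA file (via Biostrings) and delegates to
#' [theory_from_sequence()].
#'
#' @inheritParams theory_from_sequence
#' @param fasta Path to a FASTA file.
#' @export
theory_from_fasta <- function(fasta, bp_per_px = 366.67, psf_sigma_px = 1.5,
                              circular = TRUE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA files", call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) == 0L) stop("no sequences in ", fasta, call. = FALSE)
  theory_from_sequence(as.character(ss[[1]]), bp_per_px = bp_per_px,
                       psf_sigma_px = psf_sigma_px, circular = circular,
                       id = names(ss)[[1]])
}

#' Random PSF-smoothed reference barcode
#'
#' Gaussian white noise circularly convolved with the PSF kernel and
#' z-normalized. Serves as a download-free reference both for null-model
#' calibration and for simulated assembly experiments: it shares the
#' second-order statistics (smoothness scale) of theory barcodes without any
#' genomic structure.
#'
#' @param length_px Number of pixels (>= 10 * psf_sigma_px).
#' @param psf_sigma_px PSF standard deviation in pixels (0 gives white noise).
#' @param seed Integer seed.
#' @param id Barcode id.
#' @param circular Circular flag recorded on the result (the convolution is
#'   always circular so the series is stationary).
#' @return A `theory_barcode`.
#' @export
random_reference <- function(length_px, psf_sigma_px = 1.5, seed = 1L,
                             id = "random_ref", circular = TRUE) {
  length_px <- as.integer(length_px)
  if (length_px < 10 * max(psf_sigma_px, 1)) {
    stop("length_px too short for psf_sigma_px = ", psf_sigma_px, call. = FALSE)
  }
  x <- with_split_seed(seed, 0L, stats::rnorm(length_px))
  prof <- convolve_kernel(x, gaussian_kernel(psf_sigma_px), circular = TRUE)
  b <- barcode(id, prof, source = "synthetic")
  b <- znormalize(b)
  b$bp_per_px <- NA_real_
  b$psf_sigma_px <- psf_sigma_px
  b$circular <- circular
  class(b) <- c("theory_barcode", "barcode")
  b
}

#' Add synthetic noise at a given SNVR
#'
#' Adds i.i.d. Gaussian noise with variance `Var(signal) / snvr` per pixel,
#' so SNVR is the ratio of signal variance to added-noise variance. Noise is
#' added after PSF blurring (the camera sees the blurred profile).
#'
#' @param fragment A `barcode`.
#' @param snvr Positive synthetic-noise variance ratio.
#' @param seed Integer seed.
#' @return The noisy `barcode`.
#' @export
add_noise <- function(fragment, snvr, seed = 1L) {
  stopifnot(snvr > 0)
  v <- fragment$intensity
  s2 <- stats::var(v)
  if (!is.finite(s2) || s2 <= 0) {
    stop("zero-variance signal: cannot scale noise for '", fragment$id, "'",
         call. = FALSE)
  }
  eps <- with_split_seed(seed, 1L, stats::rnorm(length(v), sd = sqrt(s2 / snvr)))
  fragment$intensity <- v + eps
  fragment
}

#' Sample synthetic fragments with ground truth
#'
#' Draws `cfg$n_barcodes` fragments from a theory barcode: start positions
#' uniform on the (optionally circular) reference, lengths Normal(mean, sd)
#' truncated to `[min_len_px, reference length]`, orientation uniform on
#' +/-, per-fragment length rescaling Normal(1, rescale_jitter_sd), then
#' additive noise at the configured SNVR. The ground-truth table records the
#' exact draws, sufficient to reconstruct each noiseless fragment
#' bit-exactly.
#'
#' @param theory A `theory_barcode`.
#' @param cfg A [sim_config()].
#' @return List with `set` (a `barcode_set`) and `gt` (data.frame with
#'   columns barcode_id, gt_start (0-based px), gt_orientation, gt_rescale,
#'   gt_length).
#' @export
sample_fragments <- function(theory, cfg) {
  stopifnot(inherits(theory, "barcode"), inherits(cfg, "sim_config"))
  L <- n_px(theory)
  if (cfg$mean_len_px > L) stop("mean fragment length exceeds reference length", call. = FALSE)
  circ <- isTRUE(cfg$circular) && isTRUE(theory$circular)
  n <- cfg$n_barcodes
  draws <- with_split_seed(cfg$seed, 2L, {
    len <- round(stats::rnorm(n, cfg$mean_len_px, cfg$sd_len_px))
    len <- pmin(pmax(len, cfg$min_len_px), L)
    start <- if (circ) sample.int(L, n, replace = TRUE) - 1L else {
      vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
    }
    orient <- sample(c("+", "-"), n, replace = TRUE)
    resc <- if (cfg$rescale_jitter_sd > 0) stats::rnorm(n, 1, cfg$rescale_jitter_sd) else rep(1, n)
    list(len = as.integer(len), start = as.integer(start), orient = orient,
         resc = resc)
  })
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("frag%0", width, "d"), seq_len(n))
  bcs <- vector("list", n)
  for (i in seq_len(n)) {
    idx0 <- draws$start[i] + seq_len(draws$len[i]) - 1L
    idx <- if (circ) (idx0 %% L) + 1L else idx0 + 1L
    vals <- theory$intensity[idx]
    b <- barcode(ids[i], vals, source = "synthetic")
    if (draws$orient[i] == "-") b <- reverse_barcode(b)
    if (draws$resc[i] != 1) b <- rescale_barcode(b, draws$resc[i])
    if (is.finite(cfg$snvr)) b <- add_noise(b, cfg$snvr, seed = split_seed(cfg$seed, 100L + i))
    bcs[[i]] <- b
  }
  gt <- data.frame(barcode_id = ids, gt_start = draws$start,
                   gt_orientation = draws$orient, gt_rescale = draws$resc,
                   gt_length = draws$len, stringsAsFactors = FALSE)
  list(set = barcode_set(bcs, pixel_to_bp = theory$bp_per_px), gt = gt)
}

#' Write / read a ground-truth table
#' @param gt Ground-truth data.frame from [sample_fragments()].
#' @param path File path.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character",
                                   "numeric", "integer"))
}
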