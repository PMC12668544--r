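#' Consensus generation parameters
#'
#' @param pcc_cutoff Single-linkage cluster cutoff on PCC (clusters are cut
#'   at distance 1 - pcc_cutoff; default 0.5).
#' @param min_overlap Minimum shared pixels for a pairwise PCC to count
#'   (default: the overlap window width, 300 px).
#' @param max_stretch Maximum stretch/compression during realignment
#'   (default 0.05, i.e. +/-5%).
#' @param iterations Number of amplitude-adjust / draft / realign rounds
#'   (the pipeline's X; default 5).
#' @param stretch_step Grid step for the realignment stretch search
#'   (default 0.01, matching the rescale grid resolution).
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(pcc_cutoff = 0.5, min_overlap = 300L,
                             max_stretch = 0.05, iterations = 5L,
                             stretch_step = 0.01) {
  stopifnot(pcc_cutoff > 0, pcc_cutoff < 1, min_overlap >= 2,
            max_stretch > 0, max_stretch < 1, iterations >= 0)
  structure(list(pcc_cutoff = pcc_cutoff, min_overlap = as.integer(min_overlap),
                 max_stretch = max_stretch, iterations = as.integer(iterations),
                 stretch_step = stretch_step),
            class = "consensus_params")
}

#' Pairwise PCC table of an island
#'
#' Pearson correlations over the mutually covered island columns for every
#' pair of placed barcodes whose shared coverage is at least `min_overlap`
#' pixels; pairs below that are NA (absent).
#'
#' @param layout An `island_layout`.
#' @param set The `barcode_set`.
#' @param min_overlap Minimum shared pixel count.
#' @param block Optional precomputed block matrix (rows in layout order).
#' @return Symmetric matrix of PCCs with NA diagonal/absent pairs.
#' @export
island_pairwise_pcc <- function(layout, set, min_overlap = 300L, block = NULL) {
  if (is.null(block)) block <- block_matrix(layout, set)
  n <- nrow(block)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(block), rownames(block)))
  if (n < 2L) return(out)
  cov <- !is.na(block)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- which(cov[i, ] & cov[j, ])
      if (length(shared) < min_overlap) next
      out[i, j] <- out[j, i] <- cpp_pcc_at(block[i, ], block[j, ],
                                           shared - 1L, shared - 1L)
    }
  }
  out
}

# Mean / population sd of x over index set idx.
overlap_stats <- function(x, idx) {
  v <- x[idx]
  m <- mean(v)
  list(mu = m, sigma = sqrt(mean((v - m)^2)))
}

#' Amplitude-adjust the barcodes of an island
#'
#' Corrects molecule-to-molecule intensity differences (illumination,
#' photobleaching, staining) before averaging. Barcodes are single-linkage
#' clustered on distance 1 - PCC and the tree is cut at 1 - `pcc_cutoff`;
#' within clusters, merge nodes are traversed from the highest PCC downward
#' and at each node the best-correlated pair (i1, i2) across the two merged
#' groups is mapped to the common mean (mu_i1 + mu_i2)/2 and the common
#' standard deviation sqrt((sigma_i1^2 + sigma_i2^2)/2), with the statistics
#' taken over the pair's mutual overlap region so that after the correction
#' the two barcodes match there exactly. Barcodes outside every cluster are
#' left unadjusted.
#'
#' @param layout An `island_layout`.
#' @param set The `barcode_set`.
#' @param params A [consensus_params()].
#' @param znorm Start from z-normalized copies (the pipeline default); set
#'   FALSE to adjust the raw intensities, e.g. when molecule-to-molecule
#'   amplitude differences are themselves of interest.
#' @return Named list of adjusted intensity vectors in barcode raw frame,
#'   one per layout row.
#' @export
amplitude_adjust <- function(layout, set, params = consensus_params(),
                             znorm = TRUE) {
  ids <- layout$barcode_id
  vals <- stats::setNames(lapply(ids, function(id) {
    if (znorm) znormalize(set[[id]])$intensity else set[[id]]$intensity
  }), ids)
  if (length(ids) < 2L) return(vals)
  block <- block_matrix(layout, set, znorm = FALSE,
                        values = vals)
  pcc <- island_pairwise_pcc(layout, set, min_overlap = params$min_overlap,
                             block = block)
  if (all(is.na(pcc))) return(vals)
  d <- 1 - pcc
  d[is.na(d)] <- 2            # absent pairs: farther than any real distance
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  # merge nodes with height <= 1 - cutoff, processed by ascending height
  # (descending PCC); ties by merge order (id-stable from hclust input order)
  node_order <- order(hc$height, seq_along(hc$height))
  groups <- lapply(seq_along(ids), function(i) i)   # leaf -> member indices
  node_members <- vector("list", length(hc$height))
  cov <- !is.na(block)
  for (k in node_order) {
    if (hc$height[k] > 1 - params$pcc_cutoff) next
    left <- hc$merge[k, 1]; right <- hc$merge[k, 2]
    lm <- if (left < 0) -left else node_members[[left]]
    rm_ <- if (right < 0) -right else node_members[[right]]
    node_members[[k]] <- c(lm, rm_)
    # best-correlated pair across the two groups
    sub <- pcc[lm, rm_, drop = FALSE]
    if (all(is.na(sub))) next
    best <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i1 <- lm[best[1]]; i2 <- rm_[best[2]]
    shared <- which(cov[i1, ] & cov[i2, ])
    if (length(shared) < 2L) next
    # island columns -> barcode raw indices for the shared stretch
    adj <- function(i) {
      rowvals <- block[i, ]
      st <- overlap_stats(rowvals, shared)
      st
    }
    s1 <- adj(i1); s2 <- adj(i2)
    if (s1$sigma <= 0 || s2$sigma <= 0) next
    mu_t <- (s1$mu + s2$mu) / 2
    s_t <- sqrt((s1$sigma^2 + s2$sigma^2) / 2)
    vals[[ids[i1]]] <- (vals[[ids[i1]]] - s1$mu) * (s_t / s1$sigma) + mu_t
    vals[[ids[i2]]] <- (vals[[ids[i2]]] - s2$mu) * (s_t / s2$sigma) + mu_t
    block[i1, cov[i1, ]] <- (block[i1, cov[i1, ]] - s1$mu) * (s_t / s1$sigma) + mu_t
    block[i2, cov[i2, ]] <- (block[i2, cov[i2, ]] - s2$mu) * (s_t / s2$sigma) + mu_t
  }
  vals
}

#' Draft consensus from a block matrix
#'
#' Per-column mean over covered cells only (missing cells are never counted
#' as zeros), with per-position coverage. Zero-coverage columns are trimmed
#' at the ends; internal zero-coverage columns are linearly interpolated and
#' reported with coverage 0.
#'
#' @param block A `block_matrix`.
#' @param island_id Identifier carried on the result.
#' @return A `consensus_barcode`: list with `island_id`, `intensity`,
#'   `coverage`, `iterations_run`.
#' @export
draft_consensus <- function(block, island_id = "island1") {
  if (nrow(block) == 0L) stop("empty block", call. = FALSE)
  cov <- colSums(!is.na(block))
  if (all(cov == 0)) stop("all-missing block", call. = FALSE)
  keep <- range(which(cov > 0))
  cols <- keep[1]:keep[2]
  vals <- colMeans(block[, cols, drop = FALSE], na.rm = TRUE)
  covv <- cov[cols]
  if (any(covv == 0)) {
    good <- which(covv > 0)
    vals[covv == 0] <- stats::approx(good, vals[good], xout = which(covv == 0))$y
  }
  structure(list(island_id = island_id, intensity = as.numeric(vals),
                 coverage = as.integer(covv), iterations_run = 0L,
                 offset = keep[1] - 1L),
            class = "consensus_barcode")
}

#' @export
print.consensus_barcode <- function(x, ...) {
  cat(sprintf("<consensus_barcode '%s'> %d px, coverage %d-%d (mean %.1f), %d iteration(s)\n",
              x$island_id, length(x$intensity), min(x$coverage), max(x$coverage),
              mean(x$coverage), x$iterations_run))
  invisible(x)
}

#' Realign island members to a consensus
#'
#' Each barcode is independently re-placed by its best full-length PCC
#' against the consensus over all offsets and a stretch grid within
#' +/- `max_stretch` of its current rescale (orientation fixed). Stretches
#' that hit the grid boundary are kept (clipped to the searched range). The
#' returned layout is re-normalized to min start 0.
#'
#' @param layout An `island_layout`.
#' @param set The `barcode_set`.
#' @param consensus A `consensus_barcode`.
#' @param params A [consensus_params()].
#' @param values Optional adjusted intensities (as from
#'   [amplitude_adjust()]) to align instead of z-normalized originals.
#' @param base_rescale Per-row rescale factors the stretch window is
#'   anchored to (defaults to the layout's current factors). The iterative
#'   pipeline anchors to the assembly-time factors so the total stretch
#'   stays within +/- `max_stretch` across all rounds rather than
#'   compounding.
#' @return The updated `island_layout`.
#' @export
realign_to_consensus <- function(layout, set, consensus,
                                 params = consensus_params(), values = NULL,
                                 base_rescale = NULL) {
  cons <- consensus$intensity
  stretches <- seq(1 - params$max_stretch, 1 + params$max_stretch,
                   by = params$stretch_step)
  if (is.null(base_rescale)) base_rescale <- layout$rescale
  out <- layout
  for (i in seq_len(nrow(layout))) {
    id <- layout$barcode_id[i]
    v <- if (!is.null(values) && !is.null(values[[id]])) values[[id]]
         else znormalize(set[[id]])$intensity
    if (layout$orientation[i] == "-") v <- rev(v)
    n <- length(v)
    best <- NULL
    for (s in stretches) {
      r_new <- base_rescale[i] * s
      m <- as.integer(round(r_new * n))
      if (m < 8L || m > length(cons)) next
      vv <- stats::approx(seq_len(n) - 1, v, xout = seq(0, n - 1, length.out = m))$y
      hit <- cpp_best_window_pcc(cons, vv, m)
      if (is.na(hit$C)) next
      if (is.null(best) || hit$C > best$C + 1e-12) {
        best <- list(C = hit$C, start = hit$l1, r = r_new, m = m)
      }
    }
    if (!is.null(best)) {
      out$start[i] <- best$start + consensus$offset
      out$stop[i] <- out$start[i] + best$m
      out$rescale[i] <- best$r
    }
  }
  shift <- min(out$start)
  out$start <- as.integer(out$start - shift)
  out$stop <- as.integer(out$stop - shift)
  out
}

#' Run the consensus pipeline on one island
#'
#' Iterates amplitude adjustment, column-mean drafting and realignment
#' `iterations` times (the pipeline's X), then drafts the final consensus
#' from the final adjusted layout. Island membership never changes; only
#' amplitudes and placements do.
#'
#' @param layout An `island_layout`.
#' @param set The `barcode_set`.
#' @param params A [consensus_params()].
#' @return List with `consensus` (a `consensus_barcode`) and `layout` (the
#'   final `island_layout`).
#' @export
run_consensus <- function(layout, set, params = consensus_params()) {
  island_id <- attr(layout, "island_id") %||% "island1"
  if (params$iterations == 0L) {
    cons <- draft_consensus(block_matrix(layout, set), island_id)
    return(list(consensus = cons, layout = layout))
  }
  cur <- layout
  base_rescale <- layout$rescale
  for (it in seq_len(params$iterations)) {
    vals <- amplitude_adjust(cur, set, params)
    block <- block_matrix(cur, set, values = vals)
    cons <- draft_consensus(block, island_id)
    cur <- realign_to_consensus(cur, set, cons, params, values = vals,
                                base_rescale = base_rescale)
    attr(cur, "island_id") <- island_id
    class(cur) <- c("island_layout", "data.frame")
  }
  vals <- amplitude_adjust(cur, set, params)
  cons <- draft_consensus(block_matrix(cur, set, values = vals), island_id)
  cons$iterations_run <- params$iterations
  list(consensus = cons, layout = cur)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a consensus barcode as TSV (`position  intensity  coverage`)
#' @param consensus A `consensus_barcode`.
#' @param path Output file.
#' @export
write_consensus <- function(consensus, path) {
  utils::write.table(
    data.frame(position = seq_along(consensus$intensity) - 1L,
               intensity = consensus$intensity,
               coverage = consensus$coverage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
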