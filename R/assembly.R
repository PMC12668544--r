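#' Assembly consistency parameters
#'
#' Tolerances for accepting an overlap into the graph: the maximum allowed
#' pixel difference between the implied and existing placements, and the
#' maximum allowed relative difference between rescaling factors.
#'
#' @param px_diff Allowed pixel difference (default 50 px: comfortably above
#'   the few-px scatter of correct placements, well below the scale of
#'   genuine misplacements).
#' @param sc_diff Allowed relative scaling difference (default 0.05, the
#'   span of the rescaling search grid).
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(px_diff = 50, sc_diff = 0.05) {
  stopifnot(px_diff > 0, sc_diff > 0)
  structure(list(px_diff = px_diff, sc_diff = sc_diff),
            class = "assembly_params")
}

# --- placement geometry -----------------------------------------------------
# A placement is list(p, o, r): barcode raw pixel u maps to island coordinate
#   p + r * u          (o == "+")
#   p + r * (n - u)    (o == "-")
# so the placed interval is [p, p + r * n] for either orientation.

flip_o <- function(o) if (o == "+") "-" else "+"

# Placement of the reference implied by the query's placement and an edge
# (edge: d, r, off = l2 - l1 in query raw coordinates, n_ref, n_query).
compose_placement <- function(pl_q, edge, n_ref, n_query) {
  r_i <- pl_q$r * edge$r
  o_i <- if (edge$d == "+") pl_q$o else flip_o(pl_q$o)
  p_i <- if (pl_q$o == "+") {
    pl_q$p + pl_q$r * edge$off
  } else {
    pl_q$p + pl_q$r * (n_query - edge$off) - r_i * n_ref
  }
  list(p = p_i, o = o_i, r = r_i)
}

# Affine frame map x_B = q + s * x_A (f == "+") or x_B = q - s * x_A
# (f == "-") sending placement pl_A of a barcode of n raw px to pl_B.
frame_map <- function(pl_A, pl_B, n) {
  s <- pl_B$r / pl_A$r
  f <- if (pl_A$o == pl_B$o) "+" else "-"
  q <- if (f == "+") pl_B$p - s * pl_A$p else pl_B$p + s * (pl_A$p + pl_A$r * n)
  list(q = q, s = s, f = f)
}

apply_frame_map <- function(m, pl, n) {
  if (m$f == "+") {
    list(p = m$q + m$s * pl$p, o = pl$o, r = m$s * pl$r)
  } else {
    list(p = m$q - m$s * (pl$p + pl$r * n), o = flip_o(pl$o), r = m$s * pl$r)
  }
}

invert_frame_map <- function(m) {
  if (m$f == "+") list(q = -m$q / m$s, s = 1 / m$s, f = "+")
  else list(q = m$q / m$s, s = 1 / m$s, f = "-")
}

#' Consistency of two placements of the same barcode
#'
#' Two placements (in the same frame) are consistent when their orientations
#' agree, their rescaling factors differ by at most `sc_diff` relatively,
#' and their start positions differ by at most `px_diff` pixels.
#'
#' @param placement_a,placement_b Placements: lists with `p` (start px),
#'   `o` (`"+"`/`"-"`), `r` (rescale).
#' @param p An [assembly_params()].
#' @return Logical.
#' @export
consistent <- function(placement_a, placement_b, p = assembly_params()) {
  placement_a$o == placement_b$o &&
    abs(placement_a$r / placement_b$r - 1) <= p$sc_diff &&
    abs(placement_a$p - placement_b$p) <= p$px_diff
}

# --- graph state ------------------------------------------------------------

new_assembly_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$placement <- list()   # id -> list(p, o, r)
  g$comp_of <- character(0)
  g$members <- list()     # comp id -> character vector
  g$pending <- list()     # merge tables: deferred overlaps
  g$log <- list()
  g$ncomp <- 0L
  g
}

edge_of <- function(row) {
  list(d = row$d, r = row$r, off = row$l2 - row$l1,
       q = row$query_id, ref = row$ref_id, s = row$s_stouffer)
}

# Implied island-frame placement of `new_id` (one endpoint of `edge`), given
# that the other endpoint is already placed.
implied_placement <- function(edge, new_id, g, lens) {
  if (edge$ref == new_id) {
    pl_q <- g$placement[[edge$q]]
    compose_placement(pl_q, edge, lens[[edge$ref]], lens[[edge$q]])
  } else {
    pl_ref <- g$placement[[edge$ref]]
    # reference's placement in the query's own frame
    pl_ref_qframe <- list(p = edge$off, o = edge$d, r = edge$r)
    m <- frame_map(pl_ref_qframe, pl_ref, lens[[edge$ref]])
    apply_frame_map(m, list(p = 0, o = "+", r = 1), lens[[edge$q]])
  }
}

# Frame map comp(other endpoint of edge) -> comp(anchored endpoint): maps the
# frame holding edge$ref onto the frame holding edge$q... generalized below.
# Returns the map FROM the component frame of `from_id` TO that of `to_id`,
# where from_id and to_id are the edge's two endpoints in different comps.
cross_map <- function(edge, from_id, to_id, g, lens) {
  impl <- implied_placement(edge, from_id, g, lens)  # from_id in to_id's frame
  frame_map(g$placement[[from_id]], impl, lens[[from_id]])
}

accept_edge <- function(g, edge, status = "accepted", reason = "") {
  g$log[[length(g$log) + 1L]] <-
    data.frame(query_id = edge$q, ref_id = edge$ref, s_stouffer = edge$s,
               status = status, reason = reason, stringsAsFactors = FALSE)
  invisible(g)
}

place_vertex <- function(g, id, pl, comp) {
  g$placement[[id]] <- pl
  g$comp_of[[id]] <- comp
  g$members[[comp]] <- c(g$members[[comp]], id)
  invisible(g)
}

#' Add one significant overlap to the assembly graph
#'
#' Implements the four-case merge logic. Case 1, both barcodes new: start a
#' new component. Cases 2/3, one barcode new: the overlap is accepted only
#' if a previously deferred overlap in the component's merge table connects
#' the same new barcode consistently; otherwise it is deferred. Case 4, both
#' placed: within one component the edge is accepted iff it agrees with the
#' current placements; across components, a consistent second independent
#' overlap triggers a component merge (the smaller component's frame is
#' re-anchored onto the larger), otherwise the overlap joins the merge
#' table. Overlaps must be presented in descending Stouffer order.
#'
#' @param g An assembly graph (from `build_islands`'s internals).
#' @param row One row of a significant-overlap data.frame.
#' @param set The `barcode_set`.
#' @param p An [assembly_params()].
#' @return The (mutated) graph, invisibly.
#' @export
add_overlap <- function(g, row, set, p = assembly_params()) {
  lens <- lapply(set, n_px)
  edge <- edge_of(row)
  qin <- !is.null(g$placement[[edge$q]])
  rin <- !is.null(g$placement[[edge$ref]])

  if (!qin && !rin) {                       # case 1: both new
    g$ncomp <- g$ncomp + 1L
    comp <- paste0("c", g$ncomp)
    g$members[[comp]] <- character(0)
    pl_q <- list(p = 0, o = "+", r = 1)
    place_vertex(g, edge$q, pl_q, comp)
    place_vertex(g, edge$ref,
                 compose_placement(pl_q, edge, lens[[edge$ref]], lens[[edge$q]]),
                 comp)
    accept_edge(g, edge)
    return(invisible(g))
  }

  if (xor(qin, rin)) {                      # case 2/3: one new
    new_id <- if (qin) edge$ref else edge$q
    comp <- g$comp_of[[if (qin) edge$q else edge$ref]]
    impl_now <- implied_placement(edge, new_id, g, lens)
    hit <- NULL
    for (k in seq_along(g$pending)) {
      pe <- g$pending[[k]]
      other <- setdiff(c(pe$q, pe$ref), new_id)
      if (!(new_id %in% c(pe$q, pe$ref))) next
      if (is.null(g$placement[[other]])) next
      if (g$comp_of[[other]] != comp) next
      impl_prev <- implied_placement(pe, new_id, g, lens)
      if (consistent(impl_prev, impl_now, p)) { hit <- k; break }
    }
    if (!is.null(hit)) {
      pe <- g$pending[[hit]]
      place_vertex(g, new_id, implied_placement(pe, new_id, g, lens), comp)
      g$pending[[hit]] <- NULL
      accept_edge(g, pe, reason = "resolved from merge table")
      accept_edge(g, edge)
    } else {
      g$pending[[length(g$pending) + 1L]] <- edge
      accept_edge(g, edge, status = "deferred", reason = "awaiting confirming overlap")
    }
    return(invisible(g))
  }

  # case 4: both placed
  comp_q <- g$comp_of[[edge$q]]
  comp_r <- g$comp_of[[edge$ref]]
  if (comp_q == comp_r) {
    impl <- implied_placement(edge, edge$ref, g, lens)
    if (consistent(g$placement[[edge$ref]], impl, p)) {
      accept_edge(g, edge)
    } else {
      accept_edge(g, edge, status = "dropped",
                  reason = "inconsistent with existing placements")
    }
    return(invisible(g))
  }
  # cross-component: need a second, consistent overlap in the merge table
  map_now <- cross_map(edge, edge$ref, edge$q, g, lens)  # comp_r -> comp_q
  hit <- NULL
  for (k in seq_along(g$pending)) {
    pe <- g$pending[[k]]
    if (is.null(g$placement[[pe$q]]) || is.null(g$placement[[pe$ref]])) next
    cq <- g$comp_of[[pe$q]]; cr <- g$comp_of[[pe$ref]]
    if (identical(sort(c(cq, cr)), sort(c(comp_q, comp_r))) &&
        !(pe$q == edge$q && pe$ref == edge$ref)) {
      map_prev <- if (cr == comp_r) cross_map(pe, pe$ref, pe$q, g, lens)
                  else invert_frame_map(cross_map(pe, pe$q, pe$ref, g, lens))
      # both maps are comp_r -> comp_q; compare flip, scale, and a test point
      x0 <- g$placement[[edge$ref]]$p
      pt_now <- if (map_now$f == "+") map_now$q + map_now$s * x0 else map_now$q - map_now$s * x0
      pt_prev <- if (map_prev$f == "+") map_prev$q + map_prev$s * x0 else map_prev$q - map_prev$s * x0
      if (map_now$f == map_prev$f &&
          abs(map_now$s / map_prev$s - 1) <= p$sc_diff &&
          abs(pt_now - pt_prev) <= p$px_diff) {
        hit <- k
        attr(hit, "map") <- map_prev
        break
      }
    }
  }
  if (!is.null(hit)) {
    m <- attr(hit, "map")                   # comp_r -> comp_q (higher-score pair)
    if (length(g$members[[comp_r]]) > length(g$members[[comp_q]])) {
      m <- invert_frame_map(m)              # re-anchor the smaller component
      src <- comp_q; dst <- comp_r
    } else {
      src <- comp_r; dst <- comp_q
    }
    for (id in g$members[[src]]) {
      g$placement[[id]] <- apply_frame_map(m, g$placement[[id]], lens[[id]])
      g$comp_of[[id]] <- dst
    }
    g$members[[dst]] <- c(g$members[[dst]], g$members[[src]])
    g$members[[src]] <- NULL
    pe <- g$pending[[hit[[1]]]]
    g$pending[[hit[[1]]]] <- NULL
    accept_edge(g, pe, reason = "component merge")
    accept_edge(g, edge, reason = "component merge")
  } else {
    g$pending[[length(g$pending) + 1L]] <- edge
    accept_edge(g, edge, status = "deferred",
                reason = "awaiting confirming cross-component overlap")
  }
  invisible(g)
}

#' Build barcode islands from significant overlaps
#'
#' Feeds the significant overlaps, in descending Stouffer order (ties broken
#' by query then reference id), through the consistency-checked merge logic
#' and emits one island layout per connected component with at least two
#' members. Barcodes that never acquire an accepted edge are reported as
#' unplaced, not as one-barcode islands.
#'
#' @param sig Significant-overlap data.frame (from [filter_significant()]).
#' @param set The `barcode_set`.
#' @param p An [assembly_params()].
#' @return List with `graph` (internal graph state), `islands` (list of
#'   `island_layout` data.frames: barcode_id, start, stop, orientation,
#'   rescale; starts normalized to min 0), `edge_log` (per-overlap
#'   accept/defer/drop record), and `unplaced` ids.
#' @export
build_islands <- function(sig, set, p = assembly_params()) {
  g <- new_assembly_graph()
  if (nrow(sig) > 0L) {
    sig <- sig[order(-sig$s_stouffer, sig$query_id, sig$ref_id), , drop = FALSE]
    for (i in seq_len(nrow(sig))) add_overlap(g, sig[i, ], set, p)
  }
  comps <- names(g$members)
  islands <- list()
  for (comp in comps) {
    ids <- sort(g$members[[comp]])
    if (length(ids) < 2L) next
    rows <- lapply(ids, function(id) {
      pl <- g$placement[[id]]
      n <- n_px(set[[id]])
      data.frame(barcode_id = id, start = pl$p,
                 stop = pl$p + round(pl$r * n),
                 orientation = pl$o, rescale = pl$r, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    shift <- min(tab$start)
    tab$start <- as.integer(round(tab$start - shift))
    tab$stop <- tab$start + as.integer(round(tab$rescale * vapply(ids, function(id) n_px(set[[id]]), integer(1))))
    rownames(tab) <- NULL
    attr(tab, "island_id") <- paste0("island", length(islands) + 1L)
    class(tab) <- c("island_layout", "data.frame")
    islands[[length(islands) + 1L]] <- tab
  }
  # order islands by size descending for stable reporting
  if (length(islands) > 1L) {
    ord <- order(-vapply(islands, nrow, integer(1)),
                 vapply(islands, function(t) t$barcode_id[1], character(1)))
    islands <- islands[ord]
    for (i in seq_along(islands)) attr(islands[[i]], "island_id") <- paste0("island", i)
  }
  edge_log <- if (length(g$log)) do.call(rbind, g$log) else
    data.frame(query_id = character(0), ref_id = character(0),
               s_stouffer = numeric(0), status = character(0),
               reason = character(0))
  placed <- names(g$placement)[vapply(names(g$placement), function(id) {
    any(edge_log$status == "accepted" &
          (edge_log$query_id == id | edge_log$ref_id == id))
  }, logical(1))]
  unplaced <- setdiff(names(set), placed)
  list(graph = g, islands = islands, edge_log = edge_log, unplaced = unplaced)
}

#' Block representation of an island
#'
#' A matrix with one row per island member (z-normalized by default,
#' oriented and rescaled to its placed width) over the island's pixel
#' columns; cells not covered by a barcode are NA (missing), never zero.
#'
#' @param layout An `island_layout`.
#' @param set The `barcode_set`.
#' @param znorm Z-normalize each row before placing (default TRUE).
#' @param values Optional named list of intensity vectors (raw barcode
#'   frame) overriding the set's values, e.g. amplitude-adjusted copies.
#' @return Numeric matrix with rownames = barcode ids, class `block_matrix`.
#' @export
block_matrix <- function(layout, set, znorm = TRUE, values = NULL) {
  stopifnot(inherits(layout, "island_layout"))
  span <- max(layout$stop)
  if (min(layout$start) < 0) stop("layout has negative start positions", call. = FALSE)
  mat <- matrix(NA_real_, nrow = nrow(layout), ncol = span,
                dimnames = list(layout$barcode_id, NULL))
  for (i in seq_len(nrow(layout))) {
    id <- layout$barcode_id[i]
    b <- set[[id]]
    if (is.null(b)) stop("layout references unknown barcode '", id, "'", call. = FALSE)
    v <- if (!is.null(values) && !is.null(values[[id]])) values[[id]] else {
      if (znorm) znormalize(b)$intensity else b$intensity
    }
    if (layout$orientation[i] == "-") v <- rev(v)
    m <- layout$stop[i] - layout$start[i]
    if (m > span || layout$stop[i] > span) stop("placement out of range", call. = FALSE)
    if (length(v) != m) {
      v <- stats::approx(seq_along(v) - 1, v, xout = seq(0, length(v) - 1, length.out = m))$y
    }
    mat[i, (layout$start[i] + 1L):layout$stop[i]] <- v
  }
  class(mat) <- c("block_matrix", class(mat))
  mat
}

#' Write island layout tables / export the overlap graph as DOT
#'
#' @param islands List of `island_layout` tables.
#' @param dir Output directory.
#' @export
write_islands <- function(islands, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in islands) {
    utils::write.table(as.data.frame(tab),
                       file.path(dir, paste0(attr(tab, "island_id"), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_islands
#' @param edge_log Edge log from [build_islands()].
#' @param path Output DOT file.
#' @export
export_graph_dot <- function(edge_log, path) {
  acc <- edge_log[edge_log$status == "accepted", , drop = FALSE]
  lines <- c("graph overlaps {",
             sprintf('  "%s" -- "%s" [label="%.2f"];',
                     acc$query_id, acc$ref_id, acc$s_stouffer),
             "}")
  writeLines(lines, path)
  invisible(path)
}
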