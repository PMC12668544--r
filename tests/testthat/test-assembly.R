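# Independent pixel-mapping oracle: island coordinate of reference raw
# pixel u, derived by mapping through the query's placement, without the
# package's placement composition.
map_ref_pixel <- function(pl_q, edge, n_ref, n_query, u) {
  # ref raw pixel u in query raw coordinates
  x <- if (edge$d == "+") edge$off + edge$r * u else edge$off + edge$r * (n_ref - u)
  # query raw coordinate x in island coordinates
  if (pl_q$o == "+") pl_q$p + pl_q$r * x else pl_q$p + pl_q$r * (n_query - x)
}

test_that("placement consistency respects both tolerances and orientation", {
  p <- assembly_params(px_diff = 50, sc_diff = 0.05)
  a <- list(p = 100, o = "+", r = 1.00)
  expect_true(consistent(a, a, p))
  expect_true(consistent(a, list(p = 150, o = "+", r = 1.00), p))   # boundary
  expect_false(consistent(a, list(p = 151, o = "+", r = 1.00), p))
  expect_true(consistent(a, list(p = 100, o = "+", r = 1.05), p))
  expect_false(consistent(a, list(p = 100, o = "+", r = 1.06), p))
  expect_false(consistent(a, list(p = 100, o = "-", r = 1.00), p))
})

test_that("placement composition agrees with a pixel-mapping oracle", {
  set.seed(71)
  for (i in 1:40) {
    pl_q <- list(p = runif(1, 0, 500), o = sample(c("+", "-"), 1),
                 r = runif(1, 0.9, 1.1))
    edge <- list(d = sample(c("+", "-"), 1), r = runif(1, 0.95, 1.05),
                 off = round(runif(1, -200, 200)))
    n_ref <- sample(300:600, 1); n_query <- sample(300:600, 1)
    pl_i <- denseogm:::compose_placement(pl_q, edge, n_ref, n_query)
    for (u in c(0, n_ref %/% 2, n_ref)) {
      want <- map_ref_pixel(pl_q, edge, n_ref, n_query, u)
      got <- if (pl_i$o == "+") pl_i$p + pl_i$r * u else pl_i$p + pl_i$r * (n_ref - u)
      expect_lt(abs(want - got), 1e-9)
    }
  }
})

test_that("frame maps compose, apply and invert exactly", {
  set.seed(72)
  for (i in 1:20) {
    pl_a <- list(p = runif(1, 0, 400), o = sample(c("+", "-"), 1), r = runif(1, 0.9, 1.1))
    pl_b <- list(p = runif(1, 0, 400), o = sample(c("+", "-"), 1), r = runif(1, 0.9, 1.1))
    n <- sample(200:500, 1)
    m <- denseogm:::frame_map(pl_a, pl_b, n)
    back <- denseogm:::apply_frame_map(m, pl_a, n)
    expect_lt(abs(back$p - pl_b$p), 1e-9)
    expect_identical(back$o, pl_b$o)
    expect_lt(abs(back$r - pl_b$r), 1e-12)
    inv <- denseogm:::invert_frame_map(m)
    round_trip <- denseogm:::apply_frame_map(inv, back, n)
    expect_lt(abs(round_trip$p - pl_a$p), 1e-9)
    expect_identical(round_trip$o, pl_a$o)
  }
})

noiseless_sim <- function(n, seed, ref_len = 3000, len = 700) {
  th <- memo(paste0("nl_th_", ref_len), random_reference(ref_len, 1.5, seed = 70))
  cfg <- sim_config(n_barcodes = n, mean_len_px = len, sd_len_px = 0,
                    snvr = Inf, rescale_jitter_sd = 0, circular = FALSE,
                    seed = seed, min_len_px = 300)
  list(sim = sample_fragments(th, cfg), theory = th)
}

# Significant-overlap rows for every scorable pair, with exact scores and a
# synthetic Stouffer ordering by score (avoids needing a calibrated null for
# the geometry tests).
sig_from_pairs <- function(set, p = overlap_params()) {
  tab <- all_pairs_overlaps(set, p)
  tab <- tab[tab$C > 0.99, , drop = FALSE]
  tab$p_local <- rep(1e-10, nrow(tab))
  tab$p_leftover <- ifelse(tab$single_score, NA_real_, 1e-10)
  tab$s_stouffer <- 10 + tab$C
  tab
}

test_that("a single overlap seeds a two-vertex component", {
  nl <- noiseless_sim(4, seed = 73)
  ids <- nl$sim$gt$barcode_id[1:2]
  sub <- barcode_set(lapply(ids, function(id) nl$sim$set[[id]]))
  sig <- sig_from_pairs(sub)
  if (nrow(sig) == 1L) {
    asm <- build_islands(sig, sub, assembly_params())
    expect_length(asm$islands, 1L)
    expect_equal(nrow(asm$islands[[1]]), 2L)
    expect_equal(sum(asm$edge_log$status == "accepted"), 1L)
  } else {
    succeed("sampled fragments do not overlap; covered by larger fixtures")
  }
})

test_that("noiseless fragments assemble into islands at exact GT geometry", {
  nl <- noiseless_sim(14, seed = 74)
  sig <- sig_from_pairs(nl$sim$set)
  asm <- build_islands(sig, nl$sim$set, assembly_params())
  expect_gt(length(asm$islands), 0L)
  total <- 0L
  for (tab in asm$islands) {
    d <- anchor_island(tab, nl$sim$gt, nl$sim$set, n_px(nl$theory),
                       circular = FALSE)
    expect_true(all(d$orientation_match))
    expect_true(all(d$distance == 0))
    total <- total + nrow(tab)
  }
  expect_gt(total, 6L)

  # every accepted edge is consistent with the final placements
  g <- asm$graph
  lens <- lapply(nl$sim$set, n_px)
  acc <- asm$edge_log[asm$edge_log$status == "accepted", ]
  for (k in seq_len(nrow(acc))) {
    row <- sig[sig$query_id == acc$query_id[k] & sig$ref_id == acc$ref_id[k], ]
    edge <- list(d = row$d, r = row$r, off = row$l2 - row$l1,
                 q = row$query_id, ref = row$ref_id)
    impl <- denseogm:::implied_placement(edge, row$ref_id, g, lens)
    expect_true(consistent(g$placement[[row$ref_id]], impl, assembly_params()))
  }

  # determinism: a rerun yields identical layouts
  asm2 <- build_islands(sig, nl$sim$set, assembly_params())
  expect_identical(lapply(asm2$islands, as.data.frame),
                   lapply(asm$islands, as.data.frame))
})

test_that("conflicting cross-component overlaps defer instead of merging", {
  th <- random_reference(4000, 1.5, seed = 75)
  slice <- function(id, from, len) barcode(id, th$intensity[(from + 1):(from + len)])
  # two well-separated regions, two fragments each
  set <- barcode_set(list(slice("a1", 0, 700), slice("a2", 300, 700),
                          slice("b1", 2500, 700), slice("b2", 2800, 700)))
  p <- overlap_params()
  mk <- function(q, r) cand_row(best_local_overlap(set[[r]], set[[q]], p))
  within <- rbind(mk("a1", "a2"), mk("b1", "b2"))
  within$s_stouffer <- c(10, 9)
  # forged cross-component edges with incompatible implied offsets
  forge <- function(q, r, off) {
    data.frame(query_id = q, ref_id = r, d = "+", r = 1, l1 = 0L,
               l2 = as.integer(off), C = 0.99, C_leftover = 0.9,
               n_leftover = 100L, implied_offset = as.integer(off),
               single_score = FALSE, s_stouffer = 8)
  }
  cross <- rbind(forge("a1", "b1", 100), forge("a2", "b2", 300))
  cross$s_stouffer <- c(8, 7)
  # a1-b1 offset 100 vs a2-b2 offset 300: given a1/a2 differ by 300 px and
  # b1/b2 by 300 px, the two cross edges disagree by 200 px > px_diff
  within$p_local <- cross$p_local <- 1e-10
  within$p_leftover <- cross$p_leftover <- 1e-10
  asm <- build_islands(rbind(within, cross), set, assembly_params())
  expect_length(asm$islands, 2L)
  expect_equal(sum(asm$edge_log$status == "deferred"), 2L)
  # and with compatible offsets the components do merge
  cross2 <- rbind(forge("a1", "b1", 100), forge("a2", "b2", 100))
  cross2$s_stouffer <- c(8, 7)
  cross2$p_local <- 1e-10; cross2$p_leftover <- 1e-10
  asm2 <- build_islands(rbind(within, cross2), set, assembly_params())
  expect_length(asm2$islands, 1L)
  expect_equal(nrow(asm2$islands[[1]]), 4L)
})

test_that("block matrices place, orient and rescale rows losslessly", {
  th <- random_reference(2000, 1.5, seed = 76)
  b1 <- barcode("m1", th$intensity[101:700])
  b2 <- barcode("m2", th$intensity[101:700])
  set <- barcode_set(list(b1, b2))
  tab <- data.frame(barcode_id = c("m1", "m2"), start = c(0L, 0L),
                    stop = c(600L, 600L), orientation = c("+", "+"),
                    rescale = c(1, 1))
  class(tab) <- c("island_layout", "data.frame")
  attr(tab, "island_id") <- "t"
  blk <- block_matrix(tab, set)
  expect_identical(blk[1, ], blk[2, ])
  expect_equal(blk[1, ], znormalize(b1)$intensity, ignore_attr = TRUE)

  # single reversed, rescaled row reconstructs rescale(orient(znorm(b)))
  tab2 <- data.frame(barcode_id = "m1", start = 0L,
                     stop = as.integer(round(1.04 * 600)), orientation = "-",
                     rescale = 1.04)
  class(tab2) <- c("island_layout", "data.frame")
  attr(tab2, "island_id") <- "t2"
  blk2 <- block_matrix(tab2, set)
  want <- rescale_barcode(reverse_barcode(znormalize(b1)), 1.04)$intensity
  expect_equal(blk2[1, ], want, ignore_attr = TRUE)

  # uncovered cells are missing, not zero
  tab3 <- tab
  tab3$start <- c(0L, 100L); tab3$stop <- c(600L, 700L)
  blk3 <- block_matrix(tab3, set)
  expect_true(all(is.na(blk3[2, 1:100])))
  expect_false(anyNA(blk3[1, 1:600]))

  expect_error(block_matrix(tab, barcode_set(list(b1))), "unknown barcode")
})
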