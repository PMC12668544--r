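make_layout <- function(ids, start, stop, orientation = "+", rescale = 1,
                        island_id = "t") {
  tab <- data.frame(barcode_id = ids, start = as.integer(start),
                    stop = as.integer(stop),
                    orientation = rep_len(orientation, length(ids)),
                    rescale = rep_len(rescale, length(ids)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("island_layout", "data.frame")
  attr(tab, "island_id") <- island_id
  tab
}

test_that("island pairwise correlations match the shared-column oracle", {
  th <- random_reference(2000, 1.5, seed = 81)
  b1 <- barcode("m1", th$intensity[1:600])
  b2 <- barcode("m2", th$intensity[201:800])
  b3 <- barcode("m3", th$intensity[1201:1700])
  set <- barcode_set(list(b1, b2, b3))
  tab <- make_layout(c("m1", "m2", "m3"), c(0, 200, 1200),
                     c(600, 800, 1700))
  pcc <- island_pairwise_pcc(tab, set, min_overlap = 100)
  expect_equal(pcc["m1", "m2"], 1, tolerance = 1e-12)    # identical overlap
  expect_true(is.na(pcc["m1", "m3"]))                    # disjoint
  expect_true(is.na(diag(pcc))[1])

  # oracle over the explicit shared column set, with noise
  b2n <- add_noise(b2, 2, seed = 5); b2n$id <- "m2"
  setn <- barcode_set(list(b1, b2n, b3))
  pccn <- island_pairwise_pcc(tab, setn, min_overlap = 100)
  blk <- block_matrix(tab, setn)
  shared <- which(!is.na(blk[1, ]) & !is.na(blk[2, ]))
  expect_equal(pccn["m1", "m2"],
               pcc_index_oracle(blk[1, ], blk[2, ], shared, shared),
               tolerance = 1e-10)
})

test_that("amplitude adjustment maps a correlated pair onto shared moments", {
  # raw-scale arithmetic: b1 with mean 0 / sd 1, b2 = 10 + 2 * b1
  set.seed(82)
  base <- rnorm(400)
  base <- (base - mean(base)) / sqrt(mean((base - mean(base))^2))
  set <- barcode_set(list(barcode("m1", base), barcode("m2", 10 + 2 * base)))
  tab <- make_layout(c("m1", "m2"), c(0, 0), c(400, 400))
  vals <- amplitude_adjust(tab, set, consensus_params(min_overlap = 100),
                           znorm = FALSE)
  for (id in c("m1", "m2")) {
    v <- vals[[id]]
    expect_lt(abs(mean(v) - 5), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - sqrt(2.5)), 1e-9)
  }

  # already-identical barcodes are unchanged
  set2 <- barcode_set(list(barcode("m1", base), barcode("m2", base)))
  vals2 <- amplitude_adjust(tab, set2, consensus_params(min_overlap = 100),
                            znorm = FALSE)
  expect_equal(vals2[["m1"]], base, tolerance = 1e-12)
  expect_equal(vals2[["m2"]], base, tolerance = 1e-12)
})

test_that("after a pairwise merge the overlap moments agree to 1e-9", {
  th <- random_reference(2500, 1.5, seed = 83)
  ids <- c("m1", "m2")
  starts <- c(0, 400)
  bcs <- lapply(seq_along(ids), function(i) {
    b <- barcode(ids[i], th$intensity[(starts[i] + 1):(starts[i] + 900)])
    b <- add_noise(b, snvr = 2, seed = 90 + i)
    # molecule-to-molecule amplitude differences
    b$intensity <- b$intensity * (1 + 0.3 * i) + 5 * i
    b
  })
  set <- barcode_set(bcs)
  tab <- make_layout(ids, starts, starts + 900)
  params <- consensus_params(min_overlap = 300)
  vals <- amplitude_adjust(tab, set, params, znorm = FALSE)
  blk <- block_matrix(tab, set, values = vals)
  shared <- which(!is.na(blk[1, ]) & !is.na(blk[2, ]))
  expect_gte(length(shared), 300L)
  mom <- function(v) c(mean(v), sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(mom(blk[1, shared]) - mom(blk[2, shared]))), 1e-9)
})

test_that("consensus drafting averages covered cells only", {
  th <- random_reference(1200, 1.5, seed = 84)
  b1 <- barcode("m1", th$intensity[1:500])
  b2 <- barcode("m2", th$intensity[201:700])
  set <- barcode_set(list(b1, b2))

  single <- make_layout("m1", 0, 500)
  cons1 <- draft_consensus(block_matrix(single, set))
  expect_equal(cons1$intensity, znormalize(b1)$intensity, tolerance = 1e-12)
  expect_true(all(cons1$coverage == 1L))

  both <- make_layout(c("m1", "m2"), c(0, 200), c(500, 700))
  blk <- block_matrix(both, set)
  cons2 <- draft_consensus(blk)
  expect_length(cons2$intensity, 700L)
  expect_equal(cons2$coverage, c(rep(1L, 200), rep(2L, 300), rep(1L, 200)))
  # a column covered by one row equals that row's value
  expect_equal(cons2$intensity[1:200], blk[1, 1:200], ignore_attr = TRUE)
  expect_equal(cons2$intensity[501:700], blk[2, 501:700], ignore_attr = TRUE)
  expect_equal(cons2$intensity[201:500],
               colMeans(blk[, 201:500]), ignore_attr = TRUE)

  expect_error(draft_consensus(matrix(NA_real_, 2, 10)), "all-missing")
})

test_that("averaging k noisy copies beats the median single copy", {
  wins <- 0L
  trials <- 100L
  for (t in seq_len(trials)) {
    truth <- random_reference(400, 1.5, seed = 8000 + t)
    k <- 8L
    bcs <- lapply(seq_len(k), function(i) {
      add_noise(barcode(paste0("m", i), truth$intensity), snvr = 1,
                seed = t * 100 + i)
    })
    set <- barcode_set(bcs)
    tab <- make_layout(paste0("m", 1:k), rep(0, k), rep(400, k))
    blk <- block_matrix(tab, set)
    cons <- draft_consensus(blk)
    c_cons <- cor(cons$intensity, truth$intensity)
    c_rows <- apply(blk, 1, cor, y = truth$intensity)
    if (c_cons > median(c_rows)) wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.95)
})

test_that("realignment is a fixed point on optimal layouts and recovers perturbations", {
  th <- random_reference(2000, 1.5, seed = 85)
  ids <- paste0("m", 1:4)
  starts <- c(0, 300, 600, 900)
  set <- barcode_set(lapply(seq_along(ids), function(i) {
    barcode(ids[i], th$intensity[(starts[i] + 1):(starts[i] + 800)])
  }))
  tab <- make_layout(ids, starts, starts + 800)
  params <- consensus_params(min_overlap = 300)
  cons <- draft_consensus(block_matrix(tab, set))

  fixed <- realign_to_consensus(tab, set, cons, params)
  expect_equal(fixed$start, tab$start)
  expect_equal(fixed$rescale, tab$rescale)

  pert <- tab
  pert$start[2] <- pert$start[2] + 10L
  cons_p <- draft_consensus(block_matrix(pert, set))
  back <- realign_to_consensus(pert, set, cons_p, params)
  expect_lte(abs(back$start[2] - tab$start[2]), 1L)

  # stretch beyond the +/-5% window clips to the searched boundary
  stretched <- tab
  stretched$rescale[3] <- 1.0
  set_st <- set
  set_st[["m3"]] <- rescale_barcode(set[["m3"]], 1 / 1.08)
  stretched$stop[3] <- stretched$start[3] + n_px(set_st[["m3"]])
  cons_s <- draft_consensus(block_matrix(make_layout(ids[-3], starts[-3],
                                                     starts[-3] + 800), set))
  out <- realign_to_consensus(stretched, set_st, cons_s, params)
  expect_lte(out$rescale[3], 1.05 + 1e-9)   # cannot exceed the searched window
  expect_gte(out$rescale[3], 1.04 - 1e-9)   # driven to (near) the boundary
})

test_that("the consensus pipeline is a fixed point on noiseless islands", {
  th <- random_reference(1800, 1.5, seed = 86)
  ids <- paste0("m", 1:3)
  starts <- c(0, 300, 600)
  set <- barcode_set(lapply(seq_along(ids), function(i) {
    barcode(ids[i], th$intensity[(starts[i] + 1):(starts[i] + 800)])
  }))
  tab <- make_layout(ids, starts, starts + 800)
  params0 <- consensus_params(min_overlap = 300, iterations = 0L)
  draft_only <- run_consensus(tab, set, params0)
  expect_equal(draft_only$consensus$intensity,
               draft_consensus(block_matrix(tab, set))$intensity)
  expect_identical(draft_only$layout, tab)

  # one round reaches the fixed point: more rounds change nothing
  res1 <- run_consensus(tab, set, consensus_params(min_overlap = 300,
                                                   iterations = 1L))
  res3 <- run_consensus(tab, set, consensus_params(min_overlap = 300,
                                                   iterations = 3L))
  expect_equal(res3$consensus$intensity, res1$consensus$intensity,
               tolerance = 1e-9)
  expect_equal(res3$layout$start, res1$layout$start)
  expect_equal(res1$layout$start, tab$start)
  expect_setequal(res3$layout$barcode_id, tab$barcode_id)
  expect_equal(res3$consensus$iterations_run, 3L)
})
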