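test_that("zero drift gives zero shifts; planted integer drift is recovered exactly", {
  img <- matrix(0, 60, 60)
  img[20:30, 25:35] <- 5
  img[40:44, 10:14] <- 3
  expect_identical(estimate_shift(img, img), c(0L, 0L))
  shifted <- menquant:::translate_image(img, c(3, -2))
  expect_equal(estimate_shift(img, shifted), c(-3, 2))
})

test_that("shift estimate equals brute-force cross-correlation over a +/-10 px window", {
  set.seed(11)
  ref <- matrix(0, 48, 48)
  ref[cbind(sample(10:38, 6), sample(10:38, 6))] <- runif(6, 3, 9)
  ref <- ref + matrix(runif(48 * 48, 0, 0.2), 48)
  for (sh in list(c(4, 7), c(-6, 1), c(0, -9))) {
    img <- menquant:::translate_image(ref, sh)
    # exhaustive oracle: correlate the shifted-back image with the reference
    best <- c(NA, NA); best_cc <- -Inf
    for (dy in -10:10) for (dx in -10:10) {
      cc <- sum(ref * menquant:::translate_image(img, c(dy, dx)))
      if (cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
    }
    expect_equal(estimate_shift(ref, img), best)
    expect_equal(best, -sh)  # the correction undoes the planted drift
  }
})

test_that("featureless frames give zero shift with a warning", {
  flat <- matrix(1, 30, 30)
  expect_warning(s <- estimate_shift(flat, flat + 0), "featureless")
  expect_identical(s, c(0L, 0L))
})

test_that("marker segmentation: blank image, two blobs, IoU against truth masks", {
  expect_equal(max(segment_marker(matrix(5, 40, 40))), 0)

  fx <- make_cell_image(ny = 50, nx = 50, center = c(15, 15), radius = 6,
                        baseline = 300)
  fx2 <- make_cell_image(ny = 50, nx = 50, center = c(35, 35), radius = 5,
                         baseline = 300)
  lab <- segment_marker(fx$img + fx2$img)
  expect_equal(max(lab), 2)
  cen <- label_centroids(lab)
  expect_lt(min(abs(cen$row - 15) + abs(cen$col - 15)), 1)
  expect_lt(min(abs(cen$row - 35) + abs(cen$col - 35)), 1)

  # nucleolus masks from a noisy synthetic movie reach IoU >= 0.9
  cfg <- movie_config(n_cells = 1, noise_sd = 0.10, seed = 8)
  sim <- generate_movie(cfg)
  for (t in c(5, 20, 35)) {
    fr <- get_frame(sim$movie, t, "nucleolus")
    bg <- estimate_background(fr, sim$truth$cell_masks[[t]] > 0)
    seg <- segment_marker(fr, background = bg) > 0
    truth <- sim$truth$nucleolus_masks[[t]] > 0
    iou <- sum(seg & truth) / sum(seg | truth)
    expect_gte(iou, 0.9)
  }
})

test_that("segmentation and SPB detection are invariant to multiplicative gain", {
  fx <- make_cell_image(ny = 50, nx = 50, center = c(25, 25), radius = 7,
                        baseline = 200)
  expect_identical(segment_marker(fx$img), segment_marker(fx$img * 4))
  cell <- matrix(TRUE, 50, 50)
  spot <- make_cell_image(ny = 50, nx = 50, center = c(25, 25), radius = 20,
                          baseline = 50, spot = c(20, 30), spot_peak = 400)
  p1 <- detect_spbs(spot$img, cell)
  p2 <- detect_spbs(spot$img * 2.5, cell)
  expect_equal(p1[, c("row", "col")], p2[, c("row", "col")])
})

test_that("SPB detection: none, one, and two planted spots", {
  cell <- matrix(TRUE, 40, 40)
  expect_equal(nrow(detect_spbs(matrix(7, 40, 40), cell)), 0)

  one <- make_cell_image(ny = 40, nx = 40, center = c(20, 20), radius = 18,
                         baseline = 50, spot = c(14, 22), spot_peak = 300)
  p1 <- detect_spbs(one$img, cell)
  expect_equal(nrow(p1), 1)
  expect_lte(max(abs(p1[1, c("row", "col")] - c(14, 22))), 1)

  img2 <- one$img
  d2 <- (row(img2) - 26)^2 + (col(img2) - 18)^2
  img2 <- img2 + 200 * exp(-d2 / 2) * (d2 <= 25)
  p2 <- detect_spbs(img2, cell)
  expect_equal(nrow(p2), 2)
  ord <- order(p2[, "row"])
  expect_lte(max(abs(p2[ord[1], c("row", "col")] - c(14, 22))), 1)
  expect_lte(max(abs(p2[ord[2], c("row", "col")] - c(26, 18))), 1)
  # sorted by intensity
  expect_gte(p2[1, "intensity"], p2[2, "intensity"])
})

test_that("backward-overlap tracking: stationary identity, moving cells, disappearance", {
  lab <- matrix(0L, 30, 30); lab[5:10, 5:10] <- 1L; lab[18:24, 18:24] <- 2L
  masks <- list(lab, lab, lab)
  tr <- track_cells(masks)
  expect_true(all(mapply(function(a, b) all(a == b), tr$labels, masks)))

  # per-frame displacement below the cell radius keeps identities
  mk <- function(dy) {
    m <- matrix(0L, 40, 40)
    m[(6 + dy):(12 + dy), 6:12] <- 1L
    m[25:31, (20 + dy):(26 + dy)] <- 2L
    m
  }
  moving <- lapply(c(0, 2, 4, 6), mk)
  trm <- track_cells(moving)
  for (t in 1:4) {
    expect_equal(sort(unique(trm$labels[[t]][trm$labels[[t]] > 0])), c(1L, 2L))
    expect_true(all(trm$labels[[t]][moving[[t]] == 1L] == 1L))
  }

  # a cell absent from frame 3 onward: its track ends at frame 2
  gone <- list(lab, lab, {
    m <- lab; m[m == 1L] <- 0L; m
  })
  trg <- track_cells(gone)
  tab <- trg$table
  id1_frames <- tab$frame[tab$cell_id == unique(trg$labels[[1]][lab == 1L])]
  expect_equal(max(id1_frames), 2)
})

test_that("tracking agrees with brute-force maximal-overlap bipartite matching", {
  set.seed(5)
  for (rep_i in 1:5) {
    # two frames with 3 jittered cells
    centers <- cbind(sample(8:32, 3), sample(8:32, 3))
    while (min(dist(centers)) < 12) centers <- cbind(sample(8:32, 3), sample(8:32, 3))
    mk <- function(jit) {
      m <- matrix(0L, 40, 40)
      for (i in 1:3) {
        cy <- centers[i, 1] + jit[i, 1]; cx <- centers[i, 2] + jit[i, 2]
        m[max(1, cy - 4):min(40, cy + 4), max(1, cx - 4):min(40, cx + 4)] <- i
      }
      m
    }
    f2 <- mk(matrix(0L, 3, 2))
    f1 <- mk(matrix(sample(-2:2, 6, TRUE), 3, 2))
    tr <- track_cells(list(f1, f2))
    # oracle: best permutation by total overlap
    ov <- sapply(1:3, function(i) sapply(1:3, function(j) {
      sum(f1 == i & f2 == j)
    }))
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    tot <- vapply(perms, function(p) sum(ov[cbind(p, 1:3)]), numeric(1))
    best <- perms[[which.max(tot)]]
    got <- vapply(1:3, function(i) unique(tr$labels[[1]][f1 == i]), integer(1))
    expect_equal(got, best)
  }
})

test_that("drift correction then tracking matches tracking of the drift-free movie", {
  cfg_d <- movie_config(n_cells = 2, noise_sd = 0.05,
                        drift_px_per_frame = c(0.2, -0.15), seed = 3)
  cfg_0 <- movie_config(n_cells = 2, noise_sd = 0.05,
                        drift_px_per_frame = c(0, 0), seed = 3)
  sim_d <- generate_movie(cfg_d)
  sim_0 <- generate_movie(cfg_0)
  dc <- correct_drift(sim_d$movie, "nucleolus")
  o <- sim_d$truth$shifts
  expected <- cbind(o[nrow(o), 1] - o[, 1], o[nrow(o), 2] - o[, 2])
  expect_true(all(dc$shifts == expected))
  # apply the estimated correction to the drifted truth masks and track
  masks_corr <- lapply(seq_len(cfg_d$n_frames), function(t) {
    menquant:::translate_image(sim_d$truth$cell_masks[[t]], dc$shifts[t, ])
  })
  tr_corr <- track_cells(masks_corr)
  tr_free <- track_cells(sim_0$truth$cell_masks)
  # same identity assignment cell-for-cell (masks differ by a constant offset)
  for (t in c(1, 10, 25, 40)) {
    a <- tr_corr$labels[[t]]; b <- tr_free$labels[[t]]
    for (i in sort(unique(b[b > 0]))) {
      ids <- unique(a[a > 0 & menquant:::translate_image(b, o[nrow(o), ]) == i])
      expect_length(ids, 1)
      expect_equal(ids, i)
    }
  }
})

test_that("bud assignment recovers the planted lineage and honors the edge rules", {
  cfg <- movie_config(n_cells = 2, noise_sd = 0.02, seed = 5)
  sim <- generate_movie(cfg)
  marker <- lapply(seq_len(n_frames(sim$movie)), function(t) {
    fr <- get_frame(sim$movie, t, "spb")
    bg <- estimate_background(fr, sim$truth$cell_masks[[t]] > 0)
    segment_marker(fr, background = bg)
  })
  tr <- track_cells(sim$truth$cell_masks)
  links <- assign_buds(tr$labels, marker)
  ev <- sim$truth$events
  for (i in seq_len(nrow(ev))) {
    row <- links[links$bud_id == ev$bud_id[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$mother_id, ev$cell[i])
    expect_equal(row$marker_frame, ev$entry_frame[i])
  }
  # a cell with the marker from frame 1 is never called a bud
  expect_false(any(links$bud_id %in% ev$cell))
  # no marker ever appearing in a new cell: no links at all
  empty_marker <- replicate(3, matrix(0L, 30, 30), simplify = FALSE)
  lab <- matrix(0L, 30, 30); lab[5:12, 5:12] <- 1L
  no_links <- assign_buds(list(lab, lab, lab), empty_marker)
  expect_equal(nrow(no_links), 0)
})

test_that("background estimation is the median outside the cells", {
  img <- matrix(100, 30, 30)
  cells <- matrix(FALSE, 30, 30); cells[10:20, 10:20] <- TRUE
  img[cells] <- 900
  expect_equal(estimate_background(img, cells), 100)
  # linear gradient: equals the brute-force median of outside pixels
  grad <- outer(seq_len(30), seq_len(30), function(i, j) i + 2 * j)
  expect_equal(estimate_background(grad, cells),
               stats::median(grad[!cells]))
  expect_error(estimate_background(img, matrix(TRUE, 30, 30)), "outside")
})
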