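test_that("flatfield correction removes smooth shading, preserves flats", {
  flat <- matrix(1000, 64, 64)
  out <- flatfield_correct(flat)
  expect_equal(out, flat, tolerance = 1e-6)

  # multiplicative linear shading on a flat texture: CV drops >= 5-fold
  shade <- outer(seq(0.7, 1.3, length.out = 128), rep(1, 128))
  img <- shade * 1000
  cv <- function(m) sd(m) / mean(m)
  corrected <- flatfield_correct(img)
  expect_gt(cv(img) / cv(corrected), 5)
  expect_equal(mean(corrected), mean(img), tolerance = 1e-6)
  expect_true(all(corrected >= 0))

  expect_warning(out0 <- flatfield_correct(matrix(0, 8, 8)), "zero")
  expect_equal(out0, matrix(0, 8, 8))
})

test_that("nuclei segmentation finds isolated nuclei at true positions", {
  set.seed(21)
  # pure-noise field -> no labels
  noise <- matrix(rnorm(200 * 200, 200, 20), 200, 200)
  expect_equal(max(segment_nuclei(noise, pixel_size_um = 0.65)$labels), 0L)

  # 20 well-separated synthetic nuclei via the renderer
  p <- test_sim_params()
  p$image_shape <- c(420L, 420L)
  grid <- expand.grid(x = seq(50, 370, length.out = 5),
                      y = seq(50, 370, length.out = 4))
  tr <- as_ground_truth(tibble::tibble(
    plate = "p1", well = "B02", field = 1L, object = seq_len(20),
    x_px = grid$x, y_px = grid$y,
    nucleus_area_um2 = 170, cell_area_um2 = 900,
    width_to_length = 0.85, orientation = 0,
    clump = seq_len(20), clump_size = 1L, edu_label = 0L,
    is_feeder = FALSE))
  fi <- render_field(tr, p, seed = 3)
  nuc <- segment_nuclei(fi$channels$dapi, pixel_size_um = p$pixel_size_um)
  expect_equal(max(nuc$labels), 20L)
  cent <- mask_centroids(nuc)
  for (i in seq_len(20)) {
    d <- sqrt((cent$x - tr$x_px[i])^2 + (cent$y - tr$y_px[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("the splitting coefficient separates fused nuclei", {
  # dumbbell: two disks radius 11 whose neck is narrower than the disks
  img <- matrix(200, 120, 120)
  for (i in 1:120) for (j in 1:120) {
    if ((i - 48)^2 + (j - 60)^2 <= 121 || (i - 72)^2 + (j - 60)^2 <= 121) {
      img[i, j] <- 3200
    }
  }
  nuc <- segment_nuclei(img, segmentation_params(), pixel_size_um = 0.65)
  expect_equal(max(nuc$labels), 2L)
})

test_that("cell segmentation grows nuclei into the membrane foreground", {
  p <- segmentation_params()
  # one nucleus centred in a bright disk -> cell recovers the disk
  base <- matrix(200, 140, 140)
  disk <- base
  for (i in 1:140) for (j in 1:140) {
    if ((i - 70)^2 + (j - 70)^2 <= 40^2) disk[i, j] <- 1700
  }
  nuc_lab <- matrix(0L, 140, 140)
  for (i in 1:140) for (j in 1:140) {
    if ((i - 70)^2 + (j - 70)^2 <= 11^2) nuc_lab[i, j] <- 1L
  }
  nuclei <- phenoplate:::label_mask(nuc_lab, "nucleus")
  cells <- segment_cells(disk, nuclei, p)
  truth <- disk > 200
  pred <- cells$labels == 1L
  jacc <- sum(truth & pred) / sum(truth | pred)
  expect_gt(jacc, 0.9)

  # two touching disks -> two labels, each containing only its nucleus
  two <- matrix(200, 140, 200)
  for (i in 1:140) for (j in 1:200) {
    if ((i - 70)^2 + (j - 62)^2 <= 38^2 ||
        (i - 70)^2 + (j - 136)^2 <= 38^2) two[i, j] <- 1700
  }
  nl <- matrix(0L, 140, 200)
  for (i in 1:140) for (j in 1:200) {
    if ((i - 70)^2 + (j - 62)^2 <= 10^2) nl[i, j] <- 1L
    if ((i - 70)^2 + (j - 136)^2 <= 10^2) nl[i, j] <- 2L
  }
  nuclei2 <- phenoplate:::label_mask(nl, "nucleus")
  cells2 <- segment_cells(two, nuclei2, p)
  expect_setequal(unique(as.integer(cells2$labels[cells2$labels > 0])),
                  c(1L, 2L))
  expect_true(all(cells2$labels[nl == 1L] == 1L))
  expect_true(all(cells2$labels[nl == 2L] == 2L))

  # zero-foreground membrane channel -> every cell equals its nucleus
  flat <- matrix(200, 140, 200) + matrix(rnorm(140 * 200, 0, 2), 140, 200)
  cells3 <- segment_cells(flat, nuclei2, p)
  expect_equal(cells3$labels, nl)
  expect_setequal(cells3$provenance$flagged_no_cytoplasm, c(1L, 2L))
})

test_that("border-object removal matches a per-pixel edge scan", {
  m <- matrix(0L, 30, 30)
  m[1:4, 10:14] <- 1L  # touches top edge
  m[10:14, 10:14] <- 2L
  m[25:30, 2:5] <- 3L  # touches bottom edge
  mask <- phenoplate:::label_mask(m, "cell")
  out <- remove_border_objects(mask)
  expect_equal(sort(unique(as.integer(out$labels[out$labels > 0]))), 1L)
  expect_equal(out$provenance$removed_border, c(1L, 3L))
  expect_equal(sum(out$labels > 0), sum(m == 2L))

  # all-interior labels -> identity relabelling
  m2 <- matrix(0L, 20, 20)
  m2[5:8, 5:8] <- 1L; m2[12:15, 12:15] <- 2L
  out2 <- remove_border_objects(phenoplate:::label_mask(m2, "cell"))
  expect_equal(out2$labels, m2)

  # random masks against the brute-force oracle
  set.seed(31)
  for (rep in 1:10) {
    mr <- random_label_mask()
    edge <- unique(c(mr[1, ], mr[nrow(mr), ], mr[, 1], mr[, ncol(mr)]))
    survivors_oracle <- setdiff(sort(unique(mr[mr > 0])), edge)
    out_r <- remove_border_objects(phenoplate:::label_mask(mr, "cell"))
    expect_equal(length(unique(out_r$labels[out_r$labels > 0])),
                 length(survivors_oracle))
    expect_equal(out_r$provenance$id_map, survivors_oracle)
  }
})

test_that("segmentation is deterministic and threshold-monotone", {
  p <- test_sim_params()
  tr <- sample_well_population(p, "Fn5", seed = 77)
  fi <- render_field(tr[tr$field == 1, ], p, seed = 78)
  n1 <- segment_nuclei(fi$channels$dapi, pixel_size_um = p$pixel_size_um)
  n2 <- segment_nuclei(fi$channels$dapi, pixel_size_um = p$pixel_size_um)
  expect_identical(n1$labels, n2$labels)

  areas <- sapply(c(0.05, 0.15, 0.4), function(ct) {
    sum(segment_nuclei(fi$channels$dapi,
                       segmentation_params(common_threshold = ct),
                       p$pixel_size_um)$labels > 0)
  })
  expect_true(all(diff(areas) <= 0))
})
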