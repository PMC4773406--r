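test_that("degenerate populations behave as specified", {
  p <- test_sim_params()
  p$conditions$Fn1$expected_attached_cells <- 0
  p$conditions$Fn1$feeder_rate <- 0
  expect_equal(nrow(sample_well_population(p, "Fn1", seed = 1)), 0L)

  p2 <- test_sim_params()
  p2$conditions$Fn1$clump_geometric_p <- 1
  p2$conditions$Fn1$feeder_rate <- 0
  p2$well_effect_sdlog <- 0
  tr <- sample_well_population(p2, "Fn1", seed = 2)
  expect_true(all(tr$clump_size == 1L))

  expect_error(sample_well_population(p, "Fn99", seed = 1),
               "condition not present")
})

test_that("clump sizes follow the geometric law with the correct p", {
  set.seed(11)
  sizes <- phenoplate:::rgeom_sizes(1000, 0.4)
  se <- sqrt((1 - 0.4) / 0.4^2 / 1000)
  expect_lt(abs(mean(sizes) - 1 / 0.4), 3 * se)

  # chi-square goodness of fit not rejected at alpha = 0.01, n = 5000
  sizes2 <- phenoplate:::rgeom_sizes(5000, 0.4)
  fit <- fit_geometric_clumps(sizes2)
  expect_lt(abs(fit$p_hat - 0.4), 0.02)
  expect_gt(stats::pchisq(fit$chisq, fit$df, lower.tail = FALSE), 0.01)
})

test_that("true EdU label fraction converges to the preset", {
  p <- test_sim_params()
  p$conditions$Fn25$feeder_rate <- 0
  labs <- unlist(lapply(1:8, function(s) {
    sample_well_population(p, "Fn25", seed = 100 + s)$edu_label
  }))
  f <- p$conditions$Fn25$edu_positive_fraction
  tol <- 3 * sqrt(f * (1 - f) / length(labs))
  expect_lt(abs(mean(labs) - f), tol)
})

test_that("simulation is a pure function of (params, layout, seed)", {
  p <- test_sim_params()
  tr1 <- sample_well_population(p, "Fn5", seed = 42)
  tr2 <- sample_well_population(p, "Fn5", seed = 42)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))

  f1 <- render_field(tr1[tr1$field == 1, ], p, seed = 7)
  f2 <- render_field(tr2[tr2$field == 1, ], p, seed = 7)
  expect_identical(f1$channels, f2$channels)
  f3 <- render_field(tr1[tr1$field == 1, ], p, seed = 8)
  expect_false(identical(f1$channels$dapi, f3$channels$dapi))
})

test_that("rendered fields honour the intensity model", {
  p <- test_sim_params()
  # empty truth -> pure noise, no foreground, strictly positive brightfield
  fi <- render_field(empty_table("ground_truth"), p, seed = 5)
  bg <- p$intensity$background
  expect_lt(max(fi$channels$dapi), bg[["dapi"]] + 8 * 20)
  expect_true(all(fi$channels$brightfield >= 1))

  # single EdU-negative cell: nucleus-region median within the negative
  # component's 99% range (shifted by background)
  tr <- tibble::tibble(plate = "p1", well = "B02", field = 1L, object = 1L,
                       x_px = 140, y_px = 140, nucleus_area_um2 = 170,
                       cell_area_um2 = 800, width_to_length = 0.8,
                       orientation = 0.3, clump = 1L, clump_size = 1L,
                       edu_label = 0L, is_feeder = FALSE)
  tr <- as_ground_truth(tr)
  fi2 <- render_field(tr, p, seed = 6)
  nuc <- segment_nuclei(fi2$channels$dapi, pixel_size_um = p$pixel_size_um)
  med <- measure_intensity(nuc, fi2$channels$edu488)$median_intensity
  neg <- p$intensity$edu_neg
  lims <- bg[["edu488"]] +
    stats::qlnorm(c(0.005, 0.995), neg[["meanlog"]], neg[["sdlog"]])
  expect_gt(med, lims[1] - 3 * 20)
  expect_lt(med, lims[2] + 3 * 20)
})

test_that("simulate_plate writes complete plates with derived seeds", {
  lay <- suppressWarnings(plate_layout(
    data.frame(well = c("B02", "B03", "B04"),
               condition = c("Fn1", "Fn5", "Fn25"))))
  p <- test_sim_params()
  sim <- simulate_plate(lay, p, seed = 9)
  expect_length(sim$images, 3L * p$n_fields)
  expect_true(all(sim$truth$clump_size >= 1L))
  # clump sizes equal the multiplicity of each clump id within a well
  for (w in unique(sim$truth$well)) {
    tw <- sim$truth[sim$truth$well == w, ]
    mult <- table(tw$clump)
    expect_true(all(tw$clump_size == as.integer(mult[as.character(tw$clump)])))
  }
  # disk round trip via the plate_io naming convention
  out <- tempfile()
  sim2 <- simulate_plate(lay, p, seed = 9, output_dir = out)
  refs <- discover_images(out, pixel_size_um = p$pixel_size_um)
  expect_equal(nrow(refs), 3L * p$n_fields)
  fi <- read_field_image(refs[refs$well == "B03" & refs$field == 2L, ])
  expect_equal(fi$channels$dapi,
               sim$images[["B03_f2"]]$channels$dapi)
  tr_back <- read_table(file.path(out, "ground_truth.csv"), "ground_truth")
  expect_equal(as.data.frame(tr_back), as.data.frame(sim2$truth))

  expect_error(simulate_plate(lay, simulation_params(conditions = list(
    Fn1 = test_sim_params()$conditions$Fn1)), seed = 1),
    "no simulation parameters")
})

test_that("default presets order true cell counts Fn25 > Fn5 > Fn1", {
  p <- test_sim_params()
  means <- sapply(c("Fn1", "Fn5", "Fn25"), function(cc) {
    mean(sapply(1:6, function(s) {
      nrow(sample_well_population(p, cc, seed = 300 + s))
    }))
  })
  expect_gt(means[["Fn25"]], means[["Fn5"]])
  expect_gt(means[["Fn5"]], means[["Fn1"]])
})

test_that("identical parameter blocks make conditions exchangeable", {
  p <- test_sim_params()
  p$conditions$Fn5 <- p$conditions$Fn1
  p$conditions$Fn25 <- p$conditions$Fn1
  counts <- lapply(c("Fn1", "Fn5", "Fn25"), function(cc) {
    sapply(1:10, function(s) {
      nrow(sample_well_population(p, cc, seed = 400 + s * 7))
    })
  })
  m <- sapply(counts, mean)
  pooled_se <- sqrt(sum(sapply(counts, var) / 10))
  expect_lt(max(m) - min(m), 4 * pooled_se)
})

test_that("wells with fewer cells carry proportionally more singles", {
  p <- test_sim_params()
  p$conditions$Fn5$feeder_rate <- 0
  p$well_effect_sdlog <- 0.4 # spread well densities for the contrast
  res <- t(sapply(1:24, function(s) {
    tr <- sample_well_population(p, "Fn5", seed = 500 + s)
    c(n = nrow(tr), single = mean(tr$clump_size == 1L))
  }))
  expect_lt(stats::cor(res[, "n"], res[, "single"]), 0)
})
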