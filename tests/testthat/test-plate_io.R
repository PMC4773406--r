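test_that("plate layout validation enforces the 96-well conventions", {
  lay <- suppressWarnings(
    plate_layout(data.frame(well = c("B02", "B03", "B04"),
                            condition = c("Fn1", "Fn5", "Fn25"))))
  expect_s3_class(lay, "plate_layout")
  expect_equal(sort(lay$conditions), c("Fn1", "Fn25", "Fn5"))
  expect_equal(nrow(lay$assay_wells), 3L)

  expect_error(plate_layout(data.frame(well = "A01", condition = "Fn1")),
               "border")
  expect_error(plate_layout(data.frame(well = c("B02", "B2"),
                                       condition = c("Fn1", "Fn1"))),
               "malformed well name")
  expect_error(plate_layout(data.frame(well = c("B02", "B02"),
                                       condition = c("Fn1", "Fn5"))),
               "duplicated")
  expect_warning(plate_layout(data.frame(well = character(),
                                         condition = character())),
                 "no assay wells")
})

test_that("exactly the 60 interior wells are assignable", {
  expect_length(interior_wells(), 60L)
  expect_length(border_wells(), 36L)
  full <- suppressWarnings(
    plate_layout(data.frame(well = interior_wells(), condition = "Fn1")))
  expect_equal(nrow(full$assay_wells), 60L)
  for (w in c("A05", "H05", "C01", "C12")) {
    expect_error(plate_layout(data.frame(well = w, condition = "Fn1")),
                 "border")
  }
})

test_that("layouts load from CSV and empty conditions mean unused", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(well = c("B02", "B03", "A01"),
                       condition = c("Fn1", "Fn5", "")),
            path, row.names = FALSE)
  lay <- suppressWarnings(load_plate_layout(path))
  expect_equal(unname(lay$wells[["A01"]]), "unused")
  expect_equal(unname(lay$wells[["B02"]]), "Fn1")
})

test_that("random column-block layouts give balanced triplicates", {
  lay <- random_plate_layout(wells_per_condition = 6, seed = 3)
  tab <- table(lay$assay_wells$condition)
  expect_true(all(tab == 6L))
  # each column block of three rows carries all three conditions
  cols <- substr(lay$assay_wells$well, 2, 3)
  for (cl in unique(cols)) {
    rows_in <- lay$assay_wells[cols == cl, ]
    blocks <- split(rows_in$condition,
                    substr(rows_in$well, 1, 1) %in% c("B", "C", "D"))
    for (bl in blocks) expect_setequal(bl, c("Fn1", "Fn5", "Fn25"))
  }
})

test_that("image discovery groups channels and reports incomplete fields", {
  root <- tempfile()
  dir.create(root)
  for (w in c("B02", "B03")) {
    for (f in 1:2) {
      for (ch in c("dapi", "edu488", "cellmask647", "brightfield")) {
        file.create(file.path(root, sprintf("%s_f%d_%s.tif", w, f, ch)))
      }
    }
  }
  refs <- discover_images(root)
  expect_equal(nrow(refs), 4L)
  expect_equal(nrow(attr(refs, "diagnostics")), 0L)

  # drop one channel -> that field is reported, not silently dropped
  file.remove(file.path(root, "B03_f2_edu488.tif"))
  refs2 <- discover_images(root)
  expect_equal(nrow(refs2), 3L)
  diag <- attr(refs2, "diagnostics")
  expect_equal(diag$well, "B03")
  expect_equal(diag$missing, "edu488")

  # unparseable file name -> warning, remaining fields intact
  file.create(file.path(root, "strange-name.tif"))
  expect_warning(refs3 <- discover_images(root), "naming convention")
  expect_equal(nrow(refs3), 3L)

  # no matching files at all
  empty_root <- tempfile()
  dir.create(empty_root)
  refs4 <- discover_images(empty_root)
  expect_equal(nrow(refs4), 0L)
})

test_that("table round trips are the identity, including missing values", {
  tab <- random_object_table(50, seed = 7)
  tab$n_per_clump[3] <- 4L
  tab$brightfield_median[10] <- NA_real_
  path <- tempfile(fileext = ".csv")
  write_table(tab, path)
  back <- read_table(path, "object_table")
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # property: randomised tables round trip exactly
  for (s in 1:3) {
    t2 <- random_object_table(20, seed = s)
    t2$nucleus_area_um2[1] <- pi * 1e3 # full double precision preserved
    write_table(t2, path)
    expect_identical(read_table(path, "object_table")$nucleus_area_um2,
                     t2$nucleus_area_um2)
  }

  # well summary with NA standard deviations (n = 1 wells)
  lay <- plate_layout(data.frame(well = "B02", condition = "Fn1")) |>
    suppressWarnings()
  obj <- random_object_table(1, seed = 1)
  obj$qc_stage <- "cell"
  obj$n_per_clump <- 1L
  cl <- as_clump_table(tibble::tibble(plate = "p1", well = "B02",
                                      field = 1L, clump = 1L,
                                      clump_size = 1L, members = "1"))
  ws <- suppressWarnings(summarise_wells(obj, cl, lay))
  expect_true(is.na(ws$nucleus_area_um2_sd))
  write_table(ws, path)
  back_ws <- read_table(path, "well_summary")
  expect_equal(as.data.frame(back_ws), as.data.frame(ws))
})

test_that("schema violations raise typed errors naming the columns", {
  tab <- random_object_table(5)
  path <- tempfile(fileext = ".csv")
  df <- as.data.frame(tab)
  df$edu488_median <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_table(path, "object_table"), "edu488_median")
  expect_error(write_table(tibble::tibble(a = 1), path), "typed")
})

test_that("16-bit TIFF images round trip exactly", {
  m <- matrix(sample(0:65535, 32 * 24, replace = TRUE), 32, 24)
  path <- tempfile(fileext = ".tif")
  phenoplate:::write_image_tiff(m, path)
  expect_equal(phenoplate:::read_image_tiff(path), m)
})
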