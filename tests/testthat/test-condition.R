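make_summaries <- function(n_wells = 18, seed = 1) {
  set.seed(seed)
  wells <- interior_wells()[seq_len(n_wells)]
  conds <- rep(c("Fn1", "Fn5", "Fn25"), length.out = n_wells)
  cols <- phenoplate:::well_summary_stat_cols()
  df <- tibble::tibble(plate = "p1", well = wells, condition = conds,
                       cell_count = rpois(n_wells, 80) + 1L,
                       n_clumps = rpois(n_wells, 50) + 1L,
                       edu_positive_fraction = runif(n_wells, 0.2, 0.4),
                       fraction_single = runif(n_wells, 0.3, 0.8),
                       inverse_mean_clump_size = runif(n_wells, 0.5, 1))
  for (cc in cols) df[[cc]] <- rnorm(n_wells)
  as_well_summary(df)
}

test_that("the feature matrix is standardised with listwise deletion", {
  s <- make_summaries()
  fm <- build_feature_matrix(s)
  expect_equal(unname(colMeans(fm$matrix)), rep(0, ncol(fm$matrix)),
               tolerance = 1e-10)
  expect_equal(unname(apply(fm$matrix, 2, sd)), rep(1, ncol(fm$matrix)),
               tolerance = 1e-10)
  expect_equal(nrow(fm$matrix), 18L)

  # a well with a missing aggregate is dropped and logged
  s2 <- s
  s2$edu_positive_fraction[4] <- NA
  expect_message(fm2 <- build_feature_matrix(s2), "dropped")
  expect_equal(nrow(fm2$matrix), 17L)
  expect_equal(fm2$dropped_wells, s$well[4])

  # constant columns are dropped with a warning
  s3 <- s
  s3$fraction_single <- 0.5
  expect_warning(fm3 <- build_feature_matrix(s3), "constant")
  expect_false("fraction_single" %in% fm3$feature_names)

  # duplicated wells produce identical rows
  s4 <- rbind(s, s[1, ])
  s4$well[nrow(s4)] <- "G11"
  fm4 <- build_feature_matrix(as_well_summary(s4))
  expect_equal(unname(fm4$matrix[1, ]),
               unname(fm4$matrix[nrow(fm4$matrix), ]))
})

test_that("PCA matches a brute-force eigendecomposition", {
  set.seed(13)
  for (rep in 1:3) {
    m <- matrix(rnorm(20 * 9), 20, 9)
    z <- scale(m)
    pca <- run_pca(z)
    ev <- eigen(cov(z), symmetric = TRUE)
    expect_equal(pca$variance_fraction, ev$values / sum(ev$values),
                 tolerance = 1e-8)
    expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-12)
    expect_equal(abs(pca$loadings), abs(ev$vectors), tolerance = 1e-8)
    # orthonormal loadings
    expect_equal(crossprod(pca$loadings), diag(9), tolerance = 1e-8)
    # reconstruction restores the centred matrix
    expect_equal(pca$scores %*% t(pca$loadings),
                 scale(z, center = TRUE, scale = FALSE),
                 ignore_attr = TRUE, tolerance = 1e-8)
    # deterministic sign convention
    pca2 <- run_pca(z)
    expect_identical(pca$loadings, pca2$loadings)
    for (j in seq_len(9)) {
      expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
    }
  }

  # single varying direction -> PC1 carries all variance
  base <- rnorm(10)
  m1 <- cbind(base, 2 * base, -base) +
    matrix(0, 10, 3)
  pca1 <- run_pca(m1)
  expect_equal(pca1$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("coverage ellipses have chi-square geometry and calibration", {
  set.seed(14)
  sc <- matrix(rnorm(400), 200, 2)
  e <- group_ellipse(sc, condition = "iso")
  r <- sqrt(qchisq(0.68, 2))
  expect_lt(abs(e$semi_axes[1] - r) / r, 0.15)
  expect_lt(abs(e$semi_axes[2] - r) / r, 0.15)

  # coverage calibration on a large correlated sample
  S <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  L <- chol(S)
  x <- matrix(rnorm(2 * 5000), ncol = 2) %*% L
  ec <- group_ellipse(x, coverage = 0.68)
  inside <- phenoplate:::inside_ellipse(x, ec)
  expect_lt(abs(mean(inside) - 0.68), 0.03)

  # displaced clouds do not overlap; coincident clouds do
  e1 <- group_ellipse(sc, condition = "a")
  e2 <- group_ellipse(sweep(sc, 2, c(10, 0), "+"), condition = "b")
  expect_false(ellipses_overlap(e1, e2))
  expect_true(ellipses_overlap(e1, group_ellipse(sc, condition = "c")))

  # too few wells: no ellipse
  expect_warning(out <- group_ellipse(sc[1:2, , drop = FALSE]), "fewer")
  expect_null(out)
})

test_that("condition comparison reports ranges and rankings", {
  s <- make_summaries()
  s$cell_count <- ifelse(s$condition == "Fn25", 150L,
                         ifelse(s$condition == "Fn5", 90L, 40L))
  cmp <- compare_conditions(s)
  expect_equal(cmp$ranking, c("Fn25", "Fn5", "Fn1"))
  expect_equal(nrow(cmp$stats), 3L)
  expect_true(all(c("cell_count_min", "cell_count_max",
                    "edu_fraction_mean") %in% names(cmp$stats)))
  expect_s3_class(cmp$densities$nucleus_area_um2_mean$Fn1, "tbl_df")

  # single condition: report without ranking, no error
  cmp1 <- compare_conditions(s[s$condition == "Fn1", ])
  expect_null(cmp1$ranking)
  expect_equal(nrow(cmp1$stats), 1L)
})
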