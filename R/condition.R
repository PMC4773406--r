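# Condition-level analysis: per-condition feature ranges and the
# principal component analysis that separates substrate conditions in
# feature space, with bivariate-normal coverage ellipses on the first two
# components.

#' Build the standardised well-by-feature matrix
#'
#' Columns are the transformed means and standard deviations of the 6
#' morphology and 2 intensity features (all cells), plus log10 cell
#' count, the EdU-positive fraction, the fraction of single cells and
#' the inverse mean clump size. Because the features mix units, each
#' column is centred and scaled to unit variance. Wells with any missing
#' feature are removed (listwise deletion, logged); constant columns are
#' dropped with a warning.
#'
#' @param summaries a `well_summary` tibble
#' @return list with `matrix` (standardised, rows named by well),
#'   `wells`, `conditions`, `feature_names`, `center`, `scale` and
#'   `dropped_wells`
#' @export
build_feature_matrix <- function(summaries) {
  stopifnot(nrow(summaries) >= 3L)
  stat_cols <- as.vector(t(outer(OBJECT_FEATURES, c("_mean", "_sd"),
                                 paste0)))
  m <- as.matrix(summaries[stat_cols])
  m <- cbind(m,
             log10_cell_count = log10(pmax(summaries$cell_count, 1L)),
             edu_positive_fraction = summaries$edu_positive_fraction,
             fraction_single = summaries$fraction_single,
             inverse_mean_clump_size = summaries$inverse_mean_clump_size)
  rownames(m) <- summaries$well
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message(sum(!complete), " well(s) dropped for missing features: ",
            paste(summaries$well[!complete], collapse = ", "))
  }
  m <- m[complete, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[, !constant, drop = FALSE]
  }
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  z <- scale(m, center = ctr, scale = scl)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(matrix = z,
       wells = rownames(z),
       conditions = summaries$condition[complete],
       feature_names = colnames(z),
       center = ctr, scale = scl,
       dropped_wells = summaries$well[!complete])
}

#' Principal component analysis of the feature matrix
#'
#' Singular value decomposition of the standardised matrix. The sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive, making repeated runs identical.
#'
#' @param matrix standardised wells-by-features matrix (from
#'   [build_feature_matrix()])
#' @return a `pca_result` list: `scores` (wells x components),
#'   `loadings` (features x components, orthonormal columns),
#'   `variance_fraction` (non-increasing, sums to 1) and `feature_names`
#' @export
run_pca <- function(matrix) {
  stopifnot(nrow(matrix) >= 2L, ncol(matrix) >= 2L)
  n <- nrow(matrix)
  sv <- svd(scale(matrix, center = TRUE, scale = FALSE))
  # fix signs: largest |loading| positive per component
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(matrix)
  loadings <- sv$v
  rownames(loadings) <- colnames(matrix)
  ev <- sv$d^2 / (n - 1)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = ev / sum(ev),
                 feature_names = colnames(matrix)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<pca_result> %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(vf), 100 * vf[1], 100 * vf[2]))
  invisible(x)
}

#' Bivariate-normal coverage ellipse for one condition
#'
#' Fits a bivariate normal to the condition's scores on two components
#' and returns the contour containing the requested probability mass
#' (chi-square quantile with 2 degrees of freedom).
#'
#' @param scores two-column score matrix
#' @param coverage probability mass inside the ellipse (default 0.68)
#' @param condition label carried on the result
#' @return a `group_ellipse`: `condition`, `centre`, `semi_axes`
#'   (descending), `angle` (radians, orientation of the major axis),
#'   `cov` and `coverage`
#' @export
group_ellipse <- function(scores, coverage = 0.68,
                          condition = NA_character_) {
  stopifnot(is.matrix(scores), ncol(scores) == 2L,
            coverage > 0, coverage < 1)
  if (nrow(scores) < 3L) {
    warning("fewer than 3 wells; no ellipse fitted for ", condition,
            call. = FALSE)
    return(NULL)
  }
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  r2 <- stats::qchisq(coverage, df = 2)
  e <- eigen(S, symmetric = TRUE)
  structure(list(condition = condition, centre = ctr,
                 semi_axes = sqrt(pmax(e$values, 0) * r2),
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 cov = S, coverage = coverage),
            class = "group_ellipse")
}

#' Boundary points of a coverage ellipse
#' @param e a `group_ellipse`
#' @param n number of boundary points
#' @return n-by-2 matrix of boundary coordinates
#' @export
ellipse_boundary <- function(e, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  circ <- cbind(e$semi_axes[1] * cos(th), e$semi_axes[2] * sin(th))
  rot <- matrix(c(cos(e$angle), sin(e$angle),
                  -sin(e$angle), cos(e$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, e$centre, "+")
}

inside_ellipse <- function(points, e) {
  r2 <- stats::qchisq(e$coverage, df = 2)
  d <- sweep(points, 2, e$centre)
  Sinv <- solve(e$cov)
  maha <- rowSums((d %*% Sinv) * d)
  maha <= r2 + 1e-12
}

#' Do two coverage ellipses overlap?
#'
#' Evaluated by dense boundary sampling: the ellipses overlap when either
#' centre lies inside the other ellipse or any boundary point of one lies
#' inside the other.
#'
#' @param e1,e2 `group_ellipse` objects
#' @param n boundary points sampled per ellipse
#' @return logical
#' @export
ellipses_overlap <- function(e1, e2, n = 720L) {
  if (inside_ellipse(rbind(e1$centre), e2) ||
      inside_ellipse(rbind(e2$centre), e1)) return(TRUE)
  any(inside_ellipse(ellipse_boundary(e1, n), e2)) ||
    any(inside_ellipse(ellipse_boundary(e2, n), e1))
}

#' Per-condition comparison report
#'
#' @param summaries a `well_summary` tibble with at least 2 conditions
#'   (a single condition yields a report without ranking)
#' @param density_features well-mean features for which per-condition
#'   density tables are produced
#' @return list with `stats` (per condition: mean/min/max of cell count,
#'   EdU fraction and inverse mean clump size), `ranking` (conditions by
#'   decreasing mean cell count; `NULL` for a single condition) and
#'   `densities` (per feature, per condition: tibble of x/density)
#' @export
compare_conditions <- function(summaries,
                               density_features = c(
                                 "nucleus_area_um2_mean",
                                 "nucleus_roundness_mean",
                                 "nucleus_width_to_length_mean")) {
  conds <- sort(unique(summaries$condition))
  rng <- function(x) c(mean = mean(x, na.rm = TRUE),
                       min = suppressWarnings(min(x, na.rm = TRUE)),
                       max = suppressWarnings(max(x, na.rm = TRUE)))
  st <- lapply(conds, function(cc) {
    s <- summaries[summaries$condition == cc, , drop = FALSE]
    tibble::tibble(condition = cc, n_wells = nrow(s),
                   cell_count_mean = rng(s$cell_count)[["mean"]],
                   cell_count_min = rng(s$cell_count)[["min"]],
                   cell_count_max = rng(s$cell_count)[["max"]],
                   edu_fraction_mean =
                     mean(s$edu_positive_fraction, na.rm = TRUE),
                   edu_fraction_min =
                     suppressWarnings(min(s$edu_positive_fraction, na.rm = TRUE)),
                   edu_fraction_max =
                     suppressWarnings(max(s$edu_positive_fraction, na.rm = TRUE)),
                   inverse_mean_clump_size_mean =
                     mean(s$inverse_mean_clump_size, na.rm = TRUE),
                   fraction_single_mean =
                     mean(s$fraction_single, na.rm = TRUE))
  })
  st <- do.call(rbind, st)
  ranking <- if (length(conds) >= 2L) {
    st$condition[order(st$cell_count_mean, decreasing = TRUE)]
  } else NULL
  dens <- lapply(setNames(density_features, density_features), function(f) {
    lapply(setNames(conds, conds), function(cc) {
      v <- summaries[[f]][summaries$condition == cc]
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NULL)
      d <- stats::density(v)
      tibble::tibble(x = d$x, density = d$y)
    })
  })
  list(stats = st, ranking = ranking, densities = dens)
}
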