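# Well-level aggregation of cell-based measurements.
#
# Features are variance-stabilised before averaging: right-skewed,
# strictly positive quantities (areas, intensity medians) are log10
# transformed; left-skewed ratios bounded at 1 (roundness,
# width-to-length) are squared. Each well is then summarised by the mean
# and standard deviation of each transformed feature, computed over all
# cells and separately over single cells, plus the cell count, the
# EdU-positive fraction, the fraction of single cells and the inverse
# mean clump size.

#' Default per-feature transforms
#' @return named character vector mapping feature name to `"log10"` or
#'   `"square"`
#' @export
default_feature_transforms <- function() {
  c(nucleus_area_um2 = "log10", cell_area_um2 = "log10",
    dapi_median = "log10", edu488_median = "log10",
    brightfield_median = "log10",
    nucleus_roundness = "square", cell_roundness = "square",
    nucleus_width_to_length = "square", cell_width_to_length = "square")
}

#' Transform a feature vector for aggregation
#'
#' @param values numeric vector
#' @param feature feature name (looked up in `transforms`)
#' @param transforms named map feature -> `"log10"`, `"square"` or
#'   `"identity"`
#' @return transformed values; under `log10`, non-positive entries are
#'   returned as `NA` with a warning (they are excluded from aggregates)
#' @export
transform_feature <- function(values, feature,
                              transforms = default_feature_transforms()) {
  tr <- transforms[[feature]]
  if (is.null(tr) || tr == "identity") return(values)
  if (tr == "square") return(values^2)
  if (tr == "log10") {
    bad <- !is.na(values) & values <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive value(s) in '", feature,
              "' excluded from log10 aggregation", call. = FALSE)
      values[bad] <- NA_real_
    }
    return(log10(values))
  }
  stop("unknown transform: ", tr, call. = FALSE)
}

mean_sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(NA_real_, NA_real_))
  c(mean(x), if (length(x) > 1L) stats::sd(x) else NA_real_)
}

#' EdU-positive fraction from the density residual over the main peak
#'
#' EdU median intensities in a well form a dominant low-intensity
#' population (EdU-negative cells at background label level) plus a
#' high-intensity population of cells that were in S phase during the
#' pulse. The estimator (1) log10-transforms the values, (2) estimates
#' the empirical density by Gaussian kernel density estimation with the
#' Silverman bandwidth, (3) fits a Gaussian to the main peak and (4)
#' reports the area under the empirical density not explained by that
#' peak.
#'
#' @param edu_medians raw (untransformed) EdU median intensities, one per
#'   cell
#' @param min_n minimum number of cells for density estimation; below it
#'   the result is `NA` with a warning
#' @param method `"quadratic"` (default): the peak Gaussian's centre,
#'   width and height come from a quadratic fit to the log-density over
#'   the contiguous half-maximum region around the mode — width is
#'   therefore measured at the smoothed scale and the null (no positive
#'   population) residual is close to zero. `"mirror"`: sigma from the
#'   sub-mode half of the data reflected about the mode (at the data
#'   scale, then convolved with the bandwidth), height matched to the
#'   density at the mode. `"em"`: two-component Gaussian mixture via
#'   \pkg{mclust}; the positive fraction is the mass of components above
#'   the main peak.
#' @param noise_floor multiple of the pointwise kernel-density sampling
#'   standard error subtracted before rectifying the residual; suppresses
#'   spurious positive mass from density-estimate wiggle
#' @param adjust bandwidth multiplier passed to [stats::density()]
#' @return fraction in \[0, 1\], or `NA` when fewer than `min_n` values
#' @export
edu_positive_fraction <- function(edu_medians, min_n = 30L,
                                  method = c("quadratic", "mirror", "em"),
                                  noise_floor = 0.5, adjust = 1) {
  method <- match.arg(method)
  x <- edu_medians[!is.na(edu_medians) & edu_medians > 0]
  if (length(x) < min_n) {
    warning("fewer than ", min_n, " EdU values; fraction set to NA",
            call. = FALSE)
    return(NA_real_)
  }
  lx <- log10(x)
  n <- length(lx)
  if (stats::sd(lx) == 0) return(0)
  d <- stats::density(lx, bw = "nrd0", adjust = adjust)
  bw <- d$bw
  imode <- which.max(d$y)
  fm0 <- d$y[imode]
  if (method == "em") {
    return(edu_fraction_em(lx, d$x[imode]))
  }
  if (method == "quadratic") {
    # contiguous half-maximum region around the mode
    lo <- imode; while (lo > 1L && d$y[lo - 1L] >= fm0 / 2) lo <- lo - 1L
    hi <- imode; while (hi < length(d$y) && d$y[hi + 1L] >= fm0 / 2) hi <- hi + 1L
    w <- lo:hi
    b <- coef(stats::lm(log(d$y[w]) ~ stats::poly(d$x[w], 2, raw = TRUE)))
    if (all(is.finite(b)) && b[3] < 0) {
      mode <- -b[2] / (2 * b[3])
      fmode <- exp(b[1] - b[2]^2 / (4 * b[3]))
      sig_eff <- 1 / sqrt(-2 * b[3])
    } else {
      mode <- d$x[imode]; fmode <- fm0; sig_eff <- bw
    }
  } else { # mirror
    mode <- d$x[imode]; fmode <- fm0
    left <- d$y[seq_len(imode)]
    below <- which(left < fm0 / 2)
    hwhm <- if (length(below)) mode - d$x[max(below)] else mode - d$x[1]
    s_init <- hwhm / sqrt(2 * log(2))
    dd <- mode - lx[lx <= mode & lx >= mode - 3 * s_init]
    # truncated half-normal second-moment correction for the 3-sigma window
    corr <- 1 - 3 * stats::dnorm(3) / (stats::pnorm(3) - 0.5)
    sig <- sqrt(mean(dd^2) / corr)
    sig_eff <- sqrt(sig^2 + bw^2)
  }
  mass <- min(1, fmode * sig_eff * sqrt(2 * pi))
  g <- mass * stats::dnorm(d$x, mode, sig_eff)
  # pointwise KDE sampling sd: sqrt(f * R(K) / (n h)), R(K) = 1/(2 sqrt(pi))
  se <- sqrt(d$y * 0.2820948 / (n * bw))
  dx <- d$x[2] - d$x[1]
  min(1, max(0, sum(pmax(d$y - g - noise_floor * se, 0)) * dx))
}

edu_fraction_em <- function(lx, mode) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    stop("method = 'em' requires the mclust package", call. = FALSE)
  }
  fit <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) return(NA_real_)
  mu <- fit$parameters$mean
  pro <- fit$parameters$pro
  main <- which.min(abs(mu - mode))
  sum(pro[mu > mu[main]])
}

#' Geometric clump-size fit for one well
#'
#' Clump counts fall off roughly exponentially with clump size, i.e. the
#' sizes follow a geometric law on support 1, 2, 3, ... The maximum
#' likelihood estimate of its parameter is the inverse mean clump size.
#'
#' @param sizes integer clump sizes (>= 1)
#' @return list with `p_hat` (inverse mean size), `n_clumps`,
#'   `chisq` and `df` (goodness-of-fit statistic of observed versus
#'   expected geometric counts, sizes pooled beyond the last expected
#'   count of at least 5; `NA` when no pooled class remains)
#' @export
fit_geometric_clumps <- function(sizes) {
  sizes <- sizes[!is.na(sizes)]
  if (!length(sizes)) {
    return(list(p_hat = NA_real_, n_clumps = 0L, chisq = NA_real_,
                df = NA_real_))
  }
  stopifnot(all(sizes >= 1))
  n <- length(sizes)
  p <- 1 / mean(sizes)
  # pool the tail where expected counts drop below 5
  kmax <- max(sizes)
  exp_k <- n * p * (1 - p)^(seq_len(kmax) - 1L)
  cut <- which(exp_k >= 5)
  chisq <- NA_real_; df <- NA_real_
  if (length(cut) >= 1L && p < 1) {
    k <- max(cut)
    obs <- tabulate(pmin(sizes, k + 1L), nbins = k + 1L)
    expd <- c(exp_k[seq_len(k)], n * (1 - p)^k)
    chisq <- sum((obs - expd)^2 / expd)
    df <- max(0L, k + 1L - 2L) # classes - 1 - one fitted parameter
  }
  list(p_hat = p, n_clumps = n, chisq = chisq, df = df)
}

#' Aggregate one well to its summary row
#'
#' @param table annotated `object_table` at stage `"cell"` (with
#'   `n_per_clump` filled), already restricted or restrictable to `well`
#' @param clumps matching `clump_table`
#' @param well well name
#' @param condition substrate condition label for the well
#' @param plate plate identifier
#' @param transforms per-feature transform map
#' @param edu_min_n minimum cells for the EdU density estimate
#' @return a one-row `well_summary` tibble; standard deviations are `NA`
#'   (not zero) when only one value contributes
#' @export
aggregate_well <- function(table, clumps, well, condition = NA_character_,
                           plate = "plate1",
                           transforms = default_feature_transforms(),
                           edu_min_n = 30L) {
  rows <- table[table$well == well, , drop = FALSE]
  cl <- clumps[clumps$well == well, , drop = FALSE]
  stopifnot(all(rows$qc_stage == "cell"))
  n_cells <- nrow(rows)
  n_clumps <- nrow(cl)
  out <- list(plate = plate, well = well, condition = condition,
              cell_count = n_cells, n_clumps = n_clumps)
  if (n_cells > 0L) {
    out$edu_positive_fraction <-
      suppressWarnings(edu_positive_fraction(rows$edu488_median,
                                             min_n = edu_min_n))
    singles <- sum(cl$clump_size == 1L)
    out$fraction_single <- singles / n_cells
    out$inverse_mean_clump_size <- n_clumps / n_cells
  } else {
    out$edu_positive_fraction <- NA_real_
    out$fraction_single <- NA_real_
    out$inverse_mean_clump_size <- NA_real_
  }
  single_rows <- rows[!is.na(rows$n_per_clump) & rows$n_per_clump == 1L, ,
                      drop = FALSE]
  for (f in OBJECT_FEATURES) {
    all_v <- mean_sd_or_na(
      suppressWarnings(transform_feature(rows[[f]], f, transforms)))
    sg_v <- mean_sd_or_na(
      suppressWarnings(transform_feature(single_rows[[f]], f, transforms)))
    out[[paste0(f, "_mean")]] <- all_v[1]
    out[[paste0(f, "_sd")]] <- all_v[2]
    out[[paste0("single_", f, "_mean")]] <- sg_v[1]
    out[[paste0("single_", f, "_sd")]] <- sg_v[2]
  }
  as_well_summary(tibble::as_tibble(out))
}

#' Aggregate every assay well of a plate
#'
#' @param table annotated `object_table` at stage `"cell"`
#' @param clumps `clump_table` for the same plate
#' @param layout [plate_layout()] supplying the condition labels; wells
#'   with no retained cells still get a summary row (count 0, aggregates
#'   missing)
#' @param ... passed to [aggregate_well()]
#' @return a `well_summary` tibble, one row per assay well
#' @export
summarise_wells <- function(table, clumps, layout, ...) {
  rows <- lapply(seq_len(nrow(layout$assay_wells)), function(i) {
    w <- layout$assay_wells$well[i]
    aggregate_well(table, clumps, well = w,
                   condition = layout$assay_wells$condition[i],
                   plate = layout$plate_id, ...)
  })
  out <- do.call(rbind, rows)
  as_well_summary(out)
}
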