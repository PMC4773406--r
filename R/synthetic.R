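# Synthetic plate simulator.
#
# Generates ground-truthed object populations and rendered four-channel
# field images with the statistical structure the pipeline assumes:
# condition-dependent attached-cell counts, clump sizes drawn from a
# geometric law (support 1, 2, 3, ...; a single cell is a clump of size
# 1), a two-population log-normal EdU intensity mixture shared across
# conditions, log-normal morphology, and rare oversized feeder
# contaminants. Clump members are packed in mutual contact; distinct
# clumps keep a clearance (default 8 px) so distance-0 clump detection
# is unambiguous on the rendered images.

#' Simulation parameters
#'
#' The per-condition defaults emulate the behaviour of dissociated iPSCs
#' on a fibronectin concentration gradient: attachment (and therefore
#' retrieved cell count) rises with coating concentration, the tendency
#' to form clumps rises with it too (lower geometric parameter), the
#' proliferative fraction does not depend on the substrate, cells on the
#' low-adhesion substrate stay smaller and rounder while cells on the
#' high-adhesion substrate spread into larger, more variable shapes.
#'
#' @param conditions named list of per-condition blocks; each block has
#'   `expected_attached_cells` (per well), `clump_geometric_p` in (0, 1],
#'   `edu_positive_fraction` in \[0, 1\], `nucleus_area_um2` and
#'   `cell_area_um2` (log-normal `meanlog`/`sdlog`), `elongation`
#'   (beta shape1/shape2 for the width-to-length ratio) and
#'   `feeder_rate` (probability of one oversized contaminant per well)
#' @param intensity intensity model: per-channel `background` means and
#'   `background_sd`s, `dapi_scale`, `cellmask_scale`, and the negative
#'   and positive EdU log-normal components (`edu_neg`, `edu_pos`,
#'   each `meanlog`/`sdlog`; the positive mean must exceed the negative)
#' @param pixel_size_um micrometres per pixel (default 0.65, a typical
#'   10x widefield scale)
#' @param image_shape field dimensions in pixels
#' @param n_fields fields of view per well
#' @param clearance_px minimum gap between distinct clumps
#' @param well_effect_sdlog SD (log scale) of the per-well attachment
#'   multiplier; set 0 for exchangeable wells
#' @return a `simulation_params` object
#' @export
simulation_params <- function(
    conditions = list(
      Fn1 = list(expected_attached_cells = 45,
                 clump_geometric_p = 0.85,
                 edu_positive_fraction = 0.30,
                 nucleus_area_um2 = c(meanlog = log(160), sdlog = 0.22),
                 cell_area_um2 = c(meanlog = log(650), sdlog = 0.28),
                 elongation = c(shape1 = 8, shape2 = 2),
                 feeder_rate = 0.10),
      Fn5 = list(expected_attached_cells = 75,
                 clump_geometric_p = 0.63,
                 edu_positive_fraction = 0.30,
                 nucleus_area_um2 = c(meanlog = log(175), sdlog = 0.25),
                 cell_area_um2 = c(meanlog = log(1000), sdlog = 0.36),
                 elongation = c(shape1 = 5.5, shape2 = 3.5),
                 feeder_rate = 0.10),
      Fn25 = list(expected_attached_cells = 100,
                  clump_geometric_p = 0.55,
                  edu_positive_fraction = 0.30,
                  nucleus_area_um2 = c(meanlog = log(180), sdlog = 0.26),
                  cell_area_um2 = c(meanlog = log(1100), sdlog = 0.40),
                  elongation = c(shape1 = 5, shape2 = 4),
                  feeder_rate = 0.10)),
    intensity = list(
      background = c(dapi = 200, edu488 = 200, cellmask647 = 200,
                     brightfield = 500),
      background_sd = c(dapi = 20, edu488 = 20, cellmask647 = 20,
                        brightfield = 10),
      dapi_scale = 3000,
      cellmask_scale = 1500,
      edu_neg = c(meanlog = log(300), sdlog = 0.25),
      edu_pos = c(meanlog = log(3000), sdlog = 0.30)),
    pixel_size_um = 0.65,
    image_shape = c(480L, 480L),
    n_fields = 9L,
    clearance_px = 8,
    well_effect_sdlog = 0.15) {
  for (nm in names(conditions)) {
    b <- conditions[[nm]]
    stopifnot(b$expected_attached_cells >= 0,
              b$clump_geometric_p > 0, b$clump_geometric_p <= 1,
              b$edu_positive_fraction >= 0, b$edu_positive_fraction <= 1,
              b$feeder_rate >= 0, b$feeder_rate <= 1)
  }
  if (intensity$edu_pos[["meanlog"]] <= intensity$edu_neg[["meanlog"]]) {
    stop("EdU mixture is not separable: positive log-mean must exceed ",
         "the negative log-mean", call. = FALSE)
  }
  stopifnot(pixel_size_um > 0, all(image_shape >= 64L), n_fields >= 1L,
            clearance_px >= 0, well_effect_sdlog >= 0)
  structure(list(conditions = conditions, intensity = intensity,
                 pixel_size_um = pixel_size_um,
                 image_shape = as.integer(image_shape),
                 n_fields = as.integer(n_fields),
                 clearance_px = clearance_px,
                 well_effect_sdlog = well_effect_sdlog),
            class = "simulation_params")
}

# geometric sizes on support 1, 2, 3, ...
rgeom_sizes <- function(n, p) stats::rgeom(n, p) + 1L

area_to_axes <- function(area_px, w2l) {
  a <- sqrt(area_px / (pi * w2l))
  c(a = a, b = a * w2l)
}

ellipse_outline_pts <- function(area_px, w2l, angle, n = 32L) {
  ax <- area_to_axes(area_px, w2l)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- ax[1] * cos(th); v <- ax[2] * sin(th)
  cbind(u * cos(angle) - v * sin(angle), u * sin(angle) + v * cos(angle))
}

# radius of an ellipse (semi-axes a >= b, rotated by phi) along
# direction theta
ellipse_dir_radius <- function(a, b, phi, theta) {
  a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
}

point_in_ellipse_px <- function(pt, centre, area_px, w2l, angle) {
  ax <- area_to_axes(area_px, w2l)
  dx <- pt[1] - centre[1]; dy <- pt[2] - centre[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / ax[1])^2 + (v / ax[2])^2 <= 1
}

ellipse_pixels <- function(cx, cy, area_px, w2l, angle, shape) {
  ax <- area_to_axes(area_px, w2l)
  xr <- max(1L, floor(cx - ax[1])):min(shape[1], ceiling(cx + ax[1]))
  yr <- max(1L, floor(cy - ax[1])):min(shape[2], ceiling(cy + ax[1]))
  if (!length(xr) || !length(yr)) return(matrix(integer(), 0, 2))
  dx <- rep(xr, times = length(yr)) - cx
  dy <- rep(yr, each = length(xr)) - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  sel <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
  cbind(rep(xr, times = length(yr))[sel], rep(yr, each = length(xr))[sel])
}

#' Sample the ground-truth object population of one well
#'
#' A per-well log-normal multiplier (SD `well_effect_sdlog`) models
#' plating variability; it scales the expected cell count and the odds
#' of clump growth together, so denser wells form proportionally fewer
#' single cells. Given the multiplier, the number of clumps is Poisson
#' with the expected total cell count matching
#' `expected_attached_cells` times the multiplier; clump sizes are
#' i.i.d. geometric (with exactly `clump_geometric_p` when
#' `well_effect_sdlog = 0`), EdU labels i.i.d. Bernoulli. Clumps are
#' assigned to fields uniformly and packed so members touch while
#' distinct clumps stay at least `clearance_px` apart and no object
#' reaches the field border.
#'
#' @param params [simulation_params()]
#' @param condition condition label (must exist in `params$conditions`)
#' @param seed integer seed; the draw is a pure function of
#'   (params, condition, seed)
#' @param well,plate identifiers carried into the table
#' @return a `ground_truth` tibble, one row per cell
#' @export
sample_well_population <- function(params, condition, seed = 1L,
                                   well = "B02", plate = "plate1") {
  if (!condition %in% names(params$conditions)) {
    stop("condition not present in simulation parameters: ", condition,
         call. = FALSE)
  }
  b <- params$conditions[[condition]]
  set.seed(seed)
  # per-well random effect on attachment (coating/seeding variability);
  # denser wells clump more (cells meet more often), modelled by scaling
  # the odds of clump growth with the well multiplier, so wells with
  # fewer cells carry proportionally more single cells
  well_mult <- stats::rlnorm(1L, -params$well_effect_sdlog^2 / 2,
                             params$well_effect_sdlog)
  p <- b$clump_geometric_p
  p_eff <- p / (p + (1 - p) * well_mult)
  n_clumps <- stats::rpois(1L, well_mult * b$expected_attached_cells *
                             p_eff)
  sizes <- if (n_clumps > 0L) rgeom_sizes(n_clumps, p_eff)
           else integer(0)
  feeder <- stats::runif(1) < b$feeder_rate
  if (feeder) sizes <- c(sizes, 1L)
  n_clumps_all <- length(sizes)
  if (n_clumps_all == 0L) return(empty_table("ground_truth"))
  is_feeder_clump <- c(rep(FALSE, n_clumps), if (feeder) TRUE)
  fields <- sample.int(params$n_fields, n_clumps_all, replace = TRUE)
  px_area <- params$pixel_size_um^2
  shape <- params$image_shape
  rows <- list()
  obj_id <- 0L
  # sample every clump's member geometry first ...
  geom <- lapply(seq_len(n_clumps_all), function(ci) {
      k <- sizes[ci]
      if (is_feeder_clump[ci]) {
        cell_areas <- stats::runif(1, 6500, 9000)
        nuc_areas <- stats::runif(1, 350, 550)
      } else {
        cell_areas <- stats::rlnorm(k, b$cell_area_um2[["meanlog"]],
                                    b$cell_area_um2[["sdlog"]])
        nuc_areas <- stats::rlnorm(k, b$nucleus_area_um2[["meanlog"]],
                                   b$nucleus_area_um2[["sdlog"]])
        cell_areas <- pmax(cell_areas, 2 * nuc_areas)
      }
      w2l <- pmin(pmax(stats::rbeta(k, b$elongation[["shape1"]],
                                    b$elongation[["shape2"]]), 0.2), 1)
      angles <- stats::runif(k, 0, pi)
      r_eff <- sqrt((cell_areas / px_area) / (pi * w2l)) # major semi-axis
      a_ax <- r_eff; b_ax <- r_eff * w2l
      offs <- matrix(0, k, 2)
      if (k > 1L) {
        # tangent placements using directional ellipse radii so members
        # genuinely touch; among valid candidates take the one closest
        # to the clump seed point to keep the clump compact
        for (j in 2:k) {
          best <- NULL
          for (try in seq_len(40L)) {
            anchor <- sample.int(j - 1L, 1L)
            th <- stats::runif(1, 0, 2 * pi)
            gap <- ellipse_dir_radius(a_ax[anchor], b_ax[anchor],
                                      angles[anchor], th) +
              ellipse_dir_radius(a_ax[j], b_ax[j], angles[j], th)
            cand <- offs[anchor, ] + 0.95 * gap * c(cos(th), sin(th))
            prev <- seq_len(j - 1L)
            dd <- offs[prev, , drop = FALSE] -
              matrix(cand, j - 1L, 2, byrow = TRUE)
            d <- sqrt(rowSums(dd^2))
            dirs <- atan2(-dd[, 2], -dd[, 1]) # from existing towards cand
            lim <- vapply(prev, function(q) {
              ellipse_dir_radius(a_ax[q], b_ax[q], angles[q], dirs[q]) +
                ellipse_dir_radius(a_ax[j], b_ax[j], angles[j], dirs[q])
            }, numeric(1))
            if (all(d >= 0.70 * lim) &&
                (is.null(best) || sum(cand^2) < sum(best^2))) {
              best <- cand
            }
          }
          offs[j, ] <- if (is.null(best)) cand else best
        }
      }
      list(ci = ci, k = k, cell_areas = cell_areas, nuc_areas = nuc_areas,
           w2l = w2l, angles = angles, offs = offs,
           edu = stats::rbinom(k, 1L, b$edu_positive_fraction),
           extent = max(sqrt(rowSums(offs^2)) + r_eff))
  })
  # ... then place, largest extent first, each clump in its assigned
  # field (falling back to the other fields when that one is full).
  # Clearance between clumps is enforced on the actual cell outlines:
  # sampled boundary points of a candidate member must stay clearance_px
  # away from every placed cell's boundary, with a bounding-radius
  # pre-check and a centre-containment check for the nested case.
  geom <- geom[order(vapply(geom, `[[`, numeric(1), "extent"),
                     decreasing = TRUE)]
  placed <- rep(list(list()), params$n_fields) # per field, per cell
  for (g in geom) {
    r_mem <- sqrt((g$cell_areas / px_area) / (pi * g$w2l))
    area_px_mem <- g$cell_areas / px_area
    mem_pts <- lapply(seq_len(g$k), function(j) {
      ellipse_outline_pts(area_px_mem[j], g$w2l[j], g$angles[j])
    })
    lo <- g$extent + 3
    hi <- shape - g$extent - 3
    if (any(hi <= lo)) {
      stop("cannot pack a clump of extent ", round(g$extent),
           " px into the field; reduce expected_attached_cells or ",
           "cell areas", call. = FALSE)
    }
    ok_at <- function(cand, in_fld) {
      for (j in seq_len(g$k)) {
        cj <- cand + g$offs[j, ]
        pj <- sweep(mem_pts[[j]], 2, cj, "+")
        for (pc in placed[[in_fld]]) {
          gap <- sqrt(sum((pc$centre - cj)^2))
          if (gap >= pc$r + r_mem[j] + params$clearance_px) next
          if (point_in_ellipse_px(cj, pc$centre, pc$area_px, pc$w2l,
                                  pc$angle) ||
              point_in_ellipse_px(pc$centre, cj, area_px_mem[j],
                                  g$w2l[j], g$angles[j])) return(FALSE)
          dmin <- min(vapply(seq_len(nrow(pj)), function(q) {
            min((pc$pts[, 1] - pj[q, 1])^2 + (pc$pts[, 2] - pj[q, 2])^2)
          }, numeric(1)))
          if (sqrt(dmin) < params$clearance_px) return(FALSE)
        }
      }
      TRUE
    }
    found <- FALSE
    fld <- fields[g$ci]
    others <- setdiff(seq_len(params$n_fields), fld)
    for (f_try in c(fld, others[sample.int(length(others))])) {
      for (try in seq_len(200L)) {
        cand <- c(stats::runif(1, lo, hi[1]), stats::runif(1, lo, hi[2]))
        if (ok_at(cand, f_try)) { found <- TRUE; break }
      }
      if (found) { fld <- f_try; break }
    }
    if (!found) {
      stop("plate too crowded to place all clumps with the required ",
           "clearance; reduce expected_attached_cells", call. = FALSE)
    }
    for (j in seq_len(g$k)) {
      cj <- cand + g$offs[j, ]
      placed[[fld]][[length(placed[[fld]]) + 1L]] <-
        list(centre = cj, r = r_mem[j], area_px = area_px_mem[j],
             w2l = g$w2l[j], angle = g$angles[j],
             pts = sweep(mem_pts[[j]], 2, cj, "+"))
    }
    for (j in seq_len(g$k)) {
      obj_id <- obj_id + 1L
      rows[[obj_id]] <- tibble::tibble(
        plate = plate, well = well, field = fld, object = obj_id,
        x_px = cand[1] + g$offs[j, 1] - 1, # 0-based pixel-centre coords
        y_px = cand[2] + g$offs[j, 2] - 1,
        nucleus_area_um2 = g$nuc_areas[j],
        cell_area_um2 = g$cell_areas[j],
        width_to_length = g$w2l[j], orientation = g$angles[j],
        clump = g$ci, clump_size = g$k,
        edu_label = if (is_feeder_clump[g$ci]) 0L else g$edu[j],
        is_feeder = is_feeder_clump[g$ci])
    }
  }
  tr <- as_ground_truth(do.call(rbind, rows))
  tr[order(tr$field, tr$object), ]
}

#' Render one field image from ground truth
#'
#' Nuclei are filled ellipses in the DAPI channel; the EdU channel adds a
#' per-cell intensity drawn from the negative or positive log-normal
#' component according to the true label (over the nucleus region); the
#' membrane channel renders the cell bodies, clump members sharing
#' touching boundaries; brightfield is strictly positive background plus
#' noise. All channels get additive Gaussian noise and are rounded to
#' 16-bit integers. The output is a pure function of (truth, params,
#' seed).
#'
#' @param truth `ground_truth` rows for one (well, field)
#' @param params [simulation_params()]
#' @param seed integer seed
#' @param well,field identifiers (defaulted from `truth` when it has
#'   rows)
#' @return a [field_image()]
#' @export
render_field <- function(truth, params, seed = 1L,
                         well = NULL, field = NULL) {
  if (nrow(truth)) {
    stopifnot(length(unique(truth$well)) == 1L,
              length(unique(truth$field)) == 1L)
    well <- truth$well[1]; field <- truth$field[1]
  } else {
    if (is.null(well)) well <- "B02"
    if (is.null(field)) field <- 1L
  }
  set.seed(seed)
  it <- params$intensity
  shape <- params$image_shape
  px_area <- params$pixel_size_um^2
  fg <- lapply(CHANNEL_NAMES, function(ch) matrix(0, shape[1], shape[2]))
  names(fg) <- CHANNEL_NAMES
  if (nrow(truth)) {
    ord <- order(truth$object)
    for (i in ord) {
      cx <- truth$x_px[i] + 1; cy <- truth$y_px[i] + 1
      npx <- ellipse_pixels(cx, cy, truth$nucleus_area_um2[i] / px_area,
                            truth$width_to_length[i],
                            truth$orientation[i], shape)
      cpx <- ellipse_pixels(cx, cy, truth$cell_area_um2[i] / px_area,
                            truth$width_to_length[i],
                            truth$orientation[i], shape)
      dapi_level <- it$dapi_scale * stats::runif(1, 0.9, 1.1)
      edu_comp <- if (truth$edu_label[i] == 1L) it$edu_pos else it$edu_neg
      edu_level <- stats::rlnorm(1, edu_comp[["meanlog"]],
                                 edu_comp[["sdlog"]])
      cm_level <- it$cellmask_scale * stats::runif(1, 0.9, 1.1)
      if (nrow(npx)) {
        fg$dapi[npx] <- pmax(fg$dapi[npx], dapi_level)
        fg$edu488[npx] <- pmax(fg$edu488[npx], edu_level)
      }
      if (nrow(cpx)) {
        fg$cellmask647[cpx] <- pmax(fg$cellmask647[cpx], cm_level)
      }
    }
  }
  ch <- lapply(CHANNEL_NAMES, function(nm) {
    img <- it$background[[nm]] +
      matrix(stats::rnorm(prod(shape), 0, it$background_sd[[nm]]),
             shape[1], shape[2]) + fg[[nm]]
    img <- round(pmin(pmax(img, 0), 65535))
    if (nm == "brightfield") img <- pmax(img, 1)
    img
  })
  names(ch) <- CHANNEL_NAMES
  field_image(well, field, ch, params$pixel_size_um)
}

#' Sample EdU median intensities for one synthetic well
#'
#' Draws directly from the intensity model (background level plus the
#' negative or positive log-normal component) without rendering images;
#' used to study the EdU-positive fraction estimator at scale.
#'
#' @param params [simulation_params()]
#' @param n number of cells
#' @param fraction true positive fraction
#' @param seed integer seed
#' @return list with `values` (length n) and `labels` (0/1 truth)
#' @export
sample_edu_medians <- function(params, n, fraction, seed = 1L) {
  set.seed(seed)
  it <- params$intensity
  lab <- stats::rbinom(n, 1L, fraction)
  v <- ifelse(lab == 1L,
              stats::rlnorm(n, it$edu_pos[["meanlog"]],
                            it$edu_pos[["sdlog"]]),
              stats::rlnorm(n, it$edu_neg[["meanlog"]],
                            it$edu_neg[["sdlog"]]))
  list(values = it$background[["edu488"]] + v, labels = lab)
}

derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full plate
#'
#' For every assay well of the layout, samples the ground-truth
#' population and renders all fields. Per-well and per-field seeds are
#' derived deterministically from the master seed, so the whole plate is
#' a pure function of (layout, params, seed).
#'
#' @param layout [plate_layout()]; every condition must have a parameter
#'   block
#' @param params [simulation_params()]
#' @param seed master integer seed
#' @param output_dir if non-`NULL`, field images are written there as
#'   16-bit TIFFs following the `{well}_f{field}_{channel}.tif`
#'   convention, together with `ground_truth.csv` and `layout.csv`, and
#'   the returned `images` element holds file paths instead of in-memory
#'   images
#' @return list with `truth` (`ground_truth` tibble for the whole
#'   plate), `images` (named list `well_f<field>` of [field_image()]s,
#'   or of path vectors when writing to disk), `layout` and `params`
#' @export
simulate_plate <- function(layout, params = simulation_params(),
                           seed = 1L, output_dir = NULL) {
  missing_cond <- setdiff(layout$conditions, names(params$conditions))
  if (length(missing_cond)) {
    stop("no simulation parameters for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  aw <- layout$assay_wells
  well_seeds <- derive_seeds(seed, nrow(aw) * (params$n_fields + 1L))
  dim(well_seeds) <- c(nrow(aw), params$n_fields + 1L)
  truth_all <- list()
  images <- list()
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  for (i in seq_len(nrow(aw))) {
    w <- aw$well[i]
    tr <- sample_well_population(params, aw$condition[i],
                                 seed = well_seeds[i, 1L], well = w,
                                 plate = layout$plate_id)
    truth_all[[i]] <- tr
    for (fld in seq_len(params$n_fields)) {
      fi <- render_field(tr[tr$field == fld, , drop = FALSE], params,
                         seed = well_seeds[i, fld + 1L],
                         well = w, field = fld)
      key <- sprintf("%s_f%d", w, fld)
      if (is.null(output_dir)) {
        images[[key]] <- fi
      } else {
        paths <- vapply(CHANNEL_NAMES, function(chn) {
          p <- file.path(output_dir,
                         sprintf("%s_f%d_%s.tif", w, fld, chn))
          write_image_tiff(fi$channels[[chn]], p)
          p
        }, character(1))
        images[[key]] <- paths
      }
    }
  }
  truth <- do.call(rbind, truth_all)
  truth <- as_ground_truth(truth)
  if (!is.null(output_dir)) {
    write_table(truth, file.path(output_dir, "ground_truth.csv"))
    utils::write.csv(
      data.frame(well = aw$well, condition = aw$condition),
      file.path(output_dir, "layout.csv"), row.names = FALSE)
  }
  list(truth = truth, images = images, layout = layout, params = params)
}
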