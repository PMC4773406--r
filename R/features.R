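# Per-object phenotypic measurements.
#
# Nine features per cell: 6 morphology (area, roundness, width-to-length
# for nucleus and cell), 2 intensity (DAPI and EdU medians; brightfield is
# carried as a QC column) and 1 context feature (clump size, filled in by
# annotate_clump_size()). Roundness is the isoperimetric score 4*pi*A/P^2
# with the perimeter taken as the boundary chain length using
# Vossepoel-Smeulders weights (0.948 per isothetic step, 1.340 per
# diagonal step), which removes most of the rasterisation bias of naive
# pixel counting. Width-to-length is the minor/major axis ratio of the
# second-central-moment equivalent ellipse.

# clockwise Moore neighbourhood, rows = (dx, dy) starting west
MOORE_OFFSETS <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1,
                          0, 1, 1, 1, 1, 0, 1, -1),
                        ncol = 2, byrow = TRUE)

# boundary chain length of one object given its pixel coordinates
contour_perimeter <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(NA_real_)
  x0 <- min(px[, 1]) - 1L; y0 <- min(px[, 2]) - 1L
  m <- matrix(FALSE, max(px[, 1]) - x0 + 2L, max(px[, 2]) - y0 + 2L)
  m[cbind(px[, 1] - x0 + 1L, px[, 2] - y0 + 1L)] <- TRUE
  # start: leftmost column, topmost row; entered from the west
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 2], start[, 1]), , drop = FALSE][1, ]
  cur <- start
  back_dir <- 1L # index into MOORE_OFFSETS pointing at the backtrack pixel
  straight <- 0L; diagonal <- 0L
  first_move <- NA_integer_
  max_iter <- 4L * n + 8L
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    for (s in seq_len(8L)) {
      d <- ((back_dir - 1L + s) %% 8L) + 1L
      nxt <- cur + MOORE_OFFSETS[d, ]
      if (m[nxt[1], nxt[2]]) {
        if (d %% 2L == 1L) straight <- straight + 1L else diagonal <- diagonal + 1L
        # new backtrack: direction from the next pixel towards the last
        # background neighbour examined (the one just before d)
        prev <- ((d - 2L) %% 8L) + 1L
        bg <- cur + MOORE_OFFSETS[prev, ]
        rel <- bg - nxt
        back_dir <- which(MOORE_OFFSETS[, 1] == rel[1] &
                            MOORE_OFFSETS[, 2] == rel[2])
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found) return(NA_real_) # isolated pixel (cannot happen for n > 1)
    if (iter == 1L) first_move <- d
    if (iter > 1L && all(cur == start)) {
      # Jacob's criterion: stop when re-entering the start along the same
      # first move; checking one step ahead
      for (s in seq_len(8L)) {
        d2 <- ((back_dir - 1L + s) %% 8L) + 1L
        nxt2 <- cur + MOORE_OFFSETS[d2, ]
        if (m[nxt2[1], nxt2[2]]) break
      }
      if (d2 == first_move) break
    }
  }
  0.948 * straight + 1.340 * diagonal
}

object_pixel_list <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  nr <- nrow(lab)
  px <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
  split.data.frame(px, lab[idx])
}

#' Measure per-object morphology
#'
#' @param mask a `label_mask`
#' @param pixel_size_um micrometres per pixel
#' @return tibble with one row per label: `object`, `area_um2` (pixel
#'   count times the pixel area), `roundness` (4*pi*A/P^2, clipped to
#'   (0, 1]), `width_to_length` (minor/major equivalent-ellipse axis
#'   ratio, in (0, 1]) and `flagged` (single-pixel objects, for which
#'   roundness and width-to-length default to 1)
#' @export
measure_morphology <- function(mask, pixel_size_um = 0.65) {
  stopifnot(pixel_size_um > 0)
  objs <- object_pixel_list(mask$labels)
  if (!length(objs)) {
    return(tibble::tibble(object = integer(), area_um2 = numeric(),
                          roundness = numeric(), width_to_length = numeric(),
                          flagged = logical()))
  }
  ids <- as.integer(names(objs))
  res <- lapply(objs, function(px) {
    a_px <- nrow(px)
    if (a_px == 1L) {
      return(c(a_px, 1, 1, 1))
    }
    per <- contour_perimeter(px)
    rnd <- if (is.na(per) || per <= 0) 1 else min(1, 4 * pi * a_px / per^2)
    # second central moments with the 1/12 pixel-extent term
    cxx <- stats::var(px[, 1]) * (a_px - 1) / a_px + 1 / 12
    cyy <- stats::var(px[, 2]) * (a_px - 1) / a_px + 1 / 12
    cxy <- stats::cov(px[, 1], px[, 2]) * (a_px - 1) / a_px
    tr <- cxx + cyy
    det <- cxx * cyy - cxy^2
    disc <- sqrt(max(0, tr^2 / 4 - det))
    l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
    w2l <- if (l1 <= 0) 1 else min(1, sqrt(l2 / l1))
    c(a_px, rnd, max(w2l, .Machine$double.eps), 0)
  })
  res <- unname(do.call(rbind, res))
  tibble::tibble(object = ids,
                 area_um2 = res[, 1] * pixel_size_um^2,
                 roundness = res[, 2],
                 width_to_length = res[, 3],
                 flagged = res[, 4] > 0)[order(ids), ]
}

#' Measure per-object median intensity
#'
#' @param mask a `label_mask`
#' @param channel intensity matrix aligned with the mask
#' @return tibble with columns `object` and `median_intensity`
#' @export
measure_intensity <- function(mask, channel) {
  stopifnot(identical(dim(mask$labels), dim(channel)))
  idx <- which(mask$labels > 0L)
  if (!length(idx)) {
    return(tibble::tibble(object = integer(), median_intensity = numeric()))
  }
  med <- tapply(channel[idx], mask$labels[idx], stats::median)
  tibble::tibble(object = as.integer(names(med)),
                 median_intensity = as.numeric(med))
}

#' Assemble the per-object table for one field
#'
#' Joins nucleus and cell morphology with the three intensity medians
#' (measured on the nucleus region: DAPI and EdU are nuclear signals).
#' All rows start at `qc_stage = "nuclei"`; the filter cascade advances
#' them.
#'
#' @param nuclei nucleus `label_mask`
#' @param cells cell `label_mask` with labels corresponding one-to-one to
#'   the nuclei
#' @param channels named list of intensity matrices (`dapi`, `edu488`,
#'   `brightfield` are used)
#' @param metadata list with `plate`, `well`, `field`
#' @param pixel_size_um micrometres per pixel
#' @param intensity_region `"nucleus"` (default) or `"cell"`: region over
#'   which the intensity medians are taken
#' @return an `object_table` tibble
#' @export
build_object_table <- function(nuclei, cells, channels,
                               metadata = list(plate = "plate1",
                                               well = "B02", field = 1L),
                               pixel_size_um = 0.65,
                               intensity_region = c("nucleus", "cell")) {
  intensity_region <- match.arg(intensity_region)
  n_ids <- sort(unique(nuclei$labels[nuclei$labels > 0L]))
  c_ids <- sort(unique(cells$labels[cells$labels > 0L]))
  if (!identical(n_ids, c_ids)) {
    stop("nucleus/cell label correspondence violated: labels differ",
         call. = FALSE)
  }
  if (!length(n_ids)) return(empty_table("object_table"))
  # every nucleus pixel must carry its own cell label (containment)
  nuc_idx <- which(nuclei$labels > 0L)
  if (!all(cells$labels[nuc_idx] == nuclei$labels[nuc_idx])) {
    stop("nucleus/cell label correspondence violated: a cell region does ",
         "not contain its nucleus", call. = FALSE)
  }
  nm <- measure_morphology(nuclei, pixel_size_um)
  cm <- measure_morphology(cells, pixel_size_um)
  imask <- if (intensity_region == "nucleus") nuclei else cells
  med <- lapply(c("dapi", "edu488", "brightfield"), function(ch) {
    mi <- measure_intensity(imask, channels[[ch]])
    mi$median_intensity[match(nm$object, mi$object)]
  })
  df <- tibble::tibble(
    plate = metadata$plate, well = metadata$well,
    field = as.integer(metadata$field), object = nm$object,
    nucleus_area_um2 = nm$area_um2,
    nucleus_roundness = nm$roundness,
    nucleus_width_to_length = nm$width_to_length,
    cell_area_um2 = cm$area_um2,
    cell_roundness = cm$roundness,
    cell_width_to_length = cm$width_to_length,
    dapi_median = med[[1]], edu488_median = med[[2]],
    brightfield_median = med[[3]],
    n_per_clump = NA_integer_, qc_stage = "nuclei")
  as_object_table(df)
}
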