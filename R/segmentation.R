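# Nuclei and cell segmentation.
#
# The stages mirror a standard high-content workflow: flatfield correction,
# nuclei detection on the DAPI channel, nucleus-seeded cytoplasm detection
# on the membrane-stain channel, and border-object removal. The nucleus
# detector is an open algorithm honouring the three interpretable
# parameters instrument software exposes: an expected nucleus diameter
# (sets the smoothing scale and debris floor), a splitting coefficient
# (how aggressively touching nuclei are separated) and a common threshold
# (foreground level as a fraction of the robust intensity range).

#' Segmentation parameters
#'
#' @param nucleus_diameter_um expected nucleus diameter in micrometres;
#'   sets the smoothing scale and the debris floor (10% of the nominal
#'   nucleus area)
#' @param splitting_coefficient fraction of a component's maximum interior
#'   distance used as the watershed seed-suppression depth; larger values
#'   split touching nuclei less aggressively
#' @param common_threshold nuclei foreground threshold as a fraction of
#'   the robust intensity range (1st to 99th percentile) above background
#' @param cytoplasm_threshold membrane-stain foreground threshold, same
#'   construction
#' @param cell_smoothing_px Gaussian sigma (pixels) applied to the
#'   membrane channel before thresholding
#' @return a `segmentation_params` list
#' @export
segmentation_params <- function(nucleus_diameter_um = 18,
                                splitting_coefficient = 0.40,
                                common_threshold = 0.05,
                                cytoplasm_threshold = 0.05,
                                cell_smoothing_px = 1.5) {
  stopifnot(nucleus_diameter_um > 0, splitting_coefficient > 0,
            common_threshold > 0, common_threshold < 1,
            cytoplasm_threshold > 0, cytoplasm_threshold < 1,
            cell_smoothing_px > 0)
  structure(list(nucleus_diameter_um = nucleus_diameter_um,
                 splitting_coefficient = splitting_coefficient,
                 common_threshold = common_threshold,
                 cytoplasm_threshold = cytoplasm_threshold,
                 cell_smoothing_px = cell_smoothing_px),
            class = "segmentation_params")
}

label_mask <- function(labels, kind, provenance = list()) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind, provenance = provenance),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> kind=%s, %d object(s), %dx%d px\n",
              x$kind, max(x$labels), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Flatfield correction
#'
#' Divides out a smooth illumination surface estimated from the image
#' itself by heavy Gaussian blurring (at a scale far above the cell
#' diameter), then rescales so the output mean equals the input mean.
#'
#' @param image 2-D non-negative intensity matrix
#' @param sigma_px blur scale in pixels; default one eighth of the larger
#'   image dimension
#' @return corrected matrix, non-negative, same mean as the input
#' @export
flatfield_correct <- function(image, sigma_px = max(dim(image)) / 8) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (all(image == 0)) {
    warning("flatfield correction skipped: image is constant zero",
            call. = FALSE)
    return(image)
  }
  surf <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(image), sigma = sigma_px,
                   boundary = "replicate")))
  surf[surf <= 0] <- min(surf[surf > 0])
  out <- image / surf
  out <- out * (mean(image) / mean(out))
  pmax(out, 0)
}

robust_range <- function(v) {
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  q[2] - q[1]
}

# Detection threshold for a smoothed channel: background (median) plus
# the stated fraction of the robust signal range (here the 99.9th
# percentile minus the median, so the range tracks the object intensity
# level even when objects cover only a small fraction of the field).
# A noise floor of 6 robust SDs of the smoothed image keeps empty fields
# empty instead of thresholding into the noise.
detection_threshold <- function(sm, fraction) {
  v <- as.numeric(sm)
  bg <- stats::median(v)
  rng <- stats::quantile(v, 0.999, names = FALSE) - bg
  bg + max(fraction * rng, 6 * stats::mad(v))
}

# Shrink each foreground component to its half-maximum contour. Gaussian
# blur moves a step edge's half-maximum very little, so the refined
# region tracks the true object outline instead of the blur halo.
halfmax_refine <- function(sm, fg, bg) {
  comps <- bwlabel8(fg)
  n <- max(comps)
  if (n == 0L) return(fg)
  idx <- which(comps > 0L)
  peak <- vapply(split(sm[idx], comps[idx]), max, numeric(1))
  peak <- peak[order(as.integer(names(peak)))]
  keep <- sm[idx] >= bg + 0.5 * (peak[comps[idx]] - bg)
  out <- matrix(FALSE, nrow(fg), ncol(fg))
  out[idx[keep]] <- TRUE
  out
}

# merge 4-connected components that touch diagonally -> 8-connected labels
bwlabel8 <- function(fg) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n < 2L) return(lab)
  pairs <- adjacent_label_pairs(lab, max_chebyshev = 1L)
  if (nrow(pairs)) {
    comp <- union_find_components(n, pairs)
    lab[lab > 0L] <- comp[lab[lab > 0L]]
  }
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# label pairs whose pixels come within a Chebyshev distance; used both for
# 8-connectivity merging (distance 1) and clump adjacency (distance 2)
adjacent_label_pairs <- function(lab, max_chebyshev = 1L) {
  nr <- nrow(lab); nc <- ncol(lab)
  offs <- expand.grid(dx = 0:max_chebyshev, dy = -max_chebyshev:max_chebyshev)
  offs <- offs[!(offs$dx == 0 & offs$dy <= 0), , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    xr <- seq_len(nr - dx)
    yr <- if (dy >= 0) seq_len(nc - dy) else seq(1 - dy, nc)
    a <- lab[xr, yr, drop = FALSE]
    b <- lab[xr + dx, yr + dy, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      acc[[length(acc) + 1L]] <- cbind(pmin(a[sel], b[sel]),
                                       pmax(a[sel], b[sel]))
    }
  }
  if (!length(acc)) return(matrix(integer(), 0L, 2L))
  unique(do.call(rbind, acc))
}

union_find_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing at a scale derived from the expected nucleus
#' diameter, foreground thresholding at background plus
#' `common_threshold` times the robust (1st-99th percentile) intensity
#' range, then a distance-transform watershed whose seed-suppression
#' depth is `splitting_coefficient` times the maximum interior distance
#' of each connected component. Components smaller than 10% of the
#' nominal nucleus area are discarded as debris.
#'
#' @param dapi corrected DAPI intensity matrix
#' @param params [segmentation_params()]
#' @param pixel_size_um micrometres per pixel
#' @return a `label_mask` of kind `"nucleus"` with consecutive labels
#' @export
segment_nuclei <- function(dapi, params = segmentation_params(),
                           pixel_size_um = 0.65) {
  stopifnot(pixel_size_um > 0)
  diam_px <- params$nucleus_diameter_um / pixel_size_um
  sigma <- diam_px / 8
  sm <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(dapi), sigma = sigma)))
  thr <- detection_threshold(sm, params$common_threshold)
  fg <- sm > thr
  if (any(fg)) fg <- halfmax_refine(sm, fg, stats::median(as.numeric(sm)))
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  if (any(fg)) {
    comps <- bwlabel8(fg)
    nxt <- 0L
    for (k in seq_len(max(comps))) {
      idx <- which(comps == k, arr.ind = TRUE)
      x0 <- max(1L, min(idx[, 1]) - 1L); x1 <- min(nrow(fg), max(idx[, 1]) + 1L)
      y0 <- max(1L, min(idx[, 2]) - 1L); y1 <- min(ncol(fg), max(idx[, 2]) + 1L)
      loc <- comps[x0:x1, y0:y1, drop = FALSE] == k
      dm <- EBImage::distmap(EBImage::Image(loc * 1))
      tol <- params$splitting_coefficient * max(dm)
      ws <- as.matrix(EBImage::imageData(
        EBImage::watershed(dm, tolerance = tol, ext = 1L)))
      sel <- ws > 0
      out[x0:x1, y0:y1][sel] <- nxt + ws[sel]
      nxt <- nxt + max(ws)
    }
    # debris floor: 10% of the nominal nucleus area
    floor_px <- 0.10 * pi * (diam_px / 2)^2
    sizes <- tabulate(out, nbins = max(out))
    drop <- which(sizes < floor_px)
    if (length(drop)) out[out %in% drop] <- 0L
    out <- relabel_consecutive(out)
  }
  label_mask(out, "nucleus",
             provenance = list(params = params,
                               pixel_size_um = pixel_size_um,
                               threshold = thr))
}

#' Segment cells around nuclei from a membrane-stain image
#'
#' Seeded region growing: the membrane-stain foreground (background plus
#' `cytoplasm_threshold` times the robust range) is partitioned among the
#' nucleus seeds by [EBImage::propagate()], guaranteeing one cell per
#' nucleus with the cell region containing its nucleus. Nuclei whose cell
#' did not grow beyond the nucleus itself (no surrounding foreground) are
#' flagged in the provenance.
#'
#' @param cellmask corrected membrane-stain intensity matrix
#' @param nuclei nucleus `label_mask` aligned with `cellmask`
#' @param params [segmentation_params()]
#' @return a `label_mask` of kind `"cell"`; labels match the nucleus
#'   labels one-to-one
#' @export
segment_cells <- function(cellmask, nuclei,
                          params = segmentation_params()) {
  stopifnot(identical(dim(cellmask), dim(nuclei$labels)))
  sm <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(cellmask),
                   sigma = params$cell_smoothing_px)))
  thr <- detection_threshold(sm, params$cytoplasm_threshold)
  fg <- sm > thr
  if (any(fg)) fg <- halfmax_refine(sm, fg, stats::median(as.numeric(sm)))
  fg <- fg | nuclei$labels > 0L
  cells <- as.matrix(EBImage::imageData(EBImage::propagate(
    EBImage::Image(sm), seeds = EBImage::Image(nuclei$labels), mask = fg)))
  storage.mode(cells) <- "integer"
  n <- max(nuclei$labels)
  cell_sizes <- tabulate(cells, nbins = n)
  nuc_sizes <- tabulate(nuclei$labels, nbins = n)
  flagged <- which(cell_sizes <= nuc_sizes)
  label_mask(cells, "cell",
             provenance = list(params = params, threshold = thr,
                               flagged_no_cytoplasm = flagged))
}

#' Labels touching the image border
#'
#' @param mask a `label_mask`
#' @return integer vector of labels with at least one pixel on row 1, the
#'   last row, column 1 or the last column
#' @export
border_labels <- function(mask) {
  lab <- mask$labels
  edge <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  sort(unique(edge[edge > 0L]))
}

#' Remove objects touching the image border
#'
#' Deletes every label whose region touches the field edge (cells cut by
#' the field of view would otherwise bias morphology), relabels the
#' survivors consecutively and records the removal in the provenance.
#'
#' @param mask a `label_mask`
#' @return a `label_mask` with `provenance$removed_border` (original
#'   labels removed) and `provenance$id_map` (new label -> original label)
#' @export
remove_border_objects <- function(mask) {
  drop <- border_labels(mask)
  lab <- mask$labels
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- setdiff(sort(unique(mask$labels[mask$labels > 0L])), drop)
  lab <- relabel_consecutive(lab)
  prov <- mask$provenance
  prov$removed_border <- drop
  prov$id_map <- keep # position = new label, value = original label
  label_mask(lab, mask$kind, prov)
}

# zero out all labels not in keep; labels retain their original ids
restrict_mask <- function(mask, keep) {
  lab <- mask$labels
  lab[!(lab %in% keep)] <- 0L
  label_mask(lab, mask$kind, mask$provenance)
}
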