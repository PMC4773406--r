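# End-to-end drivers: field image -> object/clump tables -> well
# summaries.

#' Process one field image
#'
#' Flatfield-corrects the DAPI and membrane channels, segments nuclei
#' and cells, runs the object-filter cascade, detects clumps among the
#' retained cells and tags each cell with its clump size.
#'
#' @param fi a [field_image()]
#' @param seg [segmentation_params()]
#' @param thresholds [filter_thresholds()]
#' @param plate plate identifier for the output tables
#' @param flatfield apply flatfield correction (disable for synthetic
#'   images with no shading to save time)
#' @return list with `objects` (annotated `object_table` at stage
#'   `"cell"`), `clumps` (`clump_table`) and `counts` (per-stage object
#'   counts)
#' @export
process_field <- function(fi, seg = segmentation_params(),
                          thresholds = filter_thresholds(),
                          plate = "plate1", flatfield = TRUE) {
  dapi <- fi$channels$dapi
  cm <- fi$channels$cellmask647
  if (flatfield) {
    dapi <- flatfield_correct(dapi)
    cm <- flatfield_correct(cm)
  }
  nuclei <- segment_nuclei(dapi, seg, fi$pixel_size_um)
  cells <- segment_cells(cm, nuclei, seg)
  meta <- list(plate = plate, well = fi$well, field = fi$field)
  casc <- run_cascade(nuclei, cells,
                      channels = list(dapi = dapi,
                                      edu488 = fi$channels$edu488,
                                      brightfield = fi$channels$brightfield),
                      t = thresholds, metadata = meta,
                      pixel_size_um = fi$pixel_size_um)
  clumps <- detect_clumps(cells, keep = casc$final_ids, metadata = meta)
  objects <- annotate_clump_size(casc$table, clumps)
  list(objects = objects, clumps = clumps, counts = casc$counts)
}

#' Process a set of field images into plate-level tables
#'
#' @param images named list of [field_image()]s (e.g. the `images`
#'   element of [simulate_plate()]), or a reference tibble from
#'   [discover_images()] whose rows are read on demand
#' @param layout [plate_layout()]
#' @param seg [segmentation_params()]
#' @param thresholds [filter_thresholds()]
#' @param flatfield apply flatfield correction per field
#' @param ... passed to [summarise_wells()]
#' @return list with `objects`, `clumps`, `summaries` (one row per assay
#'   well) and `counts` (summed per-stage object counts)
#' @export
process_plate <- function(images, layout, seg = segmentation_params(),
                          thresholds = filter_thresholds(),
                          flatfield = TRUE, ...) {
  if (is.data.frame(images)) {
    refs <- images
    images <- lapply(seq_len(nrow(refs)), function(i) {
      read_field_image(refs[i, , drop = FALSE])
    })
  }
  res <- lapply(images, process_field, seg = seg,
                thresholds = thresholds, plate = layout$plate_id,
                flatfield = flatfield)
  objects <- do.call(rbind, lapply(res, `[[`, "objects"))
  clumps <- do.call(rbind, lapply(res, `[[`, "clumps"))
  counts <- Reduce(`+`, lapply(res, `[[`, "counts"))
  summaries <- summarise_wells(objects, clumps, layout, ...)
  list(objects = objects, clumps = clumps, summaries = summaries,
       counts = counts)
}
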