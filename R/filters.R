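# Object-selection cascade: Nuclei -> Nuclei 2 -> Cell unselected -> Cell.
#
# Boundary semantics follow the assay protocol wording: "between a and b"
# is the closed interval [a, b]; "below x" and "over x" are strict. The
# cell-area ceiling removes the rare oversized feeder-cell contaminants
# (mouse embryonic fibroblasts carried over from maintenance culture).

#' Object-filter thresholds
#'
#' @param nucleus_area_min,nucleus_area_max nucleus area window
#'   (micrometres squared), closed interval
#' @param edu_median_max EdU median intensity ceiling (strict, AU)
#' @param dapi_median_min,dapi_median_max DAPI median window (closed, AU)
#' @param brightfield_min brightfield median floor (strict, AU)
#' @param cell_area_max cell area ceiling (strict, micrometres squared);
#'   removes oversized feeder contaminants
#' @param strict if `FALSE`, the strict comparisons become non-strict
#' @return a `filter_thresholds` list
#' @export
filter_thresholds <- function(nucleus_area_min = 60,
                              nucleus_area_max = 600,
                              edu_median_max = 10000,
                              dapi_median_min = 500,
                              dapi_median_max = 10000,
                              brightfield_min = 0,
                              cell_area_max = 6000,
                              strict = TRUE) {
  stopifnot(nucleus_area_min < nucleus_area_max,
            dapi_median_min < dapi_median_max,
            is.finite(c(nucleus_area_min, nucleus_area_max, edu_median_max,
                        dapi_median_min, dapi_median_max, brightfield_min,
                        cell_area_max)))
  structure(list(nucleus_area_min = nucleus_area_min,
                 nucleus_area_max = nucleus_area_max,
                 edu_median_max = edu_median_max,
                 dapi_median_min = dapi_median_min,
                 dapi_median_max = dapi_median_max,
                 brightfield_min = brightfield_min,
                 cell_area_max = cell_area_max,
                 strict = strict),
            class = "filter_thresholds")
}

lt <- function(x, y, strict) if (strict) x < y else x <= y
gt <- function(x, y, strict) if (strict) x > y else x >= y

#' Nuclei quality filter (stage "nuclei" -> "nuclei2")
#'
#' Keeps objects with nucleus area inside the closed window, EdU median
#' strictly below the ceiling, DAPI median inside the closed window and
#' brightfield median strictly above the floor. Removal reasons are
#' recorded per criterion in the `removed` attribute.
#'
#' @param table an `object_table` at stage `"nuclei"`
#' @param t [filter_thresholds()]
#' @return the surviving rows at stage `"nuclei2"`; attribute `removed`
#'   is a tibble of removed rows with a `reason` column
#' @export
select_nuclei2 <- function(table, t = filter_thresholds()) {
  stopifnot(all(table$qc_stage == "nuclei"))
  s <- t$strict
  ok_area <- table$nucleus_area_um2 >= t$nucleus_area_min &
    table$nucleus_area_um2 <= t$nucleus_area_max
  ok_edu <- lt(table$edu488_median, t$edu_median_max, s)
  ok_dapi <- table$dapi_median >= t$dapi_median_min &
    table$dapi_median <= t$dapi_median_max
  ok_bf <- gt(table$brightfield_median, t$brightfield_min, s)
  keep <- ok_area & ok_edu & ok_dapi & ok_bf
  reason <- vapply(seq_len(nrow(table)), function(i) {
    paste(c("nucleus_area", "edu_median", "dapi_median",
            "brightfield")[!c(ok_area[i], ok_edu[i], ok_dapi[i], ok_bf[i])],
          collapse = ";")
  }, character(1))
  out <- table[keep, , drop = FALSE]
  out$qc_stage <- rep("nuclei2", nrow(out))
  removed <- table[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  attr(out, "removed") <- removed
  out
}

#' Cell-area filter (stage "cell_unselected" -> "cell")
#'
#' Keeps objects with cell area strictly below the ceiling; the removed
#' tail is where oversized feeder contaminants end up.
#'
#' @param table an `object_table` at stage `"cell_unselected"`
#' @param t [filter_thresholds()]
#' @return surviving rows at stage `"cell"`; attribute `removed` holds
#'   the removed rows with reasons
#' @export
select_cells <- function(table, t = filter_thresholds()) {
  stopifnot(all(table$qc_stage == "cell_unselected"))
  keep <- lt(table$cell_area_um2, t$cell_area_max, t$strict)
  out <- table[keep, , drop = FALSE]
  out$qc_stage <- rep("cell", nrow(out))
  removed <- table[!keep, , drop = FALSE]
  removed$reason <- rep("cell_area", nrow(removed))
  attr(out, "removed") <- removed
  out
}

#' Run the full object-selection cascade on one field
#'
#' Composes [build_object_table()], [select_nuclei2()], border-object
#' removal (on the cell region) and [select_cells()], returning the final
#' `"cell"` population together with the per-stage counts.
#'
#' @param nuclei nucleus `label_mask`
#' @param cells matching cell `label_mask`
#' @param channels named list of intensity matrices
#' @param t [filter_thresholds()]
#' @param metadata list with `plate`, `well`, `field`
#' @param pixel_size_um micrometres per pixel
#' @return list with `table` (final `object_table`, stage `"cell"`),
#'   `counts` (named vector: nuclei, nuclei2, cell_unselected, cell),
#'   `removed` (rows removed at any stage, with reasons) and `final_ids`
#'   (mask labels of the retained cells)
#' @export
run_cascade <- function(nuclei, cells, channels, t = filter_thresholds(),
                        metadata = list(plate = "plate1", well = "B02",
                                        field = 1L),
                        pixel_size_um = 0.65) {
  tab <- build_object_table(nuclei, cells, channels, metadata,
                            pixel_size_um)
  n0 <- nrow(tab)
  tab2 <- select_nuclei2(tab, t)
  rm1 <- attr(tab2, "removed")
  n1 <- nrow(tab2)
  border <- border_labels(cells)
  on_border <- tab2$object %in% border
  rm2 <- tab2[on_border, , drop = FALSE]
  if (nrow(rm2)) rm2$reason <- "border"
  tab3 <- tab2[!on_border, , drop = FALSE]
  tab3$qc_stage <- rep("cell_unselected", nrow(tab3))
  n2 <- nrow(tab3)
  tab4 <- select_cells(tab3, t)
  rm3 <- attr(tab4, "removed")
  n3 <- nrow(tab4)
  removed <- rbind(rm1, rm2, rm3)
  attr(tab4, "removed") <- NULL
  list(table = tab4,
       counts = c(nuclei = n0, nuclei2 = n1, cell_unselected = n2,
                  cell = n3),
       removed = removed,
       final_ids = tab4$object)
}
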