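# Clump detection and the per-cell context feature.
#
# Two retained cells belong to one clump when their regions are adjacent
# at distance 0. Because seeded region growing can leave a one-pixel
# separation line between touching cells, adjacency is evaluated on the
# regions dilated by one pixel (equivalently: two labels are adjacent
# when any pair of their pixels is within Chebyshev distance 2). Clumps
# are the connected components of this region-adjacency graph; a single
# cell is a clump of size 1.

#' Detect clumps on a cell mask
#'
#' @param cells cell `label_mask`; labels must correspond to the final
#'   `"cell"` population
#' @param keep optional integer vector of labels to restrict to (labels
#'   filtered out by the cascade are ignored); default: all labels
#' @param metadata list with `plate`, `well`, `field`
#' @return a `clump_table` tibble: one row per clump with its size and a
#'   `;`-separated member id list; every retained cell appears in exactly
#'   one clump
#' @export
detect_clumps <- function(cells, keep = NULL,
                          metadata = list(plate = "plate1", well = "B02",
                                          field = 1L)) {
  lab <- cells$labels
  ids <- sort(unique(lab[lab > 0L]))
  if (!is.null(keep)) {
    ids <- intersect(ids, as.integer(keep))
    lab[!(lab %in% ids)] <- 0L
  }
  if (!length(ids)) return(empty_table("clump_table"))
  pairs <- adjacent_label_pairs(lab, max_chebyshev = 2L)
  # map original labels to 1..n for the union-find, then back
  pr <- cbind(match(pairs[, 1], ids), match(pairs[, 2], ids))
  comp <- union_find_components(length(ids), pr)
  rows <- lapply(sort(unique(comp)), function(k) {
    members <- ids[comp == k]
    tibble::tibble(plate = metadata$plate, well = metadata$well,
                   field = as.integer(metadata$field), clump = k,
                   clump_size = length(members),
                   members = paste(members, collapse = ";"))
  })
  as_clump_table(do.call(rbind, rows))
}

clump_members <- function(clumps) {
  lapply(strsplit(clumps$members, ";", fixed = TRUE), as.integer)
}

#' Tag each cell with the size of its clump
#'
#' Fills the context feature `n_per_clump` for every row of the object
#' table; rows with `n_per_clump == 1` form the single-cell population.
#'
#' @param table an `object_table` (stage `"cell"`)
#' @param clumps the matching `clump_table`
#' @return the object table with `n_per_clump` filled
#' @export
annotate_clump_size <- function(table, clumps) {
  if (nrow(table) == 0L) return(table)
  key_t <- paste(table$well, table$field, table$object)
  mem <- clump_members(clumps)
  key_c <- unlist(lapply(seq_len(nrow(clumps)), function(i) {
    paste(clumps$well[i], clumps$field[i], mem[[i]])
  }))
  size_c <- unlist(lapply(seq_len(nrow(clumps)), function(i) {
    rep(clumps$clump_size[i], length(mem[[i]]))
  }))
  if (anyDuplicated(key_c)) {
    stop("integrity error: an object appears in more than one clump",
         call. = FALSE)
  }
  idx <- match(key_t, key_c)
  if (anyNA(idx)) {
    stop("integrity error: object(s) missing from the clump table: ",
         paste(utils::head(key_t[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  table$n_per_clump <- as.integer(size_c[idx])
  table
}

#' Clump-size histogram for one well
#'
#' @param clumps a `clump_table`
#' @param well well name (default: all rows)
#' @return named integer vector: count of clumps per size; zero-count
#'   sizes omitted; the total equals the number of clumps
#' @export
clump_size_histogram <- function(clumps, well = NULL) {
  sizes <- if (is.null(well)) clumps$clump_size else
    clumps$clump_size[clumps$well == well]
  if (!length(sizes)) return(setNames(integer(0), character(0)))
  tb <- table(sizes)
  setNames(as.integer(tb), names(tb))
}
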