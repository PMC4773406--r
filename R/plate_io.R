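# Plate layout parsing/validation, image discovery and tabular IO.
#
# Conventions: 96-well plates, well names "A01".."H12" (letter row +
# zero-padded column). Border wells (row A, row H, column 01, column 12)
# are never assayed: they are reserved to buffer edge effects, leaving the
# 60 interior wells assignable. Images are single-plane grayscale 16-bit
# TIFFs, one file per channel, four channels per field.

WELL_ROWS <- LETTERS[1:8]
WELL_COLS <- sprintf("%02d", 1:12)

#' All 96 well names of a standard plate
#' @return character vector of length 96, row-major ("A01".."H12")
#' @export
all_wells <- function() {
  as.vector(t(outer(WELL_ROWS, WELL_COLS, paste0)))
}

#' Border wells of a 96-well plate
#'
#' Row A, row H, column 01 and column 12; these wells buffer evaporation
#' and temperature edge effects and must not carry an assay condition.
#' @return character vector of 36 well names
#' @export
border_wells <- function() {
  w <- all_wells()
  w[substr(w, 1, 1) %in% c("A", "H") | substr(w, 2, 3) %in% c("01", "12")]
}

#' Interior (assignable) wells of a 96-well plate
#' @return character vector of 60 well names
#' @export
interior_wells <- function() {
  setdiff(all_wells(), border_wells())
}

is_valid_well <- function(x) {
  grepl("^[A-H](0[1-9]|1[0-2])$", x)
}

#' Construct a validated plate layout
#'
#' @param wells data frame with columns `well` and `condition`. Wells not
#'   listed, and wells with condition `NA` or `""`, are treated as
#'   `"unused"`.
#' @param plate_id plate identifier carried into downstream tables.
#' @return a `plate_layout` object: list with `plate_id`, `wells` (named
#'   character vector over all 96 wells), `conditions` (assay condition
#'   labels) and `assay_wells` (tibble of well/condition pairs).
#' @details Border wells carrying a condition are rejected. Conditions
#'   present in fewer than 3 wells (below a technical triplicate) trigger
#'   a warning, as replicate-level statistics become unreliable.
#' @export
plate_layout <- function(wells, plate_id = "plate1") {
  stopifnot(is.data.frame(wells))
  if (!all(c("well", "condition") %in% names(wells))) {
    stop("layout table must have columns 'well' and 'condition'", call. = FALSE)
  }
  wells$condition <- as.character(wells$condition)
  wells$condition[is.na(wells$condition) | wells$condition == ""] <- "unused"
  bad <- !is_valid_well(wells$well)
  if (any(bad)) {
    stop(sprintf("malformed well name(s) in layout row(s) %s: %s",
                 paste(which(bad), collapse = ", "),
                 paste(unique(wells$well[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(wells$well)) {
    stop("duplicated well assignment in layout: ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "),
         call. = FALSE)
  }
  assign <- setNames(rep("unused", 96L), all_wells())
  assign[wells$well] <- wells$condition
  border_used <- intersect(names(assign)[assign != "unused"], border_wells())
  if (length(border_used)) {
    stop(sprintf(paste0("border well(s) %s carry a condition; border wells ",
                        "must stay unused to buffer edge effects"),
                 paste(border_used, collapse = ", ")),
         call. = FALSE)
  }
  assay <- assign[assign != "unused"]
  conditions <- sort(unique(assay))
  if (length(assay) == 0L) {
    warning("layout assigns no assay wells (empty layout)", call. = FALSE)
  }
  n_per <- table(assay)
  thin <- names(n_per)[n_per < 3]
  if (length(thin)) {
    warning("condition(s) below technical triplicate (<3 wells): ",
            paste(thin, collapse = ", "), call. = FALSE)
  }
  structure(
    list(plate_id = plate_id,
         wells = assign,
         conditions = conditions,
         assay_wells = tibble::tibble(well = names(assay),
                                      condition = unname(assay))),
    class = "plate_layout")
}

#' Load a plate layout from a CSV file
#'
#' The file must contain a header `well,condition`; every row maps one well
#' to a substrate condition label (e.g. `Fn1`, `Fn5`, `Fn25`) or `unused`.
#' @param path path to the CSV file
#' @param plate_id plate identifier (defaults to the file name without
#'   extension)
#' @return a validated [plate_layout()]
#' @export
load_plate_layout <- function(path, plate_id = NULL) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  plate_layout(df, plate_id = plate_id)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("<plate_layout> ", x$plate_id, ": ",
      nrow(x$assay_wells), " assay wells, conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Random column-block plate layout
#'
#' Lays conditions out the way gradient assays are plated in practice:
#' within each plate column, blocks of three consecutive interior rows
#' receive the three conditions in a randomly permuted order, so that each
#' triplet carries one technical replicate per condition and row/column
#' position biases average out across triplets.
#'
#' @param conditions condition labels (must be 3 for the triplet scheme)
#' @param wells_per_condition replicate wells per condition (= number of
#'   triplets laid out); at most 20 on a 96-well plate
#' @param seed integer seed for the per-column permutations
#' @param plate_id plate identifier
#' @return a [plate_layout()]
#' @export
random_plate_layout <- function(conditions = c("Fn1", "Fn5", "Fn25"),
                                wells_per_condition = 6L,
                                seed = 1L, plate_id = "plate1") {
  stopifnot(length(conditions) == 3L, wells_per_condition >= 1L,
            wells_per_condition <= 20L)
  set.seed(seed)
  blocks <- list(c("B", "C", "D"), c("E", "F", "G"))
  slots <- expand.grid(block = 1:2, col = sprintf("%02d", 2:11),
                       stringsAsFactors = FALSE)
  rows <- NULL
  for (i in seq_len(wells_per_condition)) {
    rws <- blocks[[slots$block[i]]]
    perm <- sample(conditions)
    rows <- rbind(rows, data.frame(well = paste0(rws, slots$col[i]),
                                   condition = perm,
                                   stringsAsFactors = FALSE))
  }
  plate_layout(rows, plate_id = plate_id)
}

# ---- field images -----------------------------------------------------------

#' Construct a field image
#'
#' One field of view: four co-registered single-plane intensity arrays
#' (DAPI, EdU/488, membrane stain/647, brightfield) plus the isotropic
#' pixel size in micrometres.
#'
#' @param well well name
#' @param field field index within the well (1..9)
#' @param channels named list of four numeric matrices of identical
#'   dimensions, names `dapi`, `edu488`, `cellmask647`, `brightfield`;
#'   intensities must be non-negative
#' @param pixel_size_um micrometres per pixel (> 0)
#' @return a `field_image` object
#' @export
field_image <- function(well, field, channels, pixel_size_um) {
  if (!setequal(names(channels), CHANNEL_NAMES)) {
    stop("channels must be named exactly: ",
         paste(CHANNEL_NAMES, collapse = ", "), call. = FALSE)
  }
  channels <- channels[CHANNEL_NAMES]
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all four channels must share identical dimensions", call. = FALSE)
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0)
  structure(list(well = well, field = as.integer(field),
                 channels = channels, pixel_size_um = pixel_size_um),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> well %s field %d, %dx%d px, %.3g um/px\n",
              x$well, x$field, d[1], d[2], x$pixel_size_um))
  invisible(x)
}

naming_to_regex <- function(naming) {
  # swap placeholders for sentinels, regex-escape the literal part, then
  # substitute the capture groups
  rx <- naming
  rx <- sub("{well}", "\001W\001", rx, fixed = TRUE)
  rx <- sub("{field}", "\001F\001", rx, fixed = TRUE)
  rx <- sub("{channel}", "\001C\001", rx, fixed = TRUE)
  rx <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", rx)
  rx <- sub("\001W\001", "([A-H][0-9]{2})", rx, fixed = TRUE)
  rx <- sub("\001F\001", "([0-9]+)", rx, fixed = TRUE)
  rx <- sub("\001C\001", "([A-Za-z0-9]+)", rx, fixed = TRUE)
  paste0("^", rx, "$")
}

naming_groups <- function(naming) {
  pos <- c(well = regexpr("{well}", naming, fixed = TRUE),
           field = regexpr("{field}", naming, fixed = TRUE),
           channel = regexpr("{channel}", naming, fixed = TRUE))
  if (any(pos < 0)) {
    stop("naming pattern must contain {well}, {field} and {channel}",
         call. = FALSE)
  }
  rank(pos)
}

#' Discover field images below a directory
#'
#' Scans `root` for files matching the naming convention and groups them
#' into fields. A field is usable only when all four channels are present;
#' incomplete fields are reported in the `diagnostics` attribute rather
#' than silently dropped. Files whose names do not parse are skipped with
#' a warning.
#'
#' @param root directory containing the image files
#' @param naming filename template with `{well}`, `{field}` and
#'   `{channel}` placeholders
#' @param pixel_size_um pixel size recorded on the returned references
#' @return tibble with one row per complete field (columns `well`,
#'   `field`, one path column per channel, `pixel_size_um`); attribute
#'   `diagnostics` lists incomplete fields and their missing channels
#' @export
discover_images <- function(root, naming = "{well}_f{field}_{channel}.tif",
                            pixel_size_um = 0.65) {
  if (!dir.exists(root)) stop("directory not found: ", root, call. = FALSE)
  files <- list.files(root)
  rx <- naming_to_regex(naming)
  ord <- naming_groups(naming)
  m <- regmatches(files, regexec(rx, files))
  parsed <- lengths(m) == 4L
  unparsed <- files[!parsed & grepl("\\.tiff?$", files, ignore.case = TRUE)]
  if (length(unparsed)) {
    warning("skipping ", length(unparsed), " file(s) not matching the ",
            "naming convention: ", paste(utils::head(unparsed, 5),
                                         collapse = ", "), call. = FALSE)
  }
  if (!any(parsed)) {
    out <- tibble::tibble(well = character(), field = integer(),
                          dapi = character(), edu488 = character(),
                          cellmask647 = character(),
                          brightfield = character(),
                          pixel_size_um = numeric())
    attr(out, "diagnostics") <- tibble::tibble(well = character(),
                                               field = integer(),
                                               missing = character())
    return(out)
  }
  g <- do.call(rbind, lapply(m[parsed], function(x) x[-1]))
  df <- data.frame(file = files[parsed],
                   well = g[, ord["well"]],
                   field = as.integer(g[, ord["field"]]),
                   channel = g[, ord["channel"]],
                   stringsAsFactors = FALSE)
  bad_chan <- !df$channel %in% CHANNEL_NAMES
  if (any(bad_chan)) {
    warning("skipping file(s) with unknown channel name: ",
            paste(utils::head(df$file[bad_chan], 5), collapse = ", "),
            call. = FALSE)
    df <- df[!bad_chan, , drop = FALSE]
  }
  keys <- unique(df[c("well", "field")])
  keys <- keys[order(keys$well, keys$field), , drop = FALSE]
  rows <- vector("list", nrow(keys))
  diags <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$well == keys$well[i] & df$field == keys$field[i], ]
    have <- setNames(rep(NA_character_, 4L), CHANNEL_NAMES)
    have[sub$channel] <- file.path(root, sub$file)
    if (anyNA(have)) {
      diags[[length(diags) + 1L]] <- tibble::tibble(
        well = keys$well[i], field = keys$field[i],
        missing = paste(CHANNEL_NAMES[is.na(have)], collapse = ";"))
    } else {
      rows[[i]] <- tibble::tibble(well = keys$well[i], field = keys$field[i],
                                  dapi = have[["dapi"]],
                                  edu488 = have[["edu488"]],
                                  cellmask647 = have[["cellmask647"]],
                                  brightfield = have[["brightfield"]],
                                  pixel_size_um = pixel_size_um)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble::tibble(well = character(), field = integer(),
                          dapi = character(), edu488 = character(),
                          cellmask647 = character(), brightfield = character(),
                          pixel_size_um = numeric())
  }
  attr(out, "diagnostics") <-
    if (length(diags)) do.call(rbind, diags) else
      tibble::tibble(well = character(), field = integer(),
                     missing = character())
  out
}

#' Read one field image from TIFF files
#'
#' @param ref one row of the tibble returned by [discover_images()]
#' @return a [field_image()]
#' @export
read_field_image <- function(ref) {
  stopifnot(nrow(ref) == 1L)
  ch <- lapply(ref[CHANNEL_NAMES], function(p) read_image_tiff(p))
  field_image(ref$well, ref$field, ch, ref$pixel_size_um)
}

read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}

write_image_tiff <- function(mat, path) {
  tiff::writeTIFF(pmin(pmax(mat, 0), 65535) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# ---- tabular IO -------------------------------------------------------------

OBJECT_FEATURES <- c("nucleus_area_um2", "nucleus_roundness",
                     "nucleus_width_to_length", "cell_area_um2",
                     "cell_roundness", "cell_width_to_length",
                     "dapi_median", "edu488_median")

well_summary_stat_cols <- function() {
  base <- as.vector(t(outer(c("", "single_"), OBJECT_FEATURES, paste0)))
  as.vector(t(outer(base, c("_mean", "_sd"), paste0)))
}

table_schemas <- function() {
  list(
    object_table = c(plate = "character", well = "character",
                     field = "integer", object = "integer",
                     nucleus_area_um2 = "numeric",
                     nucleus_roundness = "numeric",
                     nucleus_width_to_length = "numeric",
                     cell_area_um2 = "numeric", cell_roundness = "numeric",
                     cell_width_to_length = "numeric",
                     dapi_median = "numeric", edu488_median = "numeric",
                     brightfield_median = "numeric",
                     n_per_clump = "integer", qc_stage = "character"),
    clump_table = c(plate = "character", well = "character",
                    field = "integer", clump = "integer",
                    clump_size = "integer", members = "character"),
    well_summary = c(
      c(plate = "character", well = "character", condition = "character",
        cell_count = "integer", n_clumps = "integer",
        edu_positive_fraction = "numeric", fraction_single = "numeric",
        inverse_mean_clump_size = "numeric"),
      setNames(rep("numeric", length(well_summary_stat_cols())),
               well_summary_stat_cols())),
    ground_truth = c(plate = "character", well = "character",
                     field = "integer", object = "integer",
                     x_px = "numeric", y_px = "numeric",
                     nucleus_area_um2 = "numeric", cell_area_um2 = "numeric",
                     width_to_length = "numeric", orientation = "numeric",
                     clump = "integer", clump_size = "integer",
                     edu_label = "integer", is_feeder = "logical")
  )
}

empty_table <- function(type) {
  sch <- table_schemas()[[type]]
  cols <- lapply(sch, function(cl) vector(cl, 0L))
  out <- tibble::as_tibble(cols)
  class(out) <- c(type, class(out))
  out
}

as_typed_table <- function(df, type) {
  sch <- table_schemas()[[type]]
  missing <- setdiff(names(sch), names(df))
  if (length(missing)) {
    stop(sprintf("table is not a valid %s; missing column(s): %s",
                 type, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[names(sch)]
  for (i in seq_along(sch)) {
    df[[i]] <- switch(sch[[i]],
                      character = as.character(df[[i]]),
                      integer = as.integer(df[[i]]),
                      numeric = as.numeric(df[[i]]),
                      logical = as.logical(df[[i]]))
  }
  out <- tibble::as_tibble(df)
  class(out) <- c(type, class(out))
  out
}

#' Write a pipeline table to CSV
#'
#' Numeric columns are serialised with 17 significant digits so that
#' [read_table()] restores them bit-for-bit, including missing values.
#'
#' @param table a typed table (`object_table`, `clump_table`,
#'   `well_summary` or `ground_truth`)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_table <- function(table, path) {
  type <- intersect(class(table), names(table_schemas()))
  if (!length(type)) {
    stop("not a typed pipeline table; see as_object_table() etc.",
         call. = FALSE)
  }
  sch <- table_schemas()[[type[1]]]
  out <- as.data.frame(table)[names(sch)]
  for (nm in names(sch)) {
    if (sch[[nm]] == "numeric") {
      v <- out[[nm]]
      out[[nm]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pipeline table from CSV
#'
#' @param path CSV path written by [write_table()]
#' @param type one of `"object_table"`, `"clump_table"`, `"well_summary"`,
#'   `"ground_truth"`
#' @return the typed table; a schema mismatch raises an error naming the
#'   missing columns
#' @export
read_table <- function(path, type = c("object_table", "clump_table",
                                      "well_summary", "ground_truth")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L && length(setdiff(names(table_schemas()[[type]]),
                                       names(df))) == 0L) {
    return(empty_table(type))
  }
  as_typed_table(df, type)
}

#' Coerce a data frame to a typed object table
#' @param df data frame with the object-table schema
#' @return an `object_table` tibble
#' @export
as_object_table <- function(df) as_typed_table(df, "object_table")

#' Coerce a data frame to a typed clump table
#' @param df data frame with the clump-table schema
#' @return a `clump_table` tibble
#' @export
as_clump_table <- function(df) as_typed_table(df, "clump_table")

#' Coerce a data frame to a typed well-summary table
#' @param df data frame with the well-summary schema
#' @return a `well_summary` tibble
#' @export
as_well_summary <- function(df) as_typed_table(df, "well_summary")

#' Coerce a data frame to a typed ground-truth table
#' @param df data frame with the ground-truth schema
#' @return a `ground_truth` tibble
#' @export
as_ground_truth <- function(df) as_typed_table(df, "ground_truth")
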