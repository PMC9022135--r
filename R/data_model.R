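# Core domain types and on-disk formats.
#
# Conventions fixed here and used everywhere else in the package:
#  - pixel coordinates are 0-based (row, col), row 0 = top image row;
#  - intensities are raw arbitrary units (A.U.), no normalisation at I/O;
#  - valid A.U. range for disk storage is [0, 65536).

CHANNELS <- c("DAPI", "53BP1", "gH2AX")
TREATMENTS <- c("UNTREATED", "DMSO", "ETP")

#' One fluorescence channel of one imaged field
#'
#' Container for a single-channel 2D fluorescence image together with
#' the metadata carried by the file naming convention: plate well,
#' field-of-view index and channel. Pixel values are raw detector
#' arbitrary units (A.U.).
#'
#' @param pixels Numeric matrix of non-negative intensities; rows are
#'   image rows (row 1 of the matrix is pixel row 0, the top of the
#'   image).
#' @param channel One of `"DAPI"`, `"53BP1"`, `"gH2AX"`.
#' @param pixel_size_um Physical pixel size in micrometres; default
#'   0.216 (60x lens, 2x2 camera binning).
#' @param well_id Plate coordinate such as `"B03"` (384-well layout,
#'   rows A-P, columns 1-24).
#' @param field_index Field-of-view index within the well, >= 1.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, pixel_size_um = 0.216,
                          well_id = "A01", field_index = 1L) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(dim(pixels) < 1L))
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  if (any(pixels < 0, na.rm = TRUE))
    stop("pixel intensities must be >= 0", call. = FALSE)
  channel <- match.arg(channel, CHANNELS)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0", call. = FALSE)
  validate_well_id(well_id)
  field_index <- as.integer(field_index)
  if (field_index < 1L) stop("field_index must be >= 1", call. = FALSE)
  structure(
    list(pixels = pixels, channel = channel,
         pixel_size_um = pixel_size_um,
         well_id = well_id, field_index = field_index),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s field %d channel %s: %d x %d px (%.3f um/px), range [%g, %g] A.U.\n",
              x$well_id, x$field_index, x$channel,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

validate_well_id <- function(well_id) {
  if (length(well_id) != 1L ||
      !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", well_id))
    stop("invalid 384-well id: '", well_id,
         "' (expected e.g. 'B03', rows A-P, columns 01-24)", call. = FALSE)
  invisible(well_id)
}

#' Build the on-disk file name for a field/channel image
#'
#' The naming convention is `<WELL>_f<FF>_<CHANNEL>.tif`, e.g.
#' `B03_f04_DAPI.tif`. [parse_field_filename()] is its exact inverse.
#'
#' @param well_id Well coordinate (e.g. `"B03"`).
#' @param field_index Field index >= 1 (zero-padded to two digits).
#' @param channel One of `"DAPI"`, `"53BP1"`, `"gH2AX"`.
#' @return File name string.
#' @export
field_filename <- function(well_id, field_index, channel) {
  validate_well_id(well_id)
  channel <- match.arg(channel, CHANNELS)
  sprintf("%s_f%02d_%s.tif", well_id, as.integer(field_index), channel)
}

#' Parse a field image file name into its components
#'
#' @param name File name (with or without directory part) following the
#'   `<WELL>_f<FIELD>_<CHANNEL>.tif` convention, channel one of
#'   `DAPI`, `53BP1`, `gH2AX`.
#' @return A list with elements `well_id`, `field_index` (integer) and
#'   `channel`.
#' @export
#' @examples
#' parse_field_filename("B03_f04_DAPI.tif")
parse_field_filename <- function(name) {
  base <- basename(name)
  m <- regexec("^([A-P][0-9]{2})_f([0-9]+)_(DAPI|53BP1|gH2AX)\\.tif$", base)
  g <- regmatches(base, m)[[1]]
  if (length(g) != 4L) {
    # name the offending token for a useful error
    parts <- strsplit(sub("\\.tif$", "", base), "_")[[1]]
    bad <- base
    if (length(parts) >= 1 && !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", parts[1]))
      bad <- parts[1]
    else if (length(parts) >= 2 && !grepl("^f[0-9]+$", parts[2]))
      bad <- parts[2]
    else if (length(parts) >= 3 && !parts[3] %in% CHANNELS)
      bad <- parts[3]
    stop("cannot parse field file name '", base,
         "': offending token '", bad, "'", call. = FALSE)
  }
  validate_well_id(g[2])
  fi <- as.integer(g[3])
  if (fi < 1L)
    stop("cannot parse field file name '", base,
         "': field index must be >= 1", call. = FALSE)
  list(well_id = g[2], field_index = fi, channel = g[4])
}

#' Read a single-plane grayscale TIFF as a channel image
#'
#' Supports 8/16-bit integer and 32-bit float grayscale TIFFs written
#' by [write_channel_image()]. Integer data round-trip bit-exactly;
#' float data round-trip at 32-bit float precision. Multi-plane and
#' RGB TIFFs are rejected.
#'
#' @param path TIFF file path; the file name must follow the field
#'   naming convention (see [parse_field_filename()]) so the well,
#'   field and channel metadata can be recovered.
#' @param pixel_size_um Physical pixel size to attach (not stored in
#'   the TIFF).
#' @return A [channel_image()].
#' @export
read_channel_image <- function(path, pixel_size_um = 0.216) {
  meta <- parse_field_filename(path)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(planes) != 1L)
    stop("unsupported TIFF format: multi-plane image in '", path, "'",
         call. = FALSE)
  px <- planes[[1]]
  if (length(dim(px)) != 2L)
    stop("unsupported TIFF format: RGB/multi-sample image in '", path, "'",
         call. = FALSE)
  bits <- attr(px, "bits.per.sample")
  px <- if (!is.null(bits) && bits <= 16L)
    round(matrix(as.numeric(px), nrow(px), ncol(px)) * (2^bits - 1))
  else
    # 32-bit float path: stored as A.U. / 2^16 (exact binary scaling)
    matrix(as.numeric(px), nrow(px), ncol(px)) * 65536
  channel_image(px, channel = meta$channel, pixel_size_um = pixel_size_um,
                well_id = meta$well_id, field_index = meta$field_index)
}

#' Write a channel image as a single-plane grayscale TIFF
#'
#' Images whose pixels are all whole numbers in \[0, 65535\] are stored
#' as 16-bit integer TIFF (bit-exact round trip); anything else is
#' stored as 32-bit float with an exact power-of-two scaling, valid for
#' A.U. values in \[0, 65536).
#'
#' @param image A [channel_image()].
#' @param dir Output directory (created if missing). The file name is
#'   built with [field_filename()] from the image metadata.
#' @return The written file path, invisibly.
#' @export
write_channel_image <- function(image, dir = ".") {
  stopifnot(inherits(image, "channel_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, field_filename(image$well_id, image$field_index,
                                        image$channel))
  px <- image$pixels
  if (any(px < 0) || any(px >= 65536))
    stop("pixel values outside the storable A.U. range [0, 65536)",
         call. = FALSE)
  if (all(px == round(px)) && max(px) <= 65535) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else {
    suppressWarnings(tiff::writeTIFF(px / 65536, path, bits.per.sample = 32L))
  }
  invisible(path)
}

# ---- plate layout -----------------------------------------------------------

#' Sample metadata for one plate well
#'
#' @param donor_id Donor/sample identifier.
#' @param cell_type Cell type label (e.g. `"CD4T"`, `"JURKAT"`).
#' @param treatment One of `"UNTREATED"`, `"DMSO"`, `"ETP"`.
#' @param treatment_dose_uM Dose in micromolar; must be 0 unless the
#'   treatment is `"ETP"` (default 30 for ETP, the standard
#'   etoposide challenge).
#' @param replicate Technical replicate index >= 1.
#' @return A named list of class `sample_meta`.
#' @export
sample_meta <- function(donor_id = "D1", cell_type = "JURKAT",
                        treatment = "UNTREATED",
                        treatment_dose_uM = if (treatment == "ETP") 30 else 0,
                        replicate = 1L) {
  treatment <- match.arg(treatment, TREATMENTS)
  if (treatment_dose_uM < 0)
    stop("treatment_dose_uM must be >= 0", call. = FALSE)
  if (treatment != "ETP" && treatment_dose_uM != 0)
    stop("treatment_dose_uM must be 0 unless treatment is ETP", call. = FALSE)
  replicate <- as.integer(replicate)
  if (replicate < 1L) stop("replicate must be >= 1", call. = FALSE)
  structure(list(donor_id = donor_id, cell_type = cell_type,
                 treatment = treatment,
                 treatment_dose_uM = treatment_dose_uM,
                 replicate = replicate),
            class = "sample_meta")
}

#' Plate layout: map wells to samples
#'
#' @param wells Named list mapping well ids (e.g. `"B03"`) to
#'   [sample_meta()] entries. Duplicate or invalid well ids are
#'   rejected.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells) {
  ids <- names(wells)
  if (is.null(ids) || any(ids == ""))
    stop("wells must be a named list keyed by well id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate well ids in layout: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (id in ids) validate_well_id(id)
  wells <- lapply(wells, function(w) {
    if (inherits(w, "sample_meta")) w
    else do.call(sample_meta, w)
  })
  structure(list(wells = wells), class = "plate_layout")
}

#' Layout as a data frame (one row per well)
#' @param x A [plate_layout()].
#' @param ... Unused.
#' @return data.frame with columns well_id, donor_id, cell_type,
#'   treatment, treatment_dose_uM, replicate.
#' @export
as.data.frame.plate_layout <- function(x, ...) {
  rows <- lapply(names(x$wells), function(id) {
    m <- x$wells[[id]]
    data.frame(well_id = id, donor_id = m$donor_id, cell_type = m$cell_type,
               treatment = m$treatment,
               treatment_dose_uM = m$treatment_dose_uM,
               replicate = m$replicate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a plate layout as YAML
#'
#' The YAML document is a map from well id to the sample fields of
#' [sample_meta()].
#'
#' @param path YAML file path.
#' @return [read_plate_layout()] returns a [plate_layout()];
#'   `write_plate_layout()` returns the path invisibly.
#' @export
read_plate_layout <- function(path) {
  plate_layout(yaml::read_yaml(path))
}

#' @rdname read_plate_layout
#' @param layout A [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  yaml::write_yaml(lapply(layout$wells, unclass), path)
  invisible(path)
}

# ---- per-cell tables --------------------------------------------------------

# Mandatory columns of the per-cell table, in writing order.
CELL_TABLE_COLUMNS <- c(
  "cell_id", "well_id", "field_index", "nucleus_label",
  "centroid_row", "centroid_col", "nucleus_area_px",
  "mean_nuclear_DAPI", "mean_nuclear_53BP1", "mean_nuclear_gH2AX",
  "sum_spot_53BP1", "sum_spot_gH2AX",
  "spot_count_53BP1", "spot_count_gH2AX")

#' Write / read the per-cell feature table (CSV)
#'
#' One row per cell; comma-separated, UTF-8, header row, `.` decimal
#' separator. The mandatory columns are the identification and feature
#' columns listed in the package vignette; extra metadata columns
#' (donor, treatment, replicate...) pass through unchanged.
#'
#' @param records data.frame of cell records.
#' @param path CSV path.
#' @return `write_cell_table()` the path, invisibly;
#'   [read_cell_table()] the data.frame.
#' @export
write_cell_table <- function(records, path) {
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("cell table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ord <- c(CELL_TABLE_COLUMNS, setdiff(names(records), CELL_TABLE_COLUMNS))
  write.csv(records[, ord, drop = FALSE], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("cell table at '", path, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}

# Empty cell table with the mandatory schema.
empty_cell_table <- function() {
  tab <- data.frame(cell_id = character(), well_id = character(),
                    field_index = integer(), nucleus_label = integer(),
                    centroid_row = numeric(), centroid_col = numeric(),
                    nucleus_area_px = integer(),
                    mean_nuclear_DAPI = numeric(),
                    mean_nuclear_53BP1 = numeric(),
                    mean_nuclear_gH2AX = numeric(),
                    sum_spot_53BP1 = numeric(), sum_spot_gH2AX = numeric(),
                    spot_count_53BP1 = integer(),
                    spot_count_gH2AX = integer(),
                    stringsAsFactors = FALSE)
  tab
}
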