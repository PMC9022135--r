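# Marker-specific per-cell features and positivity calling.
#
# The two marker readouts follow the staining biology: 53BP1 is a
# pre-existing nuclear pool that re-localises into foci, so its
# per-cell feature is the sum of accepted-focus integrated intensities
# ("53BP1 sum spot intensity"); gamma-H2AX is generated de novo by
# phosphorylation, so its feature is the mean nuclear intensity over
# the nucleus mask. Damage positivity is called against the negative
# control: threshold = control mean + 1 sample SD, strictly exceeded.

MARKERS <- c("53BP1", "gH2AX")

# Marker -> default per-cell feature column.
marker_feature <- function(marker) {
  switch(match.arg(marker, MARKERS),
         "53BP1" = "sum_spot_53BP1",
         "gH2AX" = "mean_nuclear_gH2AX")
}

#' Compute per-cell marker features
#'
#' @param images Named list of [channel_image()] (or matrices) per
#'   channel; `DAPI`, `53BP1` and `gH2AX` are used when present.
#' @param labelmap Nucleus label matrix from [segment_nuclei()].
#' @param spots Named list per marker of accepted-candidate data
#'   frames (rows with `nucleus_label` and `integrated_intensity`;
#'   typically the `accepted` subset of [fld_classify()] output).
#' @param well_id,field_index Metadata stamped on the records
#'   (defaults taken from the first channel image, if available).
#' @return data.frame with one row per nucleus: identification,
#'   geometry, `mean_nuclear_<channel>` for each supplied channel, and
#'   `sum_spot_<marker>` / `spot_count_<marker>` for both markers.
#' @export
compute_cell_features <- function(images, labelmap, spots = list(),
                                  well_id = NULL, field_index = NULL) {
  first <- images[[1]]
  if (is.null(well_id))
    well_id <- if (inherits(first, "channel_image")) first$well_id else "A01"
  if (is.null(field_index))
    field_index <- if (inherits(first, "channel_image")) first$field_index
                   else 1L
  labs <- sort(unique(labelmap[labelmap > 0L]))
  if (!length(labs)) return(empty_cell_table())

  geom <- measure_nuclei(labelmap, matrix(0, nrow(labelmap), ncol(labelmap)))
  rec <- data.frame(
    cell_id = sprintf("%s_f%02d_n%03d", well_id, field_index, labs),
    well_id = well_id, field_index = as.integer(field_index),
    nucleus_label = labs,
    centroid_row = geom$centroid_row, centroid_col = geom$centroid_col,
    nucleus_area_px = geom$area_px, stringsAsFactors = FALSE)

  idx <- which(labelmap > 0L)
  f <- factor(labelmap[idx], levels = labs)
  for (ch in c("DAPI", "53BP1", "gH2AX")) {
    col <- paste0("mean_nuclear_", if (ch == "gH2AX") "gH2AX" else ch)
    if (!is.null(images[[ch]])) {
      px <- if (inherits(images[[ch]], "channel_image")) images[[ch]]$pixels
            else as.matrix(images[[ch]])
      if (!all(dim(px) == dim(labelmap)))
        stop("channel ", ch, " and labelmap dimensions differ",
             call. = FALSE)
      rec[[col]] <- as.numeric(tapply(px[idx], f, mean))
    } else {
      rec[[col]] <- NA_real_
    }
  }

  for (marker in MARKERS) {
    sp <- spots[[marker]]
    sums <- setNames(numeric(length(labs)), labs)
    cnts <- setNames(integer(length(labs)), labs)
    if (!is.null(sp) && nrow(sp)) {
      bad <- setdiff(unique(sp$nucleus_label), labs)
      if (length(bad))
        stop("spot(s) reference nonexistent nucleus label(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      agg_s <- tapply(sp$integrated_intensity,
                      factor(sp$nucleus_label, levels = labs), sum)
      agg_n <- table(factor(sp$nucleus_label, levels = labs))
      sums[] <- ifelse(is.na(agg_s), 0, agg_s)
      cnts[] <- as.integer(agg_n)
    }
    rec[[paste0("sum_spot_", marker)]] <- as.numeric(sums)
    rec[[paste0("spot_count_", marker)]] <- as.integer(cnts)
  }
  rec
}

#' Negative-control positivity threshold (mean + 1 SD)
#'
#' @param control_values Feature values of the negative-control cells
#'   (>= 2 finite values).
#' @param marker Marker the threshold applies to.
#' @param feature Feature column name (defaults to the marker's
#'   standard feature).
#' @return Object of class `positivity_threshold` with `mean`, `sd`
#'   (sample SD, n-1 denominator), `threshold = mean + sd`, `n`.
#'   A zero-variance control is allowed but flagged with a warning.
#' @export
compute_threshold <- function(control_values, marker = "gH2AX",
                              feature = marker_feature(marker)) {
  v <- control_values[is.finite(control_values)]
  if (length(v) < 2L)
    stop("insufficient negative control: need >= 2 finite values, got ",
         length(v), call. = FALSE)
  m <- mean(v); s <- sd(v)
  if (s == 0)
    warning("negative control has zero variance; threshold equals its mean",
            call. = FALSE)
  structure(list(marker = match.arg(marker, MARKERS), feature = feature,
                 mean = m, sd = s, threshold = m + s, n = length(v)),
            class = "positivity_threshold")
}

#' @export
print.positivity_threshold <- function(x, ...) {
  cat(sprintf(
    "<positivity_threshold> %s (%s): mean %.4g + SD %.4g = %.4g (control n = %d)\n",
    x$marker, x$feature, x$mean, x$sd, x$threshold, x$n))
  invisible(x)
}

#' Call damage-positive cells against a threshold
#'
#' A cell is positive iff its feature value is strictly greater than
#' the threshold (ties are negative).
#'
#' @param records Cell data.frame containing the threshold's feature
#'   column (or a bare numeric vector of feature values).
#' @param threshold A [compute_threshold()] result.
#' @param marker Marker to call; must match the threshold's marker.
#' @return List with `records` (input plus logical
#'   `positive_<marker>` column) and `positive_fraction`.
#' @export
classify_positive <- function(records, threshold, marker = threshold$marker) {
  stopifnot(inherits(threshold, "positivity_threshold"))
  marker <- match.arg(marker, MARKERS)
  if (!identical(marker, threshold$marker))
    stop("threshold is for marker ", threshold$marker,
         ", not ", marker, call. = FALSE)
  if (is.numeric(records)) records <- setNames(
    data.frame(records), threshold$feature)
  if (nrow(records) == 0L)
    stop("cannot compute a positive fraction from zero cells",
         call. = FALSE)
  v <- records[[threshold$feature]]
  if (is.null(v))
    stop("records lack feature column '", threshold$feature, "'",
         call. = FALSE)
  flag <- v > threshold$threshold
  records[[paste0("positive_", marker)]] <- flag
  list(records = records, positive_fraction = mean(flag))
}

#' Summarise one well
#'
#' @param records Cell records of a single well.
#' @param thresholds Named list per marker of
#'   [compute_threshold()] results (optional; positive fractions are
#'   only reported for markers with a threshold).
#' @return List of class `well_summary`: `well_id`, `n_cells`, and per
#'   marker `median`, `mean`, `sd` (NA for a single cell), `iqr`
#'   (type-7 quantiles) and `positive_fraction`. An empty well yields
#'   `n_cells = 0` and `empty = TRUE` with no statistics.
#' @export
summarize_well <- function(records, thresholds = list()) {
  if (is.null(records) || nrow(records) == 0L)
    return(structure(list(well_id = NA_character_, n_cells = 0L,
                          empty = TRUE, markers = list()),
                     class = "well_summary"))
  if (length(unique(records$well_id)) > 1L)
    stop("records span more than one well", call. = FALSE)
  markers <- list()
  for (marker in MARKERS) {
    feat <- marker_feature(marker)
    v <- records[[feat]]
    if (is.null(v)) next
    pos <- NA_real_
    thr <- thresholds[[marker]]
    if (!is.null(thr))
      pos <- classify_positive(records, thr, marker)$positive_fraction
    markers[[marker]] <- list(
      feature = feat,
      median = median(v), mean = mean(v),
      sd = if (length(v) > 1L) sd(v) else NA_real_,
      iqr = IQR(v, type = 7),
      positive_fraction = pos)
  }
  structure(list(well_id = records$well_id[1],
                 n_cells = nrow(records), empty = FALSE,
                 markers = markers),
            class = "well_summary")
}
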