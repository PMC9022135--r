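# Nucleus segmentation from the DAPI channel.
#
# Pipeline: Gaussian smoothing -> global Otsu threshold (computed on
# the range-normalised image, hence invariant to multiplying the image
# by a positive constant) -> hole filling -> optional watershed split
# of touching nuclei on the distance transform -> area gate -> border
# exclusion -> consecutive relabeling. Labels are 4-connected (the
# labeling convention of EBImage).

#' Segmentation parameters
#'
#' @param smooth_sigma_px Gaussian smoothing sigma before thresholding
#'   (pixels).
#' @param threshold `"otsu"` for an automatic global threshold, or a
#'   fixed numeric intensity in A.U.
#' @param min_area_um2,max_area_um2 Nucleus area gate in um^2;
#'   defaults pi*(2 um)^2 .. pi*(7 um)^2, scaled from immune-cell
#'   nucleus diameters of roughly 8-10 um. Converted to pixels with
#'   the image's pixel size.
#' @param split_touching Split touching nuclei by watershed on the
#'   distance transform?
#' @param h_minima Watershed tolerance (depth, in distance-transform
#'   pixels) used to suppress shallow minima; larger values merge more
#'   seeds.
#' @param exclude_border Drop nuclei touching the image border
#'   (their area/intensity features are truncated)?
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma_px = 2,
                                threshold = "otsu",
                                min_area_um2 = pi * 2^2,
                                max_area_um2 = pi * 7^2,
                                split_touching = TRUE,
                                h_minima = 2,
                                exclude_border = TRUE) {
  if (min_area_um2 <= 0 || min_area_um2 >= max_area_um2)
    stop("need 0 < min_area_um2 < max_area_um2", call. = FALSE)
  if (smooth_sigma_px < 0) stop("smooth_sigma_px must be >= 0", call. = FALSE)
  if (!identical(threshold, "otsu") && !is.numeric(threshold))
    stop("threshold must be 'otsu' or a numeric value", call. = FALSE)
  structure(list(smooth_sigma_px = smooth_sigma_px, threshold = threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 split_touching = isTRUE(split_touching),
                 h_minima = h_minima,
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_params")
}

#' Segment nuclei from a DAPI image
#'
#' @param dapi A [channel_image()] of the DAPI channel (or a plain
#'   numeric matrix, in which case `pixel_size_um` must be given).
#' @param params A [segmentation_params()].
#' @param pixel_size_um Pixel size override when `dapi` is a matrix.
#' @return Integer label matrix of the same shape: 0 = background,
#'   1..K = nuclei, labels consecutive. A constant image yields an
#'   all-zero map.
#' @export
segment_nuclei <- function(dapi, params = segmentation_params(),
                           pixel_size_um = NULL) {
  if (inherits(dapi, "channel_image")) {
    px <- dapi$pixels
    if (is.null(pixel_size_um)) pixel_size_um <- dapi$pixel_size_um
  } else {
    px <- as.matrix(dapi)
    if (is.null(pixel_size_um))
      stop("pixel_size_um required when dapi is a plain matrix",
           call. = FALSE)
  }
  stopifnot(inherits(params, "segmentation_params"))

  sm <- if (params$smooth_sigma_px > 0)
    as.matrix(EBImage::gblur(px, sigma = params$smooth_sigma_px))
  else px

  if (identical(params$threshold, "otsu")) {
    rng <- range(sm)
    if (diff(rng) == 0) return(matrix(0L, nrow(px), ncol(px)))
    norm <- (sm - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else {
    mask <- sm > params$threshold
  }
  if (!any(mask)) return(matrix(0L, nrow(px), ncol(px)))

  mask <- EBImage::fillHull(EBImage::Image(mask * 1))

  lab <- if (params$split_touching) {
    dm <- EBImage::distmap(mask)
    EBImage::watershed(dm, tolerance = params$h_minima, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))

  # area gate (um^2 -> px) and border exclusion
  min_area_px <- params$min_area_um2 / pixel_size_um^2
  max_area_px <- params$max_area_um2 / pixel_size_um^2
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (params$exclude_border) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border_labels)
  }
  relabel <- integer(max(lab) + 1L)           # old label -> new label
  relabel[keep + 1L] <- seq_along(keep)
  matrix(relabel[lab + 1L], nrow(px), ncol(px))
}

#' Per-nucleus geometry and DAPI intensity
#'
#' @param labelmap Integer label matrix from [segment_nuclei()].
#' @param dapi DAPI [channel_image()] or matrix of the same shape.
#' @return data.frame with one row per label: `label`, 0-based
#'   centroid (`centroid_row`, `centroid_col`), `area_px`, bounding
#'   box (`bbox_row_min` .. `bbox_col_max`, 0-based, inclusive),
#'   `border_touching`, `mean_dapi`.
#' @export
measure_nuclei <- function(labelmap, dapi) {
  px <- if (inherits(dapi, "channel_image")) dapi$pixels else as.matrix(dapi)
  if (!all(dim(labelmap) == dim(px)))
    stop("labelmap and image dimensions differ (",
         paste(dim(labelmap), collapse = "x"), " vs ",
         paste(dim(px), collapse = "x"), ")", call. = FALSE)
  labs <- sort(unique(labelmap[labelmap > 0L]))
  if (length(labs) == 0L)
    return(data.frame(label = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer(),
                      bbox_row_min = integer(), bbox_row_max = integer(),
                      bbox_col_min = integer(), bbox_col_max = integer(),
                      border_touching = logical(), mean_dapi = numeric()))
  idx <- which(labelmap > 0L)
  rr <- (idx - 1L) %% nrow(labelmap) + 1L
  cc <- (idx - 1L) %/% nrow(labelmap) + 1L
  ll <- labelmap[idx]
  f <- factor(ll, levels = labs)
  area <- as.integer(table(f))
  cr <- tapply(rr, f, mean) - 1   # 0-based
  ccen <- tapply(cc, f, mean) - 1
  rmin <- tapply(rr, f, min); rmax <- tapply(rr, f, max)
  cmin <- tapply(cc, f, min); cmax <- tapply(cc, f, max)
  border <- rmin == 1 | cmin == 1 | rmax == nrow(labelmap) |
    cmax == ncol(labelmap)
  mean_dapi <- tapply(px[idx], f, mean)
  data.frame(label = labs,
             centroid_row = as.numeric(cr), centroid_col = as.numeric(ccen),
             area_px = area,
             bbox_row_min = as.integer(rmin) - 1L,
             bbox_row_max = as.integer(rmax) - 1L,
             bbox_col_min = as.integer(cmin) - 1L,
             bbox_col_max = as.integer(cmax) - 1L,
             border_touching = as.logical(border),
             mean_dapi = as.numeric(mean_dapi))
}

#' Match segmented labels to ground-truth labels by Jaccard overlap
#'
#' Greedy 1:1 matching: label pairs are matched in decreasing order of
#' Jaccard index, keeping pairs above the cutoff, each true and each
#' found label used at most once.
#'
#' @param found,truth Integer label matrices of the same shape.
#' @param min_jaccard Minimum Jaccard index for a match.
#' @return List with `matches` (data.frame truth_label, found_label,
#'   jaccard), `n_truth`, `n_found`, `recall` (matched / n_truth) and
#'   `spurious` (unmatched found labels / n_truth).
#' @export
match_labels <- function(found, truth, min_jaccard = 0.5) {
  stopifnot(all(dim(found) == dim(truth)))
  nt <- length(setdiff(unique(as.vector(truth)), 0L))
  nf <- length(setdiff(unique(as.vector(found)), 0L))
  both <- truth > 0L & found > 0L
  if (!any(both) || nt == 0L || nf == 0L)
    return(list(matches = data.frame(truth_label = integer(),
                                     found_label = integer(),
                                     jaccard = numeric()),
                n_truth = nt, n_found = nf,
                recall = if (nt) 0 else NA_real_,
                spurious = if (nt) nf / nt else NA_real_))
  ov <- table(truth = truth[both], found = found[both])
  t_area <- table(truth[truth > 0L]); f_area <- table(found[found > 0L])
  pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$Freq > 0, ]
  inter <- pairs$Freq
  uni <- as.numeric(t_area[pairs$truth]) + as.numeric(f_area[pairs$found]) -
    inter
  pairs$jaccard <- inter / uni
  pairs <- pairs[pairs$jaccard >= min_jaccard, ]
  pairs <- pairs[order(-pairs$jaccard), ]
  used_t <- character(); used_f <- character(); keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$truth[i] %in% used_t) && !(pairs$found[i] %in% used_f)) {
      keep[i] <- TRUE
      used_t <- c(used_t, pairs$truth[i]); used_f <- c(used_f, pairs$found[i])
    }
  }
  matches <- data.frame(truth_label = as.integer(pairs$truth[keep]),
                        found_label = as.integer(pairs$found[keep]),
                        jaccard = pairs$jaccard[keep])
  list(matches = matches, n_truth = nt, n_found = nf,
       recall = nrow(matches) / nt,
       spurious = (nf - nrow(matches)) / nt)
}
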