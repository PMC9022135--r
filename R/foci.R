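# Focus detection and classification.
#
# Candidate foci are local maxima of the scale-normalised
# Laplacian-of-Gaussian response (sigma^2 * -LoG, positive for bright
# blobs) inside segmented nuclei, detected permissively ("low
# stringency") so that a trainable Fisher linear discriminant can
# separate true repair foci from background detections. The
# discriminant stores per-class sufficient statistics (count, mean,
# scatter), which makes fine-tuning on additional labelled examples
# exactly equivalent to retraining on the pooled data.

# Default classifier feature set: intensity features enter on a log
# scale because focus amplitudes are heavy-tailed (log-normal in
# fluorescence data); shape and context features enter as-is.
FLD_FEATURES <- c("log_integrated_intensity", "log_amplitude",
                  "log_contrast", "area_px", "roundness", "scale_px")

#' Spot-detection parameters
#'
#' @param sigma_min_px,sigma_max_px Scale range of the LoG filter bank
#'   (pixels); the default 1-3 px brackets a diffraction-limited focus
#'   at 216 nm pixels.
#' @param n_scales Number of log-spaced scales.
#' @param response_threshold Minimum scale-normalised LoG response
#'   (A.U.); the default is deliberately permissive.
#' @param annulus_sigma Inner/outer radii of the local-background
#'   annulus, in units of the detection scale.
#' @param max_candidates_per_nucleus Cap on candidates kept per
#'   nucleus (strongest first).
#' @return Object of class `spot_detection_params`.
#' @export
spot_detection_params <- function(sigma_min_px = 1.0, sigma_max_px = 3.0,
                                  n_scales = 4L,
                                  response_threshold = 15,
                                  annulus_sigma = c(3, 5),
                                  max_candidates_per_nucleus = 50L) {
  if (sigma_min_px <= 0 || sigma_min_px >= sigma_max_px)
    stop("need 0 < sigma_min_px < sigma_max_px", call. = FALSE)
  if (response_threshold < 0)
    stop("response_threshold must be >= 0", call. = FALSE)
  if (length(annulus_sigma) != 2L || annulus_sigma[1] >= annulus_sigma[2])
    stop("annulus_sigma must be increasing (inner, outer)", call. = FALSE)
  structure(list(sigma_min_px = sigma_min_px, sigma_max_px = sigma_max_px,
                 n_scales = as.integer(n_scales),
                 response_threshold = response_threshold,
                 annulus_sigma = annulus_sigma,
                 max_candidates_per_nucleus =
                   as.integer(max_candidates_per_nucleus)),
            class = "spot_detection_params")
}

# Scale-normalised LoG response (positive at bright blobs).
log_response <- function(px, sigma) {
  sm <- as.matrix(EBImage::gblur(px, sigma = sigma))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  -sigma^2 * as.matrix(EBImage::filter2(sm, lap))
}

# TRUE where a pixel is a strict local maximum among its 8 neighbours.
local_maxima <- function(r) {
  n <- nrow(r); m <- ncol(r)
  pad <- matrix(-Inf, n + 2, m + 2); pad[2:(n + 1), 2:(m + 1)] <- r
  out <- matrix(TRUE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)]
    out <- out & (r > nb)
  }
  out
}

#' Detect candidate foci inside nuclei
#'
#' Multi-scale LoG detection: local maxima of the scale-normalised
#' response above the threshold, inside segmented nuclei, with maxima
#' closer than one detection scale across the filter bank merged into
#' the strongest response. Each candidate is featurised for the
#' Fisher classifier.
#'
#' @param image Marker [channel_image()] (or matrix).
#' @param labelmap Nucleus label matrix from [segment_nuclei()].
#' @param params A [spot_detection_params()].
#' @return data.frame, one row per candidate: `nucleus_label`, 0-based
#'   `centroid_row`/`centroid_col`, `scale_px`, `response`,
#'   `peak_intensity`, `local_background`, `integrated_intensity`
#'   (above local background within 3 detection scales), `area_px`
#'   (pixels above half-max), `contrast`, `roundness`.
#' @export
detect_candidates <- function(image, labelmap,
                              params = spot_detection_params()) {
  px <- if (inherits(image, "channel_image")) image$pixels
        else as.matrix(image)
  if (!all(dim(labelmap) == dim(px)))
    stop("image and labelmap dimensions differ", call. = FALSE)
  sigmas <- exp(seq(log(params$sigma_min_px), log(params$sigma_max_px),
                    length.out = params$n_scales))
  cand <- list()
  for (s in sigmas) {
    r <- log_response(px, s)
    hit <- local_maxima(r) & (r > params$response_threshold) & (labelmap > 0L)
    idx <- which(hit)
    if (length(idx))
      cand[[length(cand) + 1L]] <-
        data.frame(row = (idx - 1L) %% nrow(px) + 1L,
                   col = (idx - 1L) %/% nrow(px) + 1L,
                   scale_px = s, response = r[idx],
                   nucleus_label = labelmap[idx])
  }
  if (!length(cand)) return(empty_candidates())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$response), ]

  # merge duplicate maxima across scales: keep strongest, drop any
  # weaker candidate within one detection scale of a kept one
  keep <- logical(nrow(cand))
  kept_rc <- matrix(numeric(0), ncol = 2)
  kept_s <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept_rc)) {
      d <- sqrt((kept_rc[, 1] - cand$row[i])^2 +
                  (kept_rc[, 2] - cand$col[i])^2)
      if (any(d < pmax(kept_s, cand$scale_px[i]))) next
    }
    keep[i] <- TRUE
    kept_rc <- rbind(kept_rc, c(cand$row[i], cand$col[i]))
    kept_s <- c(kept_s, cand$scale_px[i])
  }
  cand <- cand[keep, ]

  # per-nucleus cap, strongest first
  cand <- do.call(rbind, lapply(split(cand, cand$nucleus_label), function(d)
    head(d[order(-d$response), ], params$max_candidates_per_nucleus)))
  if (is.null(cand) || !nrow(cand)) return(empty_candidates())

  feats <- lapply(seq_len(nrow(cand)), function(i)
    featurize_candidate(px, labelmap, cand[i, ], params))
  out <- cbind(cand, do.call(rbind, feats))
  out$centroid_row <- out$centroid_row_sub
  out$centroid_col <- out$centroid_col_sub
  rownames(out) <- NULL
  out[, c("nucleus_label", "centroid_row", "centroid_col", "scale_px",
          "response", "peak_intensity", "local_background",
          "integrated_intensity", "area_px", "contrast", "roundness",
          "log_integrated_intensity", "log_amplitude", "log_contrast")]
}

empty_candidates <- function() {
  data.frame(nucleus_label = integer(), centroid_row = numeric(),
             centroid_col = numeric(), scale_px = numeric(),
             response = numeric(), peak_intensity = numeric(),
             local_background = numeric(), integrated_intensity = numeric(),
             area_px = integer(), contrast = numeric(),
             roundness = numeric(), log_integrated_intensity = numeric(),
             log_amplitude = numeric(), log_contrast = numeric())
}

featurize_candidate <- function(px, labelmap, c1, params) {
  s <- c1$scale_px; r0 <- c1$row; c0 <- c1$col
  wlim <- ceiling(params$annulus_sigma[2] * s)
  rows <- max(1, r0 - wlim):min(nrow(px), r0 + wlim)
  cols <- max(1, c0 - wlim):min(ncol(px), c0 + wlim)
  sub <- px[rows, cols, drop = FALSE]
  lab <- labelmap[rows, cols, drop = FALSE]
  d <- sqrt(outer((rows - r0)^2, (cols - c0)^2, "+"))
  same_nuc <- lab == c1$nucleus_label
  ann <- d >= params$annulus_sigma[1] * s & d <= params$annulus_sigma[2] * s &
    same_nuc
  bg <- if (any(ann)) median(sub[ann])
        else median(px[labelmap == c1$nucleus_label])
  peak <- px[r0, c0]
  disc <- d <= 3 * s & same_nuc
  integrated <- sum(pmax(sub[disc] - bg, 0))
  half <- bg + (peak - bg) / 2
  above <- disc & sub >= half
  area <- sum(above)
  # roundness: minor/major eigenvalue ratio of the above-half-max blob
  roundness <- 1
  if (area > 1) {
    rr <- rep(rows, times = length(cols))[as.vector(above)]
    cc <- rep(cols, each = length(rows))[as.vector(above)]
    cv <- stats::cov(cbind(rr, cc))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    roundness <- if (ev[1] > 0) max(ev[2], 0) / ev[1] else 1
  }
  # intensity-weighted sub-pixel centroid over the above-half-max blob
  cr <- r0; ccol <- c0
  if (area > 0) {
    rr <- rep(rows, times = length(cols))[as.vector(above)]
    cc <- rep(cols, each = length(rows))[as.vector(above)]
    wts <- pmax(sub[above] - bg, 0)
    if (sum(wts) > 0) {
      cr <- sum(rr * wts) / sum(wts)
      ccol <- sum(cc * wts) / sum(wts)
    }
  }
  contrast <- (peak - bg) / (bg + 1)
  data.frame(peak_intensity = peak, local_background = bg,
             integrated_intensity = integrated, area_px = area,
             contrast = contrast,
             roundness = roundness,
             log_integrated_intensity = log1p(integrated),
             log_amplitude = log1p(max(peak - bg, 0)),
             log_contrast = log1p(max(contrast, 0)),
             centroid_row_sub = cr - 1, centroid_col_sub = ccol - 1)
}

# ---- Fisher linear discriminant --------------------------------------------

#' Train a Fisher linear discriminant
#'
#' Closed-form two-class discriminant: `w = (S_W + eps I)^-1 (mu1 -
#' mu0)` with `S_W` the summed within-class scatter, and decision
#' threshold `t = (w . mu1 + w . mu0) / 2` (projected-means midpoint;
#' no class priors). A candidate is accepted as a focus iff
#' `w . x > t`.
#'
#' @param focus_examples,background_examples Numeric matrices or data
#'   frames (rows = examples, columns = features) for the focus
#'   (positive) and background (negative) classes; >= 2 rows each.
#' @param features Feature names (column order of `w`); defaults to
#'   the columns of `focus_examples` intersected with the standard
#'   candidate feature set.
#' @param ridge Ridge added to `S_W`'s diagonal; `NULL` (default)
#'   uses `1e-6 * trace(S_W) / d`, `0` disables it (an exactly
#'   singular `S_W` then raises an error).
#' @return Object of class `fld_model` with fields `features`, `w`,
#'   `threshold`, `mu1`, `mu0`, `sw`, `ridge`, and the per-class
#'   sufficient statistics used by [fld_finetune()].
#' @export
fld_train <- function(focus_examples, background_examples,
                      features = NULL, ridge = NULL) {
  x1 <- as_feature_matrix(focus_examples, features)
  x0 <- as_feature_matrix(background_examples, colnames(x1))
  if (nrow(x1) < 2L || nrow(x0) < 2L)
    stop("need >= 2 examples per class", call. = FALSE)
  stats1 <- class_stats(x1); stats0 <- class_stats(x0)
  fld_from_stats(stats1, stats0, colnames(x1), ridge)
}

as_feature_matrix <- function(x, features) {
  x <- as.data.frame(x)
  if (is.null(features)) {
    features <- intersect(FLD_FEATURES, names(x))
    if (!length(features)) features <- names(x)[vapply(x, is.numeric,
                                                       logical(1))]
  }
  missing_f <- setdiff(features, names(x))
  if (length(missing_f))
    stop("missing feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(x[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Sufficient statistics of one class: n, mean, scatter about the mean.
class_stats <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  list(n = nrow(x), mean = mu, scatter = crossprod(xc))
}

fld_from_stats <- function(stats1, stats0, features, ridge = NULL) {
  d <- length(features)
  mu1 <- stats1$mean; mu0 <- stats0$mean
  if (all(mu1 == mu0))
    stop("degenerate training set: identical class means", call. = FALSE)
  sw <- stats1$scatter + stats0$scatter
  eps <- if (is.null(ridge)) 1e-6 * sum(diag(sw)) / d else ridge
  swr <- sw + diag(eps, d)
  w <- tryCatch(solve(swr, mu1 - mu0), error = function(e)
    stop("within-class scatter is singular; retrain with a positive ridge",
         call. = FALSE))
  t <- (sum(w * mu1) + sum(w * mu0)) / 2
  structure(list(features = features, w = as.numeric(w), threshold = t,
                 mu1 = as.numeric(mu1), mu0 = as.numeric(mu0),
                 sw = sw, ridge = eps,
                 stats1 = stats1, stats0 = stats0),
            class = "fld_model")
}

#' @export
print.fld_model <- function(x, ...) {
  cat("<fld_model>", length(x$features), "features:",
      paste(x$features, collapse = ", "), "\n")
  cat("  w =", paste(signif(x$w, 4), collapse = ", "),
      " threshold =", signif(x$threshold, 4),
      " (n focus =", x$stats1$n, ", n background =", x$stats0$n, ")\n")
  invisible(x)
}

#' Score and classify spot candidates
#'
#' Adds `score = w . x - t` and `accepted = score > 0` to the
#' candidate table; input order is preserved.
#'
#' @param model An [fld_train()] model.
#' @param candidates Candidate data.frame containing the model's
#'   feature columns.
#' @return The candidate data.frame with `score` and `accepted`
#'   columns appended.
#' @export
fld_classify <- function(model, candidates) {
  stopifnot(inherits(model, "fld_model"))
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L) {
    candidates$score <- numeric(0); candidates$accepted <- logical(0)
    return(candidates)
  }
  x <- as_feature_matrix(candidates, model$features)
  score <- as.numeric(x %*% model$w) - model$threshold
  candidates$score <- score
  candidates$accepted <- score > 0
  candidates
}

#' Fine-tune a Fisher discriminant on new labelled examples
#'
#' Per-class counts, means and scatters are additive, so updating the
#' stored sufficient statistics and re-solving is exactly equivalent
#' to retraining on the pooled (old + new) examples. Either class may
#' be empty in the update (its stored statistics are retained).
#'
#' @param model An [fld_train()] model.
#' @param new_focus,new_background New labelled examples (matrices or
#'   data frames with the model's feature columns); may be `NULL`.
#' @param ridge As in [fld_train()]; default recomputes the
#'   trace-scaled ridge on the pooled scatter.
#' @return Updated `fld_model`.
#' @export
fld_finetune <- function(model, new_focus = NULL, new_background = NULL,
                         ridge = NULL) {
  stopifnot(inherits(model, "fld_model"))
  upd <- function(stats, new_x) {
    if (is.null(new_x) || NROW(new_x) == 0L) return(stats)
    x <- as_feature_matrix(new_x, model$features)
    n_new <- nrow(x); mu_new <- colMeans(x)
    n <- stats$n + n_new
    mu <- (stats$n * stats$mean + n_new * mu_new) / n
    # pooled scatter about the pooled mean
    xc <- sweep(x, 2, mu_new)
    s_new <- crossprod(xc)
    dmu <- stats$mean - mu_new
    scatter <- stats$scatter + s_new +
      (stats$n * n_new / n) * tcrossprod(dmu)
    list(n = n, mean = mu, scatter = scatter)
  }
  fld_from_stats(upd(model$stats1, new_focus),
                 upd(model$stats0, new_background),
                 model$features, ridge)
}

#' Serialise / load a Fisher discriminant model (JSON)
#'
#' @param model An `fld_model`.
#' @param path JSON file path.
#' @return `write_fld_model()` the path invisibly;
#'   [read_fld_model()] the model.
#' @export
write_fld_model <- function(model, path) {
  stopifnot(inherits(model, "fld_model"))
  obj <- list(features = model$features, w = model$w,
              threshold = model$threshold,
              mu1 = model$mu1, mu0 = model$mu0,
              sw = as.numeric(model$sw), ridge = model$ridge,
              stats1 = list(n = model$stats1$n, mean = model$stats1$mean,
                            scatter = as.numeric(model$stats1$scatter)),
              stats0 = list(n = model$stats0$n, mean = model$stats0$mean,
                            scatter = as.numeric(model$stats0$scatter)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fld_model
#' @export
read_fld_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(obj$features)
  unpack <- function(s) list(n = s$n, mean = as.numeric(s$mean),
                             scatter = matrix(as.numeric(s$scatter), d, d))
  structure(list(features = obj$features, w = as.numeric(obj$w),
                 threshold = obj$threshold,
                 mu1 = as.numeric(obj$mu1), mu0 = as.numeric(obj$mu0),
                 sw = matrix(as.numeric(obj$sw), d, d), ridge = obj$ridge,
                 stats1 = unpack(obj$stats1), stats0 = unpack(obj$stats0)),
            class = "fld_model")
}

#' Label detected candidates against simulated ground truth
#'
#' A candidate is a true focus if its centroid lies within
#' `match_dist_px` of an unmatched true focus centre of the same
#' marker (greedy nearest-first matching).
#'
#' @param candidates Candidate data.frame from [detect_candidates()].
#' @param truth_foci Ground-truth focus table (0-based `row`/`col`),
#'   already filtered to one marker.
#' @param match_dist_px Match radius in pixels.
#' @return The candidate table with a logical `is_focus` column.
#' @export
label_candidates <- function(candidates, truth_foci, match_dist_px = 3) {
  candidates <- as.data.frame(candidates)
  candidates$is_focus <- FALSE
  if (!nrow(candidates) || is.null(truth_foci) || !nrow(truth_foci))
    return(candidates)
  taken <- logical(nrow(truth_foci))
  ord <- order(-candidates$response)
  for (i in ord) {
    d <- sqrt((truth_foci$row - candidates$centroid_row[i])^2 +
                (truth_foci$col - candidates$centroid_col[i])^2)
    d[taken] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= match_dist_px) {
      candidates$is_focus[i] <- TRUE
      taken[j] <- TRUE
    }
  }
  candidates
}
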