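# Synthetic fluorescence-microscopy simulator with ground truth.
#
# Emulates the three acquisition channels of the DNA-damage assay:
# DAPI-stained elliptical nuclei, punctate 53BP1 foci, and gamma-H2AX
# as a pan-nuclear level plus punctate foci. The treated (ETP-like)
# condition raises the per-cell focus rate and the pan-nuclear
# gamma-H2AX level. Foci are isotropic 2D Gaussians (the standard PSF
# approximation) with log-normal amplitudes. Noise model: Poisson shot
# noise on the clean signal, then additive Gaussian read noise
# (camera-physics order).

#' Simulation configuration
#'
#' Defaults emulate a 60x / 2x2-binned acquisition (216 nm pixels,
#' 1080 x 1280 px fields) of immune-cell nuclei, with a
#' control-to-treated contrast of a Poisson focus rate 1 -> 8
#' foci/cell for both markers and a 2.5-fold pan-nuclear gamma-H2AX
#' increase. Vehicle (`DMSO`) is simulated identically to `UNTREATED`.
#'
#' @param field_shape_px Integer (height, width) of one field.
#' @param pixel_size_um Physical pixel size, micrometres.
#' @param n_cells Nuclei per field.
#' @param nucleus_radius_um (min, max) of the nuclear semi-axes, um.
#' @param nucleus_intensity DAPI level inside nuclei, A.U.
#' @param foci_rate Named list per marker (`"53BP1"`, `"gH2AX"`) of
#'   named vectors per condition: Poisson mean foci/cell.
#' @param focus_sigma_um PSF sigma of a focus, um.
#' @param focus_amplitude `c(median=, gsd=)` of the log-normal focus
#'   peak amplitude (A.U., geometric SD > 1).
#' @param pan_nuclear_gh2ax Named vector per condition: added
#'   gamma-H2AX level inside nuclei, A.U.
#' @param background Field background level, A.U.
#' @param read_noise_sd Additive Gaussian read noise SD, A.U.
#' @param shot_noise Apply Poisson shot noise?
#' @param seed Default RNG seed used when none is passed to the
#'   simulation functions.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(field_shape_px = c(1080L, 1280L),
                              pixel_size_um = 0.216,
                              n_cells = 150L,
                              nucleus_radius_um = c(3.0, 4.5),
                              nucleus_intensity = 3000,
                              foci_rate = list(
                                "53BP1" = c(UNTREATED = 1, DMSO = 1, ETP = 8),
                                "gH2AX" = c(UNTREATED = 1, DMSO = 1, ETP = 8)),
                              focus_sigma_um = 0.35,
                              focus_amplitude = c(median = 1500, gsd = 1.6),
                              pan_nuclear_gh2ax = c(UNTREATED = 200,
                                                    DMSO = 200, ETP = 500),
                              background = 100,
                              read_noise_sd = 10,
                              shot_noise = TRUE,
                              seed = 1L) {
  cfg <- list(field_shape_px = as.integer(field_shape_px),
              pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
              nucleus_radius_um = nucleus_radius_um,
              nucleus_intensity = nucleus_intensity,
              foci_rate = foci_rate, focus_sigma_um = focus_sigma_um,
              focus_amplitude = focus_amplitude,
              pan_nuclear_gh2ax = pan_nuclear_gh2ax,
              background = background, read_noise_sd = read_noise_sd,
              shot_noise = isTRUE(shot_noise), seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (length(field_shape_px) != 2L || any(field_shape_px < 1L))
      stop("field_shape_px must be two positive integers", call. = FALSE)
    if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
    if (n_cells < 0L) stop("n_cells must be >= 0", call. = FALSE)
    if (length(nucleus_radius_um) != 2L || any(nucleus_radius_um <= 0) ||
        nucleus_radius_um[1] > nucleus_radius_um[2])
      stop("nucleus_radius_um must be positive (min, max)", call. = FALSE)
    for (mk in names(foci_rate))
      if (any(foci_rate[[mk]] < 0))
        stop("foci_rate must be >= 0 (marker ", mk, ")", call. = FALSE)
    if (focus_sigma_um <= 0) stop("focus_sigma_um must be > 0", call. = FALSE)
    if (focus_amplitude[["median"]] < 0 || focus_amplitude[["gsd"]] < 1)
      stop("focus_amplitude needs median >= 0 and gsd >= 1", call. = FALSE)
    if (any(pan_nuclear_gh2ax < 0) || background < 0 || read_noise_sd < 0)
      stop("intensity levels and noise SD must be >= 0", call. = FALSE)
    r_max_px <- nucleus_radius_um[2] / pixel_size_um
    if (n_cells > 0L && any(field_shape_px < 2 * r_max_px))
      stop("field too small to hold one nucleus", call. = FALSE)
  })
  invisible(cfg)
}

# Deterministic per-(well, field) seed stream derived from a master
# seed: polynomial string hash folded into [0, 2^31 - 2]. Adding wells
# never changes existing wells' streams.
derive_seed <- function(master_seed, well_id = "", field_index = 0L) {
  key <- paste0(well_id, ":", field_index)
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

# Place n non-overlapping ellipses (centres >= 2 * r_max apart) by
# rejection sampling; errors out after the retry budget.
place_nuclei <- function(cfg, retry_factor = 200L) {
  h <- cfg$field_shape_px[1]; w <- cfg$field_shape_px[2]
  r_px <- cfg$nucleus_radius_um / cfg$pixel_size_um
  r_max <- r_px[2]
  min_dist <- 2 * r_max
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L; budget <- retry_factor * max(cfg$n_cells, 1L)
  while (nrow(centers) < cfg$n_cells) {
    tries <- tries + 1L
    if (tries > budget)
      stop("could not place ", cfg$n_cells, " nuclei with spacing ",
           round(min_dist, 1), " px after ", budget, " attempts; ",
           "reduce n_cells or enlarge the field", call. = FALSE)
    cand <- c(runif(1, r_max, h - r_max), runif(1, r_max, w - r_max))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_dist))
      centers <- rbind(centers, cand)
  }
  if (cfg$n_cells == 0L)
    return(data.frame(cell = integer(), center_row = numeric(),
                      center_col = numeric(), semi_a_px = numeric(),
                      semi_b_px = numeric(), theta = numeric()))
  n <- cfg$n_cells
  data.frame(cell = seq_len(n),
             center_row = centers[, 1], center_col = centers[, 2],
             semi_a_px = runif(n, r_px[1], r_px[2]),
             semi_b_px = runif(n, r_px[1], r_px[2]),
             theta = runif(n, 0, pi))
}

# Pixel index set of one ellipse (1-based matrix rows/cols).
ellipse_pixels <- function(nuc, shape) {
  r_lim <- ceiling(max(nuc$semi_a_px, nuc$semi_b_px)) + 1
  rows <- max(1, floor(nuc$center_row - r_lim)):min(shape[1], ceiling(nuc$center_row + r_lim))
  cols <- max(1, floor(nuc$center_col - r_lim)):min(shape[2], ceiling(nuc$center_col + r_lim))
  dr <- rep(rows, times = length(cols)) - nuc$center_row
  dc <- rep(cols, each = length(rows)) - nuc$center_col
  u <- dr * cos(nuc$theta) + dc * sin(nuc$theta)
  v <- -dr * sin(nuc$theta) + dc * cos(nuc$theta)
  inside <- (u / nuc$semi_a_px)^2 + (v / nuc$semi_b_px)^2 <= 1
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

# Add an isotropic 2D Gaussian of peak amplitude `amp` at (r0, c0).
add_gaussian_focus <- function(img, r0, c0, amp, sigma_px) {
  wlim <- ceiling(4 * sigma_px)
  rows <- max(1, floor(r0 - wlim)):min(nrow(img), ceiling(r0 + wlim))
  cols <- max(1, floor(c0 - wlim)):min(ncol(img), ceiling(c0 + wlim))
  g <- amp * exp(-(outer((rows - r0)^2, (cols - c0)^2, "+")) /
                   (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

# Draw a point uniformly inside an ellipse, shrunk by `shrink` so foci
# (and their cores) stay inside the nucleus.
point_in_ellipse <- function(nuc, shrink = 0.85) {
  repeat {
    u <- runif(1, -1, 1); v <- runif(1, -1, 1)
    if (u^2 + v^2 <= 1) break
  }
  a <- nuc$semi_a_px * shrink; b <- nuc$semi_b_px * shrink
  dr <- u * a * cos(nuc$theta) - v * b * sin(nuc$theta)
  dc <- u * a * sin(nuc$theta) + v * b * cos(nuc$theta)
  c(nuc$center_row + dr, nuc$center_col + dc)
}

#' Simulate one multi-channel field with ground truth
#'
#' Renders the three channels of one field of view for a given
#' treatment condition and returns them together with the ground
#' truth (true nucleus geometry and per-marker focus positions,
#' amplitudes and counts). Fully reproducible for a given seed.
#'
#' @param config A [simulation_config()].
#' @param condition `"UNTREATED"`, `"DMSO"` or `"ETP"`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param well_id,field_index Metadata stamped on the images.
#' @return List with `images` (named list of [channel_image()] for
#'   `DAPI`, `53BP1`, `gH2AX`) and `truth` (list with `cells` and
#'   `foci` data frames and the field `shape`).
#' @export
simulate_field <- function(config, condition = "UNTREATED",
                           seed = config$seed,
                           well_id = "A01", field_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  condition <- match.arg(condition, TREATMENTS)
  set.seed(seed)
  shape <- config$field_shape_px
  sigma_px <- config$focus_sigma_um / config$pixel_size_um

  nuclei <- place_nuclei(config)
  nuclei$condition <- rep(condition, nrow(nuclei))

  dapi <- matrix(config$background, shape[1], shape[2])
  bp1 <- matrix(config$background, shape[1], shape[2])
  gh2ax <- matrix(config$background, shape[1], shape[2])

  pan <- config$pan_nuclear_gh2ax[[condition]]
  foci <- list()
  masks <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    nuc <- nuclei[i, ]
    px <- ellipse_pixels(nuc, shape)
    masks[[i]] <- px
    dapi[px] <- dapi[px] + config$nucleus_intensity
    gh2ax[px] <- gh2ax[px] + pan
    for (marker in names(config$foci_rate)) {
      lambda <- config$foci_rate[[marker]][[condition]]
      k <- rpois(1, lambda)
      if (k > 0) {
        for (j in seq_len(k)) {
          pos <- point_in_ellipse(nuc)
          amp <- rlnorm(1, meanlog = log(config$focus_amplitude[["median"]]),
                        sdlog = log(config$focus_amplitude[["gsd"]]))
          if (marker == "53BP1")
            bp1 <- add_gaussian_focus(bp1, pos[1], pos[2], amp, sigma_px)
          else
            gh2ax <- add_gaussian_focus(gh2ax, pos[1], pos[2], amp, sigma_px)
          foci[[length(foci) + 1L]] <-
            data.frame(cell = nuc$cell, marker = marker,
                       row = pos[1] - 1, col = pos[2] - 1, # 0-based
                       amplitude = amp, sigma_px = sigma_px)
        }
      }
    }
  }
  foci <- if (length(foci)) do.call(rbind, foci)
          else data.frame(cell = integer(), marker = character(),
                          row = numeric(), col = numeric(),
                          amplitude = numeric(), sigma_px = numeric())

  apply_noise <- function(img) {
    if (config$shot_noise)
      img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
    if (config$read_noise_sd > 0)
      img <- img + rnorm(length(img), 0, config$read_noise_sd)
    pmin(pmax(round(img), 0), 65535)
  }
  dapi <- apply_noise(dapi); bp1 <- apply_noise(bp1)
  gh2ax <- apply_noise(gh2ax)

  counts <- function(marker) {
    k <- integer(nrow(nuclei))
    if (nrow(foci)) {
      tab <- table(factor(foci$cell[foci$marker == marker],
                          levels = nuclei$cell))
      k <- as.integer(tab)
    }
    k
  }
  cells <- nuclei
  cells$n_foci_53BP1 <- counts("53BP1")
  cells$n_foci_gH2AX <- counts("gH2AX")

  mk_img <- function(px, ch)
    channel_image(px, ch, pixel_size_um = config$pixel_size_um,
                  well_id = well_id, field_index = field_index)
  list(images = list(DAPI = mk_img(dapi, "DAPI"),
                     "53BP1" = mk_img(bp1, "53BP1"),
                     gH2AX = mk_img(gh2ax, "gH2AX")),
       truth = list(cells = cells, foci = foci, shape = shape,
                    masks = masks))
}

#' Rasterise the true nucleus masks of a simulated field
#'
#' @param truth The `truth` component returned by [simulate_field()].
#' @return Integer label matrix (0 = background, cell index = label).
#' @export
ground_truth_label_map <- function(truth) {
  lab <- matrix(0L, truth$shape[1], truth$shape[2])
  for (i in seq_along(truth$masks)) lab[truth$masks[[i]]] <- i
  lab
}

#' Simulate a plate to disk
#'
#' Writes one TIFF per well/field/channel using the
#' `<WELL>_f<FF>_<CHANNEL>.tif` convention plus two ground-truth CSVs
#' (`truth_cells.csv`, `truth_foci.csv`). Each (well, field) gets its
#' own RNG stream derived deterministically from the master seed, so
#' adding wells to a layout never changes existing wells' images.
#'
#' @param layout A [plate_layout()]; the treatment of each well sets
#'   the simulated condition.
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param fields_per_well Fields of view per well (default 9).
#' @param seed Master seed (defaults to `config$seed`).
#' @return Invisibly, a list with `files` (written image paths),
#'   `truth_cells`, `truth_foci` (data frames, also written as CSV).
#' @export
simulate_plate <- function(layout, config, out_dir,
                           fields_per_well = 9L, seed = config$seed) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(config, "simulation_config"))
  if (length(layout$wells) == 0L) stop("layout is empty", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(); all_cells <- list(); all_foci <- list()
  for (well_id in names(layout$wells)) {
    meta <- layout$wells[[well_id]]
    for (fi in seq_len(fields_per_well)) {
      fs <- derive_seed(seed, well_id, fi)
      sim <- simulate_field(config, condition = meta$treatment, seed = fs,
                            well_id = well_id, field_index = fi)
      for (img in sim$images)
        files <- c(files, write_channel_image(img, out_dir))
      cells <- sim$truth$cells
      if (nrow(cells)) {
        cells$well_id <- well_id; cells$field_index <- fi
        cells$donor_id <- meta$donor_id; cells$cell_type <- meta$cell_type
        cells$replicate <- meta$replicate
        all_cells[[length(all_cells) + 1L]] <- cells
      }
      fo <- sim$truth$foci
      if (nrow(fo)) {
        fo$well_id <- well_id; fo$field_index <- fi
        all_foci[[length(all_foci) + 1L]] <- fo
      }
    }
  }
  truth_cells <- if (length(all_cells)) do.call(rbind, all_cells) else NULL
  truth_foci <- if (length(all_foci)) do.call(rbind, all_foci) else NULL
  if (!is.null(truth_cells))
    write.csv(truth_cells, file.path(out_dir, "truth_cells.csv"),
              row.names = FALSE)
  if (!is.null(truth_foci))
    write.csv(truth_foci, file.path(out_dir, "truth_foci.csv"),
              row.names = FALSE)
  invisible(list(files = files, truth_cells = truth_cells,
                 truth_foci = truth_foci))
}

#' Sample per-cell marker features from the generative model
#'
#' Draws the per-cell features implied by the simulator's signal model
#' without rendering images: the 53BP1 sum spot intensity of a cell is
#' the sum over its Poisson(\eqn{\lambda}) foci of log-normal peak
#' amplitudes times the Gaussian integral \eqn{2\pi\sigma^2}, and the
#' gamma-H2AX mean nuclear intensity is background + pan-nuclear level
#' + focus contribution spread over the nuclear area + read noise on
#' the mean. Useful for statistically calibrated experiments (e.g.
#' type-I-error studies) at scales where rendering full fields is
#' pointless.
#'
#' @param n Number of cells.
#' @param config A [simulation_config()].
#' @param condition Treatment condition.
#' @param seed RNG seed.
#' @return data.frame with columns `sum_spot_53BP1`,
#'   `mean_nuclear_gH2AX`, `n_foci_53BP1`, `n_foci_gH2AX`.
#' @export
simulate_cell_features <- function(n, config = simulation_config(),
                                   condition = "UNTREATED",
                                   seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  condition <- match.arg(condition, TREATMENTS)
  set.seed(seed)
  sigma_px <- config$focus_sigma_um / config$pixel_size_um
  focus_integral <- 2 * pi * sigma_px^2
  mean_r_um <- mean(config$nucleus_radius_um)
  area_px <- pi * (mean_r_um / config$pixel_size_um)^2

  draw_sum <- function(k) {
    if (k == 0) return(0)
    sum(rlnorm(k, log(config$focus_amplitude[["median"]]),
               log(config$focus_amplitude[["gsd"]]))) * focus_integral
  }
  k1 <- rpois(n, config$foci_rate[["53BP1"]][[condition]])
  k2 <- rpois(n, config$foci_rate[["gH2AX"]][[condition]])
  sum53 <- vapply(k1, draw_sum, numeric(1))
  sum_gh <- vapply(k2, draw_sum, numeric(1))
  pan <- config$pan_nuclear_gh2ax[[condition]]
  mean_gh <- config$background + pan + sum_gh / area_px +
    rnorm(n, 0, config$read_noise_sd / sqrt(area_px))
  data.frame(sum_spot_53BP1 = sum53,
             mean_nuclear_gH2AX = pmax(mean_gh, 0),
             n_foci_53BP1 = k1, n_foci_gH2AX = k2)
}
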