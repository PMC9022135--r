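# Pipeline orchestration: simulate -> segment -> detect/classify ->
# quantify -> stats, each stage runnable independently from the prior
# stage's on-disk outputs. Every run writes a JSON manifest (config
# snapshot, seed, file list, record counts, timestamps) so a plate
# run is reproducible and auditable.

pkg_version <- function() {
  as.character(utils::packageVersion("fociscreen"))
}

write_manifest <- function(path, stage, seed, config = NULL,
                           outputs = character(), counts = list()) {
  manifest <- list(stage = stage, package_version = pkg_version(),
                   master_seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, outputs = outputs, counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

log_info <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Simulate a plate dataset to disk (pipeline stage)
#'
#' Wraps [simulate_plate()]: writes the per-well/field/channel TIFFs,
#' the ground-truth tables and a run manifest.
#'
#' @param config A [simulation_config()].
#' @param layout A [plate_layout()].
#' @param out_dir Output directory.
#' @param fields_per_well Fields of view per well.
#' @param seed Master seed.
#' @return Invisibly, the [simulate_plate()] result plus
#'   `manifest_path`.
#' @export
run_simulate <- function(config, layout, out_dir, fields_per_well = 9L,
                         seed = config$seed) {
  validate_simulation_config(config)
  res <- simulate_plate(layout, config, out_dir,
                        fields_per_well = fields_per_well, seed = seed)
  n_cells <- if (is.null(res$truth_cells)) 0L else nrow(res$truth_cells)
  log_info("simulate: %d wells x %d fields -> %d images, %d true cells",
           length(layout$wells), fields_per_well, length(res$files), n_cells)
  mp <- write_manifest(
    file.path(out_dir, "manifest_simulate.json"), "simulate", seed,
    config = unclass(config),
    outputs = basename(res$files),
    counts = list(wells = length(layout$wells),
                  fields_per_well = fields_per_well,
                  images = length(res$files), true_cells = n_cells))
  res$manifest_path <- mp
  invisible(res)
}

#' Train per-marker focus classifiers on simulated fields
#'
#' Simulates training fields, detects candidates at low stringency,
#' labels them by proximity to the ground-truth focus centres, and
#' trains one Fisher discriminant per marker. The training simulation
#' uses its own seed, so models can be trained on data disjoint from
#' any evaluation set.
#'
#' @param config A [simulation_config()].
#' @param n_fields Training fields per condition.
#' @param conditions Conditions to draw training fields from (a mix of
#'   control and treated fields supplies both classes).
#' @param seg_params,spot_params Segmentation / detection parameters.
#' @param seed Training seed.
#' @return Named list per marker of [fld_train()] models.
#' @export
train_spot_models <- function(config, n_fields = 2L,
                              conditions = c("UNTREATED", "ETP"),
                              seg_params = segmentation_params(),
                              spot_params = spot_detection_params(),
                              seed = 1000L) {
  examples <- list("53BP1" = list(pos = list(), neg = list()),
                   gH2AX = list(pos = list(), neg = list()))
  fi <- 0L
  for (cond in conditions) for (k in seq_len(n_fields)) {
    fi <- fi + 1L
    sim <- simulate_field(config, condition = cond,
                          seed = derive_seed(seed, "TRAIN", fi))
    lab <- segment_nuclei(sim$images$DAPI, seg_params)
    for (marker in MARKERS) {
      cands <- detect_candidates(sim$images[[marker]], lab, spot_params)
      truth <- sim$truth$foci[sim$truth$foci$marker == marker, ]
      cands <- label_candidates(cands, truth)
      examples[[marker]]$pos[[fi]] <- cands[cands$is_focus, FLD_FEATURES]
      examples[[marker]]$neg[[fi]] <- cands[!cands$is_focus, FLD_FEATURES]
    }
  }
  models <- list()
  for (marker in MARKERS) {
    pos <- do.call(rbind, examples[[marker]]$pos)
    neg <- do.call(rbind, examples[[marker]]$neg)
    if (nrow(pos) < 2L || nrow(neg) < 2L)
      stop("not enough labelled training candidates for marker ", marker,
           " (", nrow(pos), " focus, ", nrow(neg), " background); ",
           "increase n_fields", call. = FALSE)
    models[[marker]] <- fld_train(pos, neg)
    log_info("train_spot_models: %s trained on %d focus / %d background",
             marker, nrow(pos), nrow(neg))
  }
  models
}

#' Quantify a plate image directory into a per-cell table
#'
#' Reads every field image matching the naming convention, segments
#' nuclei on DAPI, detects and classifies marker foci, computes the
#' per-cell features and writes one CSV row per retained nucleus with
#' the well metadata from the layout. Wells present on disk but
#' absent from the layout are skipped with a warning; unreadable
#' files are a hard error.
#'
#' @param images_dir Directory of field TIFFs.
#' @param layout A [plate_layout()] (restricting the layout restricts
#'   the output).
#' @param models Named list per marker of [fld_train()] models.
#' @param out_csv Output CSV path (optional).
#' @param seg_params,spot_params Segmentation / detection parameters.
#' @param pixel_size_um Pixel size of the images.
#' @return The per-cell data.frame, invisibly if `out_csv` is given.
#' @export
run_quantify <- function(images_dir, layout, models, out_csv = NULL,
                         seg_params = segmentation_params(),
                         spot_params = spot_detection_params(),
                         pixel_size_um = 0.216) {
  files <- list.files(images_dir, pattern = "\\.tif$", full.names = TRUE)
  if (!length(files)) stop("no fields found in '", images_dir, "'",
                           call. = FALSE)
  meta <- lapply(files, parse_field_filename)
  wells_on_disk <- unique(vapply(meta, `[[`, "", "well_id"))
  unknown <- setdiff(wells_on_disk, names(layout$wells))
  if (length(unknown)) {
    warning("skipping well(s) not in layout: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    keep <- vapply(meta, function(m) !(m$well_id %in% unknown), logical(1))
    files <- files[keep]; meta <- meta[keep]
  }
  if (!length(files))
    stop("no fields found for the wells in the layout", call. = FALSE)

  key <- vapply(meta, function(m) paste0(m$well_id, "_f", m$field_index), "")
  records <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    imgs <- list()
    for (i in sel) imgs[[meta[[i]]$channel]] <-
      read_channel_image(files[i], pixel_size_um = pixel_size_um)
    if (is.null(imgs$DAPI)) {
      warning("no DAPI image for ", k, "; skipped", call. = FALSE)
      next
    }
    lab <- segment_nuclei(imgs$DAPI, seg_params)
    spots <- list()
    for (marker in MARKERS) {
      if (is.null(imgs[[marker]]) || is.null(models[[marker]])) next
      cands <- detect_candidates(imgs[[marker]], lab, spot_params)
      cands <- fld_classify(models[[marker]], cands)
      spots[[marker]] <- cands[cands$accepted, , drop = FALSE]
    }
    rec <- compute_cell_features(imgs, lab, spots)
    if (nrow(rec)) {
      wm <- layout$wells[[rec$well_id[1]]]
      rec$donor_id <- wm$donor_id; rec$cell_type <- wm$cell_type
      rec$treatment <- wm$treatment
      rec$treatment_dose_uM <- wm$treatment_dose_uM
      rec$replicate <- wm$replicate
      records[[k]] <- rec
    }
    log_info("quantify: %s -> %d cells", k, nrow(rec))
  }
  cells <- if (length(records)) do.call(rbind, records) else {
    tab <- empty_cell_table()
    tab$donor_id <- character(0); tab$cell_type <- character(0)
    tab$treatment <- character(0); tab$treatment_dose_uM <- numeric(0)
    tab$replicate <- integer(0)
    tab
  }
  rownames(cells) <- NULL
  if (!is.null(out_csv)) {
    write_cell_table(cells, out_csv)
    write_manifest(
      file.path(dirname(out_csv), "manifest_quantify.json"), "quantify",
      seed = NA,
      outputs = basename(out_csv),
      counts = list(fields = length(unique(key)), cells = nrow(cells)))
    return(invisible(cells))
  }
  cells
}

#' Statistical report for a per-cell table
#'
#' Derives per-marker negative-control thresholds (mean + 1 SD of the
#' control condition, pooled across its replicate wells), compares
#' every treated condition against the control ([compare_conditions()]),
#' runs the inter-replicate one-way ANOVA per treatment group when a
#' `replicate` column is present, computes per-condition dual-marker
#' KDE grids, and writes `report.json` plus box/contour plots.
#'
#' @param cells Per-cell data.frame (or CSV path) with a `treatment`
#'   column and the marker feature columns.
#' @param control Negative-control treatment label (default `"DMSO"`,
#'   falling back to `"UNTREATED"` when absent).
#' @param out_dir Optional output directory for the JSON report and
#'   plots.
#' @return List of class `stats_report`.
#' @export
run_stats <- function(cells, control = "DMSO", out_dir = NULL) {
  if (is.character(cells) && length(cells) == 1L)
    cells <- read_cell_table(cells)
  if (is.null(cells$treatment))
    stop("cell table lacks the 'treatment' column", call. = FALSE)
  conds <- unique(cells$treatment)
  if (!(control %in% conds)) {
    if (identical(control, "DMSO") && "UNTREATED" %in% conds) {
      control <- "UNTREATED"
    } else {
      stop("control condition '", control, "' not present (found: ",
           paste(conds, collapse = ", "), ")", call. = FALSE)
    }
  }
  ctrl <- cells[cells$treatment == control, , drop = FALSE]
  thresholds <- list()
  for (marker in MARKERS)
    thresholds[[marker]] <-
      compute_threshold(ctrl[[marker_feature(marker)]], marker)

  comparisons <- list()
  for (cond in setdiff(conds, control)) {
    tr <- cells[cells$treatment == cond, , drop = FALSE]
    comparisons[[cond]] <- compare_conditions(ctrl, tr, thresholds)
    log_info("stats: %s vs %s (n = %d vs %d)", cond, control,
             nrow(tr), nrow(ctrl))
  }

  anova <- list()
  if (!is.null(cells$replicate)) {
    for (cond in conds) {
      sub <- cells[cells$treatment == cond, , drop = FALSE]
      reps <- split(sub, sub$replicate)
      if (length(reps) >= 2L &&
          all(vapply(reps, nrow, integer(1)) >= 2L)) {
        anova[[cond]] <- list()
        for (marker in MARKERS) {
          groups <- lapply(reps, function(r) r[[marker_feature(marker)]])
          anova[[cond]][[marker]] <- anova_oneway(groups)
        }
      }
    }
  }

  kde <- list()
  for (cond in conds) {
    sub <- cells[cells$treatment == cond, , drop = FALSE]
    kde[[cond]] <- tryCatch(
      kde2d_grid(sub$sum_spot_53BP1, sub$mean_nuclear_gH2AX, n_grid = 96L),
      error = function(e) NULL)
  }

  report <- structure(list(control = control, thresholds = thresholds,
                           comparisons = comparisons, anova = anova,
                           kde = kde,
                           n_cells = nrow(cells)),
                      class = "stats_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_stats_report(report, file.path(out_dir, "report.json"))
    plot_stats_report(cells, report, out_dir)
  }
  report
}

# Numeric JSON view of the report (KDE grids summarised by their
# mode; plots carry the full grids).
write_stats_report <- function(report, path) {
  cmp_json <- lapply(report$comparisons, function(cmp) {
    lapply(cmp$markers, function(m) list(
      feature = m$feature,
      wilcoxon_U = m$wilcoxon$statistic,
      wilcoxon_p = m$wilcoxon$p_value,
      wilcoxon_p_display = format_p(m$wilcoxon$p_value),
      threshold = m$threshold$threshold,
      positive_fraction_control = m$positive_fraction_control,
      positive_fraction_treated = m$positive_fraction_treated,
      chi2 = if (!is.null(m$chi2)) m$chi2$statistic else NULL,
      chi2_p = if (!is.null(m$chi2)) m$chi2$p_value else NULL,
      delta_median = m$delta_median))
  })
  anova_json <- lapply(report$anova, function(by_marker)
    lapply(by_marker, function(a) list(
      f_statistic = a$f_statistic, df_between = a$df_between,
      df_within = a$df_within, p_value = a$p_value,
      degenerate = a$degenerate)))
  kde_json <- lapply(report$kde, function(k) {
    if (is.null(k)) return(NULL)
    peak <- which(k$z == max(k$z), arr.ind = TRUE)[1, ]
    list(mode_x = k$x[peak[1]], mode_y = k$y[peak[2]],
         bandwidth = k$bandwidth)
  })
  jsonlite::write_json(
    list(control = report$control, n_cells = report$n_cells,
         thresholds = lapply(report$thresholds, unclass),
         comparisons = cmp_json, anova = anova_json, kde = kde_json),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# Base-graphics artifacts: per-marker box plots and the dual-marker
# density contours. Plots are diagnostics; report.json is the
# contract.
plot_stats_report <- function(cells, report, out_dir) {
  for (marker in MARKERS) {
    feat <- marker_feature(marker)
    png(file.path(out_dir, paste0("box_", marker, ".png")),
        width = 640, height = 480)
    boxplot(cells[[feat]] ~ cells$treatment, xlab = "treatment",
            ylab = feat, main = paste(marker, "by treatment"),
            col = "grey85")
    dev.off()
  }
  valid <- Filter(Negate(is.null), report$kde)
  if (length(valid) >= 1L) {
    png(file.path(out_dir, "kde2d_contours.png"), width = 640, height = 560)
    xr <- range(unlist(lapply(valid, `[[`, "x")))
    yr <- range(unlist(lapply(valid, `[[`, "y")))
    cols <- hcl.colors(length(valid), "Dark 2")
    plot(NA, xlim = xr, ylim = yr, xlab = "53BP1 sum spot intensity (A.U.)",
         ylab = "gH2AX mean nuclear intensity (A.U.)",
         main = "dual-marker kernel density")
    for (i in seq_along(valid))
      contour(valid[[i]]$x, valid[[i]]$y, valid[[i]]$z, add = TRUE,
              col = cols[i], drawlabels = FALSE, nlevels = 6)
    legend("topright", legend = names(valid), col = cols, lty = 1)
    dev.off()
  }
  invisible(NULL)
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %d cells, control = %s\n", x$n_cells,
              x$control))
  for (cond in names(x$comparisons)) {
    cat(sprintf(" %s vs %s:\n", cond, x$control))
    print(x$comparisons[[cond]])
  }
  for (cond in names(x$anova)) {
    for (marker in names(x$anova[[cond]])) {
      a <- x$anova[[cond]][[marker]]
      cat(sprintf(
        "  inter-replicate ANOVA %s/%s: F(%g, %g) = %.3g, p %s\n",
        cond, marker, a$df_between, a$df_within, a$f_statistic,
        format_p(a$p_value)))
    }
  }
  invisible(x)
}
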