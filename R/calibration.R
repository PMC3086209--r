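#' Spatial calibration from a stage micrometer
#'
#' Converts a pixel count spanning a known stage-micrometer distance into a
#' micrometers-per-pixel scale, the spatial calibration of the optical /
#' digital chain at one magnification setting.
#'
#' @param pixel_count number of pixels between the marked positions (> 0).
#' @param known_distance_um the marked distance in micrometers (> 0).
#' @param source free-text provenance of the measurement.
#' @return An object of class `"spatial_calibration"` with field
#'   `um_per_pixel`.
#' @examples
#' spatial_calibration(1000, 305)$um_per_pixel   # 0.305 um/px
#' spatial_calibration(1000, 1110)$um_per_pixel  # 1.11 um/px
#' @export
spatial_calibration <- function(pixel_count, known_distance_um,
                                source = "stage micrometer") {
  stopifnot_scalar_num(pixel_count, "pixel_count", positive = TRUE)
  stopifnot_scalar_num(known_distance_um, "known_distance_um", positive = TRUE)
  structure(
    list(um_per_pixel = known_distance_um / pixel_count, source = source),
    class = "spatial_calibration"
  )
}

#' @export
print.spatial_calibration <- function(x, ...) {
  cat(sprintf("<spatial_calibration> %.6g um/px (%s)\n",
              x$um_per_pixel, x$source))
  invisible(x)
}

#' Assemble a step-wedge measurement from known step statistics
#'
#' Builds the per-step mean/sd record that [pooled_linearity()] consumes,
#' for cases where the step statistics come from outside this package (e.g.
#' a spreadsheet). [wedge_step_means()] produces the same structure from an
#' image.
#'
#' @param means per-step mean grayscale, thinnest step first (index 0).
#' @param sds per-step standard deviations (same length; default 0).
#' @param wedge_id identifier of the physical wedge (repeats of the same
#'   wedge are averaged by [pooled_linearity()]).
#' @param radiograph_id identifier of the radiograph.
#' @return An object of class `"wedge_measurement"`.
#' @export
wedge_measurement <- function(means, sds = rep(0, length(means)),
                              wedge_id = NA_character_,
                              radiograph_id = NA_character_) {
  if (length(means) < 3L) err_validation("a step wedge needs at least 3 steps")
  if (length(sds) != length(means)) {
    err_validation("`sds` must match `means` in length")
  }
  structure(
    list(step = seq_along(means) - 1L, mean = as.numeric(means),
         sd = as.numeric(sds), wedge_id = wedge_id,
         radiograph_id = radiograph_id),
    class = "wedge_measurement"
  )
}

#' Per-step grayscale statistics of a step-wedge radiograph
#'
#' Computes the arithmetic mean and the population standard deviation
#' (divide by n: the sd describes the noise of a fixed region) of the pixel
#' values inside each step ROI.
#'
#' @param image a [radiograph()].
#' @param step_rois list of [roi()], one per step, thinnest step first;
#'   must be disjoint and inside the raster.
#' @inheritParams wedge_measurement
#' @return A `"wedge_measurement"` object.
#' @export
wedge_step_means <- function(image, step_rois, wedge_id = NA_character_,
                             radiograph_id = NA_character_) {
  if (!inherits(image, "radiograph")) {
    err_validation("`image` must be a radiograph")
  }
  if (length(step_rois) < 3L) err_validation("a step wedge needs at least 3 steps")
  for (r in step_rois) check_roi_in(r, image)
  for (i in seq_along(step_rois)) {
    for (j in seq_len(i - 1L)) {
      a <- step_rois[[i]]
      b <- step_rois[[j]]
      overlap <- a$row_start < b$row_end && b$row_start < a$row_end &&
        a$col_start < b$col_end && b$col_start < a$col_end
      if (overlap) {
        err_validation(sprintf("step ROIs %d and %d overlap", j - 1L, i - 1L))
      }
    }
  }
  px <- lapply(step_rois, function(r) as.numeric(roi_pixels(image, r)))
  wedge_measurement(
    means = vapply(px, mean, numeric(1)),
    sds = vapply(px, sd_pop, numeric(1)),
    wedge_id = wedge_id,
    radiograph_id = radiograph_id
  )
}

#' Two-point normalization of a step-wedge measurement
#'
#' Applies the affine map taking the mean grayscale of the low anchor step to
#' `target_low_pct` and of the high anchor step to `target_high_pct`
#' (defaults 20% and 80%, chosen interior to the scale because film response
#' is expected to be non-linear at the extremes). Because brightness and
#' contrast act as intercept and slope on the raw grayscale, this
#' normalization cancels them exactly: any positive affine transform of the
#' raw values leaves the output unchanged.
#'
#' @param entry a [wedge_measurement()].
#' @param anchor_low_step,anchor_high_step 0-based step indices of the
#'   anchors.
#' @param target_low_pct,target_high_pct anchor targets on the percent scale.
#' @return Numeric vector of normalized per-step values (percent scale);
#'   anchors map exactly, other steps may fall outside `[0, 100]`.
#' @export
normalize_wedge <- function(entry, anchor_low_step, anchor_high_step,
                            target_low_pct = 20, target_high_pct = 80) {
  if (!inherits(entry, "wedge_measurement")) {
    err_validation("`entry` must be a wedge_measurement")
  }
  n <- length(entry$mean)
  for (a in c(anchor_low_step, anchor_high_step)) {
    if (a < 0 || a >= n) {
      err_validation(sprintf("anchor step %d outside 0..%d", a, n - 1L))
    }
  }
  m_lo <- entry$mean[anchor_low_step + 1L]
  m_hi <- entry$mean[anchor_high_step + 1L]
  if (m_lo == m_hi) {
    err_degenerate("anchor steps have equal mean grayscale; cannot normalize")
  }
  if (m_lo > m_hi) {
    err_polarity(paste(
      "low anchor is brighter than high anchor; check film polarity",
      "or anchor order"
    ))
  }
  target_low_pct +
    (entry$mean - m_lo) / (m_hi - m_lo) * (target_high_pct - target_low_pct)
}

#' Pooled step-wedge linearity assessment
#'
#' Normalizes every radiograph's wedge measurement independently at the
#' anchor steps, averages repeat measurements of the same physical wedge per
#' step, then fits a least-squares line of averaged normalized value against
#' step index over the points whose averaged value lies within
#' `[range_lo_pct, range_hi_pct]` (default 10--90%, the region where linear
#' film response is expected). The report's r-squared is the squared Pearson
#' correlation of those points; the pass flag compares it against
#' `r2_threshold`.
#'
#' @param series list of [wedge_measurement()] objects (all with the same
#'   step count; grouped for averaging by their `wedge_id`).
#' @inheritParams normalize_wedge
#' @param range_lo_pct,range_hi_pct evaluation range bounds, percent.
#' @param r2_threshold r-squared needed for the pass flag; default 0.9959.
#' @return An object of class `"wedge_linearity"`: fit slope/intercept,
#'   `r_squared`, per-step grand means and across-wedge standard deviations
#'   (sample sd, n-1), the per-wedge averaged step values, and `pass`.
#' @export
pooled_linearity <- function(series, anchor_low_step, anchor_high_step,
                             target_low_pct = 20, target_high_pct = 80,
                             range_lo_pct = 10, range_hi_pct = 90,
                             r2_threshold = 0.9959) {
  if (inherits(series, "wedge_measurement")) series <- list(series)
  if (length(series) < 1L) err_validation("empty step-wedge series")
  ns <- vapply(series, function(e) length(e$mean), integer(1))
  if (length(unique(ns)) != 1L) {
    err_validation("all radiographs in a series must share the step count")
  }
  n_steps <- ns[1]
  if (length(series) < 2L) {
    warning("single radiograph: linearity computed without pooling")
  }

  norm <- lapply(series, normalize_wedge, anchor_low_step = anchor_low_step,
                 anchor_high_step = anchor_high_step,
                 target_low_pct = target_low_pct,
                 target_high_pct = target_high_pct)
  ids <- vapply(seq_along(series), function(i) {
    id <- series[[i]]$wedge_id
    if (is.na(id)) sprintf(".radiograph_%d", i) else as.character(id)
  }, character(1))
  wedges <- unique(ids)
  # average repeat measurements of the same wedge, per step
  by_wedge <- t(vapply(
    wedges,
    function(w) colMeans(do.call(rbind, norm[ids == w])),
    numeric(n_steps)
  ))
  rownames(by_wedge) <- wedges

  step_idx <- rep(seq_len(n_steps) - 1L, each = nrow(by_wedge))
  value <- as.vector(by_wedge)
  in_range <- value >= range_lo_pct & value <= range_hi_pct
  if (length(unique(step_idx[in_range])) < 3L) {
    err_insufficient(sprintf(
      "fewer than 3 steps fall inside the %g-%g%% evaluation range",
      range_lo_pct, range_hi_pct
    ))
  }
  x <- step_idx[in_range]
  y <- value[in_range]
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- stats::cor(x, y)^2

  structure(
    list(
      slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      r_squared = r2,
      range_lo_pct = range_lo_pct,
      range_hi_pct = range_hi_pct,
      anchor_low_step = anchor_low_step,
      anchor_high_step = anchor_high_step,
      target_low_pct = target_low_pct,
      target_high_pct = target_high_pct,
      step_means = colMeans(by_wedge),
      step_sds = apply(by_wedge, 2, function(v) {
        if (length(v) > 1L) stats::sd(v) else 0
      }),
      by_wedge = by_wedge,
      n_points_fit = sum(in_range),
      r2_threshold = r2_threshold,
      pass = r2 >= r2_threshold
    ),
    class = "wedge_linearity"
  )
}

#' @export
print.wedge_linearity <- function(x, ...) {
  cat("<wedge_linearity>\n")
  cat(sprintf("  wedges: %d, steps: %d, fit points in [%g, %g]%%: %d\n",
              nrow(x$by_wedge), length(x$step_means),
              x$range_lo_pct, x$range_hi_pct, x$n_points_fit))
  cat(sprintf("  normalized value = %.4f + %.4f * step index\n",
              x$intercept, x$slope))
  cat(sprintf("  r-squared = %.6f (threshold %.4f): %s\n",
              x$r_squared, x$r2_threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
coef.wedge_linearity <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.wedge_linearity <- function(x, ...) {
  steps <- seq_along(x$step_means) - 1L
  graphics::matplot(steps, t(x$by_wedge), pch = 1, col = "grey50",
                    xlab = "step index (thinnest first)",
                    ylab = "normalized grayscale (%)",
                    main = sprintf("Step-wedge linearity, r^2 = %.4f",
                                   x$r_squared), ...)
  graphics::points(steps, x$step_means, pch = 19)
  graphics::arrows(steps, x$step_means - x$step_sds,
                   steps, x$step_means + x$step_sds,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::abline(h = c(x$range_lo_pct, x$range_hi_pct), lty = 3)
  invisible(x)
}

#' Read step ROIs from CSV
#'
#' Reads a table with columns `step_index`, `row_start`, `row_end`,
#' `col_start`, `col_end` (0-based, half-open) into a list of [roi()]
#' objects ordered by step index.
#'
#' @param path CSV path.
#' @return List of [roi()] objects.
#' @export
read_step_rois_csv <- function(path) {
  if (!file.exists(path)) err_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("step_index", "row_start", "row_end", "col_start", "col_end")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    err_schema(sprintf("step ROI CSV missing column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  df <- df[order(df$step_index), ]
  lapply(seq_len(nrow(df)), function(i) {
    roi(df$row_start[i], df$row_end[i], df$col_start[i], df$col_end[i])
  })
}

write_step_rois_csv <- function(rois, path) {
  df <- data.frame(
    step_index = seq_along(rois) - 1L,
    row_start = vapply(rois, `[[`, integer(1), "row_start"),
    row_end = vapply(rois, `[[`, integer(1), "row_end"),
    col_start = vapply(rois, `[[`, integer(1), "col_start"),
    col_end = vapply(rois, `[[`, integer(1), "col_end")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
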