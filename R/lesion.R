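#' Fit the surface mineral gradient of a normalized profile
#'
#' Least-squares line through the contiguous run of samples on the
#' outermost (first, exterior-most) rising edge whose values lie within the
#' fit band (default 25--75% mineral density, comfortably inside the film's
#' 10--90% linear range). Positions are in micrometers, so the slope is in
#' percent mineral density per micrometer and must come out positive.
#'
#' @param profile a normalized (percent) calibrated [density_profile()].
#' @param band_lo_pct,band_hi_pct fit band bounds, percent.
#' @return An object of class `"gradient_fit"`: `slope` (%/um),
#'   `intercept` (% at position 0 um), `n_points`, `rms` residual, band.
#' @export
fit_surface_gradient <- function(profile, band_lo_pct = 25, band_hi_pct = 75) {
  if (!inherits(profile, "density_profile") || profile$units != "percent") {
    err_validation("`profile` must be a normalized (percent) density_profile")
  }
  if (band_lo_pct >= band_hi_pct) {
    err_validation("need band_lo_pct < band_hi_pct")
  }
  x <- profile_positions_um(profile)
  v <- profile$values
  # outermost maximal run of >= 3 consecutive in-band samples; step edges
  # (e.g. a grid bar shooting straight past the band) give shorter runs and
  # are skipped
  in_band <- v >= band_lo_pct & v <= band_hi_pct
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 3L)
  if (length(runs) == 0L) {
    err_insufficient(sprintf(
      "no rising edge with >= 3 consecutive samples in the %g-%g%% band (longest run: %d)",
      band_lo_pct, band_hi_pct,
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    ))
  }
  sel <- starts[runs[1]]:ends[runs[1]]
  fit <- stats::lm.fit(cbind(1, x[sel]), v[sel])
  slope <- unname(fit$coefficients[2])
  if (slope <= 0) {
    err_polarity("fitted surface gradient is not rising; check profile direction")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(fit$coefficients[1]),
      band_lo_pct = band_lo_pct,
      band_hi_pct = band_hi_pct,
      n_points = length(sel),
      rms = sqrt(mean(fit$residuals^2)),
      edge_start_um = x[sel[1]],
      edge_end_um = x[sel[length(sel)]]
    ),
    class = "gradient_fit"
  )
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<gradient_fit> slope %.4g %%/um over %d points in [%g, %g]%% (rms %.3g%%)\n",
    x$slope, x$n_points, x$band_lo_pct, x$band_hi_pct, x$rms
  ))
  invisible(x)
}

#' First threshold crossing of a profile
#'
#' Position (micrometers, sub-pixel by linear interpolation between the
#' bracketing samples) of the first exterior-to-interior crossing of
#' `level_pct` on the profile's outermost rising edge. If the very first
#' sample already sits at or above the level, its position is returned.
#'
#' @param profile a normalized, calibrated [density_profile()].
#' @param level_pct density level, percent.
#' @return Crossing position in micrometers.
#' @export
threshold_crossing <- function(profile, level_pct) {
  x <- profile_positions_um(profile)
  v <- profile$values
  if (v[1] >= level_pct) return(x[1])
  above <- which(v >= level_pct)
  if (length(above) == 0L) {
    err_no_crossing(sprintf(
      "profile never reaches %g%% (max %.3g%%)", level_pct, max(v)
    ))
  }
  i <- above[1]
  x[i - 1L] + (level_pct - v[i - 1L]) / (v[i] - v[i - 1L]) * (x[i] - x[i - 1L])
}

#' Measure erosion from an aligned, normalized pair
#'
#' Erosion is the depth-axis distance between the before mineral gradient
#' line and the parallel line of the same slope passing through the after
#' profile's crossing of the erosion threshold (default 20% mineral
#' density): `erosion = x_after - x_before`, where `x_before` is where the
#' fitted before line attains the threshold (closed form) and `x_after` is
#' the interpolated threshold crossing of the after profile. Slightly
#' negative values -- the after surface appearing *outside* the before
#' surface by no more than the noise tolerance converted to micrometers --
#' are clamped to a zero-erosion call; larger negative values raise a
#' polarity/registration error rather than silently reporting surface gain.
#'
#' @param pair an [align_profiles()] result with both profiles normalized.
#' @param fit the [fit_surface_gradient()] of the before profile.
#' @param erosion_threshold_pct threshold, percent; default 20.
#' @param noise_tolerance_pct tolerance epsilon (percent density) for the
#'   zero-erosion call; default 2.
#' @return A list of class `"erosion_measurement"`: `erosion_um`, the raw
#'   (unclamped) distance, both crossing positions, and whether the value
#'   was clamped.
#' @export
measure_erosion <- function(pair, fit, erosion_threshold_pct = 20,
                            noise_tolerance_pct = 2) {
  check_normalized_pair(pair)
  if (!inherits(fit, "gradient_fit")) {
    err_validation("`fit` must be a gradient_fit of the before profile")
  }
  x_b <- (erosion_threshold_pct - fit$intercept) / fit$slope
  x_a <- threshold_crossing(pair$after, erosion_threshold_pct)
  raw <- x_a - x_b
  tol_um <- noise_tolerance_pct / fit$slope
  if (raw < -tol_um) {
    err_polarity(sprintf(
      paste("after surface lies %.3g um outside the before surface, beyond",
            "the %.3g um noise tolerance: registration or polarity fault"),
      -raw, tol_um
    ))
  }
  structure(
    list(
      erosion_um = max(raw, 0),
      raw_um = raw,
      x_before_um = x_b,
      x_after_um = x_a,
      threshold_pct = erosion_threshold_pct,
      clamped = raw < 0
    ),
    class = "erosion_measurement"
  )
}

#' Measure demineralization depth from an aligned, normalized pair
#'
#' Demineralization is mineral loss that penetrates deeper than the (possibly
#' eroded) surface without removing more than `demin_ceiling_pct` of the
#' mineral. The surface reference is the after profile's erosion-threshold
#' crossing. The mineral deficit is computed against the before profile
#' shifted inward by the measured erosion (pure erosion then leaves no
#' deficit beyond the shifted edge); the lesion front is the innermost
#' position where the deficit still exceeds the noise tolerance `epsilon`,
#' scanned interior to exterior. The reported front position is the
#' zero-deficit linear interpolation of the segment bracketing that
#' epsilon-crossing, which removes the `epsilon`-proportional bias that
#' reading the position at `epsilon` itself would carry. Depth is front
#' minus surface reference, clamped at 0.
#'
#' @param pair an [align_profiles()] result, both profiles normalized.
#' @param erosion_um measured erosion, micrometers (from
#'   [measure_erosion()]).
#' @param demin_ceiling_pct loss ceiling, percent: samples in the lesion
#'   zone whose after density falls below `100 - demin_ceiling_pct` are
#'   flagged as erosion-zone, not demineralization, in the per-sample mask.
#' @param noise_tolerance_pct deficit tolerance epsilon, percent; default 2.
#' @param report_depth_pct optionally also report the innermost position
#'   where the after density falls below this percentage (lesion depth at a
#'   stated percentage of demineralization).
#' @param erosion_threshold_pct threshold defining the surface reference.
#' @return A list of class `"demin_measurement"`: `demin_depth_um`,
#'   `lesion_front_um`, `surface_ref_um`, the erosion-zone sample mask, and
#'   `report_depth_um` (NA unless `report_depth_pct` is given and crossed).
#' @export
measure_demineralization <- function(pair, erosion_um,
                                     demin_ceiling_pct = 80,
                                     noise_tolerance_pct = 2,
                                     report_depth_pct = NULL,
                                     erosion_threshold_pct = 20) {
  check_normalized_pair(pair)
  stopifnot_scalar_num(erosion_um, "erosion_um")
  if (erosion_um < 0) err_validation("`erosion_um` must be >= 0")
  eps <- noise_tolerance_pct

  surface_ref <- threshold_crossing(pair$after, erosion_threshold_pct)
  x <- profile_positions_um(pair$after)
  v_after <- pair$after$values
  x_before <- profile_positions_um(pair$before)
  # before profile shifted inward by the measured erosion
  before_shifted <- stats::approx(
    x_before + erosion_um, pair$before$values, xout = x
  )$y
  ok <- !is.na(before_shifted)
  deficit <- before_shifted - v_after

  front <- NA_real_
  idx <- which(ok & deficit > eps)
  if (length(idx) > 0L) {
    j <- max(idx)
    if (j >= length(x)) {
      err_validation(
        "mineral deficit persists to the profile's interior end; profile too short"
      )
    }
    d1 <- deficit[j]
    d2 <- deficit[j + 1L]
    front <- if (d1 == d2) {
      mean(x[c(j, j + 1L)])
    } else {
      x[j] + d1 / (d1 - d2) * (x[j + 1L] - x[j])
    }
  }

  depth <- if (is.na(front)) 0 else max(0, front - surface_ref)

  lesion_zone <- ok & x >= surface_ref &
    (if (is.na(front)) rep(FALSE, length(x)) else x <= front)
  erosion_zone_mask <- lesion_zone & v_after < (100 - demin_ceiling_pct)

  report_depth <- NA_real_
  if (!is.null(report_depth_pct)) {
    below <- which(v_after < report_depth_pct)
    if (length(below) > 0L) {
      j <- max(below)
      report_depth <- if (j < length(x)) {
        v1 <- v_after[j]
        v2 <- v_after[j + 1L]
        if (v1 == v2) mean(x[c(j, j + 1L)])
        else x[j] + (report_depth_pct - v1) / (v2 - v1) * (x[j + 1L] - x[j])
      } else {
        x[j]
      }
    }
  }

  structure(
    list(
      demin_depth_um = depth,
      lesion_front_um = front,
      surface_ref_um = surface_ref,
      epsilon_pct = eps,
      demin_ceiling_pct = demin_ceiling_pct,
      erosion_zone_mask = erosion_zone_mask,
      report_depth_pct = if (is.null(report_depth_pct)) NA_real_
                         else report_depth_pct,
      report_depth_um = report_depth
    ),
    class = "demin_measurement"
  )
}

check_normalized_pair <- function(pair) {
  if (!inherits(pair, "aligned_profiles")) {
    err_validation("`pair` must be an aligned_profiles object")
  }
  if (pair$before$units != "percent" || pair$after$units != "percent") {
    err_validation("both profiles must be normalized to percent mineral density")
  }
  invisible(pair)
}

#' Classify a measurement as erosion, demineralization, both or neither
#'
#' @param erosion_um,demin_depth_um measured distances, micrometers (>= 0).
#' @param eps_distance_um distance below which a measurement counts as zero;
#'   default 1 um (callers typically pass twice the pixel pitch).
#' @return One of `"none"`, `"erosion-only"`, `"demineralization-only"`,
#'   `"mixed"`.
#' @examples
#' classify_lesion(11.3, 0)   # erosion-only
#' classify_lesion(0, 10.0)   # demineralization-only
#' @export
classify_lesion <- function(erosion_um, demin_depth_um, eps_distance_um = 1) {
  if (erosion_um < 0 || demin_depth_um < 0) {
    err_validation("distances must be >= 0")
  }
  e <- erosion_um >= eps_distance_um
  d <- demin_depth_um >= eps_distance_um
  if (e && d) "mixed"
  else if (e) "erosion-only"
  else if (d) "demineralization-only"
  else "none"
}

#' Measure a lesion from a before/after radiograph pair
#'
#' The full measurement chain: extract width-averaged profiles from the same
#' ROI of both images, detect grid-fiducial peaks, register the after
#' profile to the before profile, normalize both to percent mineral density
#' using the background and sound-enamel windows, estimate profile noise
#' from the sound window, fit the before surface gradient, and measure
#' erosion and demineralization depth.
#'
#' @param before,after [radiograph()] objects of the same specimen.
#' @param region [roi()] spanning exterior background, the lesion and sound
#'   enamel (profile taken along columns, averaged across rows).
#' @param background_window,sound_window `c(lo, hi)` pixel-position ranges
#'   on the before profile's axis anchoring 0% and 100% density. The span
#'   from the start of the background window to the end of the sound window
#'   is the analysis region: it must bracket the lesion and contain no grid
#'   bars (i.e. lie between two gridlines), as the bars' near-opaque peaks
#'   would otherwise masquerade as surface crossings.
#' @param pixel_pitch_um spatial calibration override; defaults to the
#'   images' stored calibration.
#' @param erosion_threshold_pct,demin_ceiling_pct,band_lo_pct,band_hi_pct
#'   measurement thresholds, percent; defaults 20, 80, 25, 75.
#' @param noise_tolerance_pct deficit tolerance epsilon; default
#'   `max(2, 3 * sd)` with `sd` the normalized sound-window noise.
#' @param eps_distance_um zero-call distance for classification; default
#'   twice the pixel pitch.
#' @param report_depth_pct optional density percentage at which to also
#'   report the lesion depth.
#' @param axis profile axis, `"col"` (default) or `"row"`.
#' @return An object of class `"lesion_measurement"` collecting the aligned
#'   normalized profiles, gradient fit, both distance measurements, the
#'   classification and every threshold used. Methods: `print`, `summary`,
#'   `coef` (erosion and depth in um), `plot`.
#' @export
measure_lesion <- function(before, after, region,
                           background_window, sound_window,
                           pixel_pitch_um = NULL,
                           erosion_threshold_pct = 20,
                           demin_ceiling_pct = 80,
                           band_lo_pct = 25, band_hi_pct = 75,
                           noise_tolerance_pct = NULL,
                           eps_distance_um = NULL,
                           report_depth_pct = NULL,
                           axis = "col") {
  if (!is.null(pixel_pitch_um)) {
    if (inherits(pixel_pitch_um, "spatial_calibration")) {
      pixel_pitch_um <- pixel_pitch_um$um_per_pixel
    }
    before$pixel_pitch_um <- pixel_pitch_um
    after$pixel_pitch_um <- pixel_pitch_um
  }
  if (is.null(before$pixel_pitch_um)) {
    err_validation("no spatial calibration: supply `pixel_pitch_um`")
  }
  pitch <- before$pixel_pitch_um
  if (is.null(eps_distance_um)) eps_distance_um <- 2 * pitch

  p_before <- extract_profile(before, region, axis = axis)
  p_after <- extract_profile(after, region, axis = axis)
  pk_before <- detect_grid_peaks(p_before)
  pk_after <- detect_grid_peaks(p_after)
  pair <- align_profiles(p_before, p_after, pk_before, pk_after)

  pair$before <- normalize_profile(pair$before, background_window, sound_window)
  pair$after <- normalize_profile(pair$after, background_window, sound_window)

  # confine the measurement to the bar-free span between the gridlines
  # bracketing the lesion: from the start of the background window to the
  # end of the sound window (the full profile was still used for peak
  # registration above)
  span <- c(background_window[1], sound_window[2])
  pair$before <- crop_profile(pair$before, span)
  pair$after <- crop_profile(pair$after, span)

  noise_sd <- estimate_noise(pair$before, sound_window)
  if (is.null(noise_tolerance_pct)) {
    noise_tolerance_pct <- max(2, 3 * noise_sd)
  }

  fit <- fit_surface_gradient(pair$before, band_lo_pct, band_hi_pct)
  ero <- measure_erosion(pair, fit, erosion_threshold_pct,
                         noise_tolerance_pct)
  dem <- measure_demineralization(pair, ero$erosion_um, demin_ceiling_pct,
                                  noise_tolerance_pct, report_depth_pct,
                                  erosion_threshold_pct)
  cls <- classify_lesion(ero$erosion_um, dem$demin_depth_um, eps_distance_um)

  structure(
    list(
      pair = pair,
      fit = fit,
      erosion = ero,
      demineralization = dem,
      classification = cls,
      pixel_pitch_um = pitch,
      noise_sd_pct = noise_sd,
      thresholds = list(
        erosion_threshold_pct = erosion_threshold_pct,
        demin_ceiling_pct = demin_ceiling_pct,
        band_lo_pct = band_lo_pct,
        band_hi_pct = band_hi_pct,
        noise_tolerance_pct = noise_tolerance_pct,
        eps_distance_um = eps_distance_um,
        report_depth_pct = if (is.null(report_depth_pct)) NA_real_
                           else report_depth_pct
      )
    ),
    class = "lesion_measurement"
  )
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat("<lesion_measurement>\n")
  cat(sprintf("  erosion:           %8.3f um\n", x$erosion$erosion_um))
  cat(sprintf("  demineralization:  %8.3f um\n",
              x$demineralization$demin_depth_um))
  cat(sprintf("  classification:    %s\n", x$classification))
  invisible(x)
}

#' @export
summary.lesion_measurement <- function(object, ...) {
  x <- object
  cat("Lesion measurement\n")
  cat(sprintf("  pixel pitch:        %.4g um/px\n", x$pixel_pitch_um))
  cat(sprintf("  registration:       %+d px (%d peaks, rms %.3g px)\n",
              x$pair$offset_px, x$pair$n_matched_peaks, x$pair$peak_rms_px))
  cat(sprintf("  surface gradient:   %.4g %%/um (%d points, rms %.3g%%)\n",
              x$fit$slope, x$fit$n_points, x$fit$rms))
  cat(sprintf("  sound-window noise: %.3g%% (epsilon %.3g%%)\n",
              x$noise_sd_pct, x$thresholds$noise_tolerance_pct))
  cat(sprintf("  erosion:            %.3f um (threshold %g%%)\n",
              x$erosion$erosion_um, x$thresholds$erosion_threshold_pct))
  cat(sprintf("  demineralization:   %.3f um (front %.2f um, surface %.2f um)\n",
              x$demineralization$demin_depth_um,
              x$demineralization$lesion_front_um,
              x$demineralization$surface_ref_um))
  if (!is.na(x$demineralization$report_depth_pct)) {
    cat(sprintf("  depth at %g%%:        %.3f um\n",
                x$demineralization$report_depth_pct,
                x$demineralization$report_depth_um))
  }
  cat(sprintf("  classification:     %s\n", x$classification))
  invisible(x)
}

#' @export
coef.lesion_measurement <- function(object, ...) {
  c(erosion_um = object$erosion$erosion_um,
    demin_depth_um = object$demineralization$demin_depth_um)
}

#' @export
plot.lesion_measurement <- function(x, ...) {
  xb <- profile_positions_um(x$pair$before)
  graphics::plot(xb, x$pair$before$values, type = "l",
                 xlab = "depth (um), exterior to interior",
                 ylab = "mineral density (%)",
                 main = sprintf("erosion %.2f um, demineralization %.2f um (%s)",
                                x$erosion$erosion_um,
                                x$demineralization$demin_depth_um,
                                x$classification), ...)
  graphics::lines(profile_positions_um(x$pair$after), x$pair$after$values,
                  col = "red")
  graphics::abline(h = x$thresholds$erosion_threshold_pct, lty = 3)
  graphics::abline(v = c(x$erosion$x_before_um, x$erosion$x_after_um,
                         x$demineralization$lesion_front_um),
                   lty = 2, col = c("black", "red", "blue"))
  graphics::legend("bottomright", c("before", "after"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Write a structured measurement report
#'
#' Emits a versioned JSON report with every threshold, tolerance,
#' calibration value, the registration offset and both distances in
#' micrometers and pixels, plus (optionally) a plot-ready CSV of both
#' normalized profiles on their common axis.
#'
#' @param measurement a [measure_lesion()] result.
#' @param json_path output path for the JSON report.
#' @param csv_path optional output path for the profiles CSV (columns
#'   `position_px`, `position_um`, `before_pct`, `after_pct`).
#' @return The report list, invisibly.
#' @export
measurement_report <- function(measurement, json_path, csv_path = NULL) {
  if (!inherits(measurement, "lesion_measurement")) {
    err_validation("`measurement` must be a lesion_measurement")
  }
  x <- measurement
  pitch <- x$pixel_pitch_um
  report <- list(
    schema = "microrad/measurement-report",
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("microrad")),
    pixel_pitch_um = pitch,
    registration_offset_px = x$pair$offset_px,
    n_matched_peaks = x$pair$n_matched_peaks,
    thresholds = x$thresholds,
    noise_sd_pct = x$noise_sd_pct,
    gradient = list(
      slope_pct_per_um = x$fit$slope,
      intercept_pct = x$fit$intercept,
      n_points = x$fit$n_points,
      rms_pct = x$fit$rms
    ),
    erosion_um = x$erosion$erosion_um,
    erosion_px = x$erosion$erosion_um / pitch,
    demin_depth_um = x$demineralization$demin_depth_um,
    demin_depth_px = x$demineralization$demin_depth_um / pitch,
    surface_ref_um = x$demineralization$surface_ref_um,
    lesion_front_um = x$demineralization$lesion_front_um,
    report_depth_pct = x$demineralization$report_depth_pct,
    report_depth_um = x$demineralization$report_depth_um,
    classification = x$classification
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    df <- data.frame(
      position_px = profile_positions_px(x$pair$before),
      position_um = profile_positions_um(x$pair$before),
      before_pct = x$pair$before$values,
      after_pct = x$pair$after$values
    )
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

#' Read and validate a measurement report
#'
#' @param path path to a JSON report written by [measurement_report()].
#' @return The report as a list; raises a schema error when required fields
#'   are absent or the schema identifier is wrong.
#' @export
read_measurement_report <- function(path) {
  if (!file.exists(path)) err_io(sprintf("file not found: %s", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema", "schema_version", "pixel_pitch_um",
                "registration_offset_px", "thresholds", "gradient",
                "erosion_um", "erosion_px", "demin_depth_um",
                "demin_depth_px", "classification")
  missing <- setdiff(required, names(rep))
  if (length(missing) > 0L) {
    err_schema(sprintf("report missing field(s): %s",
                       paste(missing, collapse = ", ")))
  }
  if (!identical(rep$schema, "microrad/measurement-report")) {
    err_schema(sprintf("unexpected schema identifier: %s", rep$schema))
  }
  rep
}
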