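#' Construct a density profile
#'
#' A 1-D sequence of width-averaged grayscale (or normalized percent mineral
#' density) values versus depth position, running from the exterior of the
#' tooth to its interior. Sample positions are implicit: sample `i`
#' (1-based) sits at pixel position `origin_px + i - 1`, and at
#' `(origin_px + i - 1) * um_per_pixel` micrometers when calibrated.
#'
#' @param values ordered numeric values, length >= 2.
#' @param origin_px 0-based pixel index of the first sample in the source
#'   image.
#' @param um_per_pixel optional spatial calibration (> 0), or a
#'   [spatial_calibration()] object.
#' @param units `"grayscale"` (raw) or `"percent"` (normalized mineral
#'   density).
#' @param axis raster axis the profile runs along: `"col"` (one value per
#'   column) or `"row"`.
#' @return An object of class `"density_profile"`.
#' @export
density_profile <- function(values, origin_px = 0, um_per_pixel = NULL,
                            units = c("grayscale", "percent"),
                            axis = c("col", "row")) {
  units <- match.arg(units)
  axis <- match.arg(axis)
  if (!is.numeric(values) || length(values) < 2L) {
    err_validation("a profile needs at least 2 numeric samples")
  }
  if (anyNA(values)) err_validation("profile contains missing values")
  if (inherits(um_per_pixel, "spatial_calibration")) {
    um_per_pixel <- um_per_pixel$um_per_pixel
  }
  if (!is.null(um_per_pixel)) {
    stopifnot_scalar_num(um_per_pixel, "um_per_pixel", positive = TRUE)
  }
  structure(
    list(values = as.numeric(values), origin_px = as.numeric(origin_px),
         um_per_pixel = um_per_pixel, units = units, axis = axis),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    "<density_profile> %d samples from px %g, %s%s\n",
    length(x$values), x$origin_px, x$units,
    if (is.null(x$um_per_pixel)) ", uncalibrated"
    else sprintf(", %.4g um/px", x$um_per_pixel)
  ))
  invisible(x)
}

#' @export
length.density_profile <- function(x) length(x$values)

#' @export
plot.density_profile <- function(x, ...) {
  if (is.null(x$um_per_pixel)) {
    graphics::plot(profile_positions_px(x), x$values, type = "l",
                   xlab = "position (px)", ylab = x$units, ...)
  } else {
    graphics::plot(profile_positions_um(x), x$values, type = "l",
                   xlab = "position (um), exterior to interior",
                   ylab = x$units, ...)
  }
  invisible(x)
}

#' Sample positions of a profile
#'
#' @param profile a [density_profile()].
#' @return `profile_positions_px()`: 0-based pixel positions;
#'   `profile_positions_um()`: micrometer positions (requires calibration).
#' @export
profile_positions_px <- function(profile) {
  profile$origin_px + seq_along(profile$values) - 1
}

#' @rdname profile_positions_px
#' @export
profile_positions_um <- function(profile) {
  if (is.null(profile$um_per_pixel)) {
    err_validation("profile carries no spatial calibration")
  }
  profile_positions_px(profile) * profile$um_per_pixel
}

# Mean of profile values whose pixel positions lie in [window[1], window[2]].
profile_window_values <- function(profile, window, what) {
  if (length(window) != 2L || window[1] > window[2]) {
    err_validation(sprintf("`%s` must be c(lo, hi) with lo <= hi", what))
  }
  pos <- profile_positions_px(profile)
  sel <- pos >= window[1] & pos <= window[2]
  if (!any(sel)) {
    err_validation(sprintf("`%s` [%g, %g] contains no profile samples",
                           what, window[1], window[2]))
  }
  profile$values[sel]
}

#' Extract a width-averaged grayscale profile from an ROI
#'
#' Averages the ROI's pixels across its perpendicular width to produce one
#' value per position along the chosen axis, emulating the profile-plot
#' operation of image-analysis software: `axis = "col"` yields one value per
#' column (the mean over the ROI's rows). Extraction commutes with image
#' transposition (transposed image, swapped axis: identical values).
#'
#' @param image a [radiograph()].
#' @param region a [roi()] inside the raster.
#' @param axis `"col"` (default; profile runs along columns) or `"row"`.
#' @return A raw-grayscale [density_profile()], calibrated if the image is.
#' @export
extract_profile <- function(image, region, axis = c("col", "row")) {
  axis <- match.arg(axis)
  if (!inherits(image, "radiograph")) {
    err_validation("`image` must be a radiograph")
  }
  px <- roi_pixels(image, region)
  if (axis == "col") {
    values <- colMeans(px)
    origin <- region$col_start
  } else {
    values <- rowMeans(px)
    origin <- region$row_start
  }
  if (length(values) < 2L) err_validation("profile axis length must be >= 2")
  density_profile(values, origin_px = origin,
                  um_per_pixel = image$pixel_pitch_um,
                  units = "grayscale", axis = axis)
}

#' Detect grid-fiducial peaks in a raw profile
#'
#' Finds the grayscale maxima produced by the near-opaque metal grid bars:
#' local maxima with prominence at least `min_prominence`, at least
#' `min_separation_px` apart. Each peak position is refined to the centroid
#' of its half-prominence plateau (sub-sample positions allowed); peaks
#' whose plateau touches the profile ends are discarded as truncated.
#'
#' @param profile a raw-grayscale [density_profile()].
#' @param min_separation_px minimum peak separation; default half the
#'   127-um grid pitch converted to pixels when the profile is calibrated,
#'   otherwise 1/10 of the profile length.
#' @param min_prominence minimum prominence; default one tenth of the
#'   profile's value range (bars rising above sound enamel stand well clear
#'   of this; grain noise on a width-averaged profile sits far below it).
#' @param grid_pitch_um grid pitch used for the default separation.
#' @return An object of class `"grid_peaks"`: `positions_px` (strictly
#'   increasing, in the profile's pixel coordinates) and `prominences`.
#'   Finding no peaks is not an error: both fields are then empty.
#' @export
detect_grid_peaks <- function(profile, min_separation_px = NULL,
                              min_prominence = NULL, grid_pitch_um = 127) {
  if (!inherits(profile, "density_profile")) {
    err_validation("`profile` must be a density_profile")
  }
  if (profile$units != "grayscale") {
    err_validation("peak detection expects a raw grayscale profile")
  }
  v <- profile$values
  n <- length(v)
  if (is.null(min_separation_px)) {
    min_separation_px <- if (!is.null(profile$um_per_pixel)) {
      0.5 * grid_pitch_um / profile$um_per_pixel
    } else {
      n / 10
    }
  }
  if (is.null(min_prominence)) {
    min_prominence <- 0.1 * (max(v) - min(v))
  }

  # candidate maxima as runs of equal value higher than both neighbors
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- which(
    (seq_len(k) == 1L | c(-Inf, r$values[-k]) < r$values) &
      (seq_len(k) == k | c(r$values[-1], -Inf) < r$values)
  )

  peaks <- list()
  for (ci in cand) {
    i0 <- starts[ci]
    i1 <- ends[ci]
    vp <- r$values[ci]
    # prominence: lowest point toward the nearest higher ground on each side
    left_min <- vp
    j <- i0 - 1L
    while (j >= 1L && v[j] <= vp) {
      left_min <- min(left_min, v[j])
      j <- j - 1L
    }
    right_min <- vp
    j <- i1 + 1L
    while (j <= n && v[j] <= vp) {
      right_min <- min(right_min, v[j])
      j <- j + 1L
    }
    prom <- vp - max(left_min, right_min)
    if (prom < min_prominence) next
    # half-prominence plateau centroid
    thr <- vp - 0.5 * prom
    a <- i0
    while (a > 1L && v[a - 1L] >= thr) a <- a - 1L
    b <- i1
    while (b < n && v[b + 1L] >= thr) b <- b + 1L
    if (a == 1L || b == n) next  # truncated at the profile boundary
    peaks[[length(peaks) + 1L]] <- c(pos = mean(a:b), prom = prom, value = vp)
  }

  if (length(peaks) == 0L) {
    return(structure(list(positions_px = numeric(0),
                          prominences = numeric(0)),
                     class = "grid_peaks"))
  }
  m <- do.call(rbind, peaks)
  # enforce minimum separation, keeping the most prominent peaks
  keep <- logical(0)
  ord <- order(-m[, "prom"], -m[, "value"])
  chosen <- numeric(0)
  sel <- rep(FALSE, nrow(m))
  for (i in ord) {
    if (all(abs(m[i, "pos"] - chosen) >= min_separation_px)) {
      sel[i] <- TRUE
      chosen <- c(chosen, m[i, "pos"])
    }
  }
  m <- m[sel, , drop = FALSE]
  ordpos <- order(m[, "pos"])
  structure(
    list(
      positions_px = unname(profile$origin_px + m[ordpos, "pos"] - 1),
      prominences = unname(m[ordpos, "prom"])
    ),
    class = "grid_peaks"
  )
}

#' @export
print.grid_peaks <- function(x, ...) {
  cat(sprintf("<grid_peaks> %d peak(s) at px: %s\n",
              length(x$positions_px),
              paste(signif(x$positions_px, 6), collapse = ", ")))
  invisible(x)
}

#' Register a before/after profile pair on grid peaks
#'
#' Chooses the integer pixel offset, applied to the after profile's
#' position origin, that best superposes the two profiles' grid-fiducial
#' peaks: candidate offsets are generated from all peak pairings, after
#' peaks are greedily matched one-to-one to the nearest before peak within
#' half the grid spacing, and the offset maximizing the number of matches
#' and then minimizing the summed squared peak distance is selected, ties
#' broken toward the smallest absolute offset. For a pure integer shift of a
#' noiseless image the recovery is exact.
#'
#' @param before,after raw or normalized [density_profile()]s on the same
#'   axis.
#' @param peaks_before,peaks_after [detect_grid_peaks()] results; detected
#'   with defaults when omitted.
#' @return An object of class `"aligned_profiles"`: `before` and `after`
#'   trimmed to their common position axis (the after origin shifted by the
#'   chosen offset), `offset_px`, number of matched peaks and their RMS
#'   residual.
#' @export
align_profiles <- function(before, after, peaks_before = NULL,
                           peaks_after = NULL) {
  if (is.null(peaks_before)) peaks_before <- detect_grid_peaks(before)
  if (is.null(peaks_after)) peaks_after <- detect_grid_peaks(after)
  pb <- peaks_before$positions_px
  pa <- peaks_after$positions_px
  if (length(pb) < 1L || length(pa) < 1L) {
    err_alignment(sprintf(
      "need at least one grid peak in each profile (found %d before, %d after)",
      length(pb), length(pa)
    ))
  }
  tol <- if (length(pb) >= 2L) 0.5 * min(diff(sort(pb))) else Inf

  candidates <- unique(round(rep(pb, each = length(pa)) - rep(pa, length(pb))))
  cand <- lapply(candidates, function(o) {
    shifted <- pa + o
    # greedy one-to-one matching, nearest pairs first
    d <- abs(outer(shifted, pb, "-"))
    pairs <- which(d <= tol, arr.ind = TRUE)
    if (nrow(pairs) > 0L) {
      pairs <- pairs[order(d[pairs]), , drop = FALSE]
    }
    sse <- 0
    nm <- 0L
    taken_a <- rep(FALSE, length(pa))
    taken_b <- rep(FALSE, length(pb))
    for (r in seq_len(nrow(pairs))) {
      ia <- pairs[r, 1]
      ib <- pairs[r, 2]
      if (taken_a[ia] || taken_b[ib]) next
      taken_a[ia] <- taken_b[ib] <- TRUE
      sse <- sse + d[ia, ib]^2
      nm <- nm + 1L
    }
    list(offset = as.integer(o), n_matched = nm, sse = sse,
         mse = if (nm > 0L) sse / nm else Inf)
  })
  cand <- Filter(function(cc) cc$n_matched > 0L, cand)
  best <- NULL
  if (length(cand) > 0L) {
    # A periodic fiducial makes every whole-pitch offset an almost equally
    # good match (peaks truncated at the image border can even give the
    # wrong pitch more matches). Candidates within 1/4 px^2 mean squared
    # distance of the best are therefore treated as ties and resolved
    # toward the smallest absolute offset, per the registration contract.
    mse_min <- min(vapply(cand, `[[`, numeric(1), "mse"))
    tied <- Filter(function(cc) cc$mse <= mse_min + 0.25, cand)
    ord <- order(vapply(tied, function(cc) abs(cc$offset), numeric(1)),
                 -vapply(tied, `[[`, integer(1), "n_matched"))
    best <- tied[[ord[1]]]
  }
  if (is.null(best) || best$n_matched == 0L) {
    err_alignment(sprintf(
      paste("no mutually consistent peak matching found;",
            "before peaks at %s, after peaks at %s"),
      paste(signif(pb, 6), collapse = ","),
      paste(signif(pa, 6), collapse = ",")
    ))
  }

  shifted_after <- after
  shifted_after$origin_px <- after$origin_px + best$offset
  trimmed <- trim_to_common_axis(before, shifted_after)
  structure(
    list(
      before = trimmed$a,
      after = trimmed$b,
      offset_px = best$offset,
      n_matched_peaks = best$n_matched,
      peak_rms_px = sqrt(best$sse / best$n_matched)
    ),
    class = "aligned_profiles"
  )
}

trim_to_common_axis <- function(a, b) {
  lo <- max(a$origin_px, b$origin_px)
  hi <- min(a$origin_px + length(a$values) - 1,
            b$origin_px + length(b$values) - 1)
  if (hi - lo + 1 < 2) err_alignment("profiles share fewer than 2 positions")
  cut <- function(p) {
    i0 <- lo - p$origin_px + 1
    i1 <- hi - p$origin_px + 1
    p$values <- p$values[i0:i1]
    p$origin_px <- lo
    p
  }
  list(a = cut(a), b = cut(b))
}

#' @export
print.aligned_profiles <- function(x, ...) {
  cat(sprintf(
    "<aligned_profiles> offset %+d px, %d matched peak(s), rms %.3g px, %d common samples\n",
    x$offset_px, x$n_matched_peaks, x$peak_rms_px, length(x$before$values)
  ))
  invisible(x)
}

#' Normalize a profile to percent mineral density
#'
#' Applies the affine map taking the mean over the background window (black
#' background outside the tooth) to 0% and the mean over the sound window
#' (unaffected enamel) to 100% mineral density. Grid-peak samples may exceed
#' 100% -- metal attenuates more than enamel -- and this is expected.
#' Because the map is two-point affine, it cancels any positive affine
#' transform of the raw grayscale (brightness/contrast differences between
#' radiographs) exactly, and it is idempotent when re-applied with the same
#' windows.
#'
#' @param profile a [density_profile()].
#' @param background_window,sound_window `c(lo, hi)` pixel-position ranges
#'   (inclusive, in the profile's position coordinates).
#' @return A percent-units [density_profile()] on the same positions.
#' @export
normalize_profile <- function(profile, background_window, sound_window) {
  bg <- mean(profile_window_values(profile, background_window,
                                   "background_window"))
  snd <- mean(profile_window_values(profile, sound_window, "sound_window"))
  if (bg == snd) {
    err_degenerate("background and sound window means are equal")
  }
  if (bg > snd) {
    err_polarity(paste(
      "background reads brighter than sound enamel; on a negative film",
      "mineral must read brighter -- check film orientation / polarity"
    ))
  }
  out <- profile
  out$values <- (profile$values - bg) / (snd - bg) * 100
  out$units <- "percent"
  out
}

#' Crop a profile to a position window
#'
#' Restricts a profile to the samples whose pixel positions lie in
#' `[window[1], window[2]]`. Used to confine lesion measurement to the
#' bar-free analysis span between gridlines: the full-width profile is
#' needed for peak registration, but gradient fitting and threshold
#' crossings must not run into the near-opaque grid bars.
#'
#' @param profile a [density_profile()].
#' @param window `c(lo, hi)` pixel-position range (inclusive).
#' @return The cropped [density_profile()].
#' @export
crop_profile <- function(profile, window) {
  v <- profile_window_values(profile, window, "window")
  if (length(v) < 2L) err_validation("cropped profile has fewer than 2 samples")
  pos <- profile_positions_px(profile)
  out <- profile
  out$values <- v
  out$origin_px <- min(pos[pos >= window[1]])
  out
}

#' Noise level of a profile window
#'
#' Sample standard deviation (n-1) of the profile values over a
#' user-designated flat window, used to set the noise tolerance for
#' zero-calls in lesion measurement.
#'
#' @param profile a [density_profile()].
#' @param window `c(lo, hi)` pixel-position range containing at least 8
#'   samples.
#' @return Standard deviation in the profile's units.
#' @export
estimate_noise <- function(profile, window) {
  v <- profile_window_values(profile, window, "window")
  if (length(v) < 8L) {
    err_validation(sprintf(
      "noise window must contain at least 8 samples (has %d)", length(v)
    ))
  }
  stats::sd(v)
}
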