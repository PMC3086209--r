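#' Construct a radiograph image object
#'
#' A digitized microradiograph: a 2-D non-negative integer raster together
#' with its grayscale bit depth and (optionally) the spatial calibration in
#' micrometers per pixel. Twelve-bit data, as produced by typical microscope
#' cameras, are stored in 16-bit containers with values 0--4095 and no
#' rescaling.
#'
#' @param pixels integer matrix (rows x columns), all values in
#'   `[0, 2^bit_depth - 1]`; at least 2 rows and 2 columns.
#' @param bit_depth one of 8, 12, 16.
#' @param pixel_pitch_um optional micrometers per pixel (positive), usually
#'   from [spatial_calibration()].
#' @return An object of class `"radiograph"`.
#' @examples
#' img <- radiograph(matrix(0:5, 2, 3), bit_depth = 8)
#' dim(img$pixels)
#' @export
radiograph <- function(pixels, bit_depth = 16L, pixel_pitch_um = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    err_validation("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    err_validation("raster must have at least 2 rows and 2 columns")
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    err_validation("`bit_depth` must be 8, 12 or 16")
  }
  if (anyNA(pixels)) err_validation("raster contains missing values")
  if (any(pixels < 0) || any(pixels != round(pixels))) {
    err_validation("raster values must be non-negative integers")
  }
  maxval <- 2^bit_depth - 1
  if (any(pixels > maxval)) {
    err_validation(sprintf(
      "raster values exceed 2^%d - 1 = %d (max found: %d)",
      bit_depth, maxval, max(pixels)
    ))
  }
  if (!is.null(pixel_pitch_um)) {
    stopifnot_scalar_num(pixel_pitch_um, "pixel_pitch_um", positive = TRUE)
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      bit_depth = as.integer(bit_depth),
      pixel_pitch_um = pixel_pitch_um
    ),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf(
    "<radiograph> %d x %d px, %d-bit, range [%d, %d]%s\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth,
    min(x$pixels), max(x$pixels),
    if (is.null(x$pixel_pitch_um)) ", uncalibrated"
    else sprintf(", %.4g um/px", x$pixel_pitch_um)
  ))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

#' Define a rectangular region of interest
#'
#' Indices are 0-based and half-open on both axes: the ROI covers pixel rows
#' `[row_start, row_end)` and columns `[col_start, col_end)`, matching how a
#' rectangular selection is dragged out in image-analysis software.
#'
#' @param row_start,row_end,col_start,col_end integer pixel indices,
#'   `start < end` on both axes.
#' @return An object of class `"roi"`.
#' @examples
#' roi(0, 64, 100, 300)  # 64 rows x 200 columns
#' @export
roi <- function(row_start, row_end, col_start, col_end) {
  v <- c(row_start = row_start, row_end = row_end,
         col_start = col_start, col_end = col_end)
  if (any(v != round(v))) err_validation("ROI bounds must be integers")
  if (!(row_start < row_end && col_start < col_end)) {
    err_validation("ROI must satisfy start < end on both axes")
  }
  if (row_start < 0 || col_start < 0) {
    err_validation("ROI bounds must be non-negative")
  }
  v <- as.integer(v)
  structure(
    list(row_start = v[1], row_end = v[2], col_start = v[3], col_end = v[4]),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf(
    "<roi> rows [%d, %d), cols [%d, %d)\n",
    x$row_start, x$row_end, x$col_start, x$col_end
  ))
  invisible(x)
}

check_roi_in <- function(r, image) {
  if (!inherits(r, "roi")) err_validation("expected an `roi` object")
  d <- dim(image$pixels)
  if (r$row_end > d[1] || r$col_end > d[2]) {
    err_validation(sprintf(
      "ROI rows [%d,%d) cols [%d,%d) exceeds raster %d x %d",
      r$row_start, r$row_end, r$col_start, r$col_end, d[1], d[2]
    ))
  }
  invisible(r)
}

roi_pixels <- function(image, r) {
  check_roi_in(r, image)
  image$pixels[(r$row_start + 1L):r$row_end, (r$col_start + 1L):r$col_end,
               drop = FALSE]
}

#' Read a grayscale TIFF microradiograph
#'
#' Reads an uncompressed single-channel grayscale TIFF (8- or 16-bit samples,
#' either byte order, stripped or tiled layout). Twelve-bit data stored in a
#' 16-bit container are recognized when all values are <= 4095 *and* either
#' the file's ImageDescription tag declares `bit_depth=12` (as written by
#' [write_image()]) or the caller passes `bit_depth = 12`.
#'
#' @param path path to the TIFF file.
#' @param bit_depth optional override declaring the true sample depth (e.g.
#'   12 for 12-bit data in 16-bit storage).
#' @return A [radiograph()] object. Pixel pitch is restored if present in the
#'   file's ImageDescription metadata.
#' @seealso [write_image()]
#' @export
read_image <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) err_io(sprintf("file not found: %s", path))
  tf <- tiff_read(path)
  depth <- tf$bits_per_sample
  desc <- parse_image_description(tf$description)
  if (!is.null(bit_depth)) {
    if (bit_depth == 12L && depth == 16L) {
      if (max(tf$pixels) > 4095L) {
        err_validation("cannot interpret as 12-bit: values exceed 4095")
      }
      depth <- 12L
    } else if (bit_depth != depth) {
      err_validation(sprintf(
        "requested bit depth %d incompatible with %d-bit samples",
        bit_depth, depth
      ))
    }
  } else if (!is.null(desc$bit_depth) && desc$bit_depth == 12L &&
             depth == 16L && max(tf$pixels) <= 4095L) {
    depth <- 12L
  }
  radiograph(tf$pixels, bit_depth = depth, pixel_pitch_um = desc$um_per_pixel)
}

#' Write a radiograph to an uncompressed grayscale TIFF
#'
#' Always writes little-endian, single-strip, uncompressed baseline TIFF.
#' Eight-bit images use 8-bit samples; 12- and 16-bit images use 16-bit
#' samples. The true bit depth and any pixel pitch are recorded in the
#' ImageDescription tag so that [read_image()] round-trips exactly.
#'
#' @param image a [radiograph()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "radiograph")) {
    err_validation("`image` must be a radiograph object")
  }
  # re-validate in case fields were mutated after construction
  radiograph(image$pixels, image$bit_depth, image$pixel_pitch_um)
  desc <- sprintf("microrad;bit_depth=%d", image$bit_depth)
  if (!is.null(image$pixel_pitch_um)) {
    desc <- sprintf("%s;um_per_pixel=%.12g", desc, image$pixel_pitch_um)
  }
  tiff_write(
    image$pixels,
    path,
    bits_per_sample = if (image$bit_depth == 8L) 8L else 16L,
    description = desc
  )
  invisible(path)
}

parse_image_description <- function(desc) {
  out <- list(bit_depth = NULL, um_per_pixel = NULL)
  if (is.null(desc) || !nzchar(desc)) return(out)
  parts <- strsplit(desc, ";", fixed = TRUE)[[1]]
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    if (kv[1] == "bit_depth") out$bit_depth <- as.integer(kv[2])
    if (kv[1] == "um_per_pixel") out$um_per_pixel <- as.numeric(kv[2])
  }
  out
}

#' Export a density profile to CSV
#'
#' Writes a comma-separated file with a header row and columns `position_px`,
#' `position_um` (only when the profile carries a spatial calibration) and
#' `value`, one row per profile sample, suitable for spreadsheet analysis.
#'
#' @param profile a [density_profile()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
export_profile_csv <- function(profile, path) {
  if (!inherits(profile, "density_profile")) {
    err_validation("`profile` must be a density_profile object")
  }
  px <- profile_positions_px(profile)
  df <- data.frame(position_px = px)
  if (!is.null(profile$um_per_pixel)) {
    df$position_um <- px * profile$um_per_pixel
  }
  df$value <- profile$values
  ok <- tryCatch(
    {
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) err_io(sprintf("cannot write CSV to %s", path))
  invisible(path)
}

#' Read a density profile from CSV
#'
#' Reads the dialect written by [export_profile_csv()]. Required columns are
#' `position_px` and `value`; `position_um`, when present, restores the
#' spatial calibration. Unknown extra columns are ignored with a warning.
#'
#' @param path path to the CSV file.
#' @param units unit label for the restored profile (the CSV itself does not
#'   record units); default `"grayscale"`.
#' @return A [density_profile()] object.
#' @export
read_profile_csv <- function(path, units = "grayscale") {
  if (!file.exists(path)) err_io(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, fileEncoding = "UTF-8"),
    error = function(e) err_schema(sprintf("cannot parse CSV %s: %s",
                                           path, conditionMessage(e)))
  )
  required <- c("position_px", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    err_schema(sprintf("CSV missing required column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  known <- c("position_px", "position_um", "value")
  extra <- setdiff(names(df), known)
  if (length(extra) > 0L) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  if (nrow(df) < 2L) err_schema("profile CSV must contain at least 2 samples")
  upp <- NULL
  if ("position_um" %in% names(df)) {
    upp <- (df$position_um[2] - df$position_um[1]) /
      (df$position_px[2] - df$position_px[1])
  }
  density_profile(
    values = df$value,
    origin_px = df$position_px[1],
    um_per_pixel = upp,
    units = units
  )
}
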