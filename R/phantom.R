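#' Film response model for synthetic radiographs
#'
#' Parameterizes the negative-film grayscale response to x-ray attenuation.
#' The film is linear (affine) for attenuation fractions between `linear_lo`
#' and `linear_hi` -- grayscale = intercept + slope * attenuation, so
#' brightness and contrast are exactly the intercept and slope -- and rolls
#' off smoothly outside that band, emulating reciprocity failure at the
#' lightest and darkest regions of the film. Grain is additive Gaussian
#' noise applied per pixel by the generators (not by [film_response()]).
#'
#' @param intercept brightness, grayscale units.
#' @param slope contrast, grayscale units per unit attenuation fraction;
#'   must be > 0 (negative-film polarity: more attenuation, i.e. more
#'   mineral, reads brighter on digitization).
#' @param linear_lo,linear_hi bounds of the linear response region as
#'   attenuation fractions in `[0, 1]`, defaults 0.10 and 0.90.
#' @param clip_softness roll-off scale (attenuation fraction units) outside
#'   the linear region; 0 gives a hard clip. Default 0.05.
#' @param noise_sd grain noise standard deviation, grayscale units.
#' @return An object of class `"film_model"`.
#' @examples
#' fm <- film_model(intercept = 300, slope = 3000)
#' film_response(c(0.2, 0.5, 0.8), fm)
#' @export
film_model <- function(intercept = 300, slope = 3000,
                       linear_lo = 0.10, linear_hi = 0.90,
                       clip_softness = 0.05, noise_sd = 0) {
  stopifnot_scalar_num(intercept, "intercept")
  stopifnot_scalar_num(slope, "slope", positive = TRUE)
  stopifnot_scalar_num(linear_lo, "linear_lo")
  stopifnot_scalar_num(linear_hi, "linear_hi")
  stopifnot_scalar_num(clip_softness, "clip_softness")
  stopifnot_scalar_num(noise_sd, "noise_sd")
  if (!(linear_lo >= 0 && linear_hi <= 1 && linear_lo < linear_hi)) {
    err_validation("need 0 <= linear_lo < linear_hi <= 1")
  }
  if (clip_softness < 0) err_validation("`clip_softness` must be >= 0")
  if (noise_sd < 0) err_validation("`noise_sd` must be >= 0")
  structure(
    list(intercept = intercept, slope = slope,
         linear_lo = linear_lo, linear_hi = linear_hi,
         clip_softness = clip_softness, noise_sd = noise_sd),
    class = "film_model"
  )
}

#' Expected grayscale for a given x-ray attenuation
#'
#' Applies the film characteristic curve: exactly affine
#' (`intercept + slope * a`) inside the linear region, with a smooth,
#' monotone, bounded exponential roll-off outside it, matched in value and
#' first derivative at the region bounds. No noise is added here.
#'
#' @param attenuation attenuation fraction(s), >= 0 (values above 1, e.g. 10
#'   for a metal grid bar, saturate near the upper roll-off bound).
#' @param film a [film_model()].
#' @return Expected grayscale value(s), same length as `attenuation`.
#' @export
film_response <- function(attenuation, film) {
  if (!inherits(film, "film_model")) err_validation("`film` must be a film_model")
  a <- attenuation
  lo <- film$linear_lo
  hi <- film$linear_hi
  s <- film$clip_softness
  r <- a
  if (s == 0) {
    r <- clamp(a, lo, hi)
  } else {
    below <- a < lo
    above <- a > hi
    r[below] <- lo - s * (1 - exp(-(lo - a[below]) / s))
    r[above] <- hi + s * (1 - exp(-(a[above] - hi) / s))
  }
  film$intercept + film$slope * r
}

#' Ground-truth lesion geometry for phantom radiographs
#'
#' The before-image mineral density rises linearly from 0 to 1 (fraction of
#' sound enamel) over an edge of width `edge_width_um` starting at
#' `surface_position_um`, measured exterior to interior. The after image may
#' translate that edge inward by `erosion_um` (erosion: bulk surface loss,
#' gradient preserved) and/or depress the density by up to `demin_severity`
#' at the new surface, recovering linearly to sound over `demin_depth_um`
#' (demineralization: partial subsurface loss).
#'
#' @param surface_position_um position of the before-image surface, um.
#' @param edge_width_um width of the surface density ramp, um (> 0).
#' @param erosion_um eroded depth, um (>= 0).
#' @param demin_depth_um demineralization lesion depth, um (>= 0).
#' @param demin_severity maximum fractional mineral loss in the lesion, in
#'   `[0, 0.8]`: by definition a loss exceeding 80% of sound mineral at the
#'   surface counts as erosion, not demineralization, so lesion density
#'   stays at or above 20% of sound.
#' @return An object of class `"lesion_truth"`.
#' @export
lesion_truth <- function(surface_position_um = 210, edge_width_um = 2,
                         erosion_um = 0, demin_depth_um = 0,
                         demin_severity = 0) {
  stopifnot_scalar_num(surface_position_um, "surface_position_um")
  stopifnot_scalar_num(edge_width_um, "edge_width_um", positive = TRUE)
  stopifnot_scalar_num(erosion_um, "erosion_um")
  stopifnot_scalar_num(demin_depth_um, "demin_depth_um")
  stopifnot_scalar_num(demin_severity, "demin_severity")
  if (erosion_um < 0) err_validation("`erosion_um` must be >= 0")
  if (demin_depth_um < 0) err_validation("`demin_depth_um` must be >= 0")
  if (demin_severity < 0 || demin_severity > 0.8) {
    err_validation("`demin_severity` must lie in [0, 0.8]")
  }
  structure(
    list(surface_position_um = surface_position_um,
         edge_width_um = edge_width_um,
         erosion_um = erosion_um,
         demin_depth_um = demin_depth_um,
         demin_severity = demin_severity),
    class = "lesion_truth"
  )
}

#' Ground-truth mineral density of the before image
#'
#' `d_b(x) = clamp((x - s) / w, 0, 1)` where `s` is the surface position and
#' `w` the edge width.
#'
#' @param x depth position(s), um, exterior to interior.
#' @param truth a [lesion_truth()].
#' @return Density fraction(s) in `[0, 1]`.
#' @export
mineral_density_before <- function(x, truth) {
  if (!inherits(truth, "lesion_truth")) {
    err_validation("`truth` must be a lesion_truth")
  }
  clamp((x - truth$surface_position_um) / truth$edge_width_um, 0, 1)
}

#' Ground-truth mineral density of the after image
#'
#' The before edge translated inward by the erosion depth `e`, multiplied by
#' a demineralization deficit that is largest (`1 - delta`) at the new
#' surface and recovers to 1 at depth `s + e + L`:
#' `d_a(x) = clamp((x - s - e)/w, 0, 1) * (1 - delta * clamp(1 - (x - s - e)/L, 0, 1))`
#' with the second factor equal to 1 when `L = 0`. Pure erosion is thus an
#' exact translation of the before profile; pure demineralization (`e = 0`)
#' a depressed profile recovering to sound at `s + L`.
#'
#' @inheritParams mineral_density_before
#' @return Density fraction(s) in `[0, 1]`.
#' @export
mineral_density_after <- function(x, truth) {
  if (!inherits(truth, "lesion_truth")) {
    err_validation("`truth` must be a lesion_truth")
  }
  s <- truth$surface_position_um
  e <- truth$erosion_um
  w <- truth$edge_width_um
  L <- truth$demin_depth_um
  delta <- truth$demin_severity
  edge <- clamp((x - s - e) / w, 0, 1)
  deficit <- if (L == 0) {
    rep(1, length(x))
  } else {
    1 - delta * clamp(1 - (x - s - e) / L, 0, 1)
  }
  edge * deficit
}

#' Specify a synthetic tooth-slab phantom
#'
#' Describes the stated world for a before/after pair of synthetic
#' radiographs of a 100-um tooth slab: a 1-D lesion geometry constant along
#' rows (so column-averaged profiles recover ground truth exactly up to
#' noise), a metal grid fiducial rendered as near-opaque vertical bars
#' parallel to the tooth surface, and a film model. Columns map to depth via
#' `pixel_pitch_um`; depth position of column `c` (0-based) is
#' `c * pixel_pitch_um`.
#'
#' @param rows,cols image dimensions in pixels.
#' @param pixel_pitch_um micrometers per pixel (> 0).
#' @param film a [film_model()].
#' @param lesion a [lesion_truth()].
#' @param grid_pitch_um grid period, um; default 127 (200-mesh TEM grid).
#' @param grid_bar_um grid bar width, um; default 24; must be narrower than
#'   the pitch.
#' @param grid_present logical; render the grid bars?
#' @param grid_phase_um depth position of the first bar's leading edge, um.
#' @param background_attenuation attenuation fraction of the background
#'   (outside the tooth); default 0.
#' @param sound_attenuation attenuation fraction of sound enamel; default
#'   0.8 (inside the film's linear region).
#' @param brightness_jitter,contrast_jitter fractional half-widths of the
#'   uniform per-radiograph jitter applied to the film intercept and slope
#'   (one draw of each per radiograph); default 0.
#' @param after_shift_px integer column shift of the entire after image
#'   (specimen repositioned on the digitizer stage); recovered by
#'   [align_profiles()].
#' @param bit_depth grayscale bit depth of generated images; default 12.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(rows = 96, cols = 1500, pixel_pitch_um = 0.305,
                         film = film_model(), lesion = lesion_truth(),
                         grid_pitch_um = 127, grid_bar_um = 24,
                         grid_present = TRUE, grid_phase_um = 40,
                         background_attenuation = 0, sound_attenuation = 0.8,
                         brightness_jitter = 0, contrast_jitter = 0,
                         after_shift_px = 0, bit_depth = 12L) {
  stopifnot_scalar_num(rows, "rows", positive = TRUE)
  stopifnot_scalar_num(cols, "cols", positive = TRUE)
  stopifnot_scalar_num(pixel_pitch_um, "pixel_pitch_um", positive = TRUE)
  stopifnot_scalar_num(grid_pitch_um, "grid_pitch_um", positive = TRUE)
  stopifnot_scalar_num(grid_bar_um, "grid_bar_um", positive = TRUE)
  stopifnot_scalar_num(after_shift_px, "after_shift_px")
  if (!inherits(film, "film_model")) err_validation("`film` must be a film_model")
  if (!inherits(lesion, "lesion_truth")) {
    err_validation("`lesion` must be a lesion_truth")
  }
  if (grid_bar_um >= grid_pitch_um) {
    err_validation("grid bars must be narrower than the grid pitch")
  }
  if (after_shift_px != round(after_shift_px)) {
    err_validation("`after_shift_px` must be an integer")
  }
  if (background_attenuation < 0 ||
      background_attenuation >= sound_attenuation) {
    err_validation("need 0 <= background_attenuation < sound_attenuation")
  }
  width_um <- cols * pixel_pitch_um
  extent <- lesion$surface_position_um + lesion$erosion_um +
    lesion$edge_width_um + lesion$demin_depth_um
  if (extent + 10 > width_um) {
    err_validation(sprintf(
      "lesion geometry (extends to %.1f um) does not fit in the %.1f um image",
      extent, width_um
    ))
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pixel_pitch_um = pixel_pitch_um, film = film, lesion = lesion,
         grid_pitch_um = grid_pitch_um, grid_bar_um = grid_bar_um,
         grid_present = isTRUE(grid_present), grid_phase_um = grid_phase_um,
         background_attenuation = background_attenuation,
         sound_attenuation = sound_attenuation,
         brightness_jitter = brightness_jitter,
         contrast_jitter = contrast_jitter,
         after_shift_px = as.integer(after_shift_px),
         bit_depth = as.integer(bit_depth)),
    class = "phantom_spec"
  )
}

# Attenuation profile at depth positions x (um) for one epoch.
phantom_attenuation <- function(spec, x, when = c("before", "after")) {
  when <- match.arg(when)
  d <- if (when == "before") {
    mineral_density_before(x, spec$lesion)
  } else {
    mineral_density_after(x, spec$lesion)
  }
  a <- spec$background_attenuation +
    (spec$sound_attenuation - spec$background_attenuation) * d
  if (spec$grid_present) {
    in_bar <- ((x - spec$grid_phase_um) %% spec$grid_pitch_um) < spec$grid_bar_um
    a[in_bar] <- 10  # metal: effectively opaque, far beyond the film scale
  }
  a
}

# Render one radiograph from a per-column expected-attenuation vector.
render_radiograph <- function(spec, attenuation_by_col) {
  film <- spec$film
  if (spec$brightness_jitter > 0 || spec$contrast_jitter > 0) {
    film$intercept <- film$intercept *
      (1 + stats::runif(1, -spec$brightness_jitter, spec$brightness_jitter))
    film$slope <- film$slope *
      (1 + stats::runif(1, -spec$contrast_jitter, spec$contrast_jitter))
  }
  g_col <- film_response(attenuation_by_col, film)
  g <- matrix(g_col, nrow = spec$rows, ncol = spec$cols, byrow = TRUE)
  if (film$noise_sd > 0) {
    g <- g + stats::rnorm(length(g), sd = film$noise_sd)
  }
  px <- clamp(round(g), 0, 2^spec$bit_depth - 1)
  radiograph(px, bit_depth = spec$bit_depth,
             pixel_pitch_um = spec$pixel_pitch_um)
}

#' Generate a before/after phantom radiograph pair
#'
#' Renders two synthetic radiographs of the same specimen from a
#' [phantom_spec()]: the before image uses the pristine density ramp, the
#' after image applies the spec's erosion/demineralization and optional
#' whole-image column shift (grid bars shift with the specimen). Per-image
#' brightness/contrast jitter and grain noise are drawn from the seeded RNG;
#' the output is fully determined by `spec` and `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return A list with elements `before` and `after` ([radiograph()]
#'   objects) and `truth` (the [lesion_truth()] used).
#' @examples
#' pair <- generate_tooth_pair(phantom_spec(cols = 800), seed = 1)
#' pair$before
#' @export
generate_tooth_pair <- function(spec, seed) {
  if (!inherits(spec, "phantom_spec")) {
    err_validation("`spec` must be a phantom_spec")
  }
  with_seed(seed, {
    x_before <- (seq_len(spec$cols) - 1) * spec$pixel_pitch_um
    x_after <- (seq_len(spec$cols) - 1 - spec$after_shift_px) *
      spec$pixel_pitch_um
    before <- render_radiograph(spec, phantom_attenuation(spec, x_before, "before"))
    after <- render_radiograph(spec, phantom_attenuation(spec, x_after, "after"))
    list(before = before, after = after, truth = spec$lesion)
  })
}

#' Generate a synthetic step-wedge radiograph
#'
#' Renders an image of `n_steps` horizontal bands, one per wedge step, each
#' with expected grayscale `film_response(attenuation)` plus optional
#' per-radiograph brightness/contrast jitter and grain noise. Step
#' attenuations must be strictly increasing (thinnest step first).
#'
#' @param step_attenuations strictly increasing attenuation fractions, one
#'   per step; at least 3 steps.
#' @param film a [film_model()].
#' @param shape `c(rows, cols)`; rows are split evenly among the steps.
#' @param seed integer RNG seed.
#' @param brightness_jitter,contrast_jitter fractional half-widths of the
#'   uniform jitter on film intercept/slope, one draw each per radiograph.
#' @param bit_depth grayscale bit depth; default 12.
#' @return A list with elements `image` (a [radiograph()]), `rois` (list of
#'   per-step [roi()], thinnest first) and `attenuations` (the truth).
#' @export
generate_step_wedge_image <- function(step_attenuations, film = film_model(),
                                      shape = c(50 * length(step_attenuations), 200),
                                      seed = NULL,
                                      brightness_jitter = 0,
                                      contrast_jitter = 0,
                                      bit_depth = 12L) {
  n_steps <- length(step_attenuations)
  if (n_steps < 3L) err_validation("a step wedge needs at least 3 steps")
  if (any(diff(step_attenuations) <= 0)) {
    err_validation("`step_attenuations` must be strictly increasing")
  }
  if (!inherits(film, "film_model")) err_validation("`film` must be a film_model")
  rows <- as.integer(shape[1])
  cols <- as.integer(shape[2])
  band_h <- rows %/% n_steps
  if (band_h < 1L) err_validation("image too short for the requested steps")
  with_seed(seed, {
    jfilm <- film
    if (brightness_jitter > 0 || contrast_jitter > 0) {
      jfilm$intercept <- jfilm$intercept *
        (1 + stats::runif(1, -brightness_jitter, brightness_jitter))
      jfilm$slope <- jfilm$slope *
        (1 + stats::runif(1, -contrast_jitter, contrast_jitter))
    }
    g <- matrix(0, nrow = rows, ncol = cols)
    rois <- vector("list", n_steps)
    for (i in seq_len(n_steps)) {
      r0 <- (i - 1L) * band_h
      r1 <- if (i == n_steps) rows else i * band_h
      g[(r0 + 1L):r1, ] <- film_response(step_attenuations[i], jfilm)
      rois[[i]] <- roi(r0, r1, 0L, cols)
    }
    if (jfilm$noise_sd > 0) {
      g <- g + stats::rnorm(length(g), sd = jfilm$noise_sd)
    }
    px <- clamp(round(g), 0, 2^bit_depth - 1)
    list(
      image = radiograph(px, bit_depth = bit_depth),
      rois = rois,
      attenuations = step_attenuations
    )
  })
}
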