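# Shared phantom "worlds" for the recovery experiments.
#
# Geometry (um): grid bars at [40,64], [167,191], [294,318], [421,445], ...;
# tooth surface at 210, inside the 103-um hole between bars 2 and 3;
# background window [194,207] (background, bar-free, adjacent to the
# surface); sound window [270,290] (sound enamel, before bar 3). The
# analysis span [194,290] contains no grid bars.

BG_WINDOW_UM <- c(194, 207)
SOUND_WINDOW_UM <- c(270, 290)
FULL_SCALE_12BIT <- 4095

um2px <- function(um, pitch) um / pitch

# Erosion world: maximum optical magnification, 0.305 um/px.
erosion_spec <- function(erosion_um, noise_sd = 0.01 * FULL_SCALE_12BIT,
                         edge_width_um = 2.5, cols = 1500,
                         after_shift_px = 0, demin_depth_um = 0,
                         demin_severity = 0) {
  phantom_spec(
    cols = cols, pixel_pitch_um = 0.305,
    film = film_model(noise_sd = noise_sd),
    lesion = lesion_truth(
      surface_position_um = 210, edge_width_um = edge_width_um,
      erosion_um = erosion_um, demin_depth_um = demin_depth_um,
      demin_severity = demin_severity
    ),
    after_shift_px = after_shift_px
  )
}

# Demineralization world: medium magnification, 1.11 um/px. The edge width
# is 5 px, the narrowest for which the before-gradient fit keeps >= 3
# samples in a widened 10-90% band at this coarse pitch.
demin_spec <- function(demin_depth_um, demin_severity,
                       noise_sd = 0.01 * FULL_SCALE_12BIT,
                       edge_width_um = 5.55, cols = 420) {
  phantom_spec(
    cols = cols, pixel_pitch_um = 1.11,
    film = film_model(noise_sd = noise_sd),
    lesion = lesion_truth(
      surface_position_um = 210, edge_width_um = edge_width_um,
      erosion_um = 0, demin_depth_um = demin_depth_um,
      demin_severity = demin_severity
    )
  )
}

measure_pair <- function(pair, spec, ...) {
  pitch <- spec$pixel_pitch_um
  measure_lesion(
    pair$before, pair$after,
    region = roi(16, 80, 0, spec$cols),
    background_window = um2px(BG_WINDOW_UM, pitch),
    sound_window = um2px(SOUND_WINDOW_UM, pitch),
    ...
  )
}

# Aligned pair assembled directly from two profiles on a common axis
# (bypassing peak registration), for ramp-level tests.
make_aligned <- function(before, after, offset_px = 0L) {
  structure(
    list(before = before, after = after, offset_px = as.integer(offset_px),
         n_matched_peaks = 0L, peak_rms_px = 0),
    class = "aligned_profiles"
  )
}

# Normalized (percent) ramp profile: 0 -> 100 over edge_width starting at
# surface_um, sampled at pixel positions.
ramp_profile <- function(n, pitch, surface_um, edge_width_um) {
  x <- (seq_len(n) - 1) * pitch
  v <- pmin(pmax((x - surface_um) / edge_width_um, 0), 1) * 100
  density_profile(v, origin_px = 0, um_per_pixel = pitch, units = "percent")
}
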