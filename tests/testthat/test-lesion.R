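test_that("surface gradient fit recovers exact ramps", {
  # exact ramp 0 -> 100 over 20 um at 0.5 um/px
  p <- ramp_profile(140, 0.5, surface_um = 20, edge_width_um = 20)
  fit <- fit_surface_gradient(p)
  expect_equal(fit$slope, 5, tolerance = 1e-9)   # 100% / 20 um
  expect_equal(fit$rms, 0, tolerance = 1e-9)
  expect_gte(fit$n_points, 3)
  # band choice is immaterial on an exact line
  fit2 <- fit_surface_gradient(p, 10, 90)
  fit3 <- fit_surface_gradient(p, 35, 65)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
  expect_equal(fit3$slope, fit$slope, tolerance = 1e-9)
})

test_that("gradient fit on a phantom matches the ground-truth edge slope", {
  # affine film across the whole range so 0%/100% anchors map straight to
  # true density: slope must be 100 / edge width
  w_um <- 4
  spec <- phantom_spec(
    cols = 1600, pixel_pitch_um = 0.305,
    film = film_model(linear_lo = 0, linear_hi = 1, noise_sd = 0),
    lesion = lesion_truth(surface_position_um = 210, edge_width_um = w_um)
  )
  pair <- generate_tooth_pair(spec, seed = 2)
  m <- measure_pair(pair, spec)
  expect_equal(m$fit$slope, 100 / w_um, tolerance = 0.02)
})

test_that("gradient fit degenerate inputs raise classed errors", {
  p <- ramp_profile(140, 0.5, 20, 20)
  raw <- density_profile(p$values, um_per_pixel = 0.5, units = "grayscale")
  expect_error(fit_surface_gradient(raw), class = "microrad_validation_error")
  # step edge: no 3 consecutive samples inside the band
  stepp <- density_profile(c(rep(0, 30), rep(100, 30)), um_per_pixel = 0.5,
                           units = "percent")
  expect_error(fit_surface_gradient(stepp),
               class = "microrad_insufficient_data_error")
  # falling edge: polarity
  fall <- density_profile(rev(p$values), um_per_pixel = 0.5, units = "percent")
  expect_error(fit_surface_gradient(fall), class = "microrad_polarity_error")
})

test_that("threshold crossing interpolates sub-pixel and handles boundaries", {
  p <- density_profile(c(0, 100), um_per_pixel = 1, units = "percent")
  expect_equal(threshold_crossing(p, 20), 0.2, tolerance = 1e-12)
  # level 0 on a profile starting at 0: position of the first sample
  expect_equal(threshold_crossing(p, 0), 0)
  # analytic ramp: crossing of level q at s + q/100 * w
  rp <- ramp_profile(300, 0.305, surface_um = 30, edge_width_um = 12.2)
  for (q in c(5, 20, 50, 95)) {
    expect_equal(threshold_crossing(rp, q), 30 + q / 100 * 12.2,
                 tolerance = 1e-9)
  }
  expect_error(threshold_crossing(ramp_profile(60, 1, 80, 10), 20),
               class = "microrad_no_crossing_error")
})

test_that("erosion measurement equals the shift for translated ramps", {
  n <- 400
  before <- ramp_profile(n, 0.305, 30, 10)
  fit <- fit_surface_gradient(before)
  for (d in c(0, 0.85, 5, 11.3)) {
    after <- ramp_profile(n, 0.305, 30 + d, 10)
    ero <- measure_erosion(make_aligned(before, after), fit)
    expect_equal(ero$erosion_um, d, tolerance = 0.305)  # within 1 px pitch
    if (d == 0) expect_equal(ero$erosion_um, 0, tolerance = 1e-9)
  }
})

test_that("negative erosion clamps within tolerance and errors beyond", {
  before <- ramp_profile(400, 0.305, 30, 10)
  fit <- fit_surface_gradient(before)
  # slope 10 %/um, eps 2% -> tolerance 0.2 um
  slightly_out <- ramp_profile(400, 0.305, 29.9, 10)
  ero <- measure_erosion(make_aligned(before, slightly_out), fit,
                         noise_tolerance_pct = 2)
  expect_equal(ero$erosion_um, 0)
  expect_true(ero$clamped)
  far_out <- ramp_profile(400, 0.305, 28, 10)
  expect_error(
    measure_erosion(make_aligned(before, far_out), fit,
                    noise_tolerance_pct = 2),
    class = "microrad_polarity_error"
  )
})

test_that("closed-form erosion equals the brute-force offset-scan oracle", {
  set.seed(61)
  n <- 400
  before <- ramp_profile(n, 0.305, 30, 10)
  fit <- fit_surface_gradient(before)
  for (i in 1:5) {
    d <- runif(1, 0.3, 15)
    after <- ramp_profile(n, 0.305, 30 + d, 10)
    closed <- measure_erosion(make_aligned(before, after), fit)$erosion_um
    oracle <- oracle_erosion_scan(fit, after, scan_um = c(0, 20))
    expect_lt(abs(closed - oracle), 0.01 * 0.305)
  }
})

test_that("demineralization calls zero on pure erosion and identity", {
  spec <- erosion_spec(erosion_um = 15, noise_sd = 0)
  pair <- generate_tooth_pair(spec, seed = 4)
  m <- measure_pair(pair, spec)
  expect_equal(m$erosion$erosion_um, 15, tolerance = 0.305)
  expect_lt(m$demineralization$demin_depth_um, 2 * 0.305)
  expect_identical(m$classification, "erosion-only")

  spec0 <- erosion_spec(erosion_um = 0, noise_sd = 0)
  pair0 <- generate_tooth_pair(spec0, seed = 4)
  m0 <- measure_pair(pair0, spec0)
  expect_equal(coef(m0), c(erosion_um = 0, demin_depth_um = 0),
               tolerance = 0.02)
  expect_identical(m0$classification, "none")
})

test_that("demineralization depth measurement matches its closed-form geometry", {
  # The generator depresses the density ramp at the surface by (1 - delta),
  # which moves the after 20%-crossing inward; the measured erosion and the
  # depth shortfall follow in closed form. Verify the implementation tracks
  # the theory (the bias itself is documented in the vignette).
  delta <- 0.5
  L <- 10
  w <- 5.55
  spec <- demin_spec(L, delta, noise_sd = 0, edge_width_um = w)
  pair <- generate_tooth_pair(spec, seed = 9)
  m <- measure_pair(pair, spec, band_lo_pct = 10, band_hi_pct = 90)

  # true density at the normalized 20% level under the default film
  fm <- spec$film
  g_bg <- film_response(0, fm)
  g_snd <- film_response(0.8, fm)
  g20 <- g_bg + 0.2 * (g_snd - g_bg)
  d0 <- ((g20 - fm$intercept) / fm$slope) / 0.8
  u_star <- predicted_after_edge_u(d0, delta, w, L)

  pred_erosion <- w * (u_star - d0)
  pred_depth <- L - u_star * w
  expect_equal(m$erosion$erosion_um, pred_erosion, tolerance = 0.3)
  expect_equal(m$demineralization$demin_depth_um, pred_depth, tolerance = 0.3)
  # the lesion front itself is recovered without the epsilon bias
  expect_equal(m$demineralization$lesion_front_um, 210 + L, tolerance = 0.5)
  expect_identical(m$classification, "demineralization-only")
})

test_that("erosion-zone flagging and depth-at-percentage reporting work", {
  # mixed lesion: erosion plus a demineralized band
  spec <- erosion_spec(erosion_um = 10, noise_sd = 0, demin_depth_um = 20,
                       demin_severity = 0.6)
  pair <- generate_tooth_pair(spec, seed = 12)
  m <- measure_pair(pair, spec, report_depth_pct = 50)
  expect_identical(m$classification, "mixed")
  expect_gt(m$erosion$erosion_um, 5)
  expect_gt(m$demineralization$demin_depth_um, 5)
  # depth at 50%: innermost position where after density < 50%
  expect_false(is.na(m$demineralization$report_depth_um))
  expect_gt(m$demineralization$report_depth_um,
            m$demineralization$surface_ref_um)
  expect_lt(m$demineralization$report_depth_um,
            m$demineralization$lesion_front_um)
  # mask flags only samples below 100 - ceiling
  expect_type(m$demineralization$erosion_zone_mask, "logical")
})

test_that("classification thresholds distances symmetrically", {
  expect_identical(classify_lesion(11.3, 0), "erosion-only")
  expect_identical(classify_lesion(0, 10.0), "demineralization-only")
  expect_identical(classify_lesion(0, 0), "none")
  expect_identical(classify_lesion(5, 5), "mixed")
  expect_identical(classify_lesion(0.4, 0.4, eps_distance_um = 0.5), "none")
  expect_error(classify_lesion(-1, 0), class = "microrad_validation_error")
})

test_that("measurements are equivariant under common integer translation", {
  spec <- erosion_spec(erosion_um = 8, noise_sd = 0, cols = 1800)
  pair <- generate_tooth_pair(spec, seed = 5)
  m0 <- measure_pair(pair, spec)
  # shift both images by the same 40 columns: all depth measurements move
  # with the windows, distances are invariant
  shift_img <- function(img, k) {
    px <- cbind(matrix(img$pixels[, 1], nrow(img$pixels), k),
                img$pixels[, 1:(ncol(img$pixels) - k)])
    radiograph(px, img$bit_depth, img$pixel_pitch_um)
  }
  k <- 40L
  pitch <- spec$pixel_pitch_um
  m1 <- measure_lesion(
    shift_img(pair$before, k), shift_img(pair$after, k),
    region = roi(16, 80, 0, 1800),
    background_window = um2px(BG_WINDOW_UM, pitch) + k,
    sound_window = um2px(SOUND_WINDOW_UM, pitch) + k
  )
  expect_equal(m1$erosion$erosion_um, m0$erosion$erosion_um,
               tolerance = 1e-6)
  expect_equal(m1$demineralization$demin_depth_um,
               m0$demineralization$demin_depth_um, tolerance = 1e-6)
})

test_that("measured erosion increases strictly with true erosion (noise-free)", {
  depths <- c(2, 5, 10, 20, 35)
  measured <- vapply(depths, function(e) {
    spec <- erosion_spec(erosion_um = e, noise_sd = 0)
    measure_pair(generate_tooth_pair(spec, seed = 8), spec)$erosion$erosion_um
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
  expect_equal(measured, depths, tolerance = 0.305)
})

test_that("measurement reports round-trip and keep units consistent", {
  spec <- erosion_spec(erosion_um = 11.3)
  pair <- generate_tooth_pair(spec, seed = 21)
  m <- measure_pair(pair, spec)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  rep <- measurement_report(m, json, csv)
  back <- read_measurement_report(json)
  expect_equal(back$erosion_um, m$erosion$erosion_um)
  expect_equal(back$classification, m$classification)
  # px * um_per_pixel equals um to 1e-9
  expect_equal(back$erosion_px * back$pixel_pitch_um, back$erosion_um,
               tolerance = 1e-9)
  expect_equal(back$demin_depth_px * back$pixel_pitch_um,
               back$demin_depth_um, tolerance = 1e-9)
  # thresholds echoed verbatim
  expect_equal(back$thresholds$erosion_threshold_pct, 20)
  expect_equal(back$thresholds$demin_ceiling_pct, 80)
  # profiles CSV is plot-ready
  df <- read.csv(csv)
  expect_identical(names(df),
                   c("position_px", "position_um", "before_pct", "after_pct"))
  expect_equal(nrow(df), length(m$pair$before$values))

  # schema validation rejects mangled reports
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "microrad/measurement-report"), bad,
                       auto_unbox = TRUE)
  expect_error(read_measurement_report(bad), class = "microrad_schema_error")
})
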