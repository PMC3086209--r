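# Independent oracles, kept deliberately naive.

# Brute-force erosion: scan candidate depth-axis offsets of the before
# gradient line at 0.001-px resolution, minimizing the squared difference
# between the shifted line and the after profile over the after edge.
oracle_erosion_scan <- function(fit, after, scan_um, step_px = 0.001) {
  pitch <- after$um_per_pixel
  x <- profile_positions_um(after)
  v <- after$values
  edge <- v > 5 & v < 95
  stopifnot(sum(edge) >= 2)
  offsets <- seq(scan_um[1], scan_um[2], by = step_px * pitch)
  cost <- vapply(offsets, function(o) {
    pred <- fit$intercept + fit$slope * (x[edge] - o)
    sum((v[edge] - pred)^2)
  }, numeric(1))
  offsets[which.min(cost)]
}

# Closed-form prediction of where the after profile of a pure-demineralization
# phantom crosses a given true-density level d0 (depth beyond the surface, in
# units of the edge width): smallest root u of
#   u * (1 - delta * (1 - u*w/L)) = d0,  u in [0, 1].
predicted_after_edge_u <- function(d0, delta, w, L) {
  a <- delta * w / L
  b <- 1 - delta
  if (a == 0) return(d0 / b)
  disc <- b^2 + 4 * a * d0
  (-b + sqrt(disc)) / (2 * a)
}
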