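# Shared fixture builders. Everything is generated in code; no stored data.

# default test phantom: vertical muscle/fat border, 30 x 30 mm
test_phantom <- function(noise_sd_hu = 0, slope = -150, spacing = 0.5,
                         seed = 1L, size_mm = 30, angle = 90,
                         drift = rep(0, 6), hu_high = 50, hu_low = -100) {
  generate_edge_phantom(phantom_spec(
    width_mm = size_mm, height_mm = size_mm, pixel_spacing_mm = spacing,
    hu_high = hu_high, hu_low = hu_low,
    edge_slope_hu_per_mm = slope, edge_angle_deg = angle,
    noise_sd_hu = noise_sd_hu, drift_coeffs = drift, seed = seed
  ))
}

# analytic perpendicular template of an edge phantom at signed distance d (mm)
analytic_template <- function(d, hu_high = 50, hu_low = -100, slope = -150) {
  w <- (hu_low - hu_high) / slope
  mid <- (hu_high + hu_low) / 2
  v <- mid + slope * d
  v[d <= -w / 2] <- hu_high
  v[d >= w / 2] <- hu_low
  v
}

# plain ct_slice with given pixel matrix at spacing s
raw_slice <- function(pixels, s = 0.5) ct_slice(pixels, s, id = "raw")

# evaluate a second-order polynomial surface on an ny x nx grid (mm coords)
poly_surface <- function(ny, nx, s, coeffs) {
  x <- matrix((seq_len(nx) - 1) * s, ny, nx, byrow = TRUE)
  y <- matrix((seq_len(ny) - 1) * s, ny, nx)
  coeffs[1] + coeffs[2] * x + coeffs[3] * y +
    coeffs[4] * x^2 + coeffs[5] * x * y + coeffs[6] * y^2
}

icc_band_probe <- function(x) ctiq:::icc_band(x)

# median estimated slope of one phantom realization (profiles stage only)
estimated_median_slope <- function(slope, spacing, noise_sd, seed,
                                   size_mm = 30) {
  ph <- test_phantom(noise_sd_hu = noise_sd, slope = slope, spacing = spacing,
                     seed = seed, size_mm = size_mm)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth))
  summarize_sharpness(analyze_profiles(pr))$median_slope_hu_per_mm
}
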