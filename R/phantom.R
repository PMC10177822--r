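#' Specification of a two-tissue edge phantom
#'
#' Defines a synthetic CT slice containing a straight interface between two
#' homogeneous tissues (by default muscle at +50 HU and fat at -100 HU, the
#' soft-tissue pair whose border is used to measure edge sharpness in neck
#' CT). Perpendicular to the interface the noiseless gray-value profile is
#' piecewise linear: a constant high plateau, a linear ramp of exactly
#' `edge_slope_hu_per_mm`, and a constant low plateau. On top of the template
#' the generator can add a smooth second-order polynomial background drift and
#' i.i.d. Gaussian noise.
#'
#' The ramp (rather than a sigmoid) is deliberate: the steepest slope of the
#' transition then has a closed-form ground truth, so slope recovery is an
#' exact test. Pixels take the template value at their centre (no area
#' averaging). Angles are measured counter-clockwise from the +x axis; the
#' interface passes through the raster centre along direction
#' `(cos(angle), sin(angle))`, and the high-HU tissue lies on the side with
#' negative signed distance.
#'
#' @param width_mm,height_mm Raster extent in mm (each >= 20, enough for a
#'   5 mm noise window plus margins).
#' @param pixel_spacing_mm Isotropic pixel spacing in mm (> 0).
#' @param hu_high,hu_low Plateau gray values (HU); `hu_high > hu_low`.
#' @param edge_slope_hu_per_mm Signed slope of the transition ramp traversed
#'   from the high to the low tissue; must be negative.
#' @param edge_angle_deg Interface orientation, degrees CCW from +x
#'   (90 = vertical border, horizontal profiles).
#' @param noise_sd_hu Additive Gaussian noise SD in HU (>= 0).
#' @param drift_coeffs Six coefficients `c(a, b, c, d, e, f)` of the
#'   background `a + b*x + c*y + d*x^2 + e*x*y + f*y^2` with x, y in mm
#'   (units HU, HU/mm, HU/mm^2).
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return A list of class `phantom_spec`.
#' @seealso [generate_edge_phantom()]
#' @export
phantom_spec <- function(width_mm = 30, height_mm = 30, pixel_spacing_mm = 0.5,
                         hu_high = 50, hu_low = -100,
                         edge_slope_hu_per_mm = -150, edge_angle_deg = 90,
                         noise_sd_hu = 5, drift_coeffs = rep(0, 6), seed = 1L) {
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  stopifnot_scalar_num(width_mm, "width_mm", positive = TRUE)
  stopifnot_scalar_num(height_mm, "height_mm", positive = TRUE)
  if (width_mm < 20 || height_mm < 20) {
    abort("phantom must be at least 20 x 20 mm (one 5 mm window plus margins)")
  }
  stopifnot_scalar_num(hu_high, "hu_high")
  stopifnot_scalar_num(hu_low, "hu_low")
  if (hu_high <= hu_low) abort("`hu_high` must exceed `hu_low`")
  stopifnot_scalar_num(edge_slope_hu_per_mm, "edge_slope_hu_per_mm")
  if (edge_slope_hu_per_mm >= 0) {
    abort("`edge_slope_hu_per_mm` must be negative (high -> low traversal)")
  }
  stopifnot_scalar_num(noise_sd_hu, "noise_sd_hu", nonneg = TRUE)
  if (length(drift_coeffs) != 6 || !is.numeric(drift_coeffs)) {
    abort("`drift_coeffs` must be six numeric polynomial coefficients")
  }
  structure(
    list(width_mm = width_mm, height_mm = height_mm,
         pixel_spacing_mm = pixel_spacing_mm,
         hu_high = hu_high, hu_low = hu_low,
         edge_slope_hu_per_mm = edge_slope_hu_per_mm,
         edge_angle_deg = edge_angle_deg,
         noise_sd_hu = noise_sd_hu,
         drift_coeffs = as.numeric(drift_coeffs),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a two-tissue edge phantom with known ground truth
#'
#' Rasterizes the piecewise-linear edge template described by a
#' [phantom_spec()], adds the polynomial drift and Gaussian noise, and returns
#' the slice together with a ground-truth record of the exact parameters.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements:
#'   * `image`: a [ct_slice()];
#'   * `truth`: one-row tibble with `true_slope_hu_per_mm`, `true_noise_sd_hu`,
#'     `true_upper_baseline_hu`, `true_lower_baseline_hu`,
#'     `transition_width_mm`, plus the interface geometry
#'     (`border_center_x_mm`, `border_center_y_mm`, `edge_angle_deg`) needed to
#'     place a border marking on the image.
#' @examples
#' ph <- generate_edge_phantom(phantom_spec(noise_sd_hu = 0, seed = 7))
#' ph$truth$transition_width_mm  # 1 mm for 150 HU contrast at -150 HU/mm
#' @export
generate_edge_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  s <- spec$pixel_spacing_mm
  nx <- max(2L, as.integer(round(spec$width_mm / s)))
  ny <- max(2L, as.integer(round(spec$height_mm / s)))
  w_trans <- (spec$hu_low - spec$hu_high) / spec$edge_slope_hu_per_mm
  if (w_trans >= min(spec$width_mm, spec$height_mm) / 2) {
    abort(sprintf(
      "transition width %.2f mm does not fit a %.0f x %.0f mm raster; increase the raster or steepen the slope",
      w_trans, spec$width_mm, spec$height_mm
    ), class = "ctiq_sizing_error")
  }
  x <- (seq_len(nx) - 1) * s
  y <- (seq_len(ny) - 1) * s
  # interface through the pixel centre nearest the raster centre, so the
  # template knots of axis-aligned edges land on the sampling lattice
  cx <- floor((nx - 1) / 2) * s
  cy <- floor((ny - 1) / 2) * s
  th <- spec$edge_angle_deg * pi / 180
  # signed perpendicular distance to the interface; d < 0 on the high side
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  d <- (X - cx) * sin(th) - (Y - cy) * cos(th)
  mid <- (spec$hu_high + spec$hu_low) / 2
  pix <- mid + spec$edge_slope_hu_per_mm * d
  pix[d <= -w_trans / 2] <- spec$hu_high
  pix[d >= w_trans / 2] <- spec$hu_low
  cf <- spec$drift_coeffs
  if (any(cf != 0)) {
    pix <- pix + cf[1] + cf[2] * X + cf[3] * Y +
      cf[4] * X^2 + cf[5] * X * Y + cf[6] * Y^2
  }
  if (spec$noise_sd_hu > 0) {
    pix <- pix + withr::with_seed(
      spec$seed,
      matrix(rnorm(ny * nx, sd = spec$noise_sd_hu), ny, nx)
    )
  }
  truth <- tibble(
    true_slope_hu_per_mm = spec$edge_slope_hu_per_mm,
    true_noise_sd_hu = spec$noise_sd_hu,
    true_upper_baseline_hu = spec$hu_high,
    true_lower_baseline_hu = spec$hu_low,
    transition_width_mm = w_trans,
    border_center_x_mm = cx,
    border_center_y_mm = cy,
    edge_angle_deg = spec$edge_angle_deg
  )
  list(
    image = ct_slice(pix, s, id = sprintf("phantom_seed%d", spec$seed)),
    truth = truth
  )
}

#' Border marking along a phantom's true interface
#'
#' Convenience: builds a [border_spec()] centred on the interface recorded in
#' a phantom's ground truth, the way a reader would mark the fat/muscle
#' borderline on a real slice.
#'
#' @param truth The `truth` tibble from [generate_edge_phantom()].
#' @param length_mm Length of the marked segment (mm).
#' @param n_profiles,half_range_mm Passed to [border_spec()].
#' @return A [border_spec()].
#' @export
phantom_border <- function(truth, length_mm = 9, n_profiles = 10,
                           half_range_mm = 4.5) {
  th <- truth$edge_angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  ctr <- c(truth$border_center_x_mm, truth$border_center_y_mm)
  border_spec(ctr - u * length_mm / 2, ctr + u * length_mm / 2,
              n_profiles = n_profiles, half_range_mm = half_range_mm)
}

#' Generate a synthetic rater table
#'
#' Simulates an items x raters table of ordinal scores: each rating is the
#' item's latent quality plus Gaussian rater noise, rounded half away from
#' zero and clipped to the scale. Used as a fixture with known agreement
#' structure for the ICC/kappa machinery.
#'
#' @param n_items Number of rated items (>= 1).
#' @param n_raters Number of raters (>= 2; agreement is undefined for one).
#' @param latent Latent score per item (recycled if scalar); must lie within
#'   the scale.
#' @param disagreement_sd SD of the per-rating Gaussian noise, in score units.
#' @param scale_min,scale_max Scale bounds (default 1-5 Likert).
#' @param seed Integer RNG seed.
#' @return A tibble with column `item` and one integer column per rater
#'   (`rater_1`, `rater_2`, ...).
#' @examples
#' generate_rater_table(5, 2, latent = 1:5, disagreement_sd = 0, seed = 1)
#' @export
generate_rater_table <- function(n_items, n_raters, latent, disagreement_sd,
                                 scale_min = 1, scale_max = 5, seed = 1L) {
  if (n_raters < 2) abort("need at least 2 raters: agreement is undefined otherwise")
  if (n_items < 1) abort("`n_items` must be >= 1")
  if (scale_min >= scale_max) abort("`scale_min` must be below `scale_max`")
  stopifnot_scalar_num(disagreement_sd, "disagreement_sd", nonneg = TRUE)
  latent <- rep_len(as.numeric(latent), n_items)
  if (any(latent < scale_min | latent > scale_max)) {
    abort("`latent` scores must lie within the scale")
  }
  raw <- withr::with_seed(
    as.integer(seed),
    latent + matrix(rnorm(n_items * n_raters, sd = disagreement_sd),
                    n_items, n_raters)
  )
  scores <- pmin(pmax(round_half_up(raw), scale_min), scale_max)
  out <- as_tibble(scores, .name_repair = ~ paste0("rater_", seq_len(n_raters)))
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  dplyr::bind_cols(tibble(item = seq_len(n_items)), out)
}

#' Generate a synthetic dose cohort
#'
#' Draws per-examination CTDIvol (mGy) and scan length (cm) from Gaussian
#' distributions (clipped at zero) and derives the dose-length product by its
#' defining identity DLP = CTDIvol x scan length.
#'
#' @param n Number of examinations.
#' @param ctdivol_mean,ctdivol_sd CTDIvol distribution (mGy); mean > 0.
#' @param scanlen_mean,scanlen_sd Scan-length distribution (cm); mean > 0.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `exam_id`, `ctdivol`, `scan_length`, `dlp`.
#' @examples
#' generate_dose_cohort(3, 10, 0.7, 25, 1.5, seed = 2)
#' @export
generate_dose_cohort <- function(n, ctdivol_mean, ctdivol_sd,
                                 scanlen_mean, scanlen_sd, seed = 1L) {
  stopifnot_scalar_num(ctdivol_mean, "ctdivol_mean", positive = TRUE)
  stopifnot_scalar_num(scanlen_mean, "scanlen_mean", positive = TRUE)
  stopifnot_scalar_num(ctdivol_sd, "ctdivol_sd", nonneg = TRUE)
  stopifnot_scalar_num(scanlen_sd, "scanlen_sd", nonneg = TRUE)
  draws <- withr::with_seed(as.integer(seed), {
    list(ctdivol = pmax(rnorm(n, ctdivol_mean, ctdivol_sd), 0),
         scan_length = pmax(rnorm(n, scanlen_mean, scanlen_sd), .Machine$double.eps))
  })
  tibble(
    exam_id = sprintf("exam_%03d", seq_len(n)),
    ctdivol = draws$ctdivol,
    scan_length = draws$scan_length,
    dlp = draws$ctdivol * draws$scan_length
  )
}
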