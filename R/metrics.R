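#' Signal-to-noise ratio
#'
#' SNR is the upper-baseline signal (the brighter tissue, muscle in the
#' fat/muscle pairing) divided by the image noise.
#'
#' @param upper_baseline_hu Upper-baseline gray value (HU).
#' @param noise_hu Image noise (HU), strictly positive.
#' @return `upper_baseline_hu / noise_hu` (vectorized).
#' @examples
#' snr(100, 10)
#' @export
snr <- function(upper_baseline_hu, noise_hu) {
  if (any(!is.finite(noise_hu)) || any(noise_hu <= 0)) {
    abort("SNR undefined: noise must be a positive, finite HU value",
          class = "ctiq_undefined_ratio")
  }
  upper_baseline_hu / noise_hu
}

#' Contrast-to-noise ratio
#'
#' CNR is the difference between the upper and lower baselines divided by the
#' image noise.
#'
#' @param upper_baseline_hu,lower_baseline_hu Baseline gray values (HU).
#' @inheritParams snr
#' @return `(upper - lower) / noise` (vectorized).
#' @examples
#' cnr(50, -100, 7.5)
#' @export
cnr <- function(upper_baseline_hu, lower_baseline_hu, noise_hu) {
  if (any(!is.finite(noise_hu)) || any(noise_hu <= 0)) {
    abort("CNR undefined: noise must be a positive, finite HU value",
          class = "ctiq_undefined_ratio")
  }
  (upper_baseline_hu - lower_baseline_hu) / noise_hu
}

#' Estimator parameters for the image-quality pipeline
#'
#' Bundles every tunable of [evaluate_image()] with its default.
#'
#' @param step_mm Profile sampling step (mm); `NULL` = half the pixel spacing.
#' @param plateau_fraction Fraction of each profile half used for baselines.
#' @param gradient_threshold_hu_per_mm Edge-detector threshold (HU/mm).
#' @param window_mm Noise-window side (mm).
#' @param stride_px Noise-window stride (px).
#' @param dof_correct See [build_noise_map()].
#' @return A list of class `quality_params`.
#' @export
quality_params <- function(step_mm = NULL, plateau_fraction = 0.25,
                           gradient_threshold_hu_per_mm = 50,
                           window_mm = 5, stride_px = 1, dof_correct = FALSE) {
  structure(
    list(step_mm = step_mm, plateau_fraction = plateau_fraction,
         gradient_threshold_hu_per_mm = gradient_threshold_hu_per_mm,
         window_mm = window_mm, stride_px = stride_px,
         dof_correct = dof_correct),
    class = "quality_params"
  )
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = c("ctiq_stage_error", class(e)[1]), parent = e)
    }
  )
}

#' Full objective image-quality evaluation of one slice
#'
#' Orchestrates the whole pipeline on one marked border: perpendicular
#' profiles with per-profile baselines and steepest slope, medians over the
#' profiles, edge detection, the detrended sliding-window noise map, its
#' minimum as the noise value, and SNR/CNR from the median baselines. The run
#' is deterministic for fixed inputs; stage failures are re-raised with the
#' stage name.
#'
#' @param image A [ct_slice()].
#' @param border A [border_spec()] (e.g. [phantom_border()]).
#' @param params A [quality_params()].
#' @return An object of class `ct_quality` with the sharpness summary,
#'   per-profile analyses, noise value and bias note, SNR, CNR and full
#'   provenance (image id, border, parameters).
#' @examples
#' ph <- generate_edge_phantom(phantom_spec(noise_sd_hu = 6, seed = 11))
#' rep <- evaluate_image(ph$image, phantom_border(ph$truth))
#' glance(rep)
#' @export
evaluate_image <- function(image, border, params = quality_params()) {
  if (!inherits(params, "quality_params")) abort("`params` must come from quality_params()")
  profiles <- with_stage("profiles",
    extract_profiles(image, border, step_mm = params$step_mm))
  analyses <- with_stage("profiles",
    analyze_profiles(profiles, plateau_fraction = params$plateau_fraction))
  sharp <- with_stage("profiles", summarize_sharpness(analyses))
  edges <- with_stage("noise",
    detect_edges(image, params$gradient_threshold_hu_per_mm))
  nmap <- with_stage("noise",
    build_noise_map(image, edges, window_mm = params$window_mm,
                    stride_px = params$stride_px,
                    dof_correct = params$dof_correct))
  noise_hu <- with_stage("noise", as.numeric(estimate_noise(nmap)))
  # residual SDs below 1e-9 HU are numerically zero (noise-free input)
  if (!is.finite(noise_hu) || noise_hu <= 1e-9) {
    abort("stage 'metrics' failed: degenerate input, image noise is zero so SNR/CNR are undefined",
          class = c("ctiq_stage_error", "ctiq_undefined_ratio"))
  }
  structure(
    list(
      sharpness = sharp,
      analyses = analyses,
      noise_hu = noise_hu,
      noise_note = noise_bias_note(nmap),
      snr = snr(sharp$median_upper_hu, noise_hu),
      cnr = cnr(sharp$median_upper_hu, sharp$median_lower_hu, noise_hu),
      provenance = list(image_id = image$id,
                        pixel_spacing_mm = image$pixel_spacing_mm,
                        border = unclass(border), params = unclass(params))
    ),
    class = "ct_quality"
  )
}

#' @export
print.ct_quality <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ct_quality '%s'>\n", x$provenance$image_id))
  cat(sprintf("  median steepest slope: %.1f HU/mm (distance %.2f mm)\n",
              g$median_slope_hu_per_mm, g$median_distance_mm))
  cat(sprintf("  baselines: upper %.1f / lower %.1f HU\n",
              g$median_upper_hu, g$median_lower_hu))
  cat(sprintf("  noise: %.1f HU (map min over %d windows)\n",
              g$noise_hu, x$noise_note$n_valid_windows))
  cat(sprintf("  SNR %.1f, CNR %.1f\n", g$snr, g$cnr))
  invisible(x)
}

#' Tidy/glance methods for quality reports
#'
#' `tidy()` returns the per-profile analyses; `glance()` a one-row summary
#' (medians, noise, SNR, CNR). Values are kept at full precision; rounding to
#' one decimal happens only when printing or serializing.
#'
#' @param x A `ct_quality` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ct_quality <- function(x, ...) x$analyses

#' @rdname tidy.ct_quality
#' @export
glance.ct_quality <- function(x, ...) {
  dplyr::bind_cols(
    tibble(image_id = x$provenance$image_id),
    x$sharpness,
    tibble(noise_hu = x$noise_hu, snr = x$snr, cnr = x$cnr)
  )
}
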