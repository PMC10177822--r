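#' Border marking on a CT slice
#'
#' A straight segment drawn along the tissue interface to be analyzed, plus
#' the lateral scope: how many perpendicular profiles to place along it and
#' how far each profile reaches to either side.
#'
#' @param p_start,p_end Numeric length-2 points `(x, y)` in mm marking the
#'   segment; must differ.
#' @param n_profiles Number of perpendicular profiles (default 10).
#' @param half_range_mm Profile reach to each side of the border (default
#'   4.5 mm).
#' @return A list of class `border_spec`.
#' @export
border_spec <- function(p_start, p_end, n_profiles = 10, half_range_mm = 4.5) {
  p_start <- as.numeric(p_start)
  p_end <- as.numeric(p_end)
  if (length(p_start) != 2 || length(p_end) != 2 ||
      !all(is.finite(c(p_start, p_end)))) {
    abort("`p_start` and `p_end` must be finite (x, y) points in mm")
  }
  if (sqrt(sum((p_end - p_start)^2)) <= 0) abort("`p_start` and `p_end` must differ")
  if (n_profiles < 1) abort("`n_profiles` must be >= 1")
  stopifnot_scalar_num(half_range_mm, "half_range_mm", positive = TRUE)
  structure(
    list(p_start = p_start, p_end = p_end,
         n_profiles = as.integer(n_profiles), half_range_mm = half_range_mm),
    class = "border_spec"
  )
}

#' Extract perpendicular gray-value profiles across a marked border
#'
#' Places `n_profiles` stations evenly along the border segment (endpoints
#' included when `n >= 2`) and samples the image by bilinear interpolation
#' along the perpendicular through each station, at uniform steps covering
#' `+/- half_range_mm`. Profiles are oriented so that position 0 mm is on the
#' border and negative positions lie on the brighter (high-HU) side, the
#' traversal convention under which transition slopes are negative.
#'
#' @param image A [ct_slice()].
#' @param border A [border_spec()].
#' @param step_mm Sampling step along each profile; default half the pixel
#'   spacing (dense enough that the bilinear field is fully resolved).
#' @return A tibble with columns `profile` (station index), `station_x_mm`,
#'   `station_y_mm`, `position_mm` (signed distance from the border) and
#'   `value_hu`.
#' @examples
#' ph <- generate_edge_phantom(phantom_spec(noise_sd_hu = 0))
#' pr <- extract_profiles(ph$image, phantom_border(ph$truth))
#' dplyr::count(pr, profile)
#' @export
extract_profiles <- function(image, border, step_mm = NULL) {
  if (!inherits(image, "ct_slice")) abort("`image` must be a ct_slice")
  if (!inherits(border, "border_spec")) abort("`border` must be a border_spec")
  step_mm <- step_mm %||% (image$pixel_spacing_mm / 2)
  stopifnot_scalar_num(step_mm, "step_mm", positive = TRUE)
  hr <- border$half_range_mm
  n <- border$n_profiles
  seg <- border$p_end - border$p_start
  u <- seg / sqrt(sum(seg^2))
  nrm <- c(u[2], -u[1]) # unit normal to the marking
  t_frac <- if (n >= 2) seq(0, 1, length.out = n) else 0.5
  stations <- cbind(
    border$p_start[1] + t_frac * seg[1],
    border$p_start[2] + t_frac * seg[2]
  )
  # uniform grid including 0, spanning exactly +/- hr
  n_half <- max(1L, as.integer(ceiling(hr / step_mm)))
  pos <- seq(-hr, hr, length.out = 2L * n_half + 1L)

  xs <- rep(stations[, 1], each = length(pos)) + rep(pos, n) * nrm[1]
  ys <- rep(stations[, 2], each = length(pos)) + rep(pos, n) * nrm[2]
  vals <- bilinear_sample(image$pixels, image$pixel_spacing_mm, xs, ys,
                          context = "profile sample")
  out <- tibble(
    profile = rep(seq_len(n), each = length(pos)),
    station_x_mm = rep(stations[, 1], each = length(pos)),
    station_y_mm = rep(stations[, 2], each = length(pos)),
    position_mm = rep(pos, n),
    value_hu = vals
  )
  # orient so the brighter tissue sits at negative positions (high -> low)
  if (mean(out$value_hu[out$position_mm < 0]) <
      mean(out$value_hu[out$position_mm > 0])) {
    out$position_mm <- -out$position_mm
    out <- dplyr::arrange(out, .data$profile, .data$position_mm)
  }
  attr(out, "step_mm") <- pos[2] - pos[1]
  out
}

#' Estimate plateau baselines of one profile
#'
#' The upper (lower) baseline is the mean gray value over the outermost
#' `plateau_fraction` of the samples on the high (low) side of the border,
#' far enough from the transition to average pure plateau.
#'
#' @param profile A tibble with `position_mm` and `value_hu` for a single
#'   profile (one group of the [extract_profiles()] output).
#' @param plateau_fraction Fraction (0, 0.5] of each half-range used for the
#'   plateau mean; default 0.25.
#' @return One-row tibble: `upper_baseline_hu`, `lower_baseline_hu`, `flag`
#'   (`NA`, or `"inverted_or_flat"` when the high side is not brighter, in
#'   which case the baselines are `NA`).
#' @export
estimate_baselines <- function(profile, plateau_fraction = 0.25) {
  if (plateau_fraction <= 0 || plateau_fraction > 0.5) {
    abort("`plateau_fraction` must be in (0, 0.5]")
  }
  hi <- profile$value_hu[profile$position_mm < 0]
  lo <- profile$value_hu[profile$position_mm > 0]
  pos_hi <- profile$position_mm[profile$position_mm < 0]
  pos_lo <- profile$position_mm[profile$position_mm > 0]
  m_hi <- floor(plateau_fraction * length(hi))
  m_lo <- floor(plateau_fraction * length(lo))
  if (m_hi < 3 || m_lo < 3) {
    abort("fewer than 3 samples per plateau; lengthen the profile or raise `plateau_fraction`")
  }
  upper <- mean(hi[order(pos_hi)[seq_len(m_hi)]])            # most negative
  lower <- mean(lo[order(pos_lo, decreasing = TRUE)[seq_len(m_lo)]]) # most positive
  if (!(upper > lower)) {
    return(tibble(upper_baseline_hu = NA_real_, lower_baseline_hu = NA_real_,
                  flag = "inverted_or_flat"))
  }
  tibble(upper_baseline_hu = upper, lower_baseline_hu = lower, flag = NA_character_)
}

#' Steepest three-point slope of one profile
#'
#' Slides a window of three consecutive samples along the profile, fits a
#' least-squares line in each (for three equispaced points the LS slope is
#' `(v3 - v1) / (2 * step)`), and reports the most negative slope as the edge
#' sharpness. Ties are broken toward the window whose centre is nearest the
#' marked border (position 0). The signed span of the winning window
#' (`-2 * step` under the high-to-low convention) is reported as the
#' transition distance.
#'
#' @param profile A single-profile tibble with `position_mm`, `value_hu`;
#'   sampling must be uniform.
#' @return One-row tibble: `steepest_slope_hu_per_mm`,
#'   `slope_window_center_mm`, `distance_mm`, `flag` (`NA` or
#'   `"no_transition"` when no window has negative slope).
#' @export
steepest_slope <- function(profile) {
  pos <- profile$position_mm
  v <- profile$value_hu
  if (length(v) < 3) abort("need at least 3 samples for a three-point slope")
  if (!is_uniform(pos)) abort("profile sampling must be uniform for three-point windows")
  h <- pos[2] - pos[1]
  k <- seq_len(length(v) - 2L)
  slopes <- (v[k + 2L] - v[k]) / (2 * h)
  centers <- pos[k + 1L]
  s_min <- min(slopes)
  cand <- which(slopes <= s_min + 1e-12 * max(1, abs(s_min)))
  win <- cand[order(abs(centers[cand]), cand)][1L] # nearest 0, then first
  no_trans <- s_min >= 0
  tibble(
    steepest_slope_hu_per_mm = s_min,
    slope_window_center_mm = centers[win],
    distance_mm = if (no_trans) NA_real_ else -2 * h,
    flag = if (no_trans) "no_transition" else NA_character_
  )
}

#' Analyze every profile of a set
#'
#' Applies [estimate_baselines()] and [steepest_slope()] to each profile of an
#' [extract_profiles()] table.
#'
#' @param profiles Tibble from [extract_profiles()].
#' @param plateau_fraction Passed to [estimate_baselines()].
#' @return A tibble with one row per profile: baselines, steepest slope,
#'   window centre, distance and a combined `flag`.
#' @export
analyze_profiles <- function(profiles, plateau_fraction = 0.25) {
  if (!nrow(profiles)) abort("empty profile set")
  profiles |>
    dplyr::group_by(.data$profile) |>
    dplyr::group_modify(function(df, key) {
      b <- estimate_baselines(df, plateau_fraction)
      s <- steepest_slope(df)
      tibble(
        upper_baseline_hu = b$upper_baseline_hu,
        lower_baseline_hu = b$lower_baseline_hu,
        steepest_slope_hu_per_mm = s$steepest_slope_hu_per_mm,
        slope_window_center_mm = s$slope_window_center_mm,
        distance_mm = s$distance_mm,
        flag = dplyr::coalesce(b$flag, s$flag)
      )
    }) |>
    dplyr::ungroup()
}

#' Median sharpness summary over profiles
#'
#' Component-wise medians over the per-profile analyses (for an even count,
#' the mean of the central pair). Flagged profiles contribute only the
#' components they produced.
#'
#' @param analyses Tibble from [analyze_profiles()].
#' @return One-row tibble: `median_slope_hu_per_mm`, `median_upper_hu`,
#'   `median_lower_hu`, `median_distance_mm`, `n_profiles`, `n_flagged`.
#' @examples
#' summarize_sharpness(tibble::tibble(
#'   profile = 1:10, upper_baseline_hu = 50, lower_baseline_hu = -100,
#'   steepest_slope_hu_per_mm = -(1:10), slope_window_center_mm = 0,
#'   distance_mm = -0.2, flag = NA_character_
#' ))
#' @export
summarize_sharpness <- function(analyses) {
  if (!nrow(analyses)) abort("cannot summarize an empty analysis list")
  med <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  tibble(
    median_slope_hu_per_mm = med(analyses$steepest_slope_hu_per_mm),
    median_upper_hu = med(analyses$upper_baseline_hu),
    median_lower_hu = med(analyses$lower_baseline_hu),
    median_distance_mm = med(analyses$distance_mm),
    n_profiles = nrow(analyses),
    n_flagged = sum(!is.na(analyses$flag))
  )
}

#' Plot extracted profiles
#'
#' One line per perpendicular profile, gray value against signed distance from
#' the border; optionally overlays the median baselines from an analysis.
#'
#' @param profiles Tibble from [extract_profiles()].
#' @param analyses Optional tibble from [analyze_profiles()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, analyses = NULL) {
  p <- ggplot2::ggplot(profiles, ggplot2::aes(.data$position_mm, .data$value_hu,
                                              group = .data$profile)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "distance from border [mm]", y = "gray value [HU]")
  if (!is.null(analyses)) {
    smry <- summarize_sharpness(analyses)
    p <- p + ggplot2::geom_hline(
      yintercept = c(smry$median_upper_hu, smry$median_lower_hu),
      linetype = "dashed", colour = "red"
    )
  }
  p
}
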