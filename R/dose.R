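#' ICRP conversion factors for effective dose
#'
#' Body-region conversion coefficients k (mSv per mGy.cm) used to turn a
#' dose-length product into an effective dose. The head-and-neck factor
#' 0.0058 is the package default.
#'
#' @return Tibble with columns `region`, `k_msv_per_mgycm`.
#' @examples
#' icrp_k_factors()
#' @export
icrp_k_factors <- function() {
  tibble(
    region = c("head", "head_neck", "neck", "chest", "abdomen_pelvis"),
    k_msv_per_mgycm = c(0.0021, 0.0058, 0.0059, 0.014, 0.015)
  )
}

validate_dose_records <- function(records) {
  need <- c("ctdivol", "scan_length")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(sprintf("dose records need columns %s; missing: %s",
                  paste(need, collapse = ", "), paste(missing_cols, collapse = ", ")))
  }
  if (any(records$ctdivol < 0)) abort("`ctdivol` must be >= 0 mGy")
  if (any(records$scan_length <= 0)) abort("`scan_length` must be > 0 cm")
  if ("dlp" %in% names(records)) {
    expect <- records$ctdivol * records$scan_length
    off <- abs(records$dlp - expect) > 0.01 * pmax(expect, .Machine$double.eps)
    if (any(off)) {
      abort(sprintf(
        "dlp disagrees with ctdivol x scan_length by more than 1%% in %d record(s)",
        sum(off)))
    }
  }
  invisible(records)
}

#' Normalize DLP to a reference scan length
#'
#' Scan lengths vary between examinations; for comparability the dose-length
#' product is recomputed at a fixed reference length:
#' `dlp_normalized = ctdivol * reference_length_cm`.
#'
#' @param records Tibble of dose records with columns `ctdivol` (mGy) and
#'   `scan_length` (cm); an optional `dlp` column is validated against their
#'   product (1% tolerance).
#' @param reference_length_cm Reference scan length (default 25 cm, a typical
#'   mean neck scan length).
#' @return The records with a `dlp_normalized` column (mGy.cm) appended.
#' @examples
#' normalize_dlp(tibble::tibble(ctdivol = 10, scan_length = 24.3))
#' @export
normalize_dlp <- function(records, reference_length_cm = 25) {
  stopifnot_scalar_num(reference_length_cm, "reference_length_cm", positive = TRUE)
  validate_dose_records(records)
  dplyr::mutate(as_tibble(records),
                dlp_normalized = .data$ctdivol * reference_length_cm)
}

#' Effective dose from DLP
#'
#' Multiplies a dose-length product by a body-region conversion factor k.
#'
#' @param dlp Dose-length product(s), mGy.cm, each >= 0.
#' @param k Conversion factor in mSv/(mGy.cm); default 0.0058 (head and neck,
#'   see [icrp_k_factors()]).
#' @return Effective dose(s) in mSv.
#' @examples
#' effective_dose(250)    # 1.45 mSv
#' effective_dose(349.8)  # 2.02884 mSv; round_half_up(., 2) -> 2.03
#' @export
effective_dose <- function(dlp, k = 0.0058) {
  if (any(!is.finite(dlp)) || any(dlp < 0)) abort("`dlp` must be finite and >= 0")
  stopifnot_scalar_num(k, "k", positive = TRUE)
  dlp * k
}

#' Relative dose reduction between two cohorts
#'
#' @param reference_msv Reference (higher-dose) effective dose, mSv, > 0.
#' @param new_msv Comparison effective dose, mSv.
#' @return Percentage reduction `100 * (reference - new) / reference`.
#' @examples
#' dose_reduction_percent(2.03, 1.45)                # 28.57...
#' round_half_up(dose_reduction_percent(2.03, 1.45)) # 29
#' @export
dose_reduction_percent <- function(reference_msv, new_msv) {
  if (any(!is.finite(reference_msv)) || any(reference_msv <= 0)) {
    abort("`reference_msv` must be > 0")
  }
  100 * (reference_msv - new_msv) / reference_msv
}

#' Summarize a dose cohort
#'
#' Means and SDs of CTDIvol, length-normalized DLP, and effective dose for one
#' cohort of examinations.
#'
#' @inheritParams normalize_dlp
#' @param k Effective-dose conversion factor (mSv per mGy.cm).
#' @return One-row tibble: `n`, `ctdivol_mean`, `ctdivol_sd`,
#'   `dlp_norm_mean`, `dlp_norm_sd`, `effective_dose_mean_msv`,
#'   `effective_dose_sd_msv`.
#' @export
summarize_dose <- function(records, reference_length_cm = 25, k = 0.0058) {
  r <- normalize_dlp(records, reference_length_cm)
  ed <- effective_dose(r$dlp_normalized, k)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  tibble(
    n = nrow(r),
    ctdivol_mean = mean(r$ctdivol), ctdivol_sd = sd0(r$ctdivol),
    dlp_norm_mean = mean(r$dlp_normalized), dlp_norm_sd = sd0(r$dlp_normalized),
    effective_dose_mean_msv = mean(ed), effective_dose_sd_msv = sd0(ed)
  )
}

#' Compare two dose cohorts
#'
#' Side-by-side summary of a reference and a new cohort plus the percentage
#' reduction in mean effective dose.
#'
#' @param reference,new Dose-record tibbles (see [normalize_dlp()]).
#' @inheritParams summarize_dose
#' @return Tibble with one row per cohort (`cohort` = "reference"/"new") and a
#'   `reduction_percent` column (reduction of the new cohort versus the
#'   reference, repeated on both rows).
#' @export
compare_dose <- function(reference, new, reference_length_cm = 25, k = 0.0058) {
  a <- summarize_dose(reference, reference_length_cm, k)
  b <- summarize_dose(new, reference_length_cm, k)
  red <- dose_reduction_percent(a$effective_dose_mean_msv, b$effective_dose_mean_msv)
  dplyr::bind_rows(
    dplyr::mutate(a, cohort = "reference", .before = 1),
    dplyr::mutate(b, cohort = "new", .before = 1)
  ) |>
    dplyr::mutate(reduction_percent = red)
}
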