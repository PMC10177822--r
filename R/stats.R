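# Reader-agreement and group-comparison statistics.

as_rating_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else {
    df <- as.data.frame(table)
    df <- df[setdiff(names(df), c("item", "parameter"))]
    m <- as.matrix(df)
  }
  if (!is.numeric(m)) abort("rater table must be numeric (items x raters)")
  if (any(!is.finite(m))) abort("rater table must not contain missing scores")
  m
}

icc_band <- function(icc) {
  # printed band edges leave 0.75-0.76 open; resolved as good <=> icc >= 0.755
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.5) "poor"
  else if (icc < 0.755) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

#' Intraclass correlation, two-way mixed, consistency
#'
#' Single-rater consistency ICC from the two-way ANOVA decomposition with
#' items as random rows and raters as fixed columns (Shrout-Fleiss ICC(3,1)):
#' `(MS_items - MS_error) / (MS_items + (k - 1) * MS_error)`. Consistency
#' ignores systematic per-rater offsets by design. The average-measure form
#' ICC(3,k) = `(MS_items - MS_error) / MS_items` is available via
#' `average = TRUE`.
#'
#' Agreement bands: poor below 0.5, moderate 0.5 to 0.755, good 0.755 to 0.9,
#' excellent above 0.9.
#'
#' @param table Items x raters scores: a numeric matrix, or a data frame whose
#'   non-score columns `item`/`parameter` are ignored (the
#'   [generate_rater_table()] layout). At least 2 items and 2 raters.
#' @param average Return the average-measure ICC(3,k) instead of ICC(3,1).
#' @return Object of class `ctiq_icc`: `icc`, `band`, mean squares, sizes and
#'   an `undefined` flag (set, with `icc = NA`, when the between-item variance
#'   is zero so the ICC does not exist).
#' @examples
#' tab <- generate_rater_table(12, 2, latent = rep(1:4, 3), disagreement_sd = 0.4)
#' icc_consistency(tab)
#' @export
icc_consistency <- function(table, average = FALSE) {
  m <- as_rating_matrix(table)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) abort("ICC needs at least 2 items and 2 raters")
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  if (var(row_means) < 1e-12) {
    out <- list(icc = NA_real_, band = NA_character_, undefined = TRUE,
                ms_items = 0, ms_error = NA_real_, n_items = n, k_raters = k,
                type = if (average) "ICC(3,k)" else "ICC(3,1)")
    return(structure(out, class = "ctiq_icc"))
  }
  ss_items <- k * sum((row_means - grand)^2)
  ss_raters <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_items - ss_raters
  ms_items <- ss_items / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  icc <- if (average) {
    (ms_items - ms_error) / ms_items
  } else {
    (ms_items - ms_error) / (ms_items + (k - 1) * ms_error)
  }
  structure(
    list(icc = icc, band = icc_band(icc), undefined = FALSE,
         ms_items = ms_items, ms_error = ms_error, n_items = n, k_raters = k,
         type = if (average) "ICC(3,k)" else "ICC(3,1)"),
    class = "ctiq_icc"
  )
}

#' @export
print.ctiq_icc <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<%s> undefined: zero between-item variance\n", x$type))
  } else {
    cat(sprintf("<%s> %.3f (%s), %d items x %d raters\n",
                x$type, x$icc, x$band, x$n_items, x$k_raters))
  }
  invisible(x)
}

#' @export
tidy.ctiq_icc <- function(x, ...) {
  tibble(type = x$type, icc = x$icc, band = x$band, undefined = x$undefined,
         ms_items = x$ms_items, ms_error = x$ms_error,
         n_items = x$n_items, k_raters = x$k_raters)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` over the
#' categories used by either rater, with expected agreement `p_e` from the
#' marginal category frequencies. Restricted to categorical (integer Likert)
#' scores.
#'
#' @param table Items x 2 scores (matrix or data frame as in
#'   [icc_consistency()]), or pass the two rating vectors as `table` and `r2`.
#' @param r2 Optional second rating vector.
#' @return Object of class `ctiq_kappa`: `kappa`, `p_observed`, `p_expected`,
#'   `n_items` and an `undefined` flag (both raters constant and identical,
#'   `p_e = 1`).
#' @examples
#' cohens_kappa(c(1, 1, 2, 2), c(1, 1, 2, 2))
#' @export
cohens_kappa <- function(table, r2 = NULL) {
  if (!is.null(r2)) {
    m <- cbind(as.numeric(table), as.numeric(r2))
  } else {
    m <- as_rating_matrix(table)
  }
  if (ncol(m) != 2) abort("Cohen's kappa is defined for exactly 2 raters")
  cats <- sort(unique(as.vector(m)))
  f1 <- factor(m[, 1], levels = cats)
  f2 <- factor(m[, 2], levels = cats)
  tab <- base::table(f1, f2)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  undefined <- abs(1 - p_e) < 1e-12
  structure(
    list(kappa = if (undefined) NA_real_ else (p_o - p_e) / (1 - p_e),
         p_observed = p_o, p_expected = p_e, n_items = n,
         undefined = undefined),
    class = "ctiq_kappa"
  )
}

#' @export
print.ctiq_kappa <- function(x, ...) {
  if (x$undefined) {
    cat("<kappa> undefined: both raters constant and identical (p_e = 1)\n")
  } else {
    cat(sprintf("<kappa> %.3f (p_o %.3f, p_e %.3f, n %d)\n",
                x$kappa, x$p_observed, x$p_expected, x$n_items))
  }
  invisible(x)
}

#' @export
tidy.ctiq_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, p_observed = x$p_observed,
         p_expected = x$p_expected, n_items = x$n_items,
         undefined = x$undefined)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. For small samples (both sizes <= 8 by
#' default) the p-value is computed by exhaustive enumeration of all group
#' assignments of the observed (possibly tied) values; otherwise the
#' tie-corrected normal approximation is used. `U` is the number of (a, b)
#' pairs where a exceeds b, counting ties as half.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_max Use exact enumeration when both sample sizes are at most
#'   this (default 8).
#' @return One-row tibble: `U`, `p_value`, `method`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1 # all observations identical
    } else {
      z <- (u_obs - mu) / sqrt(v)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  tibble(U = u_obs, p_value = min(p, 1), method = method, n_a = n1, n_b = n2)
}

#' Welch two-sample t test
#'
#' Thin wrapper over [stats::t.test()] (unequal variances) returning a tidy
#' row.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return One-row tibble: `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2")
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Kolmogorov-Smirnov normality screen
#'
#' Tests a sample against a normal distribution with the sample's own mean and
#' SD. Note that plugging in estimated parameters makes the classical KS
#' p-value conservative (the Lilliefors effect); `method = "lilliefors"`
#' applies the corrected test from the nortest package instead.
#'
#' @param x Numeric sample, n >= 2 (Lilliefors needs n >= 4), non-constant.
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @return One-row tibble: `D`, `p_value`, `method`.
#' @export
ks_normality <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  if (length(x) < 2) abort("normality screen needs n >= 2")
  if (sd(x) == 0) abort("normality screen undefined for a constant sample")
  if (method == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      abort("method 'lilliefors' needs the nortest package")
    }
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  tibble(D = unname(ht$statistic), p_value = ht$p.value, method = method)
}

#' Descriptive summary with normality-based selection
#'
#' Computes both conventional summaries — mean with SD, and median with the
#' interquartile range as `[Q1, Q3]` (linear-interpolation quantiles) — plus
#' which of the two a KS normality screen selects for reporting: `mean_sd`
#' when normality is not rejected at `alpha`, `median_iqr` when it is rejected
#' or when the screen is undefined (constant sample).
#'
#' @param x Numeric sample.
#' @param alpha Rejection level of the normality screen (default 0.05).
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `ks_p_value`, `report_as`.
#' @examples
#' describe_sample(c(1, 2, 3, 4, 5))
#' @export
describe_sample <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (!length(x)) abort("empty sample")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  ks_p <- if (length(x) >= 2 && sd(x) > 0) ks_normality(x)$p_value else NA_real_
  tibble(
    n = length(x),
    mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
    median = q[2], q1 = q[1], q3 = q[3],
    ks_p_value = ks_p,
    report_as = if (!is.na(ks_p) && ks_p >= alpha) "mean_sd" else "median_iqr"
  )
}
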