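#' Bland-Altman mean difference and 95% limits of agreement
#'
#' For paired measurements `x1`, `x2` on the same subjects, computes the
#' mean difference `mean(d)` with `d = x1 - x2`, the 95% limits of
#' agreement `mean(d) +/- 1.96 sd(d)` (sample SD, n-1 denominator), and the
#' 95% confidence interval of each limit,
#' `limit +/- t(0.975, n-1) * sqrt(3 s^2 / n)`.
#'
#' @param x1,x2 numeric vectors of equal length (study 1 and study 2
#'   values per subject), n >= 2.
#' @return named list: `mean_difference`, `loa_lower`, `loa_upper`,
#'   `loa_lower_ci`, `loa_upper_ci` (each a length-2 vector), `n`.
#' @export
bland_altman <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  n <- length(x1)
  if (n < 2) stop("Bland-Altman limits require n >= 2 subjects")
  d <- x1 - x2
  md <- mean(d)
  s <- stats::sd(d)
  loa_lower <- md - 1.96 * s
  loa_upper <- md + 1.96 * s
  half <- stats::qt(0.975, n - 1) * sqrt(3 * s^2 / n)
  list(mean_difference = md,
       loa_lower = loa_lower, loa_upper = loa_upper,
       loa_lower_ci = c(loa_lower - half, loa_lower + half),
       loa_upper_ci = c(loa_upper - half, loa_upper + half),
       n = n)
}

#' Within-subject coefficient of variation
#'
#' `wCV = 100 * s_w / mean(c(x1, x2))` with the within-subject SD
#' `s_w = sqrt(sum(d^2) / (2 n))`, the two-replicate form of the pooled
#' within-subject standard deviation. The group mean pools all `2n`
#' measurements. A zero or sign-mixed feature makes the ratio
#' uninterpretable; the value is still returned but carries
#' `interpretable = FALSE` and is excluded from reliability grading.
#'
#' @param x1,x2 paired feature values, n >= 2.
#' @return percent wCV with attribute `interpretable` (logical).
#' @export
wcv <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  n <- length(x1)
  if (n < 2) stop("wCV requires n >= 2 subjects")
  d <- x1 - x2
  s_w <- sqrt(sum(d^2) / (2 * n))
  gm <- mean(c(x1, x2))
  all_vals <- c(x1, x2)
  interpretable <- gm != 0 && !(any(all_vals > 0) && any(all_vals < 0))
  val <- if (gm == 0) NA_real_ else 100 * s_w / abs(gm)
  structure(val, interpretable = interpretable)
}

#' Repeatability coefficient
#'
#' `r = 1.96 * sqrt(sum(d^2) / n)` (equivalently `1.96 * sqrt(2) * s_w`):
#' the value below which the absolute difference between two repeat
#' measurements on the same subject falls in 95% of cases, assuming
#' Gaussian differences.
#'
#' @param x1,x2 paired feature values, n >= 1.
#' @return scalar repeatability coefficient (feature units).
#' @export
repeatability_coefficient <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 1)
  d <- x1 - x2
  1.96 * sqrt(sum(d^2) / length(d))
}

#' Classify repeatability from the wCV
#'
#' Reliability bands on the percent within-subject CV:
#' `[0, 10]` good, `(10, 15]` acceptable, `(15, 30)` intermediate,
#' `[30, 50)` moderate-poor, `>= 50` unreliable (a wCV of exactly 50% is
#' graded unreliable; exactly 10% is graded good).
#'
#' @param wcv percent wCV (scalar or vector), must be >= 0.
#' @return character vector of class labels; `NA` input gives `NA`.
#' @export
classify_reliability <- function(wcv) {
  wcv <- as.numeric(wcv)
  if (any(wcv < 0, na.rm = TRUE)) stop("wCV must be non-negative")
  ifelse(wcv >= 50, "unreliable",
         ifelse(wcv >= 30, "moderate-poor",
                ifelse(wcv > 15, "intermediate",
                       ifelse(wcv > 10, "acceptable", "good"))))
}

#' Per-feature repeatability table
#'
#' Computes the full repeatability record — mean difference, 95% limits of
#' agreement with their CIs, wCV, repeatability coefficient and
#' reliability class — for every feature in a long-format table of paired
#' measurements.
#'
#' @param features long data.frame with columns `subject_id`, `day` (1/2),
#'   `feature_name`, `value` (one reader's data).
#' @return data.frame, one row per feature.
#' @export
repeatability_table <- function(features) {
  need <- c("subject_id", "day", "feature_name", "value")
  stopifnot(all(need %in% names(features)))
  out <- lapply(split(features, features$feature_name), function(f) {
    d1 <- f[f$day == 1, ]
    d2 <- f[f$day == 2, ]
    ok <- nrow(d1) >= 2 && nrow(d1) == nrow(d2) &&
      !anyDuplicated(d1$subject_id) && !anyDuplicated(d2$subject_id) &&
      setequal(d1$subject_id, d2$subject_id)
    if (!ok) {
      stop("feature ", f$feature_name[1],
           ": every subject needs exactly one day-1 and one day-2 value")
    }
    d2 <- d2[match(d1$subject_id, d2$subject_id), ]
    x1 <- d1$value; x2 <- d2$value
    if (anyNA(x1) || anyNA(x2)) {
      return(data.frame(feature_name = f$feature_name[1], n = nrow(d1),
                        mean_difference = NA_real_, loa_lower = NA_real_,
                        loa_upper = NA_real_, loa_lower_ci_lo = NA_real_,
                        loa_lower_ci_hi = NA_real_, loa_upper_ci_lo = NA_real_,
                        loa_upper_ci_hi = NA_real_, wcv_percent = NA_real_,
                        wcv_interpretable = FALSE,
                        repeatability_coefficient = NA_real_,
                        reliability_class = NA_character_))
    }
    ba <- bland_altman(x1, x2)
    w <- wcv(x1, x2)
    interp <- attr(w, "interpretable")
    data.frame(
      feature_name = f$feature_name[1],
      n = ba$n,
      mean_difference = ba$mean_difference,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      loa_lower_ci_lo = ba$loa_lower_ci[1], loa_lower_ci_hi = ba$loa_lower_ci[2],
      loa_upper_ci_lo = ba$loa_upper_ci[1], loa_upper_ci_hi = ba$loa_upper_ci[2],
      wcv_percent = as.numeric(w),
      wcv_interpretable = interp,
      repeatability_coefficient = repeatability_coefficient(x1, x2),
      reliability_class = if (interp) classify_reliability(as.numeric(w))
                          else NA_character_
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # keep registry order where applicable
  reg <- feature_registry()
  ord <- match(res$feature_name, reg$name)
  res[order(ifelse(is.na(ord), Inf, ord)), , drop = FALSE]
}
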