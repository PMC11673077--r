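# PA/Ao ratio, the cohort standard value (mean +/- 2 SD band) and the
# low/normal/high CHD grouping built on it.

#' PA/Ao ratio
#'
#' The ratio of the pulmonary artery diameter to the ascending aorta diameter,
#' the screening biometric of the three-vessel view. Dimensionless, so any
#' consistent pixel convention cancels.
#'
#' @param pa_px,ao_px Vessel diameters in pixels; must be positive.
#' @return `pa_px / ao_px` (vectorized).
#' @export
#' @examples
#' compute_ratio(24, 20)  # 1.2
compute_ratio <- function(pa_px, ao_px) {
  if (length(pa_px) != length(ao_px))
    caliper_abort("invalid_diameter", "pa_px and ao_px must have equal length")
  if (anyNA(pa_px) || anyNA(ao_px) || any(pa_px <= 0) || any(ao_px <= 0))
    caliper_abort("invalid_diameter", "diameters must be positive and non-missing")
  pa_px / ao_px
}

#' Cap outlier ratios
#'
#' Ratios exceeding the cap are treated as outliers and replaced by the cap
#' (default 3.5). Applied before standard-range estimation and before
#' classification. Idempotent.
#'
#' @param ratio Positive ratio(s).
#' @param cap Outlier cap, default 3.5.
#' @return List with `ratio` (capped values) and `clipped` (logical).
#' @export
#' @examples
#' clip_ratio(4.0)  # $ratio 3.5, $clipped TRUE
clip_ratio <- function(ratio, cap = 3.5) {
  if (anyNA(ratio) || any(ratio <= 0))
    caliper_abort("invalid_diameter", "ratio must be positive and non-missing")
  list(ratio = pmin(ratio, cap), clipped = ratio > cap)
}

#' Cohort standard value of the PA/Ao ratio
#'
#' The standard value is the cohort mean with a +/- 2 SD band; ratios outside
#' the band are graded low or high. `standard_range()` builds the object from
#' known parameters, [compute_standard_range()] estimates it from a cohort of
#' ratios, and [default_standard_range()] carries the bundled reference value
#' mean 1.237, 2 SD half-width 0.364 (from 270 normal fetuses).
#'
#' @param mean Cohort mean ratio.
#' @param half_width_2sd Half-width of the band, i.e. 2 x SD.
#' @param n_cases Number of cases behind the estimate (`NA` for config data).
#' @return A `standard_range` with fields `mean`, `half_width_2sd`, `lower`,
#'   `upper`, `n_cases`.
#' @export
standard_range <- function(mean, half_width_2sd, n_cases = NA_integer_) {
  stopifnot(is.finite(mean), is.finite(half_width_2sd), half_width_2sd >= 0)
  structure(list(mean = mean,
                 half_width_2sd = half_width_2sd,
                 lower = mean - half_width_2sd,
                 upper = mean + half_width_2sd,
                 n_cases = n_cases),
            class = "standard_range")
}

#' @rdname standard_range
#' @export
default_standard_range <- function() standard_range(1.237, 0.364)

#' Estimate the standard value from a cohort
#'
#' Mean and 2 x sample SD (n - 1 denominator) of the supplied ratios, which
#' should already be capped (see [clip_ratio()]).
#'
#' @param ratios Numeric vector of at least 2 ratios.
#' @return A [standard_range()].
#' @export
#' @examples
#' compute_standard_range(c(1.0, 1.2, 1.4))  # mean 1.2, half-width 0.4
compute_standard_range <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2L)
    caliper_abort("insufficient_data",
                  "need at least 2 ratios to estimate a standard range")
  s <- stats::sd(ratios)
  if (s == 0)
    caliper_warn("degenerate_cohort",
                 "cohort SD is 0; the normal band is a single point")
  standard_range(mean(ratios), 2 * s, n_cases = length(ratios))
}

#' Classify ratios against a standard range
#'
#' `low` below the band, `high` above it, `normal` within it; values exactly
#' on mean +/- 2 SD count as normal ("within" is inclusive). Ratios should be
#' capped first.
#'
#' @param ratio Numeric ratio(s).
#' @param range A [standard_range()]; defaults to the bundled reference value.
#' @return Ordered factor with levels `low < normal < high`.
#' @export
#' @examples
#' classify_ratio(c(0.80, 1.30, 1.70))  # low, normal, high
classify_ratio <- function(ratio, range = default_standard_range()) {
  stopifnot(inherits(range, "standard_range"))
  out <- ifelse(ratio < range$lower, "low",
                ifelse(ratio > range$upper, "high", "normal"))
  factor(out, levels = c("low", "normal", "high"), ordered = TRUE)
}

#' @param object A `standard_range`.
#' @param newdata Numeric ratios to classify.
#' @param ... Ignored.
#' @rdname classify_ratio
#' @export
predict.standard_range <- function(object, newdata, ...) {
  classify_ratio(newdata, object)
}

#' Per-group ratio summary
#'
#' Summarizes classified ratio records the way cohort tables are reported:
#' one pooled row for the normal cohort, and one row per low/normal/high
#' group for the CHD cohort (rows with `n = 0` and absent statistics when a
#' group is empty). Statistics are mean and sample SD of the capped ratio.
#'
#' @param records Data frame of ratio records with at least `cohort_label`
#'   (`"normal"`/`"CHD"`), `ratio` and `group` columns (see
#'   [ratio_records()]).
#' @return Data frame with columns `cohort_label`, `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(records) {
  stopifnot(all(c("cohort_label", "ratio", "group") %in% names(records)))
  row_for <- function(label, group, x) {
    data.frame(cohort_label = label, group = group, n = length(x),
               mean = if (length(x) >= 1L) mean(x) else NA_real_,
               sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list()
  norm <- records$ratio[records$cohort_label == "normal"]
  if (length(norm) > 0L) out[[1L]] <- row_for("normal", "all", norm)
  if (any(records$cohort_label == "CHD")) {
    for (g in c("low", "normal", "high")) {
      x <- records$ratio[records$cohort_label == "CHD" & records$group == g]
      out[[length(out) + 1L]] <- row_for("CHD", g, x)
    }
  }
  do.call(rbind, out)
}

#' Assemble and round-trip ratio records
#'
#' The row type of the pipeline: one measured frame per row. `ratio_records()`
#' builds the canonical data frame (computing ratio, cap flag and group when
#' not supplied); `read_ratio_records()` / `write_ratio_records()` round-trip
#' it as CSV ('.' decimal, UTF-8, header row).
#'
#' @param case_id,frame_id Character identifiers.
#' @param cohort_label `"normal"` or `"CHD"` per case.
#' @param pa_px,ao_px Measured diameters (px).
#' @param cap Outlier cap for the ratio.
#' @param range A [standard_range()] used for grouping.
#' @return Data frame with columns `case_id`, `frame_id`, `cohort_label`,
#'   `pa_px`, `ao_px`, `ratio`, `clipped`, `group`.
#' @export
ratio_records <- function(case_id, frame_id, cohort_label, pa_px, ao_px,
                          cap = 3.5, range = default_standard_range()) {
  cl <- clip_ratio(compute_ratio(pa_px, ao_px), cap = cap)
  data.frame(case_id = as.character(case_id),
             frame_id = as.character(frame_id),
             cohort_label = as.character(cohort_label),
             pa_px = pa_px, ao_px = ao_px,
             ratio = cl$ratio, clipped = cl$clipped,
             group = as.character(classify_ratio(cl$ratio, range)),
             stringsAsFactors = FALSE)
}

#' @param path CSV file path.
#' @rdname ratio_records
#' @export
read_ratio_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' @param records Data frame as produced by `ratio_records()`.
#' @rdname ratio_records
#' @export
write_ratio_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.standard_range <- function(x, ...) {
  cat(sprintf("<standard_range> mean %.4g, +/- 2SD half-width %.4g -> [%.4g, %.4g]%s\n",
              x$mean, x$half_width_2sd, x$lower, x$upper,
              if (is.na(x$n_cases)) "" else sprintf(" (n = %d)", x$n_cases)))
  invisible(x)
}
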