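# Segmentation evaluation (Dice, mDice) and screening evaluation (deviation
# score, ROC curve, AUC, per-rater comparison).

#' Dice coefficient for one class
#'
#' Pixel-wise overlap `2 TP / (2 TP + FP + FN)` between the ground-truth and
#' predicted masks for a single vessel class; 1 means identical regions.
#'
#' @param gt,pred Integer label masks of identical shape.
#' @param class_code Class to evaluate.
#' @return Dice value in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
#' dice(m, m, 1)  # 1
dice <- function(gt, pred, class_code) {
  gt <- as_label_mask(gt); pred <- as_label_mask(pred)
  if (!identical(dim(gt), dim(pred)))
    caliper_abort("shape_mismatch", "gt and pred masks differ in shape")
  g <- gt == class_code
  p <- pred == class_code
  tp <- sum(g & p); fp <- sum(!g & p); fn <- sum(g & !p)
  if (tp + fp + fn == 0L)
    caliper_abort("undefined_dice",
                  sprintf("class %s absent from both masks: Dice is 0/0", class_code))
  2 * tp / (2 * tp + fp + fn)
}

#' Per-frame mean Dice (mDice)
#'
#' Mean of the per-class Dice values over the vessel classes evaluable in the
#' frame. By default a class absent from both masks is excluded from the mean
#' (its Dice is the undefined 0/0); set `absent_value = 1` to count perfect
#' agreement on absence instead.
#'
#' @param gt,pred Integer label masks of identical shape.
#' @param classes Classes to evaluate, default `vessel_classes()`.
#' @param absent_value `NULL` (default: exclude classes absent from both) or a
#'   number substituted for their Dice.
#' @return A `dice_report`: list with `per_class` (named numeric), `mdice`
#'   and `n_classes_evaluated`.
#' @export
mdice_frame <- function(gt, pred, classes = vessel_classes(),
                        absent_value = NULL) {
  gt <- as_label_mask(gt); pred <- as_label_mask(pred)
  if (!identical(dim(gt), dim(pred)))
    caliper_abort("shape_mismatch", "gt and pred masks differ in shape")
  per <- vapply(classes, function(k) {
    if (!any(gt == k) && !any(pred == k)) {
      if (is.null(absent_value)) NA_real_ else as.numeric(absent_value)
    } else dice(gt, pred, k)
  }, numeric(1))
  names(per) <- names(classes)
  eval_ok <- !is.na(per)
  structure(list(per_class = per,
                 mdice = mean(per[eval_ok]),
                 n_classes_evaluated = sum(eval_ok)),
            class = "dice_report")
}

#' Screening deviation score
#'
#' The score used for normal-vs-CHD discrimination: the absolute deviation of
#' the (capped) PA/Ao ratio from the standard-value mean, so abnormalities
#' above and below the normal band both score high.
#'
#' @param ratio Capped ratio(s).
#' @param range A [standard_range()].
#' @return `|ratio - range$mean|`.
#' @export
screening_score <- function(ratio, range = default_standard_range()) {
  stopifnot(inherits(range, "standard_range"))
  abs(ratio - range$mean)
}

#' ROC curve and AUC for CHD screening
#'
#' Threshold sweep over the unique scores in descending order, CHD as the
#' positive class; tied scores are grouped at a single threshold. The curve
#' starts at (0, 0), ends at (1, 1) and the AUC is its trapezoidal area,
#' which equals the Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores Numeric screening scores (larger = more abnormal).
#' @param labels Case labels, a vector containing `positive` and at least one
#'   other value.
#' @param positive Positive-class label, default `"CHD"`.
#' @return A `roc_result`: list with `thresholds` (descending, leading `Inf`
#'   for the (0, 0) point), `fpr`, `tpr`, `auc`, `n_positive`, `n_negative`.
#' @export
#' @examples
#' roc_auc(c(.9, .8, .2, .1), c("CHD", "CHD", "normal", "normal"))$auc  # 1
roc_auc <- function(scores, labels, positive = "CHD") {
  if (length(scores) != length(labels))
    caliper_abort("shape_mismatch", "scores and labels must have equal length")
  pos <- labels == positive
  if (all(pos) || !any(pos))
    caliper_abort("single_class",
                  "ROC needs both positive and negative labels present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_last <- which(diff(s) != 0)            # last index of each tie group
  grp_last <- c(grp_last, length(s))
  tp <- cumsum(p)[grp_last]
  fp <- cumsum(!p)[grp_last]
  P <- sum(pos); N <- sum(!pos)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[grp_last]),
                 fpr = fpr, tpr = tpr, auc = auc,
                 n_positive = P, n_negative = N),
            class = "roc_result")
}

#' Mean AUC across raters or folds
#'
#' @param aucs Non-empty numeric vector of AUC values.
#' @return Arithmetic mean.
#' @export
mean_auc <- function(aucs) {
  if (length(aucs) == 0L)
    caliper_abort("empty_input", "mean_auc needs at least one AUC")
  mean(aucs)
}

#' Screening evaluation of manual raters
#'
#' Emulates the examiner comparison: each rater's PA/Ao measurements on a
#' common case set become capped ratios, deviation scores and an ROC AUC;
#' raters are then averaged within skill groups (arithmetic mean of per-rater
#' AUCs).
#'
#' @param ratings Data frame with columns `rater_id`, `skill_group`,
#'   `case_id`, `label` (`"normal"`/`"CHD"`), `pa_px`, `ao_px`.
#' @param range A [standard_range()] providing the score origin.
#' @param cap Outlier cap for the ratios.
#' @return A `rater_evaluation`: list with `per_rater` (data frame
#'   `rater_id`, `skill_group`, `auc`) and `per_group` (data frame
#'   `skill_group`, `n_raters`, `mean_auc`).
#' @export
rater_evaluation <- function(ratings, range = default_standard_range(),
                             cap = 3.5) {
  need <- c("rater_id", "skill_group", "case_id", "label", "pa_px", "ao_px")
  stopifnot(all(need %in% names(ratings)))
  case_sets <- tapply(ratings$case_id, ratings$rater_id,
                      function(x) paste(sort(unique(x)), collapse = "|"))
  if (length(unique(case_sets)) != 1L)
    caliper_abort("shape_mismatch", "all raters must rate the same case set")
  raters <- unique(ratings[, c("rater_id", "skill_group")])
  raters$auc <- vapply(raters$rater_id, function(rid) {
    d <- ratings[ratings$rater_id == rid, ]
    ratio <- clip_ratio(compute_ratio(d$pa_px, d$ao_px), cap = cap)$ratio
    roc_auc(screening_score(ratio, range), d$label)$auc
  }, numeric(1))
  groups <- unique(raters$skill_group)
  per_group <- data.frame(
    skill_group = groups,
    n_raters = vapply(groups, function(g) sum(raters$skill_group == g), integer(1)),
    mean_auc = vapply(groups, function(g)
      mean_auc(raters$auc[raters$skill_group == g]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(raters) <- rownames(per_group) <- NULL
  structure(list(per_rater = raters, per_group = per_group),
            class = "rater_evaluation")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report>\n")
  for (k in seq_along(x$per_class))
    cat(sprintf("  %-4s %s\n", names(x$per_class)[k],
                ifelse(is.na(x$per_class[k]), "absent (excluded)",
                       sprintf("%.4f", x$per_class[k]))))
  cat(sprintf("  mDice %.4f over %d class(es)\n", x$mdice, x$n_classes_evaluated))
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positive / %d negative, %d thresholds)\n",
              x$auc, x$n_positive, x$n_negative, length(x$thresholds)))
  invisible(x)
}

#' @param x A `roc_result`.
#' @param ... Passed to [graphics::plot()].
#' @rdname roc_auc
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
print.rater_evaluation <- function(x, ...) {
  cat("<rater_evaluation>\n  per skill group:\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
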