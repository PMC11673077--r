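test_that("Dice matches its pixel-count definition", {
  a <- rect_mask(10, 10, 2:4, 2:4)
  expect_equal(dice(a, a, 1), 1.0)

  b <- rect_mask(10, 10, 6:8, 6:8)                 # disjoint, same size
  expect_equal(dice(a, b, 1), 0.0)

  # TP = 5, FP = 5, FN = 5 -> 0.5
  gt <- matrix(0L, 5, 5); gt[1:10] <- 1L
  pr <- matrix(0L, 5, 5); pr[6:15] <- 1L
  expect_equal(dice(gt, pr, 1), 0.5)

  expect_error(dice(a, rect_mask(9, 10, 2:4, 2:4), 1), class = "shape_mismatch")
  expect_error(dice(a, b, 2), class = "undefined_dice")
})

test_that("Dice is symmetric and 1 iff regions are identical", {
  set.seed(7)
  for (k in 1:30) {
    g <- random_mask(); p <- random_mask()
    for (cls in 1:3) {
      if (!any(g == cls) && !any(p == cls)) next
      d1 <- dice(g, p, cls)
      expect_identical(d1, dice(p, g, cls))
      expect_identical(d1 == 1, identical(which(g == cls), which(p == cls)))
    }
  }
})

test_that("mDice averages evaluable classes and excludes absent-in-both", {
  g <- matrix(0L, 12, 12); g[1:3, 1:3] <- 1L; g[5:7, 5:7] <- 2L; g[9:10, 9:10] <- 3L
  p <- g
  expect_equal(mdice_frame(g, p)$mdice, 1.0)

  g2 <- g; g2[g2 == 3L] <- 0L
  p2 <- p; p2[p2 == 3L] <- 0L                    # SVC absent from both
  rep2 <- mdice_frame(g2, p2)
  expect_equal(rep2$n_classes_evaluated, 2)
  expect_equal(rep2$mdice, mean(c(dice(g2, p2, 1), dice(g2, p2, 2))))
  expect_true(is.na(rep2$per_class[["SVC"]]))
  # alternative convention: absent-in-both counts as perfect
  expect_equal(mdice_frame(g2, p2, absent_value = 1)$n_classes_evaluated, 3)
  expect_equal(mdice_frame(g2, p2, absent_value = 1)$mdice, 1.0)

  p3 <- p; p3[p3 == 2L] <- 1L                    # degraded prediction
  rep3 <- mdice_frame(g, p3)
  expect_equal(rep3$mdice,
               mean(c(dice(g, p3, 1), dice(g, p3, 2), dice(g, p3, 3))))
})

test_that("screening score is the absolute deviation from the cohort mean", {
  sr <- default_standard_range()
  expect_equal(screening_score(1.237, sr), 0)
  expect_equal(screening_score(0.873, sr), screening_score(1.601, sr))
  expect_equal(screening_score(0.873, sr), 0.364)
  x <- seq(1.237, 3, length.out = 50)
  expect_true(all(diff(screening_score(x, sr)) > 0))   # monotone in |r - mean|
})

test_that("ROC sweep handles separation, inversion and ties", {
  lab <- c("CHD", "CHD", "normal", "normal")
  expect_equal(roc_auc(c(.9, .8, .2, .1), lab)$auc, 1.0)
  expect_equal(roc_auc(c(.9, .8, .2, .1), rev(lab))$auc, 0.0)
  expect_equal(roc_auc(rep(1, 4), lab)$auc, 0.5)
  r <- roc_auc(c(.9, .8, .2, .1), lab)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$thresholds) < 0))
  expect_error(roc_auc(c(1, 2), c("CHD", "CHD")), class = "single_class")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic and its identities", {
  set.seed(11)
  for (k in 1:40) {
    n <- sample(6:60, 1)
    lab <- c("CHD", "normal", sample(c("CHD", "normal"), n - 2, TRUE))
    sc <- sample(round(rnorm(n), sample(0:2, 1)))    # induce ties
    a <- roc_auc(sc, lab)$auc
    expect_equal(a, mw_auc(sc, lab), tolerance = 1e-9)
    # complement under label flip
    flip <- ifelse(lab == "CHD", "normal", "CHD")
    expect_equal(a + roc_auc(sc, flip)$auc, 1, tolerance = 1e-9)
    # invariance under strictly monotone score transforms
    expect_equal(roc_auc(exp(2 * sc) + 1, lab)$auc, a, tolerance = 1e-9)
  }
})

test_that("AUC agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (k in 1:10) {
    lab <- c("CHD", "normal", sample(c("CHD", "normal"), 40, TRUE))
    sc <- round(rnorm(42), 1)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = lab, predictor = sc, levels = c("normal", "CHD"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(sc, lab)$auc, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("mean AUC is the arithmetic mean", {
  expect_equal(mean_auc(c(1.0, 0.5)), 0.75)
  expect_equal(mean_auc(0.883), 0.883)
  x <- runif(7)
  expect_equal(mean_auc(x), mean_auc(rev(x)))
  expect_error(mean_auc(numeric(0)), class = "empty_input")
})

test_that("rater evaluation scores each rater then averages by skill group", {
  cases <- data.frame(case_id = sprintf("c%02d", 1:12),
                      label = rep(c("normal", "CHD"), each = 6))
  perfect <- data.frame(rater_id = "r1", skill_group = "expert",
                        cases,
                        pa_px = ifelse(cases$label == "CHD", 36, 25),
                        ao_px = 20)
  ev1 <- rater_evaluation(perfect)
  expect_equal(ev1$per_rater$auc, 1.0)

  chance <- perfect
  chance$rater_id <- "r2"
  chance$pa_px <- 25                     # constant ratio -> AUC 0.5
  ev2 <- rater_evaluation(rbind(perfect, chance))
  expect_equal(ev2$per_group$mean_auc, 0.75)

  bad <- chance; bad$case_id[1] <- "c99"
  expect_error(rater_evaluation(rbind(perfect, bad)), class = "shape_mismatch")
})

test_that("rater AUC degrades as measurement noise grows", {
  cases <- data.frame(case_id = sprintf("c%02d", 1:40),
                      label = rep(c("normal", "CHD"), each = 20))
  true_ratio <- ifelse(cases$label == "CHD",
                       rep(c(0.85, 1.7), 10), 1.24)
  auc_at_noise <- function(noise_sd) {
    aucs <- vapply(1:20, function(rep) {
      withr::with_seed(1000 * noise_sd + rep, {
        tab <- data.frame(rater_id = "r", skill_group = "g", cases,
                          pa_px = pmax(1, true_ratio * 20 + rnorm(40, 0, noise_sd)),
                          ao_px = pmax(1, 20 + rnorm(40, 0, noise_sd)))
        rater_evaluation(tab)$per_rater$auc
      })
    }, numeric(1))
    mean(aucs)
  }
  curve <- vapply(c(0.5, 3, 8, 16), auc_at_noise, numeric(1))
  expect_true(all(diff(curve) < 0))
})
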