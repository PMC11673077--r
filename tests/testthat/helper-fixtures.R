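# Shared fixtures, all generated in code.

# rectangular block of one class on empty background
rect_mask <- function(h, w, rows, cols, code = 1L) {
  m <- matrix(0L, h, w)
  m[rows, cols] <- as.integer(code)
  m
}

# rotate a matrix 90 degrees (counter-clockwise in (row, col) indexing)
rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

# smooth ultrasound-like grayscale image: Gaussian bumps inside a centered
# disk, black background (so center rotation does not clip content)
smooth_phantom_image <- function(h = 96, w = 96, seed = 5, n_bumps = 6) {
  withr::with_seed(seed, {
    r <- outer(0:(h - 1), rep(1, w))
    c <- outer(rep(1, h), 0:(w - 1))
    img <- matrix(0, h, w)
    for (k in seq_len(n_bumps)) {
      cr <- runif(1, h * 0.3, h * 0.7)
      cc <- runif(1, w * 0.3, w * 0.7)
      s <- runif(1, 6, 14)
      img <- img + runif(1, 60, 180) * exp(-((r - cr)^2 + (c - cc)^2) / (2 * s^2))
    }
    d2 <- (r - (h - 1) / 2)^2 + (c - (w - 1) / 2)^2
    img[d2 > (min(h, w) * 0.38)^2] <- 0
    saturate_cast(img)
  })
}

# random multi-class label mask (not necessarily connected regions)
random_mask <- function(h = 24, w = 24, p_fg = 0.25) {
  m <- matrix(0L, h, w)
  fg <- runif(h * w) < p_fg
  m[fg] <- sample(1:3, sum(fg), replace = TRUE)
  m
}

# Mann-Whitney pair-counting AUC (ties counted 1/2): independent oracle for
# the trapezoidal ROC AUC
mw_auc <- function(scores, labels, positive = "CHD") {
  s1 <- scores[labels == positive]
  s0 <- scores[labels != positive]
  mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
}
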