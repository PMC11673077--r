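# Synthetic phantoms: rasterized elliptical vessel cross-sections with known
# axes, whole 3VV-like frames, configurable cohorts of cases, and controlled
# mask degradations. Everything downstream is testable against the known
# geometry: an ellipse with minor semi-axis b has true perpendicular
# diameter 2b, and a phantom frame has true ratio pa_2b / ao_2b.

#' Specify an elliptical vessel cross-section
#'
#' @param center `(row, col)` center, 0-based pixel coordinates.
#' @param a,b Semi-major / semi-minor axes in pixels; `a >= b > 0`. The
#'   ground-truth perpendicular diameter is `2 * b`.
#' @param theta Orientation of the major axis in degrees (0 = along columns).
#' @param class_code Vessel class the rasterization will carry.
#' @return An `ellipse_spec`.
#' @export
ellipse_spec <- function(center, a, b, theta = 0, class_code = 1L) {
  if (!(is.finite(a) && is.finite(b) && b > 0 && a >= b))
    caliper_abort("format_error", "ellipse_spec requires a >= b > 0")
  structure(list(center = as.numeric(center), a = a, b = b,
                 theta = theta, class_code = as.integer(class_code)),
            class = "ellipse_spec")
}

#' Rasterize an ellipse onto a pixel lattice
#'
#' Pixel-center-inside rasterization (no anti-aliasing): a pixel belongs to
#' the ellipse iff its integer center satisfies the rotated-ellipse
#' inequality. Counts are therefore exactly reproducible; a circle of radius
#' 10 at the canvas center contains 317 pixels (the lattice points with
#' x^2 + y^2 <= 100).
#'
#' @param spec An [ellipse_spec()].
#' @param canvas `(height, width)` in pixels; the ellipse's bounding box must
#'   fit inside it.
#' @return A `vessel_region` (see [extract_vessel_region()]).
#' @export
rasterize_ellipse <- function(spec, canvas) {
  stopifnot(inherits(spec, "ellipse_spec"), length(canvas) == 2L)
  h <- canvas[1L]; w <- canvas[2L]
  th <- spec$theta * pi / 180
  # extent of the rotated ellipse along row/col axes
  ext_c <- sqrt((spec$a * cos(th))^2 + (spec$b * sin(th))^2)
  ext_r <- sqrt((spec$a * sin(th))^2 + (spec$b * cos(th))^2)
  if (spec$center[1L] - ext_r < 0 || spec$center[1L] + ext_r > h - 1 ||
      spec$center[2L] - ext_c < 0 || spec$center[2L] + ext_c > w - 1)
    caliper_abort("out_of_canvas",
                  sprintf("ellipse extent exceeds the %d x %d canvas", h, w))
  rr <- floor(spec$center[1L] - ext_r):ceiling(spec$center[1L] + ext_r)
  cc <- floor(spec$center[2L] - ext_c):ceiling(spec$center[2L] + ext_c)
  dr <- outer(rr - spec$center[1L], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - spec$center[2L])
  # coordinates in the ellipse frame: major axis along theta
  um <- dc * cos(th) + dr * sin(th)
  vm <- -dc * sin(th) + dr * cos(th)
  inside <- (um / spec$a)^2 + (vm / spec$b)^2 <= 1
  px <- cbind(row = as.integer(outer(rr, rep(1L, length(cc)))[inside]),
              col = as.integer(outer(rep(1L, length(rr)), cc)[inside]))
  px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
  if (nrow(px) == 0L)
    caliper_abort("degenerate_region", "ellipse rasterizes to zero pixels")
  structure(list(class_code = spec$class_code, pixels = px, n_pixels = nrow(px)),
            class = "vessel_region")
}

#' Generate a phantom 3VV frame
#'
#' Rasterizes a PA and an Ao ellipse (and optionally an SVC) onto one label
#' mask and returns the mask together with its ground truth: each vessel's
#' true diameter `2b` and the implied PA/Ao ratio.
#'
#' @param pa,ao [ellipse_spec()]s for the PA (class 1) and Ao (class 2).
#' @param svc Optional [ellipse_spec()] for the SVC (class 3).
#' @param canvas `(height, width)` of the mask.
#' @return List with `mask` (integer label mask) and `truth` (list with
#'   `pa_2b`, `ao_2b`, `svc_2b` (`NA` if absent) and `ratio`).
#' @export
generate_phantom_frame <- function(pa, ao, svc = NULL, canvas = c(128, 128)) {
  specs <- list(PA = pa, Ao = ao)
  if (!is.null(svc)) specs$SVC <- svc
  regs <- lapply(specs, rasterize_ellipse, canvas = canvas)
  keys <- lapply(regs, function(r) r$pixels[, 1L] * canvas[2L] + r$pixels[, 2L])
  nm <- names(regs)
  for (i in seq_along(regs)) for (j in seq_len(i - 1L)) {
    if (length(intersect(keys[[i]], keys[[j]])) > 0L)
      caliper_abort("overlap_error",
                    sprintf("phantom vessels %s and %s overlap after rasterization",
                            nm[j], nm[i]))
  }
  mask <- matrix(0L, canvas[1L], canvas[2L])
  for (r in regs) mask[r$pixels + 1L] <- r$class_code
  truth <- list(pa_2b = 2 * pa$b, ao_2b = 2 * ao$b,
                svc_2b = if (is.null(svc)) NA_real_ else 2 * svc$b,
                ratio = pa$b / ao$b)
  list(mask = mask, truth = truth)
}

#' Specify a synthetic screening cohort
#'
#' The cohort generator emulates the structure of a fetal screening study:
#' normal cases with ratios drawn from one normal distribution and CHD cases
#' from a three-component mixture (low / normal / high groups). The normal
#' distribution defaults to mean 1.237, SD 0.182 (so its +/- 2 SD band is the
#' bundled standard value); the CHD mixture defaults (weights 0.3/0.4/0.3,
#' means 0.9/1.25/1.65, SD 0.15) are fixture choices loosely patterned on
#' reported group statistics, not measured values.
#'
#' @param n_normal,n_chd Cohort sizes.
#' @param normal_mu,normal_sigma Normal-cohort ratio distribution.
#' @param chd_weights Mixture weights for the low/normal/high CHD groups
#'   (must sum to 1).
#' @param chd_mu,chd_sigma Component means / SDs, length 3.
#' @param ao_diameter_px Fixed Ao minor full-axis (2b) in pixels; the PA's is
#'   scaled by the drawn ratio.
#' @param aspect_range Uniform range for each ellipse's a/b aspect.
#' @param ratio_limits Draws are truncated (redrawn) to this open interval so
#'   every case rasterizes to a measurable vessel.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 50, n_chd = 15,
                        normal_mu = 1.237, normal_sigma = 0.182,
                        chd_weights = c(low = 0.3, normal = 0.4, high = 0.3),
                        chd_mu = c(low = 0.9, normal = 1.25, high = 1.65),
                        chd_sigma = c(low = 0.15, normal = 0.15, high = 0.15),
                        ao_diameter_px = 30, aspect_range = c(1.1, 1.6),
                        ratio_limits = c(0.45, 3.4), seed = 1L) {
  stopifnot(abs(sum(chd_weights) - 1) < 1e-9, all(chd_sigma >= 0),
            normal_sigma >= 0, ao_diameter_px > 0,
            length(chd_mu) == 3L, length(chd_sigma) == 3L)
  structure(list(n_normal = n_normal, n_chd = n_chd,
                 normal_mu = normal_mu, normal_sigma = normal_sigma,
                 chd_weights = chd_weights, chd_mu = chd_mu,
                 chd_sigma = chd_sigma, ao_diameter_px = ao_diameter_px,
                 aspect_range = aspect_range, ratio_limits = ratio_limits,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rtruncnorm1 <- function(mu, sigma, lim) {
  repeat {
    x <- stats::rnorm(1, mu, sigma)
    if (x > lim[1] && x < lim[2]) return(x)
  }
}

#' Generate a synthetic cohort of phantom frames
#'
#' For each case a true ratio is drawn from its cohort distribution and
#' realized as a PA/Ao ellipse pair (Ao minor axis fixed, PA's scaled by the
#' ratio) with random orientations and aspects, rasterized side by side on a
#' per-case canvas. Seeded and fully reproducible.
#'
#' @param spec A [cohort_spec()].
#' @return A `phantom_cohort`: list with `masks` (list of label masks) and
#'   `truth` (data frame `case_id`, `cohort_label`, `group_drawn`,
#'   `true_ratio`, `pa_2b`, `ao_2b`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_normal + spec$n_chd
    labels <- rep(c("normal", "CHD"), c(spec$n_normal, spec$n_chd))
    groups <- character(n)
    ratios <- numeric(n)
    for (i in seq_len(n)) {
      if (labels[i] == "normal") {
        groups[i] <- "normal"
        ratios[i] <- rtruncnorm1(spec$normal_mu, spec$normal_sigma,
                                 spec$ratio_limits)
      } else {
        g <- sample(c("low", "normal", "high"), 1, prob = spec$chd_weights)
        groups[i] <- g
        k <- match(g, c("low", "normal", "high"))
        ratios[i] <- rtruncnorm1(spec$chd_mu[k], spec$chd_sigma[k],
                                 spec$ratio_limits)
      }
    }
    ao_b <- spec$ao_diameter_px / 2
    masks <- vector("list", n)
    pa_2b <- numeric(n)
    for (i in seq_len(n)) {
      pa_b <- ratios[i] * ao_b
      aspects <- stats::runif(2, spec$aspect_range[1], spec$aspect_range[2])
      thetas <- stats::runif(2, 0, 180)
      pa_a <- aspects[1] * pa_b
      ao_a <- aspects[2] * ao_b
      big <- ceiling(max(pa_a, ao_a))
      h <- 2L * big + 9L
      w <- as.integer(2 * ceiling(pa_a) + 2 * ceiling(ao_a) + 15L)
      ctr_r <- (h - 1) / 2
      pa_ctr <- c(ctr_r, ceiling(pa_a) + 3)
      ao_ctr <- c(ctr_r, w - 1 - (ceiling(ao_a) + 3))
      fr <- generate_phantom_frame(
        ellipse_spec(pa_ctr, pa_a, pa_b, thetas[1], 1L),
        ellipse_spec(ao_ctr, ao_a, ao_b, thetas[2], 2L),
        canvas = c(h, w))
      masks[[i]] <- fr$mask
      pa_2b[i] <- 2 * pa_b
    }
    truth <- data.frame(case_id = sprintf("case%04d", seq_len(n)),
                        cohort_label = labels, group_drawn = groups,
                        true_ratio = ratios, pa_2b = pa_2b, ao_2b = 2 * ao_b,
                        stringsAsFactors = FALSE)
    structure(list(masks = masks, truth = truth, spec = spec),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases (%d normal, %d CHD), seed %d\n",
              nrow(x$truth), sum(x$truth$cohort_label == "normal"),
              sum(x$truth$cohort_label == "CHD"), x$spec$seed))
  invisible(x)
}

#' Controlled degradation of a label mask
#'
#' Per-class perturbations for evaluation fixtures and noise-propagation
#' studies: morphological `erode` / `dilate` (disc structuring element of
#' radius `magnitude_px`), rigid `shift` of all foreground by `magnitude_px`
#' in a random direction, or `dropout` deleting each foreground pixel with
#' probability `magnitude_px` (interpreted as a fraction in `[0, 1]`).
#' Magnitude 0 is the identity; the class alphabet is preserved. When dilated
#' classes collide, the higher class code wins (deterministic).
#'
#' @param mask Integer label mask.
#' @param operation One of `"erode"`, `"dilate"`, `"shift"`, `"dropout"`.
#' @param magnitude_px Non-negative magnitude (pixels; a probability for
#'   `dropout`).
#' @param seed Optional seed for the random operations.
#' @return Degraded integer label mask, same shape.
#' @export
degrade_mask <- function(mask, operation = c("erode", "dilate", "shift", "dropout"),
                         magnitude_px = 1, seed = NULL) {
  mask <- as_label_mask(mask)
  operation <- match.arg(operation)
  stopifnot(magnitude_px >= 0)
  if (magnitude_px == 0) return(mask)
  run <- function() {
    out <- matrix(0L, nrow(mask), ncol(mask))
    if (operation %in% c("erode", "dilate")) {
      brush <- EBImage::makeBrush(2L * ceiling(magnitude_px) + 1L, "disc")
      for (k in sort(unique(mask[mask > 0L]))) {
        bin <- (mask == k) * 1
        bin <- if (operation == "erode") EBImage::erode(bin, brush)
               else EBImage::dilate(bin, brush)
        out[EBImage::imageData(bin) > 0.5] <- k
      }
    } else if (operation == "shift") {
      ang <- stats::runif(1, 0, 2 * pi)
      dr <- round(magnitude_px * cos(ang)); dc <- round(magnitude_px * sin(ang))
      idx <- which(mask > 0L, arr.ind = TRUE)
      nr <- idx[, 1L] + dr; nc <- idx[, 2L] + dc
      ok <- nr >= 1L & nr <= nrow(mask) & nc >= 1L & nc <= ncol(mask)
      out[cbind(nr[ok], nc[ok])] <- mask[idx[ok, , drop = FALSE]]
    } else { # dropout
      p <- min(magnitude_px, 1)
      out <- mask
      fg <- which(out > 0L)
      drop <- fg[stats::runif(length(fg)) < p]
      out[drop] <- 0L
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random connected pixel blob
#'
#' A seeded random-growth blob (start at the origin pixel, repeatedly attach
#' an unoccupied 8-neighbor of a random member) used as a test shape: it is
#' 8-connected by construction and has exactly `n_pixels` pixels.
#'
#' @param n_pixels Target size, >= 1.
#' @param class_code Vessel class carried by the region.
#' @param seed Optional integer seed.
#' @return A `vessel_region`.
#' @export
random_blob <- function(n_pixels, class_code = 1L, seed = NULL) {
  stopifnot(n_pixels >= 1)
  grow <- function() {
    side <- as.integer(ceiling(4 * sqrt(n_pixels)) + 10L)
    occ <- matrix(FALSE, side, side)
    ctr <- as.integer(side %/% 2)
    occ[ctr, ctr] <- TRUE
    px <- matrix(0L, n_pixels, 2L)
    px[1L, ] <- c(ctr, ctr)
    filled <- 1L
    while (filled < n_pixels) {
      base <- px[sample.int(filled, 1L), ]
      nb <- base + c(sample(-1:1, 1L), sample(-1:1, 1L))
      if (any(nb < 1L) || any(nb > side)) next
      if (!occ[nb[1L], nb[2L]]) {
        occ[nb[1L], nb[2L]] <- TRUE
        filled <- filled + 1L
        px[filled, ] <- nb
      }
    }
    px <- px - 1L  # 0-based
    px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
    colnames(px) <- c("row", "col")
    structure(list(class_code = as.integer(class_code), pixels = px,
                   n_pixels = nrow(px)),
              class = "vessel_region")
  }
  if (is.null(seed)) grow() else withr::with_seed(seed, grow())
}
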