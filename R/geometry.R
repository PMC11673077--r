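# Vessel geometry: region extraction, principal (long) axis, and the maximal
# chord perpendicular to that axis — the diameter definition used for the
# PA/Ao ratio. Pixel coordinates are (row, col), 0-based, pixel centers at
# integers; diameters are Euclidean distances between pixel centers.

#' Extract the region of one vessel class from a label mask
#'
#' Returns the largest 8-connected component of pixels carrying `class_code`.
#' Ties between equally large components are broken deterministically by the
#' component anchor (topmost, then leftmost pixel).
#'
#' @param mask Integer label mask (see [as_label_mask()]).
#' @param class_code Vessel class, one of `vessel_classes()`.
#' @return A `vessel_region`: list with `class_code`, `pixels` (n x 2 integer
#'   matrix of 0-based (row, col) pixel centers, row-major order) and
#'   `n_pixels`.
#' @export
#' @examples
#' m <- matrix(0L, 8, 8); m[2:6, 2:6] <- 1L
#' extract_vessel_region(m, 1)$n_pixels  # 25
extract_vessel_region <- function(mask, class_code) {
  mask <- as_label_mask(mask)
  class_code <- as.integer(class_code)
  stopifnot(length(class_code) == 1L, class_code %in% 1:3)
  idx <- which(mask == class_code)
  if (length(idx) == 0L) abort_missing_vessel(class_code)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr          # 0-based row
  c <- (idx - 1L) %/% nr         # 0-based col
  comp <- label_components_8(r, c)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # anchor = (min row, then min col at that row) of each tied component
    anchor_r <- vapply(best, function(k) min(r[comp == k]), numeric(1))
    anchor_c <- vapply(best, function(k) {
      sel <- comp == k & r == min(r[comp == k]); min(c[sel])
    }, numeric(1))
    best <- best[order(anchor_r, anchor_c)][1L]
  }
  keep <- comp == best
  px <- cbind(row = r[keep], col = c[keep])
  px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
  structure(list(class_code = class_code,
                 pixels = px,
                 n_pixels = nrow(px)),
            class = "vessel_region")
}

# 8-connected component labelling of a pixel set given 0-based (row, col)
# vectors; returns an integer component id per pixel. Adjacency is built
# vectorised (E, S, SE, SW neighbours) and components come from igraph.
label_components_8 <- function(r, c) {
  n <- length(r)
  if (n == 1L) return(1L)
  key <- r * (max(c) + 2) + c            # unique key per pixel
  lookup <- match(c((r)     * (max(c) + 2) + (c + 1),   # E
                    (r + 1) * (max(c) + 2) + (c),       # S
                    (r + 1) * (max(c) + 2) + (c + 1),   # SE
                    (r + 1) * (max(c) + 2) + (c - 1)),  # SW
                  key)
  from <- rep.int(seq_len(n), 4L)
  ok <- !is.na(lookup)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(ok))
    g <- igraph::add_edges(g, rbind(from[ok], lookup[ok]))
  as.integer(igraph::components(g)$membership)
}

#' Principal (long) axis of a vessel region
#'
#' The long axis is the principal eigenvector of the covariance of the pixel
#' (row, col) coordinates, sign-normalized so its first nonzero component is
#' positive. `anisotropy` (ratio of principal to secondary eigenvalue, >= 1)
#' lets callers detect near-circular regions where the axis orientation is
#' unstable; the diameter is insensitive to it there.
#'
#' @param region A `vessel_region`.
#' @return A `vessel_axis`: list with `direction` (unit (row, col) vector),
#'   `centroid`, `anisotropy` and `near_degenerate` (`TRUE` when
#'   anisotropy < 1.05).
#' @export
principal_axis <- function(region) {
  stopifnot(inherits(region, "vessel_region"))
  px <- region$pixels
  if (nrow(px) < 2L)
    abort_degenerate_region("principal axis needs at least 2 pixels")
  cov_m <- stats::cov(px)
  e <- eigen(cov_m, symmetric = TRUE)
  dir <- e$vectors[, 1L]
  nz <- which(abs(dir) > 1e-12)[1L]
  if (dir[nz] < 0) dir <- -dir
  lam <- pmax(e$values, 0)
  aniso <- if (lam[2L] <= .Machine$double.eps * lam[1L]) Inf else lam[1L] / lam[2L]
  structure(list(direction = dir,
                 centroid = colMeans(px),
                 anisotropy = aniso,
                 near_degenerate = is.finite(aniso) && aniso < 1.05),
            class = "vessel_axis")
}

#' Maximal chord perpendicular to the long axis
#'
#' The vessel diameter: the maximum, over pixel pairs (a, b) of the region
#' whose connecting segment is perpendicular to `axis` within a projection
#' tolerance, of the Euclidean distance ||a - b|| between pixel centers.
#' Perpendicularity on the lattice means |(a - b) . direction| <= `tol_px`.
#'
#' `perpendicular_diameter()` uses a sorted-projection sweep that enumerates
#' only pairs inside the tolerance band; `diameter_oracle()` is the literal
#' all-pairs enumeration kept as the reference implementation. Both compute
#' the identical maximum.
#'
#' @param region A `vessel_region`.
#' @param axis A `vessel_axis`, normally from [principal_axis()].
#' @param tol_px Projection tolerance in pixels (default 0.5, half the
#'   pixel-center spacing).
#' @param extent_correction If `TRUE`, add 1 px to the reported length so it
#'   counts pixel extents rather than center-to-center distance. The
#'   convention cancels in the PA/Ao ratio; default off.
#' @return A `diameter_measurement`: list with endpoints `a`, `b` (0-based
#'   (row, col)), `length_px`, the `axis` used and `tol_px`.
#' @export
perpendicular_diameter <- function(region, axis, tol_px = 0.5,
                                   extent_correction = FALSE) {
  stopifnot(inherits(region, "vessel_region"), inherits(axis, "vessel_axis"),
            tol_px >= 0)
  px <- region$pixels
  if (nrow(px) < 2L)
    abort_degenerate_region("diameter needs at least 2 pixels (a != b)")
  u <- as.vector(px %*% axis$direction)
  ord <- order(u, px[, 1L], px[, 2L])
  us <- u[ord]
  P <- px[ord, , drop = FALSE]
  n <- length(us)
  # candidate window per point: a hair wider than tol, then exact re-filter
  hi <- findInterval(us + tol_px + 1e-9, us)
  cnt <- hi - seq_len(n)
  best_len <- -Inf
  best_pair <- NULL
  # chunk the pair enumeration to bound memory on degenerate geometries
  starts <- chunk_starts(cnt, max_pairs = 2e6)
  for (k in seq_along(starts)) {
    rows <- starts[[k]]
    ck <- cnt[rows]
    if (sum(ck) == 0) next
    i_idx <- rep.int(rows, ck)
    j_idx <- i_idx + sequence(ck)
    keep <- (us[j_idx] - us[i_idx]) <= tol_px
    if (!any(keep)) next
    i_idx <- i_idx[keep]; j_idx <- j_idx[keep]
    len <- sqrt((P[i_idx, 1L] - P[j_idx, 1L])^2 +
                (P[i_idx, 2L] - P[j_idx, 2L])^2)
    m <- max(len)
    if (m > best_len) {
      w <- which(len == m)[1L]
      best_len <- m
      best_pair <- rbind(P[i_idx[w], ], P[j_idx[w], ])
    }
  }
  if (!is.finite(best_len) || best_len <= 0)
    abort_degenerate_region(
      "no admissible pixel pair perpendicular to the axis within tolerance")
  ab <- best_pair[order(best_pair[, 1L], best_pair[, 2L]), , drop = FALSE]
  structure(list(a = ab[1L, ], b = ab[2L, ],
                 length_px = best_len + if (extent_correction) 1 else 0,
                 axis = axis, tol_px = tol_px,
                 extent_correction = extent_correction),
            class = "diameter_measurement")
}

# split point indices 1..n into chunks whose pair counts stay <= max_pairs
chunk_starts <- function(cnt, max_pairs) {
  n <- length(cnt)
  out <- list()
  i <- 1L
  while (i <= n) {
    tot <- cumsum(as.numeric(cnt[i:n]))
    j <- i + max(1L, findInterval(max_pairs, tot + 1)) - 1L
    j <- min(j, n)
    out[[length(out) + 1L]] <- i:j
    i <- j + 1L
  }
  out
}

#' @rdname perpendicular_diameter
#' @export
diameter_oracle <- function(region, axis, tol_px = 0.5) {
  stopifnot(inherits(region, "vessel_region"), inherits(axis, "vessel_axis"),
            tol_px >= 0)
  px <- region$pixels
  n <- nrow(px)
  if (n < 2L)
    abort_degenerate_region("diameter needs at least 2 pixels (a != b)")
  u <- as.vector(px %*% axis$direction)
  best <- -Inf
  # literal all-pairs enumeration, blocked over rows for memory
  for (i0 in seq(1L, n, by = 512L)) {
    i1 <- min(i0 + 511L, n)
    du <- abs(outer(u[i0:i1], u, "-"))
    d <- sqrt(outer(px[i0:i1, 1L], px[, 1L], "-")^2 +
              outer(px[i0:i1, 2L], px[, 2L], "-")^2)
    d[du > tol_px] <- -Inf
    d[cbind(seq_len(i1 - i0 + 1L), i0:i1)] <- -Inf  # a != b
    m <- max(d)
    if (m > best) best <- m
  }
  if (!is.finite(best) || best <= 0)
    abort_degenerate_region(
      "no admissible pixel pair perpendicular to the axis within tolerance")
  best
}

#' Measure a whole 3VV frame
#'
#' Runs the full per-frame chain: extract each vessel region, fit its long
#' axis, measure the perpendicular diameter, and form the capped PA/Ao ratio.
#' PA and Ao are required; the SVC is measured when present.
#'
#' @param mask Integer label mask.
#' @param tol_px,extent_correction Passed to [perpendicular_diameter()].
#' @param cap Outlier cap applied to the ratio (see [clip_ratio()]).
#' @return A `frame_measurement`: list with per-vessel `diameters`
#'   (named list of `diameter_measurement`), `pa_px`, `ao_px`, `svc_px`
#'   (`NA` if absent), `ratio_raw`, `ratio` (capped) and `clipped`.
#' @export
measure_frame <- function(mask, tol_px = 0.5, extent_correction = FALSE,
                          cap = 3.5) {
  mask <- as_label_mask(mask)
  cls <- vessel_classes()
  measure_one <- function(code) {
    reg <- extract_vessel_region(mask, code)
    perpendicular_diameter(reg, principal_axis(reg), tol_px = tol_px,
                           extent_correction = extent_correction)
  }
  dia <- list(PA = measure_one(cls[["PA"]]), Ao = measure_one(cls[["Ao"]]))
  svc_px <- NA_real_
  if (any(mask == cls[["SVC"]])) {
    dia$SVC <- measure_one(cls[["SVC"]])
    svc_px <- dia$SVC$length_px
  }
  raw <- compute_ratio(dia$PA$length_px, dia$Ao$length_px)
  cl <- clip_ratio(raw, cap = cap)
  structure(list(diameters = dia,
                 pa_px = dia$PA$length_px, ao_px = dia$Ao$length_px,
                 svc_px = svc_px,
                 ratio_raw = raw, ratio = cl$ratio, clipped = cl$clipped,
                 cap = cap),
            class = "frame_measurement")
}

#' @export
print.vessel_region <- function(x, ...) {
  cat(sprintf("<vessel_region> class %s (%s): %d pixels\n",
              x$class_code, vessel_class_name(x$class_code), x$n_pixels))
  invisible(x)
}

#' @export
print.vessel_axis <- function(x, ...) {
  cat(sprintf("<vessel_axis> direction (%.4f, %.4f), anisotropy %.3f%s\n",
              x$direction[1], x$direction[2], x$anisotropy,
              if (x$near_degenerate) " [near-circular]" else ""))
  invisible(x)
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf("<diameter_measurement> %.3f px, a=(%d,%d) b=(%d,%d), tol %.2f px\n",
              x$length_px, x$a[1], x$a[2], x$b[1], x$b[2], x$tol_px))
  invisible(x)
}

#' @export
print.frame_measurement <- function(x, ...) {
  cat(sprintf("<frame_measurement> PA %.2f px, Ao %.2f px, SVC %s, PA/Ao %.4f%s\n",
              x$pa_px, x$ao_px,
              if (is.na(x$svc_px)) "absent" else sprintf("%.2f px", x$svc_px),
              x$ratio, if (x$clipped) " (capped)" else ""))
  invisible(x)
}
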