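#' Vessel class codes
#'
#' Label masks encode the background as 0 and the three vessels of the
#' three-vessel view (3VV) as integer class codes: pulmonary artery (PA) = 1,
#' ascending aorta (Ao) = 2, superior vena cava (SVC) = 3.
#'
#' @return Named integer vector `c(PA = 1L, Ao = 2L, SVC = 3L)`.
#' @export
#' @examples
#' vessel_classes()
vessel_classes <- function() c(PA = 1L, Ao = 2L, SVC = 3L)

vessel_class_name <- function(class_code) {
  cls <- vessel_classes()
  nm <- names(cls)[match(class_code, cls)]
  ifelse(is.na(nm), as.character(class_code), nm)
}

#' Validate and coerce a label mask
#'
#' A label mask is a plain integer matrix: rows/columns are pixel rows/columns
#' (0-based coordinates are used for pixel centers throughout the package) and
#' values are class codes. Validation enforces the class alphabet.
#'
#' @param x Matrix (integer-valued) of class codes.
#' @param classes Allowed codes, default `0:3` (background + PA/Ao/SVC).
#' @return The validated integer matrix.
#' @export
as_label_mask <- function(x, classes = 0:3) {
  if (!is.matrix(x) || nrow(x) < 1L || ncol(x) < 1L)
    caliper_abort("format_error", "label mask must be a matrix with at least one pixel")
  v <- as.vector(x)
  if (anyNA(v) || any(v != as.integer(v)))
    caliper_abort("format_error", "label mask values must be integers")
  bad <- setdiff(unique(as.integer(v)), as.integer(classes))
  if (length(bad) > 0L)
    caliper_abort("unknown_label",
                  sprintf("label mask contains unknown class code(s): %s",
                          paste(bad, collapse = ", ")),
                  codes = bad)
  storage.mode(x) <- "integer"
  x
}

#' Read / write label masks as grayscale PNG
#'
#' Masks travel as 8-bit grayscale PNG files whose raw pixel value is the
#' class code itself (0 = background, 1 = PA, 2 = Ao, 3 = SVC). The round trip
#' write-then-read is bit-exact. Files containing other codes are rejected
#' unless `remap` translates them.
#'
#' @param path PNG file path.
#' @param remap Optional named integer vector mapping foreign codes to class
#'   codes, e.g. `c("7" = 3)` reads value 7 as SVC.
#' @return `read_label_mask()` returns an integer matrix; `write_label_mask()`
#'   returns `path` invisibly.
#' @export
read_label_mask <- function(path, remap = NULL) {
  if (!file.exists(path))
    caliper_abort("format_error", sprintf("mask file not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L &&
        !(all(img[, , 1] == img[, , 2]) && all(img[, , 1] == img[, , 3])))
      caliper_abort("format_error",
                    sprintf("%s is a colour PNG, not a label mask", path))
    img <- img[, , 1]
  }
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  if (!is.null(remap)) {
    from <- as.integer(names(remap))
    for (k in seq_along(from)) m[m == from[k]] <- as.integer(remap[[k]])
  }
  as_label_mask(m)
}

#' @param mask Integer label mask (see [as_label_mask()]).
#' @rdname read_label_mask
#' @export
write_label_mask <- function(mask, path) {
  mask <- as_label_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}
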