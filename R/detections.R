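# Detection-based 3VV frame selection. The upstream object detector reports,
# per video frame, boxes for 18 cardiac substructures in the plain-text YOLO
# dialect: one line per box, "class cx cy w h conf", coordinates normalized
# to the unit square. A frame is a 3VV candidate when the PA, Ao and SVC are
# all detected at their class-specific confidence thresholds.

#' Substructure detection class codes
#'
#' The detector recognizes 18 cardiac substructures; codes are 0-based list
#' positions. Only PA (8), Ao (9) and SVC (10) matter for 3VV selection;
#' `detection_classes()` returns that trio (remappable via
#' [frame_selection_config()]).
#'
#' @return Named integer vector of class codes.
#' @export
substructure_classes <- function() {
  nm <- c("crux", "ventricular_septum", "right_atrium", "tricuspid_valve",
          "right_ventricle", "left_atrium", "mitral_valve", "left_ventricle",
          "PA", "Ao", "SVC", "descending_aorta", "stomach", "spine",
          "umbilical_vein", "inferior_vena_cava", "pulmonary_vein",
          "ductus_arteriosus")
  stats::setNames(0:17, nm)
}

#' @rdname substructure_classes
#' @export
detection_classes <- function() substructure_classes()[c("PA", "Ao", "SVC")]

#' Parse a YOLO-dialect detection file
#'
#' One detection per line: `class cx cy w h conf`, whitespace-separated,
#' box center/size normalized to `[0, 1]`. Malformed lines raise a
#' `parse_error` naming the line; boxes leaving the unit square or
#' confidences outside `[0, 1]` raise a `range_error`.
#'
#' @param path Detection text file; by convention named
#'   `{video_id}_{frame_id}.txt` (ids parsed from the name when not given).
#' @param video_id,frame_id Optional explicit identifiers.
#' @return Data frame with columns `video_id`, `frame_id`, `class_code`,
#'   `cx`, `cy`, `w`, `h`, `confidence` (zero rows for an empty file).
#' @export
parse_detections <- function(path, video_id = NULL, frame_id = NULL) {
  if (!file.exists(path))
    caliper_abort("parse_error", sprintf("detection file not found: %s", path))
  if (is.null(video_id) || is.null(frame_id)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    m <- regmatches(stem, regexec("^(.*)_([^_]+)$", stem))[[1L]]
    if (length(m) == 3L) {
      if (is.null(video_id)) video_id <- m[2L]
      if (is.null(frame_id)) frame_id <- m[3L]
    } else {
      if (is.null(video_id)) video_id <- stem
      if (is.null(frame_id)) frame_id <- stem
    }
  }
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  keep <- nzchar(lines_trim)
  empty <- data.frame(video_id = character(0), frame_id = character(0),
                      class_code = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  lineno <- which(keep)
  rows <- lapply(seq_along(lineno), function(k) {
    ln <- lineno[k]
    f <- strsplit(lines_trim[ln], "[[:space:]]+")[[1L]]
    if (length(f) != 6L)
      caliper_abort("parse_error",
                    sprintf("%s line %d: expected 6 fields, got %d",
                            path, ln, length(f)), line = ln)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      caliper_abort("parse_error",
                    sprintf("%s line %d: non-numeric field", path, ln), line = ln)
    if (v[1L] != as.integer(v[1L]) || v[1L] < 0 || v[1L] > 17)
      caliper_abort("parse_error",
                    sprintf("%s line %d: class must be an integer in 0..17", path, ln),
                    line = ln)
    if (any(v[2:6] < 0) || any(v[2:6] > 1))
      caliper_abort("range_error",
                    sprintf("%s line %d: normalized values outside [0, 1]", path, ln),
                    line = ln)
    if (v[2L] - v[4L] / 2 < -1e-9 || v[2L] + v[4L] / 2 > 1 + 1e-9 ||
        v[3L] - v[5L] / 2 < -1e-9 || v[3L] + v[5L] / 2 > 1 + 1e-9)
      caliper_abort("range_error",
                    sprintf("%s line %d: box leaves the unit square", path, ln),
                    line = ln)
    data.frame(video_id = video_id, frame_id = frame_id,
               class_code = as.integer(v[1L]), cx = v[2L], cy = v[3L],
               w = v[4L], h = v[5L], confidence = v[6L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Frame-selection configuration
#'
#' Defaults are the study's operating point: per-class confidence minima
#' PA 0.001, Ao 0.1, SVC 0.01, and at most two frames drawn per video.
#'
#' @param thresholds Named numeric vector `c(PA=, Ao=, SVC=)` in `[0, 1]`.
#' @param max_frames_per_video Maximum frames sampled per video (`Inf` keeps
#'   every candidate).
#' @param class_map Detection class codes for PA/Ao/SVC, default
#'   [detection_classes()].
#' @param seed Optional seed for the per-video draw.
#' @return A `frame_selection_config`.
#' @export
frame_selection_config <- function(thresholds = c(PA = 0.001, Ao = 0.1, SVC = 0.01),
                                   max_frames_per_video = 2,
                                   class_map = detection_classes(),
                                   seed = NULL) {
  stopifnot(all(c("PA", "Ao", "SVC") %in% names(thresholds)),
            all(thresholds >= 0 & thresholds <= 1),
            max_frames_per_video >= 1,
            all(c("PA", "Ao", "SVC") %in% names(class_map)))
  structure(list(thresholds = thresholds,
                 max_frames_per_video = max_frames_per_video,
                 class_map = class_map, seed = seed),
            class = "frame_selection_config")
}

#' Select 3VV frames from detections
#'
#' A frame is a 3VV candidate iff each of PA, Ao and SVC has at least one
#' detection meeting its class threshold (any-box semantics). From each
#' video's candidates, up to `max_frames_per_video` frames are drawn
#' uniformly without replacement (seeded); videos without candidates yield
#' empty selections.
#'
#' @param detections Data frame as produced by [parse_detections()] (rows
#'   from many files may be concatenated).
#' @param config A [frame_selection_config()].
#' @return Named list: one character vector of selected `frame_id`s per
#'   `video_id`, plus an attribute `candidates` (data frame of all candidate
#'   frames).
#' @export
select_3vv_frames <- function(detections, config = frame_selection_config()) {
  stopifnot(inherits(config, "frame_selection_config"))
  need <- c("video_id", "frame_id", "class_code", "confidence")
  stopifnot(all(need %in% names(detections)))
  key <- paste(detections$video_id, detections$frame_id, sep = "\r")
  passes <- function(vessel) {
    ok <- detections$class_code == config$class_map[[vessel]] &
      detections$confidence >= config$thresholds[[vessel]]
    unique(key[ok])
  }
  cand_keys <- Reduce(intersect, lapply(c("PA", "Ao", "SVC"), passes))
  parts <- strsplit(cand_keys, "\r", fixed = TRUE)
  cand <- data.frame(video_id = vapply(parts, `[`, "", 1L),
                     frame_id = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$video_id, cand$frame_id), , drop = FALSE]
  videos <- sort(unique(detections$video_id))
  pick <- function() {
    out <- stats::setNames(vector("list", length(videos)), videos)
    for (v in videos) {
      frames <- cand$frame_id[cand$video_id == v]
      if (length(frames) > config$max_frames_per_video)
        frames <- frames[sample.int(length(frames),
                                    config$max_frames_per_video)]
      out[[v]] <- frames
    }
    out
  }
  sel <- if (is.null(config$seed)) pick() else withr::with_seed(config$seed, pick())
  attr(sel, "candidates") <- cand
  sel
}
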