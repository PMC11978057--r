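# Pluggable face-detection contract.  The production system upstream of this
# package uses a fine-tuned CNN detector; here detection is an injectable
# contract so any detector can be mounted, and a fixture detector replays
# ground-truth boxes from a JSON/CSV sidecar for deterministic testing.

#' Bounding box
#'
#' Coordinates are 0-based and half-open: the box covers pixel columns
#' `[x0, x1)` and rows `[y0, y1)`, so width is exactly `x1 - x0`.
#'
#' @param x0,y0,x1,y1 Pixel coordinates, `x1 > x0`, `y1 > y0`.
#' @param score Detector confidence in \[0, 1\].
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(x0, y0, x1, y1, score = 1) {
  if (x1 <= x0 || y1 <= y0) stopf("malformed box: x1 > x0 and y1 > y0 required")
  if (score < 0 || score > 1) stopf("box score must lie in [0, 1]")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, score = score),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box [%g,%g)x[%g,%g) score %.3f>\n", x$x0, x$x1, x$y0, x$y1, x$score))
  invisible(x)
}

#' Intersection-over-union of two boxes
#' @param a,b [bounding_box] objects.
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  ih <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- iw * ih
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  if (union <= 0) 0 else inter / union
}

#' Fixture detector replaying a ground-truth box sidecar
#'
#' The sidecar is a JSON array (or data.frame) of records
#' `{frame_index, x0, y0, x1, y1, score, identity_id?}` keyed by 0-based
#' frame index.  Frames absent from the sidecar yield no detections.
#'
#' @param sidecar Path to a JSON sidecar, or a data.frame with those columns.
#' @return A `detector` object usable with [detect_faces()].
#' @export
fixture_detector <- function(sidecar) {
  df <- if (is.character(sidecar)) {
    jsonlite::fromJSON(sidecar, simplifyDataFrame = TRUE)
  } else as.data.frame(sidecar)
  needed <- c("frame_index", "x0", "y0", "x1", "y1")
  if (length(df) == 0 || !all(needed %in% names(df)))
    stopf("box sidecar needs columns %s", paste(needed, collapse = ", "))
  if (is.null(df$score)) df$score <- 1
  structure(list(kind = "fixture", boxes = df), class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  cat(sprintf("<detector: %s, %d boxes>\n", x$kind,
              if (!is.null(x$boxes)) nrow(x$boxes) else NA_integer_))
  invisible(x)
}

#' Detect faces in a frame
#'
#' Runs the detector contract on one frame and validates its output: every
#' box must satisfy the [bounding_box()] invariants (after clipping to the
#' frame) or a detector error naming the offending box is raised.  Boxes are
#' returned sorted by descending score.
#'
#' @param frame An [rgb_image].
#' @param detector A `detector` ([fixture_detector()]) or a function
#'   `(frame, frame_index) -> data.frame` of boxes.
#' @param frame_index 0-based frame index the detector may key on.
#' @return List of [bounding_box] objects, possibly empty.
#' @export
detect_faces <- function(frame, detector, frame_index = 0L) {
  raw <- if (inherits(detector, "detector")) {
    b <- detector$boxes
    b[b$frame_index == frame_index, , drop = FALSE]
  } else if (is.function(detector)) {
    detector(frame, frame_index)
  } else stopf("detector must be a 'detector' object or a function")
  if (is.null(raw) || nrow(raw) == 0L) return(list())
  h <- dim(frame)[1]; w <- dim(frame)[2]
  boxes <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    if (r$x1 <= r$x0 || r$y1 <= r$y0 || r$score < 0 || r$score > 1)
      stopf("detector contract violation at frame %d: box (%g,%g,%g,%g, score %g)",
            frame_index, r$x0, r$y0, r$x1, r$y1, r$score)
    bounding_box(max(0, r$x0), max(0, r$y0), min(w, r$x1), min(h, r$y1), r$score)
  })
  boxes[order(vapply(boxes, `[[`, numeric(1), "score"), decreasing = TRUE)]
}

#' Crop a detection and apply the canonical preprocessing
#'
#' Extracts the half-open sub-image, converts to grayscale by channel
#' averaging, and resizes to the canonical resolution.  Boxes partly outside
#' the frame are clipped with a warning; boxes degenerate after clipping
#' (less than 2 px in either dimension) are an error.
#'
#' @param frame An [rgb_image].
#' @param box A [bounding_box].
#' @param target_h,target_w Canonical resolution.
#' @return A [gray_image] at the canonical resolution.
#' @export
crop_and_preprocess <- function(frame, box,
                                target_h = canonical_size()[1],
                                target_w = canonical_size()[2]) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- max(0, floor(box$x0)); y0 <- max(0, floor(box$y0))
  x1 <- min(w, ceiling(box$x1)); y1 <- min(h, ceiling(box$y1))
  if (x0 > box$x0 || y0 > box$y0 || x1 < box$x1 || y1 < box$y1)
    warning(sprintf("box clipped to frame bounds: [%g,%g)x[%g,%g)", x0, x1, y0, y1),
            call. = FALSE)
  if (x1 - x0 < 2 || y1 - y0 < 2)
    stopf("degenerate crop after clipping: %g x %g px", x1 - x0, y1 - y0)
  sub <- unclass(frame)[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  resize_canonical(to_grayscale(rgb_image(sub)), target_h, target_w)
}
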