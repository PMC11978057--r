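# Near-real-time identification: 0.5 s frame pooling, a frames x classes
# confidence table per detection chain, temporal majority voting with an
# explicit abstention convention, 0.5 s update cadence, and the
# single-selected-identity display mode.

#' Realtime session configuration
#'
#' @param window Pooling window length, seconds (default 0.5: frames are
#'   collected for half a second before classification).
#' @param update_interval Seconds between successive windows (default 0.5,
#'   i.e. non-overlapping windows).
#' @param selected_id Identity whose windows emit overlay events, or `"ALL"`.
#' @param min_rows Minimum confidence-table rows required to vote; windows
#'   with fewer abstain rather than fabricate an identity.
#' @param iou_link IoU threshold linking detections across frames into one
#'   chain (multi-animal scenes).
#' @return A `session_config`.
#' @export
session_config <- function(window = 0.5, update_interval = 0.5,
                           selected_id = "ALL", min_rows = 1L, iou_link = 0.3) {
  stopifnot(window > 0, update_interval > 0, min_rows >= 0)
  structure(list(window = window, update_interval = update_interval,
                 selected_id = selected_id, min_rows = as.integer(min_rows),
                 iou_link = iou_link),
            class = "session_config")
}

#' Frames of one pooling window
#'
#' Selects the indices of frames with timestamps in the half-open interval
#' `[start, start + window)`; with the default window = update interval,
#' consecutive windows partition the timeline.
#'
#' @param stream A [frame_stream] (resampled to its nominal rate).
#' @param config A [session_config()].
#' @param start Window start, seconds.
#' @return Integer vector of frame indices (possibly empty).
#' @export
pool_window <- function(stream, config, start) {
  which(stream$timestamps >= start - 1e-9 &
          stream$timestamps < start + config$window - 1e-9)
}

#' Build per-chain confidence tables for a pooled window
#'
#' Runs detect -> crop/preprocess -> extract -> classify on every pooled
#' frame.  Detections are linked across frames into chains by box overlap
#' (IoU >= `iou_link` against the chain's last box), one confidence table
#' per chain; frames without detections contribute no rows.  A frame whose
#' detector or model call fails is skipped with a warning.
#'
#' @param stream A [frame_stream].
#' @param frame_indices Indices from [pool_window()].
#' @param detector Detector contract (see [detect_faces()]).
#' @param recognizer A [face_recognizer()].
#' @param config A [session_config()].
#' @return List of `confidence_table` objects: each has `rows` (frames x
#'   classes, rows summing to 1), `frame_indices`, `boxes`.
#' @export
build_confidence_table <- function(stream, frame_indices, detector, recognizer,
                                   config = session_config()) {
  chains <- list()   # each: list(rows, frame_indices, boxes, last_box)
  for (fi in frame_indices) {
    res <- tryCatch({
      boxes <- detect_faces(stream$frames[[fi]], detector, frame_index = fi - 1L)
      lapply(boxes, function(b) {
        crop <- crop_and_preprocess(stream$frames[[fi]], b,
                                    target_h = recognizer$crop_size[1],
                                    target_w = recognizer$crop_size[2])
        conf <- predict.face_recognizer(recognizer, list(crop), type = "confidence")
        list(box = b, conf = conf[1, ])
      })
    }, error = function(e) {
      warning(sprintf("frame %d skipped: %s", fi - 1L, conditionMessage(e)),
              call. = FALSE)
      list()
    })
    for (det in res) {
      linked <- FALSE
      for (ci in seq_along(chains)) {
        if (box_iou(chains[[ci]]$last_box, det$box) >= config$iou_link) {
          chains[[ci]]$rows <- rbind(chains[[ci]]$rows, det$conf)
          chains[[ci]]$frame_indices <- c(chains[[ci]]$frame_indices, fi - 1L)
          chains[[ci]]$boxes <- c(chains[[ci]]$boxes, list(det$box))
          chains[[ci]]$last_box <- det$box
          linked <- TRUE
          break
        }
      }
      if (!linked)
        chains[[length(chains) + 1L]] <- list(rows = matrix(det$conf, 1,
                                                            dimnames = list(NULL, names(det$conf))),
                                              frame_indices = fi - 1L,
                                              boxes = list(det$box),
                                              last_box = det$box)
    }
  }
  lapply(chains, function(ch)
    structure(list(rows = ch$rows, frame_indices = ch$frame_indices,
                   boxes = ch$boxes, classes = colnames(ch$rows)),
              class = "confidence_table"))
}

#' @export
print.confidence_table <- function(x, ...) {
  cat(sprintf("<confidence_table: %d frames x %d classes>\n",
              nrow(x$rows), ncol(x$rows)))
  invisible(x)
}

#' Temporal majority vote over a confidence table
#'
#' Each row votes for its argmax class (row ties to the lexicographically
#' first class); the window's identification is the modal vote.  Modal ties
#' are broken by the larger summed confidence across the tied classes, then
#' lexicographically.  Fewer than `min_rows` rows yields `"ABSTAIN"`.
#'
#' @param table A `confidence_table` (or a plain frames x classes matrix with
#'   column names).
#' @param min_rows Abstention threshold.
#' @return An `ident_result`: `predicted` (identity or `"ABSTAIN"`),
#'   `vote_counts`, `aggregate_confidence` (mean confidence of the winning
#'   class over the voted rows; 0 on abstention).
#' @export
majority_vote <- function(table, min_rows = 1L) {
  rows <- if (inherits(table, "confidence_table")) table$rows else as.matrix(table)
  classes <- colnames(rows)
  if (is.null(classes)) stopf("confidence table needs class column names")
  n <- nrow(rows)
  if (is.null(n) || n < min_rows || n == 0L) {
    return(structure(list(predicted = "ABSTAIN",
                          vote_counts = stats::setNames(integer(0), character(0)),
                          aggregate_confidence = 0, n_rows = if (is.null(n)) 0L else n),
                     class = "ident_result"))
  }
  ord <- order(classes)                       # lexicographic argmax tie-break
  votes_idx <- apply(rows[, ord, drop = FALSE], 1, which.max)
  votes <- classes[ord][votes_idx]
  counts <- table(votes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(rows[, cl]), numeric(1))
    top <- top[sums == max(sums)]
    top <- sort(top)[1]
  }
  structure(list(predicted = top,
                 vote_counts = stats::setNames(as.integer(counts), names(counts)),
                 aggregate_confidence = mean(rows[, top]),
                 n_rows = n),
            class = "ident_result")
}

#' @export
print.ident_result <- function(x, ...) {
  cat(sprintf("<ident: %s (%.3f conf, %d rows)>\n",
              x$predicted, x$aggregate_confidence, x$n_rows))
  invisible(x)
}

#' Run a realtime identification session over a stream
#'
#' Advances a pooling window across the stream at the configured update
#' cadence; each window is pooled, classified per detection chain, and
#' voted.  When `selected_id` is not `"ALL"`, overlay events (the displayed
#' bounding box) are emitted only for windows whose prediction equals the
#' selected identity — the single-animal display mode used when verifying
#' one individual at a time in a group cage.
#'
#' @param stream A [frame_stream]; resample first with [resample_stream()].
#' @param detector Detector contract.
#' @param recognizer A [face_recognizer()].
#' @param config A [session_config()].
#' @return An `id_session`: `results` (one record per window x chain:
#'   `window_start`, `chain`, `predicted`, `vote_counts`,
#'   `aggregate_confidence`, `boxes`), `overlays` (filtered records), and
#'   `config`.
#' @export
run_session <- function(stream, detector, recognizer, config = session_config()) {
  stopifnot(inherits(stream, "frame_stream"))
  results <- list()
  overlays <- list()
  if (length(stream$frames) > 0L) {
    t0 <- stream$timestamps[1]
    tmax <- stream$timestamps[length(stream$timestamps)]
    starts <- seq(t0, tmax, by = config$update_interval)
    for (ws in starts) {
      idx <- pool_window(stream, config, ws)
      tables <- build_confidence_table(stream, idx, detector, recognizer, config)
      if (length(tables) == 0L) {
        vote <- majority_vote(matrix(numeric(0), 0, length(recognizer$classes),
                                     dimnames = list(NULL, recognizer$classes)),
                              min_rows = config$min_rows)
        rec <- session_record(ws, 1L, vote, NULL)
        results[[length(results) + 1L]] <- rec
        next
      }
      for (ci in seq_along(tables)) {
        vote <- majority_vote(tables[[ci]], min_rows = config$min_rows)
        last_box <- tables[[ci]]$boxes[[length(tables[[ci]]$boxes)]]
        rec <- session_record(ws, ci, vote, last_box)
        results[[length(results) + 1L]] <- rec
        show <- vote$predicted != "ABSTAIN" &&
          (identical(config$selected_id, "ALL") ||
             identical(vote$predicted, config$selected_id))
        if (show) overlays[[length(overlays) + 1L]] <- rec
      }
    }
  }
  structure(list(results = results, overlays = overlays, config = config,
                 classes = recognizer$classes),
            class = "id_session")
}

session_record <- function(window_start, chain, vote, box) {
  list(window_start = window_start, chain = chain,
       predicted = vote$predicted,
       vote_counts = as.list(vote$vote_counts),
       aggregate_confidence = vote$aggregate_confidence,
       n_rows = vote$n_rows,
       box = if (is.null(box)) NULL
             else list(x0 = box$x0, y0 = box$y0, x1 = box$x1, y1 = box$y1,
                       score = box$score))
}

#' @export
print.id_session <- function(x, ...) {
  preds <- vapply(x$results, `[[`, character(1), "predicted")
  cat(sprintf("<id_session: %d window records, %d overlays; predictions: %s>\n",
              length(x$results), length(x$overlays),
              paste(names(table(preds)), as.integer(table(preds)),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Write a session log as JSON lines
#'
#' One JSON record per window x chain, in order; byte-identical across
#' replays of the same stream, model and seeds.
#'
#' @param session An `id_session`.
#' @param path Output path.
#' @param overlays_only Write only the overlay-filtered records.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path, overlays_only = FALSE) {
  recs <- if (overlays_only) session$overlays else session$results
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in recs)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  invisible(path)
}
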