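# frame pooling, confidence tables, temporal majority voting, sessions

conf_rows <- function(m, classes = LETTERS[seq_len(ncol(m))]) {
  colnames(m) <- classes
  m
}

test_that("pooling windows at 10 FPS hold 5 frames and partition the timeline", {
  ts <- seq(0, 3, by = 0.1)
  st <- frame_stream(lapply(seq_along(ts), function(i)
    rgb_image(array(i %% 200, dim = c(2, 2, 3)))), ts, 10)
  cfg <- session_config(window = 0.5, update_interval = 0.5)
  # full windows pool exactly 5 frames: ticks t, t+0.1, ..., t+0.4
  for (start in c(0, 0.5, 1.0, 2.5)) {
    expect_length(pool_window(st, cfg, start), 5)
  }
  # partition: no frame in two consecutive windows, all frames covered
  got <- unlist(lapply(seq(0, 3, by = 0.5), function(s) pool_window(st, cfg, s)))
  expect_equal(sort(got), seq_along(ts))
  expect_equal(anyDuplicated(got), 0)
  # gap -> empty window
  st2 <- frame_stream(st$frames[c(1, 31)], ts[c(1, 31)], 10)
  expect_length(pool_window(st2, cfg, 1.0), 0)
})

test_that("majority_vote follows mode, tie rules, and abstention", {
  # argmax pattern A A A B A
  m <- conf_rows(rbind(c(.9, .1, 0), c(.8, .1, .1), c(.7, .2, .1),
                       c(.2, .7, .1), c(.6, .3, .1)))
  v <- majority_vote(m)
  expect_equal(v$predicted, "A")
  expect_equal(as.integer(v$vote_counts["A"]), 4L)
  expect_equal(as.integer(v$vote_counts["B"]), 1L)
  expect_equal(sum(v$vote_counts), nrow(m))

  # 2-2 tie in votes, summed confidence decides: A = 1.7, B = 1.5
  mt <- conf_rows(rbind(c(.9, .1), c(.8, .2), c(0, .6), c(0, .6)))
  expect_equal(sum(mt[, "A"]), 1.7)
  expect_equal(sum(mt[, "B"]), 1.5)
  expect_equal(majority_vote(mt)$predicted, "A")

  # full tie in counts and sums: lexicographic
  ml <- conf_rows(rbind(c(.8, .2), c(.2, .8)))
  expect_equal(majority_vote(ml)$predicted, "A")

  # empty table abstains
  e <- majority_vote(conf_rows(matrix(numeric(0), 0, 2)), min_rows = 1)
  expect_equal(e$predicted, "ABSTAIN")
  # min_rows threshold
  expect_equal(majority_vote(m, min_rows = 6)$predicted, "ABSTAIN")
})

test_that("majority_vote agrees with brute force over random tables", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    m <- matrix(runif(n * 3), n, 3)
    m <- conf_rows(m / rowSums(m))
    expect_equal(majority_vote(m)$predicted, oracle_vote(m), info = paste("case", i))
  }
})

# a session fixture: 2 identities, tiny images, fixture detector
session_fixture <- function() {
  if (!is.null(.fix$session)) return(.fix$session)
  pop <- small_population()[1:2]
  train <- synth_dataset(pop, images_per_id = 10, seed = 77,
                         target_h = 60, target_w = 40)
  rec <- face_recognizer(train, extractor = "ef",
                         classifier = classifier_spec("knn", max_evals = 3),
                         seed = 5)
  vid <- synth_video(pop, duration_s = 4, fps = 10, segment_s = 2, seed = 78)
  .fix$session <- list(rec = rec, vid = vid, pop = pop)
  .fix$session
}


test_that("confidence tables have one row per detected frame", {
  fx <- session_fixture()
  st <- fx$vid$stream
  det <- fixture_detector(fx$vid$boxes)
  cfg <- session_config()
  idx <- pool_window(st, cfg, 0)
  tabs <- build_confidence_table(st, idx, det, fx$rec, cfg)
  expect_length(tabs, 1)   # one linked chain
  expect_equal(nrow(tabs[[1]]$rows), 5)
  expect_equal(rowSums(tabs[[1]]$rows), rep(1, 5), tolerance = 1e-9)

  # drop the sidecar rows of two frames: only 3 rows remain
  keep <- fx$vid$boxes[!(fx$vid$boxes$frame_index %in% c(1, 3)), ]
  tabs2 <- build_confidence_table(st, idx, fixture_detector(keep), fx$rec, cfg)
  expect_equal(sum(sapply(tabs2, function(t) nrow(t$rows))), 3)

  # single-frame table equals the direct prediction of that crop
  tabs3 <- build_confidence_table(st, idx[1], det, fx$rec, cfg)
  crop <- crop_and_preprocess(st$frames[[idx[1]]],
                              detect_faces(st$frames[[idx[1]]], det, idx[1] - 1L)[[1]],
                              60, 40)
  direct <- predict(fx$rec, list(crop), type = "confidence")
  expect_equal(tabs3[[1]]$rows[1, ], direct[1, ], tolerance = 1e-12)
})

test_that("sessions vote correctly, emit filtered overlays, and replay identically", {
  fx <- session_fixture()
  det <- fixture_detector(fx$vid$boxes)
  s_all <- run_session(fx$vid$stream, det, fx$rec, session_config())
  expect_gt(length(s_all$results), 0)
  preds <- vapply(s_all$results, `[[`, character(1), "predicted")
  # vote-count conservation per window
  for (r in s_all$results)
    if (r$predicted != "ABSTAIN")
      expect_equal(sum(unlist(r$vote_counts)), r$n_rows)
  # ALL mode: one overlay per non-abstaining record
  expect_length(s_all$overlays, sum(preds != "ABSTAIN"))

  # selected-id mode only overlays that identity's windows
  id2 <- fx$pop[[2]]$id
  s_sel <- run_session(fx$vid$stream, det, fx$rec,
                             session_config(selected_id = id2))
  expect_length(s_sel$overlays,
                sum(vapply(s_sel$results, `[[`, character(1), "predicted") == id2))
  # an identity never predicted yields zero overlays
  s_none <- run_session(fx$vid$stream, det, fx$rec,
                              session_config(selected_id = "NOBODY"))
  expect_length(s_none$overlays, 0)
  expect_equal(length(s_none$results), length(s_all$results))

  # byte-identical JSON-lines logs across replays
  d <- withr::local_tempdir()
  s_rep <- run_session(fx$vid$stream, det, fx$rec, session_config())
  write_session_log(s_all, file.path(d, "a.jsonl"))
  write_session_log(s_rep, file.path(d, "b.jsonl"))
  expect_identical(readLines(file.path(d, "a.jsonl")),
                   readLines(file.path(d, "b.jsonl")))
})

test_that("session predictions match an offline frame-by-frame re-vote", {
  fx <- session_fixture()
  det <- fixture_detector(fx$vid$boxes)
  st <- fx$vid$stream
  s <- run_session(st, det, fx$rec, session_config())
  # offline oracle: classify every frame independently, then re-vote by hand
  frame_votes <- vapply(seq_along(st$frames), function(i) {
    b <- detect_faces(st$frames[[i]], det, i - 1L)
    if (length(b) == 0) return(NA_character_)
    crop <- crop_and_preprocess(st$frames[[i]], b[[1]], 60, 40)
    predict(fx$rec, list(crop))
  }, character(1))
  for (r in s$results) {
    idx <- pool_window(st, session_config(), r$window_start)
    votes <- frame_votes[idx]
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0) next
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) expect_equal(r$predicted, top,
                                       info = sprintf("window %g", r$window_start))
  }
})
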