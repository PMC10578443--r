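# Windowing tests run against hand-built masks and tag layouts so the
# interval logic is exercised without signal synthesis.

fake_session <- function(tags, span = c(0, 3600)) {
  structure(list(participant_id = "P", session_id = "S",
                 channels = NULL, tags = sort(tags), span = span),
            class = "fake_session")
}
full_wear_mask <- function(span) {
  m <- data.frame(start = span[1], end = span[2], state = "wear")
  attr(m, "span") <- span
  m
}

test_that("a single tag yields the pre-tag event window and post-tag buffer", {
  s <- fake_session(1000)
  lab <- label_events(s, full_wear_mask(c(0, 3600)))
  expect_equal(lab$events, data.frame(start = 700, end = 1000, tag = 1000))
  expect_equal(lab$exclusion, data.frame(start = 700, end = 1300))
  expect_identical(nrow(lab$dropped), 0L)
})

test_that("tags without enough preceding wear are dropped with a reason", {
  s <- fake_session(200)
  lab <- label_events(s, full_wear_mask(c(0, 3600)))
  expect_identical(nrow(lab$events), 0L)
  expect_identical(lab$dropped$reason, "event_window_outside_wear")
})

test_that("a tag inside a previous buffer is dropped", {
  s <- fake_session(c(1000, 1240))
  lab <- label_events(s, full_wear_mask(c(0, 3600)))
  expect_identical(nrow(lab$events), 1L)
  expect_identical(lab$events$tag, 1000)
  expect_identical(lab$dropped$reason, "inside_prior_event_or_buffer")
})

test_that("event placement matches the brute-force oracle on random layouts", {
  set.seed(404)
  for (rep in 1:200) {
    span <- c(0, 7200)
    n_tags <- sample(0:12, 1)
    tags <- sort(round(runif(n_tags, span[1], span[2])))
    # random wear mask: punch 0-2 holes into the span
    holes <- iv()
    for (h in seq_len(sample(0:2, 1))) {
      a <- runif(1, span[1], span[2] - 400)
      holes <- rbind(holes, data.frame(start = a, end = a + runif(1, 60, 900)))
    }
    wear <- e4episodes:::iv_diff(data.frame(start = span[1], end = span[2]),
                                 holes)
    m <- data.frame(start = wear$start, end = wear$end, state = "wear")
    attr(m, "span") <- span
    lab <- label_events(fake_session(tags, span), m)
    orc <- oracle_windowing(tags, wear)
    expect_identical(lab$events$tag, orc$events)
    expect_equal(e4episodes:::iv_duration(lab$exclusion),
                 e4episodes:::iv_duration(e4episodes:::iv_normalize(
                   iv(orc$exclusion[, 1], orc$exclusion[, 2]))))
  }
})

test_that("nonevent sampling respects counts, exclusions and the grid", {
  span <- c(0, 3600)
  m <- full_wear_mask(span)
  # tag-free session, minimum three nonevents
  non <- sample_nonevents(m, iv(), n = 3, seed = 1)
  expect_identical(nrow(non), 3L)
  expect_true(all(non$end - non$start == 300))
  expect_true(all(non$start * 4 == round(non$start * 4)))  # 0.25 s grid
  # disjointness
  o <- order(non$start)
  expect_true(all(non$start[o][-1] >= non$end[o][-3]))

  # exactly one 300-s slot: forced placement
  m2 <- full_wear_mask(c(0, 300))
  non2 <- sample_nonevents(m2, iv(), n = 3, seed = 2)
  expect_equal(non2, data.frame(start = 0, end = 300))

  # seeded reproducibility
  expect_identical(sample_nonevents(m, iv(), 5, seed = 7),
                   sample_nonevents(m, iv(), 5, seed = 7))
})

test_that("nonevents never intersect event windows or buffers", {
  span <- c(0, 7200)
  m <- full_wear_mask(span)
  lab <- label_events(fake_session(3000, span), m)
  for (sd in 1:1000) {
    non <- sample_nonevents(m, lab$exclusion, n = 1, seed = sd)
    expect_true(non$end <= 2700 || non$start >= 3300)
  }
})

test_that("signal slices have exact per-channel lengths or are rejected", {
  s <- tiny_cohort()$sessions[[1]]
  span <- session_span(s)
  sl <- segment_signals(s, span[1] + 100, span[1] + 400)
  expect_identical(vapply(sl, length, 0L),
                   c(BVP = 19200L, EDA = 1200L, TEMP = 1200L, HR = 300L))
  # window extending past coverage is rejected
  bad <- segment_signals(s, span[2] - 100, span[2] + 200)
  expect_true(is_rejected(bad))
  expect_match(attr(bad, "reason"), "incomplete")
})

test_that("cohort window tables satisfy label and day-index contracts", {
  co <- tiny_cohort()
  w <- build_windows(co$sessions, seed = 3)
  expect_true(all(w$end - w$start == 300))
  expect_true(all(w$label %in% c("event", "nonevent")))
  expect_true(all(!is.na(w$source_tag[w$label == "event"])))
  expect_true(all(w$end[w$label == "event"] == w$source_tag[w$label == "event"]))
  expect_true(all(w$day_index >= 0))
  # event count never exceeds tag count
  expect_lte(sum(w$label == "event"),
             sum(vapply(co$sessions, function(s) length(s$tags), 0L)))
  # per-session windows are mutually non-overlapping
  for (ss in split(w, w$session)) {
    ss <- ss[order(ss$start), ]
    if (nrow(ss) > 1) expect_true(all(ss$start[-1] >= ss$end[-nrow(ss)]))
  }
  # reproducibility
  expect_identical(w, build_windows(co$sessions, seed = 3))
})

test_that("matched sampling draws one nonevent per event in each session", {
  co <- tiny_cohort()
  w <- build_windows(co$sessions,
                     windowing_params(nonevents_match_events = TRUE),
                     seed = 4)
  for (ss in split(w, w$session)) {
    expect_identical(sum(ss$label == "nonevent"), sum(ss$label == "event"))
  }
})

test_that("well-separated in-wear tags all become event windows", {
  span <- c(0, 7200)
  tags <- c(1000, 1700, 2400, 3600)  # pairwise >= 600 s apart
  lab <- label_events(fake_session(tags, span), full_wear_mask(span))
  expect_identical(lab$events$tag, tags)
})
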