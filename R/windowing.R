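# Event / buffer / nonevent windowing. A tagged event is modeled as the
# 5-min window ending at the tag; the 5 min after the tag form a buffer
# excluded from both classes; nonevents are 5-min windows sampled
# uniformly from the remaining wear time, at least three per session.

#' Windowing parameters
#'
#' @param window_len window length in seconds (default 300 = 5 min).
#' @param buffer_len post-tag buffer length in seconds (default 300).
#' @param min_nonevents_per_session minimum nonevent windows sampled per
#'   recording session.
#' @param nonevent_target_ratio cohort-wide negatives-per-positive
#'   target used by [build_windows()] to size nonevent sampling above
#'   the per-session minimum.
#' @param nonevents_match_events when `TRUE`, exactly one nonevent is
#'   sampled per event window of the same session (a matched design
#'   that equalizes class priors within every participant, useful for
#'   null-calibration studies); the minimum and target ratio are then
#'   ignored.
#' @return An object of class `windowing_params`.
#' @export
windowing_params <- function(window_len = 300, buffer_len = 300,
                             min_nonevents_per_session = 3,
                             nonevent_target_ratio = 1.67,
                             nonevents_match_events = FALSE) {
  stopifnot(window_len > 0, buffer_len >= 0,
            min_nonevents_per_session >= 0, nonevent_target_ratio >= 0)
  structure(list(window_len = window_len, buffer_len = buffer_len,
                 min_nonevents_per_session = min_nonevents_per_session,
                 nonevent_target_ratio = nonevent_target_ratio,
                 nonevents_match_events = isTRUE(nonevents_match_events)),
            class = "windowing_params")
}

#' Label event windows and buffers from session tags
#'
#' For each tag `t` (in time order) the event window is `[t - W, t)` and
#' the buffer `[t, t + B)`. A tag falling inside a previous tag's event
#' window or buffer is dropped, as is a tag whose event window is not
#' wholly inside wear time; dropped tags are returned with reasons.
#' Buffers of dropped tags still contribute to the exclusion zone used
#' by nonevent sampling, so no nonevent can sit adjacent to any tag.
#'
#' @param session an `e4_session`.
#' @param mask wear mask from [wear_mask()].
#' @param params a [windowing_params()].
#' @return List with `events` (data.frame start/end/tag), `exclusion`
#'   (intervals closed to nonevent sampling: event windows and buffers
#'   of all tags), and `dropped` (data.frame tag/reason).
#' @export
label_events <- function(session, mask, params = windowing_params()) {
  W <- params$window_len; B <- params$buffer_len
  wear <- mask_state_iv(mask, "wear")
  ev_s <- numeric(0); ev_e <- numeric(0); ev_tag <- numeric(0)
  drop_tag <- numeric(0); drop_why <- character(0)
  claimed <- iv()  # event windows + buffers of accepted tags
  excl <- iv()     # exclusion zone: [t - W, t + B) for every tag
  for (t in session$tags) {
    excl <- iv_normalize(rbind(excl, iv(t - W, t + B)))
    inside_claimed <- nrow(claimed) > 0 &&
      any(claimed$start <= t & t < claimed$end)
    if (inside_claimed) {
      drop_tag <- c(drop_tag, t); drop_why <- c(drop_why, "inside_prior_event_or_buffer")
      next
    }
    if (!iv_contains(wear, t - W, t)) {
      drop_tag <- c(drop_tag, t); drop_why <- c(drop_why, "event_window_outside_wear")
      next
    }
    ev_s <- c(ev_s, t - W); ev_e <- c(ev_e, t); ev_tag <- c(ev_tag, t)
    claimed <- iv_normalize(rbind(claimed, iv(t - W, t + B)))
  }
  list(events = data.frame(start = ev_s, end = ev_e, tag = ev_tag),
       exclusion = excl,
       dropped = data.frame(tag = drop_tag, reason = drop_why))
}

#' Sample nonevent windows from eligible wear time
#'
#' Draws `n` mutually non-overlapping windows of length `window_len`
#' uniformly at random from wear time minus the event/buffer exclusion
#' zone. Window starts lie on the 0.25-s EDA sampling grid so all
#' channels stay sample-aligned. If fewer than `n` windows fit, as many
#' as fit are returned.
#'
#' @param mask wear mask of the session.
#' @param exclusion intervals closed to sampling (from [label_events()]).
#' @param n number of windows to draw.
#' @param params a [windowing_params()].
#' @param seed RNG seed; identical seeds reproduce placements.
#' @return data.frame with `start`, `end`.
#' @export
sample_nonevents <- function(mask, exclusion, n, params = windowing_params(),
                             seed = 1L) {
  W <- params$window_len
  eligible <- iv_diff(mask_state_iv(mask, "wear"), exclusion)
  seeded(seed, {
    s_out <- numeric(0)
    free <- eligible
    for (k in seq_len(n)) {
      # feasible start counts per free interval, on the 0.25 s grid
      starts_lo <- ceiling(free$start * 4) / 4
      counts <- pmax(0, floor((free$end - W - starts_lo) * 4) + 1)
      if (nrow(free) == 0 || sum(counts) == 0) break
      pick <- sample.int(nrow(free), 1, prob = counts / sum(counts))
      off <- sample.int(counts[pick], 1) - 1
      st <- starts_lo[pick] + off / 4
      s_out <- c(s_out, st)
      free <- iv_diff(free, iv(st, st + W))
    }
    data.frame(start = sort(s_out), end = sort(s_out) + W)
  })
}

#' Slice per-channel signals for one window
#'
#' Extracts the samples of each channel covering `[start, end)`. A
#' window is rejected (with a reason) unless every channel contributes
#' exactly `rate * (end - start)` samples, i.e. the window lies wholly
#' inside channel coverage with no gaps.
#'
#' @param session an `e4_session`.
#' @param start,end window bounds in UNIX seconds.
#' @return List of numeric slices named `BVP`, `EDA`, `TEMP`, `HR`, or a
#'   `window_rejection` object carrying the rejection `reason`.
#' @export
segment_signals <- function(session, start, end) {
  out <- list()
  for (nm in names(session$channels)) {
    ch <- session$channels[[nm]]
    i0 <- round((start - ch$start_time) * ch$rate)
    i1 <- round((end - ch$start_time) * ch$rate)
    want <- round((end - start) * ch$rate)
    if (i0 < 0 || i1 > length(ch$values) || (i1 - i0) != want) {
      return(structure(list(), class = "window_rejection",
                       reason = sprintf("incomplete %s slice", nm)))
    }
    out[[nm]] <- ch$values[(i0 + 1):i1]
  }
  out
}

#' @rdname segment_signals
#' @param x object returned by `segment_signals()`.
#' @export
is_rejected <- function(x) inherits(x, "window_rejection")

#' Build the labeled window table for a cohort of sessions
#'
#' Runs wear masking, event/buffer labeling and nonevent sampling over
#' all sessions. The number of nonevents per session is
#' `max(min_nonevents_per_session, share)` where `share` allocates the
#' cohort-wide target (`nonevent_target_ratio` times the number of event
#' windows) proportionally to each session's eligible time.
#'
#' @param sessions list of `e4_session`.
#' @param params a [windowing_params()].
#' @param seed RNG seed for nonevent placement.
#' @param masks optional list of precomputed wear masks.
#' @param sleep_window passed to [wear_mask()] when masks are computed.
#' @return data.frame with one row per labeled window: `participant`,
#'   `session`, `start`, `end`, `label` (`"event"`/`"nonevent"`),
#'   `source_tag` (`NA` for nonevents) and `day_index` (ordinal calendar
#'   day within the participant's observation period, 0-based).
#' @export
build_windows <- function(sessions, params = windowing_params(), seed = 1L,
                          masks = NULL, sleep_window = c(23, 7)) {
  if (is.null(masks)) {
    masks <- lapply(sessions, wear_mask, sleep_window = sleep_window)
  }
  lab <- lapply(seq_along(sessions), function(i) {
    label_events(sessions[[i]], masks[[i]], params)
  })
  elig_time <- vapply(seq_along(sessions), function(i) {
    iv_duration(iv_diff(mask_state_iv(masks[[i]], "wear"), lab[[i]]$exclusion))
  }, 0)
  n_events <- sum(vapply(lab, function(l) nrow(l$events), 0L))
  target_neg <- round(params$nonevent_target_ratio * n_events)
  share <- if (sum(elig_time) > 0) elig_time / sum(elig_time) else
    rep(0, length(sessions))
  rows <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    n_i <- if (params$nonevents_match_events) nrow(lab[[i]]$events) else
      max(params$min_nonevents_per_session, round(target_neg * share[i]))
    non <- sample_nonevents(masks[[i]], lab[[i]]$exclusion, n_i, params,
                            seed = derive_seed(seed, i))
    ev <- lab[[i]]$events
    if (nrow(ev) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = s$participant_id, session = s$session_id,
        start = ev$start, end = ev$end, label = "event", source_tag = ev$tag)
    }
    if (nrow(non) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = s$participant_id, session = s$session_id,
        start = non$start, end = non$end, label = "nonevent",
        source_tag = NA_real_)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(participant = character(0), session = character(0),
                      start = numeric(0), end = numeric(0),
                      label = character(0), source_tag = numeric(0),
                      day_index = integer(0)))
  }
  win <- do.call(rbind, rows)
  day <- floor(win$start / 86400)
  first_day <- tapply(day, win$participant, min)
  win$day_index <- as.integer(day - first_day[win$participant])
  win <- win[order(win$participant, win$start), , drop = FALSE]
  rownames(win) <- NULL
  win
}
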