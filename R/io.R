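# E4-style session containers and folder I/O, plus sleep / non-wear
# filtering. Channel files use the wristband export dialect: row 1 is
# the UTC start timestamp (UNIX seconds), row 2 the sampling rate in Hz,
# and every following row one sample. tags.csv holds one event
# timestamp per row and may be empty or absent.

E4_RATES <- c(BVP = 64, EDA = 4, TEMP = 4, HR = 1)

#' Construct a physiological channel series
#'
#' @param name one of `"BVP"`, `"EDA"`, `"TEMP"`, `"HR"`.
#' @param start_time UTC start in UNIX seconds.
#' @param rate sampling rate in Hz (64/4/4/1 for BVP/EDA/TEMP/HR).
#' @param values numeric samples; sample `i` covers
#'   `[start_time + (i-1)/rate, start_time + i/rate)`.
#' @return An object of class `e4_channel`.
#' @export
channel_series <- function(name, start_time, rate, values) {
  name <- match.arg(name, names(E4_RATES))
  if (length(values) < 1) stop("empty channel: ", name)
  if (!all(is.finite(values))) stop("non-finite samples in channel ", name)
  if (rate != E4_RATES[[name]]) {
    warning(sprintf("channel %s has rate %g Hz, expected %g Hz",
                    name, rate, E4_RATES[[name]]))
  }
  structure(list(name = name, start_time = as.numeric(start_time),
                 rate = as.numeric(rate), values = as.numeric(values)),
            class = "e4_channel")
}

channel_end <- function(ch) ch$start_time + length(ch$values) / ch$rate

#' Construct a biosensor session
#'
#' A session bundles one channel series per required channel with the
#' self-tagged event timestamps of one contiguous recording.
#'
#' @param participant_id,session_id identifiers.
#' @param channels named list with elements `BVP`, `EDA`, `TEMP`, `HR`,
#'   each an [channel_series()].
#' @param tags numeric vector of UNIX-second event timestamps. Tags
#'   outside the joint channel coverage are dropped with a message.
#' @return An object of class `e4_session`.
#' @export
e4_session <- function(participant_id, session_id, channels, tags = numeric(0)) {
  missing <- setdiff(names(E4_RATES), names(channels))
  if (length(missing) > 0) {
    stop("missing required channel(s): ", paste(missing, collapse = ", "))
  }
  if (is.unsorted(tags)) stop("non-monotone tags")
  span <- session_span_from_channels(channels)
  inside <- tags >= span[1] & tags <= span[2]
  if (any(!inside)) {
    message(sprintf("dropped %d tag(s) outside channel coverage", sum(!inside)))
  }
  structure(list(participant_id = participant_id, session_id = session_id,
                 channels = channels[names(E4_RATES)],
                 tags = as.numeric(tags[inside])),
            class = "e4_session")
}

session_span_from_channels <- function(channels) {
  c(max(vapply(channels, function(ch) ch$start_time, 0)),
    min(vapply(channels, channel_end, 0)))
}

#' @export
print.e4_session <- function(x, ...) {
  span <- session_span(x)
  cat(sprintf("<e4_session> %s / %s: %.1f h, %d tags\n",
              x$participant_id, x$session_id,
              (span[2] - span[1]) / 3600, length(x$tags)))
  invisible(x)
}

#' Joint time coverage of a session
#'
#' @param session an `e4_session`.
#' @return `c(start, end)` of the intersection of all channel coverages.
#' @export
session_span <- function(session) session_span_from_channels(session$channels)

#' Write a session folder
#'
#' @param session an `e4_session`.
#' @param folder_path destination directory (created if needed).
#' @return `folder_path`, invisibly.
#' @export
write_session <- function(session, folder_path) {
  dir.create(folder_path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session$channels)) {
    ch <- session$channels[[nm]]
    con <- file(file.path(folder_path, paste0(nm, ".csv")), "wb")
    writeLines(c(format(ch$start_time, scientific = FALSE),
                 format(ch$rate, scientific = FALSE),
                 sprintf("%.17g", ch$values)), con)
    close(con)
  }
  con <- file(file.path(folder_path, "tags.csv"), "wb")
  if (length(session$tags) > 0) {
    writeLines(sprintf("%.17g", session$tags), con)
  }
  close(con)
  invisible(folder_path)
}

#' Read a session folder
#'
#' Parses the four channel files and the optional tags file of one
#' session folder. Participant and session ids default to the enclosing
#' folder names.
#'
#' @param folder_path path to a session folder.
#' @param participant_id,session_id optional identifier overrides.
#' @return An `e4_session`.
#' @export
read_session <- function(folder_path, participant_id = NULL,
                         session_id = NULL) {
  if (!dir.exists(folder_path)) stop("no such session folder: ", folder_path)
  channels <- list()
  for (nm in names(E4_RATES)) {
    f <- file.path(folder_path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing required channel file: ", f)
    raw <- scan(f, what = numeric(), sep = ",", quiet = TRUE)
    if (length(raw) < 3) stop("empty channel: ", f)
    channels[[nm]] <- channel_series(nm, raw[1], raw[2], raw[-c(1, 2)])
  }
  tf <- file.path(folder_path, "tags.csv")
  tags <- if (file.exists(tf)) {
    scan(tf, what = numeric(), sep = ",", quiet = TRUE)
  } else numeric(0)
  if (is.unsorted(tags)) stop("non-monotone tags in ", tf)
  e4_session(
    participant_id = participant_id %||% basename(dirname(folder_path)),
    session_id = session_id %||% basename(folder_path),
    channels = channels, tags = tags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read every session of a simulated or exported cohort
#'
#' Expects `dir` to contain one folder per participant with one session
#' folder per recording day (the layout [simulate_cohort()] writes).
#'
#' @param dir cohort root directory.
#' @return List of `e4_session` objects.
#' @export
read_cohort <- function(dir) {
  parts <- list.dirs(dir, recursive = FALSE)
  sessions <- list()
  for (p in parts) {
    for (s in list.dirs(p, recursive = FALSE)) {
      sessions[[length(sessions) + 1]] <- read_session(s)
    }
  }
  sessions
}

# ---- wear masking ----------------------------------------------------------

#' Detect non-wear periods
#'
#' The wristband reports near-zero skin conductance and ambient (rather
#' than skin) temperature when off the wrist. Periods where EDA stays
#' below `eda_floor` and TEMP below `temp_floor` for at least `min_gap`
#' contiguous seconds are classified non-wear. The rule is a heuristic
#' with configurable thresholds.
#'
#' @param session an `e4_session`.
#' @param eda_floor EDA threshold in micro-Siemens.
#' @param temp_floor temperature threshold in degrees Celsius.
#' @param min_gap minimum contiguous duration in seconds (> 0).
#' @return A wear mask: data.frame with `start`, `end`, `state` (one of
#'   `"wear"`, `"nonwear"`) partitioning the session span.
#' @export
detect_nonwear <- function(session, eda_floor = 0.03, temp_floor = 30,
                           min_gap = 300) {
  if (min_gap <= 0) stop("min_gap must be positive")
  span <- session_span(session)
  eda <- session$channels$EDA; temp <- session$channels$TEMP
  # evaluate on the 4 Hz EDA grid restricted to the joint span
  t <- eda$start_time + (seq_along(eda$values) - 1) / eda$rate
  keep <- t >= span[1] & t < span[2]
  t <- t[keep]
  ev <- eda$values[keep]
  tv <- stats::approx(temp$start_time + (seq_along(temp$values) - 1) / temp$rate,
                      temp$values, xout = t, rule = 2)$y
  low <- ev < eda_floor & tv < temp_floor
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  nw <- iv()
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] / eda$rate >= min_gap) {
      nw <- rbind(nw, iv(t[starts[i]], t[ends[i]] + 1 / eda$rate))
    }
  }
  nw <- iv_intersect(iv_normalize(nw), iv(span[1], span[2]))
  mask_from_intervals(span, nonwear = nw, sleep = iv())
}

mask_from_intervals <- function(span, nonwear, sleep) {
  whole <- iv(span[1], span[2])
  sleep <- iv_intersect(sleep, whole)
  nonwear <- iv_diff(iv_intersect(nonwear, whole), sleep)
  wear <- iv_diff(iv_diff(whole, sleep), nonwear)
  out <- rbind(
    if (nrow(wear)) cbind(wear, state = "wear"),
    if (nrow(nonwear)) cbind(nonwear, state = "nonwear"),
    if (nrow(sleep)) cbind(sleep, state = "sleep"))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "span") <- span
  out
}

# daily recurring clock interval [from_h, to_h) as absolute intervals
# covering [t0, t1); wraps past midnight when to_h <= from_h.
clock_intervals <- function(t0, t1, from_h, to_h) {
  day0 <- floor(t0 / 86400) - 1
  day1 <- floor(t1 / 86400) + 1
  s <- numeric(0); e <- numeric(0)
  for (d in day0:day1) {
    a <- d * 86400 + from_h * 3600
    b <- if (to_h > from_h) d * 86400 + to_h * 3600 else
      (d + 1) * 86400 + to_h * 3600
    s <- c(s, a); e <- c(e, b)
  }
  iv_intersect(iv(s, e), iv(t0, t1))
}

#' Apply a daily sleep mask to a session
#'
#' Marks a daily recurring clock-time interval (UTC) as sleep and
#' composes it with an existing wear mask; precedence is
#' sleep > non-wear > wear.
#'
#' @param session an `e4_session`.
#' @param sleep_window `c(from_hour, to_hour)` clock hours in `[0, 24)`;
#'   an interval wrapping midnight (e.g. `c(23, 7)`) is allowed.
#' @param mask optional wear mask from [detect_nonwear()]; by default a
#'   fully-wear mask over the session span.
#' @return A wear mask partitioning the session span into
#'   wear / nonwear / sleep intervals.
#' @export
apply_sleep_mask <- function(session, sleep_window = c(23, 7), mask = NULL) {
  if (length(sleep_window) != 2 || any(!is.finite(sleep_window)) ||
      any(sleep_window < 0) || any(sleep_window >= 24)) {
    stop("ill-formed sleep window; want clock hours c(from, to) in [0, 24)")
  }
  span <- session_span(session)
  sleep <- clock_intervals(span[1], span[2], sleep_window[1], sleep_window[2])
  nonwear <- if (is.null(mask)) iv() else {
    nw <- mask[mask$state == "nonwear", c("start", "end"), drop = FALSE]
    iv(nw$start, nw$end)
  }
  mask_from_intervals(span, nonwear = nonwear, sleep = sleep)
}

#' Full wear mask for a session
#'
#' Convenience wrapper running [detect_nonwear()] then
#' [apply_sleep_mask()].
#'
#' @param session an `e4_session`.
#' @param eda_floor,temp_floor,min_gap see [detect_nonwear()].
#' @param sleep_window see [apply_sleep_mask()]; `NULL` disables the
#'   sleep mask.
#' @return A wear mask.
#' @export
wear_mask <- function(session, eda_floor = 0.03, temp_floor = 30,
                      min_gap = 300, sleep_window = c(23, 7)) {
  m <- detect_nonwear(session, eda_floor, temp_floor, min_gap)
  if (is.null(sleep_window)) m else
    apply_sleep_mask(session, sleep_window, mask = m)
}

mask_state_iv <- function(mask, state) {
  x <- mask[mask$state == state, c("start", "end"), drop = FALSE]
  iv(x$start, x$end)
}

# ---- adherence summaries ---------------------------------------------------

#' Summarize wear adherence per participant
#'
#' Computes, per participant: total tag count, wear hours, number of
#' calendar days with any wear, mean wear hours per day and mean tags
#' per wear hour; plus cohort aggregates (column totals and unweighted
#' participant means). A participant with zero wear hours gets `NA`
#' tags per hour.
#'
#' @param sessions list of `e4_session`.
#' @param masks optional list of wear masks aligned with `sessions`;
#'   computed with default [wear_mask()] settings when absent.
#' @return List with `participants` (one row per participant) and
#'   `cohort` (totals and means).
#' @export
wear_summary <- function(sessions, masks = NULL) {
  stopifnot(length(sessions) >= 1)
  if (is.null(masks)) masks <- lapply(sessions, wear_mask)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    wear <- mask_state_iv(masks[[i]], "wear")
    days <- unique(unlist(lapply(seq_len(nrow(wear)), function(j) {
      seq(floor(wear$start[j] / 86400), floor((wear$end[j] - 1e-9) / 86400))
    })))
    data.frame(participant = s$participant_id,
               n_tags = length(s$tags),
               wear_h = iv_duration(wear) / 3600,
               days = I(list(days)))
  })
  df <- do.call(rbind, rows)
  per <- do.call(rbind, lapply(split(df, df$participant), function(g) {
    n_hours <- sum(g$wear_h)
    n_days <- length(unique(unlist(g$days)))
    data.frame(participant = g$participant[1],
               n_tags = sum(g$n_tags),
               n_hours = n_hours,
               n_days = n_days,
               mean_hours_per_day = if (n_days > 0) n_hours / n_days else NA_real_,
               mean_tags_per_hour = if (n_hours > 0) sum(g$n_tags) / n_hours else NA_real_)
  }))
  rownames(per) <- NULL
  list(participants = per, cohort = cohort_aggregates(per))
}

cohort_aggregates <- function(per) {
  list(total_tags = sum(per$n_tags),
       total_hours = sum(per$n_hours),
       total_days = sum(per$n_days),
       mean_days = mean(per$n_days),
       mean_tags = mean(per$n_tags),
       mean_hours_per_day = mean(per$mean_hours_per_day, na.rm = TRUE),
       mean_tags_per_hour = mean(per$mean_tags_per_hour, na.rm = TRUE))
}
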