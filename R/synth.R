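# Synthetic cohort generator: E4-style multichannel sessions with known
# ground-truth event physiology. Every downstream stage (ingestion,
# windowing, features, models, evaluation) is exercised against cohorts
# produced here, since no real recordings are distributed.

#' Specify the physiological signature of a tagged event
#'
#' A tagged distress event perturbs the simulated physiology in a window
#' `[tag - onset_lead, tag - onset_lead + duration)`: skin-conductance
#' response (SCR) bursts arrive faster and larger by `eda_phasic_gain`,
#' the blood-volume-pulse (BVP) amplitude envelope acquires an additional
#' linear slope `bvp_slope_shift`, and heart rate shifts by `hr_delta`.
#' Gains of 1 (EDA) and 0 (BVP slope, HR) leave the physiology unchanged,
#' giving a null cohort in which event and nonevent windows are
#' statistically indistinguishable.
#'
#' The magnitudes are free parameters of the simulator, not estimates of
#' any real cohort: they exist so that recovery of a known effect can be
#' tested at chosen signal-to-noise levels.
#'
#' @param eda_phasic_gain multiplicative gain on SCR burst rate and
#'   amplitude during events (1 = no effect).
#' @param bvp_slope_shift additive slope (envelope units per second)
#'   applied to the BVP amplitude envelope during events (0 = no effect).
#' @param hr_delta heart-rate offset in beats per minute during events.
#' @param onset_lead seconds before the tag at which physiology changes.
#' @param duration seconds of altered physiology.
#' @return An object of class `effect_spec`.
#' @export
#' @examples
#' effect_spec()              # moderate default effect
#' effect_spec_null()         # no physiological effect
effect_spec <- function(eda_phasic_gain = 2, bvp_slope_shift = 0.003,
                        hr_delta = 8, onset_lead = 240, duration = 240) {
  stopifnot(is.finite(eda_phasic_gain), eda_phasic_gain > 0,
            is.finite(bvp_slope_shift), is.finite(hr_delta),
            onset_lead >= 0, duration > 0)
  structure(list(eda_phasic_gain = eda_phasic_gain,
                 bvp_slope_shift = bvp_slope_shift,
                 hr_delta = hr_delta,
                 onset_lead = onset_lead,
                 duration = duration),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
effect_spec_null <- function() {
  effect_spec(eda_phasic_gain = 1, bvp_slope_shift = 0, hr_delta = 0)
}

#' Specify a synthetic cohort
#'
#' Describes a cohort of participants wearing a wrist biosensor during
#' waking hours: how many participants, how many recording days each,
#' daily wear duration, how often they tag distress events, the
#' physiological event signature, and how much cross-participant
#' heterogeneity (per-participant shifts in tonic EDA and HR baseline,
#' the "random intercept" a mixed-effect model can exploit) to inject.
#'
#' @param n_participants number of participants (>= 1).
#' @param days_range integer range `c(lo, hi)` of recording days per
#'   participant (a point range is allowed).
#' @param hours_range real range `c(lo, hi)` of wear hours per day.
#' @param tag_rate tagged events per wear hour; scalar or one value per
#'   participant.
#' @param effect an [effect_spec()].
#' @param nonwear_fraction proportion of nominal wear time replaced by
#'   off-wrist signal (EDA near zero, temperature near ambient).
#' @param sleep_window daily clock interval `c(start_hour, end_hour)`
#'   masked as sleep downstream; sessions are placed inside waking hours.
#' @param heterogeneity list with `eda_sd` (micro-Siemens) and `hr_sd`
#'   (bpm), the standard deviations of per-participant baseline shifts.
#' @param days optional integer vector, one fixed day count per
#'   participant, overriding `days_range`.
#' @param hours optional numeric vector, one fixed hours-per-day value
#'   per participant, overriding `hours_range`.
#' @param seed RNG seed; identical seeds give byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 8,
                        days_range = c(4, 48),
                        hours_range = c(4, 11),
                        tag_rate = 0.6,
                        effect = effect_spec(),
                        nonwear_fraction = 0.05,
                        sleep_window = c(23, 7),
                        heterogeneity = list(eda_sd = 0.5, hr_sd = 5),
                        days = NULL, hours = NULL,
                        seed = 1L) {
  stopifnot(n_participants >= 1,
            length(days_range) == 2, days_range[1] >= 1,
            days_range[2] >= days_range[1],
            length(hours_range) == 2, hours_range[1] > 0,
            hours_range[2] >= hours_range[1],
            all(tag_rate >= 0),
            length(tag_rate) %in% c(1L, n_participants),
            inherits(effect, "effect_spec"),
            nonwear_fraction >= 0, nonwear_fraction < 1)
  if (!is.null(days)) stopifnot(length(days) == n_participants, all(days >= 1))
  if (!is.null(hours)) stopifnot(length(hours) == n_participants, all(hours > 0))
  if (hours_range[2] <= 0) stop("zero wear time requested")
  structure(list(n_participants = as.integer(n_participants),
                 days_range = as.integer(days_range),
                 hours_range = as.numeric(hours_range),
                 tag_rate = as.numeric(tag_rate),
                 effect = effect,
                 nonwear_fraction = nonwear_fraction,
                 sleep_window = sleep_window,
                 heterogeneity = heterogeneity,
                 days = if (is.null(days)) NULL else as.integer(days),
                 hours = if (is.null(hours)) NULL else as.numeric(hours),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# SCR impulse response: exponential rise (tau_r) and decay (tau_d),
# normalized to unit peak. Truncated at 30 s.
scr_kernel <- function(rate, tau_r = 1, tau_d = 4, span = 30) {
  t <- seq(0, span, by = 1 / rate)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k / max(k)
}

# Simulate one contiguous session of all four channels.
# event_iv: data.frame(start, end) of altered physiology, absolute UNIX s.
simulate_channels <- function(start_time, dur_s, effect, eda_shift, hr_shift,
                              event_iv, nonwear_iv = iv()) {
  n1 <- as.integer(dur_s)            # HR, 1 Hz
  n4 <- as.integer(dur_s * 4)        # EDA / TEMP, 4 Hz
  n64 <- as.integer(dur_s * 64)      # BVP, 64 Hz

  t1 <- start_time + (0:(n1 - 1))
  t4 <- start_time + (0:(n4 - 1)) / 4
  t64 <- start_time + (0:(n64 - 1)) / 64

  in_iv <- function(t, ivs) {
    if (nrow(ivs) == 0) return(rep(FALSE, length(t)))
    hit <- rep(FALSE, length(t))
    for (i in seq_len(nrow(ivs))) hit <- hit | (t >= ivs$start[i] & t < ivs$end[i])
    hit
  }
  ev1 <- in_iv(t1, event_iv); ev4 <- in_iv(t4, event_iv); ev64 <- in_iv(t64, event_iv)

  # --- HR: bounded random walk around a participant-shifted baseline ----
  base_hr <- 75 + hr_shift
  hr <- numeric(n1)
  hr[1] <- base_hr + stats::rnorm(1, 0, 2)
  steps <- stats::rnorm(n1, 0, 0.4)
  for (i in 2:n1) {
    hr[i] <- hr[i - 1] + steps[i] - 0.01 * (hr[i - 1] - base_hr)
  }
  hr <- pmin(pmax(hr, 45), 140)
  hr_out <- hr + effect$hr_delta * ev1

  # --- BVP: quasi-periodic pulse driven by instantaneous HR -------------
  hr64 <- stats::approx(t1, hr_out, xout = t64, rule = 2)$y
  phase <- cumsum(hr64 / 60 / 64)
  env_walk <- stats::rnorm(n1, 0, 0.02)
  env1 <- 1 + cumsum(env_walk) - (seq_len(n1) / n1) * sum(env_walk)  # tethered walk
  env1 <- pmax(0.3, env1)
  env <- stats::approx(t1, env1, xout = t64, rule = 2)$y
  if (effect$bvp_slope_shift != 0 && nrow(event_iv) > 0) {
    for (i in seq_len(nrow(event_iv))) {
      sel <- t64 >= event_iv$start[i] & t64 < event_iv$end[i]
      env[sel] <- env[sel] + effect$bvp_slope_shift * (t64[sel] - event_iv$start[i])
    }
  }
  bvp <- env * sin(2 * pi * phase) + 0.3 * env * sin(4 * pi * phase + 0.8) +
    stats::rnorm(n64, 0, 0.05)

  # --- EDA: drifting tonic baseline + Poisson SCR bursts ----------------
  drift <- cumsum(stats::rnorm(n4, 0, 0.002))
  drift <- drift - (seq_len(n4) / n4) * drift[n4]
  tonic <- pmax(0.05, 2 + eda_shift + drift)
  base_rate <- 1.5 / 60 / 4          # SCRs per 4 Hz sample (1.5/min at rest)
  lambda <- base_rate * ifelse(ev4, effect$eda_phasic_gain, 1)
  arrivals <- which(stats::runif(n4) < lambda)
  phasic <- numeric(n4)
  if (length(arrivals) > 0) {
    kern <- scr_kernel(4)
    amps <- stats::rexp(length(arrivals), rate = 1 / 0.3) *
      ifelse(ev4[arrivals], effect$eda_phasic_gain, 1)
    for (j in seq_along(arrivals)) {
      idx <- arrivals[j]:min(n4, arrivals[j] + length(kern) - 1L)
      phasic[idx] <- phasic[idx] + amps[j] * kern[seq_along(idx)]
    }
  }
  eda <- tonic + phasic + stats::rnorm(n4, 0, 0.005)

  # --- TEMP: wrist skin temperature with slow drift ---------------------
  tdrift <- cumsum(stats::rnorm(n4, 0, 0.001))
  temp <- 33.5 + 0.3 * sin(2 * pi * (t4 - start_time) / dur_s) + tdrift +
    stats::rnorm(n4, 0, 0.02)

  # --- non-wear: off-wrist signal overwrites ----------------------------
  if (nrow(nonwear_iv) > 0) {
    nw4 <- in_iv(t4, nonwear_iv)
    eda[nw4] <- 0.005 + abs(stats::rnorm(sum(nw4), 0, 0.003))
    temp[nw4] <- 26 + stats::rnorm(sum(nw4), 0, 0.1)
  }

  list(
    BVP = channel_series("BVP", start_time, 64, bvp),
    EDA = channel_series("EDA", start_time, 4, eda),
    TEMP = channel_series("TEMP", start_time, 4, temp),
    HR = channel_series("HR", start_time, 1, hr_out)
  )
}

# Lay out sessions, tags and ground-truth intervals for one participant
# without synthesizing waveforms (cheap; used by both modes).
layout_participant <- function(pid, spec, p_idx) {
  n_days <- if (!is.null(spec$days)) spec$days[p_idx] else
    if (spec$days_range[1] == spec$days_range[2]) spec$days_range[1] else
      sample(spec$days_range[1]:spec$days_range[2], 1)
  rate <- if (length(spec$tag_rate) == 1) spec$tag_rate else spec$tag_rate[p_idx]
  base_day <- 19700 * 86400 + (p_idx - 1) * 60L * 86400  # disjoint calendars
  out <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    hours <- if (!is.null(spec$hours)) spec$hours[p_idx] else
      stats::runif(1, spec$hours_range[1], spec$hours_range[2])
    start_clock <- stats::runif(1, 8, max(8, min(12, 22.5 - hours)))
    start <- floor(base_day + (d - 1) * 86400 + start_clock * 3600)
    dur <- round(hours * 3600)
    n_tags <- stats::rpois(1, rate * hours)
    tags <- sort(floor(stats::runif(n_tags, start, start + dur)))
    out[[d]] <- list(participant = pid,
                     session = sprintf("%s_d%03d", pid, d),
                     start = start, dur = dur, tags = tags)
  }
  out
}

#' Simulate a synthetic cohort of biosensor sessions
#'
#' Generates per-participant, per-day sessions of BVP (64 Hz), EDA (4 Hz),
#' TEMP (4 Hz) and HR (1 Hz) with self-tagged events, per-participant
#' baseline heterogeneity, optional non-wear blocks, and a ground-truth
#' table of true event intervals. With `signals = FALSE` only the session
#' layout, tags and ground truth are generated (useful for studying tag
#' counts at full cohort scale without synthesizing waveforms).
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory; when given, session folders, a cohort
#'   manifest and ground-truth sidecar CSVs are written there.
#' @param signals logical; synthesize waveforms (default) or layout only.
#' @return A list with elements `sessions` (list of `e4_session`, empty
#'   when `signals = FALSE`), `manifest`, `ground_truth`, `tags`, and
#'   `participants` (per-participant random-intercept values).
#' @export
simulate_cohort <- function(spec, dir = NULL, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeded(spec$seed, {
    pids <- sprintf("P%02d", seq_len(spec$n_participants))
    eda_shift <- stats::rnorm(spec$n_participants, 0, spec$heterogeneity$eda_sd)
    hr_shift <- stats::rnorm(spec$n_participants, 0, spec$heterogeneity$hr_sd)
    participants <- data.frame(participant = pids,
                               eda_shift = eda_shift, hr_shift = hr_shift)

    layouts <- list()
    for (p in seq_along(pids)) {
      layouts <- c(layouts, layout_participant(pids[p], spec, p))
    }

    sessions <- list()
    gt <- list(); tag_rows <- list(); man <- list()
    for (i in seq_along(layouts)) {
      L <- layouts[[i]]
      ev <- iv()
      if (length(L$tags) > 0) {
        ev <- iv_normalize(iv(L$tags - spec$effect$onset_lead,
                              L$tags - spec$effect$onset_lead + spec$effect$duration))
        ev <- iv_intersect(ev, iv(L$start, L$start + L$dur))
        gt[[length(gt) + 1]] <- data.frame(
          participant = L$participant, session = L$session,
          tag = L$tags,
          effect_start = pmax(L$start, L$tags - spec$effect$onset_lead),
          effect_end = pmin(L$start + L$dur,
                            L$tags - spec$effect$onset_lead + spec$effect$duration))
      }
      tag_rows[[i]] <- data.frame(participant = L$participant,
                                  session = L$session,
                                  n_tags = length(L$tags))
      man[[i]] <- data.frame(participant = L$participant, session = L$session,
                             start = L$start, duration_s = L$dur)
      if (signals) {
        nw <- iv()
        if (spec$nonwear_fraction > 0) {
          nw_dur <- spec$nonwear_fraction * L$dur
          nw_start <- stats::runif(1, L$start, L$start + L$dur - nw_dur)
          nw <- iv(round(nw_start * 4) / 4, round((nw_start + nw_dur) * 4) / 4)
        }
        p_idx <- match(L$participant, pids)
        ch <- simulate_channels(L$start, L$dur, spec$effect,
                                eda_shift[p_idx], hr_shift[p_idx], ev, nw)
        sessions[[length(sessions) + 1]] <- e4_session(
          participant_id = L$participant, session_id = L$session,
          channels = ch, tags = L$tags)
      }
    }
    ground_truth <- if (length(gt)) do.call(rbind, gt) else
      data.frame(participant = character(0), session = character(0),
                 tag = numeric(0), effect_start = numeric(0),
                 effect_end = numeric(0))
    manifest <- do.call(rbind, man)
    tags <- do.call(rbind, tag_rows)
    res <- list(sessions = sessions, manifest = manifest,
                ground_truth = ground_truth, tags = tags,
                participants = participants)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (s in res$sessions) {
        write_session(s, file.path(dir, s$participant_id, s$session_id))
      }
      utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
      utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                       row.names = FALSE)
      utils::write.csv(participants, file.path(dir, "participants.csv"),
                       row.names = FALSE)
    }
    res
  })
}

#' Simulate a 5-minute in-lab session (rest or symptom exposure)
#'
#' Stand-in for controlled laboratory segments: a resting baseline or an
#' exposure condition in which the event physiology of `effect` is
#' applied continuously for the whole 5 minutes.
#'
#' @param condition `"rest"` or `"exposure"`.
#' @param effect an [effect_spec()].
#' @param seed RNG seed.
#' @param participant participant id recorded in the session.
#' @return An `e4_session` of 300 s with no tags.
#' @export
simulate_lab_session <- function(condition = c("rest", "exposure"),
                                 effect = effect_spec(), seed = 1L,
                                 participant = "LAB") {
  condition <- match.arg(condition)
  seeded(seed, {
    start <- 19700 * 86400 + 9 * 3600
    ev <- if (condition == "exposure") iv(start, start + 300) else iv()
    ch <- simulate_channels(start, 300, effect, 0, 0, ev)
    e4_session(participant_id = participant,
               session_id = paste0(participant, "_", condition),
               channels = ch, tags = numeric(0))
  })
}

#' Expected tag count of a cohort layout
#'
#' Poisson expectation of total emitted tags, `sum(rate_i * hours_i)`,
#' used as an independent check on [simulate_cohort()] tag counts.
#'
#' @param tag_rate per-participant tags per wear hour.
#' @param wear_hours per-participant total wear hours.
#' @return Expected total number of tags.
#' @export
expected_tags <- function(tag_rate, wear_hours) {
  stopifnot(length(tag_rate) == length(wear_hours))
  sum(tag_rate * wear_hours)
}
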