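# Independent oracles and cheap fixture builders shared across tests.

# internal interval constructor, aliased for test readability
iv <- e4episodes:::iv


# Brute-force windowing oracle: given sorted tag times and wear
# intervals, re-derive event windows and the nonevent exclusion zone by
# direct interval scanning, independently of label_events().
oracle_windowing <- function(tags, wear, W = 300, B = 300) {
  events <- numeric(0)      # accepted tag times
  claimed <- matrix(numeric(0), ncol = 2)
  excl <- matrix(numeric(0), ncol = 2)
  wholly_in_wear <- function(s, e) {
    any(wear$start <= s & wear$end >= e)
  }
  for (t in sort(tags)) {
    excl <- rbind(excl, c(t - W, t + B))
    in_claimed <- FALSE
    if (nrow(claimed) > 0) {
      for (r in seq_len(nrow(claimed))) {
        if (claimed[r, 1] <= t && t < claimed[r, 2]) in_claimed <- TRUE
      }
    }
    if (in_claimed) next
    if (!wholly_in_wear(t - W, t)) next
    events <- c(events, t)
    claimed <- rbind(claimed, c(t - W, t + B))
  }
  list(events = events, exclusion = excl)
}

# Brute-force pairwise-concordance AUC (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force longest-run non-wear scan on the 4 Hz grid.
oracle_nonwear_duration <- function(session, eda_floor = 0.03,
                                    temp_floor = 30, min_gap = 300) {
  eda <- session$channels$EDA; temp <- session$channels$TEMP
  low <- eda$values < eda_floor & temp$values < temp_floor
  total <- 0; run <- 0
  for (i in seq_along(low)) {
    if (low[i]) run <- run + 1 else {
      if (run / 4 >= min_gap) total <- total + run / 4
      run <- 0
    }
  }
  if (run / 4 >= min_gap) total <- total + run / 4
  total
}

# Fabricate a feature table directly (no signal synthesis): a handful
# of catalog-named feature columns, labels optionally driven by one
# feature and per-participant intercepts on another.
make_feature_tbl <- function(n = 120, n_participants = 4, n_days = 10,
                             signal_feature = "eda.phasic_max",
                             signal_strength = 2, intercept_sd = 0,
                             seed = 1) {
  set.seed(seed)
  feats <- c("bvp.slope", "bvp.sd", "hr.mean", "temp.mean",
             "eda.phasic_max", "eda.tonic_mean")
  x <- matrix(rnorm(n * length(feats)), n, length(feats),
              dimnames = list(NULL, feats))
  part <- sprintf("P%02d", sample.int(n_participants, n, replace = TRUE))
  b <- rnorm(n_participants, 0, intercept_sd)
  names(b) <- sprintf("P%02d", seq_len(n_participants))
  eta <- signal_strength * x[, signal_feature] + b[part]
  y <- rbinom(n, 1, stats::plogis(eta))
  tbl <- data.frame(participant = part,
                    session = paste0(part, "_s"),
                    start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 300,
                    label = ifelse(y == 1, "event", "nonevent"),
                    source_tag = NA_real_,
                    day_index = sample.int(n_days, n, replace = TRUE) - 1L)
  cbind(tbl, as.data.frame(x))
}

# One small signal cohort reused by several test files (built lazily).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_participants = 2, days_range = c(1, 1),
                          hours_range = c(1, 1), tag_rate = 2, seed = 42)
      cache <<- simulate_cohort(spec)
    }
    cache
  }
})
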