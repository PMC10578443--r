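# Wear-adherence arithmetic, correlation screening between symptom
# metadata and biosensor use, and the in-lab rest-vs-exposure feature
# comparison.

#' Published per-participant wear descriptives
#'
#' The per-participant descriptive table of the adolescent OCD cohort
#' that motivated this pipeline: tag counts, wear hours, wear days and
#' the derived per-day / per-hour rates for the eight participants who
#' wore the biosensor in everyday life. Used as the reference marginal
#' distribution for cohort simulation and for adherence arithmetic.
#'
#' @return data.frame with one row per participant.
#' @export
cohort_descriptives <- function() {
  data.frame(
    participant = c("0", "1", "3", "4", "5", "6", "7", "8"),
    sex = c("M", "M", "F", "M", "M", "F", "F", "F"),
    age_group = c("10-12", "10-12", "10-12", "10-12",
                  "13-16", "13-16", "13-16", "13-16"),
    n_tags = c(26, 313, 9, 6, 38, 73, 238, 936),
    n_hours = c(233.32, 372.09, 29.03, 336.71, 118.65, 419.34, 521.33, 374.93),
    n_days = c(36, 35, 4, 35, 29, 47, 48, 36),
    mean_hours_per_day = c(6.48, 10.63, 7.26, 9.62, 4.09, 8.92, 10.86, 10.41),
    mean_tags_per_hour = c(0.11, 0.84, 0.31, 0.02, 0.32, 0.17, 0.46, 2.50))
}

#' Cohort adherence summary
#'
#' Aggregates a per-participant wear table ([wear_summary()] output or
#' [cohort_descriptives()]): total tags / hours / days, unweighted
#' participant means, and the retention rate — the fraction of enrolled
#' participants who wore the device for more than `min_days` days.
#'
#' @param per per-participant data.frame with `n_tags`, `n_hours`,
#'   `n_days`.
#' @param n_enrolled number of enrolled participants (the table may
#'   only contain those who produced data).
#' @param min_days day threshold defining retention.
#' @return Named list of cohort aggregates including `retention_pct`.
#' @export
acceptability_summary <- function(per, n_enrolled = nrow(per), min_days = 7) {
  agg <- cohort_aggregates(per)
  agg$n_enrolled <- n_enrolled
  agg$n_retained <- sum(per$n_days > min_days)
  agg$retention_pct <- 100 * agg$n_retained / n_enrolled
  agg
}

#' Correlation screen between symptoms, age and biosensor use
#'
#' Spearman rank correlations (average ranks under ties) between
#' participant metadata columns (age, symptom counts and severities)
#' and biosensor-use columns (wear hours, tag rates), with p-values and
#' a significance flag at the stated threshold. With fewer than 3
#' complete participants the correlations are suppressed.
#'
#' @param per per-participant wear table (must contain `participant`).
#' @param metadata data.frame with `participant` plus numeric columns.
#' @param use_cols wear-table columns entering the matrix.
#' @param alpha significance threshold for the flag matrix.
#' @return List with `table` (merged per-participant table), `rho`,
#'   `p_value` and `significant` matrices (or `NULL` when suppressed).
#' @export
acceptability_report <- function(per, metadata,
                                 use_cols = c("n_hours",
                                              "mean_hours_per_day",
                                              "mean_tags_per_hour"),
                                 alpha = 0.01) {
  tab <- merge(per, metadata, by = "participant")
  num_cols <- c(intersect(use_cols, colnames(tab)),
                setdiff(colnames(metadata), "participant"))
  num_cols <- num_cols[vapply(tab[num_cols], is.numeric, TRUE)]
  if (nrow(tab) < 3) {
    return(list(table = tab, rho = NULL, p_value = NULL, significant = NULL))
  }
  k <- length(num_cols)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(num_cols, num_cols))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ct <- suppressWarnings(
        stats::cor.test(tab[[num_cols[i]]], tab[[num_cols[j]]],
                        method = "spearman", exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(table = tab, rho = rho, p_value = p, significant = p < alpha)
}

#' Compare feature values between lab rest and exposure conditions
#'
#' Extracts the 5-min feature vector of each participant's resting and
#' exposure segments and tabulates the top-`k` most important features
#' (per an [feature_importance()] ranking) per condition, with group
#' medians and quartiles for box-plot display. Participants missing
#' either condition are excluded with a message.
#'
#' @param lab_sessions named list; one element per participant, each a
#'   list with `rest` and `exposure` `e4_session` objects of >= 5 min.
#' @param ranking importance ranking (data.frame with `feature`), or
#'   `NULL` to use all 66 features.
#' @param k number of top features to report.
#' @return List with `values` (long data.frame participant / condition /
#'   feature / value) and `summary` (per feature and condition median
#'   and quartiles).
#' @export
rest_vs_exposure_report <- function(lab_sessions, ranking = NULL, k = 20) {
  feats <- if (is.null(ranking)) feature_catalog()$name else
    utils::head(ranking$feature, k)
  rows <- list()
  for (p in names(lab_sessions)) {
    pair <- lab_sessions[[p]]
    if (is.null(pair$rest) || is.null(pair$exposure)) {
      message("excluding participant ", p, ": missing lab condition")
      next
    }
    for (cond in c("rest", "exposure")) {
      s <- pair[[cond]]
      span <- session_span(s)
      sl <- segment_signals(s, span[1], span[1] + 300)
      if (is_rejected(sl)) {
        message("excluding participant ", p, ": segment shorter than 5 min")
        rows <- rows[!vapply(rows, function(r) r$participant[1] == p, TRUE)]
        break
      }
      fv <- extract_features(sl)[feats]
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, condition = cond, feature = names(fv),
        value = unname(fv))
    }
  }
  values <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(values)) {
    summary <- do.call(rbind, lapply(
      split(values, list(values$feature, values$condition)), function(g) {
        q <- stats::quantile(g$value, c(0.25, 0.5, 0.75))
        data.frame(feature = g$feature[1], condition = g$condition[1],
                   q25 = q[[1]], median = q[[2]], q75 = q[[3]])
      }))
    rownames(summary) <- NULL
  }
  list(values = values, summary = summary)
}
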