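# 66-feature extractor over 5-min windows: 24 BVP + 9 HR + 5 TEMP +
# 28 EDA features. The catalog is fixed-order and data-driven
# (feature_catalog()) so an alternative list can be swapped in without
# touching callers. Degenerate-signal conventions: a constant signal has
# skewness/kurtosis 0, spectral entropy 0, dominant frequency 0 and
# zero-crossing rate 0.

BVP_BANDS <- list(c(0.5, 1), c(1, 2), c(2, 3), c(3, 4), c(4, 6), c(6, 8))
EDA_BANDS <- list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.5))

#' The 66-feature catalog
#'
#' @return data.frame with `name`, `channel` and a one-line `definition`
#'   per feature, in the fixed extraction order.
#' @export
feature_catalog <- function() {
  bvp <- c(mean = "mean", sd = "standard deviation", min = "minimum",
           max = "maximum", skew = "skewness", kurt = "excess kurtosis",
           rms = "root mean square",
           abs_diff_mean = "mean |first difference|",
           abs_diff_max = "max |first difference|",
           diff_sd = "sd of first difference",
           abs_diff2_mean = "mean |second difference|",
           slope = "least-squares slope vs time",
           bp_0.5_1 = "Welch band power 0.5-1 Hz",
           bp_1_2 = "Welch band power 1-2 Hz",
           bp_2_3 = "Welch band power 2-3 Hz",
           bp_3_4 = "Welch band power 3-4 Hz",
           bp_4_6 = "Welch band power 4-6 Hz",
           bp_6_8 = "Welch band power 6-8 Hz",
           bp_total = "total power 0.5-8 Hz",
           bp_dom_rel = "dominant band power / total power",
           spec_entropy = "normalized spectral entropy 0.5-8 Hz",
           dom_freq = "dominant frequency 0.5-8 Hz",
           spec_centroid = "spectral centroid 0.5-8 Hz",
           zcr = "zero crossings per second (mean-removed)")
  hr <- c(mean = "mean", sd = "standard deviation", min = "minimum",
          max = "maximum", range = "max - min",
          slope = "least-squares slope vs time",
          abs_diff_mean = "mean |first difference|",
          rmssd = "root mean square of successive differences",
          kurt = "excess kurtosis")
  temp <- c(mean = "mean", sd = "standard deviation", min = "minimum",
            max = "maximum", slope = "least-squares slope vs time")
  eda <- c(mean = "mean", sd = "standard deviation", min = "minimum",
           max = "maximum", slope = "least-squares slope vs time",
           abs_diff_mean = "mean |first difference|",
           diff_sd = "sd of first difference",
           abs_diff2_mean = "mean |second difference|",
           tonic_mean = "tonic mean", tonic_sd = "tonic sd",
           tonic_min = "tonic minimum", tonic_max = "tonic maximum",
           tonic_slope = "tonic least-squares slope",
           phasic_mean = "phasic mean", phasic_sd = "phasic sd",
           phasic_max = "phasic maximum", phasic_rms = "phasic RMS",
           scr_count = "number of detected SCRs",
           scr_amp_mean = "mean SCR amplitude",
           scr_amp_max = "max SCR amplitude",
           scr_amp_sum = "summed SCR amplitude",
           scr_rise_mean = "mean SCR rise time (s)",
           scr_rec_half_mean = "mean SCR half-recovery time (s)",
           scr_area = "area of positive phasic component (uS*s)",
           bp_0_0.1 = "Welch band power 0-0.1 Hz",
           bp_0.1_0.2 = "Welch band power 0.1-0.2 Hz",
           bp_0.2_0.5 = "Welch band power 0.2-0.5 Hz",
           spec_entropy = "normalized spectral entropy 0-0.5 Hz")
  grp <- function(prefix, v) data.frame(
    name = paste0(prefix, ".", names(v)), channel = toupper(prefix),
    definition = unname(v))
  rbind(grp("bvp", bvp), grp("hr", hr), grp("temp", temp), grp("eda", eda))
}

#' Names of the feature columns of a table
#'
#' @param tbl data.frame possibly holding feature columns.
#' @return Character vector of columns matching the feature catalog.
#' @export
feature_columns <- function(tbl) {
  intersect(feature_catalog()$name, colnames(tbl))
}

#' Decompose EDA into tonic and phasic components
#'
#' Tonic is the zero-phase low-pass component (Butterworth order 2,
#' cutoff 0.05 Hz, forward-backward filtered); phasic is the residual,
#' so `tonic + phasic` reconstructs the input exactly.
#'
#' @param x EDA samples at `rate` Hz.
#' @param rate sampling rate in Hz (4 for the wristband).
#' @param cutoff low-pass cutoff in Hz.
#' @return List with `tonic` and `phasic` components.
#' @export
decompose_eda <- function(x, rate = 4, cutoff = 0.05) {
  if (length(x) < 12 || stats::sd(x) == 0) {
    return(list(tonic = x, phasic = rep(0, length(x))))
  }
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  tonic <- as.numeric(signal::filtfilt(bf, x))
  list(tonic = tonic, phasic = x - tonic)
}

#' Detect skin conductance responses in a phasic EDA trace
#'
#' A response is a local maximum whose trough-to-peak amplitude (from
#' the preceding local minimum, the onset) is at least `amp_threshold`.
#' Rise time is onset-to-peak; half-recovery time is peak to the first
#' sample falling below peak minus half the amplitude (missing when the
#' trace does not recover within the slice, and then excluded from the
#' half-recovery mean).
#'
#' @param phasic phasic EDA samples.
#' @param rate sampling rate in Hz.
#' @param amp_threshold minimum amplitude in micro-Siemens. The 0.05
#'   default sits at the conservative end of conventional SCR criteria
#'   (0.01-0.05) so that sensor noise on the order of a few
#'   thousandths of a micro-Siemens is not counted as responses.
#' @return data.frame with `onset`, `peak` (sample indices), `amplitude`,
#'   `rise_time`, `half_rec_time` (seconds; `NA` if unrecovered).
#' @export
detect_scrs <- function(phasic, rate = 4, amp_threshold = 0.05) {
  n <- length(phasic)
  empty <- data.frame(onset = integer(0), peak = integer(0),
                      amplitude = numeric(0), rise_time = numeric(0),
                      half_rec_time = numeric(0))
  if (n < 3) return(empty)
  d <- diff(phasic)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  mins <- which(d[-length(d)] <= 0 & d[-1] > 0) + 1L
  if (length(peaks) == 0) return(empty)
  out <- empty
  for (p in peaks) {
    prior <- mins[mins < p]
    onset <- if (length(prior) > 0) max(prior) else 1L
    amp <- phasic[p] - phasic[onset]
    if (amp < amp_threshold) next
    half_level <- phasic[p] - amp / 2
    rec_idx <- which(phasic[(p + 1):n] <= half_level)
    half_rec <- if (p < n && length(rec_idx) > 0) rec_idx[1] / rate else NA_real_
    out <- rbind(out, data.frame(onset = onset, peak = p, amplitude = amp,
                                 rise_time = (p - onset) / rate,
                                 half_rec_time = half_rec))
  }
  out
}

#' Extract the 66-feature vector of one window
#'
#' @param slices list of per-channel slices from [segment_signals()].
#' @param scr_threshold SCR amplitude threshold in micro-Siemens.
#' @return Named numeric vector of length 66 in catalog order.
#' @export
extract_features <- function(slices, scr_threshold = 0.05) {
  if (is.null(slices) || is_rejected(slices)) stop("incomplete window slices")
  bvp <- slices$BVP; hr <- slices$HR; temp <- slices$TEMP; eda <- slices$EDA

  basic <- function(x) c(mean = mean(x), sd = stats::sd(x),
                         min = min(x), max = max(x))
  diffs <- function(x) {
    d1 <- diff(x); d2 <- diff(x, differences = 2)
    c(abs_diff_mean = mean(abs(d1)), diff_sd = stats::sd(d1),
      abs_diff2_mean = mean(abs(d2)))
  }

  # --- BVP (24) ---------------------------------------------------------
  sp <- welch_psd(bvp, 64)
  bps <- vapply(BVP_BANDS, function(b) band_power(sp, b[1], b[2]), 0)
  total <- band_power(sp, 0.5, 8)
  sel <- sp$freq >= 0.5 & sp$freq < 8
  dom_freq <- if (stats::sd(bvp) == 0 || !any(sel) || max(sp$psd[sel]) <= 0) 0 else
    sp$freq[sel][which.max(sp$psd[sel])]
  centroid <- if (total > 0) sum(sp$freq[sel] * sp$psd[sel]) / sum(sp$psd[sel]) else 0
  xc <- bvp - mean(bvp)
  zc <- if (stats::sd(bvp) == 0) 0 else
    sum(diff(sign(xc + (xc == 0) * 1e-300)) != 0) / (length(bvp) / 64)
  d1 <- diff(bvp)
  f_bvp <- c(basic(bvp),
             skew = safe_skew(bvp), kurt = safe_kurt(bvp),
             rms = sqrt(mean(bvp^2)),
             abs_diff_mean = mean(abs(d1)), abs_diff_max = max(abs(d1)),
             diff_sd = stats::sd(d1),
             abs_diff2_mean = mean(abs(diff(bvp, differences = 2))),
             slope = ls_slope(bvp, 64),
             bp_0.5_1 = bps[1], bp_1_2 = bps[2], bp_2_3 = bps[3],
             bp_3_4 = bps[4], bp_4_6 = bps[5], bp_6_8 = bps[6],
             bp_total = total,
             bp_dom_rel = if (total > 0) max(bps) / total else 0,
             spec_entropy = if (stats::sd(bvp) == 0) 0 else
               spectral_entropy(sp, 0.5, 8),
             dom_freq = dom_freq, spec_centroid = centroid, zcr = zc)

  # --- HR (9) -----------------------------------------------------------
  dh <- diff(hr)
  f_hr <- c(basic(hr), range = max(hr) - min(hr), slope = ls_slope(hr, 1),
            abs_diff_mean = mean(abs(dh)), rmssd = sqrt(mean(dh^2)),
            kurt = safe_kurt(hr))

  # --- TEMP (5) ---------------------------------------------------------
  f_temp <- c(basic(temp), slope = ls_slope(temp, 4))

  # --- EDA (28) ---------------------------------------------------------
  dec <- decompose_eda(eda, 4)
  tonic <- dec$tonic; phasic <- dec$phasic
  scrs <- detect_scrs(phasic, 4, scr_threshold)
  spe <- welch_psd(eda - mean(eda), 4)
  ebps <- vapply(EDA_BANDS, function(b) band_power(spe, b[1], b[2]), 0)
  f_eda <- c(basic(eda), slope = ls_slope(eda, 4), diffs(eda),
             tonic_mean = mean(tonic), tonic_sd = stats::sd(tonic),
             tonic_min = min(tonic), tonic_max = max(tonic),
             tonic_slope = ls_slope(tonic, 4),
             phasic_mean = mean(phasic), phasic_sd = stats::sd(phasic),
             phasic_max = max(phasic), phasic_rms = sqrt(mean(phasic^2)),
             scr_count = nrow(scrs),
             scr_amp_mean = if (nrow(scrs)) mean(scrs$amplitude) else 0,
             scr_amp_max = if (nrow(scrs)) max(scrs$amplitude) else 0,
             scr_amp_sum = if (nrow(scrs)) sum(scrs$amplitude) else 0,
             scr_rise_mean = if (nrow(scrs)) mean(scrs$rise_time) else 0,
             scr_rec_half_mean = if (nrow(scrs) && any(!is.na(scrs$half_rec_time)))
               mean(scrs$half_rec_time, na.rm = TRUE) else 0,
             scr_area = sum(pmax(phasic, 0)) / 4,
             bp_0_0.1 = ebps[1], bp_0.1_0.2 = ebps[2], bp_0.2_0.5 = ebps[3],
             spec_entropy = if (stats::sd(eda) == 0) 0 else
               spectral_entropy(spe, 0, 0.5))

  out <- c(stats::setNames(f_bvp, paste0("bvp.", names(f_bvp))),
           stats::setNames(f_hr, paste0("hr.", names(f_hr))),
           stats::setNames(f_temp, paste0("temp.", names(f_temp))),
           stats::setNames(f_eda, paste0("eda.", names(f_eda))))
  cat_names <- feature_catalog()$name
  stopifnot(identical(sort(names(out)), sort(cat_names)))
  out[cat_names]
}

#' Build the feature table for a window table
#'
#' Slices each labeled window out of its session and extracts the
#' 66-feature vector; windows with incomplete slices are dropped and
#' counted in the `rejected` attribute.
#'
#' @param sessions list of `e4_session`.
#' @param windows window table from [build_windows()].
#' @return data.frame with window metadata plus 66 feature columns;
#'   attribute `rejected` holds the dropped-window rows with reasons.
#' @export
extract_feature_table <- function(sessions, windows) {
  ses_key <- vapply(sessions, function(s) s$session_id, "")
  feats <- vector("list", nrow(windows))
  reject <- logical(nrow(windows)); reason <- character(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    s <- sessions[[match(windows$session[i], ses_key)]]
    sl <- segment_signals(s, windows$start[i], windows$end[i])
    if (is_rejected(sl)) {
      reject[i] <- TRUE
      reason[i] <- attr(sl, "reason") %||% "incomplete"
      next
    }
    feats[[i]] <- extract_features(sl)
  }
  kept <- which(!reject)
  fmat <- do.call(rbind, feats[kept])
  out <- cbind(windows[kept, , drop = FALSE], as.data.frame(fmat))
  rownames(out) <- NULL
  rej <- windows[reject, , drop = FALSE]
  if (nrow(rej) > 0) rej$reason <- reason[reject]
  attr(out, "rejected") <- rej
  out
}

#' Standardize feature columns to zero mean, unit variance
#'
#' Column means and standard deviations are estimated on `fit_rows`
#' only (training rows of the current split) and applied to all rows, so
#' no statistic leaks from validation or test data. Constant columns
#' pass through unscaled with a warning.
#'
#' @param tbl feature table.
#' @param fit_rows integer row indices used to fit the scaling.
#' @return `tbl` with scaled feature columns; the fitted means/sds are
#'   attached as attribute `scaling`.
#' @export
standardize_features <- function(tbl, fit_rows = seq_len(nrow(tbl))) {
  if (length(fit_rows) == 0) stop("empty fit_rows")
  cols <- feature_columns(tbl)
  mu <- vapply(cols, function(cn) mean(tbl[[cn]][fit_rows]), 0)
  sd_ <- vapply(cols, function(cn) stats::sd(tbl[[cn]][fit_rows]), 0)
  const <- !is.finite(sd_) | sd_ == 0
  if (any(const)) {
    warning("constant feature column(s) passed through unscaled: ",
            paste(cols[const], collapse = ", "))
  }
  for (j in seq_along(cols)) {
    if (const[j]) next
    tbl[[cols[j]]] <- (tbl[[cols[j]]] - mu[j]) / sd_[j]
  }
  attr(tbl, "scaling") <- data.frame(name = cols, mean = mu, sd = sd_,
                                     constant = const)
  tbl
}
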