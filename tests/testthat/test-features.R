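slices_of <- function(bvp = NULL, eda = NULL, temp = NULL, hr = NULL) {
  list(BVP = bvp %||% rep(0, 19200), EDA = eda %||% rep(1, 1200),
       TEMP = temp %||% rep(33, 1200), HR = hr %||% rep(70, 300))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the extractor returns exactly 66 features in fixed groups", {
  fv <- extract_features(slices_of())
  cat_ <- feature_catalog()
  expect_length(fv, 66)
  expect_identical(names(fv), cat_$name)
  grp <- table(sub("\\..*", "", cat_$name))
  expect_identical(as.integer(grp[c("bvp", "hr", "temp", "eda")]),
                   c(24L, 9L, 5L, 28L))
  expect_true(all(is.finite(fv)))
})

test_that("degenerate constant signals follow the stated conventions", {
  fv <- extract_features(slices_of())
  expect_identical(unname(fv[c("bvp.sd", "bvp.slope", "bvp.zcr",
                               "bvp.spec_entropy", "bvp.dom_freq",
                               "bvp.skew", "bvp.kurt")]),
                   rep(0, 7))
  expect_identical(unname(fv["eda.scr_count"]), 0)
})

test_that("a pure sinusoid lands in the right spectral bin and band", {
  t <- (0:19199) / 64
  fv <- extract_features(slices_of(bvp = sin(2 * pi * 1.25 * t)))
  # 64-s Welch segments: bin width 1/64 Hz
  expect_lt(abs(fv[["bvp.dom_freq"]] - 1.25), 1 / 64 + 1e-9)
  bands <- fv[c("bvp.bp_0.5_1", "bvp.bp_1_2", "bvp.bp_2_3", "bvp.bp_3_4",
                "bvp.bp_4_6", "bvp.bp_6_8")]
  expect_identical(names(which.max(bands)), "bvp.bp_1_2")
  expect_gt(bands[["bvp.bp_1_2"]] / fv[["bvp.bp_total"]], 0.95)
  expect_equal(fv[["bvp.zcr"]], 2 * 1.25, tolerance = 0.02)
})

test_that("amplitude equivariance and shift invariance hold", {
  set.seed(5)
  t <- (0:19199) / 64
  x <- sin(2 * pi * 1.2 * t) + 0.3 * rnorm(19200)
  f1 <- extract_features(slices_of(bvp = x))
  f2 <- extract_features(slices_of(bvp = 3 * x))
  for (nm in c("bvp.sd", "bvp.rms", "bvp.abs_diff_max")) {
    expect_equal(f2[[nm]], 3 * f1[[nm]], tolerance = 1e-9)
  }
  for (nm in c("bvp.spec_entropy", "bvp.dom_freq", "bvp.zcr")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-9)
  }
  # pure function: identical slices give bit-identical vectors
  expect_identical(f1, extract_features(slices_of(bvp = x)))
})

test_that("EDA decomposition is exact, smooth and low-pass", {
  set.seed(6)
  x <- 2 + cumsum(rnorm(1200, 0, 0.01))
  d <- decompose_eda(x)
  expect_equal(d$tonic + d$phasic, x, tolerance = 1e-12)
  # constant input: zero phasic
  dc <- decompose_eda(rep(1.5, 1200))
  expect_identical(dc$phasic, rep(0, 1200))
  # a 0.5 Hz oscillation is almost entirely phasic (cutoff 0.05 Hz)
  s <- sin(2 * pi * 0.5 * (0:1199) / 4)
  ds <- decompose_eda(s + 2)
  mid <- 200:1000  # ignore filter edge transients
  expect_lt(max(abs(ds$tonic[mid] - mean(ds$tonic[mid]))), 0.05)
})

test_that("SCR detection recovers injected bursts", {
  expect_identical(nrow(detect_scrs(rep(0, 1200))), 0L)
  kern <- e4episodes:::scr_kernel(4)
  one <- numeric(1200); one[200:(199 + length(kern))] <- 0.5 * kern
  s1 <- detect_scrs(one, amp_threshold = 0.05)
  expect_identical(nrow(s1), 1L)
  expect_lt(abs(s1$amplitude - 0.5) / 0.5, 0.1)
  expect_gt(s1$half_rec_time, 0)
  two <- one; two[320:(319 + length(kern))] <- two[320:(319 + length(kern))] + 0.4 * kern
  s2 <- detect_scrs(two, amp_threshold = 0.05)
  expect_identical(nrow(s2), 2L)
})

test_that("standardization is fit on training rows only", {
  co <- tiny_cohort()
  w <- build_windows(co$sessions, seed = 2)
  ft <- extract_feature_table(co$sessions, w)
  cols <- feature_columns(ft)
  all_std <- standardize_features(ft)
  nonconst <- cols[!attr(all_std, "scaling")$constant]
  mus <- vapply(nonconst, function(cn) mean(all_std[[cn]]), 0)
  sds <- vapply(nonconst, function(cn) sd(all_std[[cn]]), 0)
  expect_true(all(abs(mus) < 1e-9))
  expect_true(all(abs(sds - 1) < 1e-6))

  fit_rows <- seq_len(floor(nrow(ft) / 2))
  tr_std <- standardize_features(ft, fit_rows)
  held <- setdiff(seq_len(nrow(ft)), fit_rows)
  # held-out rows standardized with training statistics differ from
  # self-standardization
  self_std <- standardize_features(ft[held, , drop = FALSE])
  expect_false(isTRUE(all.equal(tr_std[held, nonconst[1]],
                                self_std[[nonconst[1]]])))
  expect_error(standardize_features(ft, integer(0)), "empty fit_rows")
})

test_that("feature extraction is invariant to the window's clock position", {
  co <- tiny_cohort()
  s <- co$sessions[[1]]
  span <- session_span(s)
  a <- extract_features(segment_signals(s, span[1] + 100, span[1] + 400))
  # same samples viewed from a session copy shifted by one hour
  s2 <- s
  for (nm in names(s2$channels)) s2$channels[[nm]]$start_time <-
    s2$channels[[nm]]$start_time + 3600
  b <- extract_features(segment_signals(s2, span[1] + 3700, span[1] + 4000))
  expect_identical(a, b)
})
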