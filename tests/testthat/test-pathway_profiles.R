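test_that("reporter normalization is background-subtracted and Renilla-scaled", {
  expect_equal(normalize_reporter(100, 50, 100), 0)
  expect_equal(normalize_reporter(300, 50, 100), 4)
  expect_error(normalize_reporter(10, 0, 1), "Renilla")
  expect_error(normalize_reporter(-1, 10, 0), "non-negative")
  expect_warning(a <- normalize_reporter(50, 10, 80), "clamped")
  expect_equal(a, 0)
  # linearity: doubling firefly and background doubles activity
  expect_equal(normalize_reporter(600, 50, 200),
               2 * normalize_reporter(300, 50, 100))
})

test_that("replicate readings average after normalization", {
  df <- data.frame(
    pathway = rep(c("Wnt", "Notch"), each = 2),
    cell_line = "L1", treatment = "basal",
    replicate = rep(1:2, 2),
    firefly = c(300, 500, 150, 250),
    renilla = c(50, 100, 50, 50),
    firefly_negctrl = c(100, 100, 50, 50)
  )
  act <- reporter_activity(df)
  expect_equal(act$activity[act$pathway == "Wnt"], mean(c(4, 4)))
  expect_equal(act$activity[act$pathway == "Notch"], mean(c(2, 4)))
  expect_error(reporter_activity(df[-2]), "missing column")
})

test_that("fold-change against a reference profile is exact and guarded", {
  ref <- c(Wnt = 2, Notch = 0.5)
  expect_equal(relative_activity(c(Wnt = 2, Notch = 1), ref),
               c(Wnt = 1, Notch = 2))
  expect_equal(relative_activity(ref, ref), c(Wnt = 1, Notch = 1))
  expect_error(relative_activity(c(Hh = 1), ref), "lacks pathway")
  expect_error(relative_activity(c(Wnt = 1), c(Wnt = 0)), "positive")
})

test_that("digitization is strict at both thresholds across a fold grid", {
  folds <- c(0, 0.25, 0.4999, 0.5, 0.75, 1, 1.25, 1.5, 1.5001, 2, 10)
  states <- digitize_states(folds)
  expect_equal(unname(states),
               c(-1L, -1L, -1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(states %in% c(-1L, 0L, 1L)))
  # idempotent under monotone rescaling that fixes the thresholds
  rescale <- function(f) ifelse(f > 1.5, f * 2, ifelse(f < 0.5, f / 2, f))
  expect_identical(digitize_states(rescale(folds)), states)
  expect_error(digitize_states(c(-0.1, 1)), "non-negative")
  expect_error(digitize_states(1, up = 0.4, down = 0.5))
})

test_that("state correlations match the definitional formula and flag zero variance", {
  a <- c(1L, 0L, -1L)
  b <- c(1L, 1L, -1L)
  # brute-force sample Pearson through means and cross-products
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(state_correlation(a, b), r_hand)
  expect_equal(state_correlation(a, a), 1)
  expect_equal(state_correlation(a, -a), -1)
  expect_error(state_correlation(a, c(0L, 0L, 0L)), "zero variance")
  expect_error(state_correlation(a, b[1:2]), "length")

  # exhaustive over all non-constant ternary vectors of length 3
  grid <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  vecs <- as.matrix(grid[apply(grid, 1, function(v) var(v) > 0), ])
  for (i in seq_len(nrow(vecs))) {
    vi <- vecs[i, ]
    for (j in seq_len(nrow(vecs))) {
      vj <- vecs[j, ]
      expect_equal(state_correlation(vi, vj), cor(vi, vj))
    }
  }
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(13)
  states <- replicate(4, digitize_states(runif(9, 0, 3)))
  colnames(states) <- paste0("t", 1:4)
  cm <- state_correlation_matrix(states)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 4))
  flat <- cbind(states, t5 = rep(0L, 9))
  expect_warning(cm2 <- state_correlation_matrix(flat), "zero-variance")
  expect_true(all(is.na(cm2["t5", -5])))
  expect_equal(cm2[1:4, 1:4], cm)
})

test_that("concordance is inclusive at the cutoff", {
  expect_equal(flag_concordance(1), "same")
  expect_equal(flag_concordance(0.917), "same")
  expect_equal(flag_concordance(0.9169), "different")
  expect_equal(flag_concordance(0), "different")
  expect_error(flag_concordance(NA), "NA")
})

test_that("a synthetic reporter screen reproduces the concordance-grid structure", {
  set.seed(14)
  lines <- c("5637", "Biu87", "UM-UC-3", "H-bc")
  treatments <- c("none", "EH", "Ci", "Mi", "EH/Ci/Mi")
  readings <- simulate_reporter_panel(lines, treatments)
  expect_setequal(unique(readings$pathway), PATHWAYS)
  act <- reporter_activity(readings)
  expect_equal(nrow(act), 9 * length(lines) * length(treatments))

  # per cell line: digitized drug-response states vs the no-drug reference,
  # correlated between single drugs and the triple combination
  grid <- lapply(split(act, act$cell_line), function(d) {
    ref <- d[d$treatment == "none", ]
    ref_act <- setNames(ref$activity, ref$pathway)
    st <- vapply(setdiff(treatments, "none"), function(tr) {
      x <- d[d$treatment == tr, ]
      digitize_states(relative_activity(setNames(x$activity, x$pathway),
                                        ref_act))
    }, integer(9))
    state_correlation_matrix(st)
  })
  expect_length(grid, length(lines))
  for (cm in grid) {
    expect_equal(dim(cm), c(4, 4))
    ok <- !is.na(cm)
    expect_true(all(cm[ok] >= -1 & cm[ok] <= 1))
    calls <- flag_concordance(cm["EH/Ci/Mi", "EH"])
    expect_true(calls %in% c("same", "different"))
  }
  # planted activities recovered within noise: correlation of measured vs
  # true activity is high
  expect_gt(cor(act$activity, reporter_activity(
    transform(readings, firefly = firefly_negctrl +
                true_activity * renilla))$activity), 0.95)
})
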