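test_that("untreated wells survive fully and the Hill midpoint is 50%", {
  prof <- noiseless_profile(1)
  zero <- combination(Pi = 0, Pa = 0, EH = 0, Ci = 0, Ge = 0, Mi = 0,
                      panel = panel6)
  expect_equal(predict_survival(prof, zero), 100)
  single <- cell_line_profile(ec50 = c(A = 100), hill = c(A = 2.7),
                              emax = c(A = 1), noise_sd = 0)
  expect_equal(predict_survival(single, data.frame(A = 100)), 50)
  expect_error(predict_survival(single, data.frame(A = -1)), "negative dose")
})

test_that("two independent drugs compose as the exact Bliss product", {
  prof <- cell_line_profile(ec50 = c(A = 100, B = 10),
                            hill = c(A = 1, B = 2),
                            emax = c(A = 0.9, B = 0.8), noise_sd = 0)
  kA <- 0.9 * 50 / (100 + 50)
  kB <- 0.8 * 20^2 / (10^2 + 20^2)
  expect_equal(predict_survival(prof, data.frame(A = 50, B = 20)),
               100 * (1 - kA) * (1 - kB))
})

test_that("survival is monotone non-increasing per dose when independent", {
  set.seed(21)
  for (i in 1:5) {
    prof <- sample_profile(panel6, sample(c("sensitive", "moderate",
                                            "resistant", "benign"), 1),
                           noise_sd = 0)
    base <- random_combos(20)
    s0 <- predict_survival(prof, base)
    for (drug in panel6$drugs) {
      up <- base
      up[[drug]] <- vapply(up[[drug]], function(d) {
        lv <- panel6$dose_levels[[drug]]
        if (d >= max(lv)) d else min(lv[lv > d])
      }, numeric(1))
      expect_true(all(predict_survival(prof, up) <= s0 + 1e-12))
    }
    expect_true(all(s0 >= 0 & s0 <= 100))
  }
})

test_that("panel simulation is seeded, bounded and has replicate-mean noise", {
  set.seed(30)
  prof <- subpotent_profile(noise_sd = 3)
  combos <- data.frame(Pi = 0, Pa = 0, EH = 0,
                       Ci = rep(panel6$dose_levels$Ci[5], 1000),
                       Ge = 0, Mi = rep(panel6$dose_levels$Mi[5], 1000))
  truth <- predict_survival(prof, combos)[1]
  expect_gt(truth, 20)
  expect_lt(truth, 90)
  set.seed(33)
  vt <- simulate_panel(list(L = prof), combos, replicates = 3)
  expect_true(all(vt$survival >= 0 & vt$survival <= 120))
  # mean of 3 draws at sd 3: standard error 3/sqrt(3), away from truncation
  expect_equal(sd(vt$survival[, 1] - truth), 3 / sqrt(3), tolerance = 0.15)

  set.seed(33)
  vt2 <- simulate_panel(list(L = prof), combos, replicates = 3)
  expect_identical(vt$survival, vt2$survival)

  prof0 <- subpotent_profile(noise_sd = 0)
  v0 <- simulate_panel(list(L = prof0), combos[1:5, ], replicates = 2)
  expect_equal(v0$survival[, 1], predict_survival(prof0, combos[1:5, ]))
})

test_that("archetype draws separate resistant from sensitive potency", {
  set.seed(7)
  res <- replicate(100, sample_profile(panel6, "resistant")$ec50)
  sen <- replicate(100, sample_profile(panel6, "sensitive")$ec50)
  ratio <- apply(res, 1, median) / apply(sen, 1, median)
  expect_true(all(ratio >= 10))
  ben <- replicate(100, sample_profile(panel6, "benign")$emax)
  sen_e <- replicate(100, sample_profile(panel6, "sensitive")$emax)
  expect_gte(mean(colMeans(ben) <= colMeans(sen_e)), 0.95)
  set.seed(42)
  a <- sample_profile(panel6, "moderate")
  set.seed(42)
  b <- sample_profile(panel6, "moderate")
  expect_identical(a$ec50, b$ec50)
  expect_error(sample_profile(panel6, "weird"))
})

test_that("a synergistic tri-drug combination outkills 4x single agents", {
  gam <- pair_gamma("EH", "Ci", -0.5) + pair_gamma("Ci", "Mi", -0.5) +
    pair_gamma("EH", "Mi", -0.5)
  set.seed(8)
  profs <- lapply(1:5, function(i) {
    p <- sample_profile(panel6, "moderate", noise_sd = 0)
    cell_line_profile(p$ec50, p$hill, p$emax, interaction = gam,
                      noise_sd = 0, name = paste0("L", i))
  })
  tri <- combination(Pi = 0, Pa = 0, EH = 250, Ci = 1500, Ge = 0, Mi = 200,
                     panel = panel6)
  acs_tri <- mean(vapply(profs, predict_survival, numeric(1), combos = tri))
  for (drug in c("EH", "Ci", "Mi")) {
    mono <- combination(Pi = 0, Pa = 0, EH = 0, Ci = 0, Ge = 0, Mi = 0,
                        panel = panel6)
    mono[[drug]] <- 4 * tri[[drug]]
    acs_mono <- mean(vapply(profs, predict_survival, numeric(1),
                            combos = mono))
    expect_lt(acs_tri, acs_mono)
  }
})

test_that("profile construction enforces its parameter ranges", {
  expect_error(cell_line_profile(ec50 = c(A = -1), hill = c(A = 1),
                                 emax = c(A = 1)), "ec50 > 0")
  expect_error(cell_line_profile(ec50 = c(A = 1, B = 1),
                                 hill = c(A = 1, B = 1),
                                 emax = c(A = 1, B = 1),
                                 interaction = matrix(c(0, 2, 2, 0), 2,
                                   dimnames = list(c("A", "B"), c("A", "B")))),
               "<= 1")
  asym <- matrix(c(0, 0.1, -0.1, 0), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(cell_line_profile(ec50 = c(A = 1, B = 1),
                                 hill = c(A = 1, B = 1),
                                 emax = c(A = 1, B = 1),
                                 interaction = asym), "symmetric")
})
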