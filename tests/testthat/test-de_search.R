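test_that("initial populations are on-grid, seeded and uniform per drug", {
  cfg <- de_config(np = 20)
  set.seed(1)
  p1 <- init_population(panel6, cfg)
  set.seed(1)
  p2 <- init_population(panel6, cfg)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(20, 6))
  for (i in 1:20) {
    doses <- fscombo:::level_to_dose(p1[i, ], panel6)
    combo <- stats::setNames(as.data.frame(t(doses)), panel6$drugs)
    expect_length(validate_combination(combo, panel6), 0)
  }
  # frequencies over a large draw are uniform by chi-square
  big <- de_config(np = 10000)
  set.seed(2)
  pop <- init_population(panel6, big)
  for (j in 1:6) {
    expect_gt(chisq.test(table(factor(pop[, j], levels = 1:5)))$p.value,
              0.01)
  }
})

test_that("trial generation degenerates correctly at the F/CR extremes", {
  cfg1 <- de_config(np = 6, F = 0, cr = 1, stall_repair = 0)
  set.seed(3)
  pop <- init_population(panel6, cfg1)
  # F = 0, CR = 1: each trial is a pure copy of some population member
  set.seed(4)
  trials <- propose_candidates(pop, panel6, cfg1)
  keys <- apply(pop, 1, paste, collapse = "|")
  expect_true(all(apply(trials, 1, paste, collapse = "|") %in% keys))

  # CR = 0: a trial differs from its parent in at most the forced index
  cfg0 <- de_config(np = 6, F = 0.8, cr = 0, stall_repair = 0)
  set.seed(5)
  trials0 <- propose_candidates(pop, panel6, cfg0)
  expect_true(all(rowSums(trials0 != pop) <= 1))

  expect_error(propose_candidates(pop[1:3, ], panel6, cfg0), "np >= 4")
})

test_that("trial indices stay inside the level range after clamping", {
  cfg <- de_config(np = 20, F = 2)
  set.seed(6)
  pop <- init_population(panel6, cfg)
  for (za in c(FALSE, TRUE)) {
    for (i in 1:50) {
      tr <- propose_candidates(pop, panel6, cfg, zero_allowed = za)
      expect_true(all(tr >= if (za) 0 else 1) && all(tr <= 5))
    }
  }
})

test_that("greedy selection keeps parents on ties and propagates wins", {
  pop <- matrix(1L, 3, 2)
  trials <- matrix(2L, 3, 2)
  worse <- select_survivors(pop, c(1, 2, 3), trials, c(5, 5, 5))
  expect_identical(worse$pop, pop)
  better <- select_survivors(pop, c(5, 5, 5), trials, c(1, 2, 3))
  expect_identical(better$pop, trials)
  tie <- select_survivors(pop, c(2, 2, 2), trials, c(2, 2, 2))
  expect_identical(tie$pop, pop)
  expect_error(select_survivors(pop, c(1, 2), trials, c(1, 2, 3)),
               "mismatch")
})

test_that("a flat landscape leaves the best score at the constant value", {
  flat <- function(combos) matrix(50, nrow(combos), 2)
  tr <- run_fsc_loop(flat, panel6, de_config(np = 8, rounds = 3,
                                             batch_multiplier = c(1, 1),
                                             divisor = 2), seed = 1)
  expect_true(all(tr$rounds$best_acs == 50))
})

test_that("the loop is elitist, budget-bounded, cached and seed-stable", {
  set.seed(10)
  profs <- list(A = sample_profile(panel6, "sensitive", noise_sd = 3),
                B = sample_profile(panel6, "resistant", noise_sd = 3))
  oracle <- panel_oracle(profs, replicates = 3)
  cfg <- de_config(np = 12, rounds = 5, batch_multiplier = rep(1, 4),
                   divisor = 2)
  tr <- run_fsc_loop(oracle, panel6, cfg, seed = 7)
  expect_true(all(diff(tr$rounds$best_acs) <= 1e-12))
  expect_lte(max(tr$rounds$n_evaluated), 12 * 5)
  expect_equal(nrow(tr$evaluated), max(tr$rounds$n_evaluated))
  expect_false(any(duplicated(tr$evaluated[panel6$drugs])))
  expect_equal(tr$best$acs, min(tr$evaluated$acs))

  tr2 <- run_fsc_loop(panel_oracle(profs, replicates = 3), panel6, cfg,
                      seed = 7)
  expect_identical(tr$rounds, tr2$rounds)
  expect_identical(tr$evaluated, tr2$evaluated)
})

test_that("the default four-round screen stays under 1% of the design space", {
  set.seed(11)
  profs <- lapply(1:8, function(i) sample_profile(panel6, "moderate",
                                                  noise_sd = 3))
  names(profs) <- paste0("L", 1:8)
  tr <- run_fsc_loop(panel_oracle(profs), panel6, de_config(), seed = 3)
  expect_lte(max(tr$rounds$n_evaluated), 100)
  expect_lt(max(tr$rounds$frac_space), 0.01)
  expect_equal(nrow(tr$rounds), 4)
})

test_that("the zero-dose option only enters from its scheduled round", {
  set.seed(12)
  prof <- sample_profile(panel6, "moderate", noise_sd = 0)
  tr <- run_fsc_loop(panel_oracle(list(L = prof), replicates = 1), panel6,
                     de_config(np = 10, rounds = 4,
                               batch_multiplier = rep(1, 3),
                               zero_from_round = 3, divisor = 1), seed = 5)
  # all distinct evaluations from rounds 1-2 are zero-free
  n12 <- tr$rounds$n_evaluated[2]
  ev <- tr$evaluated[panel6$drugs]
  expect_gte(sum(apply(ev, 1, function(z) all(z > 0))), n12)
})

test_that("a budgeted search recovers the planted optimum on monotone surfaces", {
  top <- vapply(panel6$dose_levels, max, numeric(1))
  hits <- vapply(1:6, function(seed) {
    set.seed(seed + 1000)
    prof <- sample_profile(panel6, "moderate", noise_sd = 0)
    cfg <- de_config(np = 10, F = 0.8, cr = 0.3, rounds = 300,
                     batch_multiplier = rep(1, 299), zero_from_round = Inf,
                     divisor = 1, max_evaluations = 200, stall_repair = 0.2)
    tr <- run_fsc_loop(panel_oracle(list(L = prof), replicates = 1),
                       panel6, cfg, seed = seed)
    expect_lte(max(tr$rounds$n_evaluated), 200)
    all(tr$best$doses == top)
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("budgeted searches land in the exhaustive top 0.5% on additive surfaces", {
  ranks <- vapply(1:30, function(run) {
    set.seed(run + 500)
    tabs <- lapply(1:6, function(j) sort(runif(5, 0, 100 / 6),
                                         decreasing = TRUE))
    oracle <- function(combos) {
      lv <- mapply(function(d, levs) match(d, levs), combos,
                   panel6$dose_levels)
      lv <- matrix(lv, nrow = nrow(combos))
      s <- mapply(function(j) tabs[[j]][lv[, j]], 1:6)
      if (is.null(dim(s))) s <- matrix(s, nrow = 1)
      matrix(rowSums(s), ncol = 1)
    }
    cfg <- de_config(np = 10, F = 0.8, cr = 0.3, rounds = 300,
                     batch_multiplier = rep(1, 299), zero_from_round = Inf,
                     divisor = 1, max_evaluations = 200, stall_repair = 0.2)
    tr <- run_fsc_loop(oracle, panel6, cfg, seed = run)
    vals <- 0
    for (j in 1:6) vals <- outer(vals, tabs[[j]], "+")
    sum(sort(as.vector(vals)) < tr$best$acs - 1e-12) + 1
  }, numeric(1))
  expect_true(all(ranks <= ceiling(0.005 * 15625)))
})
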