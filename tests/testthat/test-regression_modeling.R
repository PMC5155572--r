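test_that("the quadratic design has the full term set in canonical order", {
  dm <- build_design_matrix(random_combos(10))
  expect_equal(ncol(dm$X), 1 + 6 + 6 + 15)
  expect_equal(dm$terms$type,
               c("intercept", rep("linear", 6), rep("quadratic", 6),
                 rep("bilinear", 15)))

  zero <- build_design_matrix(data.frame(Pi = 0, Pa = 0, EH = 0, Ci = 0,
                                         Ge = 0, Mi = 0))
  expect_equal(unname(zero$X[1, ]), c(1, rep(0, 27)))

  two <- build_design_matrix(data.frame(a = 2, b = 3))
  expect_equal(unname(two$X[1, ]), c(1, 2, 3, 4, 9, 6))
  expect_equal(colnames(two$X),
               c("(Intercept)", "a", "b", "a^2", "b^2", "a:b"))
})

test_that("noiseless coefficients are recovered to numerical precision", {
  set.seed(1)
  combos <- random_combos(100)
  dm <- build_design_matrix(combos)
  beta <- rnorm(28)
  y <- as.vector(dm$X %*% beta)
  m <- fit_polynomial(dm, y)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
})

test_that("R-squared and the F-test agree with brute-force recomputation", {
  set.seed(2)
  combos <- random_combos(80)
  dm <- build_design_matrix(combos)
  y <- 40 - 0.02 * combos$Ci + rnorm(80, 0, 5)
  m <- fit_polynomial(dm, y)
  # independent residual-sum route through the reported coefficients
  pred <- as.vector(dm$X[, names(m$coefficients)] %*% m$coefficients)
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(m$r_squared, 1 - rss / tss, tolerance = 1e-8)
  # and against stats::lm on the same columns
  lmfit <- lm(y ~ ., data = as.data.frame(dm$X[, -1]))
  expect_equal(m$r_squared, summary(lmfit)$r.squared, tolerance = 1e-8)
  fstat <- summary(lmfit)$fstatistic
  expect_equal(m$p_value,
               pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate regression inputs are refused with guidance", {
  combos <- random_combos(30)
  expect_error(fit_polynomial(combos, rep(1, 30)), "degenerate response")
  expect_error(fit_polynomial(combos[1:10, ], rnorm(10)), "simplify")
  expect_error(fit_polynomial(combos, rnorm(29)), "length mismatch")
})

test_that("the fit is invariant to combination row order", {
  set.seed(3)
  combos <- random_combos(60)
  y <- 30 - 0.01 * combos$Ci - 0.0001 * combos$Ci * combos$Mi +
    rnorm(60, 0, 2)
  m1 <- fit_polynomial(combos, y)
  perm <- sample(60)
  m2 <- fit_polynomial(combos[perm, ], y[perm])
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
  expect_equal(m1$r_squared, m2$r_squared, tolerance = 1e-10)
})

test_that("stepwise simplification recovers planted support", {
  set.seed(4)
  combos <- random_combos(150)
  dm <- build_design_matrix(combos)
  y0 <- 5 + 2 * combos$Pi - 0.003 * combos$Pi * combos$Pa

  # noiseless: exactly the planted terms (hierarchy off) or their closure
  exact <- simplify_model(fit_polynomial(dm, y0 + rnorm(150, 0, 1e-8)),
                          hierarchy = FALSE)
  expect_setequal(exact$retained, c("Pi", "Pi:Pa"))
  closed <- simplify_model(fit_polynomial(dm, y0 + rnorm(150, 0, 1e-8)))
  expect_setequal(closed$retained, c("Pi", "Pa", "Pi:Pa"))

  # noisy, selection-consistent penalty: planted support, no intruders
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    cmb <- random_combos(150)
    yy <- 5 + 2 * cmb$Pi - 0.003 * cmb$Pi * cmb$Pa + rnorm(150, 0, 0.5)
    r <- simplify_model(fit_polynomial(cmb, yy), penalty = 10)$retained
    vars <- unique(unlist(strsplit(gsub("\\^2", "", r), ":", fixed = TRUE)))
    all(c("Pi", "Pi:Pa") %in% r) && !length(setdiff(vars, c("Pi", "Pa")))
  }, logical(1))
  expect_gte(sum(hits), 18)

  # an infinite penalty collapses to the intercept-only model
  inf <- simplify_model(fit_polynomial(dm, y0 + rnorm(150)), penalty = Inf)
  expect_length(inf$retained, 0)
})

test_that("hierarchy keeps parents of retained children, off matches step()", {
  set.seed(5)
  combos <- random_combos(120)[c("Pi", "Pa", "EH")]
  y <- 10 + 0.5 * combos$Pi * combos$Pa + 0.2 * combos$EH + rnorm(120, 0, 3)
  on <- simplify_model(fit_polynomial(combos, y))
  terms_on <- on$design$terms
  for (lab in on$retained) {
    expect_true(all(fscombo:::term_parents(terms_on, lab) %in% on$retained))
  }
  # independent route: stats::step over the same term set, hierarchy off
  off <- simplify_model(fit_polynomial(combos, y), hierarchy = FALSE)
  D <- as.data.frame(build_design_matrix(combos)$X[, -1])
  names(D) <- make.names(names(D))
  ref <- step(lm(y ~ ., data = cbind(y = y, D)), direction = "both",
              trace = 0)
  ref_terms <- attr(terms(ref), "term.labels")
  ours <- make.names(off$retained)
  expect_setequal(ours, ref_terms)
})

test_that("interaction calls follow retained bilinear signs", {
  set.seed(6)
  combos <- random_combos(100)
  dm <- build_design_matrix(combos)
  beta <- setNames(rep(0, 28), colnames(dm$X))
  beta["(Intercept)"] <- 50
  beta["Ge"] <- -0.9
  beta["Ge^2"] <- 0.08
  beta["Ci"] <- -0.01
  beta["Ge:Mi"] <- 0.004
  beta["Ci:Mi"] <- -0.002
  y <- as.vector(dm$X %*% beta) + rnorm(100, 0, 0.01)
  rep <- interpret_interactions(fit_polynomial(dm, y))
  pairs <- rep$pairs
  call_of <- function(a, b) pairs$call[pairs$drug_a == a & pairs$drug_b == b]
  expect_equal(call_of("Ge", "Mi"), "antagonistic")
  expect_equal(call_of("Ci", "Mi"), "synergistic")
  # negative linear slope + dominant positive curvature + dominant positive
  # pair coefficient: the drug is flagged and recommended for elimination
  expect_true(rep$diminishing_returns[["Ge"]])
  expect_equal(rep$eliminate, "Ge")
})

test_that("dropped interaction terms yield 'none' calls and no eliminations", {
  set.seed(7)
  combos <- random_combos(90)
  y <- 60 - 0.03 * combos$Ci + rnorm(90, 0, 1)
  m <- simplify_model(fit_polynomial(combos, y), penalty = 10)
  rep <- interpret_interactions(m)
  expect_true(all(rep$pairs$call == "none"))
  expect_length(rep$eliminate, 0)
})
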