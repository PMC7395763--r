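# Rule grammar: parsing, formatting, evaluation, context construction.

test_that("behavioural and environmental statements parse to typed rules", {
  r <- parseRule("R1: P -> P + P, 0.44")
  expect_s4_class(r, "BehaviouralRule")
  expect_equal(r@ruleId, "R1")
  expect_equal(r@sourceType, "P")
  expect_equal(r@productType, "P")
  expect_equal(r@extraProduct, "P")
  expect_equal(evaluateProbability(r, ruleContext()), 0.44)

  e <- parseRule("E1: P -> U, environment (Glc)")
  expect_s4_class(e, "EnvironmentalRule")
  expect_true(e@amountIsReference)
  expect_equal(e@tag, "Glc")

  e2 <- parseRule("E2: Q -> 1.5e-12, environment (O2)")
  expect_false(e2@amountIsReference)
  expect_equal(e2@amount, 1.5e-12)

  m <- parseRule("mig: P -> empty + P, 0.01")
  expect_equal(m@productType, "empty")
})

test_that("malformed statements and unknown identifiers are rejected", {
  expect_error(parseRule("R2: P -> , 0.2"), "product term")
  expect_error(parseRule("P -> P, 0.2"), "missing ':'")
  expect_error(parseRule("R3: P -> P"), "missing ','")
  expect_error(parseRule("R4: P -> P, environment (Foo)"), "unknown environment tag")
  expect_error(parseRule("R5: P -> P, 0.2 * Bogus"), "unknown context variable")
  expect_error(parseRule("R6: P -> P + Q + D, 0.2"), "at most two")
  expect_error(parseRule("R7: X -> P, 0.2", cellTypes = c("P", "Q")),
               "unknown cell type 'X'")
  expect_error(parseRule("R8: P -> P, sqrt(Glc)"), "not allowed")
  expect_error(parseRule("E3: P -> -2, environment (Glc)"), "non-negative")
})

test_that("formatting a parsed rule and re-parsing round-trips", {
  lines <- c("R1: P -> P + P, 0.44",
             "q: P -> Q, 0.15 * (1 - Glc)",
             "mig: P -> empty + P, 0.01",
             "deg: D -> empty, 0.44",
             "cx: Q -> P, min(Glc, O2) * exp(-TIME) + 0.5 * #P",
             "E1: P -> U, environment (Glc)",
             "E2: Q -> 3.2e-15, environment (O2)",
             "E3: P -> U, environment (YM)")
  for (ln in lines) {
    r1 <- parseRule(ln)
    r2 <- parseRule(formatRule(r1))
    expect_equal(r2, r1, info = ln)
  }
})

test_that("probability evaluation clamps into [0,1] and is pure", {
  expect_equal(evaluateProbability(parseRule("r: P -> Q, 0.38"), ruleContext()),
               0.38)
  expect_equal(evaluateProbability(parseRule("r: P -> Q, Glc"),
                                   ruleContext(glc = 0.5)), 0.5)
  expect_equal(evaluateProbability(parseRule("r: P -> Q, 2.0 * O2"),
                                   ruleContext(o2 = 0.8)), 1.0)
  expect_equal(evaluateProbability(parseRule("r: P -> Q, Glc - 2"),
                                   ruleContext(glc = 0.5)), 0)
  ctx <- ruleContext(glc = 0.3)
  p1 <- evaluateProbability(parseRule("r: P -> Q, Glc"), ctx)
  p2 <- evaluateProbability(parseRule("r: P -> Q, Glc"), ctx)
  expect_identical(p1, p2)
})

test_that("evaluation errors carry the rule id", {
  r <- parseRule("bad: P -> Q, 1 / TIME")
  expect_error(evaluateProbability(r, ruleContext(time = 0)), "bad")
  r2 <- parseRule("needs_count: P -> Q, #P")
  expect_error(evaluateProbability(r2, ruleContext()), "#P")
})

test_that("random expressions always evaluate inside [0,1]", {
  set.seed(421)
  vars <- c("TIME", "Glc", "O2", "AGE", "TLD", "YM")
  for (i in 1:60) {
    a <- sample(vars, 1); b <- sample(vars, 1)
    expr <- sprintf("%.3f * %s %s %.3f * %s", runif(1, -3, 3), a,
                    sample(c("+", "-", "*"), 1), runif(1, -3, 3), b)
    r <- parseRule(sprintf("r%d: P -> Q, %s", i, expr))
    ctx <- ruleContext(time = runif(1), glc = runif(1, 0, 2), o2 = runif(1, 0, 2),
                       age = runif(1), tld = runif(1), ym = runif(1, 1, 3))
    p <- evaluateProbability(r, ctx)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("context variables follow the normalisation conventions", {
  cfg <- tinyConfig()
  st <- createState(cfg)
  st <- seedUniform(st, 3, c(P = 1), seed = 5)
  ctx <- buildContext(1L, st, iteration = 120, totalIterations = 240)
  expect_equal(ctx@time, 0.5)
  expect_equal(ctx@glc, 1.0)   # untouched scaffold
  expect_equal(ctx@o2, 1.0)
  expect_equal(ctx@ym, 1.0)
  expect_equal(ctx@age, 1.0)   # born at iteration 0, current 120
  expect_equal(ctx@td, 0)      # living cell

  # a cell born at iteration 100 observed at 200
  st2 <- st
  st2@cells$birth[1] <- 100L
  ctx2 <- buildContext(1L, st2, 200, 240)
  expect_equal(ctx2@age, 0.5)

  expect_warning(buildContext(1L, st, 0, 240), "iteration 0")
  expect_error(buildContext(999L, st, 10, 240), "not registered")
  expect_equal(sum(ctx@typeCounts), 3 / 125)
})
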