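demoContrib <- function() normalizeContributions(exampleExpression())

test_that("the three canonical slider selections each pick one gene", {
  cm <- demoContrib()
  # brain-specific: >= 80% from brain
  expect_identical(
    selectedIds(applyPanel(cm, ConstraintPanel("t",
      list(brain = c(80, 100))))), "g1")
  # blood- and heart-balanced: both in [30%, 45%]
  expect_identical(
    selectedIds(applyPanel(cm, ConstraintPanel("t",
      list(blood = c(30, 45), heart = c(30, 45))))), "g2")
  # liver-specific and silent in brain: brain [0,0], liver >= 50%
  expect_identical(
    selectedIds(applyPanel(cm, ConstraintPanel("t",
      list(brain = c(0, 0), liver = c(50, 100))))), "g3")
})

test_that("default sliders are vacuous; disabled panels select everything", {
  cm <- demoContrib()
  allDefault <- ConstraintPanel("t", list(brain = c(0, 100)))
  expect_identical(selectedIds(applyPanel(cm, allDefault)),
                   c("g1", "g2", "g3"))
  restrictive <- ConstraintPanel("t", list(brain = c(99, 100)),
                                 enabled = FALSE)
  expect_identical(selectedIds(applyPanel(cm, restrictive)),
                   c("g1", "g2", "g3"))
})

test_that("zero-sum features are excluded only under non-default constraints", {
  m <- rbind(g1 = c(10, 90), gz = c(0, 0))
  colnames(m) <- c("a", "b")
  cm <- normalizeContributions(ExpressionMatrix(m))
  # all defaults: the zero-sum feature rides along
  expect_identical(
    selectedIds(applyPanel(cm, ConstraintPanel("p", list(a = c(0, 100))))),
    c("g1", "gz"))
  # any non-default constraint: excluded, even one its zeros would satisfy
  expect_identical(
    selectedIds(applyPanel(cm, ConstraintPanel("p", list(a = c(0, 50))))),
    "g1")
})

test_that("exclusion at [0,0] selects exactly features with no activity in the facet", {
  m <- rbind(g1 = c(0, 50, 50), g2 = c(1e-7, 50, 50), g3 = c(30, 40, 30))
  colnames(m) <- c("brain", "heart", "liver")
  cm <- normalizeContributions(ExpressionMatrix(m))
  sel <- selectedIds(applyPanel(cm, ConstraintPanel("p",
    list(brain = c(0, 0)))))
  # g2's brain contribution is ~1e-7 % > 1e-9 tolerance: not exact zero
  expect_identical(sel, "g1")
})

test_that("constraints on unknown facets raise a config error naming the facet", {
  cm <- demoContrib()
  expect_error(applyPanel(cm, ConstraintPanel("t", list(kidney = c(10, 20)))),
               class = "configError")
  expect_error(applyPanel(cm, ConstraintPanel("t", list(kidney = c(10, 20)))),
               "kidney")
  expect_error(SliderConstraint("brain", 50, 20), class = "configError")
})

test_that("AND intersects and OR unites per-panel selections; disabled panels are vacuous", {
  # two panels over the same features, built to select {g1,g2} and {g2,g3}
  mA <- rbind(g1 = c(90, 10), g2 = c(85, 15), g3 = c(10, 90))
  colnames(mA) <- c("x", "y")
  mB <- rbind(g1 = c(10, 90), g2 = c(80, 20), g3 = c(95, 5))
  colnames(mB) <- c("u", "v")
  cms <- list(A = normalizeContributions(ExpressionMatrix(mA)),
              B = normalizeContributions(ExpressionMatrix(mB)))
  pA <- ConstraintPanel("A", list(x = c(80, 100)))
  pB <- ConstraintPanel("B", list(u = c(75, 100)))
  expect_identical(selectedIds(selectFeatures(cms,
    ConstraintSet(list(pA, pB), "AND"))), "g2")
  expect_identical(selectedIds(selectFeatures(cms,
    ConstraintSet(list(pA, pB), "OR"))), c("g1", "g2", "g3"))
  pBoff <- ConstraintPanel("B", list(u = c(75, 100)), enabled = FALSE)
  expect_identical(selectedIds(selectFeatures(cms,
    ConstraintSet(list(pA, pBoff), "AND"))), c("g1", "g2"))
  # zero enabled panels: everything
  expect_identical(selectedIds(selectFeatures(cms,
    ConstraintSet(list(
      ConstraintPanel("A", enabled = FALSE),
      ConstraintPanel("B", enabled = FALSE)), "AND"))),
    c("g1", "g2", "g3"))
})

test_that("panels with differing feature universes select on the intersection with a warning", {
  mA <- rbind(g1 = c(90, 10), g2 = c(85, 15))
  colnames(mA) <- c("x", "y")
  mB <- rbind(g2 = c(80, 20), g3 = c(95, 5))
  colnames(mB) <- c("u", "v")
  cms <- list(A = normalizeContributions(ExpressionMatrix(mA)),
              B = normalizeContributions(ExpressionMatrix(mB)))
  cset <- ConstraintSet(list(ConstraintPanel("A", list(x = c(0, 100))),
                             ConstraintPanel("B", list(u = c(0, 100)))),
                        "OR")
  expect_warning(res <- selectFeatures(cms, cset),
                 "symmetric difference: 2")
  expect_identical(selectedIds(res), "g2")
})

test_that("select matches the brute-force oracle on random matrices and constraint sets", {
  set.seed(101)
  for (rep in 1:120) {
    em <- randomExpression(sample(10:200, 1), sample(3:20, 1))
    cm <- normalizeContributions(em)
    cts <- randomConstraints(colnames(em))
    panel <- ConstraintPanel("p", lapply(cts, identity))
    got <- selectedIds(applyPanel(cm, panel))
    want <- oraclePanelSelect(contributions(cm), definedMask(cm), cts)
    expect_identical(got, want)
  }
})

test_that("multi-panel AND/OR selection matches the brute-force oracle", {
  set.seed(102)
  for (rep in 1:60) {
    em <- randomExpression(sample(10:100, 1), sample(3:12, 1))
    cm <- normalizeContributions(em)
    pc <- list(P1 = randomConstraints(colnames(em)),
               P2 = randomConstraints(colnames(em)))
    enabled <- c(P1 = stats::runif(1) < 0.8, P2 = stats::runif(1) < 0.8)
    combiner <- sample(c("AND", "OR"), 1)
    cset <- ConstraintSet(list(
      ConstraintPanel("P1", pc$P1, enabled = enabled[["P1"]]),
      ConstraintPanel("P2", pc$P2, enabled = enabled[["P2"]])), combiner)
    got <- selectedIds(selectFeatures(list(P1 = cm, P2 = cm), cset))
    want <- oracleSelect(contributions(cm), definedMask(cm), pc, enabled,
                         combiner)
    expect_identical(got, want)
    expect_identical(countSelected(list(P1 = cm, P2 = cm), cset),
                     length(want))
  }
})

test_that("tightening a constraint never grows the selection (monotonicity)", {
  set.seed(103)
  for (rep in 1:100) {
    em <- randomExpression(sample(10:100, 1), sample(3:10, 1))
    cm <- normalizeContributions(em)
    cts <- randomConstraints(colnames(em))
    base <- selectedIds(applyPanel(cm, ConstraintPanel("p", cts)))
    # tighten one constraint: raise its min or lower its max
    i <- sample(length(cts), 1L)
    b <- cts[[i]]
    if (stats::runif(1) < 0.5)
      b[1] <- min(stats::runif(1, b[1], 100), b[2])
    else
      b[2] <- max(stats::runif(1, 0, b[2]), b[1])
    cts[[i]] <- b
    tight <- selectedIds(applyPanel(cm, ConstraintPanel("p", cts)))
    expect_true(all(tight %in% base))
  }
})

test_that("AND-selection is contained in each panel, each panel in OR-selection", {
  set.seed(104)
  for (rep in 1:100) {
    em <- randomExpression(sample(10:100, 1), sample(3:10, 1))
    cm <- normalizeContributions(em)
    p1 <- ConstraintPanel("P1", randomConstraints(colnames(em)))
    p2 <- ConstraintPanel("P2", randomConstraints(colnames(em)))
    cms <- list(P1 = cm, P2 = cm)
    andSel <- selectedIds(selectFeatures(cms, ConstraintSet(list(p1, p2), "AND")))
    orSel <- selectedIds(selectFeatures(cms, ConstraintSet(list(p1, p2), "OR")))
    s1 <- selectedIds(applyPanel(cm, p1))
    s2 <- selectedIds(applyPanel(cm, p2))
    expect_true(all(andSel %in% s1) && all(andSel %in% s2))
    expect_true(all(s1 %in% orSel) && all(s2 %in% orSel))
  }
})

test_that("countSelected equals the size of the materialized selection", {
  set.seed(105)
  cm <- normalizeContributions(randomExpression(80, 8))
  for (rep in 1:30) {
    cset <- ConstraintSet(ConstraintPanel("p",
      randomConstraints(colnames(cm))))
    expect_identical(countSelected(list(p = cm), cset),
                     selectedCount(selectFeatures(list(p = cm), cset)))
  }
})

test_that("ordinal constraints select by the staining scale; missing levels fail", {
  lv <- rbind(g1 = c(liver = "High", brain = "None"),
              g2 = c(liver = "Low", brain = "Medium"),
              g3 = c(liver = NA, brain = "High"))
  expect_identical(
    selectedIds(applyOrdinal(lv, OrdinalConstraint("liver", "Medium", "High"))),
    "g1")
  # exclusion on the ordinal scale
  expect_identical(
    selectedIds(applyOrdinal(lv, OrdinalConstraint("liver", "None", "None"))),
    character(0))
  # vacuous interval still rejects missing annotation
  expect_identical(
    selectedIds(applyOrdinal(lv, OrdinalConstraint("liver", "None", "High"))),
    c("g1", "g2"))
  # no constraints: everything passes
  expect_identical(selectedIds(applyOrdinal(lv)), c("g1", "g2", "g3"))
  # unknown level labels are a parse error
  bad <- lv; bad[1, 1] <- "Strong"
  expect_error(applyOrdinal(bad, OrdinalConstraint("liver")),
               class = "parseError")
  expect_error(OrdinalConstraint("liver", "High", "Low"),
               class = "configError")
})

test_that("dual RNA + protein selection is the conjunction on shared genes", {
  m <- rbind(g1 = c(liver = 80, brain = 20),
             g2 = c(liver = 90, brain = 10),
             g3 = c(liver = 10, brain = 90))
  cm <- normalizeContributions(ExpressionMatrix(m))
  lv <- rbind(g1 = c(liver = "None"), g2 = c(liver = "High"),
              g4 = c(liver = "High"))
  rnaCset <- ConstraintSet(ConstraintPanel("rna", list(liver = c(50, 100))))
  res <- selectDual(cm, rnaCset, lv,
                    list(OrdinalConstraint("liver", "Low", "High")))
  # g1 passes RNA but fails protein (None); g2 passes both; g3 fails RNA;
  # g4 is not shared
  expect_identical(selectedIds(res), "g2")
  # no protein constraints: RNA-only selection restricted to shared genes
  res2 <- selectDual(cm, rnaCset, lv)
  expect_identical(selectedIds(res2), c("g1", "g2"))
  # empty identifier intersection is a data error
  lvOther <- rbind(x1 = c(liver = "High"))
  expect_error(selectDual(cm, rnaCset, lvOther), class = "dataError")
})

test_that("constraint sets round-trip through the JSON config with defaults omitted", {
  cset <- ConstraintSet(list(
    ConstraintPanel("cells", list(neutrophil = c(20, 100),
                                  t_cell = c(0, 5),
                                  monocyte = c(0, 100))),   # default: dropped
    ConstraintPanel("tissues", list(blood = c(15, 100)), enabled = FALSE)),
    combiner = "AND")
  js <- writeConstraintSet(cset)
  expect_false(grepl("monocyte", js))
  back <- readConstraintSet(js)
  expect_identical(back@combiner, "AND")
  expect_identical(length(back@panels), 2L)
  expect_false(back@panels[[2]]@enabled)
  cts <- back@panels[[1]]@constraints
  got <- stats::setNames(lapply(cts, function(ct) c(ct@minPct, ct@maxPct)),
                         vapply(cts, function(ct) ct@facetId, character(1)))
  expect_equal(got$neutrophil, c(20, 100))
  expect_equal(got$t_cell, c(0, 5))
  # file round-trip too
  f <- tempfile(fileext = ".json")
  writeConstraintSet(cset, f)
  expect_identical(writeConstraintSet(readConstraintSet(f)), js)
})
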