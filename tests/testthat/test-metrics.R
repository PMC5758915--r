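test_that("sensitivity and PPV handle slips and empty structures", {
  s <- parseDotBracket("(((....)))..")
  r <- sensitivityPPV(s, s)
  expect_identical(c(r$sensitivity, r$ppv, r$geometric_mean), c(1, 1, 1))

  ## one-position register slip: (2,9) matches reference (1,9) with slip on
  pred <- secondaryStructure(10L, cbind(2L, 9L))
  ref <- secondaryStructure(10L, cbind(1L, 9L))
  on_ <- sensitivityPPV(pred, ref, slip = TRUE)
  off <- sensitivityPPV(pred, ref, slip = FALSE)
  expect_identical(c(on_$sensitivity, on_$ppv), c(1, 1))
  expect_identical(c(off$sensitivity, off$ppv), c(0, 0))

  ## empty prediction: sensitivity 0, PPV undefined
  none <- secondaryStructure(10L)
  r2 <- sensitivityPPV(none, ref)
  expect_identical(r2$sensitivity, 0)
  expect_true(is.na(r2$ppv))
  ## empty reference: sensitivity undefined
  r3 <- sensitivityPPV(ref, none)
  expect_true(is.na(r3$sensitivity))

  ## greedy matching: one predicted pair satisfies at most one reference
  ref2 <- secondaryStructure(12L, cbind(c(1L, 2L), c(10L, 9L)))
  pred2 <- secondaryStructure(12L, cbind(2L, 10L))  # slips onto both
  r4 <- sensitivityPPV(pred2, ref2, slip = TRUE)
  expect_equal(r4$sensitivity, 0.5)
  expect_equal(r4$ppv, 1)
})

test_that("slip-on scores never fall below slip-off scores", {
  set.seed(64)
  for (rep_ in 1:15) {
    n <- sample(10:20, 1L)
    a <- randomStructure(n)
    b <- randomStructure(n)
    on_ <- sensitivityPPV(a, b, slip = TRUE)
    off <- sensitivityPPV(a, b, slip = FALSE)
    if (!is.na(on_$sensitivity))
      expect_gte(on_$sensitivity, off$sensitivity)
    if (!is.na(on_$ppv)) expect_gte(on_$ppv, off$ppv)
  }
})

test_that("population free-energy gaps match hand evaluation", {
  consts <- thermoConstants(T = 310)
  ## the worked two-state number: 94/6 versus 70/30 is ~1.2 kcal/mol
  expect_equal(populationDDG(c(0.94, 0.06), c(0.70, 0.30), consts), 1.2,
               tolerance = 0.03)
  expect_identical(populationDDG(c(0.7, 0.3), c(0.7, 0.3), consts), 0)
  expect_equal(populationDDG(c(0.5, 0.5), c(0.70, 0.30), consts),
               consts@kT * log(7 / 3), tolerance = 1e-12)
  ## symmetry
  expect_equal(populationDDG(c(0.9, 0.1), c(0.6, 0.4), consts),
               populationDDG(c(0.6, 0.4), c(0.9, 0.1), consts))
  expect_error(populationDDG(c(1, 0), c(0.5, 0.5), consts), "degenerate")
})

test_that("reactivity RMSD respects masks", {
  expect_identical(reactivityRMSD(reactivityProfile(c(0, 1)),
                                  reactivityProfile(c(0, 1))), 0)
  expect_equal(reactivityRMSD(reactivityProfile(c(0.5, 1.5)),
                              reactivityProfile(c(0, 1))), 0.5)
  expect_equal(reactivityRMSD(reactivityProfile(c(0, 1)),
                              reactivityProfile(c(1, 0))), 1)
  ## masked positions are excluded
  expect_equal(reactivityRMSD(reactivityProfile(c(NA, 1)),
                              reactivityProfile(c(99, 1))), 0)
  expect_error(reactivityRMSD(reactivityProfile(c(NA, NA)),
                              reactivityProfile(c(1, 2))), "no overlapping")
})

test_that("the default calibration grid spans 225 combinations", {
  g <- calibrationGrid()
  expect_identical(nrow(g), 225L)
  expect_equal(range(g$C), c(0.1, 1.5))
  expect_equal(range(g$Offset), c(0.1, 1.5))
  expect_identical(length(unique(g$C)), 15L)
})

test_that("grid search scores a small dataset and breaks ties as stated", {
  fx <- bistableExample()
  mixA <- list(list(structure = fx$structures$A, population = 1))
  dataset <- list(list(seq = fx$seq,
                       rexp = simulateShape(mixA, seed = 21L),
                       reference = fx$structures$A))
  fit <- gridSearch(dataset, Cvalues = c(0.3, 0.6),
                    OffsetValues = c(0.8, 1.1),
                    sampleSize = 400L, seed = 2L)
  expect_identical(nrow(fit$surface), 4L)
  expect_true(all(fit$surface$score >= 0 & fit$surface$score <= 1))
  ## single-conformation truth: every grid point recovers it here, and the
  ## tie-break must then report the smallest C, then smallest Offset
  if (all(fit$surface$score == fit$surface$score[1])) {
    expect_identical(fit$C, 0.3)
    expect_identical(fit$Offset, 0.8)
  }
  ## surface invariant to dataset order (single entry duplicated)
  fit2 <- gridSearch(rev(dataset), Cvalues = c(0.3, 0.6),
                     OffsetValues = c(0.8, 1.1),
                     sampleSize = 400L, seed = 2L)
  expect_equal(fit$surface$score, fit2$surface$score)
})

test_that("jackknife reports one optimum per left-out entry", {
  fx <- bistableExample()
  mixA <- list(list(structure = fx$structures$A, population = 1))
  entry <- list(seq = fx$seq, rexp = simulateShape(mixA, seed = 31L),
                reference = fx$structures$A)
  dataset <- list(entry, entry, entry)  # identical copies
  jk <- jackknifeCalibration(dataset, Cvalues = c(0.4, 0.6),
                             OffsetValues = 1.1,
                             sampleSize = 300L, seed = 3L)
  expect_identical(nrow(jk$leaveOneOut), 3L)
  ## identical copies: every subset reproduces the full-data optimum
  expect_identical(jk$stability, 1)
})
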