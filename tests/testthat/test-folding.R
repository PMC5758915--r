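test_that("a sequence with no allowed pair gives an empty ensemble", {
  pf <- partitionFunction("AAAAAA")
  expect_true(all(pairProbs(pf$probs) == 0))
  expect_identical(pf$freeEnergy, 0)
  ens <- stochasticSample("AAAAAA", n = 100L, seed = 3L)
  expect_identical(length(ens), 100L)
  expect_true(all(vapply(structures(ens),
                         function(s) nrow(basePairs(s)) == 0L, logical(1L))))
})

test_that("DP pair probabilities match exhaustive enumeration", {
  set.seed(91)
  for (rep_ in 1:4) {
    seq <- randomSequence(sample(9:13, 1L), gc = 0.6)
    bonus <- if (rep_ %% 2L) round(runif(nchar(seq), -1, 1), 2) else NULL
    o <- boltzmannOracle(seq, bonus)
    pf <- partitionFunction(seq, bonus = bonus)
    expect_lt(max(abs(pairProbs(pf$probs) - o$P)), 1e-12)
    expect_lt(abs(pf$freeEnergy - o$freeEnergy),
              1e-12 * max(1, abs(o$freeEnergy)))
  }
})

test_that("zero bonus reproduces the unrestrained partition function", {
  seq <- bistableExample()$seq
  pf0 <- partitionFunction(seq)
  pf1 <- partitionFunction(seq, bonus = rep(0, nchar(seq)))
  expect_identical(pairProbs(pf0$probs), pairProbs(pf1$probs))
  expect_identical(pf0$freeEnergy, pf1$freeEnergy)
})

test_that("per-nucleotide total pairing probability never exceeds 1", {
  set.seed(17)
  for (rep_ in 1:5) {
    seq <- randomSequence(sample(15:40, 1L), gc = 0.6)
    P <- pairProbs(partitionFunction(seq)$probs)
    tot <- rowSums(P) + colSums(P)
    expect_true(all(tot <= 1 + 1e-9))
  }
})

test_that("sampling is reproducible and input validation works", {
  seq <- "GGGAAAACCCAC"
  e1 <- stochasticSample(seq, n = 200L, seed = 11L)
  e2 <- stochasticSample(seq, n = 200L, seed = 11L)
  expect_identical(lapply(structures(e1), basePairs),
                   lapply(structures(e2), basePairs))
  expect_error(stochasticSample(seq, n = 0L), "sample size")
  expect_error(partitionFunction("ACG"), "too short")
  expect_error(partitionFunction(seq, bonus = c(0, 0)), "bonus length")
  expect_error(partitionFunction("ACGTX"), "invalid sequence character")
})

test_that("sampled frequencies agree with DP pair probabilities", {
  seq <- "GGGAAAACCCAC"
  ens <- stochasticSample(seq, n = 8000L, seed = 5L)
  Pf <- pairProbs(pairFrequencies(ens))
  P <- pairProbs(partitionFunction(seq)$probs)
  ## binomial tolerance: 4 standard errors at n = 8000
  se <- sqrt(pmax(P * (1 - P), 1e-12) / 8000)
  expect_true(all(abs(Pf - P) <= 4 * se + 1e-12))
})

test_that("pair frequencies handle degenerate ensembles", {
  s1 <- parseDotBracket("((((...)))).")
  s2 <- parseDotBracket("....((...)).")
  ens <- structureEnsemble(list(s1, s1, s1, s1))
  P <- pairProbs(pairFrequencies(ens))
  expect_true(all(P[basePairs(s1)] == 1))
  expect_identical(sum(P), 4)

  ens2 <- structureEnsemble(list(s1, s2))
  expect_true(all(pairProbs(pairFrequencies(ens2)) %in% c(0, 0.5)))
})

test_that("MEA structure maximizes the expected-accuracy objective", {
  ## single dominant entry
  P1 <- matrix(0, 10, 10); P1[1, 10] <- 0.9
  mea <- meaStructure(pairProbabilityMatrix(P1))
  expect_equal(basePairs(mea), cbind(1L, 10L), ignore_attr = TRUE)

  ## all-zero matrix: open chain
  open <- meaStructure(pairProbabilityMatrix(matrix(0, 8, 8)))
  expect_identical(nrow(basePairs(open)), 0L)

  ## random toys against the brute-force maximizer
  set.seed(33)
  for (rep_ in 1:5) {
    seq <- randomSequence(8L, gc = 0.7)
    P <- partitionFunction(seq)$probs
    mea <- meaStructure(P)
    o <- meaOracle(P)
    expect_equal(meaScore(P, mea), o$best, tolerance = 1e-9)
  }
})
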