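test_that("nucleotide classification follows the flanking-pair rule", {
  open <- secondaryStructure(8L)
  expect_true(all(classifyNucleotides(open) == "UNPAIRED"))

  iso <- secondaryStructure(8L, cbind(2L, 7L))
  cls <- classifyNucleotides(iso)
  expect_identical(as.character(cls[c(2L, 7L)]),
                   c("HELIX_END", "HELIX_END"))
  expect_true(all(cls[-c(2L, 7L)] == "UNPAIRED"))

  helix <- secondaryStructure(12L, cbind(1:3, 12:10))
  cls <- classifyNucleotides(helix)
  expect_true(all(cls[c(1, 3, 10, 12)] == "HELIX_END"))
  expect_true(all(cls[c(2, 11)] == "HELIX_INTERIOR"))
  expect_true(all(cls[4:9] == "UNPAIRED"))
})

test_that("the three classes partition every structure", {
  set.seed(7)
  for (rep_ in 1:10) {
    n <- sample(8:25, 1L)
    s <- randomStructure(n)
    expect_identical(sum(table(classifyNucleotides(s))), as.integer(n))
  }
})

test_that("default distributions order their means as observed empirically", {
  m <- classMeans(reactivityDistributions())
  expect_gt(m[["unpaired"]], m[["helixEnd"]])
  expect_gte(m[["helixEnd"]], m[["helixInterior"]])
  expect_error(reactivityDistributions(unpaired = c(0.1, 0.1)),
               "class means")
})

test_that("expectation-mode Rcalc is the class-frequency weighted mean", {
  d <- reactivityDistributions()
  m <- classMeans(d)
  open <- secondaryStructure(8L)
  ens <- structureEnsemble(list(open, open, open))
  expect_equal(reactivities(estimateRcalc(ens, d)), rep(m[["unpaired"]], 8))

  ## nucleotide 2: helix-interior in every structure of a 3-pair helix
  helix <- secondaryStructure(12L, cbind(1:3, 12:10))
  ens2 <- structureEnsemble(list(helix, helix))
  expect_equal(reactivities(estimateRcalc(ens2, d))[2],
               m[["helixInterior"]])

  ## 60/40 unpaired/helix-end mixture at nucleotide 2
  iso <- secondaryStructure(12L, cbind(2L, 11L))
  ens3 <- structureEnsemble(c(rep(list(open2 <- secondaryStructure(12L)), 3),
                              rep(list(iso), 2)))
  expect_equal(reactivities(estimateRcalc(ens3, d))[2],
               0.6 * m[["unpaired"]] + 0.4 * m[["helixEnd"]])
})

test_that("montecarlo Rcalc converges to the expectation mode", {
  d <- reactivityDistributions()
  helix <- secondaryStructure(12L, cbind(1:3, 12:10))
  open <- secondaryStructure(12L)
  ens <- structureEnsemble(c(rep(list(helix), 6000), rep(list(open), 4000)))
  ex <- reactivities(estimateRcalc(ens, d, mode = "expectation"))
  mc <- reactivities(estimateRcalc(ens, d, mode = "montecarlo", seed = 2L))
  ## CLT bound: per-draw sd is below 0.85; 3 SE over 10000 draws
  expect_true(all(abs(mc - ex) < 3 * 0.85 / sqrt(10000)))
})

test_that("simulated SHAPE profiles follow the mixture expectation", {
  d <- reactivityDistributions()
  m <- classMeans(d)
  helix <- secondaryStructure(12L, cbind(1:3, 12:10))
  open <- secondaryStructure(12L)

  ## degenerate mixture, many replicates: converges to the class mean
  prof <- simulateShape(list(list(structure = open, population = 1)),
                        d, seed = 4L, replicates = 4000L)
  expect_true(all(abs(reactivities(prof) - m[["unpaired"]]) <
                  4 * 0.8 / sqrt(4000)))

  ## 50/50 mixture: nucleotide 2 averages unpaired and helix-interior
  prof2 <- simulateShape(list(list(structure = open, population = 0.5),
                              list(structure = helix, population = 0.5)),
                         d, seed = 4L, replicates = 4000L)
  expect_lt(abs(reactivities(prof2)[2] -
                0.5 * (m[["unpaired"]] + m[["helixInterior"]])), 0.05)

  ## reproducibility and input validation
  a <- simulateShape(list(list(structure = open, population = 1)), seed = 9L)
  b <- simulateShape(list(list(structure = open, population = 1)), seed = 9L)
  expect_identical(reactivities(a), reactivities(b))
  expect_error(simulateShape(list(list(structure = open, population = 0.8))),
               "sum to 1")
})
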