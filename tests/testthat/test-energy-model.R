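dropSection <- function(lines, name) {
  ## remove a [section] block from a parameter file
  starts <- grep("^\\[", lines)
  s <- grep(paste0("^\\[", name, "\\]"), lines)
  stopifnot(length(s) == 1L)
  e <- starts[starts > s]
  e <- if (length(e)) min(e) - 1L else length(lines)
  lines[-(s:e)]
}

test_that("default parameter set is complete and round-trips edits", {
  p <- loadParams("default")
  expect_identical(dim(p@stack), c(6L, 6L))
  expect_true(all(is.finite(p@stack)))
  expect_identical(p@minHairpin, 3L)
  ## loop penalties finite across the full size range
  expect_true(all(is.finite(hairpinPenalty(p, 3:500))))
  expect_true(all(is.finite(internalPenalty(p, 1:500))))

  ## edit one stack value through the file format and read it back
  f <- system.file("extdata", "nn_params.txt", package = "shapeEnsemble")
  lines <- readLines(f)
  lines[grepl("^GC GC", lines)] <- "GC GC -9.9"
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  p2 <- loadParams(tmp)
  expect_equal(p2@stack["GC", "GC"], -9.9)
  expect_equal(p2@stack["AU", "AU"], p@stack["AU", "AU"])
})

test_that("malformed parameter files raise errors naming the field", {
  f <- system.file("extdata", "nn_params.txt", package = "shapeEnsemble")
  lines <- readLines(f)
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))

  writeLines(dropSection(lines, "hairpin"), tmp)
  expect_error(loadParams(tmp), "hairpin")

  writeLines(sub("^GC GC .*$", "GC GC notanumber", lines), tmp)
  expect_error(loadParams(tmp), "stack GC GC")

  writeLines(c(lines, "[stack]", "XX GC -1.0"), tmp)
  expect_error(loadParams(tmp), "unknown pair key")
})

test_that("structure energies follow the loop decomposition", {
  p <- loadParams()
  seq <- "GGGAAAACCCAA"
  open <- secondaryStructure(12L)
  expect_identical(structureEnergy(seq, open, p), 0)

  ## two-stack hairpin (pairs 1:3 with 10:8): zero bonus == no bonus
  hp <- secondaryStructure(12L, cbind(1:3, 10:8))
  e0 <- structureEnergy(seq, hp, p)
  expect_identical(structureEnergy(seq, hp, p, bonus = rep(0, 12)), e0)
  ## hand decomposition: GC/GC + GC/GC stacks + hairpin loop of size 4
  eHand <- p@stack["GC", "GC"] + p@stack["GC", "GC"] + hairpinPenalty(p, 4)
  expect_equal(e0, eHand)

  ## three-pair helix with uniform bonus b everywhere: +8b
  ## (two stacks x four positions each; helix ends once, interior twice)
  b <- 0.37
  expect_equal(structureEnergy(seq, hp, p, bonus = rep(b, 12)), e0 + 8 * b)

  ## disallowed pair is rejected
  bad <- secondaryStructure(12L, cbind(1L, 6L))  # G-A
  expect_error(structureEnergy(seq, bad, p), "disallowed pair")
})

test_that("bonus contribution equals stack-membership counts times bonus", {
  p <- loadParams()
  set.seed(421)
  for (rep_ in 1:20) {
    n <- sample(10:18, 1L)
    seq <- randomSequence(n, gc = 0.6)
    s <- randomStructure(n, canPairMatrix(seq))
    bonus <- round(runif(n, -1, 1), 3)
    e0 <- structureEnergy(seq, s, p)
    e1 <- structureEnergy(seq, s, p, bonus)
    expect_equal(e1 - e0, sum(stackCounts(s) * bonus), tolerance = 1e-12)
  }
})

test_that("energy is invariant to pair-list ordering", {
  p <- loadParams()
  fx <- bistableExample()
  seq <- fx$seq
  bp <- basePairs(fx$structures$A)
  s1 <- secondaryStructure(23L, bp)
  shuffled <- bp[c(3, 1, 4, 2, 5), ]
  s2 <- secondaryStructure(23L, shuffled[, c(2, 1)])  # also swap columns
  expect_identical(structureEnergy(seq, s1, p), structureEnergy(seq, s2, p))
})
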