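test_that("base-pair distance is the symmetric difference", {
  a <- secondaryStructure(12L, cbind(c(1L, 2L), c(10L, 9L)))
  b <- secondaryStructure(12L, cbind(c(1L, 3L), c(10L, 8L)))
  empty <- secondaryStructure(12L)
  expect_identical(bpDistance(a, a), 0L)
  expect_identical(bpDistance(secondaryStructure(12L, cbind(1L, 10L)),
                              empty), 1L)
  expect_identical(bpDistance(a, b), 2L)
  expect_error(bpDistance(a, secondaryStructure(13L)), "different lengths")
})

test_that("distance matrix equals pairwise bpDistance", {
  set.seed(5)
  structs <- lapply(1:8, function(i) randomStructure(15L))
  ens <- structureEnsemble(structs)
  D <- shapeEnsemble:::bpDistanceMatrix(ens)
  for (i in 1:8) for (j in 1:8)
    expect_equal(D[i, j], bpDistance(structs[[i]], structs[[j]]))
})

test_that("centroids keep exactly the majority pairs", {
  s <- parseDotBracket("(((....)))..")
  expect_equal(basePairs(centroidStructure(list(s, s, s))), basePairs(s))

  ## pair (2,9) in 2/3 of members, (3,8) in 1/3: only (2,9) survives
  a <- secondaryStructure(12L, cbind(2L, 9L))
  b <- secondaryStructure(12L, cbind(3L, 8L))
  cen <- centroidStructure(list(a, a, b))
  expect_equal(basePairs(cen), cbind(2L, 9L), ignore_attr = TRUE)

  ## frequency exactly 0.5 is excluded (strict > 0.5)
  cen2 <- centroidStructure(list(a, a, b, b))
  expect_identical(nrow(basePairs(cen2)), 0L)
  expect_error(centroidStructure(list()), "empty cluster")
})

test_that("centroid conflict resolution yields a legal structure", {
  ## (2,9) and (2,10) can both exceed 0.5 across members; higher frequency
  ## wins, the conflicting pair is dropped
  a <- secondaryStructure(12L, cbind(2L, 9L))
  b <- secondaryStructure(12L, cbind(c(2L), c(10L)))
  cen <- centroidStructure(list(a, a, a, b, b))
  expect_equal(basePairs(cen), cbind(2L, 9L), ignore_attr = TRUE)
  expect_s4_class(cen, "SecondaryStructure")
})

test_that("Shannon entropy matches hand evaluation", {
  P <- matrix(0, 10, 10)
  P[1, 10] <- 1; P[2, 9] <- 1
  expect_identical(shannonEntropy(pairProbabilityMatrix(P)), 0)

  P2 <- matrix(0, 10, 10); P2[1, 10] <- 0.5
  expect_equal(shannonEntropy(pairProbabilityMatrix(P2)),
               -(0.5 * log10(0.5)) / 10, tolerance = 1e-12)
  expect_equal(shannonEntropy(pairProbabilityMatrix(P2)), 0.01505,
               tolerance = 1e-4)

  ## non-negative on random valid matrices, with a loose upper bound
  set.seed(12)
  for (rep_ in 1:5) {
    seq <- randomSequence(20L, gc = 0.6)
    Pr <- partitionFunction(seq)$probs
    S <- shannonEntropy(Pr)
    expect_gte(S, 0)
    expect_lte(S, log10(20) * sum(pairProbs(Pr) > 0) / 20)
  }
})

test_that("clustering falls back to one cluster on homogeneous samples", {
  s <- parseDotBracket("(((....)))..")
  ens <- structureEnsemble(rep(list(s), 40))
  cl <- clusterStructures(ens)
  expect_identical(cl@k, 1L)
  expect_true(all(cl@assignments == 1L))
})

test_that("two well-separated registers are recovered exactly", {
  p <- plantedPartitionSample(sizes = c(30L, 20L), wobble = 1L, seed = 8L)
  cl <- clusterStructures(p$ensemble, kMax = 6L)
  expect_identical(cl@k, 2L)
  tab <- table(cl@assignments, p$labels)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("clustering is reproducible for the same sample", {
  p <- plantedPartitionSample(sizes = c(40L, 25L), seed = 3L)
  c1 <- clusterStructures(p$ensemble)
  c2 <- clusterStructures(p$ensemble)
  expect_identical(c1@assignments, c2@assignments)
  expect_identical(c1@k, c2@k)
})

test_that("ensemble models conserve population and order by size", {
  p <- plantedPartitionSample(sizes = c(30L, 20L), wobble = 0L, seed = 2L)
  cl <- clusterStructures(p$ensemble, kMax = 4L)
  model <- buildEnsembleModel(p$ensemble, cl, entropy = 0.1)
  expect_equal(sum(populations(model)), 1, tolerance = 1e-12)
  expect_true(all(diff(populations(model)) <= 0))
  expect_identical(length(centroids(model)), cl@k)
  ## centroid of a wobble-free cluster is its base structure
  expect_equal(sort(populations(model)), sort(c(0.6, 0.4)))
})

test_that("centroids map onto references with threshold and tie rules", {
  fx <- bistableExample()
  ens <- structureEnsemble(c(rep(list(fx$structures$A), 7),
                             rep(list(fx$structures$B), 3)))
  cl <- clusterStructures(ens, kMax = 4L)
  model <- buildEnsembleModel(ens, cl, entropy = 0)
  m <- mergeEquivalentClusters(model, fx$structures)
  expect_equal(unname(m$populations),
               c(0.7, 0.3, 0), tolerance = 1e-12)
  expect_true(all(m$assignments$accuracy == 1))

  ## a centroid far from every reference lands in "other"
  far <- secondaryStructure(23L, cbind(3L, 20L))
  modelFar <- buildEnsembleModel(structureEnsemble(list(far, far)),
                                 clusterStructures(
                                   structureEnsemble(list(far, far))),
                                 entropy = 0)
  mFar <- mergeEquivalentClusters(modelFar, fx$structures)
  expect_identical(unname(mFar$populations[["other"]]), 1)
})
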