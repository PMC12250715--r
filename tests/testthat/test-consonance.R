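test_that("threshold schemes validate their parameters", {
  expect_s4_class(thresholdScheme(0.67, 0.33, "thirds"), "ThresholdScheme")
  expect_error(thresholdScheme(0.3, 0.4), "alpha must exceed beta")
  expect_error(thresholdScheme(1.2, 0.2), "alpha")
  expect_error(thresholdScheme(0.8, -0.1), "beta")
})

test_that("classification follows the quarters and thirds rules", {
  q <- thresholdScheme(0.75, 0.25)
  expect_equal(as.character(classifyPairs(ifPairs(0.84, 0.16), q)),
               "positive_consonance")
  expect_equal(as.character(classifyPairs(ifPairs(0.60, 0.40), q)),
               "dissonance")
  expect_equal(as.character(classifyPairs(ifPairs(0, 1), q)),
               "negative_consonance")
  th <- thresholdScheme(0.67, 0.33, "thirds")
  expect_equal(as.character(classifyPairs(ifPairs(0, 1), th)),
               "negative_consonance")
  expect_equal(as.character(classifyPairs(ifPairs(0.2, 0.2), th)),
               "uncertainty")
  # dissonance zone of the thirds scale: both degrees moderate, low pi
  expect_equal(as.character(classifyPairs(ifPairs(0.5, 0.5), th)),
               "dissonance")
})

test_that("boundary convention decides whether mu = alpha qualifies", {
  inc <- thresholdScheme(0.70, 0.30, boundary = "inclusive")
  str <- thresholdScheme(0.70, 0.30, boundary = "strict")
  atBoundary <- ifPairs(0.70)
  expect_equal(as.character(classifyPairs(atBoundary, inc)),
               "positive_consonance")
  expect_equal(as.character(classifyPairs(atBoundary, str)), "dissonance")
})

test_that("classification is exhaustive, exclusive, and scale-consistent", {
  grid <- expand.grid(mu = seq(0, 1, by = 0.05), nu = seq(0, 1, by = 0.05))
  grid <- grid[grid$mu + grid$nu <= 1, ]
  pairs <- ifPairs(grid$mu, grid$nu)
  for (scale in c("quarters", "thirds")) {
    lab <- classifyPairs(pairs, thresholdScheme(0.67, 0.33, scale))
    expect_false(anyNA(lab))
    if (scale == "quarters") expect_false(any(lab == "uncertainty"))
    else expect_true(any(lab == "uncertainty"))
  }
})

test_that("with nu = 1 - mu and beta = 1 - alpha the rule is 1-D on mu", {
  set.seed(5)
  mu <- runif(200)
  for (alpha in c(0.75, 0.67, 0.6)) {
    sch <- thresholdScheme(alpha, 1 - alpha)
    lab <- classifyPairs(ifPairs(mu), sch)
    expect_equal(lab == "positive_consonance", mu >= alpha)
  }
})

test_that("per-block counts match the published threshold analysis", {
  t1 <- table1Fixture()
  expect_equal(
    unname(countPositivePerBlock(t1, thresholdScheme(0.75, 0.25))[["BestRMSD"]]),
    8)
  expect_equal(
    unname(countPositivePerBlock(t1, thresholdScheme(0.67, 0.33, "thirds"))[["RMSD_BestDS"]]),
    5)
  allOnes <- matrix(1, 4, 2, dimnames = list(paste0("p", 1:4), c("b1", "b2")))
  expect_equal(unname(countPositivePerBlock(allOnes, thresholdScheme())),
               c(4L, 4L))
})

test_that("per-pair counts match the published comparability profile", {
  t1 <- table1Fixture()
  counts <- countPositivePerPair(
    t1, list(thresholdScheme(0.67, 0.33, "thirds"), thresholdScheme(0.70, 0.30)))
  expect_equal(unname(counts["Alpha HB-London dG", "0.67/0.33"]), 4L)
  expect_equal(unname(counts["Alpha HB-London dG", "0.70/0.30"]), 3L)

  zero <- matrix(0, 2, 3, dimnames = list(c("p1", "p2"), c("b1", "b2", "b3")))
  expect_true(all(countPositivePerPair(zero, thresholdScheme()) == 0))
})

test_that("block lists with inconsistent pair sets are rejected", {
  blocks <- list(b1 = c("p1-p2" = 0.8, "p1-p3" = 0.4),
                 b2 = c("p1-p2" = 0.7, "p2-p3" = 0.5))
  expect_error(countPositivePerBlock(blocks, thresholdScheme()),
               "same pair-label set")
  blocks$b2 <- c("p1-p3" = 0.5, "p1-p2" = 0.7)  # same set, different order
  expect_equal(unname(countPositivePerBlock(blocks, thresholdScheme(0.6, 0.4))),
               c(1L, 1L))
})

test_that("threshold sweeps summarize both directions and stay monotone", {
  sw <- thresholdSweep(table1Fixture())
  expect_s4_class(sw, "SweepSummary")
  expect_equal(dim(perBlockCounts(sw)), c(5L, 4L))
  expect_equal(dim(perPairCounts(sw)), c(15L, 5L))

  single <- thresholdSweep(matrix(1, 1, 1, dimnames = list("p", "b")),
                           alphas = c(0.9, 0.6))
  expect_true(all(perBlockCounts(single) == 1))

  set.seed(9)
  rand <- matrix(runif(60), 15, 4,
                 dimnames = list(paste0("p", 1:15), paste0("b", 1:4)))
  counts <- perBlockCounts(thresholdSweep(rand, alphas = seq(0.95, 0.55, by = -0.05)))
  expect_true(all(apply(counts, 2, function(col) all(diff(col) >= 0))))

  expect_error(thresholdSweep(rand, alphas = c(0.7, 0.5)), "0.5")
})

test_that("triangle coordinates place pairs inside the unit triangle", {
  tri <- triangleCoordinates(ifPairs(c(1, 0, 0.5), c(0, 1, 0.5)))
  expect_equal(tri$x, c(1, 0, 0.5))
  expect_equal(tri$y, c(0, 1, 0.5))
  expect_true(all(tri$x >= 0 & tri$y >= 0 & tri$x + tri$y <= 1))
})

test_that("relation colors follow the conventional display semantics", {
  expect_equal(relationColors(c("positive_consonance", "dissonance",
                                "negative_consonance", "uncertainty")),
               c("green", "magenta", "red", "grey"))
})
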