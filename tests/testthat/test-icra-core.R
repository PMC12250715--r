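test_that("counters classify concordant, discordant and tied object pairs", {
  expect_equal(pairwiseCounters(c(1, 2, 3), c(1, 2, 3)),
               c(sMu = 3L, sNu = 0L, sTie = 0L))
  expect_equal(pairwiseCounters(c(1, 2, 3), c(3, 2, 1)),
               c(sMu = 0L, sNu = 3L, sTie = 0L))
  # enumerated by hand over all 6 object pairs: (1,2) discordant,
  # (1,3)/(1,4)/(2,4) concordant, (2,3) and (3,4) tied in one criterion
  expect_equal(pairwiseCounters(c(1, 2, 2, 3), c(2, 1, 3, 3)),
               c(sMu = 3L, sNu = 1L, sTie = 2L))

  expect_error(pairwiseCounters(1:3, 1:4), "same length")
  expect_error(pairwiseCounters(1, 2), "two objects")
  expect_error(pairwiseCounters(c(1, NA, 3), 1:3), "finite")
})

test_that("tie handling: unbiased drops ties, mu_biased credits double ties", {
  xs <- c(1, 1, 2)
  ys <- c(3, 3, 5)
  # pair (1,2) is tied in both criteria
  expect_equal(pairwiseCounters(xs, ys, "unbiased"),
               c(sMu = 2L, sNu = 0L, sTie = 1L))
  expect_equal(pairwiseCounters(xs, ys, "mu_biased"),
               c(sMu = 3L, sNu = 0L, sTie = 0L))
  # a single-criterion tie stays in sTie under both modes
  expect_equal(pairwiseCounters(c(1, 1, 2), c(3, 4, 5), "mu_biased"),
               c(sMu = 2L, sNu = 0L, sTie = 1L))
})

test_that("epsilon widens the tie band on evaluation differences", {
  xs <- c(1.00, 1.05, 2.00)
  ys <- c(1, 2, 3)
  expect_equal(pairwiseCounters(xs, ys, epsilon = 0)[["sTie"]], 0L)
  expect_equal(pairwiseCounters(xs, ys, epsilon = 0.1)[["sTie"]], 1L)
  expect_error(pairwiseCounters(xs, ys, epsilon = -1), "non-negative")
})

test_that("degrees normalize counters by the number of object pairs", {
  p <- degrees(c(sMu = 3, sNu = 0, sTie = 0), m = 3)
  expect_equal(agreement(p), 1)
  expect_equal(disagreement(p), 0)

  p <- degrees(c(sMu = 3, sNu = 1, sTie = 2), m = 4)
  expect_equal(agreement(p), 0.5)
  expect_equal(disagreement(p), 1 / 6)
  expect_equal(uncertainty(p), 1 / 3)

  # constant columns: everything ties, total uncertainty
  allTie <- pairwiseCounters(rep(1, 5), rep(2, 5))
  p <- degrees(allTie, m = 5)
  expect_equal(agreement(p), 0)
  expect_equal(disagreement(p), 0)
  expect_equal(uncertainty(p), 1)

  expect_error(degrees(c(sMu = 0, sNu = 0, sTie = 0), m = 1), "at least 2")
})

test_that("IFPairs enforce the intuitionistic fuzzy condition", {
  expect_error(ifPairs(0.7, 0.5), "mu \\+ nu")
  expect_error(ifPairs(-0.1, 0.5), "\\[0, 1\\]")
  p <- ifPairs(c(0.3, 0.8))
  expect_equal(disagreement(p), c(0.7, 0.2))
  expect_equal(uncertainty(p), c(0, 0), tolerance = 1e-12)
})

test_that("runICrA builds a symmetric result with unit diagonal", {
  im <- IndexMatrix(cbind(A = c(1, 5, 2, 4), B = c(10, 50, 20, 40),
                          C = c(4, 2, 3, 1)))
  res <- runICrA(im)
  expect_s4_class(res, "ICrAResult")
  mu <- agreement(res)
  nu <- disagreement(res)
  expect_equal(mu, t(mu))
  expect_equal(diag(mu), setNames(rep(1, 3), criteriaLabels(im)))
  expect_equal(diag(nu), setNames(rep(0, 3), criteriaLabels(im)))
  # A and B are the same ordering: full agreement off-diagonal
  expect_equal(mu["A", "B"], 1)
  expect_equal(nu["A", "B"], 0)
  expect_true(all(mu + nu <= 1 + 1e-12))
})

test_that("runICrA agrees exactly with the brute-force double loop", {
  set.seed(101)
  for (rep in 1:10) {
    ev <- evaluations(randomMatrix(10, 4))
    # inject some ties in half the replicates
    if (rep %% 2 == 0) ev[sample(length(ev), 6)] <- round(ev[sample(40, 6)], 0)
    im <- IndexMatrix(ev)
    for (mode in c("unbiased", "mu_biased")) {
      res <- runICrA(im, tieMode = mode)
      ref <- bruteICrA(ev, tieMode = mode)
      expect_equal(unname(agreement(res)), ref$mu)
      expect_equal(unname(disagreement(res)), ref$nu)
    }
  }
})

test_that("conservation: counters sum to m(m-1)/2 for every pair", {
  set.seed(7)
  for (m in c(2, 5, 17)) {
    im <- randomMatrix(m, 3)
    cnt <- counters(runICrA(im))
    tot <- cnt$sMu + cnt$sNu + cnt$sTie
    expect_true(all(tot[upper.tri(tot)] == m * (m - 1) / 2))
  }
})

test_that("degrees depend only on orderings, not on scales or object order", {
  set.seed(23)
  im <- randomMatrix(12, 4)
  res <- runICrA(im)

  # permutation invariance
  perm <- sample(12)
  imP <- IndexMatrix(evaluations(im)[perm, ])
  expect_equal(agreement(runICrA(imP)), agreement(res))

  # strictly increasing transform of one column
  ev2 <- evaluations(im)
  ev2[, 2] <- exp(3 * ev2[, 2]) + 1
  expect_equal(agreement(runICrA(IndexMatrix(ev2))), agreement(res))

  # negating a column swaps mu and nu for its pairs (tie-free data)
  ev3 <- evaluations(im)
  ev3[, 1] <- -ev3[, 1]
  res3 <- runICrA(IndexMatrix(ev3))
  expect_equal(agreement(res3)[1, -1], disagreement(res)[1, -1])
  expect_equal(disagreement(res3)[1, -1], agreement(res)[1, -1])
})

test_that("on tie-free data mu recovers Kendall's tau: mu = (1 + tau)/2", {
  set.seed(41)
  for (rep in 1:5) {
    x <- rnorm(15)
    y <- rnorm(15)
    p <- degrees(pairwiseCounters(x, y), m = 15)
    tau <- cor(x, y, method = "kendall")
    expect_equal(agreement(p) - disagreement(p), tau, tolerance = 1e-12)
    expect_equal(agreement(p), (1 + tau) / 2, tolerance = 1e-12)
  }
})

test_that("results serialize to twin square tables and a long table", {
  im <- IndexMatrix(cbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4),
                          C = c(4, 3, 2, 1)))
  res <- runICrA(im)
  long <- icraPairs(res)
  expect_equal(long$pair, c("A-B", "A-C", "B-C"))
  expect_equal(long$mu + long$nu + long$pi, rep(1, 3), tolerance = 1e-12)

  dir <- withr::local_tempdir()
  paths <- writeICrAResult(res, dir)
  expect_true(all(file.exists(paths)))
  muBack <- read.csv(file.path(dir, "mu.csv"), check.names = FALSE)
  expect_equal(muBack[["A"]], unname(agreement(res)[, "A"]))
})
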