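test_that("connectance counts realised links", {
  expect_equal(connectance(matrix(1, 2, 2)), 1)
  expect_equal(connectance(matrix(c(1, 1, 1, 0), 2, 2)), 0.75)
  set.seed(1)
  a <- randomSmallNet(6, 9, 20)
  expect_equal(connectance(a), sum(a > 0) / 54)
})

test_that("NODF hits its analytic anchors", {
  tri <- matrix(0, 4, 4)
  for (i in 1:4) tri[i, 1:(5 - i)] <- 1
  expect_equal(nodf(tri), 100)
  expect_equal(nodf(diag(4)), 0)           # disjoint specialists
  sameRows <- matrix(rep(c(1, 1, 0, 1), 3), 3, 4, byrow = TRUE)
  # equal row fills: every row pair contributes 0, columns drive the value
  expect_equal(nodf(sameRows), oracleNodf(sameRows))
  expect_error(nodf(matrix(5, 1, 1)), "undefined")
})

test_that("NODF agrees with the pairwise-definition oracle and with vegan", {
  set.seed(42)
  for (rep in 1:25) {
    a <- randomSmallNet(sample(2:6, 1), sample(2:6, 1), sample(8:30, 1))
    expect_equal(nodf(a), oracleNodf(a), tolerance = 1e-10)
    v <- vegan::nestednodf(a)$statistic[["NODF"]]
    expect_equal(nodf(a), v, tolerance = 1e-8)
  }
})

test_that("H2' is 1 on diagonal equal-margin and 0 on margin-proportional matrices", {
  expect_equal(as.numeric(h2prime(diag(3) * 4)), 1)
  expect_equal(as.numeric(h2prime(matrix(1, 4, 4))), 0)
  outerTab <- outer(c(1, 2), c(2, 3))    # proportional to its own margins
  expect_equal(as.numeric(h2prime(outerTab)), 0, tolerance = 1e-9)
})

test_that("H2' of the reference 3x3 matrix equals the exhaustive-enumeration value", {
  m <- matrix(c(4, 1, 0, 1, 4, 1, 0, 1, 4), 3, 3, byrow = TRUE)
  # frozen from the exhaustive oracle over all 266 margin-consistent tables
  expect_equal(as.numeric(h2prime(m)), 0.4043826023, tolerance = 1e-6)
  b <- pollinet:::h2Bounds(rowSums(m), colSums(m))
  expect_true(b$exact)
  expect_equal(b$min, 1.0947802260, tolerance = 1e-6)
  expect_equal(b$max, 2.1660849392, tolerance = 1e-6)
})

test_that("degenerate 1x1 network has H2' = 0 with a flag", {
  h <- h2prime(matrix(7, 1, 1, dimnames = list("P", "V")))
  expect_equal(as.numeric(h), 0)
  expect_true(attr(h, "degenerate"))
})

test_that("d' is 0 for availability-proportional visitors", {
  a <- outer(c(2, 1, 1), c(3, 2, 1))  # every column proportional to margins
  dimnames(a) <- list(paste0("P", 1:3), paste0("V", 1:3))
  expect_equal(unname(dprime(a)), c(0, 0, 0), tolerance = 1e-9)
})

test_that("a visitor concentrating on the rarest plant reaches d' = 1", {
  a <- matrix(c(10, 6, 0, 0, 0, 2), 3, 2,
              dimnames = list(paste0("P", 1:3), c("V1", "V2")))
  # V2 places both visits on the rarest plant (total 2 = its visits)
  expect_equal(unname(dprime(a, "V2")), 1, tolerance = 1e-9)
  expect_equal(unname(dprime(a, "V2")), oracleDprime(a, 2), tolerance = 1e-9)
})

test_that("d' of the reference 3x3 matrix matches the exhaustive oracle", {
  m <- matrix(c(4, 1, 0, 1, 4, 1, 0, 1, 4), 3, 3, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), paste0("V", 1:3)))
  # frozen from exhaustive capped-allocation enumeration
  expect_equal(unname(dprime(m)), c(0.52399050, 0.17427221, 0.52399050),
               tolerance = 1e-6)
  expect_equal(meanDprime(m), mean(dprime(m)))
})

test_that("mean d' is 1 on diagonal equal-margin networks", {
  expect_equal(meanDprime(diag(4) * 3), 1)
})

test_that("metrics are invariant under simultaneous row/column permutation", {
  set.seed(7)
  a <- randomSmallNet(4, 5, 18)
  p <- sample(4); q <- sample(5)
  b <- a[p, q]
  expect_equal(connectance(a), connectance(b))
  expect_equal(nodf(a), nodf(b))
  expect_equal(as.numeric(h2prime(a)), as.numeric(h2prime(b)), tolerance = 1e-10)
  expect_equal(sort(unname(dprime(a))), sort(unname(dprime(b))),
               tolerance = 1e-10)
})

test_that("count scaling leaves binary metrics and Q alone but moves H2' and d'", {
  a <- matrix(c(2, 1, 1, 2), 2, 2,
              dimnames = list(c("P1", "P2"), c("V1", "V2")))
  a3 <- a * 3
  expect_equal(connectance(a3), connectance(a))
  expect_equal(nodf(a3), nodf(a))
  # modularity is scale-free by construction: B and m scale together
  q1 <- bipartiteModularity(a, seed = 1)$Q
  q3 <- bipartiteModularity(a3, seed = 1)$Q
  expect_equal(q1, q3, tolerance = 1e-9)
  # the entropy-based standardisations see the finer integer granularity
  expect_false(isTRUE(all.equal(as.numeric(h2prime(a)),
                                as.numeric(h2prime(a3)), tolerance = 1e-6)))
  expect_false(isTRUE(all.equal(unname(dprime(a)), unname(dprime(a3)),
                                tolerance = 1e-6)))
})
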