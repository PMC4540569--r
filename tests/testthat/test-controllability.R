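test_that("the five-node worked example has a unique maximum matching", {
  net <- fig1Network()
  oracle <- bruteAllMaxMatchings(net)
  expect_equal(oracle$size, 3L)
  expect_equal(length(oracle$matchings), 1L)

  m <- maximumMatching(net, seed = 1)
  expect_equal(matchingSize(m), 3L)
  expect_equal(unname(links(m)), unname(oracle$matchings[[1L]]))
  expect_equal(countDrivers(net, m), 2L)
  expect_equal(driverNodes(net, m), c("1", "2"))
})

test_that("matching cardinality matches brute force and igraph on random instances", {
  skip_if_not_installed("igraph")
  for (seed in 1:30) {
    net <- randomSmallNet(sample(3:7, 1), sample(2:12, 1), seed = seed,
                          selfLoops = seed %% 3 == 0)
    oracle <- bruteAllMaxMatchings(net)
    m <- maximumMatching(net, seed = seed)
    expect_true(validObject(m))
    expect_equal(matchingSize(m), oracle$size)
    expect_equal(matchingSize(m), igraphMatchingSize(net))
  }
})

test_that("driver counting follows N_D = max(n - |M|, 1)", {
  cyc <- threeCycle()
  mc <- maximumMatching(cyc)
  expect_equal(matchingSize(mc), 3L)       # perfect matching
  expect_equal(countDrivers(cyc, mc), 1L)
  expect_equal(driverNodes(cyc, mc), "a")  # smallest-id convention

  empty <- directedNetwork(matrix(character(0), ncol = 2),
                           nodes = c("w", "x", "y", "z"))
  me <- maximumMatching(empty)
  expect_equal(matchingSize(me), 0L)
  expect_equal(countDrivers(empty, me), 4L)
  expect_setequal(driverNodes(empty, me), c("w", "x", "y", "z"))
})

test_that("control paths decompose the worked example into two stems", {
  net <- fig1Network()
  cp <- controlPaths(net, maximumMatching(net))
  expect_equal(length(stems(cp)) + length(cycles(cp)), 2L)
  expect_identical(stems(cp), list(c("1", "4"), c("2", "3", "5")))
  expect_identical(cycles(cp), list())
})

test_that("stem-cycle covers partition the node set on random networks", {
  for (seed in 1:15) {
    net <- randomSmallNet(sample(4:8, 1), sample(0:14, 1), seed = seed + 100)
    m <- maximumMatching(net, seed = seed)
    cp <- controlPaths(net, m)
    covered <- c(unlist(stems(cp)), unlist(cycles(cp)))
    expect_setequal(covered, nodes(net))
    expect_false(anyDuplicated(covered) > 0)
    # one stem per unmatched-in node
    expect_equal(length(stems(cp)),
                 length(setdiff(nodes(net), links(m)[, 2L])))
    # every matched link consecutive in exactly one stem or cycle
    pathLinks <- c(
      unlist(lapply(stems(cp), function(s)
        if (length(s) > 1L) paste(s[-length(s)], s[-1L], sep = ">"))),
      unlist(lapply(cycles(cp), function(cc)
        unique(paste(cc, c(cc[-1L], cc[1L]), sep = ">"))))
    )
    matched <- paste(links(m)[, 1L], links(m)[, 2L], sep = ">")
    expect_setequal(pathLinks[!is.na(pathLinks)], matched)
  }
})

test_that("a cycle decomposes into one cycle and no stems", {
  cyc <- threeCycle()
  cp <- controlPaths(cyc, maximumMatching(cyc))
  expect_equal(length(stems(cp)), 0L)
  expect_identical(cycles(cp), list(c("a", "b", "c")))

  iso <- directedNetwork(matrix(character(0), ncol = 2), nodes = c("p", "q"))
  cpi <- controlPaths(iso, maximumMatching(iso))
  expect_identical(stems(cpi), list("p", "q"))
})

test_that("control paths refuse a matching from a different network", {
  other <- readEdgeList(text = "a\tb")
  expect_error(controlPaths(fig1Network(), maximumMatching(other)),
               "does not belong")
})

test_that("the Kalman rank oracle certifies the cactus and rejects missing inputs", {
  net <- fig1Network()
  expect_true(kalmanRankOracle(linearSystem(net, c("1", "2")), seed = 1))
  # node 2 receives no path from node 1 alone
  expect_false(kalmanRankOracle(linearSystem(net, "1"), seed = 1))
  one <- directedNetwork(matrix(c("v", "v"), ncol = 2))
  expect_true(kalmanRankOracle(linearSystem(one, "v"), seed = 1))
  big <- generateNetwork(20, 1, seed = 1)
  expect_error(kalmanRankOracle(linearSystem(big, "g01")), "12")
})
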