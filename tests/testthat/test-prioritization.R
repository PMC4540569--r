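# Hand-built profiles let scoring be tested without running the sampler:
# influence sets and annotations are chosen so scores are known exactly.
handProfile <- function(influence) {
  new("PerturbationProfile", influence = influence,
      nodes = names(influence), nMMSets = 1L)
}

test_that("candidate scores take the best match over known disease genes", {
  dag <- ontologyDAG(c("root", "u", "v", "w"),
                     parents = list(u = "root", v = "root", w = "root"))
  ann <- list(m1 = "u", m2 = "v", m3 = "w", i = "u", x = "u", y = "w")
  prof <- handProfile(list(
    i = c("m1", "m2"), x = c("m1", "m2"), y = "m3", z = character(0),
    m1 = character(0), m2 = character(0), m3 = character(0)))
  # identical influence sets, self-similarities 1: score = |Pi_x|
  expect_equal(scoreCandidate("i", c("x"), prof, ann, dag), 2)
  expect_equal(scoreCandidate("z", c("x", "y"), prof, ann, dag), 0)
  expect_error(scoreCandidate("i", character(0), prof, ann, dag), "empty")
  # max over several disease genes equals max of individual set similarities
  sims <- vapply(c("x", "y"), function(g)
    setSimilarity(prof@influence$i, prof@influence[[g]], ann, dag), numeric(1))
  expect_equal(scoreCandidate("i", c("x", "y"), prof, ann, dag), max(sims))
})

test_that("ranking orders by descending score with mean ranks for ties", {
  dag <- ontologyDAG(c("root", "u"), parents = list(u = "root"))
  ann <- list(a = "u", b = "u", c = "u", x = "u")
  prof <- handProfile(list(
    x = c("a", "b", "c"), g1 = c("a", "b", "c"), g2 = "a", g3 = c("a", "b"),
    a = character(0), b = character(0), c = character(0)))
  rl <- rankCandidates("d", c("g1", "g2", "g3"), "x", prof, ann, dag)
  expect_identical(rl$gene, c("g1", "g3", "g2"))
  expect_identical(rl$rank, c(1, 2, 3))
  expect_true(all(diff(rl$score) <= 0))
  expect_identical(attr(rl, "tiePolicy"), "mean")

  tied <- rankCandidates("d", c("g1", "g1b", "g2"), "x",
                         handProfile(list(
                           x = c("a", "b", "c"), g1 = c("a", "b", "c"),
                           g1b = c("a", "b", "c"), g2 = "a",
                           a = character(0), b = character(0),
                           c = character(0))),
                         ann, dag)
  expect_identical(tied$rank[1:2], c(1.5, 1.5))
})

test_that("LOO-CV ranks a twin gene first and recall reaches one", {
  b <- generateDiseaseBenchmark(nDiseases = 3L, genesPerDisease = 2L,
                                moduleSize = 4L, baseNodes = 40L,
                                samples = 500L, seed = 21)
  cv <- looCV(b$associations, b$profile, b$annotations, b$dag)
  # planted genes share their module's influence: held-out twin ranks top
  expect_lte(stats::median(cv$trials$rank), 3)
  expect_equal(cv$recall$recall[cv$recall$k == 100], 1)
  expect_true(all(diff(cv$recall$recall) >= 0))
  expect_equal(nrow(cv$trials), 6L)
})

test_that("diseases with a single gene are skipped with a warning", {
  b <- generateDiseaseBenchmark(nDiseases = 2L, genesPerDisease = 2L,
                                moduleSize = 3L, baseNodes = 30L,
                                samples = 300L, seed = 31)
  assoc <- b$associations
  assoc[[1L]] <- assoc[[1L]][1L]  # cripple one disease
  expect_warning(cv <- looCV(assoc, b$profile, b$annotations, b$dag),
                 "fewer than 2")
  expect_equal(nrow(cv$trials), 2L)
})

test_that("held-out ranks are invariant to relabeling background genes", {
  dag <- ontologyDAG(c("root", "u", "v"), parents = list(u = "root", v = "root"))
  prof1 <- handProfile(list(x = "m", y = "m", bg = "q",
                            m = character(0), q = character(0)))
  ann1 <- list(x = "u", y = "u", bg = "v", m = "u", q = "v")
  cv1 <- looCV(list(d = c("x", "y")), prof1, ann1, dag)
  # rename bg -> zz everywhere
  prof2 <- handProfile(list(x = "m", y = "m", zz = "q",
                            m = character(0), q = character(0)))
  ann2 <- list(x = "u", y = "u", zz = "v", m = "u", q = "v")
  cv2 <- looCV(list(d = c("x", "y")), prof2, ann2, dag)
  expect_identical(cv1$trials$rank, cv2$trials$rank)
})

test_that("k-fold CV partitions reproducibly and reports a rank-sum AUC", {
  b <- generateDiseaseBenchmark(nDiseases = 3L, genesPerDisease = 3L,
                                moduleSize = 4L, baseNodes = 40L,
                                samples = 600L, seed = 41)
  cv2 <- suppressWarnings(
    kfoldCV(b$associations, folds = 2L, seed = 7, b$profile,
            b$annotations, b$dag))
  expect_gte(cv2$auc, 0.9)  # planted modules separate essentially perfectly
  again <- suppressWarnings(
    kfoldCV(b$associations, folds = 2L, seed = 7, b$profile,
            b$annotations, b$dag))
  expect_identical(cv2$trials, again$trials)
  expect_error(kfoldCV(list(d = c("a", "b")), folds = 5L, seed = 1,
                       b$profile, b$annotations, b$dag),
               "fewer associations")
})

test_that("the rank-sum AUC matches pairwise counting and random baselines", {
  pos <- withr::with_seed(1, runif(10))
  neg <- withr::with_seed(2, runif(50))
  expect_equal(aucFromScores(pos, neg), bruteAUC(pos, neg))
  # ties count one half
  expect_equal(aucFromScores(c(1, 1), c(1, 0)), bruteAUC(c(1, 1), c(1, 0)))
  # perfect separation
  expect_equal(aucFromScores(c(5, 6), c(1, 2, 3)), 1)
  # random scores: AUC ~ 0.5 across many replicates
  aucs <- withr::with_seed(3, vapply(1:1000, function(i)
    aucFromScores(runif(5), runif(20)), numeric(1)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
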