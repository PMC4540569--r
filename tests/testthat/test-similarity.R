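toyDAG <- function() {
  ontologyDAG(c("root", "a", "t1", "t2", "b", "t3"),
              parents = list(a = "root", t1 = "a", t2 = "a",
                             b = "root", t3 = "b"))
}

test_that("term similarity reproduces the hand-computed toy values", {
  dag <- toyDAG()
  expect_equal(termSimilarity("t1", "t1", dag), 1)
  # siblings under one parent, all is_a with w = 0.8:
  # S-values 1, 0.8, 0.64; shared {a, root}
  expect_equal(termSimilarity("t1", "t2", dag),
               (0.8 + 0.8 + 0.64 + 0.64) / (2 * (1 + 0.8 + 0.64)))
  # sharing only the root is weaker than siblinghood, but positive
  farSim <- termSimilarity("t1", "t3", dag)
  expect_gt(farSim, 0)
  expect_lt(farSim, termSimilarity("t1", "t2", dag))
  expect_equal(termSimilarity("t1", "t2", dag), termSimilarity("t2", "t1", dag))
  expect_error(termSimilarity("t1", "zzz", dag), "unknown term")
})

test_that("cross-namespace pairs score zero with a warning", {
  dag <- ontologyDAG(c("r1", "r2"), namespace = c(r1 = "biological_process",
                                                  r2 = "molecular_function"))
  expect_warning(s <- termSimilarity("r1", "r2", dag), "cross-namespace")
  expect_equal(s, 0)
})

test_that("term similarity matches an independent recursive oracle", {
  for (seed in 1:10) {
    dag <- generateOntology(4, 2, seed = seed, partOfFraction = 0.3)
    picks <- withr::with_seed(seed, {
      cbind(sample(ontologyTerms(dag), 6, replace = TRUE),
            sample(ontologyTerms(dag), 6, replace = TRUE))
    })
    for (i in seq_len(nrow(picks)))
      expect_equal(termSimilarity(picks[i, 1L], picks[i, 2L], dag),
                   oracleTermSim(picks[i, 1L], picks[i, 2L], dag))
  }
})

test_that("gene similarity is the best-match average of term pairs", {
  dag <- toyDAG()
  ann <- list(g1 = c("t1", "t2"), g2 = c("t1", "t2"), g3 = c("t2", "t3", "b"),
              g4 = "t1", g5 = "t3")
  expect_equal(geneSimilarity("g1", "g2", ann, dag), 1)
  expect_equal(geneSimilarity("g4", "g5", ann, dag),
               termSimilarity("t1", "t3", dag))
  # brute-force BMA over the 2 x 3 term grid
  grid <- outer(ann$g1, ann$g3,
                Vectorize(function(x, y) termSimilarity(x, y, dag)))
  bma <- (sum(apply(grid, 1, max)) + sum(apply(grid, 2, max))) / (2 + 3)
  expect_equal(geneSimilarity("g1", "g3", ann, dag), bma)
  expect_equal(geneSimilarity("g1", "g3", ann, dag),
               geneSimilarity("g3", "g1", ann, dag))
  expect_warning(s <- geneSimilarity("g1", "nope", ann, dag), "unannotated")
  expect_equal(s, 0)
})

test_that("set similarity solves the assignment exactly on small grids", {
  dag <- toyDAG()
  ann <- list(g1 = c("t1", "t2"), g2 = "t2", g3 = "t3", g4 = "t1", g5 = "b")
  expect_equal(setSimilarity("g1", "g1", ann, dag), 1)
  expect_equal(setSimilarity(character(0), c("g1"), ann, dag), 0)

  A <- c("g1", "g2", "g3"); B <- c("g4", "g5")
  grid <- outer(A, B, Vectorize(function(x, y) geneSimilarity(x, y, ann, dag)))
  expect_equal(setSimilarity(A, B, ann, dag), bruteAssignment(grid))
  expect_equal(setSimilarity(A, B, ann, dag), setSimilarity(B, A, ann, dag))
  # adding a gene never decreases the unnormalized similarity
  expect_gte(setSimilarity(c(A, "g5"), B, ann, dag),
             setSimilarity(A, B, ann, dag))
  # normalized variant divides by the larger set size
  expect_equal(setSimilarity(A, B, ann, dag, normalized = TRUE),
               setSimilarity(A, B, ann, dag) / 3)
})

test_that("the assignment solver equals brute force on random grids", {
  for (seed in 1:30) {
    grid <- withr::with_seed(seed, {
      nr <- sample(2:6, 1); nc <- sample(2:6, 1)
      matrix(runif(nr * nc), nr, nc)
    })
    expect_equal(ctrlpaths:::maxWeightAssignment(grid), bruteAssignment(grid))
  }
})

test_that("identity sets with maximal self-similarity sum the diagonal", {
  dag <- toyDAG()
  ann <- list(g1 = "t1", g2 = "t2", g3 = "t3")
  X <- c("g1", "g2", "g3")
  expect_equal(setSimilarity(X, X, ann, dag),
               sum(vapply(X, function(g) geneSimilarity(g, g, ann, dag),
                          numeric(1))))
})

test_that("OBO files round-trip and obsolete or dangling terms are dropped", {
  dag <- generateOntology(3, 3, seed = 2, partOfFraction = 0.3)
  path <- withr::local_tempfile(fileext = ".obo")
  writeOBO(dag, path)
  back <- readOBO(path)
  expect_identical(ontologyTerms(back), ontologyTerms(dag))
  expect_identical(back@parents, dag@parents)
  expect_identical(back@relations, dag@relations)

  text <- c("[Term]", "id: A", "namespace: biological_process", "",
            "[Term]", "id: B", "is_a: A", "is_a: GONE", "",
            "[Term]", "id: C", "is_a: A", "is_obsolete: true", "")
  small <- readOBO(text = text)
  expect_setequal(ontologyTerms(small), c("A", "B"))
  expect_identical(small@parents$B, "A")
})

test_that("annotation readers handle TSV, GAF and unknown terms", {
  dag <- toyDAG()
  ann <- readAnnotations(text = c("# c", "g1\tt1", "g1\tt2", "g2\tt3"),
                         dag = dag)
  expect_identical(ann, list(g1 = c("t1", "t2"), g2 = "t3"))
  expect_warning(
    dropped <- readAnnotations(text = c("g1\tt1", "g1\twhat"), dag = dag),
    "absent")
  expect_identical(dropped, list(g1 = "t1"))

  gaf <- c("!gaf-version: 2.1",
           paste("DB", "X1", "g1", "", "t1", "PMID:1", "IEA", "", "P",
                 sep = "\t"),
           paste("DB", "X2", "g2", "", "t3", "PMID:1", "IEA", "", "P",
                 sep = "\t"))
  expect_identical(readAnnotations(text = gaf, format = "gaf"),
                   list(g1 = "t1", g2 = "t3"))
})
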