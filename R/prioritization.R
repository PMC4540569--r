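# Candidate-gene scoring and cross-validated evaluation.

#' Score a candidate gene against a disease's known genes
#'
#' score(i) = max over known disease genes x of sim(Pi_i, Pi_x): the
#' candidate's perturbation influence is compared with each known gene's
#' influence by maximum-weight bipartite matching of gene similarities,
#' and the best match is the score.
#'
#' @param gene candidate gene identifier (a network node)
#' @param diseaseGenes non-empty character vector of known disease genes
#' @param profile a [PerturbationProfile-class]
#' @param ann named list, gene -> terms
#' @param dag an [OntologyDAG-class]
#' @param weights relation decay factors, see [defaultSemanticWeights()]
#' @param cache optional [similarityCache()]
#' @param normalized normalize set similarities (default `FALSE`)
#' @return numeric score >= 0
#' @export
scoreCandidate <- function(gene, diseaseGenes, profile, ann, dag,
                           weights = defaultSemanticWeights(), cache = NULL,
                           normalized = FALSE) {
  if (length(diseaseGenes) == 0L) stop("empty disease gene set")
  if (!gene %in% profile@nodes) stop("unknown node: ", gene)
  unknown <- setdiff(diseaseGenes, profile@nodes)
  if (length(unknown)) stop("unknown node: ", unknown[1L])
  Pi_i <- profile@influence[[gene]]
  max(vapply(diseaseGenes, function(x) {
    setSimilarity(Pi_i, profile@influence[[x]], ann, dag, weights, cache,
                  normalized)
  }, numeric(1)))
}

#' Rank candidate genes for a disease
#'
#' Scores every candidate by [scoreCandidate()] and orders them by
#' descending score. Ties receive the mean of the tied rank positions
#' (deterministic, order-independent).
#'
#' @param disease disease identifier (carried into the result)
#' @param candidates character vector of candidate genes (network nodes)
#' @param diseaseGenes known disease genes to score against
#' @inheritParams scoreCandidate
#' @return data frame with columns `disease`, `gene`, `score`, `rank`,
#'   ordered by decreasing score; attribute `tiePolicy = "mean"`
#' @export
rankCandidates <- function(disease, candidates, diseaseGenes, profile, ann,
                           dag, weights = defaultSemanticWeights(),
                           cache = NULL, normalized = FALSE) {
  cache <- cache %||% similarityCache()
  scores <- vapply(candidates, function(g) {
    scoreCandidate(g, diseaseGenes, profile, ann, dag, weights, cache,
                   normalized)
  }, numeric(1))
  rk <- rank(-scores, ties.method = "average")
  out <- data.frame(disease = disease, gene = candidates, score = scores,
                    rank = rk, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tiePolicy") <- "mean"
  out
}

# Pairwise sim(Pi_i, Pi_x) for pool genes against a disease's genes,
# memoized per (i, x) pair; the expensive inner loop of every CV trial.
diseaseSimMatrix <- function(universe, diseaseGenes, profile, ann, dag,
                             weights, cache, normalized) {
  simMat <- matrix(0, length(universe), length(diseaseGenes),
                   dimnames = list(universe, diseaseGenes))
  for (x in diseaseGenes) {
    Pi_x <- profile@influence[[x]]
    for (i in universe) {
      key <- paste0("s|", i, "\r", x)
      v <- cacheGet(cache, key)
      if (is.null(v))
        v <- cacheSet(cache, key,
                      setSimilarity(profile@influence[[i]], Pi_x, ann, dag,
                                    weights, cache, normalized))
      simMat[i, x] <- v
    }
  }
  simMat
}

# Candidate universe for cross-validation.
cvUniverse <- function(pool, profile, ann) {
  switch(pool,
    annotated = intersect(profile@nodes, names(ann)),
    all = profile@nodes,
    stop("pool must be 'annotated' or 'all'"))
}

#' Leave-one-out cross-validation of disease-gene prioritization
#'
#' For every association (d, g): g is withheld, scored against the
#' remaining genes of d, and ranked within the candidate pool (all
#' annotated network genes — or all network genes with `pool = "all"` —
#' minus the training genes). Recall at k% is the fraction of trials whose
#' withheld gene ranked within the top k% of its pool.
#'
#' Diseases with fewer than 2 genes are skipped with a warning.
#' Perturbation influences do not depend on disease labels, so one
#' profile is computed per network and shared across all trials.
#'
#' @param assoc named list, disease -> character vector of genes (all in
#'   the network)
#' @param profile a [PerturbationProfile-class]
#' @param ann named list, gene -> terms
#' @param dag an [OntologyDAG-class]
#' @param pool `"annotated"` (default) or `"all"`
#' @param kGrid integer percentages for the recall curve (default 1:100)
#' @param weights relation decay factors
#' @param cache optional [similarityCache()]
#' @param normalized normalize set similarities
#' @return a `cvReport`: list with `trials` (data frame: disease, gene,
#'   rank, poolSize), `recall` (data frame: k, recall) and `auc` (mean
#'   per-trial AUC)
#' @export
looCV <- function(assoc, profile, ann, dag, pool = c("annotated", "all"),
                  kGrid = 1:100, weights = defaultSemanticWeights(),
                  cache = NULL, normalized = FALSE) {
  pool <- match.arg(pool)
  small <- names(assoc)[lengths(assoc) < 2L]
  if (length(small)) {
    warning("skipping disease(s) with fewer than 2 genes: ",
            paste(small, collapse = ", "))
    assoc <- assoc[lengths(assoc) >= 2L]
  }
  heldout <- do.call(rbind, lapply(names(assoc), function(d) {
    data.frame(disease = d, gene = assoc[[d]], stringsAsFactors = FALSE)
  }))
  trials <- cvRun(assoc, heldout, profile, ann, dag, pool, weights, cache,
                  normalized)
  makeCVReport(trials, kGrid)
}

#' k-fold cross-validation with AUC
#'
#' Associations are partitioned into `folds` random folds (seeded); each
#' fold is withheld in turn and its genes are ranked against the
#' remaining genes of their disease. Each trial contributes a rank-based
#' AUC (withheld gene = positive, rest of the pool = negatives); the
#' report's AUC is the mean across trials. Trials whose disease loses all
#' its training genes to the fold are skipped with a warning.
#'
#' @inheritParams looCV
#' @param folds number of folds (>= 2)
#' @param seed integer seed for the fold assignment
#' @return a `cvReport`, as [looCV()], with `auc` populated
#' @export
kfoldCV <- function(assoc, folds, seed, profile, ann, dag,
                    pool = c("annotated", "all"), kGrid = 1:100,
                    weights = defaultSemanticWeights(), cache = NULL,
                    normalized = FALSE) {
  pool <- match.arg(pool)
  if (folds < 2L) stop("folds must be at least 2")
  assoc <- assoc[lengths(assoc) >= 2L]
  pairs <- do.call(rbind, lapply(names(assoc), function(d) {
    data.frame(disease = d, gene = assoc[[d]], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) < folds)
    stop("fewer associations than folds")
  fold <- withSeed(seed, sample(rep(seq_len(folds), length.out = nrow(pairs))))
  cache <- cache %||% similarityCache()
  perFold <- lapply(seq_len(folds), function(f) {
    held <- pairs[fold == f, , drop = FALSE]
    if (nrow(held) == 0L) return(NULL)
    # genes of this fold are removed from their disease's training set
    cvRun(assoc, held, profile, ann, dag, pool, weights, cache,
          normalized, foldHeld = held)
  })
  makeCVReport(do.call(rbind, perFold), kGrid)
}

# Shared CV engine returning one row per usable trial. For LOO, each
# heldout row trains on its disease minus that gene; for k-fold
# (`foldHeld` given), training removes every fold gene of the disease.
cvRun <- function(assoc, heldout, profile, ann, dag, pool, weights, cache,
                  normalized, foldHeld = NULL) {
  cache <- cache %||% similarityCache()
  # known disease genes always belong to the universe, annotated or not
  universe <- union(cvUniverse(pool, profile, ann),
                    intersect(unlist(assoc), profile@nodes))
  rows <- vector("list", nrow(heldout))
  for (d in unique(heldout$disease)) {
    genes <- assoc[[d]]
    simMat <- diseaseSimMatrix(universe, genes, profile, ann, dag, weights,
                               cache, normalized)
    idx <- which(heldout$disease == d)
    for (j in idx) {
      g <- heldout$gene[j]
      removed <- if (is.null(foldHeld)) g
                 else foldHeld$gene[foldHeld$disease == d]
      training <- setdiff(genes, removed)
      if (length(training) == 0L) {
        warning("no training genes left for disease ", d, "; trial skipped")
        next
      }
      poolGenes <- union(setdiff(universe, training), g)
      scores <- apply(simMat[poolGenes, training, drop = FALSE], 1L, max)
      rk <- rank(-scores, ties.method = "average")
      trialAUC <- aucFromScores(scores[[g]], scores[names(scores) != g])
      rows[[j]] <- data.frame(disease = d, gene = g, rank = unname(rk[[g]]),
                              poolSize = length(poolGenes), auc = trialAUC,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

makeCVReport <- function(trials, kGrid) {
  if (is.null(trials) || nrow(trials) == 0L)
    stop("no usable cross-validation trials")
  recall <- vapply(kGrid, function(k) {
    mean(trials$rank <= (k / 100) * trials$poolSize)
  }, numeric(1))
  structure(list(trials = trials,
                 recall = data.frame(k = kGrid, recall = recall),
                 auc = mean(trials$auc)),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("cvReport: %d trials, mean AUC %.3f, median rank %.1f of %.0f\n",
              nrow(x$trials), x$auc, stats::median(x$trials$rank),
              stats::median(x$trials$poolSize)))
  invisible(x)
}

#' Rank-sum AUC of positive vs negative scores
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half: AUC = (R_pos - P(P+1)/2) / (P * N) with R_pos the
#' positives' rank sum in the pooled ranking.
#'
#' @param posScores,negScores numeric vectors (each non-empty)
#' @return numeric in \[0, 1\]
#' @export
aucFromScores <- function(posScores, negScores) {
  P <- length(posScores); N <- length(negScores)
  if (P == 0L || N == 0L) stop("need both positive and negative scores")
  r <- rank(c(posScores, negScores), ties.method = "average")
  (sum(r[seq_len(P)]) - P * (P + 1) / 2) / (P * N)
}
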