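# Wang-style semantic similarity and set-set similarity by maximum-weight
# bipartite matching.

#' Default semantic-contribution weights per relation type
#'
#' Wang et al.'s published defaults: 0.8 for `is_a`, 0.6 for `part_of`.
#' @return named numeric vector
#' @export
defaultSemanticWeights <- function() c(is_a = 0.8, part_of = 0.6)

# S-values of `term`: semantic contribution of every ancestor a, defined by
# S(term) = 1 and S(a) = max over children c on paths toward `term` of
# w(rel) * S(c). Monotone relaxation over the ancestor closure.
semanticContributions <- function(term, dag, weights = defaultSemanticWeights()) {
  S <- structure(1, names = term)
  queue <- term
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    ps <- dag@parents[[t]]; rs <- dag@relations[[t]]
    for (k in seq_along(ps)) {
      w <- weights[[rs[k]]] %||% 0
      val <- w * S[[t]]
      if (is.na(S[ps[k]]) || val > S[[ps[k]]]) {
        S[[ps[k]]] <- val
        queue <- c(queue, ps[k])
      }
    }
  }
  S
}

#' Semantic similarity of two ontology terms
#'
#' Wang's measure: each term's ancestors receive S-values (semantic
#' contributions) decaying multiplicatively along child-to-parent edges,
#' with the term itself at 1; similarity is the summed S-values over the
#' shared ancestor closure divided by the two semantic values,
#' sim = sum over shared t of (S1(t) + S2(t)) / (SV(t1) + SV(t2)).
#' Symmetric, in \[0, 1\], and 1 for identical terms.
#'
#' @param t1,t2 term identifiers present in `dag`
#' @param dag an [OntologyDAG-class]
#' @param weights named numeric, relation type -> decay factor (see
#'   [defaultSemanticWeights()])
#' @return numeric in \[0, 1\]; cross-namespace pairs give 0 with a warning
#' @export
termSimilarity <- function(t1, t2, dag, weights = defaultSemanticWeights()) {
  if (!t1 %in% dag@terms) stop("unknown term: ", t1)
  if (!t2 %in% dag@terms) stop("unknown term: ", t2)
  if (dag@namespace[[t1]] != dag@namespace[[t2]]) {
    warning("cross-namespace term pair (", t1, ", ", t2, "); similarity 0")
    return(0)
  }
  S1 <- semanticContributions(t1, dag, weights)
  S2 <- semanticContributions(t2, dag, weights)
  common <- intersect(names(S1), names(S2))
  if (length(common) == 0L) return(0)
  sum(S1[common] + S2[common]) / (sum(S1) + sum(S2))
}

#' A memoization cache for gene- and term-pair similarities
#'
#' The prioritization loop reuses pairwise gene similarities heavily;
#' passing one cache through [geneSimilarity()] / [setSimilarity()] /
#' [scoreCandidate()] makes them computed once.
#'
#' @return an environment usable as the `cache` argument downstream
#' @export
similarityCache <- function() new.env(parent = emptyenv())

cacheGet <- function(cache, key) {
  if (is.null(cache)) NULL else cache[[key]]
}
cacheSet <- function(cache, key, value) {
  if (!is.null(cache)) assign(key, value, envir = cache)
  value
}

#' Best-match-average similarity of two genes
#'
#' GOSim_BMA: every term of one gene is matched to its most similar term
#' of the other gene, in both directions, and the matches are averaged:
#' (sum of row maxima + sum of column maxima) / (|T1| + |T2|) over the
#' term-similarity grid. Symmetric; 1 for identical annotation sets
#' (self-matches), 0 for an unannotated gene (with a warning).
#'
#' @param g1,g2 gene identifiers
#' @param ann named list, gene -> character vector of term identifiers
#' @param dag an [OntologyDAG-class]
#' @param weights relation decay factors, see [defaultSemanticWeights()]
#' @param cache optional [similarityCache()]
#' @return numeric in \[0, 1\]
#' @export
geneSimilarity <- function(g1, g2, ann, dag,
                           weights = defaultSemanticWeights(), cache = NULL) {
  key <- paste0("g|", paste(sort(c(g1, g2)), collapse = "\r"))
  hit <- cacheGet(cache, key)
  if (!is.null(hit)) return(hit)
  T1 <- ann[[g1]] %||% character(0)
  T2 <- ann[[g2]] %||% character(0)
  if (length(T1) == 0L || length(T2) == 0L) {
    warning("unannotated gene (", if (length(T1)) g2 else g1, "); similarity 0")
    return(cacheSet(cache, key, 0))
  }
  grid <- matrix(0, length(T1), length(T2))
  for (i in seq_along(T1)) {
    for (j in seq_along(T2)) {
      tkey <- paste0("t|", paste(sort(c(T1[i], T2[j])), collapse = "\r"))
      v <- cacheGet(cache, tkey)
      if (is.null(v))
        v <- cacheSet(cache, tkey,
                      suppressWarnings(termSimilarity(T1[i], T2[j], dag, weights)))
      grid[i, j] <- v
    }
  }
  bma <- (sum(apply(grid, 1L, max)) + sum(apply(grid, 2L, max))) /
    (length(T1) + length(T2))
  cacheSet(cache, key, bma)
}

#' Functional similarity of two gene sets by maximum-weight matching
#'
#' The sim(Pi_i, Pi_x) of the prioritization score: builds the bipartite
#' graph whose edge weights are pairwise [geneSimilarity()] values and
#' returns the total weight of a maximum-weight bipartite matching
#' (Hungarian algorithm via [clue::solve_LSAP()]). The value is the plain
#' sum of matched weights — intentionally unnormalized, so larger
#' coherent influence sets score higher; `normalized = TRUE` divides by
#' the larger set size instead.
#'
#' @param PiA,PiB character vectors of gene identifiers (either may be
#'   empty, giving 0)
#' @param ann named list, gene -> terms
#' @param dag an [OntologyDAG-class]
#' @param weights relation decay factors
#' @param cache optional [similarityCache()]
#' @param normalized divide by `max(|PiA|, |PiB|)` (default `FALSE`)
#' @return numeric >= 0
#' @export
setSimilarity <- function(PiA, PiB, ann, dag,
                          weights = defaultSemanticWeights(), cache = NULL,
                          normalized = FALSE) {
  PiA <- unique(as.character(PiA)); PiB <- unique(as.character(PiB))
  if (length(PiA) == 0L || length(PiB) == 0L) return(0)
  grid <- matrix(0, length(PiA), length(PiB))
  for (i in seq_along(PiA))
    for (j in seq_along(PiB))
      grid[i, j] <- suppressWarnings(
        geneSimilarity(PiA[i], PiB[j], ann, dag, weights, cache))
  total <- maxWeightAssignment(grid)
  if (normalized) total / max(length(PiA), length(PiB)) else total
}

# Maximum total weight over injective row->column assignments of a
# rectangular non-negative grid (solve_LSAP needs nrow <= ncol).
maxWeightAssignment <- function(grid) {
  flipped <- nrow(grid) > ncol(grid)
  if (flipped) grid <- t(grid)
  sol <- clue::solve_LSAP(grid, maximum = TRUE)
  sum(grid[cbind(seq_len(nrow(grid)), as.integer(sol))])
}
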