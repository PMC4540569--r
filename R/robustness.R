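#' Stability of perturbation influence under random edge removal
#'
#' SPi: remove a fixed fraction of links uniformly at random, recompute
#' every node's perturbation influence on the reduced network with the
#' same MMSet sampling budget, and average the per-node Jaccard overlap
#' between the influences before (Pi) and after (Pi'):
#' SPi = (1/n) * sum_i |Pi_i intersect Pi_i'| / |Pi_i union Pi_i'|.
#' A node with Pi = Pi' = empty contributes 1 (0/0 convention: a node
#' with no influence is perfectly stable) — note this inflates SPi on
#' sparse networks. Nodes are never removed, only links.
#'
#' Each repetition draws a fresh removal and a fresh sampling seed from
#' the master seed by an explicit counter, so a report is reproducible.
#'
#' @param net a [DirectedNetwork-class]
#' @param fraction fraction of links to remove, in \[0, 1)
#' @param reps number of randomized repetitions (default 20)
#' @param samples MMSet sampling budget passed to [sampleMMSets()] for the
#'   intact and every reduced network
#' @param seed optional master seed
#' @param restarts walk restarts for [sampleMMSets()]
#' @return a `stabilityReport`: list with `fraction`, `spi` (per-rep
#'   values), `mean`, `sd`
#' @export
spi <- function(net, fraction, reps = 20L, samples = 100L, seed = NULL,
                restarts = 1L) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)")
  stopifnot(reps >= 1L)
  seeds <- deriveSeeds(seed %||% sample.int(.Machine$integer.max, 1L),
                       2L * reps + 1L)
  base <- perturbationProfile(
    sampleMMSets(net, samples, seed = seeds[1L], restarts = restarts))
  nRemove <- floor(fraction * numLinks(net))
  vals <- vapply(seq_len(reps), function(r) {
    if (nRemove == 0L) return(1)  # nothing removed: Pi' = Pi exactly
    keep <- withSeed(seeds[2L * r], {
      drop <- sample.int(numLinks(net), nRemove)
      setdiff(seq_len(numLinks(net)), drop)
    })
    reduced <- directedNetwork(net@links[keep, , drop = FALSE],
                               nodes = net@nodes)
    prof <- perturbationProfile(
      sampleMMSets(reduced, samples, seed = seeds[2L * r + 1L],
                   restarts = restarts))
    meanJaccard(base@influence, prof@influence)
  }, numeric(1))
  structure(list(fraction = fraction, spi = vals, mean = mean(vals),
                 sd = stats::sd(vals)),
            class = "stabilityReport")
}

meanJaccard <- function(before, after) {
  stopifnot(identical(names(before), names(after)))
  mean(vapply(names(before), function(v) {
    a <- before[[v]]; b <- after[[v]]
    u <- union(a, b)
    if (length(u) == 0L) 1 else length(intersect(a, b)) / length(u)
  }, numeric(1)))
}

#' @export
print.stabilityReport <- function(x, ...) {
  cat(sprintf("SPi at %.0f%% edge removal: mean %.3f (sd %.3f) over %d rep(s)\n",
              100 * x$fraction, x$mean, if (is.na(x$sd)) 0 else x$sd,
              length(x$spi)))
  invisible(x)
}
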