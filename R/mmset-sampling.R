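#' All single-link alternative completions of a matching
#'
#' Given a matching and one of its links, returns every matching of the
#' same cardinality that contains all the other links: the held-out link
#' is removed and every network link from a tail unmatched in the
#' remainder to a head unmatched in the remainder completes it. The input
#' matching is always among the results. This is the elementary move of
#' the diversified-MMSet random walk.
#'
#' @param net a [DirectedNetwork-class]
#' @param m a [Matching-class] of `net`
#' @param link length-2 character vector `c(tail, head)`, a link of `m`
#' @return list of [Matching-class] objects, each of cardinality
#'   `matchingSize(m)`
#' @export
alternativeCompletions <- function(net, m, link) {
  link <- as.character(link)
  keys <- linkKeys(m@links)
  hit <- which(keys == paste(link[1L], link[2L], sep = "\r"))
  if (length(hit) != 1L) stop("link is not part of the matching")
  base <- m@links[-hit, , drop = FALSE]
  freeTail <- !(net@links[, 1L] %in% base[, 1L])
  freeHead <- !(net@links[, 2L] %in% base[, 2L])
  cand <- net@links[freeTail & freeHead, , drop = FALSE]
  lapply(seq_len(nrow(cand)), function(i) {
    new("Matching", links = canonicalLinks(rbind(base, cand[i, ])),
        network = net)
  })
}

#' Sample diversified MMSets by a link-swap random walk
#'
#' Starting from one maximum matching, repeatedly chooses a matched link
#' uniformly at random, enumerates all alternative completions
#' ([alternativeCompletions()]), moves to one chosen uniformly, and
#' records every visited state (including repeats of the current one).
#' The distinct MMSets seen after `nSamples` recorded states form the
#' collection whose control paths are the network's DCpaths.
#'
#' Single-link swaps may not connect all MMSets on adversarial graphs;
#' `restarts` runs several independent walks from differently seeded
#' initial matchings and merges the results. `window` switches to a
#' convergence stopping rule: the walk ends early once no new MMSet has
#' appeared within that many consecutive samples.
#'
#' @param net a [DirectedNetwork-class]
#' @param nSamples number of walk states to record per walk (>= 1)
#' @param seed optional master seed; identical seeds reproduce the
#'   collection exactly
#' @param restarts number of independent walks (default 1)
#' @param window optional integer; stop a walk early after this many
#'   consecutive samples without a new MMSet
#' @return an [MMSetCollection-class]
#' @examples
#' net <- readEdgeList(text = c("a\tb", "a\tc"))
#' numMMSets(sampleMMSets(net, 50, seed = 1))  # 2
#' @export
sampleMMSets <- function(net, nSamples, seed = NULL, restarts = 1L,
                         window = NULL) {
  stopifnot(nSamples >= 1L, restarts >= 1L)
  seeds <- if (is.null(seed)) rep(list(NULL), restarts)
           else as.list(deriveSeeds(seed, restarts))
  found <- list()
  taken <- 0L
  for (r in seq_len(restarts)) {
    walk <- mmsetWalk(net, nSamples, seeds[[r]], window)
    taken <- taken + walk$samples
    for (key in names(walk$found))
      if (is.null(found[[key]])) found[[key]] <- walk$found[[key]]
  }
  new("MMSetCollection", mmsets = unname(found[sort(names(found))]),
      network = net, samplesTaken = taken,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# One random walk; returns found (keyed canonical matrices) and sample count.
mmsetWalk <- function(net, nSamples, seed, window) {
  withSeed(seed, {
    m <- maximumMatching(net, seed = sample.int(.Machine$integer.max, 1L))
    found <- list()
    found[[matchingKey(m@links)]] <- m@links
    samples <- 1L
    sinceNew <- 0L
    while (samples < nSamples && matchingSize(m) > 0L) {
      pick <- sample.int(matchingSize(m), 1L)
      comps <- alternativeCompletions(net, m, m@links[pick, ])
      m <- comps[[sample.int(length(comps), 1L)]]
      samples <- samples + 1L
      key <- matchingKey(m@links)
      if (is.null(found[[key]])) {
        found[[key]] <- m@links
        sinceNew <- 0L
      } else {
        sinceNew <- sinceNew + 1L
      }
      if (!is.null(window) && sinceNew >= window) break
    }
    list(found = found, samples = samples)
  })
}

#' Exhaustively enumerate all maximum matchings of a small network
#'
#' Backtracking over the canonical link order with endpoint-disjointness
#' pruning; the independent oracle the sampler is tested against.
#' Restricted to networks with at most 20 links.
#'
#' @param net a [DirectedNetwork-class] with `numLinks(net) <= 20`
#' @return an [MMSetCollection-class] holding every MMSet
#' @export
enumerateAllMMSets <- function(net) {
  L <- numLinks(net)
  if (L > 20L)
    stop("exhaustive enumeration restricted to networks with at most 20 links")
  best <- matchingSize(maximumMatching(net))
  lk <- net@links
  results <- list()
  recurse <- function(i, chosen) {
    if (length(chosen) + (L - i + 1L) < best) return(invisible())
    if (i > L) {
      if (length(chosen) == best) {
        m <- canonicalLinks(lk[chosen, , drop = FALSE])
        results[[matchingKey(m)]] <<- m
      }
      return(invisible())
    }
    tailUsed <- lk[i, 1L] %in% lk[chosen, 1L]
    headUsed <- lk[i, 2L] %in% lk[chosen, 2L]
    if (!tailUsed && !headUsed) recurse(i + 1L, c(chosen, i))
    recurse(i + 1L, chosen)
  }
  recurse(1L, integer(0))
  new("MMSetCollection", mmsets = unname(results[sort(names(results))]),
      network = net, samplesTaken = 0L, seed = NA_integer_)
}
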