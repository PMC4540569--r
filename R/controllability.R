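#' Maximum matching of a directed network
#'
#' Computes a maximum-cardinality matching on the bipartite split graph:
#' each node v is split into an out-copy v+ and an in-copy v-, and a link
#' (u, w) becomes the bipartite edge (u+, w-). No two matched links share a
#' tail or a head. A maximum matching determines the minimum driver set:
#' N_D = max(n - |M|, 1) nodes must receive external control input.
#'
#' Augmenting-path search (Kuhn's algorithm); deterministic given node
#' order. `seed` permutes the node and adjacency order, which selects among
#' equally large matchings and is how diversified MMSets are first reached.
#' Self-loops are matchable (out-copy to in-copy of the same node).
#'
#' @param net a [DirectedNetwork-class], non-empty
#' @param seed optional integer controlling tie-breaking
#' @return a [Matching-class] of maximum cardinality
#' @examples
#' net <- readEdgeList(text = c("1\t3", "1\t4", "2\t3", "3\t5"))
#' matchingSize(maximumMatching(net))  # 3
#' @export
maximumMatching <- function(net, seed = NULL) {
  n <- numNodes(net)
  if (n == 0L) stop("network has no nodes")
  tails <- match(net@links[, 1L], net@nodes)
  heads <- match(net@links[, 2L], net@nodes)
  adj <- split(heads, factor(tails, levels = seq_len(n)))
  order <- seq_len(n)
  if (!is.null(seed)) {
    withSeed(seed, {
      order <- sample.int(n)
      adj <- lapply(adj, function(v) if (length(v) > 1L) sample(v) else v)
    })
  }
  matchOfHead <- rep(NA_integer_, n)  # in-copy -> matched tail
  visited <- logical(n)
  tryAugment <- function(u) {
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <<- TRUE
        if (is.na(matchOfHead[v]) || tryAugment(matchOfHead[v])) {
          matchOfHead[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (u in order) {
    visited[] <- FALSE
    tryAugment(u)
  }
  matched <- which(!is.na(matchOfHead))
  lk <- canonicalLinks(cbind(net@nodes[matchOfHead[matched]], net@nodes[matched]))
  new("Matching", links = lk, network = net)
}

#' Minimum number of driver nodes
#'
#' N_D = max(n - |M|, 1): the number of nodes that must receive external
#' control input for full structural control. Invariant across all MMSets
#' of a network since maximum-matching cardinality is unique.
#'
#' @param net a [DirectedNetwork-class]
#' @param m a maximum [Matching-class] of `net`
#' @return integer
#' @export
countDrivers <- function(net, m) {
  max(numNodes(net) - matchingSize(m), 1L)
}

#' Driver nodes of a matching
#'
#' The nodes whose in-copy is unmatched: control signals are injected here
#' and transmitted along the matched links. For a perfect matching (no
#' unmatched node) the formula still demands one driver; the
#' lexicographically smallest node is returned as a deterministic
#' convention.
#'
#' @param net a [DirectedNetwork-class]
#' @param m a [Matching-class] of `net`
#' @return character vector of driver node identifiers
#' @export
driverNodes <- function(net, m) {
  drivers <- setdiff(net@nodes, m@links[, 2L])
  if (length(drivers) == 0L) drivers <- sort(net@nodes)[1L]
  sort(drivers)
}

#' Control-path (stem-cycle) decomposition induced by a matching
#'
#' Decomposes the network into the control paths of one matching: stems
#' are maximal chains of matched links starting at each unmatched-in
#' (driver) node, possibly of length zero; the remaining matched links
#' necessarily form node-disjoint cycles. Together stems and cycles cover
#' every node exactly once — the cactus skeleton along which control
#' signals propagate.
#'
#' @param net a [DirectedNetwork-class]
#' @param m a [Matching-class] of `net` (validated; endpoint-disjointness
#'   violations raise an error)
#' @return a [ControlPathSet-class]
#' @examples
#' net <- readEdgeList(text = c("1\t3", "1\t4", "2\t3", "3\t5"))
#' cp <- controlPaths(net, maximumMatching(net))
#' stems(cp)  # [1, 4] and [2, 3, 5]
#' @export
controlPaths <- function(net, m) {
  validObject(m)
  if (!identical(m@network@nodes, net@nodes) ||
      !identical(linkKeys(m@network@links), linkKeys(net@links)))
    stop("matching does not belong to this network")
  succ <- structure(m@links[, 2L], names = m@links[, 1L])
  visited <- structure(logical(numNodes(net)), names = net@nodes)
  starts <- sort(setdiff(net@nodes, m@links[, 2L]))
  stems <- lapply(starts, function(s) {
    path <- s
    visited[[s]] <<- TRUE
    nxt <- succ[s]
    while (!is.na(nxt) && !visited[[nxt]]) {
      path <- c(path, unname(nxt))
      visited[[nxt]] <<- TRUE
      nxt <- succ[nxt]
    }
    path
  })
  cycles <- list()
  for (v in net@nodes[!visited]) {
    if (visited[[v]]) next
    cyc <- v
    visited[[v]] <- TRUE
    nxt <- succ[v]
    while (!is.na(nxt) && nxt != v) {
      cyc <- c(cyc, unname(nxt))
      visited[[nxt]] <- TRUE
      nxt <- succ[nxt]
    }
    # canonical rotation: cycle starts at its smallest node
    k <- which(cyc == min(cyc))[1L]
    if (k > 1L) cyc <- c(cyc[k:length(cyc)], cyc[1:(k - 1L)])
    cycles <- c(cycles, list(cyc))
  }
  new("ControlPathSet", stems = stems, cycles = cycles, matching = m)
}

#' Structured linear system for the controllability rank oracle
#'
#' Builds the structure of the linear time-invariant system
#' dX/dt = A X + B u associated with a directed network: A has a nonzero
#' entry (i, j) for every link j -> i, and B has exactly one nonzero per
#' driver column, at that driver's row.
#'
#' @param net a [DirectedNetwork-class]
#' @param drivers character vector of driver node identifiers
#' @return an object of class `linearSystem`: list with logical pattern
#'   matrices `A` (n x n) and `B` (n x m), `drivers` and `nodes`
#' @seealso [kalmanRankOracle()]
#' @export
linearSystem <- function(net, drivers) {
  n <- numNodes(net)
  if (!all(drivers %in% net@nodes)) stop("unknown driver node")
  A <- matrix(FALSE, n, n, dimnames = list(net@nodes, net@nodes))
  if (numLinks(net) > 0L)
    A[cbind(match(net@links[, 2L], net@nodes),
            match(net@links[, 1L], net@nodes))] <- TRUE
  B <- matrix(FALSE, n, length(drivers),
              dimnames = list(net@nodes, drivers))
  B[cbind(match(drivers, net@nodes), seq_along(drivers))] <- TRUE
  structure(list(A = A, B = B, drivers = drivers, nodes = net@nodes),
            class = "linearSystem")
}

#' Numeric Kalman-rank oracle for small structured systems
#'
#' Tests generic structural controllability by the Kalman rank condition:
#' draws random weights on the nonzero structure of A and B, builds the
#' controllability matrix Q_C = [B, AB, ..., A^(n-1) B] and checks whether
#' rank(Q_C) = n in any of `trials` independent draws. Generic rank holds
#' almost surely, so multiple trials only guard against degenerate draws.
#' Restricted to n <= 12 nodes: the rank condition is computationally
#' infeasible for large networks, which is exactly what the matching-based
#' machinery replaces.
#'
#' Weights are uniform on \[0.5, 1.5\]; rank uses a singular-value cutoff
#' of 1e-9 relative to the largest singular value.
#'
#' @param sys a `linearSystem` from [linearSystem()]
#' @param trials number of random weight draws (default 5)
#' @param seed optional integer seed
#' @return logical: `TRUE` iff full rank is achieved in any trial
#' @export
kalmanRankOracle <- function(sys, trials = 5L, seed = NULL) {
  n <- nrow(sys$A)
  if (n > 12L)
    stop("rank oracle restricted to systems with at most 12 nodes")
  withSeed(seed, {
    for (t in seq_len(trials)) {
      A <- matrix(0, n, n)
      A[sys$A] <- runif(sum(sys$A), 0.5, 1.5)
      B <- matrix(0, n, ncol(sys$B))
      B[sys$B] <- runif(sum(sys$B), 0.5, 1.5)
      Ak <- diag(n)
      blocks <- vector("list", n)
      blocks[[1L]] <- B
      for (k in seq_len(n - 1L)) {
        Ak <- A %*% Ak
        blocks[[k + 1L]] <- Ak %*% B
      }
      Q <- do.call(cbind, blocks)
      d <- svd(Q, nu = 0, nv = 0)$d
      if (sum(d > 1e-9 * d[1L]) == n) return(TRUE)
    }
    FALSE
  })
}
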