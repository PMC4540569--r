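#' Perturbation range of a node under one control-path set
#'
#' The nodes reachable from `node` by following matched links only — the
#' successor chain of the stem or cycle containing it. Control signals
#' transmit along the matched links, so reachability is evaluated on the
#' cactus skeleton, not on the full network. The node itself is excluded
#' even when a cycle re-reaches it (strict downstream convention).
#'
#' @param node a node identifier
#' @param cpset a [ControlPathSet-class]
#' @return character vector of influenced nodes (possibly empty)
#' @examples
#' net <- readEdgeList(text = c("1\t3", "1\t4", "2\t3", "3\t5"))
#' cp <- controlPaths(net, maximumMatching(net))
#' perturbationRange("2", cp)  # "3" "5"
#' @export
perturbationRange <- function(node, cpset) {
  net <- cpset@matching@network
  if (!node %in% net@nodes) stop("unknown node: ", node)
  for (s in cpset@stems) {
    k <- match(node, s)
    if (!is.na(k))
      return(if (k < length(s)) s[(k + 1L):length(s)] else character(0))
  }
  for (cyc in cpset@cycles) {
    if (node %in% cyc) return(setdiff(cyc, node))
  }
  character(0)
}

# Per-node ranges of one control-path set in a single pass.
cpsetRanges <- function(cpset) {
  out <- list()
  for (s in cpset@stems) {
    n <- length(s)
    for (k in seq_len(n))
      out[[s[k]]] <- if (k < n) s[(k + 1L):n] else character(0)
  }
  for (cyc in cpset@cycles) {
    for (v in cyc) out[[v]] <- setdiff(cyc, v)
  }
  out
}

#' Perturbation influence of every node over diversified control paths
#'
#' Aggregates the perturbation ranges over every MMSet in the collection:
#' Pi_i is the union over the collection's control-path sets of the nodes
#' reachable from i along matched links. One successor-map pass per MMSet.
#'
#' @param coll an [MMSetCollection-class]
#' @return a [PerturbationProfile-class]
#' @export
perturbationProfile <- function(coll) {
  net <- coll@network
  acc <- structure(vector("list", numNodes(net)), names = net@nodes)
  for (lk in coll@mmsets) {
    m <- new("Matching", links = lk, network = net)
    ranges <- cpsetRanges(controlPaths(net, m))
    for (v in names(ranges)) {
      if (length(ranges[[v]]))
        acc[[v]] <- c(acc[[v]], ranges[[v]])
    }
  }
  influence <- lapply(acc, function(x) sort(unique(x %||% character(0))))
  new("PerturbationProfile", influence = influence, nodes = net@nodes,
      nMMSets = length(coll@mmsets))
}

#' Perturbation influence Pi of a single node
#'
#' @param node a node identifier
#' @param x an [MMSetCollection-class] or a precomputed
#'   [PerturbationProfile-class]
#' @return character vector: the nodes reachable from `node` through the
#'   diversified control paths (never containing `node` itself)
#' @export
perturbationInfluence <- function(node, x) {
  profile <- if (is(x, "MMSetCollection")) perturbationProfile(x) else x
  if (!node %in% profile@nodes) stop("unknown node: ", node)
  profile@influence[[node]]
}

#' Overlapped perturbation influence of a gene set
#'
#' Intersection of the perturbation influences of several genes: the
#' shared downstream footprint, interpreted as candidate disease-related
#' pathway genes when the input genes are known disease genes.
#'
#' @param genes non-empty character vector of node identifiers
#' @param x an [MMSetCollection-class] or a [PerturbationProfile-class]
#' @return character vector (possibly empty)
#' @export
commonInfluence <- function(genes, x) {
  if (length(genes) == 0L) stop("empty gene set")
  profile <- if (is(x, "MMSetCollection")) perturbationProfile(x) else x
  unknown <- setdiff(genes, profile@nodes)
  if (length(unknown)) stop("unknown node: ", unknown[1L])
  Reduce(intersect, profile@influence[genes])
}
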