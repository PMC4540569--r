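# Accessors and show methods for the S4 containers.

#' Nodes of a directed network
#' @param x a [DirectedNetwork-class]
#' @return character vector of node identifiers
#' @export
nodes <- function(x) x@nodes

#' Links of a network, matching or collection member
#' @param x a [DirectedNetwork-class] or [Matching-class]
#' @return two-column character matrix (`tail`, `head`)
#' @export
links <- function(x) x@links

#' Number of nodes
#' @param x a [DirectedNetwork-class]
#' @return integer
#' @export
numNodes <- function(x) length(x@nodes)

#' Number of directed links
#' @param x a [DirectedNetwork-class]
#' @return integer
#' @export
numLinks <- function(x) nrow(x@links)

#' Cardinality |M| of a matching
#' @param m a [Matching-class]
#' @return integer
#' @export
matchingSize <- function(m) nrow(m@links)

#' Stems of a control-path set
#' @param x a [ControlPathSet-class]
#' @return list of node sequences, each starting at a driver node
#' @export
stems <- function(x) x@stems

#' Cycles of a control-path set
#' @param x a [ControlPathSet-class]
#' @return list of cyclic node sequences
#' @export
cycles <- function(x) x@cycles

#' Distinct MMSets held by a collection
#' @param x an [MMSetCollection-class]
#' @return list of canonical link matrices
#' @export
mmsets <- function(x) x@mmsets

#' Number of distinct MMSets in a collection
#' @param x an [MMSetCollection-class]
#' @return integer
#' @export
numMMSets <- function(x) length(x@mmsets)

#' Per-node influence sets of a perturbation profile
#' @param x a [PerturbationProfile-class]
#' @return named list, node -> character vector
#' @export
influenceSets <- function(x) x@influence

#' Terms of an ontology DAG
#' @param x an [OntologyDAG-class]
#' @return character vector of term identifiers
#' @export
ontologyTerms <- function(x) x@terms

setMethod("show", "DirectedNetwork", function(object) {
  cat(sprintf("DirectedNetwork: %d nodes, %d links (%d flagged undirected)\n",
              numNodes(object), numLinks(object), sum(object@undirected)))
})

setMethod("show", "Matching", function(object) {
  cat(sprintf("Matching of %d links on a network of %d nodes\n",
              matchingSize(object), numNodes(object@network)))
})

setMethod("show", "ControlPathSet", function(object) {
  cat(sprintf("ControlPathSet: %d stem(s), %d cycle(s) covering %d nodes\n",
              length(object@stems), length(object@cycles),
              numNodes(object@matching@network)))
})

setMethod("show", "MMSetCollection", function(object) {
  cat(sprintf("MMSetCollection: %d distinct MMSet(s) of size %d (%d samples)\n",
              numMMSets(object), nrow(object@mmsets[[1L]]),
              object@samplesTaken))
})

setMethod("show", "PerturbationProfile", function(object) {
  sz <- lengths(object@influence)
  cat(sprintf(
    "PerturbationProfile over %d MMSet(s): %d nodes, mean |Pi| = %.2f\n",
    object@nMMSets, length(object@nodes), mean(sz)))
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d root(s), namespaces: %s\n",
              length(object@terms), length(object@roots),
              paste(unique(object@namespace), collapse = ", ")))
})
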