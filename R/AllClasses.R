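#' @import methods
NULL

#' DirectedNetwork: a simple directed graph over opaque node identifiers
#'
#' The central container of the package: a set of node identifiers (strings,
#' case sensitive) and a set of directed links (ordered tail/head pairs).
#' Parallel links are collapsed (simple-digraph semantics); self-loops are
#' permitted. Links read from a source file with an `undirected` flag keep
#' that flag until [bidirectionalize()] resolves them into reciprocal
#' directed links.
#'
#' @slot nodes character vector of node identifiers (unique).
#' @slot links character matrix with columns `tail`, `head`; one row per
#'   directed link, rows unique and sorted canonically.
#' @slot undirected logical vector parallel to the rows of `links`; `TRUE`
#'   marks links flagged undirected in the source.
#'
#' @seealso [directedNetwork()], [readEdgeList()], [bidirectionalize()]
#' @export
setClass("DirectedNetwork",
  slots = c(nodes = "character", links = "matrix", undirected = "logical"))

setValidity("DirectedNetwork", function(object) {
  lk <- object@links
  if (!is.character(lk) || ncol(lk) != 2L)
    return("links must be a two-column character matrix")
  if (nrow(lk) != length(object@undirected))
    return("undirected flags must be parallel to the link rows")
  if (anyDuplicated(object@nodes))
    return("duplicate node identifiers")
  if (nrow(lk) > 0L) {
    if (!all(lk %in% object@nodes))
      return("every link endpoint must be a member of nodes")
    if (anyDuplicated(linkKeys(lk)))
      return("duplicate links (set semantics required)")
  }
  TRUE
})

#' Matching: a set of links with pairwise-distinct tails and heads
#'
#' A matching of a directed network under the node-splitting construction:
#' no two links share a tail and no two links share a head. A matching of
#' maximum cardinality is an MMSet (maximum-matching set) and determines
#' the minimum number of driver nodes.
#'
#' @slot links character matrix (`tail`, `head`), rows sorted canonically.
#' @slot network the parent [DirectedNetwork-class].
#'
#' @seealso [maximumMatching()], [matchingSize()], [controlPaths()]
#' @export
setClass("Matching",
  slots = c(links = "matrix", network = "DirectedNetwork"))

setValidity("Matching", function(object) {
  lk <- object@links
  if (!is.character(lk) || ncol(lk) != 2L)
    return("links must be a two-column character matrix")
  if (nrow(lk) == 0L) return(TRUE)
  if (anyDuplicated(lk[, 1L]))
    return("two links share a tail")
  if (anyDuplicated(lk[, 2L]))
    return("two links share a head")
  if (!all(linkKeys(lk) %in% linkKeys(object@network@links)))
    return("matched link not present in the parent network")
  TRUE
})

#' ControlPathSet: the stems and cycles induced by one matching
#'
#' The stem-cycle cover of a network generated by a single maximum
#' matching: stems are maximal chains of matched links starting at driver
#' (unmatched-in) nodes, cycles are the remaining matched links. Stems and
#' cycles are node-disjoint and jointly cover every node; singleton stems
#' (isolated drivers) are allowed.
#'
#' @slot stems list of character vectors, each an ordered node sequence
#'   beginning at a driver node.
#' @slot cycles list of character vectors, each a cyclic node sequence
#'   (the closing link back to the first node is implicit).
#' @slot matching the generating [Matching-class].
#'
#' @seealso [controlPaths()], [perturbationRange()]
#' @export
setClass("ControlPathSet",
  slots = c(stems = "list", cycles = "list", matching = "Matching"))

setValidity("ControlPathSet", function(object) {
  covered <- c(unlist(object@stems), unlist(object@cycles))
  net <- object@matching@network
  if (length(covered) != length(net@nodes) || anyDuplicated(covered) ||
      !setequal(covered, net@nodes))
    return("stems and cycles must be node-disjoint and cover all nodes")
  TRUE
})

#' MMSetCollection: distinct maximum matchings found by sampling
#'
#' Holds the distinct MMSets discovered by [sampleMMSets()] or
#' [enumerateAllMMSets()], canonicalized as sorted link matrices, together
#' with the number of random-walk samples taken.
#'
#' @slot mmsets list of canonical link matrices (each a valid maximum
#'   matching of `network`).
#' @slot network the parent [DirectedNetwork-class].
#' @slot samplesTaken integer, number of walk states recorded (0 for
#'   exhaustive enumeration).
#' @slot seed integer seed used, or `NA` for deterministic enumeration.
#'
#' @seealso [sampleMMSets()], [enumerateAllMMSets()], [perturbationProfile()]
#' @export
setClass("MMSetCollection",
  slots = c(mmsets = "list", network = "DirectedNetwork",
            samplesTaken = "integer", seed = "integer"))

setValidity("MMSetCollection", function(object) {
  if (length(object@mmsets) == 0L)
    return("collection must hold at least one matching")
  sizes <- vapply(object@mmsets, nrow, integer(1))
  if (length(unique(sizes)) != 1L)
    return("all members must have identical cardinality")
  keys <- vapply(object@mmsets, function(m) paste(linkKeys(m), collapse = ";"),
                 character(1))
  if (anyDuplicated(keys))
    return("duplicate matchings under canonical ordering")
  TRUE
})

#' PerturbationProfile: per-node perturbation influence over DCpaths
#'
#' For every node i, the perturbation influence Pi_i: the union over the
#' collection's control-path sets of the nodes reachable from i along
#' matched links. Pi_i never contains i itself (strict downstream
#' reachability).
#'
#' @slot influence named list, node -> character vector of influenced nodes.
#' @slot nodes character vector of all network nodes (names of `influence`).
#' @slot nMMSets integer, number of distinct MMSets the profile aggregates.
#'
#' @seealso [perturbationProfile()], [perturbationInfluence()],
#'   [commonInfluence()]
#' @export
setClass("PerturbationProfile",
  slots = c(influence = "list", nodes = "character", nMMSets = "integer"))

setValidity("PerturbationProfile", function(object) {
  if (!identical(names(object@influence), object@nodes))
    return("influence list must be named by nodes, in order")
  self <- mapply(function(n, s) n %in% s, object@nodes, object@influence)
  if (any(self))
    return("a node must not belong to its own perturbation influence")
  TRUE
})

#' OntologyDAG: a rooted term DAG with typed child-to-parent edges
#'
#' Minimal ontology representation for semantic-similarity scoring: term
#' identifiers, child-to-parent edges typed `is_a` or `part_of`, a
#' namespace per term and the namespace roots. Acyclic by validity check.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents named list, term -> character vector of parent terms.
#' @slot relations named list, term -> character vector of relation types
#'   (parallel to `parents`).
#' @slot namespace named character, term -> namespace.
#' @slot roots character vector of terms with no parents.
#'
#' @seealso [readOBO()], [termSimilarity()], [generateOntology()]
#' @export
setClass("OntologyDAG",
  slots = c(terms = "character", parents = "list", relations = "list",
            namespace = "character", roots = "character"))

setValidity("OntologyDAG", function(object) {
  if (!identical(names(object@parents), object@terms) ||
      !identical(names(object@relations), object@terms))
    return("parents and relations must be named by terms, in order")
  np <- lengths(object@parents)
  if (!identical(lengths(object@relations), np))
    return("relations must be parallel to parents")
  if (!setequal(object@roots, object@terms[np == 0L]))
    return("roots must be exactly the parentless terms")
  if (length(object@terms) > 0L && !any(np == 0L))
    return("a non-empty DAG needs at least one root")
  if (!topoSortable(object))
    return("ontology graph must be acyclic")
  TRUE
})

# topological sortability check used by the validity method
topoSortable <- function(dag) {
  nChildren <- integer(length(dag@terms))
  names(nChildren) <- dag@terms
  for (t in dag@terms)
    for (p in dag@parents[[t]])
      nChildren[[p]] <- nChildren[[p]] + 1L
  queue <- dag@terms[nChildren == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (p in dag@parents[[t]]) {
      nChildren[[p]] <- nChildren[[p]] - 1L
      if (nChildren[[p]] == 0L) queue <- c(queue, p)
    }
  }
  seen == length(dag@terms)
}
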