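#' Construct a directed network
#'
#' Builds a [DirectedNetwork-class] from a link table. Parallel links are
#' collapsed to one (simple-digraph semantics); a link flagged undirected
#' anywhere keeps the flag through collapsing. Self-loops are allowed.
#'
#' @param links two-column character matrix or data frame (`tail`, `head`);
#'   may have zero rows.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the union of link endpoints. Extra isolated nodes may be listed.
#' @param undirected optional logical vector parallel to the rows of
#'   `links` marking links that were undirected in the source.
#' @return a [DirectedNetwork-class]
#' @examples
#' net <- directedNetwork(cbind(c("1", "1", "2", "3"), c("3", "4", "3", "5")))
#' numNodes(net)
#' @export
directedNetwork <- function(links, nodes = NULL, undirected = NULL) {
  links <- as.matrix(links)
  if (length(links) == 0L) links <- emptyLinks()
  storage.mode(links) <- "character"
  if (ncol(links) != 2L)
    stop("links must have two columns (tail, head)")
  if (is.null(undirected)) undirected <- rep(FALSE, nrow(links))
  if (nrow(links) == 0L) {
    return(new("DirectedNetwork", nodes = sort(unique(as.character(nodes))),
               links = emptyLinks(), undirected = logical(0)))
  }
  keys <- linkKeys(links)
  # collapse parallel links, OR-ing the undirected flags
  flag <- tapply(undirected, keys, any)
  first <- !duplicated(keys)
  links <- links[first, , drop = FALSE]
  undirected <- as.logical(flag[keys[first]])
  ord <- order(links[, 1L], links[, 2L], method = "radix")
  links <- links[ord, , drop = FALSE]
  colnames(links) <- c("tail", "head")
  undirected <- undirected[ord]
  nodes <- sort(unique(c(as.character(nodes), as.vector(links))))
  new("DirectedNetwork", nodes = nodes, links = links, undirected = undirected)
}

#' Read a directed network from an edge-list TSV
#'
#' Rows are `tail<TAB>head[<TAB>direction]` with direction one of
#' `directed` / `undirected`; lines starting with `#` are skipped.
#' Duplicate rows collapse to one link (set semantics).
#'
#' @param file path to a TSV file, or a connection.
#' @param text optional character vector of lines, used instead of `file`.
#' @return a [DirectedNetwork-class]
#' @examples
#' net <- readEdgeList(text = c("a\tb", "b\tc"))
#' numLinks(net)
#' @export
readEdgeList <- function(file, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty edge list: no data rows found")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed edge-list row at line %d: %s",
                 lineNo[bad[1L]], lines[bad[1L]]))
  tail <- vapply(parts, `[[`, character(1), 1L)
  head <- vapply(parts, `[[`, character(1), 2L)
  dir <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "directed",
                character(1))
  badDir <- which(!dir %in% c("directed", "undirected"))
  if (length(badDir))
    stop(sprintf("unknown direction flag at line %d: %s",
                 lineNo[badDir[1L]], dir[badDir[1L]]))
  if (any(!nzchar(tail)) || any(!nzchar(head))) {
    bad <- which(!nzchar(tail) | !nzchar(head))[1L]
    stop(sprintf("empty node identifier at line %d", lineNo[bad]))
  }
  directedNetwork(cbind(tail, head), undirected = dir == "undirected")
}

#' Write a network as an edge-list TSV
#'
#' Inverse of [readEdgeList()]: writes `tail<TAB>head<TAB>direction` rows;
#' reading the result back yields an identical network.
#'
#' @param net a [DirectedNetwork-class]
#' @param file path or connection to write to
#' @return invisibly, the path/connection
#' @export
writeEdgeList <- function(net, file) {
  dir <- ifelse(net@undirected, "undirected", "directed")
  lines <- paste(net@links[, 1L], net@links[, 2L], dir, sep = "\t")
  writeLines(lines, file)
  invisible(file)
}

#' Resolve undirected links into reciprocal directed links
#'
#' Each link flagged undirected, say between u and v, is replaced by the
#' directed links (u, v) and (v, u); directed links and the node set are
#' unchanged. When the reverse directed link already exists only the
#' missing direction is added (no duplicates). Idempotent on its output.
#'
#' @param net a [DirectedNetwork-class]
#' @return a [DirectedNetwork-class] with no undirected flags
#' @examples
#' net <- readEdgeList(text = c("a\tb\tundirected", "b\tc\tdirected"))
#' numLinks(bidirectionalize(net))  # 3
#' @export
bidirectionalize <- function(net) {
  und <- net@links[net@undirected, , drop = FALSE]
  rev <- und[, c(2L, 1L), drop = FALSE]
  allLinks <- rbind(net@links, rev)
  directedNetwork(allLinks, nodes = net@nodes)
}

#' Read disease-gene associations from a two-column TSV
#'
#' Rows are `disease_id<TAB>gene_id` (e.g. an OMIM MIM identifier and a
#' gene symbol); `#` comment lines are skipped. Optionally drops diseases
#' with fewer than `minGenes` genes, the requirement for leave-one-out
#' cross-validation.
#'
#' @param file path to a TSV file, or a connection.
#' @param text optional character vector of lines, used instead of `file`.
#' @param minGenes drop diseases with fewer genes than this (default 0 =
#'   keep all; use 2 for cross-validation input).
#' @return named list: disease identifier -> character vector of genes
#' @examples
#' readAssociations(text = c("d1\tg1", "d1\tg2", "d2\tg3"), minGenes = 2)
#' @export
readAssociations <- function(file, text = NULL, minGenes = 0L) {
  lines <- if (!is.null(text)) text else readLines(file)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed association row at line %d: %s",
                 lineNo[bad[1L]], lines[bad[1L]]))
  disease <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  assoc <- lapply(split(gene, disease), function(g) sort(unique(g)))
  assoc[lengths(assoc) >= minGenes]
}

#' Write disease-gene associations as a two-column TSV
#' @param assoc named list, disease -> character vector of genes
#' @param file path or connection
#' @return invisibly, the path/connection
#' @export
writeAssociations <- function(assoc, file) {
  lines <- unlist(lapply(names(assoc), function(d) paste(d, assoc[[d]], sep = "\t")))
  writeLines(lines %||% character(0), file)
  invisible(file)
}
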