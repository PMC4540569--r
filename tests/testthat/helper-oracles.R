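# Independent brute-force oracles and small fixtures used across tests.
# These deliberately re-derive results by enumeration or naive recursion,
# never by calling the code paths they check.

# The 5-node worked example: links 1->3, 1->4, 2->3, 3->5.
fig1Network <- function() {
  readEdgeList(text = c("1\t3", "1\t4", "2\t3", "3\t5"))
}

threeCycle <- function() {
  readEdgeList(text = c("a\tb", "b\tc", "c\ta"))
}

randomSmallNet <- function(nNodes, nLinks, seed, selfLoops = FALSE) {
  withr::with_seed(seed, {
    ids <- c(letters, LETTERS)[seq_len(nNodes)]
    pairs <- expand.grid(t = ids, h = ids, stringsAsFactors = FALSE)
    if (!selfLoops) pairs <- pairs[pairs$t != pairs$h, ]
    pick <- pairs[sample.int(nrow(pairs), min(nLinks, nrow(pairs))), ]
    directedNetwork(cbind(pick$t, pick$h), nodes = ids)
  })
}

# All matchings of maximum cardinality, by plain recursion over links.
bruteAllMaxMatchings <- function(net) {
  lk <- links(net)
  L <- nrow(lk)
  found <- list()
  best <- -1L
  recurse <- function(i, chosen) {
    if (i > L) {
      key <- paste(sort(paste(lk[chosen, 1L], lk[chosen, 2L], sep = ">")),
                   collapse = ";")
      if (length(chosen) > best) {
        best <<- length(chosen)
        found <<- list()
      }
      if (length(chosen) == best) found[[paste0("k", key)]] <<- chosen
      return(invisible())
    }
    if (!(lk[i, 1L] %in% lk[chosen, 1L]) && !(lk[i, 2L] %in% lk[chosen, 2L]))
      recurse(i + 1L, c(chosen, i))
    recurse(i + 1L, chosen)
  }
  recurse(1L, integer(0))
  list(size = max(best, 0L),
       matchings = lapply(unname(found), function(ix) {
         m <- lk[ix, , drop = FALSE]
         m[order(m[, 1L], m[, 2L]), , drop = FALSE]
       }))
}

# Matching cardinality via igraph's bipartite matcher (independent library).
igraphMatchingSize <- function(net) {
  if (numLinks(net) == 0L) return(0L)
  lk <- links(net)
  vs <- data.frame(name = c(paste0("O_", nodes(net)), paste0("I_", nodes(net))),
                   type = rep(c(FALSE, TRUE), each = numNodes(net)))
  es <- data.frame(from = paste0("O_", lk[, 1L]), to = paste0("I_", lk[, 2L]))
  g <- igraph::graph_from_data_frame(es, directed = FALSE, vertices = vs)
  igraph::max_bipartite_match(g)$matching_size
}

# Full-network reachability (strict descendants) via igraph.
igraphDescendants <- function(net, v) {
  if (numLinks(net) == 0L) return(character(0))
  g <- igraph::graph_from_data_frame(
    as.data.frame(links(net)), directed = TRUE,
    vertices = data.frame(name = nodes(net)))
  out <- names(igraph::subcomponent(g, v, mode = "out"))
  setdiff(out, v)
}

# Maximum-weight injective assignment by exhaustive recursion (grids <= 6x6).
bruteAssignment <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  recurse <- function(i, used) {
    if (i > nr) return(0)
    best <- recurse(i + 1L, used)  # row left unassigned
    for (j in seq_len(nc)) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, grid[i, j] + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, logical(nc))
}

# Pairwise-comparison AUC (ties count one half).
bruteAUC <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Independent recursive Wang similarity: S-values by naive top-down
# recursion over the ancestor closure.
oracleTermSim <- function(t1, t2, dag, w = c(is_a = 0.8, part_of = 0.6)) {
  ancestors <- function(t) {
    out <- t; frontier <- t
    while (length(frontier)) {
      ps <- setdiff(unique(unlist(dag@parents[frontier])), out)
      out <- c(out, ps); frontier <- ps
    }
    out
  }
  svalue <- function(x, target, closure) {
    if (x == target) return(1)
    vals <- numeric(0)
    for (child in closure) {
      ps <- dag@parents[[child]]
      for (k in which(ps == x))
        vals <- c(vals, w[[dag@relations[[child]][k]]] *
                        svalue(child, target, closure))
    }
    max(vals)
  }
  c1 <- ancestors(t1); c2 <- ancestors(t2)
  S1 <- vapply(c1, svalue, numeric(1), target = t1, closure = c1)
  S2 <- vapply(c2, svalue, numeric(1), target = t2, closure = c2)
  common <- intersect(c1, c2)
  if (length(common) == 0L) return(0)
  sum(S1[common] + S2[common]) / (sum(S1) + sum(S2))
}

# Canonical key set of an MMSetCollection, for set comparisons.
collectionKeys <- function(coll) {
  sort(vapply(mmsets(coll), function(m)
    paste(paste(m[, 1L], m[, 2L], sep = ">"), collapse = ";"), character(1)))
}
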