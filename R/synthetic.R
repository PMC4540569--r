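# Synthetic inputs: random networks, toy ontologies, annotations and
# planted disease benchmarks, so the whole pipeline runs with no downloads.

#' Generate a random simple digraph
#'
#' `erdos` draws links uniformly among all ordered pairs; `scale_free`
#' grows the link set by preferential attachment (tails proportional to
#' out-degree + 1, heads to in-degree + 1). No parallel links, no
#' self-loops. The default mean out-degree of 4.8 mirrors the density of
#' a KEGG-derived human regulatory network (1579 genes, 7630 regulatory
#' relationships).
#'
#' @param n number of nodes (>= 2)
#' @param meanOutDegree target mean out-degree (default 4.8)
#' @param model `"erdos"` or `"scale_free"`
#' @param seed optional integer seed; identical seeds give identical
#'   networks
#' @return a [DirectedNetwork-class]
#' @export
generateNetwork <- function(n, meanOutDegree = 4.8,
                            model = c("erdos", "scale_free"), seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 2L)
  nodes <- sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
  m <- min(round(n * meanOutDegree), n * (n - 1L))
  if (m == 0L) return(directedNetwork(emptyLinks(), nodes = nodes))
  withSeed(seed, {
    if (model == "erdos") {
      pick <- sample.int(n * (n - 1L), m)
      tail <- (pick - 1L) %/% (n - 1L) + 1L
      off <- (pick - 1L) %% (n - 1L) + 1L
      head <- off + (off >= tail)
    } else {
      tail <- integer(m); head <- integer(m)
      outDeg <- rep(1, n); inDeg <- rep(1, n)
      seen <- new.env(parent = emptyenv())
      k <- 0L; attempts <- 0L
      while (k < m && attempts < 50L * m) {
        attempts <- attempts + 1L
        t <- sample.int(n, 1L, prob = outDeg)
        h <- sample.int(n, 1L, prob = inDeg)
        key <- paste(t, h)
        if (t == h || !is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        k <- k + 1L
        tail[k] <- t; head[k] <- h
        outDeg[t] <- outDeg[t] + 1; inDeg[h] <- inDeg[h] + 1
      }
      tail <- tail[seq_len(k)]; head <- head[seq_len(k)]
    }
    directedNetwork(cbind(nodes[tail], nodes[head]), nodes = nodes)
  })
}

#' Generate a toy ontology DAG
#'
#' A rooted `is_a` tree skeleton of the given depth and branching factor
#' plus random `part_of` cross-links: 10% of non-root terms receive one
#' extra parent drawn from a strictly shallower level, which keeps the
#' graph acyclic by construction. `depth = 1` yields the root alone.
#'
#' @param depth number of levels including the root (>= 1)
#' @param branching children per term
#' @param seed optional integer seed
#' @param partOfFraction fraction of non-root terms given a `part_of`
#'   cross-link (default 0.1)
#' @return an [OntologyDAG-class]
#' @export
generateOntology <- function(depth, branching, seed = NULL,
                             partOfFraction = 0.1) {
  stopifnot(depth >= 1L, branching >= 1L)
  total <- sum(branching^(0:(depth - 1L)))
  ids <- sprintf("GO:%07d", seq_len(total))
  level <- integer(total)
  parents <- list(); relations <- list()
  counter <- 1L
  frontier <- 1L  # index of the root
  level[1L] <- 1L
  parents[[ids[1L]]] <- character(0)
  relations[[ids[1L]]] <- character(0)
  for (d in seq_len(depth - 1L)) {
    newFrontier <- integer(0)
    for (p in frontier) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        level[counter] <- d + 1L
        parents[[ids[counter]]] <- ids[p]
        relations[[ids[counter]]] <- "is_a"
        newFrontier <- c(newFrontier, counter)
      }
    }
    frontier <- newFrontier
  }
  withSeed(seed, {
    nonRoot <- which(level > 1L)
    extra <- sample(nonRoot, size = round(partOfFraction * length(nonRoot)))
    for (i in extra) {
      shallower <- which(level < level[i])
      cand <- setdiff(ids[shallower], parents[[ids[i]]])
      if (length(cand) == 0L) next
      pick <- cand[sample.int(length(cand), 1L)]
      parents[[ids[i]]] <- c(parents[[ids[i]]], pick)
      relations[[ids[i]]] <- c(relations[[ids[i]]], "part_of")
    }
  })
  ontologyDAG(ids, parents, relations)
}

# child map and downward closure of a term
dagChildren <- function(dag) {
  ch <- structure(vector("list", length(dag@terms)), names = dag@terms)
  for (t in dag@terms)
    for (p in dag@parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  ch
}

dagDescendants <- function(dag, term, children = dagChildren(dag)) {
  out <- character(0)
  queue <- term
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, t)
    queue <- c(queue, setdiff(children[[t]], out))
  }
  unique(out)
}

#' Random gene annotations from an ontology
#'
#' Each gene receives `termsPerGene` terms drawn uniformly from `fromTerms`
#' (default: all terms); a `noise` fraction of the draws is replaced by
#' terms drawn from the whole ontology regardless of `fromTerms`.
#'
#' @param genes character vector of gene identifiers
#' @param dag an [OntologyDAG-class]
#' @param termsPerGene terms per gene (default 3)
#' @param fromTerms optional pool of terms to draw from (one coherent
#'   ontology branch, say)
#' @param noise fraction of off-pool terms (default 0.2)
#' @param seed optional integer seed
#' @return named list, gene -> character vector of terms
#' @export
generateAnnotations <- function(genes, dag, termsPerGene = 3L,
                                fromTerms = NULL, noise = 0.2, seed = NULL) {
  pool <- fromTerms %||% dag@terms
  withSeed(seed, {
    ann <- lapply(genes, function(g) {
      k <- termsPerGene
      offK <- stats::rbinom(1L, k, noise)
      sort(unique(c(sample(pool, min(k - offK, length(pool))),
                    if (offK > 0L) sample(dag@terms, offK))))
    })
    names(ann) <- genes
    ann
  })
}

#' Generate a planted disease-gene benchmark
#'
#' Builds the structure the prioritization score assumes — genes causing
#' the same disease drive the same perturbation influence. A random base
#' network is extended, per disease, with a dedicated downstream module
#' (a matched chain of new nodes) and `genesPerDisease` disease genes
#' wired into the module's entry node, so every disease gene reaches the
#' whole module along matched links under at least one MMSet. Module
#' genes are annotated coherently from one ontology branch per disease
#' (plus annotation noise), making within-disease influence sets
#' functionally similar. The construction is then verified post hoc by
#' actually sampling MMSets and checking each disease gene's perturbation
#' influence covers its module.
#'
#' @param nDiseases number of planted diseases (default 10)
#' @param genesPerDisease disease genes per disease (default 3)
#' @param moduleSize module (shared downstream set) size (default 5)
#' @param baseNodes size of the random base network (default 150)
#' @param meanOutDegree density of the base network (default 1.5; sparse
#'   enough that background influence sets stay modest)
#' @param dag optional [OntologyDAG-class]; default
#'   `generateOntology(4, 4)` (85 terms, 16 depth-2 branches)
#' @param termsPerGene annotation size per gene
#' @param noise annotation noise fraction (default 0.2)
#' @param samples MMSet sampling budget for the post-hoc verification
#'   (default 2000)
#' @param restarts walk restarts for the verification (default 2)
#' @param seed optional master seed
#' @return a `syntheticBundle`: list with `network`, `dag`, `annotations`,
#'   `associations`, `modules` (ground truth), `collection` (the verified
#'   [MMSetCollection-class]) and `profile` (its
#'   [PerturbationProfile-class])
#' @export
generateDiseaseBenchmark <- function(nDiseases = 10L, genesPerDisease = 3L,
                                     moduleSize = 5L, baseNodes = 150L,
                                     meanOutDegree = 1.5, dag = NULL,
                                     termsPerGene = 3L, noise = 0.2,
                                     samples = 2000L, restarts = 2L,
                                     seed = NULL) {
  seeds <- deriveSeeds(seed %||% sample.int(.Machine$integer.max, 1L), 6L)
  base <- generateNetwork(baseNodes, meanOutDegree, "erdos", seed = seeds[1L])
  dag <- dag %||% generateOntology(4L, 4L, seed = seeds[2L])
  children <- dagChildren(dag)
  # branch roots: grandchildren of the root, one disjoint branch per disease
  lvl2 <- unlist(lapply(children[[dag@roots[1L]]], function(t) children[[t]]))
  lvl2 <- unique(lvl2)
  if (length(lvl2) < nDiseases)
    stop("ontology too small: needs at least ", nDiseases, " depth-2 branches")
  branchRoots <- withSeed(seeds[3L], sample(lvl2, nDiseases))
  diseases <- sprintf("MIM:%06d", seq_len(nDiseases))
  extraLinks <- NULL
  modules <- list(); assoc <- list()
  for (d in seq_len(nDiseases)) {
    mod <- sprintf("%sM%d", diseases[d], seq_len(moduleSize))
    genes <- sprintf("%sG%d", diseases[d], seq_len(genesPerDisease))
    chain <- if (moduleSize > 1L) cbind(mod[-moduleSize], mod[-1L]) else NULL
    entry <- cbind(genes, rep(mod[1L], genesPerDisease))
    extraLinks <- rbind(extraLinks, chain, entry)
    modules[[diseases[d]]] <- mod
    assoc[[diseases[d]]] <- genes
  }
  net <- directedNetwork(rbind(base@links, extraLinks), nodes = base@nodes)
  # annotations: module and disease genes coherently from one branch per
  # disease, background genes from the whole ontology
  ann <- list()
  background <- setdiff(net@nodes, unlist(c(modules, assoc)))
  ann <- c(ann, generateAnnotations(background, dag, termsPerGene,
                                    noise = noise, seed = seeds[4L]))
  branchSeeds <- deriveSeeds(seeds[5L], nDiseases)
  for (d in seq_len(nDiseases)) {
    branch <- dagDescendants(dag, branchRoots[d], children)
    dd <- diseases[d]
    ann <- c(ann, generateAnnotations(c(modules[[dd]], assoc[[dd]]), dag,
                                      termsPerGene, fromTerms = branch,
                                      noise = noise, seed = branchSeeds[d]))
  }
  ann <- ann[order(names(ann))]
  coll <- sampleMMSets(net, samples, seed = seeds[6L], restarts = restarts)
  profile <- perturbationProfile(coll)
  for (dd in diseases) {
    for (g in assoc[[dd]]) {
      if (!all(modules[[dd]] %in% profile@influence[[g]]))
        stop("planted module not recovered for ", g,
             "; increase the sampling budget")
    }
  }
  structure(list(network = net, dag = dag, annotations = ann,
                 associations = assoc, modules = modules,
                 collection = coll, profile = profile),
            class = "syntheticBundle")
}

#' @export
print.syntheticBundle <- function(x, ...) {
  cat(sprintf(
    "syntheticBundle: %d-node network, %d diseases x %d genes, %d MMSets\n",
    numNodes(x$network), length(x$associations),
    length(x$associations[[1L]]), numMMSets(x$collection)))
  invisible(x)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Writes `edges.tsv`, `ontology.obo`, `annotations.tsv`,
#' `associations.tsv` and `ground_truth.json` (the planted modules).
#'
#' @param bundle a `syntheticBundle`
#' @param dir output directory (created if absent)
#' @return invisibly, `dir`
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeEdgeList(bundle$network, file.path(dir, "edges.tsv"))
  writeOBO(bundle$dag, file.path(dir, "ontology.obo"))
  writeAnnotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  writeAssociations(bundle$associations, file.path(dir, "associations.tsv"))
  jsonlite::write_json(bundle$modules, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
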