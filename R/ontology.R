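#' Construct an ontology DAG
#'
#' @param terms character vector of term identifiers
#' @param parents named list, term -> character vector of parent terms
#'   (missing entries mean no parents)
#' @param relations named list parallel to `parents` with relation types
#'   (`is_a` or `part_of`); defaults to all `is_a`
#' @param namespace named character, term -> namespace; defaults to
#'   `biological_process` for every term
#' @return an [OntologyDAG-class]
#' @export
ontologyDAG <- function(terms, parents = list(), relations = NULL,
                        namespace = NULL) {
  terms <- as.character(terms)
  p <- lapply(terms, function(t) as.character(parents[[t]] %||% character(0)))
  names(p) <- terms
  r <- lapply(terms, function(t) {
    rel <- relations[[t]] %||% rep("is_a", length(p[[t]]))
    as.character(rel)
  })
  names(r) <- terms
  ns <- structure(rep("biological_process", length(terms)), names = terms)
  if (!is.null(namespace)) ns[names(namespace)] <- namespace
  new("OntologyDAG", terms = terms, parents = p, relations = r,
      namespace = ns, roots = terms[lengths(p) == 0L])
}

#' Read an ontology from an OBO flat file
#'
#' Minimal OBO 1.2 reader covering what similarity scoring needs:
#' `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are dropped, as are
#' parent references to terms absent from the file.
#'
#' @param file path to an OBO file, or a connection
#' @param text optional character vector of lines, used instead of `file`
#' @return an [OntologyDAG-class]
#' @export
readOBO <- function(file, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- sub("\\s*!.*$", "", lines)      # strip trailing comments
  stanzaStart <- grep("^\\[", lines)
  termStart <- which(lines == "[Term]")
  if (length(termStart) == 0L) stop("no [Term] stanzas found")
  ends <- c(stanzaStart[-1L] - 1L, length(lines))
  terms <- character(0); parents <- list(); relations <- list()
  namespace <- character(0)
  for (s in termStart) {
    end <- ends[which(stanzaStart == s)]
    block <- if (s + 1L > end) character(0) else lines[(s + 1L):end]
    getv <- function(key) {
      hits <- grep(paste0("^", key, ":\\s*"), block, value = TRUE)
      trimws(sub(paste0("^", key, ":\\s*"), "", hits))
    }
    if (length(getv("is_obsolete")) && any(getv("is_obsolete") == "true")) next
    id <- getv("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    isa <- getv("is_a")
    rel <- getv("relationship")
    partOf <- trimws(sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)]))
    terms <- c(terms, id)
    parents[[id]] <- c(isa, partOf)
    relations[[id]] <- c(rep("is_a", length(isa)), rep("part_of", length(partOf)))
    ns <- getv("namespace")
    namespace[[id]] <- if (length(ns)) ns[1L] else "biological_process"
  }
  # drop references to unknown (e.g. obsolete) parents
  for (id in terms) {
    keep <- parents[[id]] %in% terms
    parents[[id]] <- parents[[id]][keep]
    relations[[id]] <- relations[[id]][keep]
  }
  ontologyDAG(terms, parents, relations, namespace)
}

#' Write an ontology DAG as an OBO flat file
#'
#' Inverse of [readOBO()] for the fields that reader understands.
#'
#' @param dag an [OntologyDAG-class]
#' @param file path or connection
#' @return invisibly, the path/connection
#' @export
writeOBO <- function(dag, file) {
  out <- c("format-version: 1.2", "")
  for (t in dag@terms) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", t),
             paste0("namespace: ", dag@namespace[[t]]))
    ps <- dag@parents[[t]]; rs <- dag@relations[[t]]
    for (k in seq_along(ps)) {
      out <- c(out, if (rs[k] == "is_a") paste0("is_a: ", ps[k])
                    else paste0("relationship: part_of ", ps[k]))
    }
    out <- c(out, "")
  }
  writeLines(out, file)
  invisible(file)
}

#' Read gene-to-term annotations
#'
#' Either a two-column TSV (`gene<TAB>term`, `#` comments skipped) or a
#' GAF 2.x file (`!` comments; gene symbol in column 3, term in column 5).
#' When `dag` is supplied, annotations to unknown terms are dropped with a
#' warning.
#'
#' @param file path or connection
#' @param text optional character vector of lines, used instead of `file`
#' @param format `"tsv"` or `"gaf"`
#' @param dag optional [OntologyDAG-class] used to validate terms
#' @return named list: gene -> character vector of term identifiers
#' @export
readAnnotations <- function(file, text = NULL, format = c("tsv", "gaf"),
                            dag = NULL) {
  format <- match.arg(format)
  lines <- if (!is.null(text)) text else readLines(file)
  comment <- if (format == "gaf") "^!" else "^\\s*#"
  lines <- lines[!grepl(comment, lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop("malformed annotation row: ", lines[bad[1L]])
    gene <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
  } else {
    bad <- which(lengths(parts) < 5L)
    if (length(bad)) stop("malformed GAF row: ", lines[bad[1L]])
    gene <- vapply(parts, `[[`, character(1), 3L)
    term <- vapply(parts, `[[`, character(1), 5L)
  }
  ann <- lapply(split(term, gene), function(x) sort(unique(x)))
  if (!is.null(dag)) {
    unknown <- setdiff(unique(unlist(ann)), dag@terms)
    if (length(unknown)) {
      warning(length(unknown), " annotation term(s) absent from the ontology; dropped")
      ann <- lapply(ann, function(x) x[x %in% dag@terms])
      ann <- ann[lengths(ann) > 0L]
    }
  }
  ann
}

#' Write gene annotations as a two-column TSV
#' @param ann named list, gene -> character vector of terms
#' @param file path or connection
#' @return invisibly, the path/connection
#' @export
writeAnnotations <- function(ann, file) {
  lines <- unlist(lapply(names(ann), function(g) paste(g, ann[[g]], sep = "\t")))
  writeLines(lines %||% character(0), file)
  invisible(file)
}
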