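# Internal helpers shared across modules.

# Canonical string key for a link matrix row set; "\r" cannot occur in a
# TSV-derived identifier so the key is collision-free.
linkKeys <- function(links) {
  if (nrow(links) == 0L) return(character(0))
  paste(links[, 1L], links[, 2L], sep = "\r")
}

# Canonical form: rows sorted lexicographically by (tail, head).
canonicalLinks <- function(links) {
  if (nrow(links) == 0L) {
    m <- matrix(character(0), ncol = 2L)
    colnames(m) <- c("tail", "head")
    return(m)
  }
  ord <- order(links[, 1L], links[, 2L], method = "radix")
  m <- links[ord, , drop = FALSE]
  colnames(m) <- c("tail", "head")
  m
}

# "k|" prefix keeps the empty matching's key a valid non-empty list name
matchingKey <- function(links)
  paste0("k|", paste(linkKeys(canonicalLinks(links)), collapse = ";"))

emptyLinks <- function() {
  m <- matrix(character(0), ncol = 2L)
  colnames(m) <- c("tail", "head")
  m
}

# Run `expr` under a temporary RNG state seeded with `seed`; seed = NULL
# uses (and advances) the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
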