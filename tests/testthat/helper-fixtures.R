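# Shared fixtures and independent oracles. Everything is built in code;
# nothing is read from disk except through the package's own writers.

# tiny ontologies used across the semantic-similarity tests ------------------

# chain: root -> a -> d1, with disease ids mapped 1:1 onto terms
chain_ontology <- function() {
  ontology_from_edges(
    edges = list(c("d1", "a"), c("a", "root")),
    disease_terms = list(d1 = "d1", a = "a", root = "root")
  )
}

# siblings d1, d2 under one root
sibling_ontology <- function() {
  ontology_from_edges(
    edges = list(c("d1", "root"), c("d2", "root")),
    disease_terms = list(d1 = "d1", d2 = "d2")
  )
}

# diamond: two upward paths from d of lengths 2 and 3
diamond_ontology <- function() {
  ontology_from_edges(
    edges = list(c("d", "a"), c("a", "root"),
                 c("d", "b"), c("b", "c"), c("c", "root")),
    disease_terms = list(d = "d")
  )
}

ontology_from_edges <- function(edges, disease_terms) {
  tmp <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(
    c("#edges",
      vapply(edges, paste, "", collapse = "\t"),
      "#diseases",
      paste(names(disease_terms),
            vapply(disease_terms, `[[`, "", 1L), sep = "\t")),
    tmp
  )
  read_disease_ontology(tmp)
}

# quadratic-space Needleman-Wunsch oracle, independent of Biostrings ----------
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- gap * (0:n)
  D[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      D[i + 1L, j + 1L] <- max(D[i, j] + s, D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  }
  D[n + 1L, m + 1L]
}

# all-pairs concordance AUC oracle
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (s in pos) tot <- tot + sum(s > neg) + 0.5 * sum(s == neg)
  tot / (length(pos) * length(neg))
}

# brute-force normalized Hamming similarity between two binary vectors
hamming_oracle <- function(u, v) 1 - sum(u != v) / length(u)

# random symmetric kernel with unit diagonal
random_kernel <- function(n, axis = "miRNA", name = "k", seed = NULL) {
  gen <- function() {
    A <- matrix(runif(n * n), n)
    K <- (A + t(A)) / 2
    diag(K) <- 1
    dimnames(K) <- list(paste0("e", seq_len(n)), paste0("e", seq_len(n)))
    similarity_kernel(K, axis = axis, name = name)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# small association object from an explicit matrix (keeps all-zero profiles)
assoc_from_matrix <- function(Y, mirna_ids = NULL, disease_ids = NULL) {
  if (is.null(mirna_ids)) mirna_ids <- sprintf("m%02d", seq_len(nrow(Y)))
  if (is.null(disease_ids)) disease_ids <- sprintf("d%02d", seq_len(ncol(Y)))
  storage.mode(Y) <- "integer"
  dimnames(Y) <- list(mirna_ids, disease_ids)
  mdaskf:::new_mda_assoc(Y)
}
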