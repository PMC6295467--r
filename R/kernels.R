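# The six base similarity kernels. Each builder returns a symmetric matrix
# in [0,1] with unit diagonal for entities whose inputs are defined;
# entities with no usable auxiliary data (no ontology node, no gene set,
# empty disease set) get the declared fallback: off-diagonal 0, diagonal 1.

#' Construct a labeled similarity kernel
#'
#' @param K Square numeric matrix with identical row and column names.
#' @param axis `"miRNA"` or `"disease"` (`"unknown"` allowed for generic
#'   matrices read back from disk).
#' @param name Kernel label, e.g. `"semantic"`, `"sequence"`, `"fused"`.
#' @param validate Check non-negativity and label agreement.
#' @return An object of class `similarity_kernel` with fields `K`, `ids`,
#'   `axis`, `name`.
#' @export
similarity_kernel <- function(K, axis, name = "kernel", validate = TRUE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (is.null(rownames(K))) {
    rownames(K) <- colnames(K) <- paste0("e", seq_len(nrow(K)))
  }
  if (validate) {
    if (!identical(rownames(K), colnames(K))) {
      abort("kernel row and column labels differ")
    }
    if (any(K < 0)) abort("similarity kernel has negative entries")
  }
  structure(
    list(K = K, ids = rownames(K), axis = axis, name = name),
    class = "similarity_kernel"
  )
}

#' @export
print.similarity_kernel <- function(x, ...) {
  cat(sprintf("<similarity_kernel> %s '%s', %d x %d, range [%.3g, %.3g]\n",
              x$axis, x$name, nrow(x$K), ncol(x$K), min(x$K), max(x$K)))
  invisible(x)
}

#' Extract the plain matrix from a kernel (or pass a matrix through)
#' @param kernel A `similarity_kernel` or numeric matrix.
#' @export
kernel_matrix <- function(kernel) {
  if (inherits(kernel, "similarity_kernel")) kernel$K else kernel
}

check_same_axis <- function(kernels) {
  ids <- lapply(kernels, function(k) k$ids)
  axes <- vapply(kernels, function(k) k$axis, "")
  if (length(unique(axes)) != 1L) abort("kernels are on different axes")
  if (!all(vapply(ids[-1L], identical, TRUE, ids[[1L]]))) {
    abort("kernels have mismatched identifier order")
  }
  invisible(TRUE)
}

# ---- disease semantic similarity -------------------------------------------

#' Semantic contribution profile of one disease in the ontology DAG
#'
#' Walks the ancestor closure `T_d` of the disease's ontology node(s) and
#' assigns each ancestor the decayed contribution
#' `D_d(t) = max over children t' of t inside T_d of delta * D_d(t')`,
#' with `D_d(d) = 1`. The semantic value `DV(d)` is the sum of the profile.
#'
#' @param ontology An `mda_ontology`.
#' @param disease Disease identifier (must map to at least one node).
#' @param delta Semantic contribution decay factor, default 0.5.
#' @return List with `disease`, `scores` (named numeric over `T_d`), `dv`.
#' @export
semantic_profile <- function(ontology, disease, delta = 0.5) {
  start <- ontology$disease_terms[[disease]]
  if (is.null(start) || length(start) == 0L) {
    abort(sprintf("disease '%s' has no ontology node", disease),
          class = "mdaskf_no_ontology_node")
  }
  # ancestor closure by upward BFS over child -> parent links
  closure <- character()
  frontier <- unique(start)
  while (length(frontier)) {
    closure <- c(closure, frontier)
    nxt <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, closure)
  }
  scores <- setNames(rep(0, length(closure)), closure)
  scores[start] <- 1
  # relax decayed contributions upward until fixpoint (DAG: terminates)
  repeat {
    changed <- FALSE
    for (child in closure) {
      for (parent in intersect(ontology$parents[[child]], closure)) {
        v <- delta * scores[[child]]
        if (v > scores[[parent]] + 1e-15) {
          scores[[parent]] <- v
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(disease = disease, scores = scores, dv = sum(scores))
}

#' Disease semantic similarity kernel from a disease ontology
#'
#' Pairwise similarity is the shared semantic contribution relative to the
#' total semantic values:
#' `K(i,j) = sum over t in T_i \eqn{\cap} T_j of (D_i(t) + D_j(t)) / (DV(i) + DV(j))`.
#'
#' @inheritParams semantic_profile
#' @param disease_ids Canonical disease ordering (kernel axis).
#' @return A `similarity_kernel` named `"semantic"` on the disease axis.
#'   Diseases without an ontology node fall back to off-diagonal 0.
#' @export
disease_semantic_kernel <- function(ontology, disease_ids, delta = 0.5) {
  q <- length(disease_ids)
  profiles <- vector("list", q)
  for (j in seq_len(q)) {
    profiles[j] <- list(tryCatch(
      semantic_profile(ontology, disease_ids[j], delta = delta),
      mdaskf_no_ontology_node = function(e) NULL
    ))
  }
  K <- diag(1, q)
  dimnames(K) <- list(disease_ids, disease_ids)
  for (i in seq_len(q - 1L)) {
    pi <- profiles[[i]]
    if (is.null(pi)) next
    for (j in seq.int(i + 1L, q)) {
      pj <- profiles[[j]]
      if (is.null(pj)) next
      common <- intersect(names(pi$scores), names(pj$scores))
      if (length(common)) {
        K[i, j] <- K[j, i] <-
          sum(pi$scores[common] + pj$scores[common]) / (pi$dv + pj$dv)
      }
    }
  }
  similarity_kernel(K, axis = "disease", name = "semantic")
}

# ---- disease functional similarity -----------------------------------------

#' Disease functional similarity kernel from a gene functional network
#'
#' Raw log-likelihood scores are min-max normalized over the whole network;
#' gene-gene functional similarity is 1 on identical genes, the normalized
#' score on network edges, 0 otherwise; gene-to-set similarity is the best
#' match into the set; and the disease-level score averages the best
#' matches of each gene in either set against the other set.
#'
#' @param gene_network An `mda_gene_network`.
#' @param disease_genes Named list disease -> gene set.
#' @param disease_ids Canonical disease ordering.
#' @return A `similarity_kernel` named `"functional"`. Diseases with an
#'   empty (or missing) gene set fall back to off-diagonal 0.
#' @export
disease_functional_kernel <- function(gene_network, disease_genes, disease_ids) {
  if (nrow(gene_network$edges) == 0L) abort("gene network has no edges")
  if (gene_network$lls_max == gene_network$lls_min) {
    abort("degenerate LLS normalization: network min equals max")
  }
  sets <- lapply(setNames(disease_ids, disease_ids), function(d) {
    unique(disease_genes[[d]])
  })
  universe <- unique(unlist(sets, use.names = FALSE))
  q <- length(disease_ids)
  K <- diag(1, q)
  dimnames(K) <- list(disease_ids, disease_ids)
  if (length(universe)) {
    FS <- matrix(0, length(universe), length(universe),
                 dimnames = list(universe, universe))
    diag(FS) <- 1
    ed <- gene_network$edges
    keep <- ed$gene_a %in% universe & ed$gene_b %in% universe
    if (any(keep)) {
      lls_star <- (ed$lls[keep] - gene_network$lls_min) /
        (gene_network$lls_max - gene_network$lls_min)
      ia <- match(ed$gene_a[keep], universe)
      ib <- match(ed$gene_b[keep], universe)
      FS[cbind(ia, ib)] <- lls_star
      FS[cbind(ib, ia)] <- lls_star
    }
    idx <- lapply(sets, match, universe)
    for (i in seq_len(q - 1L)) {
      gi <- idx[[i]]
      if (length(gi) == 0L) next
      for (j in seq.int(i + 1L, q)) {
        gj <- idx[[j]]
        if (length(gj) == 0L) next
        sub <- FS[gi, gj, drop = FALSE]
        K[i, j] <- K[j, i] <-
          (sum(apply(sub, 2L, max)) + sum(apply(sub, 1L, max))) /
          (length(gi) + length(gj))
      }
    }
  }
  similarity_kernel(K, axis = "disease", name = "functional")
}

# ---- miRNA functional similarity (MISIM) -----------------------------------

#' MISIM miRNA functional similarity kernel
#'
#' Two miRNAs are similar when the diseases they are associated with are
#' semantically similar: with `D_i` the disease set of miRNA `i` and `sim`
#' the disease semantic similarity,
#' `K(i,j) = (sum over d in D_i of max over d' in D_j sim(d,d') +
#'            sum over d in D_j of max over d' in D_i sim(d,d')) / (|D_i|+|D_j|)`.
#'
#' @param assoc An `mda_assoc` (its rows define the disease sets).
#' @param disease_semantic The disease semantic `similarity_kernel`, on the
#'   same disease axis as `assoc`.
#' @return A `similarity_kernel` named `"misim"` on the miRNA axis. miRNAs
#'   with an empty disease set (possible after cross-validation masking)
#'   fall back to off-diagonal 0.
#' @export
misim_kernel <- function(assoc, disease_semantic) {
  S <- kernel_matrix(disease_semantic)
  if (!identical(colnames(assoc$Y), colnames(S))) {
    abort("association matrix and semantic kernel disagree on the disease axis")
  }
  p <- nrow(assoc$Y)
  sets <- lapply(seq_len(p), function(i) which(assoc$Y[i, ] == 1L))
  K <- diag(1, p)
  dimnames(K) <- list(assoc$mirna_ids, assoc$mirna_ids)
  for (i in seq_len(p - 1L)) {
    di <- sets[[i]]
    if (length(di) == 0L) next
    for (j in seq.int(i + 1L, p)) {
      dj <- sets[[j]]
      if (length(dj) == 0L) next
      sub <- S[di, dj, drop = FALSE]
      K[i, j] <- K[j, i] <-
        (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
        (length(di) + length(dj))
    }
  }
  similarity_kernel(K, axis = "miRNA", name = "misim")
}

# ---- miRNA sequence similarity ---------------------------------------------

#' miRNA sequence similarity kernel by global alignment
#'
#' Needleman-Wunsch global alignment scores (match +1, mismatch -1, linear
#' gap -1 by default) normalized by the larger self-alignment score and
#' clipped at zero:
#' `K(i,j) = max(0, NW(i,j) / max(NW(i,i), NW(j,j)))`.
#'
#' @param sequences Named character vector of RNA sequences (`A/C/G/U`).
#' @param match,mismatch,gap Alignment scores; `gap` is the (negative)
#'   per-position linear gap score.
#' @return A `similarity_kernel` named `"sequence"` on the miRNA axis.
#' @export
sequence_kernel <- function(sequences, match = 1, mismatch = -1, gap = -1) {
  if (any(!nzchar(sequences))) abort("empty sequence in input")
  if (gap > 0) abort("gap score must be non-positive")
  n <- length(sequences)
  ids <- names(sequences)
  bases <- c("A", "C", "G", "U")
  sub_mat <- matrix(mismatch, 4L, 4L, dimnames = list(bases, bases))
  diag(sub_mat) <- match
  set <- Biostrings::RNAStringSet(unname(sequences))
  nw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    pa <- Biostrings::pairwiseAlignment(
      set[seq_len(j)], set[[j]],
      substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = -gap, type = "global"
    )
    nw[seq_len(j), j] <- Biostrings::score(pa)
    nw[j, seq_len(j)] <- nw[seq_len(j), j]
  }
  self <- diag(nw)
  denom <- outer(self, self, pmax)
  K <- pmax(nw / denom, 0)
  diag(K) <- 1
  similarity_kernel(K, axis = "miRNA", name = "sequence")
}

# ---- Hamming interaction-profile similarity --------------------------------

#' Hamming interaction-profile similarity kernel
#'
#' One minus the normalized Hamming distance between binary interaction
#' profiles: columns of `Y` for diseases (denominator `p`), rows for
#' miRNAs (denominator `q`).
#'
#' @param assoc An `mda_assoc`.
#' @param axis `"disease"` or `"miRNA"`.
#' @return A `similarity_kernel` named `"hamming"`.
#' @export
hamming_profile_kernel <- function(assoc, axis = c("disease", "miRNA")) {
  axis <- match.arg(axis)
  Y <- assoc$Y
  storage.mode(Y) <- "double"
  if (axis == "disease") {
    D <- crossprod(Y, 1 - Y)        # mismatches where col i has 1, col j has 0
    K <- 1 - (D + t(D)) / nrow(Y)
  } else {
    D <- tcrossprod(Y, 1 - Y)
    K <- 1 - (D + t(D)) / ncol(Y)
  }
  diag(K) <- 1
  similarity_kernel(K, axis = axis, name = "hamming")
}

# ---- assembly ---------------------------------------------------------------

#' Build all six base kernels for a dataset
#'
#' @param dataset An `mda_dataset`.
#' @param delta Semantic contribution decay factor.
#' @param match,mismatch,gap Alignment scores for the sequence kernel.
#' @return An `mda_kernels` object: `$mirna` (misim, sequence, hamming) and
#'   `$disease` (semantic, functional, hamming) lists of
#'   `similarity_kernel`s.
#' @export
build_kernels <- function(dataset, delta = 0.5,
                          match = 1, mismatch = -1, gap = -1) {
  semantic <- disease_semantic_kernel(dataset$ontology,
                                      dataset$assoc$disease_ids, delta = delta)
  functional <- disease_functional_kernel(dataset$gene_network,
                                          dataset$disease_genes,
                                          dataset$assoc$disease_ids)
  seqs <- dataset$sequences[dataset$assoc$mirna_ids]
  missing_seq <- vapply(seqs, is.null, TRUE) | is.na(seqs)
  if (any(missing_seq)) {
    abort(sprintf("no sequence for miRNA '%s'",
                  dataset$assoc$mirna_ids[missing_seq][1L]))
  }
  names(seqs) <- dataset$assoc$mirna_ids
  structure(
    list(
      mirna = list(
        misim = misim_kernel(dataset$assoc, semantic),
        sequence = sequence_kernel(seqs, match = match,
                                   mismatch = mismatch, gap = gap),
        hamming = hamming_profile_kernel(dataset$assoc, "miRNA")
      ),
      disease = list(
        semantic = semantic,
        functional = functional,
        hamming = hamming_profile_kernel(dataset$assoc, "disease")
      )
    ),
    class = "mda_kernels"
  )
}

#' @export
print.mda_kernels <- function(x, ...) {
  cat(sprintf("<mda_kernels> miRNA axis: %s | disease axis: %s\n",
              paste(names(x$mirna), collapse = ", "),
              paste(names(x$disease), collapse = ", ")))
  invisible(x)
}

#' Rebuild the association-derived kernels from a (possibly masked) Y
#'
#' The Hamming profile kernels (both axes) and the MISIM kernel are the
#' only kernels that depend on the association matrix; rebuilding them
#' from a masked matrix is what keeps cross-validation free of label
#' leakage. The disease semantic kernel never depends on `Y` and is reused
#' as-is inside MISIM.
#'
#' @param kernels A [build_kernels()] result.
#' @param assoc The (masked) `mda_assoc` to rebuild from.
#' @param recompute Subset of `c("hamming", "misim")`.
#' @return The updated `mda_kernels`.
#' @export
rebuild_y_kernels <- function(kernels, assoc,
                              recompute = c("hamming", "misim")) {
  if ("hamming" %in% recompute) {
    kernels$mirna$hamming <- hamming_profile_kernel(assoc, "miRNA")
    kernels$disease$hamming <- hamming_profile_kernel(assoc, "disease")
  }
  if ("misim" %in% recompute) {
    kernels$mirna$misim <- misim_kernel(assoc, kernels$disease$semantic)
  }
  kernels
}
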