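# Synthetic data generator with planted block structure. Emulates all five
# input sources so the full pipeline is testable without any download:
# a bipartite stochastic-block association matrix, a two-level ontology
# whose subtrees align with the disease blocks, per-block gene cliques with
# high within-block linkage scores, disease gene sets drawn from the
# block's clique, and per-block miRNA sequences mutated from a common
# ancestor. Entities are assigned to blocks round-robin.

#' Simulate a planted-block miRNA-disease dataset
#'
#' @param p,q Numbers of miRNAs and diseases. The defaults (60 x 40) keep a
#'   full cross-validation suite fast while leaving every kernel
#'   informative.
#' @param n_blocks Number of planted blocks shared by both axes.
#' @param d_in,d_out Bernoulli association densities within and across
#'   blocks; `d_out < d_in` is what makes the signal recoverable.
#' @param mut_rate Per-position mutation probability applied to each
#'   block's length-22 ancestor sequence.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-for-bit. `NULL` uses the current RNG state.
#' @param genes_per_block Size of each block's gene clique.
#' @return An `mda_dataset` whose `$blocks` field holds the planted block
#'   assignment of every miRNA and disease and whose `$params` records the
#'   generation parameters.
#' @examples
#' ds <- simulate_mda_dataset(p = 20, q = 15, seed = 42)
#' ds$blocks$disease
#' @export
simulate_mda_dataset <- function(p = 60L, q = 40L, n_blocks = 3L,
                                 d_in = 0.6, d_out = 0.05, mut_rate = 0.1,
                                 seed = NULL, genes_per_block = 8L) {
  if (n_blocks < 1L || p < n_blocks || q < n_blocks) {
    abort("need p >= n_blocks, q >= n_blocks, n_blocks >= 1")
  }
  if (!(d_out >= 0 && d_out < d_in && d_in <= 1)) {
    abort("need 0 <= d_out < d_in <= 1")
  }
  if (mut_rate < 0 || mut_rate > 1) abort("mut_rate must be in [0, 1]")
  gen <- function() {
    mirna_ids <- sprintf("mir-%04d", seq_len(p))
    disease_ids <- sprintf("dis-%04d", seq_len(q))
    mb <- setNames(((seq_len(p) - 1L) %% n_blocks) + 1L, mirna_ids)
    db <- setNames(((seq_len(q) - 1L) %% n_blocks) + 1L, disease_ids)

    same <- outer(mb, db, "==")
    dens <- ifelse(same, d_in, d_out)
    Y <- matrix(rbinom(p * q, 1L, as.numeric(dens)), p, q,
                dimnames = list(mirna_ids, disease_ids))
    # every miRNA and disease keeps at least one association so that no
    # interaction profile is empty before masking
    for (i in which(rowSums(Y) == 0L)) {
      Y[i, sample(which(db == mb[i]), 1L)] <- 1L
    }
    for (j in which(colSums(Y) == 0L)) {
      Y[sample(which(mb == db[j]), 1L), j] <- 1L
    }
    assoc <- new_mda_assoc(Y)

    # ontology: root -> block nodes -> one term per disease
    parents <- c(
      lapply(setNames(sprintf("B%02d", seq_len(n_blocks)),
                      sprintf("B%02d", seq_len(n_blocks))),
             function(...) "ROOT"),
      lapply(setNames(paste0("T.", disease_ids), paste0("T.", disease_ids)),
             function(x) character())
    )
    for (j in seq_len(q)) {
      parents[[paste0("T.", disease_ids[j])]] <- sprintf("B%02d", db[j])
    }
    ontology <- new_mda_ontology(
      parents, lapply(setNames(disease_ids, disease_ids),
                      function(d) paste0("T.", d))
    )

    # gene network: within-block cliques with high LLS, sparse weak
    # cross-block edges
    genes <- lapply(seq_len(n_blocks), function(b) {
      sprintf("gene-b%d-%02d", b, seq_len(genes_per_block))
    })
    ga <- character(); gb <- character(); lls <- numeric()
    for (b in seq_len(n_blocks)) {
      cmb <- utils::combn(genes[[b]], 2L)
      ga <- c(ga, cmb[1L, ]); gb <- c(gb, cmb[2L, ])
      lls <- c(lls, runif(ncol(cmb), 2.5, 3.5))
    }
    if (n_blocks > 1L) {
      for (b in seq_len(n_blocks)) {
        other <- setdiff(seq_len(n_blocks), b)
        for (x in seq_len(2L)) {
          b2 <- other[sample.int(length(other), 1L)]
          ga <- c(ga, sample(genes[[b]], 1L))
          gb <- c(gb, sample(genes[[b2]], 1L))
          lls <- c(lls, runif(1L, 0.5, 1.0))
        }
      }
    } else {
      # a single weak edge keeps the min-max normalization non-degenerate
      lls[1L] <- 0.5
    }
    edges <- tibble(gene_a = ga, gene_b = gb, lls = lls)
    edges <- edges[!duplicated(t(apply(cbind(ga, gb), 1L, sort))), ]
    gene_network <- new_gene_network(edges)

    disease_genes <- lapply(setNames(disease_ids, disease_ids), function(d) {
      pool <- genes[[db[[d]]]]
      sort(sample(pool, sample(3:5, 1L)))
    })

    # sequences: block ancestors with i.i.d. point mutations
    bases <- c("A", "C", "G", "U")
    ancestors <- replicate(n_blocks,
                           paste(sample(bases, 22L, replace = TRUE),
                                 collapse = ""))
    sequences <- vapply(seq_len(p), function(i) {
      s <- strsplit(ancestors[mb[i]], "")[[1L]]
      hit <- runif(length(s)) < mut_rate
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L), "")
      }
      paste(s, collapse = "")
    }, "")
    names(sequences) <- mirna_ids

    new_mda_dataset(
      assoc, ontology, gene_network, disease_genes, sequences,
      blocks = list(mirna = mb, disease = db),
      params = list(p = p, q = q, n_blocks = n_blocks, d_in = d_in,
                    d_out = d_out, mut_rate = mut_rate, seed = seed,
                    genes_per_block = genes_per_block)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @rdname simulate_mda_dataset
#' @export
generate_synthetic_dataset <- simulate_mda_dataset
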