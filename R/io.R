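# Readers and writers for the five plain-text input formats plus labeled
# kernel/score matrices. All formats are TAB-separated; lines that are
# blank or start with '#' are skipped (except FASTA, handled by Biostrings).

read_tsv_records <- function(path, n_fields, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < n_fields)
  if (length(bad)) {
    abort(sprintf(
      "malformed %s record in %s at line %d: expected %d tab-separated fields",
      what, path, keep[bad[1L]], n_fields
    ))
  }
  list(fields = fields, lines = keep)
}

#' Read a miRNA-disease association pair list
#'
#' @param path TSV file with two columns `mirna_id<TAB>disease_id`; lines
#'   starting with `#` are treated as comments/headers.
#' @return An [association_matrix()] object (`mda_assoc`).
#' @export
read_association_list <- function(path) {
  rec <- read_tsv_records(path, 2L, "association")
  if (length(rec$fields) == 0L) abort(sprintf("empty association file: %s", path))
  association_matrix(data.frame(
    mirna = vapply(rec$fields, `[[`, "", 1L),
    disease = vapply(rec$fields, `[[`, "", 2L)
  ))
}

#' @rdname read_association_list
#' @param assoc An `mda_assoc` object.
#' @export
write_association_list <- function(assoc, path) {
  idx <- which(assoc$Y == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  writeLines(
    c("#mirna_id\tdisease_id",
      paste(assoc$mirna_ids[idx[, 1L]], assoc$disease_ids[idx[, 2L]], sep = "\t")),
    path
  )
  invisible(path)
}

new_mda_ontology <- function(parents, disease_terms) {
  terms <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
  edges <- cbind(
    rep(names(parents), lengths(parents)),
    unlist(parents, use.names = FALSE)
  )
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) abort("disease ontology contains a cycle")
  }
  structure(
    list(parents = parents, terms = terms, disease_terms = disease_terms),
    class = "mda_ontology"
  )
}

#' @export
print.mda_ontology <- function(x, ...) {
  cat(sprintf("<mda_ontology> %d terms, %d mapped diseases\n",
              length(x$terms), length(x$disease_terms)))
  invisible(x)
}

#' Read a disease ontology (DAG) file
#'
#' Two dialects are accepted. The sectioned dialect has an `#edges` section
#' of `term_id<TAB>parent_term_id` child-to-parent links followed by a
#' `#diseases` section of `disease_id<TAB>term_id` mappings. The tree-number
#' dialect is a plain two-column `disease_id<TAB>tree_number` file (e.g.
#' `Melanoma<TAB>C04.557.465`): parent links are derived by truncating the
#' last dot-separated segment, mirroring MeSH tree numbers.
#'
#' @param path Path to the ontology file.
#' @return An `mda_ontology` object with fields `parents` (named list,
#'   child term -> parent terms), `terms`, and `disease_terms` (named list,
#'   disease -> mapped term(s)).
#' @export
read_disease_ontology <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  has_sections <- any(trimmed == "#edges") && any(trimmed == "#diseases")
  if (has_sections) {
    section <- ""
    edge_child <- character()
    edge_parent <- character()
    map_dis <- character()
    map_term <- character()
    for (i in seq_along(trimmed)) {
      ln <- trimmed[i]
      if (!nzchar(ln)) next
      if (ln %in% c("#edges", "#diseases")) {
        section <- ln
        next
      }
      if (startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 2L) {
        abort(sprintf("malformed ontology record in %s at line %d", path, i))
      }
      if (section == "#edges") {
        edge_child <- c(edge_child, f[1L]); edge_parent <- c(edge_parent, f[2L])
      } else if (section == "#diseases") {
        map_dis <- c(map_dis, f[1L]); map_term <- c(map_term, f[2L])
      } else {
        abort(sprintf("ontology record outside a section in %s at line %d", path, i))
      }
    }
    parents <- split(edge_parent, factor(edge_child, levels = unique(edge_child)))
    parents <- lapply(parents, unique)
    disease_terms <- lapply(split(map_term, factor(map_dis, levels = unique(map_dis))), unique)
    return(new_mda_ontology(parents, disease_terms))
  }
  # tree-number dialect
  rec <- read_tsv_records(path, 2L, "ontology")
  dis <- vapply(rec$fields, `[[`, "", 1L)
  tn <- vapply(rec$fields, `[[`, "", 2L)
  ontology_from_tree_numbers(dis, tn)
}

#' Build an ontology from MeSH-style tree numbers
#'
#' @param disease_ids,tree_numbers Parallel character vectors mapping each
#'   disease to one tree number (repeat the disease for multiple numbers).
#' @return An `mda_ontology`.
#' @export
ontology_from_tree_numbers <- function(disease_ids, tree_numbers) {
  nodes <- unique(tree_numbers)
  # close under prefix truncation so every ancestor exists as a node
  all_nodes <- character()
  for (tn in nodes) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    all_nodes <- c(all_nodes, vapply(seq_along(parts), function(k) {
      paste(parts[seq_len(k)], collapse = ".")
    }, ""))
  }
  all_nodes <- unique(all_nodes)
  parent_of <- function(tn) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    if (length(parts) <= 1L) return(character())
    paste(parts[-length(parts)], collapse = ".")
  }
  parents <- lapply(setNames(all_nodes, all_nodes), parent_of)
  parents <- parents[lengths(parents) > 0L]
  disease_terms <- lapply(
    split(tree_numbers, factor(disease_ids, levels = unique(disease_ids))),
    unique
  )
  new_mda_ontology(parents, disease_terms)
}

#' @rdname read_disease_ontology
#' @param ontology An `mda_ontology` object.
#' @export
write_disease_ontology <- function(ontology, path) {
  edge_lines <- unlist(lapply(names(ontology$parents), function(ch) {
    paste(ch, ontology$parents[[ch]], sep = "\t")
  }), use.names = FALSE)
  map_lines <- unlist(lapply(names(ontology$disease_terms), function(d) {
    paste(d, ontology$disease_terms[[d]], sep = "\t")
  }), use.names = FALSE)
  writeLines(c("#edges", edge_lines, "#diseases", map_lines), path)
  invisible(path)
}

new_gene_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b", "lls") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) abort("gene network contains self-loop edges")
  structure(
    list(
      edges = as_tibble(edges),
      gene_ids = unique(c(edges$gene_a, edges$gene_b)),
      lls_min = min(edges$lls), lls_max = max(edges$lls)
    ),
    class = "mda_gene_network"
  )
}

#' @export
print.mda_gene_network <- function(x, ...) {
  cat(sprintf("<mda_gene_network> %d genes, %d edges, LLS in [%.3g, %.3g]\n",
              length(x$gene_ids), nrow(x$edges), x$lls_min, x$lls_max))
  invisible(x)
}

#' Read a gene functional-linkage network
#'
#' @param path TSV with columns `gene_a<TAB>gene_b<TAB>lls_score` (raw
#'   log-likelihood scores, HumanNet style).
#' @return An `mda_gene_network` with the edge table and network-wide
#'   `lls_min`/`lls_max` used for min-max normalization.
#' @export
read_gene_network <- function(path) {
  rec <- read_tsv_records(path, 3L, "gene network")
  if (length(rec$fields) == 0L) abort(sprintf("empty gene network file: %s", path))
  lls <- suppressWarnings(as.numeric(vapply(rec$fields, `[[`, "", 3L)))
  if (anyNA(lls)) {
    abort(sprintf("malformed gene network record in %s at line %d: non-numeric score",
                  path, rec$lines[which(is.na(lls))[1L]]))
  }
  new_gene_network(tibble(
    gene_a = vapply(rec$fields, `[[`, "", 1L),
    gene_b = vapply(rec$fields, `[[`, "", 2L),
    lls = lls
  ))
}

#' @rdname read_gene_network
#' @param network An `mda_gene_network`.
#' @export
write_gene_network <- function(network, path) {
  writeLines(
    c("#gene_a\tgene_b\tlls",
      sprintf("%s\t%s\t%.17g", network$edges$gene_a, network$edges$gene_b,
              network$edges$lls)),
    path
  )
  invisible(path)
}

#' Read a disease-to-gene map
#'
#' @param path TSV with columns `disease_id<TAB>gene_id` (SIDD style).
#' @return A named list mapping each disease to its deduplicated gene set.
#' @export
read_disease_genes <- function(path) {
  rec <- read_tsv_records(path, 2L, "disease-gene")
  dis <- vapply(rec$fields, `[[`, "", 1L)
  gene <- vapply(rec$fields, `[[`, "", 2L)
  lapply(split(gene, factor(dis, levels = unique(dis))), unique)
}

#' @rdname read_disease_genes
#' @param disease_genes Named list disease -> gene ids.
#' @export
write_disease_genes <- function(disease_genes, path) {
  lines <- unlist(lapply(names(disease_genes), function(d) {
    paste(d, disease_genes[[d]], sep = "\t")
  }), use.names = FALSE)
  writeLines(c("#disease_id\tgene_id", lines), path)
  invisible(path)
}

#' Read miRNA sequences from FASTA
#'
#' Sequences are upper-cased and DNA-style `T` is mapped to `U`, so both
#' RNA and DNA FASTA files are accepted.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences over `{A,C,G,U}`.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence in %s: %s", path,
                  names(seqs)[!nzchar(seqs)][1L]))
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    abort(sprintf("non-ACGU character in sequence %s", names(seqs)[bad][1L]))
  }
  seqs
}

#' @rdname read_sequences
#' @param sequences Named character vector of sequences.
#' @export
write_sequences <- function(sequences, path) {
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path)
  invisible(path)
}

#' Write / read a labeled square matrix (similarity kernel or score matrix)
#'
#' The format is TSV with identifiers in the first row and first column;
#' values are written with 17 significant digits so that
#' `read_kernel(write_kernel(K, f))` reproduces `K` exactly.
#'
#' @param kernel A [similarity_kernel()] (or any labeled numeric matrix).
#' @param path Output path.
#' @return `write_kernel` returns `path` invisibly; `read_kernel` returns a
#'   `similarity_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  K <- kernel_matrix(kernel)
  axis <- if (inherits(kernel, "similarity_kernel")) kernel$axis else "unknown"
  name <- if (inherits(kernel, "similarity_kernel")) kernel$name else "kernel"
  header <- paste(c(sprintf("#%s:%s", axis, name), colnames(K)), collapse = "\t")
  body <- vapply(seq_len(nrow(K)), function(i) {
    paste(c(rownames(K)[i], sprintf("%.17g", K[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(sprintf("not a kernel matrix file: %s", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  meta <- strsplit(sub("^#", "", header[1L]), ":", fixed = TRUE)[[1L]]
  ids <- header[-1L]
  n <- length(ids)
  if (length(lines) - 1L != n) {
    abort(sprintf("non-square kernel matrix in %s: %d columns, %d rows",
                  path, n, length(lines) - 1L))
  }
  K <- matrix(NA_real_, n, n, dimnames = list(character(n), ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n + 1L) {
      abort(sprintf("malformed kernel row in %s at line %d", path, i + 1L))
    }
    rownames(K)[i] <- f[1L]
    K[i, ] <- as.numeric(f[-1L])
  }
  if (anyNA(K)) abort(sprintf("non-numeric kernel entries in %s", path))
  similarity_kernel(
    K,
    axis = if (length(meta) >= 1L && meta[1L] %in% c("miRNA", "disease")) meta[1L] else "unknown",
    name = if (length(meta) >= 2L) meta[2L] else "kernel",
    validate = FALSE
  )
}

#' Load and align the five input files into one dataset
#'
#' The association file defines the canonical miRNA and disease universes
#' (sorted lexicographically); auxiliary sources are aligned onto them.
#' Entities present in the association matrix but missing from an auxiliary
#' source are retained — the kernel builders give them the declared
#' fallback (off-diagonal 0, diagonal 1).
#'
#' @param assoc_path,ontology_path,gene_net_path,disease_gene_path,fasta_path
#'   Paths to the five inputs (see the reader functions for formats).
#' @param quiet Suppress the load report.
#' @return An `mda_dataset`: list with `assoc`, `ontology`, `gene_network`,
#'   `disease_genes`, `sequences`.
#' @export
load_dataset <- function(assoc_path, ontology_path, gene_net_path,
                         disease_gene_path, fasta_path, quiet = FALSE) {
  assoc <- read_association_list(assoc_path)
  ontology <- read_disease_ontology(ontology_path)
  gene_network <- read_gene_network(gene_net_path)
  disease_genes <- read_disease_genes(disease_gene_path)
  sequences <- read_sequences(fasta_path)
  ds <- new_mda_dataset(assoc, ontology, gene_network, disease_genes, sequences)
  if (!quiet) {
    n_ont <- sum(assoc$disease_ids %in% names(ontology$disease_terms))
    n_gen <- sum(assoc$disease_ids %in% names(disease_genes))
    n_seq <- sum(assoc$mirna_ids %in% names(sequences))
    message(sprintf(
      paste0("loaded %d miRNAs x %d diseases (%d associations); ",
             "ontology terms for %d/%d diseases, gene sets for %d/%d, ",
             "sequences for %d/%d miRNAs"),
      nrow(assoc$Y), ncol(assoc$Y), sum(assoc$Y),
      n_ont, ncol(assoc$Y), n_gen, ncol(assoc$Y), n_seq, nrow(assoc$Y)
    ))
  }
  ds
}

new_mda_dataset <- function(assoc, ontology, gene_network, disease_genes,
                            sequences, blocks = NULL, params = NULL) {
  structure(
    list(assoc = assoc, ontology = ontology, gene_network = gene_network,
         disease_genes = disease_genes, sequences = sequences,
         blocks = blocks, params = params),
    class = "mda_dataset"
  )
}

#' @export
print.mda_dataset <- function(x, ...) {
  cat(sprintf("<mda_dataset> %d miRNAs x %d diseases, %d associations%s\n",
              nrow(x$assoc$Y), ncol(x$assoc$Y), sum(x$assoc$Y),
              if (!is.null(x$blocks)) " (synthetic, planted blocks)" else ""))
  invisible(x)
}

#' Write all five dataset files to a directory
#'
#' @param dataset An `mda_dataset`.
#' @param dir Output directory (created if needed).
#' @return A named character vector of the written paths.
#' @export
write_mda_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    assoc = file.path(dir, "associations.tsv"),
    ontology = file.path(dir, "disease_ontology.tsv"),
    gene_net = file.path(dir, "gene_network.tsv"),
    disease_genes = file.path(dir, "disease_genes.tsv"),
    fasta = file.path(dir, "mirna_sequences.fasta")
  )
  write_association_list(dataset$assoc, paths[["assoc"]])
  write_disease_ontology(dataset$ontology, paths[["ontology"]])
  write_gene_network(dataset$gene_network, paths[["gene_net"]])
  write_disease_genes(dataset$disease_genes, paths[["disease_genes"]])
  write_sequences(dataset$sequences, paths[["fasta"]])
  if (!is.null(dataset$blocks)) {
    truth <- file.path(dir, "truth.tsv")
    writeLines(
      c("#entity_id\taxis\tblock",
        paste(names(dataset$blocks$mirna), "miRNA", dataset$blocks$mirna, sep = "\t"),
        paste(names(dataset$blocks$disease), "disease", dataset$blocks$disease, sep = "\t")),
      truth
    )
    paths <- c(paths, truth = truth)
  }
  paths
}

#' @rdname write_mda_dataset
#' @export
read_mda_dataset <- function(dir, quiet = FALSE) {
  load_dataset(
    file.path(dir, "associations.tsv"),
    file.path(dir, "disease_ontology.tsv"),
    file.path(dir, "gene_network.tsv"),
    file.path(dir, "disease_genes.tsv"),
    file.path(dir, "mirna_sequences.fasta"),
    quiet = quiet
  )
}
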