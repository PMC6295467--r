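#' Build a binary miRNA-disease association matrix from a pair list
#'
#' Converts a two-column table of known (miRNA, disease) pairs into the
#' binary bipartite matrix `Y` (p miRNAs x q diseases) that every
#' downstream step consumes. Identifiers are ordered lexicographically so
#' the matrix is reproducible regardless of row order in the input.
#'
#' @param pairs A data frame whose first two columns are miRNA and disease
#'   identifiers (one row per known association). Extra columns are ignored.
#' @return An object of class `mda_assoc`: a list with `Y` (binary matrix
#'   with dimnames), `mirna_ids` and `disease_ids`.
#' @details Duplicated pairs are collapsed to a single 1 with a warning.
#'   The column `Y[, j]` is the interaction profile of disease `j`
#'   and the row `Y[i, ]` the interaction profile of miRNA `i`.
#' @examples
#' assoc <- association_matrix(
#'   data.frame(mirna = c("m1", "m1", "m2"), disease = c("d1", "d2", "d2"))
#' )
#' assoc$Y
#' @export
association_matrix <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) {
    abort("association pair list is empty")
  }
  if (ncol(pairs) < 2L) {
    abort("association pair list needs two columns: mirna, disease")
  }
  mir <- as.character(pairs[[1L]])
  dis <- as.character(pairs[[2L]])
  if (anyNA(mir) || anyNA(dis) || any(mir == "") || any(dis == "")) {
    abort("association pair list contains missing identifiers")
  }
  key <- paste(mir, dis, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warn(sprintf("removed %d duplicated association pair(s)", n_dup))
    keep <- !duplicated(key)
    mir <- mir[keep]
    dis <- dis[keep]
  }
  mirna_ids <- sort(unique(mir))
  disease_ids <- sort(unique(dis))
  Y <- matrix(0L, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  Y[cbind(match(mir, mirna_ids), match(dis, disease_ids))] <- 1L
  new_mda_assoc(Y)
}

new_mda_assoc <- function(Y) {
  stopifnot(is.matrix(Y), !is.null(rownames(Y)), !is.null(colnames(Y)))
  if (!all(Y %in% c(0L, 1L))) abort("association matrix entries must be 0 or 1")
  if (anyDuplicated(rownames(Y)) || anyDuplicated(colnames(Y))) {
    abort("duplicated identifiers in association matrix")
  }
  structure(
    list(Y = Y, mirna_ids = rownames(Y), disease_ids = colnames(Y)),
    class = "mda_assoc"
  )
}

#' @export
print.mda_assoc <- function(x, ...) {
  cat(sprintf(
    "<mda_assoc> %d miRNAs x %d diseases, %d known associations\n",
    nrow(x$Y), ncol(x$Y), sum(x$Y)
  ))
  invisible(x)
}

#' @export
dim.mda_assoc <- function(x) dim(x$Y)

#' Tidy an association matrix into a long pair table
#'
#' @param x An `mda_assoc` object.
#' @param known_only If `TRUE` (default) return only the known pairs.
#' @param ... Unused.
#' @return A tibble with columns `mirna`, `disease`, `known`.
#' @method tidy mda_assoc
#' @export
tidy.mda_assoc <- function(x, known_only = TRUE, ...) {
  out <- tibble(
    mirna = rep(x$mirna_ids, times = length(x$disease_ids)),
    disease = rep(x$disease_ids, each = length(x$mirna_ids)),
    known = as.integer(x$Y)
  )
  if (known_only) out <- dplyr::filter(out, .data$known == 1L)
  out
}

# Return a copy with the given positive entries (2-column index matrix or
# pair tibble) reset to 0 -- the masking primitive used by every CV scheme.
mask_assoc <- function(assoc, idx) {
  Y <- assoc$Y
  Y[idx] <- 0L
  new_mda_assoc(Y)
}
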