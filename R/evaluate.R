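# Cross-validation protocols and ranking metrics. All three schemes mask
# known associations (set their Y entries to 0), rebuild the
# association-derived kernels from the masked matrix (to avoid label
# leakage), refit, and rank the held-out positives among the pairs that
# are unknown in the original matrix. The input dataset is never mutated.

#' Area under the ROC curve for two score sets
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counting one half.
#'
#' @param scores_pos,scores_neg Numeric score vectors, both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    abort("AUC is undefined when either class is empty")
  }
  np <- length(scores_pos)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(scores_neg))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: scores are sorted in decreasing order
#' (stable, positives listed before negatives on exact ties) and precision
#' is accumulated at each recall step.
#'
#' @inheritParams compute_auc
#' @return AUPR in `(0, 1]`.
#' @export
compute_aupr <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    abort("AUPR is undefined when either class is empty")
  }
  np <- length(scores_pos)
  s <- c(scores_pos, scores_neg)
  lab <- c(rep(1L, np), rep(0L, length(scores_neg)))
  ord <- order(s, decreasing = TRUE)   # stable: ties keep input order
  lab <- lab[ord]
  hits <- cumsum(lab)
  sum((hits / seq_along(lab))[lab == 1L]) / np
}

# rank of score s within {s} + neg (1 = best), and its AUC contribution
rank_of <- function(s, neg) 1 + sum(neg > s) + 0.5 * sum(neg == s)
conc_of <- function(s, neg) (sum(neg < s) + 0.5 * sum(neg == s)) / length(neg)

# Merge per-positive ranks (each against an equal-size negative pool) into
# one ranking and compute average precision on it. Used for pooling across
# folds that share the negative universe.
pooled_ap_from_ranks <- function(ranks) {
  r <- sort(ranks)
  i <- seq_along(r)
  mean(i / (r + i - 1))
}

fit_masked <- function(assoc_masked, kernels, fusion, laprls, recompute) {
  ks <- rebuild_y_kernels(kernels, assoc_masked, recompute)
  mda_skf(assoc_masked, kernels = ks, fusion = fusion, laprls = laprls)
}

new_mda_cv <- function(scheme, per_unit, ranks, pooled_auc, pooled_aupr,
                       fusion, laprls) {
  structure(
    list(scheme = scheme, per_unit = per_unit, ranks = ranks,
         pooled_auc = pooled_auc, pooled_aupr = pooled_aupr,
         fusion = fusion, laprls = laprls),
    class = "mda_cv"
  )
}

#' @export
print.mda_cv <- function(x, ...) {
  cat(sprintf("<mda_cv> scheme=%s, pooled AUC=%.4f%s\n",
              x$scheme, x$pooled_auc,
              if (is.na(x$pooled_aupr)) ""
              else sprintf(", pooled AUPR=%.4f", x$pooled_aupr)))
  invisible(x)
}

#' Tidy per-fold (or per-disease) cross-validation metrics
#' @param x An `mda_cv` object.
#' @param ... Unused.
#' @method tidy mda_cv
#' @export
tidy.mda_cv <- function(x, ...) x$per_unit

#' One-row pooled cross-validation summary
#' @param x An `mda_cv` object.
#' @param ... Unused.
#' @method glance mda_cv
#' @export
glance.mda_cv <- function(x, ...) {
  tibble(scheme = x$scheme, pooled_auc = x$pooled_auc,
         pooled_aupr = x$pooled_aupr,
         n_units = nrow(x$per_unit), n_positives = nrow(x$ranks))
}

#' Plot per-unit cross-validation AUCs
#' @param object An `mda_cv` object.
#' @param ... Unused.
#' @method autoplot mda_cv
#' @export
autoplot.mda_cv <- function(object, ...) {
  df <- object$per_unit
  df$unit <- factor(df$unit, levels = df$unit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$pooled_auc, linetype = 2) +
    ggplot2::labs(x = object$scheme, y = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Global leave-one-out cross-validation
#'
#' Each known association is masked in turn, the association-derived
#' kernels are rebuilt from the masked matrix, the model is refit, and the
#' held-out pair is ranked against all pairs unknown in the original
#' matrix. The pooled AUC averages each held-out positive's concordance
#' against the unknown-pair scores of its own refit; the pooled AUPR
#' merges the per-positive ranks into one ranking.
#'
#' @param dataset An `mda_dataset`.
#' @param fusion A [fusion_config()].
#' @param laprls A [laprls_config()].
#' @param recompute Which association-derived kernels to rebuild inside
#'   each fold: subset of `c("hamming", "misim")`. The default rebuilds
#'   both; `recompute = "hamming"` is the fast mode (MISIM is the
#'   expensive rebuild at leave-one-out granularity).
#' @param kernels Optional precomputed [build_kernels()] result.
#' @return An `mda_cv` object.
#' @export
run_global_loocv <- function(dataset, fusion = fusion_config(),
                             laprls = laprls_config(),
                             recompute = c("hamming", "misim"),
                             kernels = NULL) {
  assoc <- dataset$assoc
  pos <- which(assoc$Y == 1L, arr.ind = TRUE)
  if (nrow(pos) < 2L) abort("global LOOCV needs at least two positives")
  if (is.null(kernels)) kernels <- build_kernels(dataset)
  neg_idx <- which(assoc$Y == 0L)
  rows <- vector("list", nrow(pos))
  for (f in seq_len(nrow(pos))) {
    masked <- mask_assoc(assoc, pos[f, , drop = FALSE])
    fit <- fit_masked(masked, kernels, fusion, laprls, recompute)
    s <- fit$F_star[pos[f, 1L], pos[f, 2L]]
    neg <- fit$F_star[neg_idx]
    rows[[f]] <- tibble(
      fold = f,
      mirna = assoc$mirna_ids[pos[f, 1L]],
      disease = assoc$disease_ids[pos[f, 2L]],
      score = s,
      rank = rank_of(s, neg),
      auc = conc_of(s, neg),
      n_neg = length(neg)
    )
  }
  ranks <- dplyr::bind_rows(rows)
  per_unit <- tibble(unit = "pooled", n_pos = nrow(ranks),
                     n_neg = length(neg_idx),
                     auc = mean(ranks$auc),
                     aupr = pooled_ap_from_ranks(ranks$rank))
  new_mda_cv("global-loocv", per_unit, ranks,
             pooled_auc = mean(ranks$auc),
             pooled_aupr = pooled_ap_from_ranks(ranks$rank),
             fusion, laprls)
}

#' Local (per-disease) leave-one-out cross-validation
#'
#' For each disease with at least one known miRNA, its whole association
#' column is masked, the model refit, and all miRNAs ranked for that
#' disease; the disease's AUC/AUPR uses its true miRNAs as positives and
#' the remaining miRNAs as negatives. The summary AUC is the mean over
#' evaluated diseases. Diseases associated with every miRNA are skipped
#' with a warning.
#'
#' @inheritParams run_global_loocv
#' @return An `mda_cv` object; `pooled_auc` is the mean per-disease AUC.
#' @export
run_local_loocv <- function(dataset, fusion = fusion_config(neighbors = 192L),
                            laprls = laprls_config(2^-1),
                            recompute = c("hamming", "misim"),
                            kernels = NULL) {
  assoc <- dataset$assoc
  npos <- colSums(assoc$Y)
  if (!any(npos >= 1L)) abort("local LOOCV needs a disease with a positive")
  if (is.null(kernels)) kernels <- build_kernels(dataset)
  p <- nrow(assoc$Y)
  units <- list(); rows <- list()
  for (j in which(npos >= 1L)) {
    if (npos[j] == p) {
      warn(sprintf("disease '%s' is associated with every miRNA; skipped",
                   assoc$disease_ids[j]))
      next
    }
    masked <- mask_assoc(assoc, cbind(seq_len(p), j))
    fit <- fit_masked(masked, kernels, fusion, laprls, recompute)
    sc <- fit$F_star[, j]
    is_pos <- assoc$Y[, j] == 1L
    auc <- compute_auc(sc[is_pos], sc[!is_pos])
    aupr <- compute_aupr(sc[is_pos], sc[!is_pos])
    units[[length(units) + 1L]] <- tibble(
      unit = assoc$disease_ids[j], n_pos = sum(is_pos), n_neg = sum(!is_pos),
      auc = auc, aupr = aupr
    )
    rows[[length(rows) + 1L]] <- tibble(
      fold = j, mirna = assoc$mirna_ids[is_pos],
      disease = assoc$disease_ids[j],
      score = sc[is_pos],
      rank = vapply(sc[is_pos], rank_of, 0, neg = sc[!is_pos]),
      auc = vapply(sc[is_pos], conc_of, 0, neg = sc[!is_pos]),
      n_neg = sum(!is_pos)
    )
  }
  per_unit <- dplyr::bind_rows(units)
  new_mda_cv("local-loocv", per_unit, dplyr::bind_rows(rows),
             pooled_auc = mean(per_unit$auc),
             pooled_aupr = mean(per_unit$aupr),
             fusion, laprls)
}

#' k-fold cross-validation over known associations
#'
#' Known pairs are randomly partitioned into `folds` non-overlapping sets
#' (unstratified, seed-controlled). Each fold is masked in turn; held-out
#' positives are scored against all pairs unknown in the original matrix.
#'
#' @inheritParams run_global_loocv
#' @param folds Number of folds, default 5.
#' @param seed Integer seed for the fold partition.
#' @return An `mda_cv` with per-fold and pooled AUC/AUPR.
#' @export
run_kfold_cv <- function(dataset, folds = 5L, seed = 1L,
                         fusion = fusion_config(), laprls = laprls_config(),
                         recompute = c("hamming", "misim"),
                         kernels = NULL) {
  assoc <- dataset$assoc
  pos <- which(assoc$Y == 1L, arr.ind = TRUE)
  if (folds < 2L) abort("folds must be >= 2")
  if (nrow(pos) < folds) abort("fewer positives than folds")
  if (is.null(kernels)) kernels <- build_kernels(dataset)
  perm <- withr::with_seed(seed, sample.int(nrow(pos)))
  fold_of <- integer(nrow(pos))
  fold_of[perm] <- rep_len(seq_len(folds), nrow(pos))
  neg_idx <- which(assoc$Y == 0L)
  units <- vector("list", folds); rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- pos[fold_of == f, , drop = FALSE]
    masked <- mask_assoc(assoc, test)
    fit <- fit_masked(masked, kernels, fusion, laprls, recompute)
    s_pos <- fit$F_star[test]
    s_neg <- fit$F_star[neg_idx]
    units[[f]] <- tibble(
      unit = sprintf("fold%d", f), n_pos = nrow(test), n_neg = length(s_neg),
      auc = compute_auc(s_pos, s_neg), aupr = compute_aupr(s_pos, s_neg)
    )
    rows[[f]] <- tibble(
      fold = f,
      mirna = assoc$mirna_ids[test[, 1L]],
      disease = assoc$disease_ids[test[, 2L]],
      score = s_pos,
      rank = vapply(s_pos, rank_of, 0, neg = s_neg),
      auc = vapply(s_pos, conc_of, 0, neg = s_neg),
      n_neg = length(s_neg)
    )
  }
  ranks <- dplyr::bind_rows(rows)
  new_mda_cv("kfold", dplyr::bind_rows(units), ranks,
             pooled_auc = mean(ranks$auc),
             pooled_aupr = pooled_ap_from_ranks(ranks$rank),
             fusion, laprls)
}

#' Top candidate miRNAs for one disease
#'
#' Ranks the miRNAs whose association with the disease is unknown in `Y`
#' by predicted score (descending; ties broken by miRNA identifier).
#'
#' @param fit A fitted `mda_skf` (or a labeled score matrix).
#' @param disease Disease identifier.
#' @param n Number of candidates, default 50.
#' @param assoc Required when `fit` is a plain matrix.
#' @return Tibble with columns `rank`, `mirna`, `disease`, `score`.
#' @export
top_candidates <- function(fit, disease, n = 50L, assoc = NULL) {
  if (inherits(fit, "mda_skf")) {
    scores <- fit$F_star
    assoc <- fit$assoc
  } else {
    scores <- fit
    if (is.null(assoc)) abort("assoc is required with a plain score matrix")
  }
  if (!disease %in% colnames(scores)) {
    abort(sprintf("unknown disease '%s'", disease))
  }
  unknown <- assoc$Y[, disease] == 0L
  if (!any(unknown)) {
    warn(sprintf("all miRNAs are already associated with '%s'", disease))
    return(tibble(rank = integer(), mirna = character(),
                  disease = character(), score = numeric()))
  }
  s <- unname(scores[unknown, disease])
  df <- tibble(mirna = rownames(scores)[unknown],
               disease = disease,
               score = s)
  df <- dplyr::arrange(df, dplyr::desc(.data$score), .data$mirna)
  if (nrow(df) < n) {
    warn(sprintf("only %d unknown pairs available for '%s' (requested %d)",
                 nrow(df), disease, n))
  }
  df <- head(df, n)
  dplyr::mutate(df, rank = dplyr::row_number(), .before = 1L)
}
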