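# Similarity Kernel Fusion (SKF) and its comparators.
#
# SKF iterates, for each kernel l of a triple,
#   P_l^{t+1} = alpha * S_l %*% (mean of the other P_r^t) %*% t(S_l)
#               + (1 - alpha) * (mean of the other P_r^0)
# where P_l^0 is the column-normalized kernel and S_l the kNN-sparsified,
# row-normalized kernel -- both computed once from the original kernels.
# The fixed (1 - alpha) anchor retains the original information of every
# kernel; a mutual-neighborhood weight matrix then damps entries between
# entities that are not close in the fused kernel.

#' Fusion configuration
#'
#' @param method `"skf"`, `"snf"` or `"avg"`.
#' @param alpha Anchor mixing weight in (0,1); the update keeps a fixed
#'   `(1-alpha)` share of the initial normalized kernels. Default 0.1.
#' @param neighbors Neighborhood size `k` for sparsification and the weight
#'   matrix; clamped to the kernel dimension. Default 36 (the local
#'   leave-one-out protocol uses a larger neighborhood, typically 192, via
#'   its own configuration).
#' @param iterations Number of diffusion iterations `T`, default 10.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(method = c("skf", "snf", "avg"), alpha = 0.1,
                          neighbors = 36L, iterations = 10L) {
  method <- match.arg(method)
  if (method == "skf" && (alpha < 0 || alpha >= 1)) {
    abort("alpha must lie in [0, 1); 0 is the pure-anchor limit")
  }
  if (neighbors < 1L) abort("neighbors must be >= 1")
  if (iterations < 1L) abort("iterations must be >= 1")
  structure(
    list(method = method, alpha = alpha,
         neighbors = as.integer(neighbors), iterations = as.integer(iterations)),
    class = "fusion_config"
  )
}

#' Column-normalize a kernel
#'
#' `P(i,j) = K(i,j) / sum_k K(k,j)`; every column of `P` sums to 1. An
#' all-zero column `j` falls back to the unit column `e_j`.
#'
#' @param K Non-negative square matrix (or `similarity_kernel`).
#' @return A column-stochastic matrix.
#' @export
normalize_kernel <- function(K) {
  K <- kernel_matrix(K)
  if (any(K < 0)) abort("kernel has negative entries")
  cs <- colSums(K)
  zero <- cs == 0
  cs[zero] <- 1
  P <- sweep(K, 2L, cs, "/")
  if (any(zero)) {
    for (j in which(zero)) {
      P[, j] <- 0
      P[j, j] <- 1
    }
  }
  P
}

# k-nearest-neighbor index sets per row: the k largest entries of K[i, ],
# always including i; ties at the k-th rank broken by lower index.
neighbor_sets <- function(K, k) {
  K <- kernel_matrix(K)
  n <- nrow(K)
  k <- min(as.integer(k), n)
  lapply(seq_len(n), function(i) {
    ord <- order(K[i, ], seq_len(n) * -1, decreasing = TRUE)
    top <- ord[seq_len(k)]
    if (!(i %in% top)) top[k] <- i
    sort(top)
  })
}

#' Sparsify a kernel onto k-nearest neighborhoods
#'
#' Keeps, in each row `i`, only the `k` largest entries (self always
#' included; ties at the cut broken by lower index) and renormalizes the
#' row to sum to 1. Rows whose retained mass is zero fall back to `e_i`.
#'
#' @param K Non-negative square matrix (or `similarity_kernel`).
#' @param k Neighborhood size, clamped to `nrow(K)`.
#' @return A row-stochastic sparse (in pattern) matrix.
#' @export
sparsify_kernel <- function(K, k) {
  K <- kernel_matrix(K)
  if (any(K < 0)) abort("kernel has negative entries")
  n <- nrow(K)
  nb <- neighbor_sets(K, k)
  S <- matrix(0, n, n, dimnames = dimnames(K))
  for (i in seq_len(n)) {
    m <- sum(K[i, nb[[i]]])
    if (m == 0) {
      S[i, i] <- 1
    } else {
      S[i, nb[[i]]] <- K[i, nb[[i]]] / m
    }
  }
  S
}

# Mutual-neighborhood weight matrix: 1 when each entity is in the other's
# kNN set, 0 when neither is, 0.5 otherwise.
weight_matrix_from_sets <- function(nb, n) {
  inN <- matrix(FALSE, n, n)
  for (i in seq_len(n)) inN[i, nb[[i]]] <- TRUE   # inN[i, j]: j in N_i
  w <- matrix(0.5, n, n)
  w[inN & t(inN)] <- 1
  w[!inN & !t(inN)] <- 0
  diag(w) <- 1
  w
}

#' Weight matrix of mutual kNN membership
#'
#' @param K Kernel whose rows define the neighborhoods.
#' @param k Neighborhood size.
#' @return Symmetric matrix with entries in `{0, 0.5, 1}` and unit diagonal.
#' @export
weight_matrix <- function(K, k) {
  K <- kernel_matrix(K)
  w <- weight_matrix_from_sets(neighbor_sets(K, k), nrow(K))
  dimnames(w) <- dimnames(K)
  w
}

#' Fuse a triple of similarity kernels with Similarity Kernel Fusion
#'
#' @param kernels List of three `similarity_kernel`s on the same axis and
#'   identifier order (two kernels allowed when `allow_pair = TRUE`).
#' @param config A [fusion_config()].
#' @param allow_pair Permit the two-kernel generalization (the averaging
#'   over the remaining kernels then has a single term).
#' @return An object of class `skf_fusion`: `$kernel` the fused
#'   `similarity_kernel` (weighted and symmetrized), `$unweighted` the
#'   pre-weight average of the final iterates, `$w` the weight matrix,
#'   `$trace` a tibble of per-kernel relative errors
#'   `E_t = ||P^t - P^{t-1}||_F / ||P^{t-1}||_F`, plus the `$P0` and `$S`
#'   operator lists.
#' @export
skf_fuse <- function(kernels, config = fusion_config(), allow_pair = FALSE) {
  L <- length(kernels)
  if (L != 3L && !(allow_pair && L == 2L)) {
    abort("SKF integrates exactly three kernels (set allow_pair for two)")
  }
  check_same_axis(kernels)
  axis <- kernels[[1L]]$axis
  ids <- kernels[[1L]]$ids
  n <- length(ids)
  k <- min(config$neighbors, n)
  P0 <- lapply(kernels, normalize_kernel)
  S <- lapply(kernels, function(x) sparsify_kernel(x, k))
  # the denominator in the cross average is fixed at 2 (three-kernel form);
  # for the two-kernel generalization a single term remains
  denom <- if (L == 3L) 2 else 1
  anchor <- lapply(seq_len(L), function(l) {
    Reduce(`+`, P0[-l]) / denom
  })
  P <- P0
  trace <- vector("list", config$iterations)
  for (t in seq_len(config$iterations)) {
    Pnew <- vector("list", L)
    for (l in seq_len(L)) {
      cross <- Reduce(`+`, P[-l]) / denom
      Pnew[[l]] <- config$alpha * (S[[l]] %*% cross %*% t(S[[l]])) +
        (1 - config$alpha) * anchor[[l]]
    }
    rel_err <- vapply(seq_len(L), function(l) {
      norm(Pnew[[l]] - P[[l]], "F") / norm(P[[l]], "F")
    }, 0)
    trace[[t]] <- tibble(iteration = t, kernel = seq_len(L),
                         kernel_name = vapply(kernels, function(x) x$name, ""),
                         rel_error = rel_err)
    P <- Pnew
  }
  K <- Reduce(`+`, P) / L
  w <- weight_matrix_from_sets(neighbor_sets(K, k), n)
  Kw <- w * K
  Kw <- (Kw + t(Kw)) / 2
  dimnames(Kw) <- list(ids, ids)
  dimnames(w) <- list(ids, ids)
  dimnames(K) <- list(ids, ids)
  structure(
    list(
      kernel = similarity_kernel(Kw, axis = axis, name = "fused"),
      unweighted = K, w = w,
      trace = dplyr::bind_rows(trace),
      P0 = P0, S = S, config = config
    ),
    class = "skf_fusion"
  )
}

#' @export
print.skf_fusion <- function(x, ...) {
  final <- dplyr::filter(x$trace, .data$iteration == max(.data$iteration))
  cat(sprintf(
    "<skf_fusion> %s axis, n=%d, alpha=%g, k=%d, T=%d; final E_T: %s\n",
    x$kernel$axis, nrow(x$kernel$K), x$config$alpha, x$config$neighbors,
    x$config$iterations, paste(signif(final$rel_error, 3), collapse = ", ")
  ))
  invisible(x)
}

#' Tidy the SKF convergence trace
#' @param x An `skf_fusion` object.
#' @param ... Unused.
#' @return Tibble with columns `iteration`, `kernel`, `kernel_name`,
#'   `rel_error`.
#' @method tidy skf_fusion
#' @export
tidy.skf_fusion <- function(x, ...) x$trace

#' Plot the SKF convergence trace
#' @param object An `skf_fusion` object.
#' @param ... Unused.
#' @method autoplot skf_fusion
#' @export
autoplot.skf_fusion <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$rel_error,
                               colour = .data$kernel_name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = expression(E[t]), colour = "kernel") +
    ggplot2::theme_minimal()
}

#' Element-wise average kernel fusion
#'
#' @param kernels List of `similarity_kernel`s on the same axis/order.
#' @return The element-wise mean as a `similarity_kernel` named `"fused"`.
#' @export
avg_fuse <- function(kernels) {
  check_same_axis(kernels)
  K <- Reduce(`+`, lapply(kernels, kernel_matrix)) / length(kernels)
  similarity_kernel(K, axis = kernels[[1L]]$axis, name = "fused")
}

#' Similarity Network Fusion comparator
#'
#' Cross-diffusion without the fixed anchor:
#' `P_l^{t+1} = S_l %*% (mean of the other P_r^t) %*% t(S_l)`, with
#' column renormalization each iteration, final averaging and
#' symmetrization. Included as a benchmark against SKF.
#'
#' @inheritParams skf_fuse
#' @return The fused `similarity_kernel`.
#' @export
snf_fuse <- function(kernels, config = fusion_config(method = "snf")) {
  L <- length(kernels)
  if (L < 2L) abort("SNF needs at least two kernels")
  check_same_axis(kernels)
  ids <- kernels[[1L]]$ids
  n <- length(ids)
  k <- min(config$neighbors, n)
  P <- lapply(kernels, normalize_kernel)
  S <- lapply(kernels, function(x) sparsify_kernel(x, k))
  for (t in seq_len(config$iterations)) {
    Pnew <- vector("list", L)
    for (l in seq_len(L)) {
      cross <- Reduce(`+`, P[-l]) / (L - 1)
      Pnew[[l]] <- normalize_kernel(S[[l]] %*% cross %*% t(S[[l]]))
    }
    P <- Pnew
  }
  K <- Reduce(`+`, P) / L
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  similarity_kernel(K, axis = kernels[[1L]]$axis, name = "fused")
}

#' Fuse with the configured method
#'
#' @param kernels List of `similarity_kernel`s.
#' @param config A [fusion_config()]; its `method` selects SKF, SNF or AVG.
#' @return The fused `similarity_kernel`.
#' @export
fuse_kernels <- function(kernels, config = fusion_config()) {
  switch(config$method,
    skf = skf_fuse(kernels, config)$kernel,
    snf = snf_fuse(kernels, config),
    avg = avg_fuse(kernels)
  )
}
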