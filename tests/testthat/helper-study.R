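# Multi-seed 5-fold study comparing the three fusion strategies on
# default planted synthetic data. Computed once per session and shared by
# the tests that read different aspects of it (ordering, recovery level).
study_cache <- new.env(parent = emptyenv())

fusion_study <- function(seeds = 1:10) {
  key <- paste0("s", paste(seeds, collapse = "_"))
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  rows <- lapply(seeds, function(s) {
    ds <- simulate_mda_dataset(seed = s)
    ks <- build_kernels(ds)
    vapply(c("skf", "avg", "snf"), function(m) {
      cv <- suppressWarnings(run_kfold_cv(
        ds, folds = 5, seed = s, kernels = ks,
        fusion = fusion_config(m)
      ))
      c(auc = cv$pooled_auc, aupr = cv$pooled_aupr)
    }, c(auc = 0, aupr = 0))
  })
  out <- list(
    auc = t(vapply(rows, function(r) r["auc", ], c(skf = 0, avg = 0, snf = 0))),
    aupr = t(vapply(rows, function(r) r["aupr", ], c(skf = 0, avg = 0, snf = 0)))
  )
  study_cache[[key]] <- out
  out
}
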