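test_that("semantic profiles decay along the ancestor chain", {
  prof <- semantic_profile(chain_ontology(), "d1")
  expect_equal(prof$scores[["d1"]], 1)
  expect_equal(prof$scores[["a"]], 0.5)
  expect_equal(prof$scores[["root"]], 0.25)
  expect_equal(prof$dv, 1.75)

  # isolated node: profile is just the disease itself
  iso <- ontology_from_edges(list(c("x", "y")), list(d = "d", x = "x"))
  expect_equal(semantic_profile(iso, "d")$dv, 1)

  # diamond: ancestor takes the best (max) decayed path, not the sum
  dia <- semantic_profile(diamond_ontology(), "d")
  expect_equal(dia$scores[["root"]], 0.25)

  expect_error(semantic_profile(chain_ontology(), "nope"),
               class = "mdaskf_no_ontology_node")
})

test_that("each ancestor scores exactly delta times its best in-closure child", {
  for (seed in 1:5) {
    ds <- simulate_mda_dataset(p = 6, q = 8, seed = seed)
    for (d in ds$assoc$disease_ids) {
      prof <- semantic_profile(ds$ontology, d)
      start <- ds$ontology$disease_terms[[d]]
      for (t in setdiff(names(prof$scores), start)) {
        kids <- names(prof$scores)[vapply(names(prof$scores), function(ch) {
          t %in% ds$ontology$parents[[ch]]
        }, TRUE)]
        expect_equal(prof$scores[[t]], 0.5 * max(prof$scores[kids]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("disease semantic kernel matches hand-derived DAG values", {
  sib <- disease_semantic_kernel(sibling_ontology(), c("d1", "d2"))
  expect_equal(sib$K["d1", "d2"], 1 / 3, tolerance = 1e-12)
  expect_equal(diag(sib$K), c(d1 = 1, d2 = 1))

  ch <- disease_semantic_kernel(chain_ontology(), c("d1", "a"))
  expect_equal(ch$K["d1", "a"], 9 / 13, tolerance = 1e-12)

  # disjoint components share no ancestors
  two <- ontology_from_edges(list(c("d1", "r1"), c("d2", "r2")),
                             list(d1 = "d1", d2 = "d2"))
  expect_equal(disease_semantic_kernel(two, c("d1", "d2"))$K["d1", "d2"], 0)

  # disease missing from the ontology: fallback row
  k <- disease_semantic_kernel(sibling_ontology(), c("d1", "d2", "dX"))
  expect_equal(k$K["dX", c("d1", "d2")], c(d1 = 0, d2 = 0))
  expect_equal(k$K["dX", "dX"], 1)
})

test_that("disease functional kernel follows the LLS min-max construction", {
  # edges (g1,g2)=2, (g3,g4)=1, (g1,g4)=3: network min 1, max 3
  net <- mdaskf:::new_gene_network(tibble::tibble(
    gene_a = c("g1", "g3", "g1"), gene_b = c("g2", "g4", "g4"),
    lls = c(2, 1, 3)
  ))
  dg <- list(dA = "g1", dB = "g2", dC = "g1", dD = "g5")
  k <- disease_functional_kernel(net, dg, c("dA", "dB", "dC", "dD"))
  # raw LLS 2 with min 1, max 3 -> normalized 0.5; singleton sets -> 0.5
  expect_equal(k$K["dA", "dB"], 0.5, tolerance = 1e-12)
  # identical singleton sets -> 1
  expect_equal(k$K["dA", "dC"], 1)
  # no connecting edges -> 0
  expect_equal(k$K["dB", "dD"], 0)
  expect_equal(k$K["dD", "dD"], 1)

  # degenerate normalization: all scores equal
  flat <- mdaskf:::new_gene_network(tibble::tibble(
    gene_a = "g1", gene_b = "g2", lls = 1
  ))
  expect_error(disease_functional_kernel(flat, dg, c("dA", "dB")),
               "degenerate")
})

test_that("functional kernel averages best matches across both gene sets", {
  # G_i={g1}, G_j={g2}, LLS*(g1,g2)=0.8 -> (0.8+0.8)/2 = 0.8;
  # extreme edges (g8,g9)=0 and (g8,g7)=1 pin the min-max range to [0,1]
  net <- mdaskf:::new_gene_network(tibble::tibble(
    gene_a = c("g1", "g8", "g8"), gene_b = c("g2", "g9", "g7"),
    lls = c(0.8, 0, 1)
  ))
  k <- disease_functional_kernel(net, list(di = "g1", dj = "g2"),
                                 c("di", "dj"))
  expect_equal(k$K["di", "dj"], 0.8, tolerance = 1e-12)
})

test_that("MISIM scores disease-set agreement through semantic similarity", {
  ont <- sibling_ontology()
  sem <- disease_semantic_kernel(ont, c("d1", "d2"))
  # identical single-disease sets -> 1
  Y <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  a <- assoc_from_matrix(Y, c("m1", "m2"), c("d1", "d2"))
  expect_equal(misim_kernel(a, sem)$K["m1", "m2"], 1)

  # disjoint singleton sets -> the cross semantic similarity (1/3 here)
  Y2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  a2 <- assoc_from_matrix(Y2, c("m1", "m2"), c("d1", "d2"))
  k2 <- misim_kernel(a2, sem)
  expect_equal(k2$K[1, 2], sem$K["d1", "d2"], tolerance = 1e-12)

  # zero semantic similarity everywhere -> 0
  two <- ontology_from_edges(list(c("d1", "r1"), c("d2", "r2")),
                             list(d1 = "d1", d2 = "d2"))
  sem0 <- disease_semantic_kernel(two, c("d1", "d2"))
  expect_equal(misim_kernel(a2, sem0)$K[1, 2], 0)

  # empty disease set (post-masking): fallback row
  Y3 <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  a3 <- assoc_from_matrix(Y3, c("m1", "m2"), c("d1", "d2"))
  k3 <- misim_kernel(a3, sem)
  expect_equal(unname(k3$K[2, 1]), 0)
  expect_equal(unname(k3$K[2, 2]), 1)

  expect_error(misim_kernel(a3, similarity_kernel(diag(2), "disease")),
               "disease axis")
})

test_that("MISIM weighted-average formula matches a hand evaluation", {
  # D_1={d1}, D_2={d1,d2}: (max(s11,s12) + s11 + s12) / 3
  ont <- sibling_ontology()
  sem <- disease_semantic_kernel(ont, c("d1", "d2"))
  Y <- matrix(c(1L, 1L, 0L, 1L), 2, 2)
  a <- assoc_from_matrix(Y, c("m1", "m2"), c("d1", "d2"))
  s12 <- sem$K["d1", "d2"]
  expect_equal(unname(misim_kernel(a, sem)$K[1, 2]),
               (max(1, s12) + 1 + s12) / 3, tolerance = 1e-12)
})

test_that("sequence kernel equals the normalized clipped NW score", {
  seqs <- c(m1 = "ACGU", m2 = "ACGA", m3 = "ACGU")
  k <- sequence_kernel(seqs)
  # NW(ACGU, ACGA) = 3 - 1 = 2; self scores 4 -> 0.5
  expect_equal(k$K["m1", "m2"], 0.5, tolerance = 1e-12)
  expect_equal(k$K["m1", "m3"], 1)
  # negative raw scores clip to 0
  k2 <- sequence_kernel(c(a = "AAAA", b = "UUUU"))
  expect_equal(k2$K["a", "b"], 0)
  expect_error(sequence_kernel(c(a = "")), "empty")
})

test_that("sequence kernel agrees with an independent DP oracle", {
  bases <- c("A", "C", "G", "U")
  withr::with_seed(99, {
    seqs <- vapply(1:8, function(i) {
      paste(sample(bases, sample(3:12, 1), replace = TRUE), collapse = "")
    }, "")
  })
  names(seqs) <- paste0("m", 1:8)
  k <- sequence_kernel(seqs)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      nw <- nw_oracle(seqs[i], seqs[j])
      self_i <- nw_oracle(seqs[i], seqs[i])
      self_j <- nw_oracle(seqs[j], seqs[j])
      expect_equal(unname(k$K[i, j]), max(0, nw / max(self_i, self_j)),
                   tolerance = 1e-12)
    }
  }
})

test_that("Hamming profile kernel matches hand counts and the oracle", {
  Y <- matrix(c(1L, 0L, 1L, 0L,
                1L, 1L, 0L, 0L,
                0L, 1L, 0L, 1L), 4, 3)
  a <- assoc_from_matrix(Y)
  kd <- hamming_profile_kernel(a, "disease")
  # columns [1,0,1,0] vs [1,1,0,0], p=4 -> 1 - 2/4 = 0.5
  expect_equal(unname(kd$K[1, 2]), 0.5)
  # complementary profiles -> 0
  expect_equal(unname(kd$K[1, 3]), 0)
  # identical profiles -> 1
  Yi <- cbind(Y, Y[, 1])
  ai <- assoc_from_matrix(Yi)
  expect_equal(unname(hamming_profile_kernel(ai, "disease")$K[1, 4]), 1)

  for (seed in 1:5) {
    Yr <- withr::with_seed(seed, matrix(rbinom(60, 1, 0.4), 10, 6))
    ar <- assoc_from_matrix(Yr)
    kd <- hamming_profile_kernel(ar, "disease")$K
    km <- hamming_profile_kernel(ar, "miRNA")$K
    for (i in 1:6) for (j in 1:6) {
      expect_equal(unname(kd[i, j]), hamming_oracle(Yr[, i], Yr[, j]))
    }
    for (i in 1:10) for (j in 1:10) {
      expect_equal(unname(km[i, j]), hamming_oracle(Yr[i, ], Yr[j, ]))
    }
  }
})

test_that("all six base kernels are symmetric, unit-diagonal and in [0,1]", {
  for (seed in c(2, 7)) {
    ds <- simulate_mda_dataset(p = 15, q = 10, seed = seed)
    ks <- build_kernels(ds)
    for (k in c(ks$mirna, ks$disease)) {
      K <- kernel_matrix(k)
      expect_lt(max(abs(K - t(K))), 1e-12)
      expect_true(all(K >= 0 & K <= 1 + 1e-12))
      expect_equal(unname(diag(K)), rep(1, nrow(K)))
    }
  }
})
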