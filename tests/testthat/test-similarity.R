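test_that("similarity matrix normalizes scores into unit-diagonal r", {
  recs <- list(seq_record("s1", "ACDEFGHIKLMNP"),
               seq_record("s2", "ACDEFGHIKLMNP"),
               seq_record("s3", "ACDEFGHIKLMNP"))
  sim <- build_similarity(sequence_set(recs))
  expect_equal(unname(sim$r), matrix(1, 3, 3))

  # r_ij = s_ij / sqrt(s_ii s_jj), recomputed element-wise
  sim2 <- build_similarity(simulate_families(
    sim_config(seed = 2, n_per_group = 1))$set)
  d <- unname(diag(sim2$s))
  for (i in 1:4) for (j in 1:4)
    expect_equal(unname(sim2$r[i, j]),
                 unname(sim2$s[i, j]) / sqrt(d[i] * d[j]),
                 tolerance = 1e-12)
  expect_equal(sim2$r, t(sim2$r))
  expect_true(all(diag(sim2$r) == 1))
})

test_that("similarity scores match independently recomputed alignments", {
  set.seed(21)
  recs <- lapply(1:5, function(i) seq_record(paste0("r", i),
                                             random_peptide(6)))
  sim <- build_similarity(sequence_set(recs))
  for (i in 1:5) for (j in i:5) {
    ora <- brute_force_align_score(recs[[i]]$residues, recs[[j]]$residues)
    expect_equal(sim$s[i, j], ora,
                 info = paste("pair", i, j))
  }
})

test_that("rank-1 r embeds as a single dimension", {
  r <- matrix(1, 4, 4)
  expect_warning(emb <- embed_similarity(r, k = 3), "positive eigenvalues")
  expect_equal(emb$eigenvalues[1], 4)
  expect_true(all(abs(emb$coordinates[, 1] - emb$coordinates[1, 1]) < 1e-9))
  if (emb$k > 1) expect_true(all(abs(emb$coordinates[, -1]) < 1e-9))
})

test_that("two-block r separates blocks by coordinate sign", {
  n <- 6
  r <- matrix(0.6, n, n)
  r[1:3, 1:3] <- 0.9
  r[4:6, 4:6] <- 0.9
  diag(r) <- 1
  emb <- embed_similarity(r, k = 3)
  # the block contrast lives in one dimension: signs split 3 vs 3
  split_dim <- which(apply(emb$coordinates, 2, function(x)
    all(sign(x[1:3]) == sign(x[1])) && all(sign(x[4:6]) == -sign(x[1]))))
  expect_length(split_dim, 1L)
  # eigen-oracle: coordinates reproduce the direct numeric decomposition
  eg <- eigen(r, symmetric = TRUE)
  X_direct <- eg$vectors[, 1:3] %*% diag(sqrt(eg$values[1:3]))
  expect_equal(abs(unname(emb$coordinates)), abs(X_direct),
               tolerance = 1e-9)
})

test_that("embedding dot products reproduce rank-k correlation matrices", {
  set.seed(13)
  for (k in 2:4) {
    X <- matrix(rnorm(12 * k), 12, k)
    X <- X / sqrt(rowSums(X^2))  # unit rows -> unit diagonal, psd rank k
    r <- tcrossprod(X)
    diag(r) <- 1
    emb <- embed_similarity(r, k = k)
    G <- tcrossprod(emb$coordinates)
    expect_lt(max(abs(G - r)), 1e-6)
  }
})

test_that("reconstruction error is non-increasing in k and under refinement", {
  set.seed(31)
  X <- matrix(rnorm(10 * 6), 10, 6)
  X <- X / sqrt(rowSums(X^2))
  r <- tcrossprod(X); diag(r) <- 1
  errs <- vapply(1:5, function(k)
    embed_similarity(r, k = k)$reconstruction_error, 0)
  expect_true(all(diff(errs) <= 1e-12))
  e_plain <- embed_similarity(r, k = 2)$reconstruction_error
  e_ref <- embed_similarity(r, k = 2, refine = TRUE)$reconstruction_error
  expect_lte(e_ref, e_plain + 1e-12)
})

test_that("embedding is order-invariant up to per-dimension sign", {
  sim <- simulate_families(sim_config(seed = 17, n_per_group = 3))
  s1 <- build_similarity(sim$set)
  perm <- sample(length(sim$set))
  s2 <- build_similarity(sequence_set(sim$set$records[perm]))
  e1 <- embed_similarity(s1, k = 3)
  e2 <- embed_similarity(s2, k = 3)
  X1 <- e1$coordinates[rownames(e2$coordinates), , drop = FALSE]
  for (d in 1:3)
    expect_true(max(abs(X1[, d] - e2$coordinates[, d])) < 1e-8 ||
                max(abs(X1[, d] + e2$coordinates[, d])) < 1e-8)
})

test_that("anchored classification recovers generator truth", {
  sim <- simulate_families(sim_config(seed = 23, n_per_group = 6))
  emb <- embed_similarity(build_similarity(sim$set), k = 4)
  anchors <- sim_anchor_table(sim$truth)
  cl <- classify_sequences(emb, anchors, method = "nearest-centroid")
  expect_equal(ari(cl$assignments$cluster, sim$truth$group), 1)
  # anchors recover their own labels
  own <- merge(cl$assignments, anchors, by = "id")
  expect_true(all(own$cluster == ifelse(own$clade.y == "mammal", "mammal",
    paste0("fish_", own$isoform.y, "_", own$clade.y))))
})

test_that("sign-quadrant classification works on fish-only embeddings", {
  sim <- simulate_families(sim_config(seed = 29, n_per_group = 6))
  fish_idx <- which(sim$truth$taxon_class == "fish")
  fish_set <- sequence_set(sim$set$records[fish_idx])
  truth <- sim$truth[fish_idx, ]
  emb <- embed_similarity(build_similarity(fish_set), k = 3)
  anchors <- sim_anchor_table(truth)
  cl <- classify_sequences(emb, anchors, method = "sign-quadrant",
                           isoform_dim = 2, clade_dim = 3)
  expect_equal(cl$assignments$isoform, truth$isoform)
  expect_equal(cl$assignments$clade, truth$fish_clade)
})

test_that("single-cluster input inherits the anchor's label", {
  sim <- simulate_families(sim_config(seed = 37, n_per_group = 6))
  idx <- which(sim$truth$group == "fish_a_neoteleostei")
  one <- sequence_set(sim$set$records[idx])
  emb <- embed_similarity(build_similarity(one), k = 2)
  anchors <- data.frame(id = sim$truth$id[idx][1], isoform = "a",
                        clade = "neoteleostei")
  cl <- classify_sequences(emb, anchors, method = "nearest-centroid")
  expect_true(all(cl$assignments$cluster == "fish_a_neoteleostei"))
})

test_that("conflicting anchors raise an ambiguity error", {
  sim <- simulate_families(sim_config(seed = 41, n_per_group = 4))
  fish_idx <- which(sim$truth$taxon_class == "fish")
  emb <- embed_similarity(build_similarity(
    sequence_set(sim$set$records[fish_idx])), k = 3)
  truth <- sim$truth[fish_idx, ]
  # label two anchors from opposite isoform clusters with the same isoform
  bad <- data.frame(
    id = c(truth$id[truth$isoform == "a"][1],
           truth$id[truth$isoform == "b"][1]),
    isoform = c("a", "a"),
    clade = c("neoteleostei", "neoteleostei"))
  expect_error(classify_sequences(emb, bad, method = "sign-quadrant"),
               "does not separate")
})
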