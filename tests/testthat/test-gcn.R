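toy_assoc <- function(n_m = 8, n_d = 6, p = 0.3, seed = 31) {
  set.seed(seed)
  matrix(rbinom(n_m * n_d, 1, p), n_m, n_d,
         dimnames = list(sprintf("m%02d", 1:n_m), sprintf("d%02d", 1:n_d)))
}

test_that("unified adjacency has the bipartite block structure and round-trips", {
  a <- toy_assoc()
  g <- build_unified_adjacency(a)
  adj <- g$adjacency
  expect_equal(dim(adj), c(14, 14))
  expect_equal(adj, t(adj))
  expect_true(all(adj[1:8, 1:8] == 0))        # N_MM = 0
  expect_true(all(adj[9:14, 9:14] == 0))      # N_DD = 0
  expect_equal(sum(adj), 2 * sum(a))
  expect_equal(extract_association_block(g), a)

  # single association -> exactly two symmetric nonzeros
  a1 <- matrix(0L, 3, 2, dimnames = list(paste0("m", 1:3), paste0("d", 1:2)))
  a1[2, 1] <- 1L
  g1 <- build_unified_adjacency(a1)
  nz <- which(g1$adjacency != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 2)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("2 4", "4 2"))

  # empty matrix -> zero adjacency
  expect_true(all(build_unified_adjacency(a1 * 0L)$adjacency == 0))
})

test_that("adjacency normalisation matches closed forms and spectral bounds", {
  # edgeless graph: A_hat = I, degrees 1 -> identity
  a0 <- matrix(0L, 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_equal(unname(normalize_adjacency(build_unified_adjacency(a0))),
               diag(4))
  # single edge u-v: degrees 2, entries 1/2 on the {u, v} block
  a1 <- matrix(1L, 1, 1, dimnames = list("m1", "d1"))
  n1 <- normalize_adjacency(build_unified_adjacency(a1))
  expect_equal(unname(n1), matrix(0.5, 2, 2))
  # eigenvalues within [-1, 1], 1 attained (eigen-solver oracle)
  set.seed(32)
  for (rep in 1:5) {
    n_m <- sample(5:50, 1); n_d <- sample(5:50, 1)
    a <- matrix(rbinom(n_m * n_d, 1, 0.2), n_m, n_d)
    ev <- eigen(normalize_adjacency(build_unified_adjacency(a)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
    expect_equal(max(ev), 1, tolerance = 1e-9)
  }
})

test_that("the GCN forward pass is identity on edgeless graphs and permutation-equivariant", {
  h0 <- matrix(runif(4 * 3), 4)
  rownames(h0) <- paste0("n", 1:4)
  w_id <- diag(3)
  a0 <- matrix(0L, 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  n0 <- normalize_adjacency(build_unified_adjacency(a0))
  expect_equal(unname(gcn_forward(n0, pmax(h0, 0), w_id, w_id)),
               unname(pmax(h0, 0)))

  set.seed(33)
  a <- toy_assoc(5, 4, 0.4)
  adj <- normalize_adjacency(build_unified_adjacency(a))
  h <- matrix(runif(9 * 6), 9)
  w1 <- matrix(rnorm(6 * 5), 6); w2 <- matrix(rnorm(5 * 4), 5)
  perm <- sample(9)
  out <- gcn_forward(adj, h, w1, w2)
  out_p <- gcn_forward(adj[perm, perm], h[perm, , drop = FALSE], w1, w2)
  expect_equal(unname(out_p), unname(out[perm, , drop = FALSE]))

  expect_error(gcn_forward(adj, h, matrix(0, 5, 5), w2), "does not match")
})

test_that("pair scoring is the sigmoid inner product of embeddings", {
  a <- toy_assoc(4, 3, 0.5)
  g <- build_unified_adjacency(a)
  h0 <- matrix(runif(7 * 4), 7)
  model <- train_link_predictor(g, h0,
                                pos_pairs = which(a == 1, arr.ind = TRUE),
                                neg_pairs = which(a == 0, arr.ind = TRUE),
                                spec = gcn_spec(c(4L, 3L, 2L), epochs = 5))
  # orthogonal embeddings score exactly 0.5
  model2 <- model
  model2$embeddings[1, ] <- c(1, 0)
  model2$embeddings[model2$n_m + 1, ] <- c(0, 1)
  s <- score_pairs(model2, tibble::tibble(mirna = "m01", disease = "d01"))
  expect_equal(s$score, 0.5)
  # scaling both embeddings pushes the score away from 0.5 monotonically
  model2$embeddings[1, ] <- c(1, 1)
  s1 <- score_pairs(model2, tibble::tibble(mirna = "m01", disease = "d01"))
  model2$embeddings[1, ] <- c(3, 3)
  model2$embeddings[model2$n_m + 1, ] <- c(0, 3)
  s3 <- score_pairs(model2, tibble::tibble(mirna = "m01", disease = "d01"))
  expect_gt(s3$score, s1$score)
  # full score matrix
  sm <- score_matrix(model)
  expect_equal(dim(sm), c(4, 3))
  expect_true(all(sm > 0 & sm < 1))
  expect_error(score_pairs(model, tibble::tibble(mirna = "zz", disease = "d01")),
               "unknown node")
})

test_that("training descends, is deterministic, and never sees test edges", {
  set.seed(34)
  spec <- synthetic_spec(n_m = 40, n_d = 30, latent_rank = 2, density = 0.08,
                         seed = 17)
  truth <- generate_associations(spec)
  a <- truth$a
  folds <- make_folds(a, 4, seed = 17)
  fd <- folds[[1]]
  a_train <- a
  a_train[cbind(fd$test_pos$mirna, fd$test_pos$disease)] <- 0
  g <- build_unified_adjacency(a_train)
  # the training graph contains exactly the train positives
  expect_equal(sum(g$adjacency), 2 * nrow(fd$train_pos))
  h0 <- cbind(gip_similarity(a_train, "mirna"),
              a_train)[, 1:16] |> rbind(
    cbind(gip_similarity(a_train, "disease"), t(a_train))[, 1:16])
  gs <- gcn_spec(c(16L, 8L, 4L), epochs = 80, seed = 5)
  m1 <- train_link_predictor(g, h0, fd$train_pos, fd$train_neg, gs)
  m2 <- train_link_predictor(g, h0, fd$train_pos, fd$train_neg, gs)
  expect_identical(m1$embeddings, m2$embeddings)
  expect_lt(m1$loss[length(m1$loss)], m1$loss[1])
  # negatives overlapping the training graph are rejected
  expect_error(
    train_link_predictor(g, h0, fd$train_pos, fd$train_pos, gs),
    "absent from the training graph")
  expect_error(
    train_link_predictor(g, h0, fd$train_pos[0, ], fd$train_neg, gs),
    "empty positive")
})
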