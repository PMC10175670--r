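test_that("scheme-1 contributions decay geometrically along chains and take the max over paths", {
  chain <- chain_ontology()
  w <- contribution_scheme1(chain, "d", decay = 0.5)
  expect_equal(w[c("d", "p", "r")], c(d = 1, p = 0.5, r = 0.25))
  expect_equal(semantic_value(w), 1.75)

  dia <- diamond_ontology()
  wd <- contribution_scheme1(dia, "d", decay = 0.5)
  expect_equal(unname(wd["d"]), 1)
  # two length-2 paths r -> p -> d; the max over paths gives 0.25, not 0.5^1
  expect_equal(unname(wd["r"]), 0.25)
  expect_equal(semantic_value(wd), 2.25)

  expect_error(contribution_scheme1(chain, "nope"), "unknown disease")
  expect_error(contribution_scheme1(chain, "d", decay = 1.5), "decay")
})

test_that("scheme-2 weights are the negative log document frequency", {
  # 4 diseases; x := the private parent of d1 appears in exactly 1 DAG
  onto <- disease_ontology(
    tibble::tibble(child = c("d1", "d2", "d3", "d4", "x"),
                   parent = c("x", "r", "r", "r", "r")),
    disease_terms = c("d1", "d2", "d3", "d4"))
  w <- contribution_scheme2(onto, "d1")
  expect_equal(unname(w["x"]), log(4))      # n(x) = 1 of 4, natural log
  expect_equal(unname(w["r"]), 0)           # in every DAG -> -log(1)
  counts <- term_dag_counts(onto)
  # weight strictly decreases as document frequency increases
  expect_true(w["x"] > w["d1"] || counts["x"] <= counts["d1"])
  expect_gt(w["x"], w["r"])
})

test_that("pairwise similarity matches hand values, is symmetric, and bounded", {
  sib <- sibling_ontology()
  expect_equal(pairwise_semantic_similarity(sib, "X", "Y", 1), 3 / 7)
  expect_equal(pairwise_semantic_similarity(sib, "Y", "X", 1),
               pairwise_semantic_similarity(sib, "X", "Y", 1))
  expect_equal(pairwise_semantic_similarity(sib, "X", "X", 1), 1)

  # disjoint ancestor sets -> 0
  two <- disease_ontology(
    tibble::tibble(child = c("a", "b"), parent = c("ra", "rb")),
    disease_terms = c("a", "b"))
  expect_equal(pairwise_semantic_similarity(two, "a", "b", 1), 0)
})

test_that("scheme-1 weights equal the path-enumeration oracle on random small DAGs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    onto <- random_dag_ontology(n, edge_prob = stats::runif(1, 0.2, 0.8))
    d <- sample(onto$terms, 1)
    w <- contribution_scheme1(onto, d, decay = 0.5)
    for (x in names(w)) {
      expect_equal(unname(w[x]), oracle_scheme1_weight(onto, d, x, 0.5),
                   info = sprintf("rep %d, d=%s, x=%s", rep, d, x))
    }
  }
})

test_that("similarity matrix averages both schemes and matches the oracle", {
  sib <- sibling_ontology()
  fsm <- semantic_similarity_matrix(sib, c("X", "Y"))
  expect_true(isSymmetric(fsm$values, tol = 1e-12))
  expect_equal(unname(diag(fsm$values)), c(1, 1))
  expect_equal(fsm$values, (fsm$fs1 + fsm$fs2) / 2)
  expect_true(all(fsm$values >= 0 & fsm$values <= 1))

  set.seed(202)
  for (rep in 1:10) {
    onto <- random_dag_ontology(sample(3:8, 1))
    dis <- sample(onto$terms, min(3, length(onto$terms)))
    fsm <- semantic_similarity_matrix(onto, dis)
    for (i in seq_along(dis)) for (j in seq_along(dis)) {
      expect_equal(fsm$fs1[i, j], oracle_fs1(onto, dis[i], dis[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("diseases absent from the ontology get zero similarity and a fallback flag", {
  sib <- sibling_ontology()
  expect_warning(fsm <- semantic_similarity_matrix(sib, c("X", "Y", "Z")),
                 "absent from the ontology")
  expect_equal(unname(fsm$values["Z", c("X", "Y")]), c(0, 0))
  expect_false(any(fsm$defined["Z", ]))
  expect_true(fsm$defined["X", "Y"])
})

test_that("adding a shared ancestor never decreases scheme-1 similarity", {
  set.seed(303)
  for (rep in 1:15) {
    onto <- random_dag_ontology(sample(3:7, 1))
    dis <- sample(onto$terms, 2)
    before <- pairwise_semantic_similarity(onto, dis[1], dis[2], 1)
    # new root above everything is shared by both ancestor sets
    edges2 <- dplyr::bind_rows(
      onto$edges,
      tibble::tibble(child = setdiff(onto$terms,
                                     onto$edges$child),
                     parent = "NEWROOT"))
    onto2 <- disease_ontology(edges2, onto$disease_terms)
    after <- pairwise_semantic_similarity(onto2, dis[1], dis[2], 1)
    expect_gte(after, before - 1e-12)
  }
})

test_that("cyclic parent graphs are rejected", {
  expect_error(
    disease_ontology(tibble::tibble(child = c("a", "b"), parent = c("b", "a"))),
    "cycle")
  expect_error(
    disease_ontology(tibble::tibble(child = "a", parent = "a")),
    "self-loop")
})
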