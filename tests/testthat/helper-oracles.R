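# Independent brute-force oracles used to cross-check the implementation.

# All downward paths from ancestor `x` to disease `d` in the ontology,
# following parent->child edges; returns the max over paths of decay^length.
# Independent of the package's BFS dynamic programme.
oracle_scheme1_weight <- function(onto, d, x, decay = 0.5) {
  if (identical(x, d)) return(1)
  kids_of <- function(term) onto$edges$child[onto$edges$parent == term]
  best <- -Inf
  walk <- function(term, depth) {
    for (k in kids_of(term)) {
      if (identical(k, d)) {
        best <<- max(best, decay^(depth + 1))
      } else {
        walk(k, depth + 1)
      }
    }
  }
  walk(x, 0)
  if (is.finite(best)) best else NA_real_
}

# Ancestor-set enumeration oracle for pairwise scheme-1 similarity.
oracle_fs1 <- function(onto, a, b, decay = 0.5) {
  va <- term_ancestors(onto, a)
  vb <- term_ancestors(onto, b)
  wa <- vapply(va, function(x) oracle_scheme1_weight(onto, a, x, decay), 0)
  wb <- vapply(vb, function(x) oracle_scheme1_weight(onto, b, x, decay), 0)
  names(wa) <- va; names(wb) <- vb
  if (identical(a, b)) return(1)
  shared <- intersect(va, vb)
  if (length(shared) == 0) return(0)
  sum(wa[shared] + wb[shared]) / (sum(wa) + sum(wb))
}

# AUC by exhaustive concordant-pair counting (ties count half).
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  grid <- outer(sp, sn, function(p, n) (p > n) + 0.5 * (p == n))
  mean(grid)
}

# AUPR by explicit threshold sweep over the distinct scores: the area under
# the step precision-recall curve, sum over recall increments of precision.
oracle_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0; r_prev <- 0
  for (i in seq_along(ths)) {
    # with ties, positives at the tied score enter in score order consistent
    # with average precision over the descending sort
    keep <- scores >= ths[i]
    tp <- sum(labels[keep] == 1)
    prec <- tp / sum(keep)
    rec <- tp / n_pos
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# Random DAG on n labelled nodes: child->parent edges always point from a
# higher to a lower position in a fixed order, so acyclicity holds by
# construction. Returns a disease_ontology over all nodes.
random_dag_ontology <- function(n, edge_prob = 0.5) {
  stopifnot(n >= 2)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < edge_prob
  # guarantee weak connectivity towards node 1 so every node has >= 1 parent
  forced <- cbind(row = seq_len(n - 1), col = 2:n)
  edges <- unique(rbind(pairs[keep, , drop = FALSE][, c(1, 2), drop = FALSE],
                        forced))
  tibble::tibble(child = nodes[edges[, 2]], parent = nodes[edges[, 1]]) |>
    disease_ontology()
}

# Small deterministic fixtures
chain_ontology <- function() {
  disease_ontology(tibble::tibble(child = c("d", "p"), parent = c("p", "r")),
                   disease_terms = "d")
}

diamond_ontology <- function() {
  disease_ontology(
    tibble::tibble(child = c("d", "d", "p1", "p2"),
                   parent = c("p1", "p2", "r", "r")),
    disease_terms = "d")
}

# X and Y are siblings below A, which sits below root R.
sibling_ontology <- function() {
  disease_ontology(
    tibble::tibble(child = c("X", "Y", "A"), parent = c("A", "A", "R")),
    disease_terms = c("X", "Y"))
}
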