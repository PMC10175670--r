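#' Unified bipartite adjacency matrix
#'
#' Stacks miRNA and disease nodes into one graph: the off-diagonal blocks are
#' the association matrix and its transpose, the within-class blocks are zero.
#' Node order is miRNAs (rows of `a`) followed by diseases (columns of `a`).
#'
#' @param a binary association matrix, miRNAs x diseases, with dimnames.
#' @return list of class `unified_graph` with `adjacency`
#'   ((n_m + n_d) square symmetric 0/1 matrix), `n_m`, `n_d`, `mirna_ids`,
#'   `disease_ids`.
#' @export
build_unified_adjacency <- function(a) {
  stopifnot(is.matrix(a), all(a %in% c(0, 1)))
  n_m <- nrow(a); n_d <- ncol(a)
  adj <- rbind(cbind(matrix(0, n_m, n_m), a),
               cbind(t(a), matrix(0, n_d, n_d)))
  ids <- c(rownames(a) %||% paste0("m", seq_len(n_m)),
           colnames(a) %||% paste0("d", seq_len(n_d)))
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj, n_m = n_m, n_d = n_d,
                 mirna_ids = ids[seq_len(n_m)],
                 disease_ids = ids[n_m + seq_len(n_d)]),
            class = "unified_graph")
}

#' Recover the association matrix from a unified graph
#'
#' @param g a [build_unified_adjacency()] result.
#' @return the miRNAs x diseases binary block.
#' @export
extract_association_block <- function(g) {
  g$adjacency[seq_len(g$n_m), g$n_m + seq_len(g$n_d), drop = FALSE]
}

#' Symmetrically normalised adjacency with self-loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of the
#' self-loop-augmented adjacency. Self-loops guarantee positive degrees, so no
#' division-by-zero case exists; eigenvalues lie in \[-1, 1\] with 1 attained.
#'
#' @param g a `unified_graph` or a plain symmetric adjacency matrix.
#' @return dense normalised adjacency matrix.
#' @export
normalize_adjacency <- function(g) {
  adj <- if (inherits(g, "unified_graph")) g$adjacency else g
  a_hat <- adj + diag(nrow(adj))
  d_inv_sqrt <- 1 / sqrt(rowSums(a_hat))
  out <- a_hat * tcrossprod(d_inv_sqrt)
  dimnames(out) <- dimnames(adj)
  out
}

#' GCN architecture and training specification
#'
#' Two graph-convolution layers (`code_dim -> h1 -> h2`), ReLU after the
#' first layer and identity after the second, followed by an inner-product
#' decoder with a sigmoid: `score(m, d) = sigmoid(<h_m, h_d>)`. Training
#' minimises binary cross-entropy over a balanced positive/negative pair set
#' with full-batch Adam.
#'
#' @param layer_dims integer vector `c(input, h1, h2)`; default
#'   `c(128, 64, 32)`. Exactly two GCN layers.
#' @param epochs full-batch training steps; default 200.
#' @param learning_rate Adam step size; default 0.01.
#' @param seed integer seed for weight initialisation.
#' @return a `gcn_spec` list.
#' @export
gcn_spec <- function(layer_dims = c(128L, 64L, 32L), epochs = 200,
                     learning_rate = 0.01, seed = 1L) {
  stopifnot(length(layer_dims) == 3, epochs >= 1, learning_rate > 0)
  structure(list(layer_dims = as.integer(layer_dims),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "gcn_spec")
}

#' Two-layer GCN forward pass
#'
#' `H1 = relu(N H0 W1)`, `H2 = N H1 W2` with `N` the normalised adjacency.
#'
#' @param adj_norm normalised adjacency from [normalize_adjacency()].
#' @param h0 initial node embedding matrix (nodes x input width).
#' @param w1,w2 layer weight matrices.
#' @return final node embeddings (nodes x `ncol(w2)`).
#' @export
gcn_forward <- function(adj_norm, h0, w1, w2) {
  if (ncol(h0) != nrow(w1)) {
    stop("embedding width ", ncol(h0), " does not match W1 input ",
         nrow(w1), call. = FALSE)
  }
  h1 <- pmax(adj_norm %*% h0 %*% w1, 0)
  out <- adj_norm %*% h1 %*% w2
  rownames(out) <- rownames(h0)
  out
}

# Resolve a 2-column pair set (mirna, disease; ids or indices) to unified
# node indices.
resolve_pairs <- function(pairs, mirna_ids, disease_ids) {
  pairs <- as.data.frame(pairs)[, 1:2]
  names(pairs) <- c("mirna", "disease")
  if (is.numeric(pairs$mirna)) {
    mi <- as.integer(pairs$mirna)
    di <- as.integer(pairs$disease)
    if (any(mi < 1 | mi > length(mirna_ids)) ||
        any(di < 1 | di > length(disease_ids))) {
      stop("pair index out of range", call. = FALSE)
    }
  } else {
    mi <- match(as.character(pairs$mirna), mirna_ids)
    di <- match(as.character(pairs$disease), disease_ids)
    if (anyNA(mi) || anyNA(di)) {
      bad <- unique(c(pairs$mirna[is.na(mi)], pairs$disease[is.na(di)]))
      stop("unknown node id(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  cbind(mirna = mi, disease = di)
}

#' Train the GCN link predictor on a balanced pair set
#'
#' The training graph must not contain the held-out test edges: build it from
#' the association matrix with test positives zeroed. Positive and negative
#' training pairs are used 1:1.
#'
#' @param graph a `unified_graph` built from the TRAINING association matrix.
#' @param h0 stacked embedding matrix (miRNA rows then disease rows), width
#'   equal to `spec$layer_dims[1]`.
#' @param pos_pairs,neg_pairs two-column pair sets (miRNA, disease), as ids or
#'   indices; positives are edges of the training graph, negatives are
#'   non-edges.
#' @param spec a [gcn_spec()].
#' @return object of class `mda_gcn` with trained weights `w1`, `w2`, the
#'   normalised adjacency, final node `embeddings`, per-epoch `loss`, and id
#'   vectors.
#' @export
train_link_predictor <- function(graph, h0, pos_pairs, neg_pairs, spec) {
  stopifnot(inherits(graph, "unified_graph"))
  n_m <- graph$n_m; n_d <- graph$n_d
  if (nrow(h0) != n_m + n_d) {
    stop("h0 must stack miRNA then disease embeddings (",
         n_m + n_d, " rows)", call. = FALSE)
  }
  if (ncol(h0) != spec$layer_dims[1]) {
    stop("h0 width does not match spec input width", call. = FALSE)
  }
  pos <- resolve_pairs(pos_pairs, graph$mirna_ids, graph$disease_ids)
  neg <- resolve_pairs(neg_pairs, graph$mirna_ids, graph$disease_ids)
  if (nrow(pos) == 0) stop("empty positive pair set", call. = FALSE)
  a_block <- extract_association_block(graph)
  if (any(a_block[neg] != 0)) {
    stop("negative pairs must be absent from the training graph",
         call. = FALSE)
  }
  node_m <- c(pos[, 1], neg[, 1])
  node_d <- n_m + c(pos[, 2], neg[, 2])
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  n_pairs <- length(y)
  adj_norm <- normalize_adjacency(graph)
  dims <- spec$layer_dims
  set.seed(spec$seed)
  lim1 <- sqrt(6 / (dims[1] + dims[2]))
  lim2 <- sqrt(6 / (dims[2] + dims[3]))
  w1 <- matrix(stats::runif(dims[1] * dims[2], -lim1, lim1), dims[1], dims[2])
  w2 <- matrix(stats::runif(dims[2] * dims[3], -lim2, lim2), dims[2], dims[3])
  st <- list(mW1 = w1 * 0, vW1 = w1 * 0, mW2 = w2 * 0, vW2 = w2 * 0)
  lr <- spec$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss <- numeric(spec$epochs)
  nh0 <- adj_norm %*% h0
  for (epoch in seq_len(spec$epochs)) {
    z1 <- nh0 %*% w1
    h1 <- pmax(z1, 0)
    nh1 <- adj_norm %*% h1
    h2 <- nh1 %*% w2
    logits <- rowSums(h2[node_m, , drop = FALSE] * h2[node_d, , drop = FALSE])
    p <- sigmoid(logits)
    loss[epoch] <- -mean(y * log(pmax(p, 1e-12)) +
                           (1 - y) * log(pmax(1 - p, 1e-12)))
    if (!is.finite(loss[epoch])) {
      stop("GCN training diverged at epoch ", epoch, call. = FALSE)
    }
    e <- (p - y) / n_pairs
    dh2 <- matrix(0, n_m + n_d, dims[3])
    cm <- rowsum(e * h2[node_d, , drop = FALSE], group = node_m)
    dh2[as.integer(rownames(cm)), ] <- dh2[as.integer(rownames(cm)), ] + cm
    cd <- rowsum(e * h2[node_m, , drop = FALSE], group = node_d)
    dh2[as.integer(rownames(cd)), ] <- dh2[as.integer(rownames(cd)), ] + cd
    dw2 <- crossprod(nh1, dh2)
    dh1 <- (adj_norm %*% dh2) %*% t(w2)
    dz1 <- dh1 * (z1 > 0)
    dw1 <- crossprod(nh0, dz1)
    # Adam updates
    st$mW1 <- beta1 * st$mW1 + (1 - beta1) * dw1
    st$vW1 <- beta2 * st$vW1 + (1 - beta2) * dw1^2
    st$mW2 <- beta1 * st$mW2 + (1 - beta1) * dw2
    st$vW2 <- beta2 * st$vW2 + (1 - beta2) * dw2^2
    bc1 <- 1 - beta1^epoch; bc2 <- 1 - beta2^epoch
    w1 <- w1 - lr * (st$mW1 / bc1) / (sqrt(st$vW1 / bc2) + eps)
    w2 <- w2 - lr * (st$mW2 / bc1) / (sqrt(st$vW2 / bc2) + eps)
  }
  emb <- gcn_forward(adj_norm, h0, w1, w2)
  rownames(emb) <- c(graph$mirna_ids, graph$disease_ids)
  structure(list(w1 = w1, w2 = w2, adj_norm = adj_norm, h0 = h0,
                 embeddings = emb, loss = loss, spec = spec,
                 n_m = n_m, n_d = n_d,
                 mirna_ids = graph$mirna_ids,
                 disease_ids = graph$disease_ids),
            class = "mda_gcn")
}

#' Score miRNA-disease pairs with a trained model
#'
#' @param model a trained [train_link_predictor()] object.
#' @param pairs two-column pair set (miRNA, disease), ids or indices.
#' @return tibble with columns `mirna`, `disease`, `score` (in (0, 1)).
#' @export
score_pairs <- function(model, pairs) {
  stopifnot(inherits(model, "mda_gcn"))
  idx <- resolve_pairs(pairs, model$mirna_ids, model$disease_ids)
  hm <- model$embeddings[idx[, 1], , drop = FALSE]
  hd <- model$embeddings[model$n_m + idx[, 2], , drop = FALSE]
  tibble::tibble(
    mirna = model$mirna_ids[idx[, 1]],
    disease = model$disease_ids[idx[, 2]],
    score = as.numeric(sigmoid(rowSums(hm * hd)))
  )
}

#' Full score matrix over all miRNA-disease pairs
#'
#' @param model a trained [train_link_predictor()] object.
#' @return n_m x n_d matrix of scores in (0, 1) with dimnames.
#' @export
score_matrix <- function(model) {
  stopifnot(inherits(model, "mda_gcn"))
  hm <- model$embeddings[seq_len(model$n_m), , drop = FALSE]
  hd <- model$embeddings[model$n_m + seq_len(model$n_d), , drop = FALSE]
  s <- sigmoid(tcrossprod(hm, hd))
  dimnames(s) <- list(model$mirna_ids, model$disease_ids)
  s
}

#' @export
print.mda_gcn <- function(x, ...) {
  cat("<mda_gcn> ", x$n_m, " miRNAs + ", x$n_d, " diseases; layers ",
      paste(x$spec$layer_dims, collapse = " -> "), "; final BCE ",
      format(x$loss[length(x$loss)], digits = 5), "\n", sep = "")
  invisible(x)
}
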