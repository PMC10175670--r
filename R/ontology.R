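#' Construct a disease ontology from parent-child edges
#'
#' The ontology is a directed acyclic graph of terms in which each edge points
#' from a child term to one of its parents. For every disease term `d` the
#' induced ancestor DAG contains `d` itself together with every term reachable
#' from `d` by following child-to-parent edges; semantic similarity between
#' diseases is computed on these induced DAGs.
#'
#' @param edges data frame with columns `child` and `parent` (term identifiers
#'   as character strings); additional columns are ignored.
#' @param disease_terms character vector of term identifiers that correspond to
#'   diseases in the association matrix. Defaults to all terms, i.e. an
#'   identity disease-to-term mapping.
#' @return An object of class `disease_ontology` with elements `terms`,
#'   `edges` (tibble child/parent), `disease_terms`, and `parents` (named list
#'   mapping each term to its direct parents).
#' @export
disease_ontology <- function(edges, disease_terms = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges))) {
    if (ncol(edges) >= 2) {
      names(edges)[1:2] <- c("child", "parent")
    } else {
      stop("`edges` must have columns `child` and `parent`", call. = FALSE)
    }
  }
  edges <- dplyr::distinct(edges, .data$child, .data$parent)
  edges <- dplyr::mutate(edges,
                         child = as.character(.data$child),
                         parent = as.character(.data$parent))
  if (any(edges$child == edges$parent)) {
    stop("invalid ontology: self-loop edge detected", call. = FALSE)
  }
  if (!is.null(disease_terms)) disease_terms <- as.character(disease_terms)
  terms <- sort(unique(c(edges$child, edges$parent, disease_terms)))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = terms)
    if (!igraph::is_dag(g)) {
      stop("invalid ontology: cycle detected in parent graph", call. = FALSE)
    }
  }
  if (is.null(disease_terms)) disease_terms <- terms
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  structure(
    list(terms = terms, edges = edges, disease_terms = disease_terms,
         parents = parents),
    class = "disease_ontology"
  )
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("<disease_ontology> ", length(x$terms), " terms, ",
      nrow(x$edges), " edges, ", length(x$disease_terms),
      " disease terms\n", sep = "")
  invisible(x)
}

#' Ancestor closure of a term
#'
#' Returns the term itself plus all terms reachable via child-to-parent edges.
#' Terms absent from the ontology have an empty closure.
#'
#' @param onto a [disease_ontology()].
#' @param term a term identifier.
#' @return character vector of ancestor term ids (including `term`), or
#'   `character(0)` if the term is not in the ontology.
#' @export
term_ancestors <- function(onto, term) {
  if (!term %in% onto$terms) return(character(0))
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(onto$parents[frontier], use.names = FALSE)),
      seen
    )
  }
  sort(unique(seen))
}

#' Ancestor contribution weights, scheme 1 (decaying maximum-path weight)
#'
#' The disease itself contributes 1; every ancestor `x` contributes
#' `decay` times the largest contribution among x's children inside the
#' disease's ancestor DAG. With a uniform decay this equals
#' `decay^h` where `h` is the minimum downward hop count from `x` to `d`.
#'
#' @param onto a [disease_ontology()].
#' @param d disease term id; must be present in the ontology.
#' @param decay decay factor in (0, 1); default 0.5.
#' @return named numeric vector of contributions over the ancestor DAG of `d`.
#' @export
contribution_scheme1 <- function(onto, d, decay = 0.5) {
  if (!is.numeric(decay) || decay <= 0 || decay >= 1) {
    stop("`decay` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!d %in% onto$terms) {
    stop("unknown disease term: ", d, call. = FALSE)
  }
  dag <- term_ancestors(onto, d)
  # hop distance from d upward: BFS over child->parent edges restricted to DAG(d)
  dist <- stats::setNames(rep(Inf, length(dag)), dag)
  dist[d] <- 0
  frontier <- d
  h <- 0
  while (length(frontier) > 0) {
    h <- h + 1
    nxt <- setdiff(
      intersect(unique(unlist(onto$parents[frontier], use.names = FALSE)), dag),
      names(dist)[is.finite(dist)]
    )
    dist[nxt] <- h
    frontier <- nxt
  }
  w <- decay^dist
  w[d] <- 1
  w
}

#' Ancestor contribution weights, scheme 2 (information content)
#'
#' Each ancestor `x` of `d` contributes `-log(n(x) / |D|)` where `n(x)` counts
#' the disease terms whose ancestor DAG contains `x` and `|D|` is the number
#' of disease terms. Common ancestors are down-weighted; an ancestor shared by
#' every disease contributes 0.
#'
#' @inheritParams contribution_scheme1
#' @param dag_counts optional precomputed named vector of `n(x)` counts (see
#'   [term_dag_counts()]); computed on the fly when `NULL`.
#' @param log_base base of the logarithm; natural log by default. The base
#'   rescales all scheme-2 weights uniformly and cancels in the similarity
#'   ratio, so it only matters if raw weights are inspected.
#' @return named numeric vector of non-negative contributions.
#' @export
contribution_scheme2 <- function(onto, d, dag_counts = NULL,
                                 log_base = exp(1)) {
  if (!d %in% onto$terms) {
    stop("unknown disease term: ", d, call. = FALSE)
  }
  if (is.null(dag_counts)) dag_counts <- term_dag_counts(onto)
  dag <- term_ancestors(onto, d)
  n_dis <- length(onto$disease_terms)
  nx <- dag_counts[dag]
  if (any(is.na(nx) | nx == 0)) {
    stop("term appears in no disease DAG; scheme-2 weight undefined",
         call. = FALSE)
  }
  stats::setNames(-log(nx / n_dis, base = log_base), dag)
}

#' Count, for every term, the disease DAGs containing it
#'
#' @param onto a [disease_ontology()].
#' @return named integer vector over all terms: number of disease terms whose
#'   ancestor closure contains the term.
#' @export
term_dag_counts <- function(onto) {
  counts <- stats::setNames(integer(length(onto$terms)), onto$terms)
  for (d in onto$disease_terms) {
    anc <- term_ancestors(onto, d)
    counts[anc] <- counts[anc] + 1L
  }
  counts
}

#' Semantic value of a disease (sum of ancestor contributions)
#'
#' @param cm named numeric contribution vector from [contribution_scheme1()]
#'   or [contribution_scheme2()].
#' @return the sum of all contributions.
#' @export
semantic_value <- function(cm) {
  if (length(cm) == 0) stop("empty contribution map", call. = FALSE)
  sum(cm)
}

#' Semantic similarity between two diseases under one contribution scheme
#'
#' Shared-ancestor contributions from both diseases are summed and normalised
#' by the two semantic values:
#' `sum over shared x of (W_A(x) + W_B(x)) / (Df(A) + Df(B))`.
#' Diseases with disjoint ancestor sets score 0; a disease with itself scores 1.
#'
#' @inheritParams contribution_scheme1
#' @param a,b disease term ids.
#' @param scheme 1 (decay weights) or 2 (information content).
#' @param dag_counts optional precomputed [term_dag_counts()] (scheme 2 only).
#' @return similarity in \[0, 1\].
#' @export
pairwise_semantic_similarity <- function(onto, a, b, scheme = 1, decay = 0.5,
                                         dag_counts = NULL) {
  wa <- switch(as.character(scheme),
    "1" = contribution_scheme1(onto, a, decay),
    "2" = contribution_scheme2(onto, a, dag_counts),
    stop("`scheme` must be 1 or 2", call. = FALSE))
  wb <- switch(as.character(scheme),
    "1" = contribution_scheme1(onto, b, decay),
    "2" = contribution_scheme2(onto, b, dag_counts))
  shared <- intersect(names(wa), names(wb))
  denom <- sum(wa) + sum(wb)
  if (identical(a, b)) return(1)
  if (length(shared) == 0 || denom == 0) return(0)
  sum(wa[shared] + wb[shared]) / denom
}

#' Disease semantic similarity matrix (average of both schemes)
#'
#' Computes the scheme-1 and scheme-2 similarity matrices over the requested
#' diseases and returns their elementwise average together with a mask of the
#' pairs for which semantic similarity is defined (both diseases present in
#' the ontology). Diseases absent from the ontology get similarity 0 to every
#' other disease and are flagged in the mask so that downstream integration
#' can fall back to the Gaussian interaction-profile kernel.
#'
#' @inheritParams contribution_scheme1
#' @param diseases ordered character vector of disease ids; defaults to the
#'   ontology's disease terms.
#' @param log_base scheme-2 logarithm base (natural log by default).
#' @return list with `values` (square symmetric matrix in \[0, 1\] with unit
#'   diagonal), `defined` (logical matrix: semantic similarity available for
#'   the pair), `fs1`, `fs2` (the per-scheme matrices), and `ids`.
#' @export
semantic_similarity_matrix <- function(onto, diseases = NULL, decay = 0.5,
                                       log_base = exp(1)) {
  if (is.null(diseases)) diseases <- onto$disease_terms
  diseases <- as.character(diseases)
  n <- length(diseases)
  in_onto <- diseases %in% onto$terms
  if (any(!in_onto)) {
    warning("diseases absent from the ontology (semantic similarity 0, ",
            "Gaussian fallback applies): ",
            paste(diseases[!in_onto], collapse = ", "), call. = FALSE)
  }
  counts <- term_dag_counts(onto)
  w1 <- vector("list", n)
  w2 <- vector("list", n)
  for (i in seq_len(n)) {
    if (in_onto[i]) {
      w1[[i]] <- contribution_scheme1(onto, diseases[i], decay)
      w2[[i]] <- contribution_scheme2(onto, diseases[i], counts, log_base)
    } else {
      w1[[i]] <- numeric(0)
      w2[[i]] <- numeric(0)
    }
  }
  pair_sim <- function(wl) {
    m <- diag(1, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        wa <- wl[[i]]; wb <- wl[[j]]
        shared <- intersect(names(wa), names(wb))
        denom <- sum(wa) + sum(wb)
        s <- if (length(shared) == 0 || denom == 0) 0 else
          sum(wa[shared] + wb[shared]) / denom
        m[i, j] <- m[j, i] <- s
      }
    }
    m
  }
  fs1 <- pair_sim(w1)
  fs2 <- pair_sim(w2)
  # a disease missing from the ontology is not similar even to itself
  diag(fs1)[!in_onto] <- 0
  diag(fs2)[!in_onto] <- 0
  fs <- (fs1 + fs2) / 2
  dimnames(fs) <- dimnames(fs1) <- dimnames(fs2) <- list(diseases, diseases)
  defined <- outer(in_onto, in_onto, `&`)
  dimnames(defined) <- dimnames(fs)
  list(values = fs, defined = defined, fs1 = fs1, fs2 = fs2, ids = diseases)
}
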