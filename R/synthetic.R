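#' Specification for a synthetic miRNA-disease dataset
#'
#' Defaults emulate the HMDD v2.0 benchmark shape: 495 miRNAs x 383 diseases
#' at density 5430/(495*383) (about 2.864% positive cells, i.e. 97.14%
#' sparsity), with rank-5 planted structure. Smaller shapes are passed for
#' desk-scale experiments.
#'
#' @param n_m,n_d numbers of miRNAs and diseases.
#' @param latent_rank rank of the planted factor model; default 5.
#' @param density target fraction of positive cells, in (0, 0.5).
#' @param ontology_depth,branching shape of the random ontology tree.
#' @param extra_edge_fraction fraction of terms receiving one extra parent
#'   (multiple inheritance) while preserving acyclicity; default 0.2.
#' @param fm_noise amplitude of uniform noise added to the functional
#'   similarity, in \[0, 1\]; default 0.1.
#' @param fm_missing fraction of off-diagonal miRNA pairs whose functional
#'   similarity is marked missing; default 0.3.
#' @param seed integer seed recorded in all outputs.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_m = 495L, n_d = 383L, latent_rank = 5L,
                           density = 5430 / (495 * 383),
                           ontology_depth = 6L, branching = 3L,
                           extra_edge_fraction = 0.2,
                           fm_noise = 0.1, fm_missing = 0.3, seed = 1L) {
  stopifnot(density > 0, density < 0.5,
            latent_rank <= min(n_m, n_d),
            ontology_depth >= 1, branching >= 1,
            fm_noise >= 0, fm_noise <= 1,
            fm_missing >= 0, fm_missing < 1)
  structure(list(n_m = as.integer(n_m), n_d = as.integer(n_d),
                 latent_rank = as.integer(latent_rank), density = density,
                 ontology_depth = as.integer(ontology_depth),
                 branching = as.integer(branching),
                 extra_edge_fraction = extra_edge_fraction,
                 fm_noise = fm_noise, fm_missing = fm_missing,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random rooted ontology DAG
#'
#' Builds a complete rooted tree of the requested depth and branching factor
#' (edges child -> parent), then adds one extra parent to a random fraction of
#' non-root terms, always choosing a parent from a strictly shallower level so
#' the graph stays acyclic. Leaf terms are mapped to disease identifiers
#' `d001, d002, ...`; when the dataset has more diseases than leaves, the
#' excess diseases remain outside the ontology (their semantic similarity is
#' undefined and the Gaussian kernel fallback applies).
#'
#' @param spec a [synthetic_spec()].
#' @return a [disease_ontology()] whose `disease_terms` are the mapped
#'   disease ids (leaf terms renamed).
#' @export
generate_ontology <- function(spec) {
  set.seed(spec$seed)
  depth <- spec$ontology_depth; b <- spec$branching
  # level l has b^l terms; term names t<level>_<index>
  levels <- lapply(0:depth, function(l) {
    if (l == 0) "root" else sprintf("t%d_%03d", l, seq_len(b^l))
  })
  edges <- purrr::map_dfr(seq_len(depth), function(l) {
    kids <- levels[[l + 1]]
    parents <- levels[[l]][ceiling(seq_along(kids) / b)]
    tibble::tibble(child = kids, parent = parents)
  })
  non_root <- unlist(levels[-1])
  n_extra <- round(spec$extra_edge_fraction * length(non_root))
  if (n_extra > 0) {
    picked <- sample(non_root, n_extra)
    extra <- purrr::map_dfr(picked, function(term) {
      lvl <- as.integer(sub("^t(\\d+)_.*$", "\\1", term))
      pool <- setdiff(unlist(levels[seq_len(lvl)]),
                      edges$parent[edges$child == term])
      if (length(pool) == 0) return(NULL)
      tibble::tibble(child = term, parent = sample(pool, 1))
    })
    edges <- dplyr::bind_rows(edges, extra)
  }
  leaves <- levels[[depth + 1]]
  n_mapped <- min(spec$n_d, length(leaves))
  disease_ids <- sprintf("d%03d", seq_len(spec$n_d))
  mapping <- stats::setNames(leaves[seq_len(n_mapped)],
                             disease_ids[seq_len(n_mapped)])
  # rename mapped leaves to their disease ids (identity mapping downstream)
  rename <- stats::setNames(names(mapping), mapping)
  edges <- dplyr::mutate(
    edges,
    child = dplyr::coalesce(rename[.data$child], .data$child),
    parent = dplyr::coalesce(rename[.data$parent], .data$parent))
  disease_ontology(edges, disease_terms = names(mapping))
}

#' Generate a planted low-rank binary association matrix
#'
#' Latent factors `U` (n_m x r) and `V` (n_d x r) are drawn from a standard
#' normal; the `q = floor(density * n_m * n_d)` cells with the largest values
#' of `U V'` become positives. The planted truth is returned so recovery can
#' be tested.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `a` (binary matrix, miRNA ids `m001...`, disease ids
#'   `d001...`), `u`, `v`, `threshold` (score cut that produced the
#'   positives), and `spec`.
#' @export
generate_associations <- function(spec) {
  set.seed(spec$seed + 1L)
  u <- matrix(stats::rnorm(spec$n_m * spec$latent_rank), spec$n_m)
  v <- matrix(stats::rnorm(spec$n_d * spec$latent_rank), spec$n_d)
  score <- tcrossprod(u, v)
  # epsilon guards the exact-density case (e.g. 5430/(495*383)) against
  # floating-point floor(5429.999...)
  q <- floor(spec$density * spec$n_m * spec$n_d + 1e-9)
  cut <- sort(score, decreasing = TRUE)[q]
  a <- matrix(as.integer(score >= cut), spec$n_m, spec$n_d)
  dimnames(a) <- list(sprintf("m%03d", seq_len(spec$n_m)),
                      sprintf("d%03d", seq_len(spec$n_d)))
  list(a = a, u = u, v = v, threshold = cut, spec = spec)
}

#' Generate a noisy miRNA functional-similarity matrix
#'
#' Cosine similarity of the planted miRNA factors `U`, rescaled from
#' \[-1, 1\] to \[0, 1\], plus uniform noise of amplitude `fm_noise`, clipped
#' to \[0, 1\], symmetrised, diagonal 1. A `fm_missing` fraction of
#' off-diagonal pairs is set to `NA` (missing), triggering the kernel
#' fallback during integration.
#'
#' @param truth result of [generate_associations()] (the planted factors).
#' @param fm_noise,fm_missing override the spec values when not `NULL`.
#' @return square matrix with miRNA ids and `NA` for missing pairs.
#' @export
generate_functional_similarity <- function(truth, fm_noise = NULL,
                                           fm_missing = NULL) {
  spec <- truth$spec
  fm_noise <- fm_noise %||% spec$fm_noise
  fm_missing <- fm_missing %||% spec$fm_missing
  set.seed(spec$seed + 2L)
  u <- truth$u
  un <- u / sqrt(rowSums(u^2))
  fm <- (tcrossprod(un) + 1) / 2
  n <- nrow(fm)
  noise <- matrix(stats::runif(n * n, -fm_noise, fm_noise), n)
  fm <- fm + (noise + t(noise)) / 2
  fm[fm < 0] <- 0; fm[fm > 1] <- 1
  diag(fm) <- 1
  if (fm_missing > 0) {
    up <- which(upper.tri(fm))
    drop <- sample(up, round(fm_missing * length(up)))
    fm[drop] <- NA
    fm <- (function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m })(fm)
  }
  dimnames(fm) <- list(rownames(truth$a), rownames(truth$a))
  fm
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing the three pipeline inputs (ontology,
#' association matrix, functional similarity) plus the planted truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `onto`, `a`, `fm`, `truth`, `spec`.
#' @export
simulate_mda_dataset <- function(spec = synthetic_spec()) {
  onto <- generate_ontology(spec)
  truth <- generate_associations(spec)
  fm <- generate_functional_similarity(truth)
  list(onto = onto, a = truth$a, fm = fm, truth = truth, spec = spec)
}

#' Build a case-study candidate panel from a synthetic dataset
#'
#' Mirrors the published case-analysis design: one well-annotated anchor
#' miRNA is examined against a panel of diseases with known association
#' status. The anchor is the eligible miRNA (at least `n_pos` observed
#' associations) whose degree is closest to the median eligible degree — a
#' typical well-annotated node rather than an extreme hub. Panel positives
#' are the anchor's `n_pos` strongest planted associations (the analogue of
#' well-established disease links); panel negatives are the `n_neg` diseases
#' whose planted affinity with the anchor is most negative (clearly unrelated
#' diseases). The panel is deterministic given the dataset.
#'
#' @param ds a [simulate_mda_dataset()] result (the planted truth is needed).
#' @param n_pos,n_neg panel sizes; defaults 7 and 3.
#' @return list with `anchor` (miRNA id), `candidates` (character vector,
#'   positives then negatives), and `labels` (1/0 ground truth per candidate).
#' @export
case_study_panel <- function(ds, n_pos = 7, n_neg = 3) {
  deg <- rowSums(ds$a)
  elig <- which(deg >= n_pos)
  if (length(elig) == 0) stop("no miRNA has ", n_pos, " associations",
                              call. = FALSE)
  anchor_i <- elig[which.min(abs(deg[elig] - stats::median(deg[elig])))]
  planted <- tcrossprod(ds$truth$u, ds$truth$v)[anchor_i, ]
  pos_idx <- which(ds$a[anchor_i, ] == 1)
  pos_d <- colnames(ds$a)[pos_idx[order(planted[pos_idx],
                                        decreasing = TRUE)][seq_len(n_pos)]]
  neg_idx <- which(ds$a[anchor_i, ] == 0)
  neg_d <- colnames(ds$a)[neg_idx[order(planted[neg_idx])][seq_len(n_neg)]]
  list(anchor = rownames(ds$a)[anchor_i],
       candidates = c(pos_d, neg_d),
       labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Degrade an association matrix to a structure-free null
#'
#' Re-places the same number of positives uniformly at random over the matrix
#' cells, destroying the planted low-rank structure while preserving shape
#' and density. Used as the shuffled-label null for calibration.
#'
#' @param a binary association matrix.
#' @param seed integer seed.
#' @return binary matrix of the same shape, dimnames preserved.
#' @export
shuffle_associations <- function(a, seed = 1L) {
  set.seed(seed)
  out <- matrix(0L, nrow(a), ncol(a), dimnames = dimnames(a))
  out[sample(length(a), sum(a))] <- 1L
  out
}
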