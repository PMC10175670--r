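#' Balanced k-fold splits over known associations
#'
#' Shuffles the positive (associated) cells of the binary association matrix
#' with the given seed and partitions them into `k` near-equal test folds.
#' For each fold, negatives are sampled uniformly without replacement from the
#' zero cells at a 1:1 ratio to the positives, disjoint between the train and
#' test roles of that fold.
#'
#' @param a binary association matrix, miRNAs x diseases.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle and negative sampling.
#' @return list of `k` fold splits; each is a list with `fold`, tibbles
#'   `train_pos`, `test_pos`, `train_neg`, `test_neg` (columns `mirna`,
#'   `disease` as integer indices), and `seed`.
#' @export
make_folds <- function(a, k = 5, seed = 1L) {
  stopifnot(is.matrix(a), k >= 2)
  pos <- which(a == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < k) stop("fewer positives (", n_pos, ") than folds", call. = FALSE)
  zero <- which(a == 0)
  set.seed(seed)
  # positives in shuffled order, dealt round-robin into folds -> near-equal
  # test sizes (exactly equal when k divides the positive count)
  fold_of <- sample(rep(seq_len(k), length.out = n_pos))
  as_pairs <- function(idx) {
    tibble::tibble(mirna = unname(pos[idx, 1]), disease = unname(pos[idx, 2]))
  }
  lapply(seq_len(k), function(f) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    negs <- sample(zero, n_pos, replace = FALSE)
    neg_test <- negs[seq_along(test_idx)]
    neg_train <- negs[length(test_idx) + seq_along(train_idx)]
    to_pairs <- function(flat) {
      tibble::tibble(mirna = as.integer((flat - 1) %% nrow(a) + 1),
                     disease = as.integer((flat - 1) %/% nrow(a) + 1))
    }
    list(fold = f,
         train_pos = as_pairs(train_idx),
         test_pos = as_pairs(test_idx),
         train_neg = to_pairs(neg_train),
         test_neg = to_pairs(neg_test),
         seed = seed)
  })
}

#' Classification and ranking metrics for one fold
#'
#' AUC is the rank statistic (probability a positive outscores a negative,
#' ties counted half). AUPR is the area under the step-interpolated
#' precision-recall curve (average precision). MCC, F1, precision and recall
#' are computed from the confusion matrix at the score threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 true labels, same length.
#' @param threshold score cut for the confusion-matrix metrics; default 0.5.
#' @return one-row tibble: `auc`, `aupr`, `mcc`, `f1`, `precision`, `recall`,
#'   plus the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC/AUPR", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp_cum <- cumsum(labels[ord])
  prec_at <- tp_cum / seq_along(ord)
  aupr <- sum(prec_at[labels[ord] == 1]) / n_pos
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  tibble::tibble(auc = auc, aupr = aupr, mcc = mcc, f1 = f1,
                 precision = precision, recall = recall,
                 tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Aggregate per-fold metric reports
#'
#' Means plus both standard-deviation conventions (sample, n-1 denominator,
#' and population, n denominator) are reported for every metric column.
#'
#' @param reports data frame of per-fold metrics, one row per fold (e.g.
#'   stacked [compute_metrics()] rows).
#' @return tibble with columns `metric`, `mean`, `sd_sample`, `sd_population`.
#' @export
aggregate_folds <- function(reports) {
  reports <- tibble::as_tibble(reports)
  stopifnot(nrow(reports) >= 1)
  num <- dplyr::select(reports, dplyr::where(is.numeric))
  num <- dplyr::select(num, -dplyr::any_of(c("fold", "tp", "fp", "fn", "tn")))
  sd_pop <- function(x) {
    sqrt(mean((x - mean(x))^2))
  }
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd_sample = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      sd_population = sd_pop(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, c("auc", "aupr", "mcc", "f1",
                                         "precision", "recall")))
}

# Train the full pipeline (similarities -> features -> dual AE -> GCN) on one
# training association matrix. Shared by CV folds and the case-study harness.
fit_mda_pipeline <- function(a_train, fs = NULL, fm = NULL,
                             train_pos, train_neg, config) {
  gd <- gip_similarity(a_train, "disease", config$gamma_prime,
                       config$convention)
  gm <- gip_similarity(a_train, "mirna", config$gamma_prime,
                       config$convention)
  sd_int <- if (is.null(fs)) {
    list(values = gd,
         provenance = matrix(0L, nrow(gd), ncol(gd), dimnames = dimnames(gd)))
  } else {
    integrate_disease_similarity(fs, gd)
  }
  sm_int <- integrate_mirna_similarity(fm, gm)
  f_d <- build_disease_features(sd_int, a_train, config$fusion)
  f_m <- build_mirna_features(sm_int, a_train, config$fusion)
  ae_m <- train_autoencoder(f_m, autoencoder_spec(
    ncol(f_m), config$ae_hidden, config$code_dim, config$ae_epochs,
    config$ae_lr, seed = config$seed_ae_m))
  ae_d <- train_autoencoder(f_d, autoencoder_spec(
    ncol(f_d), config$ae_hidden, config$code_dim, config$ae_epochs,
    config$ae_lr, seed = config$seed_ae_d))
  h0 <- rbind(ae_m$codes, ae_d$codes)
  graph <- build_unified_adjacency(a_train)
  model <- train_link_predictor(graph, h0, train_pos, train_neg, gcn_spec(
    c(config$code_dim, config$gcn_hidden), config$gcn_epochs,
    config$gcn_lr, seed = config$seed_gcn))
  model
}

#' Fit the full pipeline on one association matrix
#'
#' Trains similarities, features, the dual autoencoders and the GCN link
#' predictor on all positives of `a`, with an equal number of negatives
#' sampled uniformly from the zero cells. Use this for final models and
#' case-study predictions; for evaluation use [run_cross_validation()],
#' which masks held-out edges before training.
#'
#' @inheritParams run_cross_validation
#' @return a trained `mda_gcn` model (see [train_link_predictor()]).
#' @export
fit_mda <- function(a, onto = NULL, fm = NULL, seed = 1L,
                    config = mda_config()) {
  stopifnot(is.matrix(a))
  if (is.null(rownames(a))) rownames(a) <- paste0("m", seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- paste0("d", seq_len(ncol(a)))
  fs <- if (!is.null(onto)) {
    semantic_similarity_matrix(onto, colnames(a), config$decay,
                               config$log_base)
  }
  pos <- which(a == 1, arr.ind = TRUE)
  set.seed(seed)
  zeros <- which(a == 0)
  negs <- sample(zeros, nrow(pos), replace = FALSE)
  neg <- cbind(mirna = (negs - 1) %% nrow(a) + 1,
               disease = (negs - 1) %/% nrow(a) + 1)
  cfg <- config
  cfg$seed_ae_m <- seed + 1L
  cfg$seed_ae_d <- seed + 2L
  cfg$seed_gcn <- seed + 3L
  fit_mda_pipeline(a, fs, fm,
                   tibble::tibble(mirna = unname(pos[, 1]),
                                  disease = unname(pos[, 2])),
                   tibble::as_tibble(neg), cfg)
}

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: ontology decay
#' 0.5, raw kernel parameter 1, code dimension 128, autoencoder
#' input -> 512 -> 128 trained 200 epochs at Adam lr 1e-3, GCN widths
#' 128 -> 64 -> 32 trained 200 epochs at Adam lr 0.01, concatenation fusion,
#' dividing bandwidth convention, classification threshold 0.5.
#'
#' @param ... named overrides of any default.
#' @return a named list of configuration values.
#' @export
mda_config <- function(...) {
  cfg <- list(decay = 0.5, gamma_prime = 1, convention = "divide",
              fusion = "concat", code_dim = 128L, ae_hidden = 512L,
              ae_epochs = 200L, ae_lr = 1e-3,
              gcn_hidden = c(64L, 32L), gcn_epochs = 200L, gcn_lr = 0.01,
              threshold = 0.5, log_base = exp(1))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, dots)
}

#' k-fold cross-validated evaluation of the full pipeline
#'
#' For every fold: the test positives are removed from the association matrix;
#' Gaussian interaction-profile kernels, integrated similarities, node
#' features and both autoencoders are rebuilt from the masked (training)
#' matrix only; the GCN is trained on the fold's balanced train pairs; the
#' held-out balanced test pairs are scored and summarised. Test edges never
#' reach any training stage.
#'
#' @param a binary association matrix, miRNAs x diseases, with dimnames.
#' @param onto optional [disease_ontology()]; disease semantic similarity is
#'   computed once (it does not depend on associations) and integrated per
#'   fold. `NULL` means pure kernel similarity for diseases.
#' @param fm optional miRNA functional similarity matrix (`NA` = missing
#'   pair); `NULL` means pure kernel similarity for miRNAs.
#' @param k number of folds; default 5.
#' @param seed master seed; fold splits, negative sampling and all weight
#'   initialisations derive from it.
#' @param config a [mda_config()] list.
#' @return object of class `mda_cv`: `reports` (per-fold metric tibble),
#'   `summary` ([aggregate_folds()] tibble), `folds`, `config`, `seed`, `k`.
#' @export
run_cross_validation <- function(a, onto = NULL, fm = NULL, k = 5, seed = 1L,
                                 config = mda_config()) {
  stopifnot(is.matrix(a))
  if (is.null(rownames(a))) rownames(a) <- paste0("m", seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- paste0("d", seq_len(ncol(a)))
  fs <- if (!is.null(onto)) {
    semantic_similarity_matrix(onto, colnames(a), config$decay,
                               config$log_base)
  }
  folds <- make_folds(a, k, seed)
  reports <- purrr::map_dfr(folds, function(fd) {
    a_train <- a
    a_train[cbind(fd$test_pos$mirna, fd$test_pos$disease)] <- 0
    cfg <- config
    cfg$seed_ae_m <- seed + 7L * fd$fold + 1L
    cfg$seed_ae_d <- seed + 7L * fd$fold + 2L
    cfg$seed_gcn <- seed + 7L * fd$fold + 3L
    model <- fit_mda_pipeline(a_train, fs, fm,
                              fd$train_pos, fd$train_neg, cfg)
    test <- dplyr::bind_rows(fd$test_pos, fd$test_neg)
    scored <- score_pairs(model, test)
    labels <- c(rep(1L, nrow(fd$test_pos)), rep(0L, nrow(fd$test_neg)))
    dplyr::bind_cols(tibble::tibble(fold = fd$fold),
                     compute_metrics(scored$score, labels, config$threshold))
  })
  structure(list(reports = reports, summary = aggregate_folds(reports),
                 folds = folds, config = config, seed = seed, k = k,
                 n_m = nrow(a), n_d = ncol(a)),
            class = "mda_cv")
}

#' @export
print.mda_cv <- function(x, ...) {
  cat("<mda_cv> ", x$k, "-fold cross-validation, ", x$n_m, " miRNAs x ",
      x$n_d, " diseases (seed ", x$seed, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Rank candidate partners for one anchor node
#'
#' Scores each candidate pair against the anchor (a miRNA or a disease) with
#' a trained model and returns the descending ranking; ties are broken by
#' candidate id so the ranking is invariant to input order. A predicted label
#' at the threshold is included for case-study style verdict tables.
#'
#' @param model a trained [train_link_predictor()] object.
#' @param mirna,disease exactly one of these names the anchor node.
#' @param candidates character vector of candidate ids on the other side.
#' @param top_k number of top-ranked candidates to return; default all.
#' @param threshold classification threshold; default 0.5.
#' @return tibble `mirna`, `disease`, `score`, `rank`, `predicted` (0/1).
#' @export
rank_candidates <- function(model, mirna = NULL, disease = NULL, candidates,
                            top_k = Inf, threshold = 0.5) {
  if (is.null(mirna) == is.null(disease)) {
    stop("supply exactly one of `mirna` or `disease` as the anchor",
         call. = FALSE)
  }
  pairs <- if (!is.null(mirna)) {
    tibble::tibble(mirna = mirna, disease = as.character(candidates))
  } else {
    tibble::tibble(mirna = as.character(candidates), disease = disease)
  }
  cand_col <- if (!is.null(mirna)) "disease" else "mirna"
  scored <- score_pairs(model, pairs) |>
    dplyr::arrange(dplyr::desc(.data$score), .data[[cand_col]]) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  predicted = as.integer(.data$score >= threshold))
  utils::head(scored, n = if (is.finite(top_k)) top_k else nrow(scored))
}
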