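#' Gaussian interaction-profile kernel bandwidth
#'
#' Normalises the raw kernel parameter by the mean squared Euclidean norm of
#' the interaction profiles, `gamma = gamma' / mean(||p_i||^2)`, so the kernel
#' is scale-free in the number of interactions. The multiplicative form
#' `gamma = gamma' * mean(||p_i||^2)` is available via `convention`.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param gamma_prime positive raw kernel parameter; default 1.
#' @param convention `"divide"` (default) or `"multiply"`.
#' @param fallback bandwidth returned when every profile is all-zero (the
#'   normaliser would be 0); default 1.
#' @return a strictly positive scalar bandwidth.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1,
                          convention = c("divide", "multiply"),
                          fallback = 1) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  if (gamma_prime <= 0) stop("`gamma_prime` must be positive", call. = FALSE)
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) return(fallback)
  switch(convention,
         divide = gamma_prime / msq,
         multiply = gamma_prime * msq)
}

#' Gaussian interaction-profile kernel matrix
#'
#' `K[a, b] = exp(-bandwidth * ||p_a - p_b||^2)`: symmetric, unit diagonal,
#' entries in (0, 1], and positive semidefinite.
#'
#' @param profiles numeric matrix, one profile per row; row names become ids.
#' @param bandwidth positive kernel bandwidth (see [gip_bandwidth()]).
#' @return square similarity matrix over the profiles.
#' @export
gip_kernel <- function(profiles, bandwidth) {
  stopifnot(is.matrix(profiles))
  if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-bandwidth * d2)
  diag(k) <- 1
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  k
}

#' GIP similarity for diseases or miRNAs from an association matrix
#'
#' Disease profiles are the columns of the binary association matrix (length
#' = number of miRNAs); miRNA profiles are its rows (length = number of
#' diseases). Bandwidth is normalised per [gip_bandwidth()].
#'
#' @param a binary association matrix, miRNAs x diseases, with dimnames.
#' @param margin `"disease"` or `"mirna"`.
#' @param gamma_prime raw kernel parameter, default 1.
#' @param convention bandwidth convention, see [gip_bandwidth()].
#' @return square similarity matrix over the chosen node class.
#' @export
gip_similarity <- function(a, margin = c("disease", "mirna"),
                           gamma_prime = 1,
                           convention = c("divide", "multiply")) {
  margin <- match.arg(margin)
  profiles <- if (margin == "disease") t(a) else a
  bw <- gip_bandwidth(profiles, gamma_prime, convention)
  gip_kernel(profiles, bw)
}

#' Integrate a primary similarity with the GIP kernel
#'
#' Where the primary similarity (semantic for diseases, functional for
#' miRNAs) is defined for a pair, the integrated value is the arithmetic mean
#' of primary and kernel similarity; elsewhere the kernel value is used
#' unchanged. The returned provenance mask records which branch fired
#' (1 = averaged, 0 = kernel fallback).
#'
#' @param primary square matrix of primary similarity values (entries for
#'   undefined pairs are ignored).
#' @param gip square GIP kernel matrix with identical id order.
#' @param defined logical matrix, TRUE where the primary similarity exists for
#'   the pair. `NA` entries in `primary` are additionally treated as missing.
#' @return list with `values` (integrated similarity, unit diagonal),
#'   `provenance` (0/1 integer matrix), and `ids`.
#' @export
integrate_similarity <- function(primary, gip, defined = NULL) {
  stopifnot(is.matrix(primary), is.matrix(gip))
  if (!all(dim(primary) == dim(gip))) {
    stop("similarity matrices must have identical dimensions", call. = FALSE)
  }
  if (!is.null(rownames(primary)) && !is.null(rownames(gip)) &&
      !identical(rownames(primary), rownames(gip))) {
    stop("id order mismatch between primary and GIP similarity", call. = FALSE)
  }
  if (is.null(defined)) defined <- !is.na(primary)
  defined <- defined & !is.na(primary)
  vals <- ifelse(defined, (gip + primary) / 2, gip)
  diag(vals) <- 1
  dimnames(vals) <- dimnames(gip)
  prov <- matrix(as.integer(defined), nrow(gip), dimnames = dimnames(gip))
  list(values = vals, provenance = prov,
       ids = rownames(gip) %||% as.character(seq_len(nrow(gip))))
}

#' @rdname integrate_similarity
#' @param fs result of [semantic_similarity_matrix()] (or a plain matrix).
#' @export
integrate_disease_similarity <- function(fs, gip, defined = NULL) {
  if (is.list(fs) && !is.null(fs$values)) {
    if (is.null(defined)) defined <- fs$defined
    fs <- fs$values
  }
  integrate_similarity(fs, gip, defined)
}

#' @rdname integrate_similarity
#' @param fm miRNA functional similarity matrix; `NA` entries mark missing
#'   pairs. May be `NULL`, in which case the result is the pure GIP kernel.
#' @export
integrate_mirna_similarity <- function(fm, gip, defined = NULL) {
  if (is.null(fm)) {
    fm <- matrix(NA_real_, nrow(gip), ncol(gip), dimnames = dimnames(gip))
  }
  integrate_similarity(fm, gip, defined)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
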