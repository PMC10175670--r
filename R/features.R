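#' Build initial node feature matrices
#'
#' Each disease's feature vector is its integrated-similarity row concatenated
#' with its association-matrix column (the miRNA interaction profile); each
#' miRNA's feature vector is its integrated-similarity row concatenated with
#' its association-matrix row. Both classes therefore share the feature
#' dimension `n_m + n_d`, which lets the two autoencoders share one
#' architecture and matches the unified graph size.
#'
#' An alternative `fusion = "product"` reading multiplies the similarity
#' matrix into the association profiles (`SD %*% t(A)` for diseases,
#' `SM %*% A` for miRNAs) and is kept for comparison.
#'
#' @param sd,sm integrated similarity matrix (diseases resp. miRNAs), or the
#'   list returned by [integrate_similarity()].
#' @param a binary association matrix, miRNAs x diseases.
#' @param fusion `"concat"` (default) or `"product"`.
#' @return numeric feature matrix, one row per node, with row names.
#' @export
build_disease_features <- function(sd, a, fusion = c("concat", "product")) {
  fusion <- match.arg(fusion)
  if (is.list(sd) && !is.null(sd$values)) sd <- sd$values
  if (nrow(sd) != ncol(a)) {
    stop("disease similarity dimension (", nrow(sd),
         ") does not match association matrix columns (", ncol(a), ")",
         call. = FALSE)
  }
  out <- switch(fusion,
                concat = cbind(sd, t(a)),
                product = sd %*% t(a))
  rownames(out) <- colnames(a)
  stopifnot(all(is.finite(out)))
  out
}

#' @rdname build_disease_features
#' @export
build_mirna_features <- function(sm, a, fusion = c("concat", "product")) {
  fusion <- match.arg(fusion)
  if (is.list(sm) && !is.null(sm$values)) sm <- sm$values
  if (nrow(sm) != nrow(a)) {
    stop("miRNA similarity dimension (", nrow(sm),
         ") does not match association matrix rows (", nrow(a), ")",
         call. = FALSE)
  }
  out <- switch(fusion,
                concat = cbind(sm, a),
                product = sm %*% a)
  rownames(out) <- rownames(a)
  stopifnot(all(is.finite(out)))
  out
}
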