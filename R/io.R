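#' Read a miRNA-disease association edge list
#'
#' Two-column TSV `mirna<TAB>disease`; a header line is detected when the
#' first field is a common column name (`mirna`, `mirna_id`, ...). Ids are
#' deduplicated and sorted lexicographically for a stable node order;
#' duplicate edges collapse to a single association with a message.
#'
#' @param path TSV file path.
#' @return binary association matrix (miRNAs x diseases) with dimnames.
#' @export
read_associations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty association file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]][1]))
  if (first %in% c("mirna", "mirna_id", "mir", "source")) {
    fields <- fields[-1]
    if (length(fields) == 0) {
      stop("association file has a header but no rows: ", path, call. = FALSE)
    }
  }
  bad <- which(vapply(fields, length, 1L) < 2)
  if (length(bad) > 0) {
    stop("malformed association row at line ", bad[1], " of ", path,
         call. = FALSE)
  }
  edges <- tibble::tibble(
    mirna = vapply(fields, function(f) trimws(f[1]), ""),
    disease = vapply(fields, function(f) trimws(f[2]), "")
  )
  n_dup <- nrow(edges) - nrow(dplyr::distinct(edges))
  if (n_dup > 0) {
    message(n_dup, " duplicate association edge(s) collapsed")
    edges <- dplyr::distinct(edges)
  }
  mirnas <- sort(unique(edges$mirna))
  diseases <- sort(unique(edges$disease))
  a <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  a[cbind(match(edges$mirna, mirnas), match(edges$disease, diseases))] <- 1L
  a
}

#' Write an association matrix as an edge list
#'
#' @param a binary association matrix with dimnames.
#' @param path output TSV path.
#' @export
write_associations <- function(a, path) {
  pos <- which(a == 1, arr.ind = TRUE)
  edges <- tibble::tibble(mirna = rownames(a)[pos[, 1]],
                          disease = colnames(a)[pos[, 2]]) |>
    dplyr::arrange(.data$mirna, .data$disease)
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Read an ontology parent-child edge TSV
#'
#' Two-column TSV `child<TAB>parent`, header optional; opaque string ids.
#'
#' @param path TSV file path.
#' @param disease_terms optional character vector (or two-column
#'   disease-to-term mapping file path) naming the disease terms; identity
#'   mapping over all terms when absent.
#' @return a [disease_ontology()].
#' @export
read_ontology_tsv <- function(path, disease_terms = NULL) {
  edges <- readr::read_tsv(path, col_names = c("child", "parent"),
                           col_types = "cc", progress = FALSE)
  if (tolower(edges$child[1]) %in% c("child", "term", "child_id")) {
    edges <- edges[-1, ]
  }
  if (is.character(disease_terms) && length(disease_terms) == 1 &&
      file.exists(disease_terms)) {
    map <- readr::read_tsv(disease_terms, col_names = c("disease", "term"),
                           col_types = "cc", progress = FALSE)
    disease_terms <- map$term
  }
  disease_ontology(edges, disease_terms)
}

#' Read a square similarity matrix TSV
#'
#' Expects an id header row and an id index column; empty cells become `NA`
#' (missing pairs). The matrix must be square with matching ids and symmetric
#' within `tol`.
#'
#' @param path TSV file path.
#' @param tol symmetry tolerance; default 1e-9.
#' @return numeric matrix with `NA` missing entries.
#' @export
read_similarity_tsv <- function(path, tol = 1e-9) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(), id = readr::col_character()),
    na = c("", "NA"), progress = FALSE)
  ids <- df$id
  m <- as.matrix(df[setdiff(names(df), "id")])
  rownames(m) <- ids
  if (nrow(m) != ncol(m) || !identical(ids, colnames(m))) {
    stop("similarity matrix is not square with matching ids: ", path,
         call. = FALSE)
  }
  diff <- abs(m - t(m))
  diff[is.na(diff)] <- 0
  asym_na <- xor(is.na(m), is.na(t(m)))
  if (any(asym_na) || max(diff) > tol) {
    worst <- which(asym_na | diff == max(diff), arr.ind = TRUE)[1, ]
    stop("similarity matrix asymmetric beyond tolerance at pair (",
         ids[worst[1]], ", ", ids[worst[2]], "): ", path, call. = FALSE)
  }
  m
}

#' Write a square similarity matrix TSV
#'
#' Missing (`NA`) entries are written as empty cells.
#'
#' @param m square numeric matrix with dimnames.
#' @param path output TSV path.
#' @export
write_similarity_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Write pair predictions sorted by descending score
#'
#' @param scored tibble with `mirna`, `disease`, `score` (e.g. from
#'   [score_pairs()]).
#' @param path output TSV path.
#' @export
write_predictions <- function(scored, path) {
  scored |>
    dplyr::arrange(dplyr::desc(.data$score), .data$mirna, .data$disease) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Resolve a run configuration from a YAML file plus overrides
#'
#' Unknown keys are rejected; the fully resolved configuration (defaults
#' filled in) is returned and should be echoed into every output directory
#' for provenance.
#'
#' @param path optional YAML file of [mda_config()] keys.
#' @param ... named overrides applied after the file.
#' @return resolved configuration list.
#' @export
read_run_config <- function(path = NULL, ...) {
  file_cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  do.call(mda_config, utils::modifyList(file_cfg, list(...)))
}
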