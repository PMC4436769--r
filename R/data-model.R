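# Canonical upper-triangle pair order used everywhere: for genes sorted
# lexicographically, pairs (i, j) with i < j in column-major order, i.e.
# (1,2), (1,3), (2,3), (1,4), ... — the order of M[upper.tri(M)].

#' Enumerate canonical upper-triangle gene pairs
#'
#' @param n number of genes (>= 2)
#' @return two-column integer matrix of (i, j) indices, i < j, in the
#'   canonical column-major order used by all correlation vectors.
#' @keywords internal
upper_pairs <- function(n) {
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Construct an expression dataset
#'
#' Container for a features-by-samples expression matrix (log-ratio scale)
#' with per-sample group and timepoint labels.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`), `timepoint`; one row per column of `values`,
#'   in column order.
#' @param level `"probe"` or `"gene"`.
#' @param probe_to_gene optional named character vector mapping probe id to
#'   gene symbol (names = probe ids).
#' @param timepoints ordered character vector of timepoint labels; defaults
#'   to the unique timepoints in `samples` in order of first appearance.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, samples, level = c("gene", "probe"),
                               probe_to_gene = NULL, timepoints = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression matrix contains missing values; complete data required")
  if (is.null(rownames(values))) stop("expression matrix must have feature ids as rownames")
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate feature id: ", dup)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "timepoint")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  samples$timepoint <- as.character(samples$timepoint)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ", samples$sample_id[duplicated(samples$sample_id)][1L])
  }
  bad <- setdiff(unique(samples$group), c("case", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (nrow(samples) != ncol(values)) {
    stop("metadata has ", nrow(samples), " samples but matrix has ", ncol(values), " columns")
  }
  if (!is.null(colnames(values)) && !identical(colnames(values), samples$sample_id)) {
    stop("sample ids in metadata do not match matrix column names/order")
  }
  colnames(values) <- samples$sample_id
  if (is.null(timepoints)) timepoints <- unique(samples$timepoint)
  extra <- setdiff(samples$timepoint, timepoints)
  if (length(extra)) stop("timepoint(s) not in declared order: ", paste(extra, collapse = ", "))
  structure(
    list(values = values, samples = samples, level = level,
         probe_to_gene = probe_to_gene, timepoints = as.character(timepoints)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset (", x$level, " level): ",
      nrow(x$values), " features x ", ncol(x$values), " samples\n", sep = "")
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "\n")
  tab <- table(x$samples$group, x$samples$timepoint)
  print(tab)
  invisible(x)
}

#' Feature identifiers of a dataset
#' @param dataset an `expression_dataset`
#' @return character vector of feature (probe or gene) ids.
#' @export
feature_ids <- function(dataset) rownames(dataset$values)

# Column indices of one (group, timepoint) sample cell; errors if too few.
cell_columns <- function(dataset, group, timepoint, min_n = 3L) {
  keep <- dataset$samples$group == group & dataset$samples$timepoint == as.character(timepoint)
  idx <- which(keep)
  if (length(idx) < min_n) {
    stop("cell (", group, ", ", timepoint, ") has ", length(idx),
         " samples; at least ", min_n, " required")
  }
  idx
}

#' Construct a complex catalog
#'
#' @param entries named list; each element a character vector of gene symbols.
#' @param provenance free-text origin (file name, catalog version).
#' @return object of class `complex_catalog`.
#' @export
complex_catalog <- function(entries, provenance = "") {
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("every complex must be named")
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicate complex name: ", names(entries)[duplicated(names(entries))][1L])
  }
  entries <- lapply(entries, function(g) unique(trimws(as.character(g))))
  empty <- vapply(entries, function(g) length(g) == 0L || all(g == ""), logical(1))
  if (any(empty)) {
    warning("dropping ", sum(empty), " complex(es) with empty gene lists: ",
            paste(names(entries)[empty], collapse = ", "))
    entries <- entries[!empty]
  }
  structure(list(entries = entries, provenance = provenance),
            class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  sizes <- lengths(x$entries)
  cat("complex_catalog: ", length(x$entries), " complexes, sizes ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-",
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Construct a mapped complex
#'
#' A catalog entry restricted to genes measured in a dataset, with genes in
#' canonical (lexicographic) order and the pair count N = n(n-1)/2.
#'
#' @param name complex name
#' @param genes character vector of measured gene symbols
#' @return object of class `mapped_complex` with fields `name`, `genes`,
#'   `n`, `N`.
#' @export
mapped_complex <- function(name, genes) {
  genes <- sort(unique(as.character(genes)))
  n <- length(genes)
  structure(list(name = name, genes = genes, n = n, N = as.integer(n * (n - 1L) / 2)),
            class = "mapped_complex")
}

#' Construct a correlation matrix object
#'
#' Upper-triangular Pearson co-expression values of one complex in one
#' (group, timepoint) cell, stored as a vector in canonical pair order.
#'
#' @param complex_name,group,timepoint identifying labels
#' @param genes ordered gene symbols (canonical order)
#' @param upper numeric vector of length n(n-1)/2, entries in [-1, 1]
#' @return object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(complex_name, group, timepoint, genes, upper) {
  n <- length(genes)
  N <- n * (n - 1L) / 2L
  if (length(upper) != N) stop("upper vector has length ", length(upper), ", expected ", N)
  if (any(upper < -1 - 1e-12 | upper > 1 + 1e-12)) stop("correlation entries outside [-1, 1]")
  structure(list(complex_name = complex_name, group = group,
                 timepoint = as.character(timepoint), genes = genes,
                 upper = pmin(1, pmax(-1, upper))),
            class = "correlation_matrix")
}

#' Expand an upper-triangle vector to a full symmetric matrix
#'
#' @param genes ordered gene symbols
#' @param upper numeric vector in canonical pair order
#' @param diag value to place on the diagonal
#' @return symmetric numeric matrix with gene dimnames.
#' @export
upper_to_matrix <- function(genes, upper, diag = 1) {
  n <- length(genes)
  M <- matrix(diag, n, n, dimnames = list(genes, genes))
  M[upper.tri(M)] <- upper
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}
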