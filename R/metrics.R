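# Core statistics: per-complex Pearson co-expression matrices, the paired
# t-test on average correlation (significance quadruplets), the normalized
# Euclidean distance between case and control matrices, and the
# size-matched random-complex null that turns a distance into a z-score.

#' Pearson correlation of two expression profiles
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance
#' @param xname,yname labels used in error messages (gene symbols)
#' @return Pearson product-moment coefficient in [-1, 1].
#' @export
pearson <- function(x, y, xname = "x", yname = "y") {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0) stop("zero variance in expression profile of '", xname, "'")
  if (stats::sd(y) == 0) stop("zero variance in expression profile of '", yname, "'")
  stats::cor(x, y, method = "pearson")
}

#' Co-expression matrix of a complex in one (group, timepoint) cell
#'
#' All n(n-1)/2 pairwise Pearson correlations between the complex's gene
#' expression profiles, computed over that cell's samples only, stored in
#' canonical upper-triangle order.
#'
#' @param dataset gene-level [expression_dataset()]
#' @param complex a [mapped_complex()]
#' @param group `"case"` or `"control"`
#' @param timepoint timepoint label
#' @return a [correlation_matrix()].
#' @export
complex_correlation_matrix <- function(dataset, complex, group, timepoint) {
  stopifnot(inherits(complex, "mapped_complex"))
  missing_genes <- setdiff(complex$genes, rownames(dataset$values))
  if (length(missing_genes)) {
    stop("complex '", complex$name, "': gene(s) not in dataset: ",
         paste(missing_genes, collapse = ", "))
  }
  cols <- cell_columns(dataset, group, timepoint)
  X <- dataset$values[complex$genes, cols, drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("complex '", complex$name, "': zero variance in expression profile of '",
         complex$genes[which(sds == 0)[1L]], "' at (", group, ", ", timepoint, ")")
  }
  C <- stats::cor(t(X), method = "pearson")
  correlation_matrix(complex$name, group, timepoint, complex$genes,
                     C[upper.tri(C)])
}

#' Average of the upper-triangular entries
#'
#' @param M a [correlation_matrix()] (or anything with an `upper` field)
#' @return arithmetic mean of the N upper entries.
#' @export
average_upper <- function(M) mean(M$upper)

#' Paired t-test on matched correlation matrices
#'
#' Treats the N = n(n-1)/2 matched pairs (A_ij, B_ij) as paired
#' observations:
#' \deqn{t = \frac{\sum (A_{ij}-B_{ij})}
#'   {\sqrt{\frac{N \sum (A_{ij}-B_{ij})^2 - (\sum (A_{ij}-B_{ij}))^2}{N-1}}}}
#' which equals the textbook paired t, mean difference / (sd / sqrt(N)),
#' with N - 1 degrees of freedom. The two-sided p-value is returned.
#'
#' Degenerate spreads: all differences exactly zero gives p = 1 (no change);
#' identical nonzero differences give p = 0 with a warning (zero spread but
#' a real shift).
#'
#' @param A,B [correlation_matrix()] objects over the same genes
#' @return list with `t` and `p`.
#' @export
paired_t_statistic <- function(A, B) {
  check_matched(A, B)
  D <- A$upper - B$upper
  N <- length(D)
  if (N < 2) stop("paired t needs N >= 2 pairs")
  s <- sum(D)
  ss <- sum(D^2)
  denom2 <- (N * ss - s^2) / (N - 1)
  # denom2 is N * var(D); relative guard catches constant differences that
  # survive only as floating-point dust
  if (denom2 <= 0 || denom2 < 1e-12 * ss) {
    if (all(D == 0)) {
      return(list(t = 0, p = 1))
    }
    warning("complex '", A$complex_name,
            "': identical nonzero paired differences; zero spread, treating as significant")
    return(list(t = sign(s) * Inf, p = 0))
  }
  t <- s / sqrt(denom2)
  p <- 2 * stats::pt(abs(t), df = N - 1, lower.tail = FALSE)
  list(t = t, p = p)
}

check_matched <- function(A, B) {
  if (!identical(A$genes, B$genes)) {
    stop("matrices for '", A$complex_name, "' / '", B$complex_name,
         "' have mismatched gene order")
  }
  invisible(TRUE)
}

#' Signed significance code for a case-vs-control comparison
#'
#' @param A case [correlation_matrix()]
#' @param B control [correlation_matrix()]
#' @param alpha significance level (default 0.05)
#' @return +1 if the average correlation is significantly higher in the
#'   case matrix, -1 if significantly lower, 0 otherwise.
#' @export
significance_code <- function(A, B, alpha = 0.05) {
  tt <- paired_t_statistic(A, B)
  if (tt$p >= alpha) return(0L)
  as.integer(sign(average_upper(A) - average_upper(B)))
}

#' Significance quadruplet of a complex over timepoints
#'
#' @param dataset gene-level [expression_dataset()]
#' @param complex a [mapped_complex()]
#' @param timepoints timepoint labels in order (default: dataset order)
#' @param alpha significance level
#' @return integer vector of codes in {-1, 0, +1}, one per timepoint,
#'   named by timepoint.
#' @export
quadruplet <- function(dataset, complex, timepoints = dataset$timepoints,
                       alpha = 0.05) {
  codes <- vapply(timepoints, function(tp) {
    A <- complex_correlation_matrix(dataset, complex, "case", tp)
    B <- complex_correlation_matrix(dataset, complex, "control", tp)
    significance_code(A, B, alpha)
  }, integer(1))
  stats::setNames(codes, timepoints)
}

#' Normalized Euclidean distance between correlation matrices
#'
#' \deqn{d = \sqrt{\sum_{i<j} (A_{ij} - B_{ij})^2 / N}}
#' with N = n(n-1)/2; zero iff the matrices are identical.
#'
#' @param A,B matched [correlation_matrix()] objects
#' @return nonnegative distance.
#' @export
matrix_distance <- function(A, B) {
  check_matched(A, B)
  D <- A$upper - B$upper
  sqrt(sum(D^2) / length(D))
}

#' Null distribution of the matrix distance for random complexes
#'
#' Draws `n_random` gene sets of the given size uniformly without
#' replacement from the dataset's gene universe; for each, computes the
#' case-vs-control [matrix_distance()] at the timepoint. Gene sets whose
#' correlation matrices are degenerate (a zero-variance gene) are redrawn.
#'
#' @param dataset gene-level [expression_dataset()]
#' @param size complex size n
#' @param timepoint timepoint label
#' @param n_random number of random complexes (default 1000)
#' @param seed integer seed; the draw is deterministic given it
#' @return object of class `null_distribution` with fields `size`,
#'   `timepoint`, `n_random`, `mean_d`, `sd_d`, `seed`, `distances`.
#' @export
build_null <- function(dataset, size, timepoint, n_random = 1000L, seed = 1L) {
  universe <- rownames(dataset$values)
  if (size >= length(universe)) {
    stop("size ", size, " not below the gene universe (", length(universe), ")")
  }
  if (n_random < 2) stop("n_random must be >= 2")
  set.seed(as.integer(seed))
  dists <- numeric(n_random)
  for (k in seq_len(n_random)) {
    d <- NA_real_
    for (attempt in 1:100) {
      genes <- sample(universe, size)
      mc <- mapped_complex(sprintf("random_%d", k), genes)
      d <- tryCatch({
        A <- complex_correlation_matrix(dataset, mc, "case", timepoint)
        B <- complex_correlation_matrix(dataset, mc, "control", timepoint)
        matrix_distance(A, B)
      }, error = function(e) NA_real_)
      if (!is.na(d)) break
    }
    if (is.na(d)) stop("could not draw a non-degenerate random complex of size ", size)
    dists[k] <- d
  }
  structure(list(size = as.integer(size), timepoint = as.character(timepoint),
                 n_random = as.integer(n_random),
                 mean_d = mean(dists), sd_d = stats::sd(dists),
                 seed = as.integer(seed), distances = dists),
            class = "null_distribution")
}

#' z-score of an observed distance against a random-complex null
#'
#' z = (d - <x>) / S, where <x> and S are the null mean and standard
#' deviation. Significance is one-sided: only z above the threshold
#' (default 1.9) marks a complex; negative z means the observed distance is
#' smaller than the random expectation and is never significant.
#'
#' @param d observed distance
#' @param null a `null_distribution` from [build_null()] with `sd_d > 0`
#' @return the z-score.
#' @export
z_score <- function(d, null) {
  if (null$sd_d <= 0) stop("degenerate null: sd of random distances is 0")
  (d - null$mean_d) / null$sd_d
}

#' Case-minus-control difference matrix
#'
#' @param A case [correlation_matrix()]
#' @param B control [correlation_matrix()]
#' @return object of class `difference_matrix` with fields `complex_name`,
#'   `timepoint`, `genes`, `upper` (entries A_ij - B_ij in [-2, 2]).
#' @export
difference_matrix <- function(A, B) {
  check_matched(A, B)
  structure(list(complex_name = A$complex_name, timepoint = A$timepoint,
                 genes = A$genes, upper = A$upper - B$upper),
            class = "difference_matrix")
}

#' Rank genes by mean co-expression change
#'
#' For each gene, the mean of all difference-matrix entries involving it;
#' the most negative mean (strongest case-specific decorrelation) ranks
#' first. Ties break lexicographically.
#'
#' @param D a [difference_matrix()]
#' @return data.frame with columns `gene`, `mean_difference`, ascending.
#' @export
rank_gene_decorrelation <- function(D) {
  n <- length(D$genes)
  if (n < 3) stop("need at least 3 genes")
  pairs <- upper_pairs(n)
  means <- vapply(seq_len(n), function(g) {
    mean(D$upper[pairs[, "i"] == g | pairs[, "j"] == g])
  }, numeric(1))
  ord <- order(means, D$genes)
  data.frame(gene = D$genes[ord], mean_difference = means[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pooled distribution of co-expression values by complex size class
#'
#' Pools upper-triangle entries of the given matrices into small
#' (n <= size_threshold) and large (n > size_threshold) complex classes and
#' bins them at width 0.1 over [-1, 1].
#'
#' @param matrices non-empty list of [correlation_matrix()] objects
#' @param size_threshold boundary between small and large complexes
#'   (default 10)
#' @return list with elements `small` and `large`, each a list with
#'   `counts` (named bin counts), `mean` and `n_values`; plus `breaks`.
#' @export
correlation_value_distribution <- function(matrices, size_threshold = 10L) {
  if (!length(matrices)) stop("no matrices given")
  breaks <- seq(-1, 1, by = 0.1)
  bin_labels <- sprintf("[%.1f,%.1f)", utils::head(breaks, -1), breaks[-1])
  pool <- function(ms) {
    vals <- unlist(lapply(ms, `[[`, "upper"), use.names = FALSE)
    counts <- if (length(vals)) {
      graphics::hist(vals, breaks = breaks, plot = FALSE)$counts
    } else {
      integer(length(bin_labels))
    }
    list(counts = stats::setNames(counts, bin_labels),
         mean = if (length(vals)) mean(vals) else NA_real_,
         n_values = length(vals))
  }
  sizes <- vapply(matrices, function(m) length(m$genes), integer(1))
  list(small = pool(matrices[sizes <= size_threshold]),
       large = pool(matrices[sizes > size_threshold]),
       breaks = breaks)
}
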