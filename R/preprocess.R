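# Probe filtering and catalog mapping. Several probes on the array may match
# one gene; the probe kept per gene is the one whose expression best
# discriminates case from control by a one-way two-class ANOVA pooled across
# timepoints. The complex catalog is then restricted to measured genes and
# complexes smaller than min_size are dropped.

#' Score probes by two-class ANOVA discrimination
#'
#' One-way ANOVA of expression against group (case vs control), all samples
#' pooled across timepoints. With two classes F equals the squared pooled-
#' variance two-sample t statistic; computed row-wise over the matrix.
#'
#' @param dataset probe-level [expression_dataset()] with a probe map
#' @return data.frame with columns `probe_id`, `gene_symbol`, `f_stat`,
#'   `p_value`. Probes with zero variance in both groups get `p_value = 1`
#'   (and `f_stat = 0`) with a warning: they cannot discriminate.
#' @export
score_probes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$level != "probe") stop("dataset must be probe level")
  if (is.null(dataset$probe_to_gene)) stop("dataset has no probe-to-gene map")
  grp <- dataset$samples$group
  n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group; have ",
                             n1, " case and ", n2, " control")
  X1 <- dataset$values[, grp == "case", drop = FALSE]
  X2 <- dataset$values[, grp == "control", drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss1 <- rowSums((X1 - m1)^2); ss2 <- rowSums((X2 - m2)^2)
  df2 <- n1 + n2 - 2L
  # between-group SS for 2 groups: n1 n2 / (n1+n2) * (m1 - m2)^2
  ssb <- n1 * n2 / (n1 + n2) * (m1 - m2)^2
  msw <- (ss1 + ss2) / df2
  f <- ssb / msw
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  flat <- msw <= 0
  if (any(flat)) {
    warning(sum(flat), " probe(s) with zero within-group variance; p set to 1")
    f[flat] <- 0
    p[flat] <- 1
  }
  pid <- rownames(dataset$values)
  data.frame(probe_id = pid,
             gene_symbol = unname(dataset$probe_to_gene[pid]),
             f_stat = unname(f), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Select the best-discriminating probe per gene
#'
#' Smallest ANOVA p wins; ties broken by largest F, then lexicographically
#' smallest probe id, so the choice is deterministic.
#'
#' @param scores data.frame from [score_probes()]
#' @return named character vector, gene symbol -> probe id.
#' @export
select_best_probes <- function(scores) {
  if (!nrow(scores)) stop("empty score list")
  ord <- order(scores$gene_symbol, scores$p_value, -scores$f_stat, scores$probe_id)
  s <- scores[ord, , drop = FALSE]
  first <- !duplicated(s$gene_symbol)
  stats::setNames(s$probe_id[first], s$gene_symbol[first])
}

#' Collapse a probe-level dataset to gene level
#'
#' Keeps exactly the selected probes' rows, relabeled by gene symbol.
#'
#' @param dataset probe-level [expression_dataset()]
#' @param best named vector gene -> probe id, from [select_best_probes()]
#' @return gene-level [expression_dataset()] with a self probe map.
#' @export
collapse_to_genes <- function(dataset, best) {
  stopifnot(inherits(dataset, "expression_dataset"))
  absent <- setdiff(unname(best), rownames(dataset$values))
  if (length(absent)) stop("selected probe(s) absent from dataset: ",
                           paste(absent, collapse = ", "))
  genes <- sort(names(best))
  vals <- dataset$values[unname(best[genes]), , drop = FALSE]
  rownames(vals) <- genes
  expression_dataset(vals, dataset$samples, level = "gene",
                     probe_to_gene = stats::setNames(genes, genes),
                     timepoints = dataset$timepoints)
}

#' Restrict a complex catalog to measured genes
#'
#' Intersects every catalog entry with the dataset's gene set, drops
#' complexes that fall below `min_size`, and orders genes canonically
#' (lexicographically).
#'
#' @param catalog a [complex_catalog()]
#' @param dataset gene-level [expression_dataset()]
#' @param min_size minimum mapped size to keep (analysis filter; default 3)
#' @return list of [mapped_complex()] objects. Drops are reported via
#'   `message()` with counts.
#' @export
map_complexes <- function(catalog, dataset, min_size = 3L) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (dataset$level != "gene") stop("dataset must be gene level")
  universe <- rownames(dataset$values)
  mapped <- list()
  dropped <- 0L
  for (nm in names(catalog$entries)) {
    genes <- intersect(catalog$entries[[nm]], universe)
    if (length(genes) >= min_size) {
      mapped[[nm]] <- mapped_complex(nm, genes)
    } else {
      dropped <- dropped + 1L
    }
  }
  message("map_complexes: kept ", length(mapped), " of ", length(catalog$entries),
          " complexes (", dropped, " below size ", min_size, ")")
  unname(mapped)
}
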