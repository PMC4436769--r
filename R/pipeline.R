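# Orchestration: simulate or load -> probe selection -> complex mapping ->
# per-complex quadruplets, distances and z-scores -> report tables shaped
# like the study's two result tables.

#' One-sided significance of z-scores
#'
#' A distance is significant when its z-score exceeds the threshold
#' (default 1.9). Negative z (observed distance below the random
#' expectation) is never significant.
#'
#' @param z numeric vector of z-scores
#' @param threshold significance threshold
#' @return logical vector.
#' @export
significant_z <- function(z, threshold = 1.9) !is.na(z) & z > threshold

#' Configure a pipeline run
#'
#' Either `paths` (on-disk TSV inputs) or `sim_config` (a
#' [simulation_config()]) must be supplied.
#'
#' @param paths named list with `expression`, `metadata`, `catalog` and
#'   optionally `probe_map` (its presence marks the data probe-level) and
#'   `catalog_dialect` (default `"two_column"`)
#' @param sim_config a [simulation_config()]; the planted complexes become
#'   the catalog
#' @param alpha paired-t significance level (default 0.05)
#' @param z_threshold z-score significance threshold (default 1.9)
#' @param n_random random complexes per null (default 1000)
#' @param min_size analysis size filter (default 3)
#' @param report_min_size reporting size filter (default 4, i.e. size > 3)
#' @param timepoints optional explicit timepoint order
#' @param seed master seed for the null draws (and simulation, if configured
#'   without its own seed)
#' @param out_dir output directory; NULL suppresses all file output
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, sim_config = NULL, alpha = 0.05,
                            z_threshold = 1.9, n_random = 1000L,
                            min_size = 3L, report_min_size = 4L,
                            timepoints = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(paths) == is.null(sim_config)) {
    stop("supply exactly one of paths or sim_config")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (report_min_size < min_size) stop("report_min_size must be >= min_size")
  structure(list(paths = paths, sim_config = sim_config, alpha = alpha,
                 z_threshold = z_threshold, n_random = as.integer(n_random),
                 min_size = as.integer(min_size),
                 report_min_size = as.integer(report_min_size),
                 timepoints = timepoints, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Deterministic sub-seed per (size, timepoint-index), independent of
# complex identity so one null serves all complexes of a size.
null_seed <- function(master_seed, size, tp_index) {
  (as.integer(master_seed) %% 100000L) * 17389L + size * 127L + tp_index
}

#' Compare one complex between case and control over all timepoints
#'
#' @param dataset gene-level [expression_dataset()]
#' @param complex a [mapped_complex()]
#' @param alpha paired-t significance level
#' @param nulls optional named list of `null_distribution` objects, keyed
#'   `"<size>:<timepoint>"`; when present z-scores are attached
#' @param timepoints timepoint labels (default: dataset order)
#' @return object of class `comparison_result` with per-timepoint vectors
#'   `avg_case`, `avg_control`, `t_stat`, `p_value`, `code`, `distance`,
#'   `z_score`, the `quadruplet` (= `code`), and `diff_matrices` (one
#'   [difference_matrix()] per timepoint).
#' @export
compare_complex <- function(dataset, complex, alpha = 0.05, nulls = NULL,
                            timepoints = dataset$timepoints) {
  k <- length(timepoints)
  avg_case <- avg_control <- t_stat <- p_value <- dist <- z <- rep(NA_real_, k)
  code <- rep(NA_integer_, k)
  diffs <- vector("list", k)
  for (i in seq_len(k)) {
    tp <- timepoints[i]
    A <- complex_correlation_matrix(dataset, complex, "case", tp)
    B <- complex_correlation_matrix(dataset, complex, "control", tp)
    avg_case[i] <- average_upper(A)
    avg_control[i] <- average_upper(B)
    tt <- paired_t_statistic(A, B)
    t_stat[i] <- tt$t
    p_value[i] <- tt$p
    code[i] <- if (tt$p >= alpha) 0L else as.integer(sign(avg_case[i] - avg_control[i]))
    dist[i] <- matrix_distance(A, B)
    diffs[[i]] <- difference_matrix(A, B)
    if (!is.null(nulls)) {
      key <- paste0(complex$n, ":", tp)
      # a zero-spread null (e.g. case and control literally identical) makes
      # z undefined; report NA (never significant) instead of aborting
      if (!is.null(nulls[[key]]) && nulls[[key]]$sd_d > 0) {
        z[i] <- z_score(dist[i], nulls[[key]])
      }
    }
  }
  structure(list(complex_name = complex$name, n = complex$n,
                 genes = complex$genes, timepoints = as.character(timepoints),
                 avg_case = avg_case, avg_control = avg_control,
                 t_stat = t_stat, p_value = p_value, code = code,
                 quadruplet = code, distance = dist, z_score = z,
                 diff_matrices = diffs),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison_result '", x$complex_name, "' (n = ", x$n, ")\n", sep = "")
  cat("  quadruplet: (", paste(x$code, collapse = ", "), ")\n", sep = "")
  cat("  d:", sprintf("%.3f", x$distance), "\n")
  if (!all(is.na(x$z_score))) cat("  z:", sprintf("%.2f", x$z_score), "\n")
  invisible(x)
}

#' Run the full pipeline
#'
#' Simulates or loads the data, collapses probes to genes if needed, maps
#' the catalog, builds one random-complex null per (complex size,
#' timepoint), compares every complex, and (if `out_dir` is set) writes
#' `full_results.tsv`, `quadruplets.tsv`, `distances.tsv`,
#' `null_summary.tsv` and per-complex difference matrices under
#' `difference_matrices/`. Counts at every filter step are reported via
#' `message()`.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with `results` (list of `comparison_result`),
#'   `dataset`, `complexes`, `nulls`, `quadruplet_table`, `distance_table`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$sim_config)) {
    dataset <- simulate_dataset(config$sim_config)
    entries <- stats::setNames(
      lapply(config$sim_config$complex_specs, spec_gene_names),
      vapply(config$sim_config$complex_specs, `[[`, "", "name"))
    catalog <- complex_catalog(entries, provenance = "simulated")
  } else {
    p <- config$paths
    dataset <- read_expression_matrix(p$expression, p$metadata,
                                      probe_map_path = p$probe_map,
                                      timepoints = config$timepoints)
    dialect <- if (is.null(p$catalog_dialect)) "two_column" else p$catalog_dialect
    catalog <- read_complex_catalog(p$catalog, dialect = dialect)
  }
  if (!is.null(config$timepoints)) dataset$timepoints <- as.character(config$timepoints)

  if (dataset$level == "probe") {
    scores <- score_probes(dataset)
    best <- select_best_probes(scores)
    message("probe selection: ", nrow(scores), " probes -> ", length(best), " genes")
    dataset <- collapse_to_genes(dataset, best)
  }

  complexes <- map_complexes(catalog, dataset, min_size = config$min_size)
  results <- list()
  skipped <- character(0)

  nulls <- list()
  sizes <- sort(unique(vapply(complexes, `[[`, integer(1), "n")))
  for (sz in sizes) {
    for (i in seq_along(dataset$timepoints)) {
      tp <- dataset$timepoints[i]
      nulls[[paste0(sz, ":", tp)]] <- build_null(
        dataset, sz, tp, n_random = config$n_random,
        seed = null_seed(config$seed, sz, i))
    }
  }

  for (cx in complexes) {
    r <- tryCatch(
      compare_complex(dataset, cx, alpha = config$alpha, nulls = nulls),
      error = function(e) conditionMessage(e))
    if (is.character(r)) {
      skipped <- c(skipped, paste0(cx$name, ": ", r))
    } else {
      results[[cx$name]] <- r
    }
  }
  message("analysis: ", length(results), " complexes compared, ",
          length(skipped), " skipped")
  for (s in skipped) message("  skipped ", s)
  results <- unname(results)

  qt <- report_quadruplets(results, report_min_size = config$report_min_size)
  dt <- report_distances(results, z_threshold = config$z_threshold,
                         report_min_size = config$report_min_size)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (length(results)) {
      write_results_table(results, file.path(config$out_dir, "full_results.tsv"),
                          table = "full")
    }
    utils::write.table(qt, file.path(config$out_dir, "quadruplets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dt, file.path(config$out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ns <- do.call(rbind, lapply(nulls, function(nl) data.frame(
      size = nl$size, timepoint = nl$timepoint, n_random = nl$n_random,
      mean_d = sprintf("%.10g", nl$mean_d), sd_d = sprintf("%.10g", nl$sd_d),
      seed = nl$seed, stringsAsFactors = FALSE)))
    utils::write.table(ns, file.path(config$out_dir, "null_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm_dir <- file.path(config$out_dir, "difference_matrices")
    dir.create(dm_dir, showWarnings = FALSE)
    for (r in results) {
      for (D in r$diff_matrices) {
        fn <- sprintf("%s_t%s.tsv", gsub("[^A-Za-z0-9._-]", "_", r$complex_name),
                      D$timepoint)
        write_difference_matrix(D, file.path(dm_dir, fn))
      }
    }
  }
  invisible(list(results = results, dataset = dataset, complexes = complexes,
                 nulls = nulls, quadruplet_table = qt, distance_table = dt,
                 skipped = skipped))
}

#' Quadruplet report table
#'
#' Rows with size >= `report_min_size` (the study tables use size > 3) and
#' a quadruplet different from all-zero, sorted by descending size then
#' name. Filtering never alters values.
#'
#' @param results list of `comparison_result` objects
#' @param report_min_size minimum size to report (default 4)
#' @return data.frame with columns `complex`, `size`, `t<tp>` per timepoint.
#' @export
report_quadruplets <- function(results, report_min_size = 4L) {
  tps <- if (length(results)) results[[1L]]$timepoints else character(0)
  cols <- c("complex", "size", paste0("t", tps, recycle0 = TRUE))
  rows <- Filter(function(r) r$n >= report_min_size && any(r$code != 0L), results)
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), integer(0)), rep(list(integer(0)), length(tps))), cols))
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(c(list(complex = r$complex_name, size = r$n),
                    stats::setNames(as.list(r$code), paste0("t", tps))),
                  stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$size, out$complex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance/z-score report table
#'
#' Rows with size >= `report_min_size` and at least one z-score above the
#' threshold, ordered by earliest significant timepoint, then descending
#' size, then name.
#'
#' @param results list of `comparison_result` objects
#' @param z_threshold significance threshold on z (default 1.9)
#' @param report_min_size minimum size to report (default 4)
#' @return data.frame with columns `complex`, `size`, `d<tp>` and `z<tp>`
#'   per timepoint, and `n_significant`.
#' @export
report_distances <- function(results, z_threshold = 1.9, report_min_size = 4L) {
  tps <- if (length(results)) results[[1L]]$timepoints else character(0)
  cols <- c("complex", "size",
            as.vector(rbind(paste0("d", tps, recycle0 = TRUE),
                            paste0("z", tps, recycle0 = TRUE))), "n_significant")
  keep <- Filter(function(r) {
    r$n >= report_min_size && any(significant_z(r$z_score, z_threshold))
  }, results)
  if (!length(keep)) {
    proto <- c(list(character(0), integer(0)),
               rep(list(numeric(0)), 2L * length(tps)), list(integer(0)))
    out <- as.data.frame(stats::setNames(proto, cols))
    return(out)
  }
  out <- do.call(rbind, lapply(keep, function(r) {
    row <- list(complex = r$complex_name, size = r$n)
    for (i in seq_along(tps)) {
      row[[paste0("d", tps[i])]] <- r$distance[i]
      row[[paste0("z", tps[i])]] <- r$z_score[i]
    }
    row$n_significant <- sum(significant_z(r$z_score, z_threshold))
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  first_sig <- vapply(keep, function(r) {
    which(significant_z(r$z_score, z_threshold))[1L]
  }, integer(1))
  ord <- order(first_sig, -out$size, out$complex)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a quadruplet report table
#'
#' Counts, over the given rows, how many have a non-zero code at the first
#' timepoint and how many of those are +1; also reports how many all-zero
#' rows were present (they would be excluded from the printed table).
#'
#' @param rows data.frame as produced by [report_quadruplets()] (columns
#'   `complex`, `size`, then one code column per timepoint in order)
#' @return list with `nonzero_t1`, `plus_one_t1`, `all_zero_excluded`.
#' @export
summarize_table1 <- function(rows) {
  code_cols <- setdiff(names(rows), c("complex", "size"))
  if (!nrow(rows)) {
    return(list(nonzero_t1 = 0L, plus_one_t1 = 0L, all_zero_excluded = 0L))
  }
  t1 <- rows[[code_cols[1L]]]
  codes <- as.matrix(rows[, code_cols, drop = FALSE])
  list(nonzero_t1 = sum(t1 != 0L),
       plus_one_t1 = sum(t1 == 1L),
       all_zero_excluded = sum(rowSums(codes != 0L) == 0L))
}
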