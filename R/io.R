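# Readers and writers for the plain-text interchange formats:
#   expression matrix  TSV, row 1 = "feature_id" + sample ids
#   sample metadata    TSV: sample_id, group, timepoint
#   probe map          TSV: probe_id, gene_symbol
#   complex catalog    CORUM-style TSV or simple two-column TSV
#   result tables      TSV mirroring the quadruplet / distance reports

#' Read an expression matrix with its sample metadata
#'
#' @param path tab-delimited expression file; first column `feature_id`,
#'   remaining columns one per sample, header row of sample ids.
#' @param metadata_path tab-delimited metadata with columns `sample_id`,
#'   `group` (case/control), `timepoint`.
#' @param probe_map_path optional tab-delimited file with columns
#'   `probe_id`, `gene_symbol`; attaching it marks the dataset probe-level.
#' @param timepoints optional ordered timepoint labels; default order of
#'   first appearance in the metadata.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, metadata_path, probe_map_path = NULL,
                                   timepoints = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file has no sample columns: ", path)
  fid <- raw[[1L]]
  if (anyDuplicated(fid)) stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  sample_ids <- colnames(raw)[-1L]

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
  req <- c("sample_id", "group", "timepoint")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(sample_ids, meta$sample_id)
  if (length(absent)) {
    stop("sample(s) in expression header absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), req, drop = FALSE]

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(fid, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]) &
                   !(raw[[j + 1L]] %in% c("NA", "NaN")))
    if (length(bad)) {
      stop("non-numeric value '", raw[[j + 1L]][bad[1L]], "' at feature '",
           fid[bad[1L]], "', sample '", sample_ids[j], "'")
    }
    if (anyNA(v)) {
      stop("missing value at feature '", fid[which(is.na(v))[1L]],
           "', sample '", sample_ids[j], "'; complete data required")
    }
    vals[, j] <- v
  }

  probe_to_gene <- NULL
  level <- "gene"
  if (!is.null(probe_map_path)) {
    pm <- utils::read.delim(probe_map_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    pm_miss <- setdiff(c("probe_id", "gene_symbol"), names(pm))
    if (length(pm_miss)) stop("probe map missing column(s): ", paste(pm_miss, collapse = ", "))
    probe_to_gene <- stats::setNames(pm$gene_symbol, pm$probe_id)
    level <- "probe"
  }
  expression_dataset(vals, meta, level = level, probe_to_gene = probe_to_gene,
                     timepoints = timepoints)
}

#' Write an expression dataset to a TSV bundle
#'
#' Writes the expression matrix and sample metadata (and probe map, if any)
#' in the formats [read_expression_matrix()] accepts; full numeric precision.
#'
#' @param dataset an [expression_dataset()]
#' @param path expression TSV path
#' @param metadata_path metadata TSV path
#' @param probe_map_path optional probe map TSV path
#' @export
write_expression_matrix <- function(dataset, path, metadata_path,
                                    probe_map_path = NULL) {
  df <- data.frame(feature_id = rownames(dataset$values),
                   format(dataset$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples[, c("sample_id", "group", "timepoint")],
                     metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(probe_map_path)) {
    if (is.null(dataset$probe_to_gene)) stop("dataset has no probe map to write")
    pm <- data.frame(probe_id = names(dataset$probe_to_gene),
                     gene_symbol = unname(dataset$probe_to_gene),
                     stringsAsFactors = FALSE)
    utils::write.table(pm, probe_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a protein-complex catalog
#'
#' @param path tab-delimited catalog file
#' @param dialect `"corum"`: one complex per line, a name column and a
#'   semicolon-separated gene-symbol column; `"two_column"`: one
#'   (complex_name, gene) pair per line, no header.
#' @param name_col,genes_col column names for the corum dialect (defaults
#'   match CORUM's `ComplexName` / `subunits(Gene name)`); if the file has
#'   no header matching `name_col`, the first two columns are used.
#' @return a [complex_catalog()].
#' @export
read_complex_catalog <- function(path, dialect = c("corum", "two_column"),
                                 name_col = "ComplexName",
                                 genes_col = "subunits(Gene name)") {
  dialect <- match.arg(dialect)
  if (dialect == "corum") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character",
                             quote = "")
    if (all(c(name_col, genes_col) %in% names(raw))) {
      nm <- raw[[name_col]]; gl <- raw[[genes_col]]
    } else if (ncol(raw) >= 2L) {
      nm <- raw[[1L]]; gl <- raw[[2L]]
    } else {
      stop("corum catalog needs a name column and a gene-symbols column: ", path)
    }
    bad <- which(is.na(nm) | nm == "" | is.na(gl))
    if (length(bad)) stop("unreadable catalog line ", bad[1L] + 1L, " in ", path)
    entries <- stats::setNames(strsplit(gl, ";", fixed = TRUE), nm)
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(raw) < 2L) stop("two_column catalog needs two columns: ", path)
    bad <- which(is.na(raw[[1L]]) | raw[[1L]] == "" | is.na(raw[[2L]]) | raw[[2L]] == "")
    if (length(bad)) stop("unreadable catalog line ", bad[1L], " in ", path)
    entries <- split(raw[[2L]], factor(raw[[1L]], levels = unique(raw[[1L]])))
  }
  complex_catalog(entries, provenance = basename(path))
}

#' Write a complex catalog
#'
#' @param catalog a [complex_catalog()]
#' @param path output TSV path
#' @param dialect output format, see [read_complex_catalog()]
#' @export
write_complex_catalog <- function(catalog, path, dialect = c("corum", "two_column")) {
  dialect <- match.arg(dialect)
  if (dialect == "corum") {
    df <- data.frame(
      ComplexName = names(catalog$entries),
      `subunits(Gene name)` = vapply(catalog$entries, paste, "", collapse = ";"),
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(
      complex = rep(names(catalog$entries), lengths(catalog$entries)),
      gene = unlist(catalog$entries, use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(NULL)
}

#' Flatten comparison results to a data frame
#'
#' One row per complex; per-timepoint columns for averages, t, p, code,
#' distance and z-score.
#'
#' @param results list of `comparison_result` objects from
#'   [compare_complex()] / [run_pipeline()]
#' @return data.frame with columns `complex`, `size` and, per timepoint `tp`,
#'   `avg_case_tp`, `avg_control_tp`, `t_tp`, `p_tp`, `code_tp`, `d_tp`, `z_tp`.
#' @export
results_to_data_frame <- function(results) {
  if (!length(results)) stop("empty result list")
  tps <- results[[1L]]$timepoints
  rows <- lapply(results, function(r) {
    out <- list(complex = r$complex_name, size = r$n)
    for (k in seq_along(tps)) {
      tp <- tps[k]
      out[[paste0("avg_case_", tp)]] <- r$avg_case[k]
      out[[paste0("avg_control_", tp)]] <- r$avg_control[k]
      out[[paste0("t_", tp)]] <- r$t_stat[k]
      out[[paste0("p_", tp)]] <- r$p_value[k]
      out[[paste0("code_", tp)]] <- r$code[k]
      out[[paste0("d_", tp)]] <- r$distance[k]
      out[[paste0("z_", tp)]] <- if (is.null(r$z_score)) NA_real_ else r$z_score[k]
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a results table
#'
#' @param results non-empty list of `comparison_result` objects
#' @param path output TSV path
#' @param table `"quadruplets"` (complex, size, one code column per
#'   timepoint), `"distances"` (complex, size, d and z per timepoint, 2
#'   decimals), or `"full"` (every field, full precision).
#' @export
write_results_table <- function(results, path,
                                table = c("quadruplets", "distances", "full")) {
  table <- match.arg(table)
  if (!length(results)) stop("empty result list")
  tps <- results[[1L]]$timepoints
  df <- results_to_data_frame(results)
  if (table == "quadruplets") {
    out <- df[, c("complex", "size", paste0("code_", tps))]
    names(out) <- c("complex", "size", paste0("t", tps))
  } else if (table == "distances") {
    out <- df[, "complex", drop = FALSE]
    out$size <- df$size
    for (tp in tps) {
      out[[paste0("d", tp)]] <- sprintf("%.2f", df[[paste0("d_", tp)]])
      out[[paste0("z", tp)]] <- sprintf("%.2f", df[[paste0("z_", tp)]])
    }
  } else {
    out <- df
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "size"
    out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a difference matrix as a square TSV
#'
#' Square layout with gene symbols as row and column headers; diagonal 0.
#'
#' @param D a `difference_matrix` from [difference_matrix()]
#' @param path output TSV path
#' @export
write_difference_matrix <- function(D, path) {
  M <- upper_to_matrix(D$genes, D$upper, diag = 0)
  df <- data.frame(gene = rownames(M), format(M, digits = 10, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
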