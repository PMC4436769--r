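# Synthetic two-group time-course expression data with planted complex-level
# correlation structure. Complex genes are drawn, per (group, timepoint)
# cell, from a zero-mean multivariate normal with an equicorrelation block
# (optionally with one "anti-member" gene negatively correlated to the rest);
# background genes are independent Gaussian noise. All downstream metrics are
# correlation-based and therefore location/scale free, so Gaussian unit-scale
# marginals are sufficient.

#' Specify a planted complex for simulation
#'
#' @param name complex name
#' @param size number of genes (>= 3)
#' @param rho target intra-complex correlation. Either a single number
#'   (all cells), or a matrix with rownames `c("case", "control")` and one
#'   column per timepoint. Each value must exceed `-1/(size-1)` (the
#'   equicorrelation positive-semidefiniteness bound) and be below 1.
#' @param anti_member optional 1-based index of one gene given correlation
#'   `-rho_anti` to every other member (the others stay equicorrelated at
#'   `rho`), emulating a subunit dissociated from the complex network.
#' @param rho_anti magnitude of the anti-member's negative correlation,
#'   in `[0, 1)`.
#' @param anti_groups groups in which the anti-member pattern is active
#'   (default `"case"` only).
#' @param anti_timepoints timepoints in which the pattern is active
#'   (default all).
#' @return object of class `complex_spec`.
#' @export
complex_spec <- function(name, size, rho, anti_member = NULL, rho_anti = 0,
                         anti_groups = "case", anti_timepoints = NULL) {
  if (size < 3) stop("complex '", name, "': size must be >= 3")
  if (!is.null(anti_member)) {
    if (anti_member < 1 || anti_member > size) stop("anti_member index out of range")
    if (rho_anti < 0 || rho_anti >= 1) stop("rho_anti must be in [0, 1)")
  }
  structure(list(name = name, size = as.integer(size), rho = rho,
                 anti_member = anti_member, rho_anti = rho_anti,
                 anti_groups = anti_groups, anti_timepoints = anti_timepoints),
            class = "complex_spec")
}

# rho for one (group, timepoint) cell from the spec's scalar or matrix form.
spec_rho <- function(spec, group, timepoint, timepoints) {
  if (is.matrix(spec$rho)) {
    k <- match(as.character(timepoint), colnames(spec$rho))
    if (is.na(k)) k <- match(as.character(timepoint), as.character(timepoints))
    spec$rho[group, k]
  } else {
    spec$rho
  }
}

# Correlation matrix for one cell: equicorrelation at rho, optionally with
# one anti-member at -rho_anti to all others. PSD verified numerically.
spec_sigma <- function(spec, group, timepoint, timepoints) {
  n <- spec$size
  rho <- spec_rho(spec, group, timepoint, timepoints)
  if (rho <= -1 / (n - 1) || rho >= 1) {
    stop("complex '", spec$name, "': rho = ", rho,
         " outside the equicorrelation bound (-1/(n-1), 1) for n = ", n)
  }
  S <- matrix(rho, n, n); diag(S) <- 1
  anti_on <- !is.null(spec$anti_member) &&
    group %in% spec$anti_groups &&
    (is.null(spec$anti_timepoints) ||
       as.character(timepoint) %in% as.character(spec$anti_timepoints))
  if (anti_on) {
    a <- spec$anti_member
    S[a, ] <- -spec$rho_anti; S[, a] <- -spec$rho_anti; S[a, a] <- 1
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("complex '", spec$name, "': requested correlation structure at (",
         group, ", ", timepoint, ") is not positive semi-definite")
  }
  S
}

#' Configure a synthetic dataset
#'
#' Defaults emulate the study design the package targets: four timepoints
#' (months 1, 3, 6, 15) with 15 case and 15 control samples each.
#'
#' @param complex_specs list of [complex_spec()] objects
#' @param n_background_genes independent noise genes outside any complex
#' @param timepoints ordered timepoint labels
#' @param samples_per_cell samples per (group, timepoint) cell (>= 3)
#' @param noise_sd standard deviation of background genes
#' @param seed mandatory integer seed
#' @param group_shift optional named numeric vector: additive mean shift
#'   applied to the named genes in case samples (all timepoints), used to
#'   plant two-class ANOVA-detectable effects
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(complex_specs = list(),
                              n_background_genes = 500,
                              timepoints = c("1", "3", "6", "15"),
                              samples_per_cell = 15,
                              noise_sd = 1,
                              seed,
                              group_shift = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (samples_per_cell < 3) stop("samples_per_cell must be >= 3")
  for (s in complex_specs) {
    if (!inherits(s, "complex_spec")) stop("complex_specs must be complex_spec objects")
  }
  nm <- vapply(complex_specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate complex names in complex_specs")
  structure(list(complex_specs = complex_specs,
                 n_background_genes = as.integer(n_background_genes),
                 timepoints = as.character(timepoints),
                 samples_per_cell = as.integer(samples_per_cell),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 group_shift = group_shift),
            class = "simulation_config")
}

# Gene names: complex genes <ComplexName>_g01..; background BG00001..
spec_gene_names <- function(spec) {
  sprintf("%s_g%02d", gsub("[^A-Za-z0-9]", ".", spec$name), seq_len(spec$size))
}

#' Simulate a gene-level expression dataset
#'
#' For every (group, timepoint) cell, each planted complex is drawn from a
#' multivariate normal with its specified equicorrelation structure;
#' background genes are independent `N(0, noise_sd^2)`. Deterministic given
#' the config seed.
#'
#' @param config a [simulation_config()]
#' @return gene-level [expression_dataset()] with a self probe map.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tps <- config$timepoints
  m <- config$samples_per_cell
  groups <- c("case", "control")

  cgenes <- unlist(lapply(config$complex_specs, spec_gene_names), use.names = FALSE)
  bgenes <- if (config$n_background_genes > 0)
    sprintf("BG%05d", seq_len(config$n_background_genes)) else character(0)
  genes <- c(cgenes, bgenes)
  if (anyDuplicated(genes)) stop("generated gene names collide")

  meta <- expand.grid(rep = seq_len(m), group = groups, timepoint = tps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_t%s_s%02d", meta$group, meta$timepoint, meta$rep)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = nrow(meta),
                 dimnames = list(genes, meta$sample_id))

  for (tp in tps) {
    for (g in groups) {
      cols <- which(meta$group == g & meta$timepoint == tp)
      for (spec in config$complex_specs) {
        S <- spec_sigma(spec, g, tp, tps)
        X <- MASS::mvrnorm(n = m, mu = rep(0, spec$size), Sigma = S)
        vals[spec_gene_names(spec), cols] <- t(X)
      }
      if (length(bgenes)) {
        vals[bgenes, cols] <- matrix(stats::rnorm(length(bgenes) * m,
                                                  sd = config$noise_sd),
                                     nrow = length(bgenes))
      }
    }
  }
  if (!is.null(config$group_shift)) {
    unknown <- setdiff(names(config$group_shift), genes)
    if (length(unknown)) stop("group_shift names not in gene set: ",
                              paste(unknown, collapse = ", "))
    case_cols <- which(meta$group == "case")
    for (gn in names(config$group_shift)) {
      vals[gn, case_cols] <- vals[gn, case_cols] + config$group_shift[[gn]]
    }
  }
  expression_dataset(vals, meta[, c("sample_id", "group", "timepoint")],
                     level = "gene",
                     probe_to_gene = stats::setNames(genes, genes),
                     timepoints = tps)
}

#' Expand a gene-level dataset to probe level with decoy probes
#'
#' Each gene becomes `probes_per_gene` probes: probe 1 carries the gene's
#' signal unchanged; the remaining probes add heavy independent noise, so
#' discrimination-based probe selection has a planted correct answer.
#'
#' @param dataset gene-level [expression_dataset()]
#' @param probes_per_gene number of probes per gene (>= 1)
#' @param decoy_noise_sd standard deviation of the decoy probes' added noise
#' @param seed integer seed
#' @return probe-level [expression_dataset()] with probe ids
#'   `<gene>_p1 .. _p<k>` and the matching probe map.
#' @export
make_probe_level <- function(dataset, probes_per_gene, decoy_noise_sd = 5, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$level != "gene") stop("dataset must be gene level")
  if (probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  set.seed(as.integer(seed))
  genes <- rownames(dataset$values)
  k <- as.integer(probes_per_gene)
  probe_ids <- as.vector(t(outer(genes, seq_len(k),
                                 function(g, i) sprintf("%s_p%d", g, i))))
  vals <- matrix(NA_real_, nrow = length(probe_ids), ncol = ncol(dataset$values),
                 dimnames = list(probe_ids, colnames(dataset$values)))
  for (gi in seq_along(genes)) {
    base <- dataset$values[gi, ]
    rows <- (gi - 1L) * k + seq_len(k)
    vals[rows[1L], ] <- base
    if (k > 1L) {
      for (r in rows[-1L]) {
        vals[r, ] <- base + stats::rnorm(length(base), sd = decoy_noise_sd)
      }
    }
  }
  expression_dataset(vals, dataset$samples, level = "probe",
                     probe_to_gene = stats::setNames(rep(genes, each = k), probe_ids),
                     timepoints = dataset$timepoints)
}

#' Write a self-contained synthetic fixture bundle
#'
#' Simulates a dataset from `config` and writes the four files the readers
#' accept: `expression.tsv`, `metadata.tsv`, `probe_map.tsv` and
#' `catalog.tsv` (two-column dialect listing the planted complexes).
#'
#' @param config a [simulation_config()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, the simulated [expression_dataset()].
#' @export
write_fixture_bundle <- function(config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  ds <- simulate_dataset(config)
  write_expression_matrix(ds,
                          file.path(out_dir, "expression.tsv"),
                          file.path(out_dir, "metadata.tsv"),
                          file.path(out_dir, "probe_map.tsv"))
  entries <- stats::setNames(lapply(config$complex_specs, spec_gene_names),
                             vapply(config$complex_specs, `[[`, "", "name"))
  if (length(entries)) {
    write_complex_catalog(complex_catalog(entries, provenance = "synthetic"),
                          file.path(out_dir, "catalog.tsv"), dialect = "two_column")
  }
  invisible(ds)
}

#' Read a simulation config from a YAML file
#'
#' Top-level keys mirror [simulation_config()] arguments
#' (`n_background_genes`, `timepoints`, `samples_per_cell`, `noise_sd`,
#' `seed`) plus `complexes`, a list of entries with `name`, `size` and
#' either a scalar `rho` or per-timepoint vectors `rho_case` /
#' `rho_control`, and optionally `anti_member`, `rho_anti`, `anti_groups`,
#' `anti_timepoints`.
#'
#' @param path YAML file path
#' @param seed optional seed overriding the file's `seed` key
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  cfg <- yaml::read_yaml(path)
  tps <- as.character(if (is.null(cfg$timepoints)) c("1", "3", "6", "15") else cfg$timepoints)
  specs <- lapply(cfg$complexes, function(cx) {
    rho <- if (!is.null(cx$rho_case) || !is.null(cx$rho_control)) {
      rc <- rep_len(as.numeric(if (is.null(cx$rho_case)) 0 else cx$rho_case), length(tps))
      rl <- rep_len(as.numeric(if (is.null(cx$rho_control)) 0 else cx$rho_control), length(tps))
      matrix(rbind(rc, rl), 2, length(tps),
             dimnames = list(c("case", "control"), tps))
    } else {
      as.numeric(if (is.null(cx$rho)) 0 else cx$rho)
    }
    complex_spec(cx$name, cx$size, rho,
                 anti_member = cx$anti_member,
                 rho_anti = if (is.null(cx$rho_anti)) 0 else cx$rho_anti,
                 anti_groups = if (is.null(cx$anti_groups)) "case" else cx$anti_groups,
                 anti_timepoints = cx$anti_timepoints)
  })
  simulation_config(
    complex_specs = specs,
    n_background_genes = if (is.null(cfg$n_background_genes)) 500 else cfg$n_background_genes,
    timepoints = tps,
    samples_per_cell = if (is.null(cfg$samples_per_cell)) 15 else cfg$samples_per_cell,
    noise_sd = if (is.null(cfg$noise_sd)) 1 else cfg$noise_sd,
    seed = if (!is.null(seed)) seed else cfg$seed)
}
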