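# Fixtures are built in code; nothing is stored on disk.

# A deterministic gene-level dataset with explicit values (no simulation):
# useful for IO round trips and bookkeeping tests.
tiny_dataset <- function(n_genes = 4, samples_per_cell = 3,
                         timepoints = c("1", "3"), seed = 1) {
  set.seed(seed)
  meta <- expand.grid(rep = seq_len(samples_per_cell),
                      group = c("case", "control"), timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_t%s_s%d", meta$group, meta$timepoint, meta$rep)
  vals <- matrix(round(rnorm(n_genes * nrow(meta)), 6), nrow = n_genes,
                 dimnames = list(sprintf("G%02d", seq_len(n_genes)), meta$sample_id))
  expression_dataset(vals, meta[, c("sample_id", "group", "timepoint")],
                     level = "gene", timepoints = timepoints)
}

# Null simulation: k independent equicorrelation-0 complexes, no background.
null_sim_config <- function(n_complexes = 1, size = 5, samples_per_cell = 15,
                            timepoints = c("1", "3", "6", "15"),
                            n_background = 0, seed = 1) {
  specs <- lapply(seq_len(n_complexes), function(i)
    complex_spec(sprintf("NULL%03d", i), size, rho = 0))
  simulation_config(specs, n_background_genes = n_background,
                    timepoints = timepoints,
                    samples_per_cell = samples_per_cell, seed = seed)
}

# The planted differential scenario: case rho 0.6 vs control rho 0.1 at the
# first timepoint, rho 0 both groups elsewhere. One plain complex for
# quadruplet recovery and one with an anti-member for gene ranking.
planted_sim_config <- function(seed, size = 8, samples_per_cell = 15) {
  tps <- c("1", "3", "6", "15")
  rho <- matrix(0, 2, 4, dimnames = list(c("case", "control"), tps))
  rho["case", "1"] <- 0.6
  rho["control", "1"] <- 0.1
  simulation_config(
    list(complex_spec("QUAD", size, rho),
         complex_spec("ANTI", size, rho, anti_member = 3, rho_anti = 0.6,
                      anti_groups = "case", anti_timepoints = "1")),
    n_background_genes = 0, timepoints = tps,
    samples_per_cell = samples_per_cell, seed = seed)
}

planted_complex <- function(name = "QUAD", size = 8) {
  mapped_complex(name, sprintf("%s_g%02d", name, seq_len(size)))
}

# Fabricate a correlation_matrix-shaped object from an upper vector, for
# formula-level tests (bypasses sampling; still validated for range/length).
cm_from_upper <- function(upper, name = "CPLX", group = "case", tp = "1") {
  n <- (1 + sqrt(1 + 8 * length(upper))) / 2
  stopifnot(n == round(n))
  correlation_matrix(name, group, tp, sprintf("g%02d", seq_len(n)), upper)
}

# The 14 quadruplets printed in the study's average-correlation table
# (complex, size, codes at months 1, 3, 6, 15): used as worked-example input.
printed_quadruplet_table <- function() {
  data.frame(
    complex = c("Parvulin-associated-pre-rRNP-complex", "20S-proteasome",
                "immunoproteasome", "B-Ksr1-MEK-MAPK-14-3-3-complex",
                "Gata1-Fog1-MeCP1-complex", "Drosha-complex",
                "BLOC-1-biogenesis-of-lysosome-related-organelles",
                "Metallothionein-3-complex", "Brd4-Rfc-complex", "MCM-complex",
                "Agap11-AP3-complex", "Kif3-cadherin-catenin-complex",
                "Sarcoglycan-sarcospan-syntrophin-dystrobrevin",
                "Wave-2-complex-Rac-activated"),
    size = c(40L, 14L, 14L, 8L, 8L, 7L, 6L, 6L, 5L, 5L, 4L, 4L, 4L, 4L),
    t1  = c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, -1L),
    t3  = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, -1L, 0L, 0L, 0L, 0L),
    t6  = c(0L, 0L, 0L, -1L, 0L, 0L, -1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L),
    t15 = c(-1L, 0L, 0L, 0L, 0L, 0L, 0L, -1L, 0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

# Fabricate a comparison_result for report-layer tests.
fake_result <- function(name, n, code, distance = rep(0.2, length(code)),
                        z = rep(NA_real_, length(code)),
                        tps = c("1", "3", "6", "15")) {
  structure(list(complex_name = name, n = n,
                 genes = sprintf("%s_g%02d", name, seq_len(n)),
                 timepoints = tps,
                 avg_case = rep(0.1, length(tps)),
                 avg_control = rep(0.05, length(tps)),
                 t_stat = rep(1, length(tps)), p_value = rep(0.5, length(tps)),
                 code = as.integer(code), quadruplet = as.integer(code),
                 distance = distance, z_score = z,
                 diff_matrices = vector("list", length(tps))),
            class = "comparison_result")
}
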