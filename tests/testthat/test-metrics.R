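test_that("pearson matches hand-computed values and rejects flat profiles", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3), xname = "Gflat"), "Gflat")
  expect_error(pearson(c(1, 2), c(1, 2)), "at least 3")
})

test_that("complex correlation matrices have canonical length and order", {
  ds <- tiny_dataset(n_genes = 3, samples_per_cell = 5, seed = 61)
  mc <- mapped_complex("C3", c("G01", "G02", "G03"))
  A <- complex_correlation_matrix(ds, mc, "case", "1")
  expect_length(A$upper, 3L)
  expect_identical(A$genes, c("G01", "G02", "G03"))
  # entries agree with pairwise pearson in (1,2),(1,3),(2,3) order
  cols <- ds$samples$group == "case" & ds$samples$timepoint == "1"
  expected <- c(pearson(ds$values["G01", cols], ds$values["G02", cols]),
                pearson(ds$values["G01", cols], ds$values["G03", cols]),
                pearson(ds$values["G02", cols], ds$values["G03", cols]))
  expect_equal(A$upper, expected, tolerance = 1e-12)

  # duplicated profiles give correlation 1
  ds$values["G02", ] <- ds$values["G01", ]
  A2 <- complex_correlation_matrix(ds, mc, "case", "1")
  expect_equal(A2$upper[1], 1.0)
})

test_that("equicorrelated blocks recover the planted rho at 500 samples", {
  rho <- matrix(0.7, 2, 1, dimnames = list(c("case", "control"), "1"))
  cfg <- simulation_config(list(complex_spec("EQ", 6, rho)),
                           n_background_genes = 0, timepoints = "1",
                           samples_per_cell = 500, seed = 63)
  ds <- simulate_dataset(cfg)
  A <- complex_correlation_matrix(ds, planted_complex("EQ", 6), "case", "1")
  expect_lt(abs(average_upper(A) - 0.7), 0.05)
})

test_that("average_upper is the arithmetic mean of the upper entries", {
  expect_equal(average_upper(cm_from_upper(c(0.2, 0.4, 0.6))), 0.4)
  expect_equal(average_upper(cm_from_upper(rep(0.3, 10))), 0.3)
  set.seed(65)
  u <- runif(15, -1, 1)
  expect_equal(average_upper(cm_from_upper(u)), sum(u) / length(u),
               tolerance = 1e-12)
})

test_that("paired t matches the textbook computation on random matrix pairs", {
  set.seed(67)
  for (k in 1:1000) {
    n <- sample(3:8, 1)
    N <- n * (n - 1) / 2
    A <- cm_from_upper(runif(N, -1, 1))
    B <- cm_from_upper(runif(N, -1, 1))
    got <- paired_t_statistic(A, B)
    D <- A$upper - B$upper
    t_ref <- mean(D) / (stats::sd(D) / sqrt(N))
    expect_equal(got$t, t_ref, tolerance = 1e-10)
    ref <- stats::t.test(A$upper, B$upper, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("worked paired-t values and degenerate spreads behave as specified", {
  A <- cm_from_upper(c(0.1, 0.2, 0.3))
  B <- cm_from_upper(c(0, 0, 0))
  got <- paired_t_statistic(A, B)
  expect_equal(got$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(got$t, 4), 3.4641)

  # symmetric differences give t = 0 (fabricated 2-pair object)
  A2 <- structure(list(complex_name = "S", genes = c("a", "b"),
                       upper = c(1, -1) / 2), class = "correlation_matrix")
  B2 <- structure(list(complex_name = "S", genes = c("a", "b"),
                       upper = c(0, 0)), class = "correlation_matrix")
  expect_equal(paired_t_statistic(A2, B2)$t, 0)

  # identical matrices: no change, p = 1, code 0
  same <- paired_t_statistic(A, A)
  expect_equal(same$p, 1)
  expect_identical(significance_code(A, A), 0L)

  # identical nonzero differences: zero spread but a real shift
  C <- cm_from_upper(c(0.5, 0.6, 0.7))
  Cs <- cm_from_upper(c(0.3, 0.4, 0.5))
  expect_warning(deg <- paired_t_statistic(C, Cs), "zero spread")
  expect_equal(deg$p, 0)
})

test_that("significance codes carry the sign of the average change", {
  # large planted shift: +1, and antisymmetric under swapping the groups
  set.seed(69)
  N <- 45
  A <- cm_from_upper(pmin(1, runif(N, 0.5, 0.9)))
  B <- cm_from_upper(runif(N, -0.1, 0.1))
  expect_identical(significance_code(A, B), 1L)
  expect_identical(significance_code(B, A), -1L)
  expect_identical(significance_code(A, B), -significance_code(B, A))
})

test_that("matrix distance matches hand values and a double-loop oracle", {
  A <- cm_from_upper(c(0.5, 0.1, -0.2))
  expect_equal(matrix_distance(A, A), 0)

  B <- cm_from_upper(A$upper - 0.4)
  expect_equal(matrix_distance(A, B), 0.4, tolerance = 1e-12)

  C <- cm_from_upper(A$upper - c(0.3, 0, 0))
  expect_equal(matrix_distance(A, C), sqrt(0.09 / 3), tolerance = 1e-12)
  expect_equal(round(matrix_distance(A, C), 6), 0.173205)

  naive_d <- function(A, B) {
    MA <- upper_to_matrix(A$genes, A$upper)
    MB <- upper_to_matrix(B$genes, B$upper)
    n <- length(A$genes)
    acc <- 0; N <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      acc <- acc + (MA[i, j] - MB[i, j])^2
      N <- N + 1
    }
    sqrt(acc / N)
  }
  set.seed(71)
  for (k in 1:200) {
    n <- sample(3:10, 1)
    N <- n * (n - 1) / 2
    X <- cm_from_upper(runif(N, -1, 1))
    Y <- cm_from_upper(runif(N, -1, 1))
    expect_equal(matrix_distance(X, Y), naive_d(X, Y), tolerance = 1e-12)
    expect_equal(matrix_distance(X, Y), matrix_distance(Y, X), tolerance = 1e-15)
  }

  Z <- correlation_matrix("other", "case", "1", c("x1", "x2", "x3"), A$upper)
  expect_error(matrix_distance(A, Z), "mismatched gene order")
})

test_that("random-complex nulls are deterministic and degenerate on equal groups", {
  ds <- tiny_dataset(n_genes = 12, samples_per_cell = 5, timepoints = "1", seed = 73)
  # make control columns copies of case columns: every distance is 0
  case_cols <- which(ds$samples$group == "case")
  ctrl_cols <- which(ds$samples$group == "control")
  ds$values[, ctrl_cols] <- ds$values[, case_cols]
  nl <- build_null(ds, size = 4, timepoint = "1", n_random = 2, seed = 3)
  expect_equal(nl$mean_d, 0)
  expect_equal(nl$sd_d, 0)

  ds2 <- tiny_dataset(n_genes = 12, samples_per_cell = 5, timepoints = "1", seed = 74)
  n1 <- build_null(ds2, size = 4, timepoint = "1", n_random = 50, seed = 7)
  n2 <- build_null(ds2, size = 4, timepoint = "1", n_random = 50, seed = 7)
  expect_identical(n1$distances, n2$distances)
  expect_error(build_null(ds2, size = 12, timepoint = "1"), "universe")
})

test_that("z-scores are standardized distances with a degenerate-null guard", {
  nl <- structure(list(mean_d = 0.2, sd_d = 0.05), class = "null_distribution")
  expect_equal(z_score(0.2, nl), 0)
  expect_equal(z_score(0.25, nl), 1.0)
  expect_true(significant_z(z_score(0.35, nl)))
  expect_false(significant_z(z_score(0.25, nl)))
  nl0 <- structure(list(mean_d = 0.2, sd_d = 0), class = "null_distribution")
  expect_error(z_score(0.3, nl0), "degenerate null")
})

test_that("difference matrices subtract entrywise and are antisymmetric", {
  set.seed(75)
  A <- cm_from_upper(runif(10, -1, 1))
  B <- cm_from_upper(runif(10, -1, 1))
  D <- difference_matrix(A, B)
  expect_equal(D$upper, A$upper - B$upper, tolerance = 1e-15)
  D0 <- difference_matrix(A, A)
  expect_true(all(D0$upper == 0))
  Drev <- difference_matrix(B, A)
  expect_equal(D$upper, -Drev$upper, tolerance = 1e-15)
})

test_that("gene decorrelation ranking agrees with a brute-force scan", {
  set.seed(77)
  A <- cm_from_upper(runif(15, -1, 1))
  B <- cm_from_upper(runif(15, -1, 1))
  D <- difference_matrix(A, B)
  rk <- rank_gene_decorrelation(D)

  M <- upper_to_matrix(D$genes, D$upper, diag = NA)
  brute <- sapply(D$genes, function(g) mean(M[g, D$genes != g]))
  expect_equal(stats::setNames(rk$mean_difference, rk$gene),
               brute[order(brute, names(brute))], tolerance = 1e-12)
  expect_false(is.unsorted(rk$mean_difference))

  # all-zero differences: lexicographic order
  Dz <- difference_matrix(A, A)
  rkz <- rank_gene_decorrelation(Dz)
  expect_identical(rkz$gene, sort(D$genes))
  expect_true(all(rkz$mean_difference == 0))
})

test_that("a planted case-only anti-member ranks first", {
  rho <- matrix(0.6, 2, 1, dimnames = list(c("case", "control"), "1"))
  cfg <- simulation_config(
    list(complex_spec("AM", 6, rho, anti_member = 4, rho_anti = 0.6,
                      anti_groups = "case")),
    n_background_genes = 0, timepoints = "1", samples_per_cell = 50, seed = 79)
  ds <- simulate_dataset(cfg)
  mc <- planted_complex("AM", 6)
  A <- complex_correlation_matrix(ds, mc, "case", "1")
  B <- complex_correlation_matrix(ds, mc, "control", "1")
  rk <- rank_gene_decorrelation(difference_matrix(A, B))
  expect_identical(rk$gene[1], "AM_g04")
})

test_that("correlation value distributions pool by size class and conserve counts", {
  small <- cm_from_upper(c(0.15, 0.25, 0.35))           # 3 genes
  large <- cm_from_upper(rep(0.05, 11 * 10 / 2))        # 11 genes
  dist1 <- correlation_value_distribution(list(small))
  expect_equal(sum(dist1$small$counts), 3)
  expect_equal(sum(dist1$large$counts), 0)

  both <- correlation_value_distribution(list(small, large))
  expect_equal(sum(both$small$counts) + sum(both$large$counts),
               length(small$upper) + length(large$upper))
  expect_equal(both$large$mean, 0.05)

  # on null data both class means sit near zero
  cfg <- simulation_config(
    list(complex_spec("SM", 5, 0), complex_spec("LG", 12, 0)),
    n_background_genes = 0, timepoints = "1", samples_per_cell = 15, seed = 81)
  ds <- simulate_dataset(cfg)
  ms <- list(complex_correlation_matrix(ds, planted_complex("SM", 5), "control", "1"),
             complex_correlation_matrix(ds, planted_complex("LG", 12), "control", "1"))
  nulldist <- correlation_value_distribution(ms)
  expect_lt(abs(nulldist$small$mean), 0.2)  # only 10 pairs; loose bound
  expect_lt(abs(nulldist$large$mean), 0.1)
})

test_that("all metrics are invariant to positive rescaling of a gene profile", {
  ds <- tiny_dataset(n_genes = 5, samples_per_cell = 8,
                     timepoints = c("1", "3"), seed = 83)
  mc <- mapped_complex("CX", feature_ids(ds))
  q1 <- quadruplet(ds, mc, alpha = 0.05)
  A1 <- complex_correlation_matrix(ds, mc, "case", "1")
  B1 <- complex_correlation_matrix(ds, mc, "control", "1")

  ds$values["G03", ] <- ds$values["G03", ] * 37.5
  q2 <- quadruplet(ds, mc, alpha = 0.05)
  A2 <- complex_correlation_matrix(ds, mc, "case", "1")
  B2 <- complex_correlation_matrix(ds, mc, "control", "1")
  expect_identical(q1, q2)
  expect_equal(A1$upper, A2$upper, tolerance = 1e-12)
  expect_equal(matrix_distance(A1, B1), matrix_distance(A2, B2), tolerance = 1e-12)
})
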