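# The synthetic cohort generators: depth model expectations, mutation
# matrix marginals and planted interactions, SV truth labels, AID
# generator contracts, survival generator contracts, and determinism.

make_flat_panel <- function(n_probes, probe_count = n_probes) {
  cc <- cohort_config(n_samples = 1, probe_count = probe_count, seed = 1)
  make_panel(cc, panel_spec(n_genes = 4, chromosomes = "chr1"))
}

test_that("depth ratios converge to purity * cn/2 + (1 - purity)", {
  n <- 20000
  cc <- cohort_config(n_samples = 1, mean_depth_tumor = 100,
                      mean_depth_normal = 100, depth_dispersion = 1e-4,
                      purity = 1, probe_count = n, seed = 3)
  panel <- make_panel(cc, panel_spec(n_genes = 4, chromosomes = "chr1"))
  truth <- tibble::tibble(sample_id = "S001", chrom = "chr1",
                          start = min(panel$start), end = max(panel$end),
                          cn = 3L)
  d <- simulate_depths(panel, truth, cc)
  ratio <- mean(d$tumor$depth) / mean(d$normal$depth)
  expect_lt(abs(ratio - 1.5), 0.015)

  # purity 0.6: expected ratio 0.6 * 1.5 + 0.4 = 1.3, within 1%
  cc6 <- cohort_config(n_samples = 1, mean_depth_tumor = 100,
                       mean_depth_normal = 100, depth_dispersion = 1e-4,
                       purity = 0.6, probe_count = n, seed = 4)
  d6 <- simulate_depths(panel, truth, cc6)
  expect_lt(abs(mean(d6$tumor$depth) / mean(d6$normal$depth) - 1.3),
            0.013)

  # no events: genome-wide mean ratio ~ 1
  d0 <- simulate_depths(panel, truth[0, ], cc)
  expect_lt(abs(mean(d0$tumor$depth) / mean(d0$normal$depth) - 1), 0.01)
})

test_that("depth simulation validates truth events", {
  cc <- cohort_config(n_samples = 1, probe_count = 100, seed = 1)
  panel <- make_panel(cc, panel_spec(n_genes = 4, chromosomes = "chr1"))
  off_panel <- tibble::tibble(sample_id = "S001", chrom = "chr9",
                              start = 0, end = 1e6, cn = 3L)
  expect_error(simulate_depths(panel, off_panel, cc), "outside the panel")
  neutral <- tibble::tibble(sample_id = "S001", chrom = "chr1",
                            start = min(panel$start), end = max(panel$end),
                            cn = 2L)
  expect_error(simulate_depths(panel, neutral, cc), "no-ops")
})

test_that("generators are deterministic given (config, seed)", {
  cc <- cohort_config(n_samples = 3, probe_count = 300, seed = 17)
  panel <- make_panel(cc, panel_spec(n_genes = 6, chromosomes = c("chr1", "chr3")))
  truth <- simulate_cnv_truth(panel, cc)
  expect_identical(truth, simulate_cnv_truth(panel, cc))
  expect_identical(simulate_depths(panel, truth, cc),
                   simulate_depths(panel, truth, cc))
  sv1 <- simulate_sv_candidates(10, 10, seed = 5)
  sv2 <- simulate_sv_candidates(10, 10, seed = 5)
  expect_identical(sv1, sv2)
  expect_false(identical(sv1, simulate_sv_candidates(10, 10, seed = 6)))
  m1 <- simulate_mutation_matrix(c(A = 0.2, B = 0.3), n_samples = 50, seed = 2)
  expect_identical(m1, simulate_mutation_matrix(c(A = 0.2, B = 0.3),
                                                n_samples = 50, seed = 2))
  a1 <- simulate_aid_sequence(2000, n_mutations = 10, seed = 9)
  expect_identical(a1, simulate_aid_sequence(2000, n_mutations = 10, seed = 9))
})

test_that("mutation matrix matches requested marginals and log-odds", {
  n <- 10000
  inter <- tibble::tibble(feature_a = "A", feature_b = "B", log_odds = 0)
  m <- simulate_mutation_matrix(c(A = 0.2, B = 0.45, C = 0.1),
                                interactions = inter, n_samples = n, seed = 8)
  for (f in c("A", "B", "C")) {
    p <- c(A = 0.2, B = 0.45, C = 0.1)[[f]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(m[[f]]) - p), 3 * se)
  }
  # empirical odds ratio ~ 1 under log-odds 0
  a <- sum(m$A == 1 & m$B == 1); b <- sum(m$A == 1 & m$B == 0)
  c_ <- sum(m$A == 0 & m$B == 1); d <- sum(m$A == 0 & m$B == 0)
  expect_lt(abs(log((a * d) / (b * c_))), 0.2)
})

test_that("hard exclusivity and infeasible interactions behave as specified", {
  inter <- tibble::tibble(feature_a = "A", feature_b = "B", log_odds = -Inf)
  m <- simulate_mutation_matrix(c(A = 0.2, B = 0.2), interactions = inter,
                                n_samples = 5000, seed = 3)
  expect_equal(sum(m$A == 1 & m$B == 1), 0)

  dup <- tibble::tibble(feature_a = c("A", "A"), feature_b = c("B", "C"),
                        log_odds = c(1, 1))
  expect_error(
    simulate_mutation_matrix(c(A = 0.2, B = 0.2, C = 0.2),
                             interactions = dup, n_samples = 10),
    "at most one interaction"
  )
  expect_error(simulate_mutation_matrix(c(A = 0, B = 0.5), n_samples = 10),
               "in \\(0, 1\\)")
})

test_that("SV truth labels follow the candidate classes", {
  sim0 <- simulate_sv_candidates(n_true = 0, n_artifact = 30, seed = 2)
  expect_true(all(!sim0$truth$is_true))

  sim <- simulate_sv_candidates(n_true = 25, n_artifact = 25,
                                include_normals = TRUE, seed = 2)
  expect_true(all(!is.na(sim$truth$class[sim$truth$is_true])))
  expect_true(all(is.na(sim$truth$class[!sim$truth$is_true])))
  expect_true(all(!sim$candidates$is_true[sim$candidates$is_normal]))
  # canonical breakpoint order
  cand <- sim$candidates
  rank_a <- mmcap:::chrom_rank(cand$chrom_a)
  rank_b <- mmcap:::chrom_rank(cand$chrom_b)
  expect_true(all(rank_a < rank_b |
                    (rank_a == rank_b & cand$pos_a <= cand$pos_b)))
})

test_that("AID generator honours aid_fraction at the motif level", {
  all_aid <- simulate_aid_sequence(5000, target_wrcy_density = 0.01,
                                   n_mutations = 30, aid_fraction = 1,
                                   seed = 4)
  sites <- find_motif_sites(all_aid$sequence)
  expect_true(all(all_aid$variants$pos %in% sites$pos))
  expect_true(all(all_aid$variants$ref %in% c("C", "G")))

  no_aid <- simulate_aid_sequence(5000, target_wrcy_density = 0.01,
                                  n_mutations = 30, aid_fraction = 0,
                                  seed = 4)
  sites0 <- find_motif_sites(no_aid$sequence)
  expect_equal(sum(no_aid$variants$pos %in% sites0$pos), 0)

  expect_error(
    simulate_aid_sequence(200, target_wrcy_density = 0.005,
                          n_mutations = 150, aid_fraction = 1, seed = 1),
    "exceeds available"
  )
})

test_that("survival generator respects censoring and rate contracts", {
  m <- simulate_mutation_matrix(c(IGLL5 = 0.18), n_samples = 200, seed = 5)
  s0 <- simulate_survival(m, "IGLL5", hazard_ratio = 1.46,
                          baseline_rate = 0.1, censor_rate = 0, seed = 6)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time > 0))
  expect_setequal(unique(s0$group[m$IGLL5 == 1]), "mutant")
  expect_error(
    simulate_survival(m, "IGLL5", baseline_rate = -1, seed = 1),
    "> 0"
  )
})
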