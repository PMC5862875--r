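# Threshold tuning (lexicographic precision-first grid search), filter
# application monotonicity, the panel-of-normals guarantee, candidate
# classification, and breakpoint annotation.

cand_tbl <- function(sr, pe, is_true = NULL, is_normal = FALSE) {
  tibble::tibble(
    candidate_id = sprintf("sv%03d", seq_along(sr)),
    chrom_a = "chr1", pos_a = seq_along(sr) * 1000, strand_a = "+",
    chrom_b = "chr2", pos_b = seq_along(sr) * 2000, strand_b = "+",
    sr = as.integer(sr), pe = as.integer(pe),
    sample_id = "S001",
    is_normal = rep_len(is_normal, length(sr)),
    is_true = rep_len(is_true %||% FALSE, length(sr))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the worked tuning instance reaches its known optimum minimally", {
  cand <- cand_tbl(sr = c(5, 3, 1, 0, 2), pe = c(6, 4, 0, 2, 1),
                   is_true = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  th <- tune_thresholds(cand)
  expect_equal(th$achieved_precision, 1)
  expect_equal(th$achieved_recall, 1)
  expect_equal(c(th$min_sr, th$min_pe, th$min_total), c(3L, 0L, 0L))
})

test_that("inseparable support gives precision 0.5 at full recall", {
  cand <- cand_tbl(sr = c(2, 2), pe = c(2, 2), is_true = c(TRUE, FALSE))
  th <- tune_thresholds(cand)
  expect_equal(th$achieved_precision, 0.5)
  expect_equal(th$achieved_recall, 1)
})

test_that("single-class truth is rejected with guidance", {
  cand <- cand_tbl(sr = 1:3, pe = 1:3, is_true = TRUE)
  expect_error(tune_thresholds(cand), "apply_thresholds")
})

test_that("tuner matches the brute-force oracle on random instances", {
  withr::with_seed(51, {
    for (i in 1:30) {
      n_t <- sample(3:20, 1); n_f <- sample(3:20, 1)
      cand <- cand_tbl(
        sr = c(rpois(n_t, 8), rpois(n_f, 2)),
        pe = c(rpois(n_t, 8), rpois(n_f, 2)),
        is_true = rep(c(TRUE, FALSE), c(n_t, n_f))
      )
      th <- tune_thresholds(cand)
      oracle <- oracle_tune(cand$sr, cand$pe, cand$is_true)
      expect_equal(th$achieved_precision, oracle$precision)
      expect_equal(th$achieved_recall, oracle$recall)
      expect_true(oracle_is_minimal(
        c(th$min_sr, th$min_pe, th$min_total), oracle$optima
      ))
    }
  })
})

test_that("apply_thresholds follows the rule and is monotone", {
  cand <- cand_tbl(sr = c(3, 2), pe = c(4, 4))
  expect_equal(nrow(apply_thresholds(cand, list(min_sr = 0, min_pe = 0,
                                                min_total = 0))), 2)
  kept <- apply_thresholds(cand, list(min_sr = 3, min_pe = 4, min_total = 0))
  expect_equal(kept$candidate_id, "sv001")

  withr::with_seed(52, {
    for (i in 1:100) {
      cand <- cand_tbl(sr = rpois(20, 4), pe = rpois(20, 4))
      t1 <- as.integer(c(sample(0:4, 1), sample(0:4, 1), sample(0:8, 1)))
      t2 <- t1 + sample(0:2, 3, replace = TRUE)
      r1 <- apply_thresholds(cand, list(min_sr = t1[1], min_pe = t1[2],
                                        min_total = t1[3]))
      r2 <- apply_thresholds(cand, list(min_sr = t2[1], min_pe = t2[2],
                                        min_total = t2[3]))
      expect_true(all(r2$candidate_id %in% r1$candidate_id))
    }
  })
})

test_that("normal-panel tuning always excludes every normal candidate", {
  withr::with_seed(53, {
    for (i in 1:50) {
      n_n <- sample(2:30, 1); n_t <- sample(2:30, 1)
      cand <- dplyr::bind_rows(
        cand_tbl(rpois(n_n, sample(1:6, 1)), rpois(n_n, sample(1:6, 1)),
                 is_normal = TRUE),
        cand_tbl(rpois(n_t, 20), rpois(n_t, 20), is_normal = FALSE)
      )
      th <- tune_normal_panel(cand)
      normals <- cand[cand$is_normal, ]
      expect_equal(nrow(apply_thresholds(normals, th)), 0)
    }
  })
})

test_that("normal-panel thresholds are minimal and keep strong tumor calls", {
  # normals max out at (sr=2, pe=3) but never jointly high
  cand <- dplyr::bind_rows(
    cand_tbl(sr = c(2, 0, 1), pe = c(0, 3, 1), is_normal = TRUE),
    cand_tbl(sr = 20, pe = 20, is_normal = FALSE)
  )
  th <- tune_normal_panel(cand)
  expect_equal(nrow(apply_thresholds(cand[cand$is_normal, ], th)), 0)
  expect_equal(nrow(apply_thresholds(cand[!cand$is_normal, ], th)), 1)
  # componentwise minimality: no smaller triple also excludes all normals
  tr <- c(th$min_sr, th$min_pe, th$min_total)
  for (j in 1:3) {
    if (tr[j] == 0) next
    smaller <- as.list(setNames(tr, c("min_sr", "min_pe", "min_total")))
    smaller[[j]] <- smaller[[j]] - 1L
    expect_gt(nrow(apply_thresholds(cand[cand$is_normal, ], smaller)), 0)
  }

  expect_warning(th0 <- tune_normal_panel(cand_tbl(1, 1, is_normal = FALSE)),
                 "no normal-sample candidates")
  expect_equal(c(th0$min_sr, th0$min_pe, th0$min_total), c(0L, 0L, 0L))
})

test_that("candidates are classified by breakpoint regions", {
  rt <- default_region_table()
  igh_pos <- mean(c(rt$start[rt$label == "IGH"], rt$end[rt$label == "IGH"]))
  at <- function(label) {
    r <- rt[rt$label == label, ]
    mean(c(r$start, r$end))
  }
  cand <- tibble::tibble(
    candidate_id = sprintf("sv%03d", 1:6),
    chrom_a = c("chr11", "chr14", "chr14", "chr8", "chr3", "chr8"),
    pos_a = c(at("t(11;14)"), igh_pos, igh_pos, at("MYC") - 2e6,
              5e7, at("MYC")),
    chrom_b = c("chr14", "chr22", "chr4", "chr8", "chr7", "chr12"),
    pos_b = c(igh_pos, at("t(14;22)"), at("t(4;14)"), at("MYC"), 6e7, 9e7)
  )
  out <- classify_translocation(cand, rt)
  expect_equal(as.character(out$class),
               c("t(11;14)", "t(14;22)", "t(4;14)", "MYC-ITX", "other",
                 "MYC-CTX"))

  # short intra-chromosomal MYC separation is local noise, not MYC-ITX
  near <- tibble::tibble(candidate_id = "sv900", chrom_a = "chr8",
                         pos_a = at("MYC"), chrom_b = "chr8",
                         pos_b = at("MYC") + 5e4)
  expect_equal(as.character(classify_translocation(near, rt)$class), "other")
})

test_that("breakpoint annotation honours the 1 Mb window and distance sort", {
  cand <- tibble::tibble(candidate_id = "sv001", chrom_a = "chr13",
                         pos_a = 1e7, chrom_b = "chr14", pos_b = 2e7)
  genes <- tibble::tibble(
    chrom = c("chr13", "chr13", "chr13"),
    start = c(1.04e7, 1.12e7, 9.99e6),
    end = c(1.05e7, 1.13e7, 1.001e7),
    gene = c("FLT3", "FARAWAY", "INSIDE")
  )
  ann <- annotate_breakpoints(cand, genes)
  expect_equal(ann$gene, c("INSIDE", "FLT3")) # 1.2 Mb gene excluded
  expect_equal(ann$distance[1], 0)
  expect_equal(ann$distance[2], 4e5)

  empty <- annotate_breakpoints(cand, genes[0, ])
  expect_equal(nrow(empty), 0)
})
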