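# Variant filtering rules, run-to-run matching, VAF concordance,
# binomial thinning, the yield curve, and the diploid-locus clonality
# summary.

variant_tbl <- function(n, effect = "missense", in_igh = FALSE,
                        germline = FALSE, vaf = 0.4, depth = 100,
                        sample_id = "S001", chrom = "chr1",
                        pos = seq_len(n) * 100, gene = "GENE") {
  n_alt <- round(vaf * depth)
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = pos,
    ref = "A", alt = "T", gene = gene,
    effect = rep_len(effect, n), ref_count = depth - n_alt,
    alt_count = n_alt, vaf = n_alt / depth, caller_flags = "mutect",
    germline_flagged = rep_len(germline, n), in_igh = rep_len(in_igh, n),
    cosmic_annotated = FALSE, deleterious_predicted = TRUE
  )
}

test_that("filtering drops each rule with a recorded reason", {
  calls <- dplyr::bind_rows(
    variant_tbl(7, pos = 1:7 * 100),
    variant_tbl(1, effect = "silent", pos = 800),
    variant_tbl(1, in_igh = TRUE, pos = 900),
    variant_tbl(1, germline = TRUE, pos = 1000)
  )
  kept <- filter_variants(calls)
  expect_equal(nrow(kept), 7)
  log <- variant_drop_log(kept)
  expect_equal(sort(log$drop_reason), c("germline", "igh", "silent"))

  # idempotence
  again <- filter_variants(kept)
  expect_equal(nrow(again), 7)
  expect_equal(nrow(variant_drop_log(again)), 0)
  expect_equal(as.data.frame(again), as.data.frame(kept),
               ignore_attr = TRUE)
})

test_that("matching partitions exactly on the five-field key", {
  a <- variant_tbl(5)
  m_same <- match_variants(a, a)
  expect_equal(nrow(m_same$shared), 5)
  expect_equal(nrow(m_same$unique_a), 0)

  b <- variant_tbl(5, pos = 5000 + 1:5 * 100)
  m_disj <- match_variants(a, b)
  expect_equal(nrow(m_disj$shared), 0)
  expect_equal(nrow(m_disj$unique_a) + nrow(m_disj$unique_b), 10)

  # multi-allelic: same position, different alt are distinct variants
  c1 <- variant_tbl(1, pos = 100)
  c2 <- dplyr::mutate(c1, alt = "G")
  m_multi <- match_variants(c1, c2)
  expect_equal(nrow(m_multi$shared), 0)

  # partition sizes always add up
  m <- match_variants(a, dplyr::bind_rows(a[1:2, ], b))
  expect_equal(nrow(m$shared) + nrow(m$unique_a), nrow(a))
})

test_that("VAF concordance reports R^2 and unique-call tallies", {
  a <- variant_tbl(5, vaf = 0.4)
  a$vaf <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- vaf_concordance(match_variants(a, a))
  expect_equal(same$r_squared, 1)

  # perfectly linear but non-identical VAFs
  b <- a
  b$vaf <- a$vaf / 2
  lin <- vaf_concordance(match_variants(a, b))
  expect_equal(lin$r_squared, 1)

  few <- vaf_concordance(match_variants(a[1:2, ], a[1:2, ]))
  expect_true(is.na(few$r_squared))

  uniq <- vaf_concordance(match_variants(a, a[1:3, ]))
  expect_equal(uniq$n_unique_a, 2)
  expect_equal(uniq$max_alt_count_unique_a, 40)
})

test_that("thinning is identity at 1, zero at 0, unbiased in between", {
  calls <- variant_tbl(1, depth = 1000, vaf = 0.4) # alt = 400
  expect_identical(downsample_counts(calls, 1), calls)
  zero <- downsample_counts(calls, 0, seed = 1)
  expect_equal(zero$alt_count + zero$ref_count, 0)
  expect_true(is.na(zero$vaf))

  thinned <- purrr::map_dbl(1:500, function(s) {
    downsample_counts(calls, 0.25, seed = s)$alt_count
  })
  se <- sqrt(400 * 0.25 * 0.75 / 500)
  expect_lt(abs(mean(thinned) - 100), 3 * se)
})

test_that("yield curve detects saturation for high-VAF deep calls only", {
  withr::with_seed(61, {
    deep <- variant_tbl(60, depth = 1200, vaf = 0.35,
                        pos = 1:60 * 50)
    curve <- yield_curve(deep, fractions = seq(0.1, 1, 0.1), seed = 2)
    expect_equal(curve$n_detected[10],
                 sum(deep$alt_count >= 4 & deep$vaf >= 0.05))
    expect_true(all(diff(curve$n_detected) >= 0 - 3)) # monotone up to noise
    expect_lt(attr(curve, "plateau_fraction"), 0.5)

    # a low-VAF spectrum keeps yielding with depth: no early plateau
    low <- variant_tbl(80, depth = 1200, vaf = 0.012, pos = 1:80 * 50)
    curve_low <- yield_curve(low, fractions = seq(0.1, 1, 0.1),
                             min_alt = 4, min_vaf = 0.005, seed = 3)
    p <- attr(curve_low, "plateau_fraction")
    expect_true(is.na(p) || p >= 0.5)
    expect_gt(curve_low$n_detected[10], curve_low$n_detected[2])
  })
})

test_that("clonality summary uses diploid loci and interpolated quantiles", {
  calls <- variant_tbl(4, gene = "IGLL5", pos = c(100, 200, 300, 400))
  calls$vaf <- c(0.39, 0.5, 0.58, 0.6)
  calls$alt_count <- round(calls$vaf * 100)
  calls$ref_count <- 100 - calls$alt_count

  res <- summarize_clonality(calls, cnv_calls = NULL)
  expect_equal(res$vaf_q1, 0.39 + 0.75 * (0.5 - 0.39)) # type-7 interpolation
  expect_equal(res$vaf_median, 0.54)

  single <- summarize_clonality(variant_tbl(1, vaf = 0.5), NULL)
  expect_equal(single$vaf_median, 0.5)

  # a variant inside a called deletion is excluded
  cnv <- tibble::tibble(sample_id = "S001", chrom = "chr1", start = 0,
                        end = 250, state = "loss")
  res_del <- summarize_clonality(calls, cnv)
  expect_equal(res_del$n, 2) # pos 100 and 200 fall in [0, 250)
})
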