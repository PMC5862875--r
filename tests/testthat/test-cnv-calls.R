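# Noise-band filtering, state assignment cut-points, arm-event coverage
# arithmetic, and hyperdiploidy scoring.

make_test_segments <- function(means, n_probes = 100, arm = "1p",
                               arm_n = 400) {
  k <- length(means)
  tibble::tibble(
    sample_id = "S001", chrom = "chr1", arm = arm,
    start = (seq_len(k) - 1) * 1e6, end = seq_len(k) * 1e6,
    first_probe = sprintf("p%d", seq_len(k)),
    last_probe = sprintf("p%d", seq_len(k)),
    n_probes = rep(n_probes, k)[seq_len(k)], mean_lr = means,
    arm_n_probes = arm_n
  )
}

test_that("segments inside the noise band stay neutral; landmarks get states", {
  noise <- make_test_noise(0, 0.1) # band +/- 0.196
  seg <- make_test_segments(c(0.02, 0.58, -1.0, -1.7, 1.2))
  calls <- filter_segments(seg, noise)
  expect_equal(as.character(calls$state),
               c("neutral", "gain", "loss", "homozygous_loss",
                 "amplification"))
  # closed-form tail: mean 0.58, se = 0.1/sqrt(100) => p ~ 2*pnorm(-58)
  expect_lt(calls$p_value[2], 1e-10)
  expect_equal(calls$p_value[1], 2 * pnorm(-0.02 / (0.1 / sqrt(100))))
})

test_that("a significant mean inside the band is still neutral", {
  noise <- make_test_noise(0, 0.1)
  seg <- make_test_segments(0.15, n_probes = 10000)
  calls <- filter_segments(seg, noise)
  expect_lt(calls$p_value[1], 1e-6) # tiny tail probability...
  expect_equal(as.character(calls$state), "neutral") # ...but sub-noise
})

test_that("retained calls are monotone in alpha", {
  withr::with_seed(41, {
    noise <- make_test_noise(0, 0.1)
    for (rep in 1:20) {
      seg <- make_test_segments(runif(8, -0.6, 0.6),
                                n_probes = sample(10:60, 8, replace = TRUE))
      lo <- filter_segments(seg, noise, alpha = 0.01)
      hi <- filter_segments(seg, noise, alpha = 0.10)
      kept_lo <- which(lo$state != "neutral")
      kept_hi <- which(hi$state != "neutral")
      expect_true(all(kept_lo %in% kept_hi))
    }
  })
})

test_that("arm events need min_arm_fraction coverage by same-sign segments", {
  noise <- make_test_noise(0, 0.05)
  # whole-arm gain: one segment covering all 400 arm probes
  whole <- make_test_segments(0.6, n_probes = 400)
  ev <- call_arm_events(filter_segments(whole, noise))
  expect_equal(ev$status, "gain")

  # focal 5% deletion: no arm event
  focal <- make_test_segments(c(-1, 0), n_probes = c(20, 380))
  ev2 <- call_arm_events(filter_segments(focal, noise))
  expect_equal(ev2$status, "none")
  expect_equal(ev2$loss_fraction, 0.05)

  # two same-sign segments jointly covering 70%
  joint <- make_test_segments(c(0.6, 0, 0.62), n_probes = c(160, 120, 120))
  ev3 <- call_arm_events(filter_segments(joint, noise))
  expect_equal(ev3$gain_fraction, 0.7)
  expect_equal(ev3$status, "gain")
})

test_that("hyperdiploidy scores whole-chromosome gains of odd chromosomes", {
  arms <- function(chroms, status) {
    purrr::map_dfr(chroms, function(ch) {
      tibble::tibble(sample_id = "S001", chrom = paste0("chr", ch),
                     arm = paste0(ch, c("p", "q")),
                     gain_fraction = 1, loss_fraction = 0,
                     status = status)
    })
  }
  three_gains <- dplyr::bind_rows(arms(c(3, 5, 9), "gain"),
                                  arms(c(2, 7), "none"))
  hrd <- detect_hyperdiploidy(three_gains)
  expect_equal(hrd$hrd_score, 3)
  expect_true(hrd$hyperdiploid)

  none <- arms(c(3, 5, 7), "none")
  hrd0 <- detect_hyperdiploidy(none)
  expect_equal(hrd0$hrd_score, 0)
  expect_false(hrd0$hyperdiploid)

  one <- dplyr::bind_rows(arms(3, "gain"), arms(c(5, 7), "none"))
  hrd1 <- detect_hyperdiploidy(one)
  expect_equal(hrd1$hrd_score, 1)
  expect_false(hrd1$hyperdiploid)

  # acrocentric: only a q arm defined; its gain counts as whole-chromosome
  acro <- tibble::tibble(sample_id = "S001", chrom = "chr15", arm = "15q",
                         gain_fraction = 1, loss_fraction = 0,
                         status = "gain")
  hrd15 <- detect_hyperdiploidy(dplyr::bind_rows(acro, arms(3, "gain")))
  expect_equal(hrd15$hrd_score, 2)
  expect_true(hrd15$hyperdiploid)

  # even-chromosome gains never contribute
  even <- arms(c(2, 4, 6, 8), "gain")
  expect_equal(nrow(detect_hyperdiploidy(even)), 0)
})
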