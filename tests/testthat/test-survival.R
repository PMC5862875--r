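# Kaplan-Meier, log-rank, and the binary-covariate Cox fit, against hand
# calculations, a grid-search partial-likelihood oracle, a permutation
# null, and the survival package as an external cross-check.

surv_tbl <- function(time, event, group) {
  tibble::tibble(sample_id = sprintf("P%02d", seq_along(time)),
                 time = time, event = event, group = group)
}

test_that("KM with no censoring equals the empirical survival function", {
  km <- km_curve(surv_tbl(c(1, 2, 3), c(1, 1, 1), "all"))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  cens <- km_curve(surv_tbl(c(1, 2, 3), c(0, 0, 0), "all"))
  expect_true(all(cens$survival == 1))
})

test_that("KM matches the hand-computed product over risk sets", {
  # times 1e, 2c, 3e, 3e, 4c, 5e  (e = event, c = censored)
  rec <- surv_tbl(c(1, 2, 3, 3, 4, 5), c(1, 0, 1, 1, 0, 1), "all")
  km <- km_curve(rec)
  # S(1) = 5/6; S(3) = 5/6 * (1 - 2/4) = 5/12; S(5) = 5/12 * 0 = 0
  expect_equal(km$survival[km$time == 1], 5 / 6)
  expect_equal(km$survival[km$time == 3], 5 / 12)
  expect_equal(km$survival[km$time == 5], 0)
})

test_that("log-rank is null on identical groups and matches survdiff", {
  base <- surv_tbl(c(1, 2, 3, 4), c(1, 1, 0, 1), "a")
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, group = "b"))
  lr <- logrank_test(dup)
  expect_lt(lr$statistic, 1e-12)
  expect_equal(lr$p_value, 1)

  skip_if_not_installed("survival")
  withr::with_seed(91, {
    rec <- surv_tbl(rexp(40, rate = rep(c(0.1, 0.25), each = 20)),
                    rbinom(40, 1, 0.8),
                    rep(c("WT", "mutant"), each = 20))
  })
  lr2 <- logrank_test(rec)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = rec)
  expect_equal(lr2$statistic, sd2$chisq, tolerance = 1e-8)
})

test_that("log-rank p agrees with a permutation oracle on a toy instance", {
  rec <- surv_tbl(c(1, 2, 3, 4, 5, 6, 7, 8), c(1, 1, 1, 0, 1, 1, 0, 1),
                  rep(c("a", "b"), 4))
  obs <- logrank_test(rec)$statistic
  withr::with_seed(92, {
    perm <- replicate(10000, {
      shuffled <- rec
      shuffled$group <- sample(rec$group)
      logrank_test(shuffled)$statistic
    })
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_perm - logrank_test(rec)$p_value), 0.1)
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  rec <- surv_tbl(c(1, 2, 3, 4), c(1, 1, 1, 1),
                  c("mutant", "WT", "mutant", "WT"))
  fit <- cox_hr(rec)
  # independent naive partial log-likelihood over the event times
  x <- as.numeric(rec$group == "mutant")
  pll <- function(b) {
    sum(vapply(which(rec$event == 1), function(i) {
      risk <- rec$time >= rec$time[i]
      b * x[i] - log(sum(exp(b * x[risk])))
    }, numeric(1)))
  }
  b_opt <- stats::optimize(pll, c(-5, 5), maximum = TRUE,
                           tol = 1e-9)$maximum
  expect_lt(abs(fit$log_hr - b_opt), 1e-4)
})

test_that("Cox matches coxph (Breslow ties) and is scale-invariant", {
  skip_if_not_installed("survival")
  withr::with_seed(93, {
    n <- 300
    x <- rbinom(n, 1, 0.3)
    rec <- surv_tbl(rexp(n, 0.1 * 1.8^x), rbinom(n, 1, 0.85),
                    ifelse(x == 1, "mutant", "WT"))
  })
  fit <- cox_hr(rec)
  cp <- survival::coxph(
    survival::Surv(time, event) ~ I(group == "mutant"),
    data = rec, ties = "breslow"
  )
  expect_equal(fit$log_hr, unname(coef(cp)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(vcov(cp)))), tolerance = 1e-6)

  rescaled <- dplyr::mutate(rec, time = time * 365)
  expect_equal(cox_hr(rescaled)$hr, fit$hr, tolerance = 1e-10)
})

test_that("identical event processes give HR near 1 and degenerate groups fail softly", {
  withr::with_seed(94, {
    rec <- surv_tbl(rexp(400, 0.1), 1,
                    rep(c("mutant", "WT"), each = 200))
  })
  fit <- cox_hr(rec)
  expect_lt(abs(fit$log_hr), 0.25)

  one_sided <- surv_tbl(c(1, 2, 3, 4), c(1, 1, 0, 0),
                        c("WT", "WT", "mutant", "mutant"))
  expect_warning(bad <- cox_hr(one_sided), "non-estimable")
  expect_false(bad$estimable)
  expect_true(is.na(glance(bad)$hr))
})

test_that("a strong planted effect is detected with high power", {
  withr::with_seed(95, {
    sig <- purrr::map_lgl(1:20, function(i) {
      x <- rbinom(400, 1, 0.5)
      rec <- surv_tbl(rexp(400, 0.1 * 3^x), 1,
                      ifelse(x == 1, "mutant", "WT"))
      logrank_test(rec)$p_value < 0.05
    })
  })
  expect_gte(mean(sig), 0.95)
})
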