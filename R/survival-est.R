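# Progression analysis: Kaplan-Meier product-limit estimate, two-group
# log-rank test, and a single-binary-covariate Cox proportional-hazards
# fit (Newton iteration on the Breslow partial likelihood). Implemented
# in-repo so the exact-oracle tests apply to the code that ships.

#' Kaplan-Meier product-limit curve
#'
#' Computes the product-limit estimate per group. With no censoring the
#' curve equals the empirical survival function at every event time.
#'
#' @param records Survival tibble: `time` (> 0), `event` (0/1), optional
#'   `group`.
#' @return A tibble of class `mm_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_curve <- function(records) {
  assert_cols(records, c("time", "event"))
  if (any(records$time <= 0)) abort("survival times must be > 0")
  if (!"group" %in% names(records)) records$group <- "all"
  out <- records |>
    group_by(.data$group) |>
    dplyr::group_modify(function(d, g) {
      times <- sort(unique(d$time))
      n_risk <- vapply(times, function(t) sum(d$time >= t), numeric(1))
      n_event <- vapply(times, function(t) sum(d$time == t & d$event == 1),
                        numeric(1))
      n_censor <- vapply(times, function(t) sum(d$time == t & d$event == 0),
                         numeric(1))
      tibble(time = times, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor,
             survival = cumprod(1 - n_event / n_risk))
    }) |>
    ungroup()
  class(out) <- c("mm_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom over the pooled
#' distinct event times. Identical groups give a statistic near 0 and
#' p near 1.
#'
#' @param records Survival tibble: `time`, `event`, `group` (two levels).
#' @return One-row tibble: `statistic`, `df`, `p_value`, plus observed and
#'   expected events per group.
#' @export
logrank_test <- function(records) {
  assert_cols(records, c("time", "event", "group"))
  groups <- sort(unique(as.character(records$group)), method = "radix")
  if (length(groups) != 2) abort("log-rank test needs exactly two groups")
  g1 <- records$group == groups[1]
  event_times <- sort(unique(records$time[records$event == 1]))
  o_minus_e <- 0
  v <- 0
  o1 <- 0; e1 <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(records$time == t & records$event == 1)
    d1 <- sum(records$time == t & records$event == 1 & g1)
    e <- d * n1 / n
    o1 <- o1 + d1; e1 <- e1 + e
    o_minus_e <- o_minus_e + (d1 - e)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  tibble(
    statistic = stat, df = 1L,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    group_1 = groups[1], observed_1 = o1, expected_1 = e1
  )
}

#' Cox proportional-hazards fit for a single binary covariate
#'
#' Maximizes the Breslow partial likelihood by Newton iteration for the
#' indicator `x = 1` of the mutant group, and reports the hazard ratio
#' with a Wald 95% confidence interval. When one group has no events the
#' hazard ratio is unbounded and the fit is reported as non-estimable.
#'
#' @param records Survival tibble: `time`, `event`, `group` (two levels;
#'   a `"mutant"` level is coded `x = 1` by default, otherwise the second
#'   level in C-locale order — or set `mutant` explicitly).
#' @param conf_level Confidence level for the Wald interval.
#' @param mutant Optional group label to code as `x = 1`.
#' @return An object of class `mm_cox`: `log_hr`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `n_event`, `estimable`.
#' @export
cox_hr <- function(records, conf_level = 0.95, mutant = NULL) {
  assert_cols(records, c("time", "event", "group"))
  # radix sort is locale-independent, so the default contrast is stable
  groups <- sort(unique(as.character(records$group)), method = "radix")
  if (length(groups) != 2) abort("cox_hr needs exactly two groups")
  mutant <- mutant %||%
    (if ("mutant" %in% groups) "mutant" else groups[2])
  x <- as.numeric(records$group == mutant)
  time <- records$time
  event <- records$event

  if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0) {
    warn("one group has no events; hazard ratio is non-estimable")
    return(new_mm_cox(NA, NA, NA, NA, NA, length(x), sum(event),
                      conf_level, mutant, estimable = FALSE))
  }

  # Breslow partial likelihood with binary x: at event time j with d_j
  # events, risk set holds n0_j wild-type and n1_j mutant subjects:
  #   l(b) = b * sum_j d1_j - sum_j d_j * log(n0_j + n1_j * exp(b))
  ev_times <- sort(unique(time[event == 1]))
  d <- vapply(ev_times, function(t) sum(time == t & event == 1), numeric(1))
  d1 <- vapply(ev_times, function(t) sum(time == t & event == 1 & x == 1),
               numeric(1))
  n1 <- vapply(ev_times, function(t) sum(time >= t & x == 1), numeric(1))
  n0 <- vapply(ev_times, function(t) sum(time >= t & x == 0), numeric(1))

  b <- 0
  for (it in 1:100) {
    eb <- exp(b)
    frac <- n1 * eb / (n0 + n1 * eb)
    score <- sum(d1) - sum(d * frac)
    info <- sum(d * frac * (1 - frac))
    if (info <= 0) break
    step <- score / info
    b <- b + step
    if (abs(step) < 1e-10) break
  }
  if (!is.finite(b) || abs(b) > 15) {
    warn("Cox fit diverged; hazard ratio is non-estimable")
    return(new_mm_cox(NA, NA, NA, NA, NA, length(x), sum(event),
                      conf_level, mutant, estimable = FALSE))
  }
  eb <- exp(b)
  frac <- n1 * eb / (n0 + n1 * eb)
  se <- 1 / sqrt(sum(d * frac * (1 - frac)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_mm_cox(b, se, exp(b), exp(b - z * se), exp(b + z * se),
             length(x), sum(event), conf_level, mutant, estimable = TRUE)
}

new_mm_cox <- function(log_hr, se, hr, ci_low, ci_high, n, n_event,
                       conf_level, mutant, estimable) {
  structure(
    list(log_hr = log_hr, se = se, hr = hr, ci_low = ci_low,
         ci_high = ci_high,
         p_value = if (estimable) {
           2 * pnorm(-abs(log_hr / se))
         } else {
           NA_real_
         },
         n = n, n_event = n_event, conf_level = conf_level,
         mutant = mutant, estimable = estimable),
    class = "mm_cox"
  )
}

#' @export
print.mm_cox <- function(x, ...) {
  if (!x$estimable) {
    cat("Cox fit: non-estimable (a group has no events)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Cox proportional hazards (%s vs other): HR = %.2f (%d%% CI %.2f-%.2f), p = %.3g, n = %d (%d events)\n",
    x$mutant, x$hr, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$p_value, x$n, x$n_event
  ))
  invisible(x)
}

#' @rdname cox_hr
#' @param x An `mm_cox` object.
#' @param ... Unused.
#' @export
tidy.mm_cox <- function(x, ...) {
  tibble(term = paste0("group", x$mutant), estimate = x$log_hr,
         std.error = x$se, statistic = x$log_hr / x$se,
         p.value = x$p_value)
}

#' @rdname cox_hr
#' @export
glance.mm_cox <- function(x, ...) {
  tibble(hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value, n = x$n, n_event = x$n_event,
         estimable = x$estimable)
}
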