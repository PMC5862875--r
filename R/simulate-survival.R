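# Synthetic time-to-progression records with a planted hazard ratio.

#' Simulate survival records from a mutation matrix feature
#'
#' Event times are exponential with rate `baseline_rate * hazard_ratio^x`,
#' where `x` is the sample's 0/1 indicator for `feature`. Censoring times
#' are independent exponential with rate `censor_rate` (`0` disables
#' censoring).
#'
#' @param matrix A mutation matrix (see [simulate_mutation_matrix()] or
#'   [build_matrix()]).
#' @param feature Feature column whose carriers form the `mutant` group.
#' @param hazard_ratio Planted hazard ratio (> 0).
#' @param baseline_rate Baseline event rate (> 0), per time unit.
#' @param censor_rate Censoring rate (>= 0).
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `time`, `event` (0/1), `group`
#'   (`"mutant"`/`"WT"`).
#' @export
simulate_survival <- function(matrix, feature, hazard_ratio = 1.46,
                              baseline_rate = 0.1, censor_rate = 0.02,
                              seed = 1L) {
  assert_cols(matrix, c("sample_id", feature))
  if (baseline_rate <= 0 || hazard_ratio <= 0) {
    abort("`baseline_rate` and `hazard_ratio` must be > 0")
  }
  if (censor_rate < 0) abort("`censor_rate` must be >= 0")
  x <- as.numeric(matrix[[feature]])
  n <- length(x)
  with_seed(substream_seed(seed, "survival"), {
    t_event <- rexp(n, rate = baseline_rate * hazard_ratio^x)
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    tibble(
      sample_id = matrix$sample_id,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      group = if_else(x > 0, "mutant", "WT")
    )
  })
}
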