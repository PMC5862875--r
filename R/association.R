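# Pairwise co-occurrence / mutual exclusivity across the mutation matrix:
# Fisher's exact test via hypergeometric tail summation in both one-sided
# directions.

#' Test all feature pairs for co-occurrence and mutual exclusivity
#'
#' For each pair, the 2x2 table over samples is tested with Fisher's exact
#' test, computed by exact hypergeometric tail summation: `p_cooccur` is
#' the one-sided tail toward tables with more double-mutants (OR > 1),
#' `p_exclusive` the tail toward fewer (OR < 1). Raw p-values are primary;
#' a Benjamini-Hochberg column over `2 * min(p)` is provided alongside.
#' Zero-variance features are skipped (message); degenerate zero-margin
#' tables return p = 1 with OR reported missing.
#'
#' @param matrix An `mm_matrix` (or samples x features 0/1 tibble whose
#'   first column is `sample_id`).
#' @param features Optional subset of feature columns to test.
#' @param alpha Significance level used for the direction flag.
#' @return A tibble per pair: `feature_a`, `feature_b`, `a`, `b`, `c`, `d`
#'   (2x2 counts: both, A-only, B-only, neither), `odds_ratio`,
#'   `p_cooccur`, `p_exclusive`, `direction`
#'   (`co-occurring`/`exclusive`/`none`), `p_bh`.
#' @export
pairwise_association <- function(matrix, features = NULL, alpha = 0.05) {
  feats <- features %||% setdiff(names(matrix), "sample_id")
  missing <- setdiff(feats, names(matrix))
  if (length(missing) > 0) {
    abort(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(matrix)[feats])
  storage.mode(m) <- "integer"
  keep <- apply(m, 2, function(x) length(unique(x)) > 1)
  if (any(!keep)) {
    inform(sprintf("skipping zero-variance feature(s): %s",
                   paste(feats[!keep], collapse = ", ")))
  }
  feats <- feats[keep]
  m <- m[, keep, drop = FALSE]
  if (length(feats) < 2) {
    return(tibble(feature_a = character(), feature_b = character(),
                  a = integer(), b = integer(), c = integer(), d = integer(),
                  odds_ratio = numeric(), p_cooccur = numeric(),
                  p_exclusive = numeric(), direction = character(),
                  p_bh = numeric()))
  }
  pairs <- utils::combn(seq_along(feats), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    x <- m[, i]; y <- m[, j]
    a <- sum(x == 1 & y == 1)
    b <- sum(x == 1 & y == 0)
    c_ <- sum(x == 0 & y == 1)
    d <- sum(x == 0 & y == 0)
    ft <- fisher_tails(a, b, c_, d)
    tibble(feature_a = feats[i], feature_b = feats[j],
           a = a, b = b, c = c_, d = d,
           odds_ratio = ft$odds_ratio,
           p_cooccur = ft$p_greater, p_exclusive = ft$p_less)
  })
  res |>
    mutate(
      direction = dplyr::case_when(
        .data$p_cooccur < alpha ~ "co-occurring",
        .data$p_exclusive < alpha ~ "exclusive",
        TRUE ~ "none"
      ),
      p_bh = stats::p.adjust(pmin(1, 2 * pmin(.data$p_cooccur,
                                              .data$p_exclusive)),
                             method = "BH")
    )
}

#' One-sided Fisher exact tails of a 2x2 table
#'
#' Hypergeometric tail probabilities with margins fixed: `p_greater` is
#' `P(X >= a)` (co-occurrence direction), `p_less` is `P(X <= a)`
#' (exclusivity direction), where `X` is the count in the top-left cell.
#' Zero-margin tables return both tails 1 and a missing odds ratio.
#'
#' @param a,b,c,d 2x2 cell counts (both, A-only, B-only, neither).
#' @return A list: `p_greater`, `p_less`, `odds_ratio`.
#' @export
fisher_tails <- function(a, b, c, d) {
  r1 <- a + b # A-positive samples
  k <- a + c  # B-positive samples
  n <- a + b + c + d
  if (r1 == 0 || k == 0 || r1 == n || k == n) {
    return(list(p_greater = 1, p_less = 1, odds_ratio = NA_real_))
  }
  or <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
  if (a == 0) or <- 0
  list(
    p_greater = phyper(a - 1, r1, n - r1, k, lower.tail = FALSE),
    p_less = phyper(a, r1, n - r1, k),
    odds_ratio = or
  )
}
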