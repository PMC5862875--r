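# Independent oracles used across the suite. These re-derive expected
# values by brute force (enumeration, direct summation, naive scans) and
# never call the package code paths they check.

# Hypergeometric tails of a 2x2 table by direct enumeration over all
# tables with the observed margins, using only choose() arithmetic.
oracle_fisher_tails <- function(a, b, c, d) {
  r1 <- a + b
  k <- a + c
  n <- a + b + c + d
  xs <- max(0, r1 + k - n):min(r1, k)
  probs <- choose(r1, xs) * choose(n - r1, k - xs) / choose(n, k)
  list(
    p_greater = sum(probs[xs >= a]),
    p_less = sum(probs[xs <= a])
  )
}

# Exact upper binomial tail P(X >= k) by direct pmf summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  xs <- k:n
  sum(choose(n, xs) * p^xs * (1 - p)^(n - xs))
}

# Brute-force threshold tuner: full grid to observed maxima + 1,
# lexicographic (precision, recall); returns the optimal performance and
# the set of optimal triples.
oracle_tune <- function(sr, pe, lab) {
  grid <- expand.grid(s = 0:(max(sr) + 1), p = 0:(max(pe) + 1),
                      t = 0:(max(sr + pe) + 1))
  perf <- t(apply(grid, 1, function(g) {
    pass <- sr >= g[1] & pe >= g[2] & (sr + pe) >= g[3]
    np <- sum(pass)
    c(np, if (np > 0) sum(pass & lab) / np else NA_real_,
      sum(pass & lab) / sum(lab))
  }))
  ok <- perf[, 1] > 0
  grid <- grid[ok, ]; perf <- perf[ok, ]
  best_p <- max(perf[, 2])
  at <- perf[, 2] >= best_p - 1e-12
  best_r <- max(perf[at, 3])
  opt <- grid[at & perf[, 3] >= best_r - 1e-12, , drop = FALSE]
  list(precision = best_p, recall = best_r, optima = as.matrix(opt))
}

# TRUE iff triple x is componentwise-minimal within the optima set.
oracle_is_minimal <- function(x, optima) {
  !any(apply(optima, 1, function(o) all(o <= x) && any(o < x)))
}

# Naive WRCY/RGYW scan: compare every 4-mer against the explicitly
# enumerated motif strings (8 forward, 8 reverse).
oracle_motif_scan <- function(sequence) {
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  wrcy <- as.vector(outer(as.vector(outer(W, R, paste0)), Y,
                          function(a, b) paste0(a, "C", b)))
  rgyw <- as.vector(outer(as.vector(outer(R, Y, function(a, b) {
    paste0(a, "G", b)
  })), W, paste0))
  n <- nchar(sequence)
  starts <- seq_len(n - 3L)
  fours <- substring(sequence, starts, starts + 3L)
  out <- rbind(
    data.frame(pos = starts[fours %in% wrcy] + 2L, strand = "+"),
    data.frame(pos = starts[fours %in% rgyw] + 1L, strand = "-")
  )
  out <- out[order(out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# Small flat/step log2-ratio track on one arm, for segmentation tests.
make_test_track <- function(values, sample_id = "S001", chrom = "chr1",
                            arm = "1p") {
  n <- length(values)
  tibble::tibble(
    probe_id = sprintf("probe%06d", seq_len(n)),
    chrom = chrom, start = (seq_len(n) - 1) * 100, end = seq_len(n) * 100,
    sample_id = sample_id, masked = FALSE, log2_ratio = values,
    arm = arm
  )
}

# Minimal hand-built noise model (diploid N(mean, sd), alpha band).
make_test_noise <- function(mean = 0, sd = 0.1, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  structure(
    list(components = tibble::tibble(weight = 1, mean = mean, sd = sd),
         diploid_index = 1L, band_low = mean - z * sd,
         band_high = mean + z * sd, alpha = alpha, n_obs = 1000L,
         bic = NA_real_, loglik_trace = numeric()),
    class = "mm_noise_model"
  )
}

# Depth tables over a uniform one-chromosome panel with given per-probe
# tumor and normal depths.
make_depth_pair <- function(tumor, normal, sample_id = "S001") {
  n <- length(tumor)
  base <- tibble::tibble(
    probe_id = sprintf("probe%06d", seq_len(n)),
    chrom = "chr1", start = (seq_len(n) - 1) * 100, end = seq_len(n) * 100,
    sample_id = sample_id
  )
  list(tumor = dplyr::mutate(base, depth = tumor),
       normal = dplyr::mutate(base, depth = normal))
}
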