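# Synthetic mutation matrices with planted pairwise interactions, and
# synthetic sequences with planted AID-type hypermutation.

#' Simulate a binary mutation matrix with planted pairwise log-odds
#'
#' Samples are independent. Non-interacting features are Bernoulli with
#' their marginal frequency. Each interacting pair is drawn from the 2x2
#' joint distribution that matches both marginals and the requested odds
#' ratio `exp(log_odds)` (Plackett construction). `log_odds = -Inf` plants
#' hard exclusivity, `+Inf` hard co-occurrence.
#'
#' @param marginal_freqs Named numeric vector of per-feature mutation
#'   frequencies, each in (0, 1).
#' @param interactions Tibble with columns `feature_a`, `feature_b`,
#'   `log_odds`; a feature may appear in at most one interaction.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return A samples x features tibble (first column `sample_id`, entries
#'   0/1) of class `mm_matrix`, with feature types all `"snv_gene"`.
#' @export
simulate_mutation_matrix <- function(marginal_freqs,
                                     interactions = NULL,
                                     n_samples = 95,
                                     seed = 1L) {
  feats <- names(marginal_freqs)
  if (is.null(feats) || any(feats == "")) {
    abort("`marginal_freqs` must be a named vector")
  }
  if (anyDuplicated(feats)) abort("features must be distinct")
  if (any(marginal_freqs <= 0 | marginal_freqs >= 1)) {
    abort("marginal frequencies must lie in (0, 1)")
  }
  if (is.null(interactions)) {
    interactions <- tibble(feature_a = character(), feature_b = character(),
                           log_odds = numeric())
  }
  assert_cols(interactions, c("feature_a", "feature_b", "log_odds"))
  inter_feats <- c(interactions$feature_a, interactions$feature_b)
  if (anyDuplicated(inter_feats)) {
    abort("a feature may appear in at most one interaction")
  }
  if (!all(inter_feats %in% feats)) {
    abort("interaction features must appear in `marginal_freqs`")
  }

  with_seed(substream_seed(seed, "mutation_matrix"), {
    m <- matrix(0L, nrow = n_samples, ncol = length(feats),
                dimnames = list(NULL, feats))
    solo <- setdiff(feats, inter_feats)
    for (f in solo) m[, f] <- rbinom(n_samples, 1, marginal_freqs[[f]])
    for (i in seq_len(nrow(interactions))) {
      fa <- interactions$feature_a[i]
      fb <- interactions$feature_b[i]
      jp <- plackett_joint(marginal_freqs[[fa]], marginal_freqs[[fb]],
                           interactions$log_odds[i])
      cell <- sample(4, n_samples, replace = TRUE, prob = jp)
      m[, fa] <- as.integer(cell %in% c(1L, 2L)) # 11, 10
      m[, fb] <- as.integer(cell %in% c(1L, 3L)) # 11, 01
    }
    new_mm_matrix(
      bind_cols(tibble(sample_id = sprintf("S%03d", seq_len(n_samples))),
                as_tibble(m)),
      feature_types = setNames(rep("snv_gene", length(feats)), feats)
    )
  })
}

# Joint cell probabilities (p11, p10, p01, p00) matching marginals p1, p2
# and odds ratio exp(log_odds).
plackett_joint <- function(p1, p2, log_odds) {
  lo_bound <- max(0, p1 + p2 - 1)
  hi_bound <- min(p1, p2)
  p11 <- if (identical(log_odds, -Inf)) {
    lo_bound
  } else if (identical(log_odds, Inf)) {
    hi_bound
  } else if (abs(log_odds) < 1e-12) {
    p1 * p2
  } else {
    psi <- exp(log_odds)
    s <- 1 + (p1 + p2) * (psi - 1)
    disc <- s^2 - 4 * psi * (psi - 1) * p1 * p2
    (s - sqrt(disc)) / (2 * (psi - 1))
  }
  if (p11 < lo_bound - 1e-9 || p11 > hi_bound + 1e-9) {
    abort(sprintf(
      "infeasible (marginal, log-odds) combination: joint probability %.4f outside feasible bounds [%.4f, %.4f]",
      p11, lo_bound, hi_bound
    ))
  }
  p11 <- min(max(p11, lo_bound), hi_bound)
  c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
}

#' Simulate a sequence with planted AID-type mutations at WRCY motifs
#'
#' Generates a random sequence containing at least the requested number of
#' AID hotspot motifs (WRCY on the forward strand, RGYW on the reverse;
#' W = A/T, R = A/G, Y = C/T), then plants `n_mutations` point mutations:
#' a fraction `aid_fraction` are AID-type (C->T or C->G at a motif C, or the
#' reverse-strand equivalent G->A/G->C at a motif G); the remainder fall
#' uniformly on non-motif C/G positions so the mutation universe matches
#' the binomial signature test's C/G background.
#'
#' @param length Sequence length (bp).
#' @param target_wrcy_density Desired motif sites per bp (motifs are
#'   planted; random background may add more).
#' @param n_mutations Total mutations to emit.
#' @param aid_fraction Fraction of mutations that are AID-type, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: `sequence` (single string) and `variants` (tibble with
#'   `pos` 1-based, `ref`, `alt`, `strand`).
#' @export
simulate_aid_sequence <- function(length, target_wrcy_density = 0.01,
                                  n_mutations = 40, aid_fraction = 0.5,
                                  seed = 1L) {
  stopifnot(length >= 8, n_mutations >= 0)
  assert_scalar_in(aid_fraction, 0, 1, "aid_fraction")
  with_seed(substream_seed(seed, "aid_sequence"), {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    n_plant <- max(1L, round(target_wrcy_density * length))
    # non-overlapping 4-mer slots for planted motifs
    slots <- seq(1L, length - 3L, by = 5L)
    plant_at <- sort(sample(slots, min(n_plant, base::length(slots))))
    for (s in plant_at) {
      base[s:(s + 3L)] <- c(sample(c("A", "T"), 1), sample(c("A", "G"), 1),
                            "C", sample(c("C", "T"), 1))
    }
    seqc <- paste(base, collapse = "")

    sites <- find_motif_sites(seqc)
    cg_pos <- which(base %in% c("C", "G"))
    nonmotif_cg <- setdiff(cg_pos, sites$pos)

    n_aid <- round(aid_fraction * n_mutations)
    n_bg <- n_mutations - n_aid
    if (n_aid > nrow(sites)) {
      abort(sprintf("n_mutations exceeds available motif sites (%d AID mutations requested, %d sites)",
                    n_aid, nrow(sites)))
    }
    if (n_bg > base::length(nonmotif_cg)) {
      abort("n_mutations exceeds available non-motif C/G positions")
    }

    aid_rows <- sites[sample.int(nrow(sites), n_aid), , drop = FALSE]
    aid_vars <- if (n_aid > 0) {
      tibble(
        pos = aid_rows$pos,
        ref = ifelse(aid_rows$strand == "+", "C", "G"),
        alt = ifelse(aid_rows$strand == "+",
                     sample(c("T", "G"), n_aid, replace = TRUE),
                     sample(c("A", "C"), n_aid, replace = TRUE)),
        strand = aid_rows$strand
      )
    }
    bg_pos <- if (n_bg > 0) sample(nonmotif_cg, n_bg) else integer()
    bg_vars <- if (n_bg > 0) {
      ref <- base[bg_pos]
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                    character(1))
      tibble(pos = bg_pos, ref = ref, alt = alt, strand = "+")
    }
    vars <- bind_rows(aid_vars, bg_vars)
    if (nrow(vars) > 0) vars <- arrange(vars, .data$pos)
    list(sequence = seqc, variants = vars)
  })
}
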