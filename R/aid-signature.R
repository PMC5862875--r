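# AID (activation-induced cytidine deaminase) hypermutation signature:
# WRCY/RGYW motif scan and the one-sided exact binomial enrichment test.

#' Find AID hotspot motif sites in a sequence
#'
#' Forward-strand sites are the positions of the C in every WRCY match
#' (W = A/T, R = A/G, Y = C/T); reverse-strand sites are the positions of
#' the G in every RGYW match. Overlapping matches are all reported.
#'
#' @param sequence A single DNA string over A/C/G/T.
#' @return A tibble: `pos` (1-based), `strand` (`"+"` forward WRCY,
#'   `"-"` reverse RGYW).
#' @export
#' @examples
#' find_motif_sites("AGCT") # C of the WRCY match at position 3
find_motif_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  # lookahead so overlapping motifs are all found
  fwd <- gregexpr("(?=[AT][AG]C[CT])", sequence, perl = TRUE)[[1]]
  rev <- gregexpr("(?=[AG]G[CT][AT])", sequence, perl = TRUE)[[1]]
  fwd <- fwd[fwd > 0]
  rev <- rev[rev > 0]
  out <- bind_rows(
    tibble(pos = as.integer(fwd) + 2L, strand = "+"),
    tibble(pos = as.integer(rev) + 1L, strand = "-")
  )
  arrange(out, .data$pos, .data$strand)
}

#' Test variants for enrichment of the c-AID signature
#'
#' Counts variants that are C->T or C->G at a forward-strand motif C (or
#' G->A / G->C at a reverse-strand motif G) and compares the count against
#' a binomial null in which each C/G mutation falls on a motif C/G with
#' probability equal to the motif fraction of all C/G positions in the
#' sequence footprint. The p-value is the one-sided exact binomial upper
#' tail `P(X >= n_at_motif)`.
#'
#' @param variants Variant tibble with `pos` (1-based on `sequence`),
#'   `ref`, `alt`.
#' @param sequence The gene-footprint DNA string the positions refer to.
#' @return A one-row tibble of class `mm_aid_test`: `n_mutations`,
#'   `n_at_motif`, `background_p`, `p_value`.
#' @export
aid_signature_test <- function(variants, sequence) {
  assert_cols(variants, c("pos", "ref", "alt"))
  base <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n_cg <- sum(base %in% c("C", "G"))
  if (n_cg == 0) abort("sequence contains no C/G positions; background undefined")
  sites <- find_motif_sites(sequence)
  background_p <- length(unique(sites$pos)) / n_cg

  fwd_sites <- sites$pos[sites$strand == "+"]
  rev_sites <- sites$pos[sites$strand == "-"]
  at_motif <- (variants$ref == "C" & variants$alt %in% c("T", "G") &
                 variants$pos %in% fwd_sites) |
    (variants$ref == "G" & variants$alt %in% c("A", "C") &
       variants$pos %in% rev_sites)

  n <- nrow(variants)
  k <- sum(at_motif)
  p <- if (k == 0) 1 else pbinom(k - 1, n, background_p, lower.tail = FALSE)
  structure(
    tibble(n_mutations = n, n_at_motif = k,
           background_p = background_p, p_value = p),
    class = c("mm_aid_test", class(tibble())))
}

#' Flag expression outliers by the upper Tukey fence
#'
#' Flags samples whose expression exceeds `Q3 + k * IQR` (upper tail only:
#' the rule targets overexpression). Quantiles use linear interpolation
#' between order statistics, the convention shared across the package.
#'
#' @param values Tibble with `sample_id` and `value` (e.g. FPKM), or a
#'   numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return The input with an `outlier` logical column (a tibble either
#'   way).
#' @export
expression_outliers <- function(values, k = 1.5) {
  if (!is.data.frame(values)) {
    values <- tibble(sample_id = seq_along(values), value = values)
  }
  assert_cols(values, "value")
  q1 <- mm_quantile(values$value, 0.25)
  q3 <- mm_quantile(values$value, 0.75)
  mutate(values, outlier = .data$value > q3 + k * (q3 - q1))
}
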