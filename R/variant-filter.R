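# Variant filtering rules, set matching between sequencing runs, and VAF
# concordance.

NONSYNONYMOUS_EFFECTS <- c("missense", "nonsense", "frameshift_ins",
                           "frameshift_del", "splice")
DROPPED_EFFECTS <- c("silent", "intronic", "intergenic", "flanking")

#' Filter somatic variant calls to high-confidence events
#'
#' A call survives iff its effect is not silent/intronic/intergenic/
#' flanking, it is not in the IGH locus (where somatic hypermutation
#' dominates), and it was not flagged as likely germline by any caller.
#' The first failing rule is recorded per dropped call in the `drop_log`
#' attribute (`variant_drop_log()`), so filtering is idempotent.
#'
#' @param calls Variant call tibble with `effect`, `in_igh`,
#'   `germline_flagged`.
#' @param drop_effects Effect classes to remove.
#' @return The surviving calls; dropped calls with reasons in
#'   `attr(, "drop_log")`.
#' @export
filter_variants <- function(calls, drop_effects = DROPPED_EFFECTS) {
  assert_cols(calls, c("effect", "in_igh", "germline_flagged"))
  reason <- dplyr::case_when(
    calls$effect %in% drop_effects ~ as.character(calls$effect),
    calls$in_igh ~ "igh",
    calls$germline_flagged ~ "germline",
    TRUE ~ NA_character_
  )
  kept <- calls[is.na(reason), , drop = FALSE]
  attr(kept, "drop_log") <- mutate(calls[!is.na(reason), , drop = FALSE],
                                   drop_reason = reason[!is.na(reason)])
  kept
}

#' @rdname filter_variants
#' @param filtered Output of [filter_variants()].
#' @export
variant_drop_log <- function(filtered) {
  attr(filtered, "drop_log") %||%
    abort("no drop log attached; was this produced by filter_variants()?")
}

#' Match variants between two call sets
#'
#' Variants match on the exact key `(sample_id, chrom, pos, ref, alt)`;
#' a multi-allelic site (same position, different alt) yields distinct
#' variants. The three partitions are disjoint and exhaustive.
#'
#' @param set_a,set_b Variant call tibbles.
#' @return A list: `shared` (key plus `vaf_a`, `vaf_b`, `alt_count_a`,
#'   `alt_count_b`), `unique_a`, `unique_b`.
#' @export
match_variants <- function(set_a, set_b) {
  key <- c("sample_id", "chrom", "pos", "ref", "alt")
  assert_cols(set_a, c(key, "vaf"))
  assert_cols(set_b, c(key, "vaf"))
  shared <- inner_join(
    set_a |> select(dplyr::all_of(key), vaf_a = "vaf",
                    alt_count_a = dplyr::any_of("alt_count")),
    set_b |> select(dplyr::all_of(key), vaf_b = "vaf",
                    alt_count_b = dplyr::any_of("alt_count")),
    by = key
  )
  list(
    shared = shared,
    unique_a = anti_join(set_a, set_b, by = key),
    unique_b = anti_join(set_b, set_a, by = key)
  )
}

#' Summarise VAF concordance between two matched call sets
#'
#' Reports the squared Pearson correlation of shared VAFs together with the
#' unique-variant tallies (counts with VAF below `low_vaf`, and the largest
#' alternate-read count among set-A-unique variants).
#'
#' @param matched Output of [match_variants()].
#' @param low_vaf Low-VAF cutoff for the unique-variant tallies.
#' @return A one-row tibble: `n_shared`, `r_squared`, `n_unique_a`,
#'   `n_unique_b`, `n_unique_low_vaf_a`, `n_unique_low_vaf_b`,
#'   `max_alt_count_unique_a`.
#' @export
vaf_concordance <- function(matched, low_vaf = 0.10) {
  shared <- matched$shared
  r2 <- if (nrow(shared) < 3) {
    NA_real_
  } else if (max(abs(shared$vaf_a - shared$vaf_b)) < 1e-12) {
    1 # identical VAF vectors (correlation is degenerate when constant)
  } else if (sd(shared$vaf_a) == 0 || sd(shared$vaf_b) == 0) {
    NA_real_
  } else {
    stats::cor(shared$vaf_a, shared$vaf_b)^2
  }
  tibble(
    n_shared = nrow(shared),
    r_squared = r2,
    n_unique_a = nrow(matched$unique_a),
    n_unique_b = nrow(matched$unique_b),
    n_unique_low_vaf_a = sum(matched$unique_a$vaf < low_vaf),
    n_unique_low_vaf_b = sum(matched$unique_b$vaf < low_vaf),
    max_alt_count_unique_a = if (nrow(matched$unique_a) > 0) {
      max(matched$unique_a$alt_count)
    } else {
      NA_real_
    }
  )
}
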