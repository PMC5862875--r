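# Classification of filtered translocation candidates into canonical
# classes, and breakpoint-proximity gene annotation.

TRANSLOCATION_CLASSES <- c("t(11;14)", "t(4;14)", "t(8;14)", "t(6;14)",
                           "t(14;20)", "t(14;16)", "t(14;22)",
                           "MYC-ITX", "MYC-CTX", "other-IGH", "other")

#' Classify translocation candidates into canonical classes
#'
#' A pure function of breakpoints and the region table. A candidate with
#' one breakpoint in the IGH region is matched against the partner windows
#' (`t(11;14)`, `t(4;14)`, ...; unmatched partners give `other-IGH`).
#' Otherwise, `MYC-ITX` when both breakpoints lie on the MYC chromosome
#' with one inside the MYC region and separation at least
#' `myc_min_separation`; `MYC-CTX` when exactly one breakpoint is in the
#' MYC region and the partner chromosome differs. Everything else is
#' `other`.
#'
#' @param candidates Candidate tibble (`chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`).
#' @param region_table Region definitions, see [default_region_table()].
#' @param myc_min_separation Minimum intra-chromosomal separation (bp) for
#'   MYC-ITX.
#' @return The candidates with a `class` column (factor over the canonical
#'   labels).
#' @export
classify_translocation <- function(candidates,
                                   region_table = default_region_table(),
                                   myc_min_separation = 1e5) {
  assert_cols(candidates, c("chrom_a", "pos_a", "chrom_b", "pos_b"))
  igh <- region_table[region_table$role == "igh", ][1, ]
  myc <- region_table[region_table$role == "myc", ][1, ]
  partners <- region_table[region_table$role == "partner", ]

  in_region <- function(chrom, pos, r) {
    chrom == r$chrom & pos >= r$start & pos < r$end
  }
  classify_one <- function(chrom_a, pos_a, chrom_b, pos_b) {
    a_igh <- in_region(chrom_a, pos_a, igh)
    b_igh <- in_region(chrom_b, pos_b, igh)
    if (a_igh || b_igh) {
      oc <- if (a_igh) chrom_b else chrom_a
      op <- if (a_igh) pos_b else pos_a
      for (i in seq_len(nrow(partners))) {
        if (in_region(oc, op, partners[i, ])) return(partners$label[i])
      }
      return("other-IGH")
    }
    a_myc <- in_region(chrom_a, pos_a, myc)
    b_myc <- in_region(chrom_b, pos_b, myc)
    if ((a_myc || b_myc) && chrom_a == myc$chrom && chrom_b == myc$chrom) {
      if (abs(pos_a - pos_b) >= myc_min_separation) return("MYC-ITX")
      return("other")
    }
    if (xor(a_myc, b_myc)) {
      oc <- if (a_myc) chrom_b else chrom_a
      if (oc != myc$chrom) return("MYC-CTX")
    }
    "other"
  }
  cls <- purrr::pmap_chr(
    candidates[c("chrom_a", "pos_a", "chrom_b", "pos_b")],
    classify_one
  )
  mutate(candidates, class = factor(cls, levels = TRANSLOCATION_CLASSES))
}

#' Annotate breakpoints with nearby genes
#'
#' Lists genes whose interval intersects `[pos - window, pos + window]`
#' around each breakpoint, sorted by distance (0 when the breakpoint falls
#' inside the gene).
#'
#' @param candidates Candidate tibble with `candidate_id`, `chrom_a`,
#'   `pos_a`, `chrom_b`, `pos_b`.
#' @param gene_bed Gene intervals (`chrom`, `start`, `end`, `gene`).
#' @param window Search window around each breakpoint (bp, default 1 Mb).
#' @return A long tibble: `candidate_id`, `breakpoint` (`"a"`/`"b"`),
#'   `gene`, `distance`.
#' @export
annotate_breakpoints <- function(candidates, gene_bed, window = 1e6) {
  assert_cols(candidates, c("candidate_id", "chrom_a", "pos_a",
                            "chrom_b", "pos_b"))
  if (nrow(gene_bed) > 0) assert_cols(gene_bed, c("chrom", "start", "end", "gene"))
  long <- bind_rows(
    candidates |>
      select("candidate_id", chrom = "chrom_a", pos = "pos_a") |>
      mutate(breakpoint = "a"),
    candidates |>
      select("candidate_id", chrom = "chrom_b", pos = "pos_b") |>
      mutate(breakpoint = "b")
  )
  if (nrow(gene_bed) == 0 || nrow(long) == 0) {
    return(tibble(candidate_id = character(), breakpoint = character(),
                  gene = character(), distance = numeric()))
  }
  purrr::pmap_dfr(long, function(candidate_id, chrom, pos, breakpoint) {
    g <- gene_bed[gene_bed$chrom == chrom &
                    gene_bed$start < pos + window &
                    gene_bed$end > pos - window, ]
    if (nrow(g) == 0) return(tibble())
    dist <- pmax(0, pmax(g$start - pos, pos - g$end))
    tibble(candidate_id = candidate_id, breakpoint = breakpoint,
           gene = g$gene, distance = dist) |>
      arrange(.data$distance)
  })
}
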