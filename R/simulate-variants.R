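# MAF-like somatic variant calls derived from a mutation matrix: the
# shape the merged multi-caller output takes after upstream calling.

#' Simulate somatic variant calls from a mutation matrix
#'
#' For every (sample, gene) entry of 1, emits one non-synonymous call at a
#' probe of that gene with binomial read counts at the given depth and a
#' clonal diploid-heterozygous target VAF scaled by purity. Background
#' calls exercising the filtering rules (silent and intronic variants,
#' IGH-locus calls, germline-flagged calls) are added at rate
#' `background_per_sample`.
#'
#' @param matrix An `mm_matrix` of `snv_gene` features.
#' @param panel A probe panel (positions and IGH probes are drawn from it).
#' @param mean_depth Mean total read depth per call.
#' @param purity Tumor purity; clonal het VAF targets `purity / 2`.
#' @param background_per_sample Mean number of to-be-filtered background
#'   calls per sample.
#' @param seed Integer seed.
#' @return A MAF-like variant call tibble (see [read_variants()]).
#' @export
simulate_variant_calls <- function(matrix, panel, mean_depth = 104,
                                   purity = 0.8, background_per_sample = 3,
                                   seed = 1L) {
  assert_cols(panel, c("chrom", "start", "gene", "region_class"))
  feats <- names(feature_types(matrix))[feature_types(matrix) == "snv_gene"]
  gene_probe <- panel |>
    dplyr::filter(.data$gene %in% feats) |>
    group_by(.data$gene) |>
    dplyr::slice(1) |>
    ungroup()
  igh_probes <- panel[panel$region_class == "IGH", , drop = FALSE]
  bases <- c("A", "C", "G", "T")

  with_seed(substream_seed(seed, "variant_calls"), {
    mk_call <- function(sample_id, gene, chrom, start, effect, in_igh,
                        germline, vaf_target) {
      depth <- max(10L, rpois(1, mean_depth))
      n_alt <- rbinom(1, depth, vaf_target)
      ref_b <- sample(bases, 1)
      tibble(
        sample_id = sample_id, chrom = chrom,
        pos = start + sample.int(50L, 1), ref = ref_b,
        alt = sample(setdiff(bases, ref_b), 1), gene = gene,
        effect = effect, ref_count = depth - n_alt, alt_count = n_alt,
        vaf = n_alt / depth,
        caller_flags = paste(sample(c("mutect", "strelka", "varscan2",
                                      "somaticsniper", "samtools"),
                                    sample(2:3, 1)), collapse = ","),
        germline_flagged = germline, in_igh = in_igh,
        cosmic_annotated = runif(1) < 0.2,
        deleterious_predicted = runif(1) < 0.6
      )
    }
    driver <- purrr::map_dfr(matrix$sample_id, function(sid) {
      hit <- feats[purrr::map_int(feats, ~ matrix[[.x]][matrix$sample_id == sid]) == 1L]
      purrr::map_dfr(hit, function(g) {
        p <- gene_probe[gene_probe$gene == g, ]
        mk_call(sid, g, p$chrom, p$start,
                effect = sample(NONSYNONYMOUS_EFFECTS, 1,
                                prob = c(0.7, 0.1, 0.08, 0.08, 0.04)),
                in_igh = FALSE, germline = FALSE,
                vaf_target = purity / 2)
      })
    })
    background <- purrr::map_dfr(matrix$sample_id, function(sid) {
      k <- rpois(1, background_per_sample)
      if (k == 0) return(tibble())
      purrr::map_dfr(seq_len(k), function(i) {
        kind <- sample(c("silent", "intronic", "igh", "germline"), 1)
        if (kind == "igh" && nrow(igh_probes) > 0) {
          p <- igh_probes[sample.int(nrow(igh_probes), 1), ]
          mk_call(sid, "IGH", p$chrom, p$start, effect = "missense",
                  in_igh = TRUE, germline = FALSE, vaf_target = 0.3)
        } else {
          p <- panel[sample.int(nrow(panel), 1), ]
          mk_call(sid, p$gene, p$chrom, p$start,
                  effect = if (kind %in% c("silent", "intronic")) kind else "missense",
                  in_igh = FALSE, germline = kind == "germline",
                  vaf_target = if (kind == "germline") 0.5 else 0.3)
        }
      })
    })
    bind_rows(driver, background) |>
      arrange(.data$sample_id, chrom_rank(.data$chrom), .data$pos)
  })
}
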