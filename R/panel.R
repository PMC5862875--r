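# Probe panel construction: the coordinate backbone for depth and CNV work.
# All coordinates are 0-based half-open throughout the package.

#' Describe a capture panel design
#'
#' Builds the structured annotation a panel is generated from: chromosomes
#' with arm boundaries, gene footprints, and region classes. The default
#' emulates a myeloma capture design: exon-targeted probes over a large gene
#' set plus unbiased tiling of the IGH locus (chr14), the MYC locus (chr8),
#' and the immunoglobulin lambda locus (chr22, spanning IGLL5).
#'
#' @param n_genes Number of ordinary gene targets (the full design uses 465).
#' @param chromosomes Character vector of chromosome names to place genes on.
#' @param chrom_length Length (bp) of each synthetic chromosome.
#' @param centromere_frac Fraction of chromosome length at which the p/q
#'   boundary sits. Acrocentric chromosomes (13, 14, 15, 21, 22) get no p arm.
#' @param gene_span Footprint (bp) of each gene target.
#' @param locus_span Footprint (bp) of each tiled locus (IGH/MYC/IGL).
#' @return A list with `arms` and `genes` tibbles, class `mm_panel_spec`.
#' @export
#' @examples
#' spec <- panel_spec(n_genes = 20, chromosomes = c("chr1", "chr2"))
#' panel <- make_panel(cohort_config(n_samples = 2, probe_count = 400), spec)
panel_spec <- function(n_genes = 465,
                       chromosomes = paste0("chr", 1:22),
                       chrom_length = 2e8,
                       centromere_frac = 0.4,
                       gene_span = 1e4,
                       locus_span = 1e6) {
  if (n_genes < 1) abort("`n_genes` must be >= 1 (empty gene list)")
  acrocentric <- paste0("chr", c(13, 14, 15, 21, 22))
  arms <- purrr::map_dfr(chromosomes, function(ch) {
    if (ch %in% acrocentric) {
      tibble(chrom = ch, arm = paste0(chrom_label(ch), "q"),
             start = 0, end = chrom_length)
    } else {
      cen <- round(chrom_length * centromere_frac)
      tibble(chrom = ch,
             arm = paste0(chrom_label(ch), c("p", "q")),
             start = c(0, cen), end = c(cen, chrom_length))
    }
  })

  # Known myeloma genes pinned to their real chromosomes so the downstream
  # feature names line up; the rest filled in as GENE###.
  pinned <- tibble(
    gene = c("NRAS", "FAM46C", "KRAS", "BRAF", "TP53", "DIS3", "BRCA2",
             "FLT3", "RB1", "CCND1", "WHSC1", "FGFR3", "CCND3", "MAF",
             "MAFB", "WWOX"),
    chrom = c("chr1", "chr1", "chr12", "chr7", "chr17", "chr13", "chr13",
              "chr13", "chr13", "chr11", "chr4", "chr4", "chr6", "chr16",
              "chr20", "chr16")
  )
  pinned <- dplyr::filter(pinned, .data$chrom %in% chromosomes)
  n_fill <- max(0L, n_genes - nrow(pinned))
  fill <- tibble(
    gene = sprintf("GENE%03d", seq_len(n_fill)),
    chrom = rep_len(chromosomes, n_fill)
  )
  genes <- bind_rows(head(pinned, n_genes), fill)

  # Deterministic, evenly spaced gene footprints spanning both arms; the
  # tiled loci sit telomeric (past the gene band) as IGH/IGL/MYC do.
  genes <- genes |>
    group_by(.data$chrom) |>
    mutate(
      start = round(chrom_length * (0.05 + 0.9 * (row_number() - 1) /
                                      pmax(1, n()))),
      end = .data$start + gene_span,
      region_class = "gene"
    ) |>
    ungroup()

  loci <- tibble(
    gene = c("IGH", "MYC", "IGL"),
    chrom = c("chr14", "chr8", "chr22"),
    start = round(chrom_length * 0.96),
    end = pmin(round(chrom_length * 0.96) + locus_span, chrom_length),
    region_class = c("IGH", "MYC", "IGL")
  )
  loci <- dplyr::filter(loci, .data$chrom %in% chromosomes)

  structure(
    list(arms = arms, genes = bind_rows(genes, loci), chrom_length = chrom_length),
    class = "mm_panel_spec"
  )
}

chrom_label <- function(chrom) sub("^chr", "", chrom)

# Natural chromosome ordering: chr1 < chr2 < ... < chr22 < chrX < chrY.
chrom_rank <- function(chrom) {
  lab <- chrom_label(chrom)
  num <- suppressWarnings(as.numeric(lab))
  num[lab == "X"] <- 23
  num[lab == "Y"] <- 24
  num[is.na(num)] <- 25 + match(lab[is.na(num)], sort(unique(lab[is.na(num)])))
  num
}

#' Generate a probe panel from a design specification
#'
#' Tiles capture probes across the gene footprints and tiled loci of a
#' design, allocating probes proportionally to footprint size. Probes are
#' 0-based half-open, sorted by (chromosome, start), non-overlapping, and
#' each carries a gene (or locus) label, a region class, and an arm label.
#'
#' @param config A [cohort_config()]; its `probe_count` sets the panel size.
#' @param spec A [panel_spec()].
#' @return A tibble with columns `probe_id`, `chrom`, `start`, `end`,
#'   `gene`, `region_class`, `arm`.
#' @export
make_panel <- function(config, spec = panel_spec()) {
  stopifnot(inherits(spec, "mm_panel_spec"))
  genes <- spec$genes
  arms <- spec$arms
  if (nrow(genes) == 0) abort("panel spec has an empty gene list")
  check_arm_overlap(arms)

  probe_count <- config$probe_count
  spans <- genes$end - genes$start
  if (any(spans <= 0)) abort("gene footprints must have positive span")
  n_per <- pmax(1L, floor(probe_count * spans / sum(spans)))

  panel <- purrr::pmap_dfr(
    list(genes$gene, genes$chrom, genes$start, genes$end,
         genes$region_class, n_per),
    function(gene, chrom, start, end, region_class, k) {
      width <- max(1L, floor((end - start) / k))
      starts <- start + (seq_len(k) - 1L) * width
      tibble(chrom = chrom, start = starts,
             end = pmin(starts + width, end),
             gene = gene, region_class = region_class)
    }
  )

  panel <- panel |>
    mutate(arm = arm_of(.data$chrom, .data$start, arms)) |>
    arrange(chrom_rank(.data$chrom), .data$start) |>
    mutate(probe_id = sprintf("probe%06d", row_number())) |>
    select("probe_id", "chrom", "start", "end", "gene", "region_class", "arm")

  if (any(is.na(panel$arm))) {
    abort("some probes fall outside every defined arm; check `spec$arms`")
  }
  panel
}

# Map positions to arm labels; errors on overlapping arm definitions.
arm_of <- function(chrom, pos, arms) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[i] & pos >= arms$start[i] & pos < arms$end[i]
    out[hit] <- arms$arm[i]
  }
  out
}

check_arm_overlap <- function(arms) {
  by_chrom <- split(arms, arms$chrom)
  for (a in by_chrom) {
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)])) {
      abort(sprintf("overlapping arm definitions on %s", a$chrom[1]))
    }
  }
  invisible(arms)
}

#' Summarise a panel by region class
#'
#' @param panel A probe panel from [make_panel()].
#' @return A tibble of probe counts per region class.
#' @export
panel_class_histogram <- function(panel) {
  assert_cols(panel, c("region_class"))
  panel |> dplyr::count(.data$region_class, name = "n_probes")
}
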