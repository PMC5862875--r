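# Readers and writers for the standard formats. Coordinates are 0-based
# half-open internally and in BED/BEDPE; MAF-like variant positions are
# 1-based and converted nowhere (they stay 1-based in the VariantCall
# tables, as in VCF/MAF). Parsers reject malformed input with file and
# line numbers rather than coercing.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, col_types = col_types, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("%s: malformed line %d (%s)", path, probs$row[1] + 1L,
                  probs$expected[1]))
  }
  out
}

#' Read and write a probe panel as BED
#'
#' BED is 0-based half-open; the name field packs `gene|region_class|arm`.
#'
#' @param path File path.
#' @return `read_bed()`: a panel tibble (`probe_id` regenerated in file
#'   order after sorting).
#' @export
read_bed <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), name = readr::col_character()
  ))
  bad <- which(raw$start > raw$end | raw$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (start > end or negative)",
                  path, bad[1] + 1L))
  }
  parts <- stringr::str_split_fixed(raw$name, stringr::fixed("|"), 3)
  if (any(parts == "")) {
    abort(sprintf("%s: malformed line %d (name must be gene|region_class|arm)",
                  path, which(parts == "", arr.ind = TRUE)[1, 1] + 1L))
  }
  raw |>
    mutate(gene = parts[, 1], region_class = parts[, 2], arm = parts[, 3]) |>
    arrange(chrom_rank(.data$chrom), .data$start) |>
    mutate(probe_id = sprintf("probe%06d", row_number())) |>
    select("probe_id", "chrom", "start", "end", "gene", "region_class", "arm")
}

#' @rdname read_bed
#' @param panel A panel tibble.
#' @export
write_bed <- function(panel, path) {
  assert_cols(panel, c("chrom", "start", "end", "gene", "region_class", "arm"))
  panel |>
    mutate(name = paste(.data$gene, .data$region_class, .data$arm,
                        sep = "|")) |>
    select("chrom", "start", "end", "name") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read and write translocation candidates as BEDPE
#'
#' Standard ten BEDPE columns plus `sr`, `pe`, `sample_id`, `is_normal`.
#' Breakpoints are stored as 1 bp intervals (`end = pos`, `start = pos - 1`).
#' Writing then reading a canonical table is the identity.
#'
#' @param path File path.
#' @return `read_bedpe()`: a candidate tibble.
#' @export
read_bedpe <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    chrom1 = readr::col_character(), start1 = readr::col_double(),
    end1 = readr::col_double(), chrom2 = readr::col_character(),
    start2 = readr::col_double(), end2 = readr::col_double(),
    name = readr::col_character(), score = readr::col_double(),
    strand1 = readr::col_character(), strand2 = readr::col_character(),
    sr = readr::col_integer(), pe = readr::col_integer(),
    sample_id = readr::col_character(), is_normal = readr::col_logical()
  ))
  bad <- which(raw$start1 > raw$end1 | raw$start2 > raw$end2 |
                 raw$sr < 0 | raw$pe < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (negative support or start > end)",
                  path, bad[1] + 1L))
  }
  raw |>
    mutate(candidate_id = .data$name, chrom_a = .data$chrom1,
           pos_a = .data$end1, strand_a = .data$strand1,
           chrom_b = .data$chrom2, pos_b = .data$end2,
           strand_b = .data$strand2) |>
    select("candidate_id", "chrom_a", "pos_a", "strand_a", "chrom_b",
           "pos_b", "strand_b", "sr", "pe", "sample_id", "is_normal")
}

#' @rdname read_bedpe
#' @param candidates A candidate tibble.
#' @export
write_bedpe <- function(candidates, path) {
  assert_cols(candidates, c("candidate_id", "chrom_a", "pos_a", "chrom_b",
                            "pos_b", "sr", "pe", "sample_id", "is_normal"))
  candidates |>
    mutate(
      chrom1 = .data$chrom_a, start1 = .data$pos_a - 1, end1 = .data$pos_a,
      chrom2 = .data$chrom_b, start2 = .data$pos_b - 1, end2 = .data$pos_b,
      name = .data$candidate_id, score = .data$sr + .data$pe,
      strand1 = if ("strand_a" %in% names(candidates)) .data$strand_a else "+",
      strand2 = if ("strand_b" %in% names(candidates)) .data$strand_b else "+"
    ) |>
    select("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
           "score", "strand1", "strand2", "sr", "pe", "sample_id",
           "is_normal") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read and write somatic variant calls (MAF-like TSV)
#'
#' Positions are 1-based (VCF/MAF convention). `caller_flags` is a
#' comma-separated caller list.
#'
#' @param path File path.
#' @return `read_variants()`: a variant call tibble; VAF consistency with
#'   the read counts is checked.
#' @export
read_variants <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double(), ref = readr::col_character(),
    alt = readr::col_character(), gene = readr::col_character(),
    effect = readr::col_character(), ref_count = readr::col_integer(),
    alt_count = readr::col_integer(), vaf = readr::col_double(),
    caller_flags = readr::col_character(),
    germline_flagged = readr::col_logical(),
    in_igh = readr::col_logical(),
    cosmic_annotated = readr::col_logical(),
    deleterious_predicted = readr::col_logical()
  ))
  tot <- raw$ref_count + raw$alt_count
  vaf_ok <- ifelse(tot > 0, abs(raw$vaf - raw$alt_count / tot) < 1e-9,
                   is.na(raw$vaf) | raw$vaf == 0)
  bad <- which(!vaf_ok | raw$alt_count < 0 | raw$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (vaf inconsistent with counts)",
                  path, bad[1] + 1L))
  }
  raw
}

#' @rdname read_variants
#' @param calls A variant call tibble.
#' @export
write_variants <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Read and write survival records
#'
#' TSV with `sample_id`, `time`, `event`, `group`.
#'
#' @param path File path.
#' @export
read_survival <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(), time = readr::col_double(),
    event = readr::col_integer(), group = readr::col_character()
  ))
  bad <- which(raw$time <= 0 | !(raw$event %in% c(0L, 1L)))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (time <= 0 or event not 0/1)",
                  path, bad[1] + 1L))
  }
  raw
}

#' @rdname read_survival
#' @param records A survival tibble.
#' @export
write_survival <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read and write per-probe depth tables
#'
#' TSV with `probe_id`, `chrom`, `start`, `end`, `sample_id`, `depth`.
#'
#' @param path File path.
#' @export
read_depths <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    probe_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    sample_id = readr::col_character(), depth = readr::col_double()
  ))
  bad <- which(raw$depth < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (negative depth)", path, bad[1] + 1L))
  }
  raw
}

#' @rdname read_depths
#' @param depths A depth tibble.
#' @export
write_depths <- function(depths, path) {
  readr::write_tsv(depths, path)
  invisible(path)
}
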