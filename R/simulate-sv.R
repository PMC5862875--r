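# Synthetic translocation candidates: true events drawn at canonical
# partner loci, artifact calls scattered at random, both with Poisson
# split-read / discordant-pair support.

#' Canonical translocation region table
#'
#' One row per region used by [classify_translocation()]: the IGH and MYC
#' loci and the canonical partner windows, keyed by translocation label.
#' Coordinates follow GRCh37 gene neighbourhoods (1 Mb windows around the
#' partner oncogene).
#'
#' @return A tibble with columns `label`, `role` (`igh`, `myc`, `partner`),
#'   `chrom`, `start`, `end`.
#' @export
default_region_table <- function() {
  tibble(
    label = c("IGH", "MYC", "t(11;14)", "t(4;14)", "t(8;14)", "t(6;14)",
              "t(14;20)", "t(14;16)", "t(14;22)"),
    role = c("igh", "myc", rep("partner", 7)),
    chrom = c("chr14", "chr8", "chr11", "chr4", "chr8", "chr6", "chr20",
              "chr16", "chr22"),
    start = c(106032614, 128247680, 68955873, 1303099, 128247680, 41334454,
              38783000, 78632868, 22680474),
    end = c(107288051, 129253674, 69969242, 2939993, 129253674, 42334875,
            39783000, 79662868, 23680474)
  )
}

#' Simulate translocation candidates with truth labels
#'
#' True candidates are placed with one breakpoint in the IGH (or MYC) locus
#' and the other in a canonical partner window; artifact candidates join two
#' random positions. Split-read (`sr`) and discordant-pair (`pe`) support
#' counts are Poisson with class-specific rates. With `include_normals`,
#' artifact candidates are also emitted for normal samples, emulating the
#' recurrent artifact calls a panel of normals is used to remove.
#'
#' @param n_true,n_artifact Candidate counts per class (tumors).
#' @param true_sr_rate,true_pe_rate Poisson support rates for true calls.
#' @param artifact_sr_rate,artifact_pe_rate Rates for artifact calls.
#' @param n_samples Number of tumor samples to spread candidates over.
#' @param include_normals Also emit artifact candidates in normal samples.
#' @param region_table Region table, see [default_region_table()].
#' @param seed Integer seed.
#' @return A list: `candidates` (BEDPE-shaped tibble with `sr`, `pe`,
#'   `sample_id`, `is_normal`) and `truth` (per-candidate `candidate_id`,
#'   `is_true`, `class`; plus per-sample true classes in `sample_truth`).
#' @export
simulate_sv_candidates <- function(n_true, n_artifact,
                                   true_sr_rate = 20, true_pe_rate = 20,
                                   artifact_sr_rate = 1, artifact_pe_rate = 1,
                                   n_samples = max(1L, n_true),
                                   include_normals = FALSE,
                                   region_table = default_region_table(),
                                   seed = 1L) {
  stopifnot(n_true >= 0, n_artifact >= 0)
  rates <- c(true_sr_rate, true_pe_rate, artifact_sr_rate, artifact_pe_rate)
  if (any(rates <= 0)) abort("Poisson support rates must be > 0")

  igh <- region_table[region_table$role == "igh", ]
  partners <- region_table[region_table$role == "partner", ]
  chroms <- paste0("chr", 1:22)

  with_seed(substream_seed(seed, "sv"), {
    mk_true <- function(i) {
      p <- partners[sample(nrow(partners), 1), ]
      tibble(
        chrom_a = igh$chrom, pos_a = round(runif(1, igh$start, igh$end)),
        chrom_b = p$chrom, pos_b = round(runif(1, p$start, p$end)),
        class = p$label
      )
    }
    mk_artifact <- function(i) {
      tibble(
        chrom_a = sample(chroms, 1),
        pos_a = round(runif(1, 1, 1.5e8)),
        chrom_b = sample(chroms, 1),
        pos_b = round(runif(1, 1, 1.5e8)),
        class = NA_character_
      )
    }
    true_bp <- if (n_true > 0) purrr::map_dfr(seq_len(n_true), mk_true) else NULL
    n_art_total <- n_artifact + if (include_normals) n_artifact else 0L
    art_bp <- if (n_art_total > 0) {
      purrr::map_dfr(seq_len(n_art_total), mk_artifact)
    }

    cand <- bind_rows(
      if (!is.null(true_bp)) mutate(
        true_bp,
        is_true = TRUE, is_normal = FALSE,
        sr = rpois(n_true, true_sr_rate),
        pe = rpois(n_true, true_pe_rate)
      ),
      if (!is.null(art_bp)) mutate(
        art_bp,
        is_true = FALSE,
        is_normal = rep(c(FALSE, TRUE),
                        c(n_artifact, n_art_total - n_artifact)),
        sr = rpois(n_art_total, artifact_sr_rate),
        pe = rpois(n_art_total, artifact_pe_rate)
      )
    )
    if (is.null(cand) || nrow(cand) == 0) {
      cand <- tibble(chrom_a = character(), pos_a = numeric(),
                     chrom_b = character(), pos_b = numeric(),
                     class = character(), is_true = logical(),
                     is_normal = logical(), sr = integer(), pe = integer())
    }
    cand <- cand |>
      mutate(
        sample_id = sprintf("S%03d", sample(n_samples, n(), replace = TRUE)),
        strand_a = "+", strand_b = "+",
        candidate_id = sprintf("sv%04d", row_number())
      ) |>
      canonical_breakpoint_order()

    truth <- cand |> select("candidate_id", "is_true", "class")
    sample_truth <- cand |>
      dplyr::filter(.data$is_true) |>
      distinct(.data$sample_id, .data$class)
    list(
      candidates = cand |> select(
        "candidate_id", "chrom_a", "pos_a", "strand_a",
        "chrom_b", "pos_b", "strand_b", "sr", "pe",
        "sample_id", "is_normal", "is_true", "class"
      ),
      truth = truth,
      sample_truth = sample_truth
    )
  })
}

# Order breakpoints canonically: lower (chrom rank, position) first.
canonical_breakpoint_order <- function(cand) {
  flip <- chrom_rank(cand$chrom_a) > chrom_rank(cand$chrom_b) |
    (cand$chrom_a == cand$chrom_b & cand$pos_a > cand$pos_b)
  flip[is.na(flip)] <- FALSE
  swap <- function(a, b) {
    tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
    list(a, b)
  }
  ch <- swap(cand$chrom_a, cand$chrom_b)
  po <- swap(cand$pos_a, cand$pos_b)
  st <- swap(cand$strand_a, cand$strand_b)
  cand$chrom_a <- ch[[1]]; cand$chrom_b <- ch[[2]]
  cand$pos_a <- po[[1]]; cand$pos_b <- po[[2]]
  cand$strand_a <- st[[1]]; cand$strand_b <- st[[2]]
  cand
}
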