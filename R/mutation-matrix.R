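# The samples x features binary mutation matrix spanning SNVs, CNVs, and
# translocations, plus hypermutator exclusion.

new_mm_matrix <- function(tbl, feature_types, burden = NULL) {
  structure(tbl, feature_types = feature_types, burden = burden,
            class = c("mm_matrix", class(tbl)))
}

#' Feature metadata of a mutation matrix
#' @param matrix An `mm_matrix`.
#' @return Named character vector of feature types.
#' @export
feature_types <- function(matrix) attr(matrix, "feature_types")

#' Per-sample mutation burden of a mutation matrix
#' @param matrix An `mm_matrix`.
#' @return Tibble `sample_id`, `burden` (mutations per Mb), or `NULL`.
#' @export
mutation_burden <- function(matrix) attr(matrix, "burden")

#' Build the integrative mutation matrix
#'
#' One row per sample, one 0/1 column per feature. An `snv_gene` feature is
#' 1 iff the sample has at least one non-synonymous call (missense,
#' nonsense, frameshift, splice) in the gene; `cnv_arm` features come from
#' arm-event status (`"1q+"` gain, `"13q-"` loss, and `HRD` from the
#' hyperdiploidy flag); `translocation` features from the classified call
#' table. Composite features (e.g. `RAS = KRAS | NRAS`) are ORs of their
#' members, recomputed from member columns. Feature order is deterministic:
#' as declared in `feature_spec`.
#'
#' @param variant_calls Filtered variant calls (`sample_id`, `gene`,
#'   `effect`).
#' @param cnv_arm_events Arm events from [call_arm_events()], or `NULL`.
#' @param translocation_calls Classified calls (`sample_id`, `class`), or
#'   `NULL`.
#' @param feature_spec List with `snv_genes`, `cnv_arms` (labels like
#'   `"1q+"`/`"13q-"`), `translocations`, `composites` (named list of
#'   member gene vectors), `hyperdiploidy` (tibble `sample_id`,
#'   `hyperdiploid`, optional). Defaults are derived from the data
#'   (all observed genes/arms/classes, sorted).
#' @param sample_ids Cohort sample ids (declares samples with no calls).
#' @param panel_mb Panel footprint in Mb, for mutations-per-Mb burden.
#' @return An `mm_matrix` tibble.
#' @export
build_matrix <- function(variant_calls, cnv_arm_events = NULL,
                         translocation_calls = NULL, feature_spec = list(),
                         sample_ids = NULL, panel_mb = 3.3) {
  assert_cols(variant_calls, c("sample_id", "gene", "effect"))
  sample_ids <- sample_ids %||% sort(unique(c(
    variant_calls$sample_id,
    cnv_arm_events$sample_id,
    translocation_calls$sample_id
  )))
  spec <- feature_spec
  spec$snv_genes <- spec$snv_genes %||% sort(unique(variant_calls$gene))
  spec$cnv_arms <- spec$cnv_arms %||% default_arm_features(cnv_arm_events)
  spec$translocations <- spec$translocations %||%
    sort(unique(as.character(translocation_calls$class)))
  spec$composites <- spec$composites %||% list()

  n <- length(sample_ids)
  cols <- list(sample_id = sample_ids)
  types <- character()

  nonsyn <- variant_calls[variant_calls$effect %in% NONSYNONYMOUS_EFFECTS, ]
  for (g in spec$snv_genes) {
    cols[[g]] <- as.integer(sample_ids %in% nonsyn$sample_id[nonsyn$gene == g])
    types[g] <- "snv_gene"
  }
  for (lab in spec$cnv_arms) {
    arm <- substr(lab, 1, nchar(lab) - 1)
    dir <- if (endsWith(lab, "+")) "gain" else "loss"
    hit <- cnv_arm_events$sample_id[cnv_arm_events$arm == arm &
                                      cnv_arm_events$status == dir]
    cols[[lab]] <- as.integer(sample_ids %in% hit)
    types[lab] <- "cnv_arm"
  }
  if (!is.null(spec$hyperdiploidy)) {
    hrd <- spec$hyperdiploidy
    cols[["HRD"]] <- as.integer(
      sample_ids %in% hrd$sample_id[hrd$hyperdiploid]
    )
    types["HRD"] <- "cnv_arm"
  }
  for (cl in spec$translocations) {
    hit <- translocation_calls$sample_id[
      as.character(translocation_calls$class) == cl
    ]
    cols[[cl]] <- as.integer(sample_ids %in% hit)
    types[cl] <- "translocation"
  }
  tbl <- as_tibble(cols)
  for (nm in names(spec$composites)) {
    members <- intersect(spec$composites[[nm]], names(tbl))
    if (length(members) == 0) abort(sprintf(
      "composite feature %s has no member columns in the matrix", nm
    ))
    tbl[[nm]] <- as.integer(rowSums(tbl[members]) > 0)
    types[nm] <- "composite"
  }

  burden <- variant_calls |>
    dplyr::count(.data$sample_id) |>
    dplyr::right_join(tibble(sample_id = sample_ids), by = "sample_id") |>
    mutate(burden = dplyr::coalesce(.data$n, 0L) / panel_mb) |>
    select("sample_id", "burden")

  new_mm_matrix(tbl, feature_types = types, burden = burden)
}

default_arm_features <- function(arm_events) {
  if (is.null(arm_events)) return(character())
  ev <- arm_events[arm_events$status != "none", , drop = FALSE]
  sort(unique(paste0(ev$arm, if_else(ev$status == "gain", "+", "-"))))
}

#' Exclude hypermutator samples from a mutation matrix
#'
#' Drops samples whose mutation burden exceeds the upper Tukey-style fence
#' `Q3 + k * IQR` of the cohort burden (default `k = 3`, an extreme-outlier
#' fence). Any number of samples can be dropped; the rule is not "exactly
#' one". Dropped ids are reported via message and the `dropped_samples`
#' attribute.
#'
#' @param matrix An `mm_matrix` with a burden attribute, or a tibble plus
#'   an explicit `burden` tibble.
#' @param k Fence multiplier on the IQR.
#' @param burden Optional override burden tibble (`sample_id`, `burden`).
#' @return The matrix without hypermutator rows.
#' @export
exclude_hypermutators <- function(matrix, k = 3, burden = NULL) {
  b <- burden %||% mutation_burden(matrix)
  if (is.null(b)) abort("no mutation burden available; pass `burden`")
  fence <- mm_quantile(b$burden, 0.75) +
    k * (mm_quantile(b$burden, 0.75) - mm_quantile(b$burden, 0.25))
  dropped <- b$sample_id[b$burden > fence]
  if (length(dropped) > 0) {
    inform(sprintf("excluding %d hypermutator sample(s): %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- matrix[!(matrix$sample_id %in% dropped), , drop = FALSE]
  attr(out, "feature_types") <- feature_types(matrix)
  attr(out, "burden") <- b[!(b$sample_id %in% dropped), , drop = FALSE]
  attr(out, "dropped_samples") <- dropped
  if (!inherits(out, "mm_matrix")) class(out) <- c("mm_matrix", class(out))
  out
}
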