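# Precision-first tuning of minimal-evidence thresholds for translocation
# candidates, and the panel-of-normals variant used for MYC calls.

new_sv_thresholds <- function(min_sr, min_pe, min_total,
                              precision = NA_real_, recall = NA_real_) {
  structure(
    list(min_sr = as.integer(min_sr), min_pe = as.integer(min_pe),
         min_total = as.integer(min_total),
         achieved_precision = precision, achieved_recall = recall),
    class = "mm_sv_thresholds"
  )
}

#' @export
print.mm_sv_thresholds <- function(x, ...) {
  cat(sprintf(
    "SV thresholds: sr >= %d, pe >= %d, sr+pe >= %d (precision %s, recall %s)\n",
    x$min_sr, x$min_pe, x$min_total,
    format(x$achieved_precision), format(x$achieved_recall)
  ))
  invisible(x)
}

#' @export
tidy.mm_sv_thresholds <- function(x, ...) {
  tibble(min_sr = x$min_sr, min_pe = x$min_pe, min_total = x$min_total,
         achieved_precision = x$achieved_precision,
         achieved_recall = x$achieved_recall)
}

#' Tune evidence thresholds to maximize precision, then recall
#'
#' Exhaustive grid search over `(min_sr, min_pe, min_total)` up to the
#' observed support maxima. The objective is lexicographic: maximize
#' precision, then recall; among optima a componentwise-minimal triple is
#' returned (least aggressive filter with identical performance), realised
#' by taking the lexicographically smallest optimum in the order
#' `(min_total, min_pe, min_sr)` — any strictly smaller optimum would
#' precede it in that order, so the returned triple is minimal. Triples
#' that pass zero candidates are excluded — precision over an empty call
#' set is treated as invalid, not 1.
#'
#' @param candidates Candidate tibble with `sr` and `pe` columns.
#' @param truth Logical vector (or name of a logical column in
#'   `candidates`, default `"is_true"`) marking true candidates.
#' @return An `mm_sv_thresholds` with achieved precision/recall on the
#'   input.
#' @export
tune_thresholds <- function(candidates, truth = "is_true") {
  assert_cols(candidates, c("sr", "pe"))
  lab <- if (is.character(truth) && length(truth) == 1L) {
    assert_cols(candidates, truth)
    candidates[[truth]]
  } else {
    truth
  }
  stopifnot(is.logical(lab), length(lab) == nrow(candidates))
  if (all(lab) || all(!lab)) {
    abort(paste(
      "tuning needs both true and false labels;",
      "use apply_thresholds() with explicit values instead"
    ))
  }
  counts <- threshold_pass_counts(candidates$sr, candidates$pe, lab)
  valid <- counts$n_pass > 0
  precision <- ifelse(valid, counts$n_true_pass / counts$n_pass, NA_real_)
  recall <- counts$n_true_pass / sum(lab)

  p_best <- max(precision[valid])
  at_p <- valid & precision >= p_best - 1e-12
  r_best <- max(recall[at_p])
  opt <- which(at_p & recall >= r_best - 1e-12)
  # lexicographically smallest optimum in (total, pe, sr): any strictly
  # smaller optimum would precede it, so this one is componentwise-minimal
  ord <- order(counts$min_total[opt], counts$min_pe[opt], counts$min_sr[opt])
  best <- opt[ord[1]]
  new_sv_thresholds(counts$min_sr[best], counts$min_pe[best],
                    counts$min_total[best],
                    precision = precision[best], recall = recall[best])
}

# Pass counts for every threshold triple on the full integer grid
# 0..max+1 in each coordinate, via 3D suffix sums over the (sr, pe, total)
# lattice. Returns a tibble with one row per triple.
threshold_pass_counts <- function(sr, pe, lab) {
  nS <- max(sr) + 2L
  nP <- max(pe) + 2L
  nT <- max(sr + pe) + 2L
  tally <- function(keep) {
    arr <- array(0, dim = c(nS, nP, nT))
    idx <- cbind(sr[keep] + 1L, pe[keep] + 1L, sr[keep] + pe[keep] + 1L)
    for (r in seq_len(nrow(idx))) {
      arr[idx[r, 1], idx[r, 2], idx[r, 3]] <-
        arr[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
    }
    # suffix-sum each dimension: arr[a,b,c] = # with sr>=a-1, pe>=b-1, tot>=c-1
    for (a in (nS - 1):1) arr[a, , ] <- arr[a, , ] + arr[a + 1, , ]
    for (b in (nP - 1):1) arr[, b, ] <- arr[, b, ] + arr[, b + 1, ]
    for (cc in (nT - 1):1) arr[, , cc] <- arr[, , cc] + arr[, , cc + 1]
    arr
  }
  all_arr <- tally(rep(TRUE, length(sr)))
  true_arr <- tally(lab)
  grid <- expand.grid(min_sr = 0:(nS - 1L), min_pe = 0:(nP - 1L),
                      min_total = 0:(nT - 1L), KEEP.OUT.ATTRS = FALSE)
  tibble(
    min_sr = as.integer(grid$min_sr),
    min_pe = as.integer(grid$min_pe),
    min_total = as.integer(grid$min_total),
    n_pass = as.vector(all_arr),
    n_true_pass = as.vector(true_arr)
  )
}

#' Apply evidence thresholds to translocation candidates
#'
#' Retains a candidate iff `sr >= min_sr`, `pe >= min_pe`, and
#' `sr + pe >= min_total`. The retained set is monotone non-increasing in
#' each threshold.
#'
#' @param candidates Candidate tibble with `sr`, `pe`.
#' @param thresholds An `mm_sv_thresholds` (or list with `min_sr`,
#'   `min_pe`, `min_total`).
#' @return The retained candidate rows.
#' @export
apply_thresholds <- function(candidates, thresholds) {
  assert_cols(candidates, c("sr", "pe"))
  candidates |>
    dplyr::filter(
      .data$sr >= thresholds$min_sr,
      .data$pe >= thresholds$min_pe,
      .data$sr + .data$pe >= thresholds$min_total
    )
}

#' Tune thresholds against a panel of normals
#'
#' Returns the componentwise-smallest threshold triple under which zero
#' normal-sample candidates are retained; applied to tumor candidates this
#' yields the somatic call set. When several minimal triples exist, the one
#' retaining the most tumor candidates (then lexicographically smallest) is
#' returned.
#'
#' @param candidates Candidate tibble with `sr`, `pe`, `is_normal`.
#' @return An `mm_sv_thresholds`; precision/recall are `NA` (no truth
#'   labels are involved).
#' @export
tune_normal_panel <- function(candidates) {
  assert_cols(candidates, c("sr", "pe", "is_normal"))
  normals <- candidates[candidates$is_normal, ]
  tumors <- candidates[!candidates$is_normal, ]
  if (nrow(normals) == 0) {
    warn("no normal-sample candidates; returning pass-through thresholds (0, 0, 0)")
    return(new_sv_thresholds(0L, 0L, 0L))
  }
  # A minimal zero-leakage triple only takes values 0 or (observed normal
  # support value + 1) in each coordinate, so the grid is restricted there.
  grid <- as.matrix(expand.grid(
    min_sr = sort(unique(c(0L, normals$sr + 1L))),
    min_pe = sort(unique(c(0L, normals$pe + 1L))),
    min_total = sort(unique(c(0L, normals$sr + normals$pe + 1L))),
    KEEP.OUT.ATTRS = FALSE
  ))
  leak <- apply(grid, 1, function(g) {
    sum(normals$sr >= g[1] & normals$pe >= g[2] &
          (normals$sr + normals$pe) >= g[3])
  })
  ok <- grid[leak == 0L, , drop = FALSE]
  kept <- apply(ok, 1, function(g) {
    sum(tumors$sr >= g[1] & tumors$pe >= g[2] &
          (tumors$sr + tumors$pe) >= g[3])
  })
  # most tumor calls retained, then lexicographically smallest in
  # (total, pe, sr): any componentwise-smaller zero-leakage triple retains
  # at least as many tumor calls and precedes in that order, so the
  # returned triple is componentwise-minimal
  ord <- order(-kept, ok[, 3], ok[, 2], ok[, 1])
  best <- ok[ord[1], ]
  new_sv_thresholds(best[1], best[2], best[3])
}
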