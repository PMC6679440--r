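#' Confusion counts between called and true variant sets
#'
#' Treats calls and truth as sets of variant identities and counts true
#' positives, false positives and false negatives by set arithmetic.
#'
#' @param calls,truth Data frames of variant identities; the join uses the
#'   columns in `by` (duplicated rows are collapsed first).
#' @param by Key columns defining variant identity. Defaults to
#'   `chrom`/`pos`/`alt` plus `sample_id` when both tables carry it.
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`.
#' @export
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", pos = 1:4, alt = "T")
#' truth <- tibble::tibble(chrom = "chr1", pos = 3:6, alt = "T")
#' confusion(calls, truth)
confusion <- function(calls, truth, by = NULL) {
  calls <- as_tibble(calls)
  truth <- as_tibble(truth)
  if (is.null(by)) {
    by <- intersect(c("sample_id", "chrom", "pos", "alt"),
                    intersect(names(calls), names(truth)))
    if (length(by) == 0) {
      abort("calls and truth share no key columns; supply `by`")
    }
  }
  calls <- distinct(select(calls, all_of(by)))
  truth <- distinct(select(truth, all_of(by)))
  tp <- nrow(semi_join(calls, truth, by = by))
  tibble(
    tp = tp,
    fp = nrow(calls) - tp,
    fn = nrow(truth) - tp
  )
}

# Round half away from zero; base round() rounds half to even, which is not
# how benchmark percentages are conventionally printed.
round_half_up <- function(x) floor(x + 0.5)

#' Performance measures from confusion counts
#'
#' Computes sensitivity (TPR), precision (PPV), false discovery rate
#' (FDR = 1 - PPV) and the F1 score:
#' `TPR = TP / (TP + FN)`, `PPV = TP / (TP + FP)`,
#' `F1 = 2 * TP / (2 * TP + FP + FN)`.
#' Measures with an undefined denominator are `NA` rather than an error.
#' Integer-percent renderings (rounding half up) are returned alongside the
#' fractions.
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `fn` (from
#'   [confusion()]), or a numeric vector/list with those names.
#' @return A one-row tibble: the counts, fractional `tpr`, `ppv`, `fdr`,
#'   `f1`, and integer-percent `tpr_pct`, `ppv_pct`, `fdr_pct`, `f1_pct`.
#' @export
#' @examples
#' performance(tibble::tibble(tp = 525, fp = 31, fn = 78))
performance <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  if (is.null(tp) || is.null(fp) || is.null(fn)) {
    abort("counts must provide tp, fp and fn")
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  fdr <- if (is.na(ppv)) NA_real_ else 1 - ppv
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  pct <- function(x) if (is.na(x)) NA_real_ else round_half_up(100 * x)
  tibble(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    tpr = tpr, ppv = ppv, fdr = fdr, f1 = f1,
    tpr_pct = pct(tpr), ppv_pct = pct(ppv),
    fdr_pct = pct(fdr), f1_pct = pct(f1)
  )
}
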