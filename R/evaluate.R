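#' Match detected nuclei to ground-truth cells
#'
#' Greedy nearest-centroid matching (closest pairs first) within a
#' distance gate; each detected nucleus and each truth cell is used at
#' most once.
#'
#' @param nuclei tibble from [segment_nuclei()] (columns `nucleus_id`,
#'   `x_um`, `y_um`).
#' @param truth tibble with `cell_id`, `x_um`, `y_um`.
#' @param max_dist_um matching gate (default 5 µm).
#' @return Tibble: `cell_id`, `nucleus_id`, `match_dist_um`.
#' @export
match_cells_to_truth <- function(nuclei, truth, max_dist_um = 5) {
  if (nrow(nuclei) == 0L || nrow(truth) == 0L) {
    return(tibble::tibble(cell_id = integer(0), nucleus_id = integer(0),
                          match_dist_um = numeric(0)))
  }
  d <- outer(truth$x_um, nuclei$x_um, `-`)^2 +
    outer(truth$y_um, nuclei$y_um, `-`)^2
  d <- sqrt(d)
  cand <- which(d <= max_dist_um, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(cell_id = integer(0), nucleus_id = integer(0),
                          match_dist_um = numeric(0)))
  }
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  used_t <- logical(nrow(truth)); used_n <- logical(nrow(nuclei))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ti <- cand[i, 1]; ni <- cand[i, 2]
    if (used_t[ti] || used_n[ni]) next
    used_t[ti] <- TRUE; used_n[ni] <- TRUE
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = truth$cell_id[ti], nucleus_id = nuclei$nucleus_id[ni],
      match_dist_um = d[ti, ni])
  }
  dplyr::bind_rows(rows)
}

#' Classification metrics against ground truth
#'
#' Confusion-matrix summary of nucleus-level marker calls over the matched
#' truth cells: accuracy, sensitivity (recall on truth positives) and
#' specificity (recall on truth negatives), each on the percentage scale,
#' plus the nucleus detection rate.
#'
#' @param calls tibble from [call_marker_on_nuclei()].
#' @param nuclei tibble from [segment_nuclei()].
#' @param truth tibble with `cell_id`, `x_um`, `y_um`, `positive`.
#' @param max_dist_um matching gate passed to [match_cells_to_truth()].
#' @return One-row tibble: `n_truth`, `n_detected`, `n_matched`,
#'   `detection_rate_pct`, `tp`, `tn`, `fp`, `fn`, `accuracy_pct`,
#'   `sensitivity_pct`, `specificity_pct`.
#' @export
classification_metrics <- function(calls, nuclei, truth, max_dist_um = 5) {
  m <- match_cells_to_truth(nuclei, truth, max_dist_um)
  joined <- m |>
    dplyr::inner_join(truth[, c("cell_id", "positive")], by = "cell_id") |>
    dplyr::inner_join(calls[, c("nucleus_id", "positive")],
                      by = "nucleus_id", suffix = c("_truth", "_call"))
  tp <- sum(joined$positive_truth & joined$positive_call)
  tn <- sum(!joined$positive_truth & !joined$positive_call)
  fp <- sum(!joined$positive_truth & joined$positive_call)
  fn <- sum(joined$positive_truth & !joined$positive_call)
  tibble::tibble(
    n_truth = nrow(truth), n_detected = nrow(nuclei), n_matched = nrow(m),
    detection_rate_pct = 100 * nrow(m) / nrow(truth),
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy_pct = 100 * (tp + tn) / max(1L, nrow(joined)),
    sensitivity_pct = 100 * tp / max(1L, tp + fn),
    specificity_pct = 100 * tn / max(1L, tn + fp))
}
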