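#' Relative quantification by the 2^-ddCt method
#'
#' ddCt = (Ct_target - Ct_reference)_test - (Ct_target - Ct_reference)_calibrator;
#' the fold change of the target in the test sample relative to the
#' calibrator, each normalized to the internal-control gene (beta-actin
#' role), is 2^-ddCt. Vectorized.
#'
#' @param ct_target_test,ct_ref_test Threshold cycles of target and
#'   reference gene in the test sample.
#' @param ct_target_cal,ct_ref_cal Threshold cycles in the calibrator
#'   sample.
#' @return Fold change(s), positive numeric.
#' @export
#' @examples
#' ddct_fold_change(25, 20, 24, 20) # 0.5
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_cal, ct_ref_cal) {
  args <- list(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal)
  if (any(vapply(args, function(a) any(is.na(a) | !is.finite(a) | a <= 0),
                 logical(1)))) {
    abort("Ct values must be positive and finite")
  }
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Per-replicate qPCR fold changes
#'
#' Takes a tidy table of threshold cycles with one or more technical
#' measurements per (replicate, condition): Ct values are first averaged
#' within each replicate x condition (the conventional handling of technical
#' triplicates), each biological replicate's fold change is computed with
#' [ddct_fold_change()] against its own calibrator measurement, and fold
#' changes are then summarized across replicates.
#'
#' @param records Tibble with columns `replicate`, `condition` (`"test"` or
#'   `"calibrator"`), `ct_target`, `ct_reference`.
#' @return An object of class `qpcr_result`: tibble of per-replicate fold
#'   changes; [glance()] gives their mean and standard deviation.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   replicate = rep(1:3, each = 2),
#'   condition = rep(c("test", "calibrator"), 3),
#'   ct_target = c(22, 25, 21.8, 24.9, 22.1, 25.2),
#'   ct_reference = c(20, 20, 20.1, 20, 19.9, 20.1)
#' )
#' glance(qpcr_fold_changes(recs))
qpcr_fold_changes <- function(records) {
  needed <- c("replicate", "condition", "ct_target", "ct_reference")
  if (!all(needed %in% names(records))) {
    abort(paste0("records must have columns ", paste(needed, collapse = ", ")))
  }
  if (!all(records$condition %in% c("test", "calibrator"))) {
    abort("condition must be 'test' or 'calibrator'")
  }
  avg <- records |>
    dplyr::group_by(.data$replicate, .data$condition) |>
    dplyr::summarise(ct_target = mean(.data$ct_target),
                     ct_reference = mean(.data$ct_reference),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(avg, names_from = "condition",
                             values_from = c("ct_target", "ct_reference"))
  if (anyNA(wide)) abort("every replicate needs both a test and a calibrator record")
  out <- tibble(
    replicate = wide$replicate,
    fold_change = ddct_fold_change(wide$ct_target_test,
                                   wide$ct_reference_test,
                                   wide$ct_target_calibrator,
                                   wide$ct_reference_calibrator)
  )
  structure(out, class = c("qpcr_result", class(out)))
}
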