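#' Cross-tabulate a predicted mask against ground truth
#'
#' Per-pixel confusion counts of a binary prediction against a binary truth
#' mask (foreground = 1).  Multi-class label maps should be reduced to
#' one-vs-rest binary masks for the class of interest first.
#'
#' @param pred,truth binary 0/1 matrices of equal shape (logical accepted).
#' @return An object of class `"confusion"`: list with integer `TP`, `FP`,
#'   `TN`, `FN` summing to the pixel count.
#' @export
confusion <- function(pred, truth) {
  pred <- as_binary_matrix(pred, "pred")
  truth <- as_binary_matrix(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` must share dimensions")
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 FP = sum(pred == 1L & truth == 0L),
                 TN = sum(pred == 0L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  s <- tryCatch(seg_scores(x), error = function(e) NULL)
  if (!is.null(s))
    cat(sprintf("  TPR %.1f %%  SPC %.1f %%  ACC %.1f %%\n",
                s["TPR"], s["SPC"], s["ACC"]))
  invisible(x)
}

#' Sensitivity, specificity and balanced accuracy
#'
#' `TPR = 100 * TP / (TP + FN)` (sensitivity),
#' `SPC = 100 * TN / (TN + FP)` (specificity) and the balanced accuracy
#' `ACC = (TPR + SPC) / 2`, all in percent.  Balanced accuracy weighs both
#' classes equally, so it is robust to the foreground/background imbalance
#' typical of segmentation masks.
#'
#' @param x a `"confusion"` from [confusion()], or a list with fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `c(TPR, SPC, ACC)` in percent.
#' @examples
#' seg_scores(list(TP = 88, FN = 12, TN = 92, FP = 8))   # ACC 90 %
#' @export
seg_scores <- function(x) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(x)))
    stop("`x` must carry TP, FP, TN and FN counts")
  if (x$TP + x$FN == 0)
    stop("sensitivity undefined: no positive pixels in the ground truth")
  if (x$TN + x$FP == 0)
    stop("specificity undefined: no negative pixels in the ground truth")
  tpr <- 100 * x$TP / (x$TP + x$FN)
  spc <- 100 * x$TN / (x$TN + x$FP)
  c(TPR = tpr, SPC = spc, ACC = (tpr + spc) / 2)
}
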