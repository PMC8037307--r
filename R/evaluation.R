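# Correction-accuracy metrics and statistical comparison, plus ground-truth
# field-error metrics that exist only for synthetic data.

#' Score a corrected reversed-PE pair
#'
#' LNCC similarity of the uncorrected and the corrected pair with a common
#' window, the accuracy measure used throughout evaluation.
#'
#' @param i1,i2 uncorrected volumes.
#' @param e1,e2 corrected volumes.
#' @param window odd LNCC window edge length.
#' @return list of class `sac_pair_score` with `lncc_uncorrected`,
#'   `lncc_corrected`.
#' @export
score_pair <- function(i1, i2, e1, e2, window = 9L) {
  structure(list(lncc_uncorrected = lncc(i1, i2, window),
                 lncc_corrected = lncc(e1, e2, window)),
            class = "sac_pair_score")
}

#' Paired t test on accuracy scores
#'
#' Classical paired t test on the per-pair differences with `n - 1` degrees
#' of freedom.  When the differences have zero variance (e.g. identical
#' score lists) the test statistic is undefined; the result is flagged
#' `degenerate` instead of dividing by zero.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 3).
#' @return list with `t`, `p` (two-sided), `df`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 3)
  d <- scores_a - scores_b
  n <- length(d)
  if (sd(d) == 0)
    return(list(t = 0, p = NA_real_, df = n - 1L, degenerate = TRUE))
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Field error against a known ground truth
#'
#' Mean per-voxel Euclidean norm of `predicted - truth` within the mask
#' (endpoint error, voxels) and the Pearson correlation of the
#' phase-encoding components within the mask.
#'
#' @param predicted,truth displacement fields of equal extents.
#' @param mask binary volume (nonzero = evaluate here).
#' @param pe_axis phase-encoding axis for the component correlation.
#' @return list of class `sac_field_error` with `mean_endpoint_error`,
#'   `pe_component_correlation`.
#' @export
field_error <- function(predicted, truth, mask, pe_axis = c("y", "x", "z")) {
  pe_axis <- match.arg(pe_axis)
  up <- as_field_array(predicted)
  ut <- as_field_array(truth)
  if (!all(dim(up) == dim(ut)))
    stop("field extents must agree", call. = FALSE)
  m <- as_vol_array(mask) != 0
  if (!any(m)) stop("mask selects no voxels", call. = FALSE)
  diff2 <- (up[, , , 1] - ut[, , , 1])^2 + (up[, , , 2] - ut[, , , 2])^2 +
    (up[, , , 3] - ut[, , , 3])^2
  pe <- match(pe_axis, c("x", "y", "z"))
  pcor <- cor(up[, , , pe][m], ut[, , , pe][m])
  structure(list(mean_endpoint_error = mean(sqrt(diff2[m])),
                 pe_component_correlation = pcor),
            class = "sac_field_error")
}

#' Summarize pair scores as a delimited table
#'
#' One row per pair plus a trailing summary row (mean and sd), shaped like
#' the accuracy tables the method is reported with.
#'
#' @param scores list of [score_pair()] results.
#' @param path optional file to write the tab-delimited table to.
#' @return data frame, invisibly when `path` is given.
#' @export
score_table <- function(scores, path = NULL) {
  df <- data.frame(
    pair = seq_along(scores),
    lncc_uncorrected = vapply(scores, `[[`, numeric(1), "lncc_uncorrected"),
    lncc_corrected = vapply(scores, `[[`, numeric(1), "lncc_corrected"))
  summary <- data.frame(
    pair = NA_integer_,
    lncc_uncorrected = mean(df$lncc_uncorrected),
    lncc_corrected = mean(df$lncc_corrected))
  out <- rbind(df, summary)
  out$row <- c(as.character(df$pair), "mean")
  out <- out[, c("row", "lncc_uncorrected", "lncc_corrected")]
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
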