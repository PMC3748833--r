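pair_keys <- function(structure) {
  p <- structure$pairs
  if (nrow(p) == 0L) character(0) else paste(p[, 1L], p[, 2L])
}

#' Classify predicted base pairs against a reference structure
#'
#' Exact set arithmetic on the two pair sets: true positives occur in both
#' the reference (comparative) and the predicted structure, false
#' negatives only in the reference, false positives only in the
#' prediction.
#'
#' @param predicted,reference [secondary_structure] objects on the same
#'   sequence length.
#' @return A list of two-column integer matrices `TP`, `FP`, `FN`.
#' @export
classify_pairs <- function(predicted, reference) {
  stopifnot(inherits(predicted, "secondary_structure"),
            inherits(reference, "secondary_structure"))
  if (predicted$n != reference$n) {
    stop(sprintf("structures have different lengths (%d vs %d)", predicted$n, reference$n),
         call. = FALSE)
  }
  kp <- pair_keys(predicted)
  kr <- pair_keys(reference)
  sel <- function(st, keep) st$pairs[pair_keys(st) %in% keep, , drop = FALSE]
  list(TP = sel(predicted, intersect(kp, kr)),
       FP = sel(predicted, setdiff(kp, kr)),
       FN = sel(reference, setdiff(kr, kp)))
}

#' Count compatible false-positive pairs
#'
#' A false-positive pair is *compatible* with the reference structure —
#' and hence neutral with respect to accuracy — when it could exist in the
#' reference: adding the pair alone to the reference pair set violates
#' none of position uniqueness, non-crossing, or the hairpin bound `h`.
#' Each false-positive pair is tested independently.
#'
#' @param fp Two-column matrix of false-positive pairs (as from
#'   [classify_pairs()]).
#' @param reference The reference [secondary_structure].
#' @param h Minimum hairpin loop size (default 3).
#' @return The count `xi`, an integer in `0..nrow(fp)`.
#' @export
compatible_count <- function(fp, reference, h = 3L) {
  stopifnot(inherits(reference, "secondary_structure"))
  fp <- as.matrix(fp)
  if (length(fp) == 0L) return(0L)
  storage.mode(fp) <- "integer"
  ref <- reference$pairs
  used <- logical(reference$n)
  used[c(ref)] <- TRUE
  xi <- 0L
  for (r in seq_len(nrow(fp))) {
    i <- fp[r, 1L]; j <- fp[r, 2L]
    if (j - i - 1L < h) next
    if (used[i] || used[j]) next
    crosses <- any((ref[, 1L] < i & i < ref[, 2L] & ref[, 2L] < j) |
                     (i < ref[, 1L] & ref[, 1L] < j & j < ref[, 2L]))
    if (!crosses) xi <- xi + 1L
  }
  xi
}

#' Sensitivity and selectivity of a predicted structure
#'
#' Base-pair prediction accuracy against a reference (comparative)
#' structure: `sensitivity = TP / (TP + FN)` and
#' `selectivity = TP / (TP + (FP - xi))`, where `xi` counts
#' false-positive pairs compatible with the reference (see
#' [compatible_count()]). A ratio with a zero denominator is reported as
#' `NA` and flagged in the `*_defined` fields rather than propagated as
#' `NaN`.
#'
#' @inheritParams classify_pairs
#' @param h Minimum hairpin loop size used for the compatibility test.
#' @return An object of class `accuracy_report` with fields `tp`, `fn`,
#'   `fp`, `xi`, `sensitivity`, `selectivity`, `sensitivity_defined`,
#'   `selectivity_defined`, `n`. [tidy()] returns it as a one-row tibble.
#' @examples
#' ref <- from_dotbracket("((((....))))")
#' prd <- from_dotbracket("(((......)))")
#' accuracy_report(prd, ref)
#' @export
accuracy_report <- function(predicted, reference, h = 3L) {
  cls <- classify_pairs(predicted, reference)
  tp <- nrow(cls$TP); fp <- nrow(cls$FP); fn <- nrow(cls$FN)
  xi <- compatible_count(cls$FP, reference, h = h)
  sens_def <- (tp + fn) > 0L
  sel_def <- (tp + fp - xi) > 0L
  structure(
    list(tp = tp, fn = fn, fp = fp, xi = xi,
         sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
         selectivity = if (sel_def) tp / (tp + (fp - xi)) else NA_real_,
         sensitivity_defined = sens_def,
         selectivity_defined = sel_def,
         n = predicted$n),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> TP = %d, FN = %d, FP = %d, xi = %d\n",
              x$tp, x$fn, x$fp, x$xi))
  cat(sprintf("  sensitivity = %s, selectivity = %s\n",
              if (x$sensitivity_defined) sprintf("%.4f", x$sensitivity) else "undefined",
              if (x$selectivity_defined) sprintf("%.4f", x$selectivity) else "undefined"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname accuracy_report
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble::tibble(n = x$n, tp = x$tp, fn = x$fn, fp = x$fp, xi = x$xi,
                 sensitivity = x$sensitivity, selectivity = x$selectivity)
}

#' @rdname accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) tidy(x, ...)

#' Batch accuracy over pairs of structures
#'
#' Per-sequence sensitivity/selectivity rows plus the summary point
#' (arithmetic mean selectivity, mean sensitivity) over sequences, the
#' presentation used for accuracy scatter plots in the folding literature.
#'
#' @param predicted,reference Lists of [secondary_structure] objects of
#'   equal length (optionally named).
#' @param h Minimum hairpin loop size.
#' @return A tibble with one row per sequence (columns `name`, `n`, `tp`,
#'   `fn`, `fp`, `xi`, `sensitivity`, `selectivity`) and attributes
#'   `mean_sensitivity`, `mean_selectivity` (means over defined values).
#' @export
accuracy_table <- function(predicted, reference, h = 3L) {
  stopifnot(length(predicted) == length(reference))
  nms <- names(predicted) %||% sprintf("seq_%d", seq_along(predicted))
  rows <- lapply(seq_along(predicted), function(k) {
    r <- tidy(accuracy_report(predicted[[k]], reference[[k]], h = h))
    tibble::add_column(r, name = nms[k], .before = 1L)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_sensitivity") <- mean(out$sensitivity, na.rm = TRUE)
  attr(out, "mean_selectivity") <- mean(out$selectivity, na.rm = TRUE)
  out
}
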