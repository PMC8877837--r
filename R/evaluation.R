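#' Confusion counts and classification metrics
#'
#' The positive class throughout is `isLy` (lying): `tp` counts correct
#' lying classifications, `tn` correct not-lying classifications, `fp`
#' not-lying frames classified as lying, and `fn` lying frames classified as
#' not-lying.  Specificity is therefore the not-lying detection rate.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d, TN %d, FP %d, FN %d>\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' @rdname confusion_counts
#' @param truth,predicted character vectors of labels in
#'   `{"isLy", "notLy"}`, equal length.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  ok <- c("isLy", "notLy")
  bad <- setdiff(unique(c(truth, predicted)), ok)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  confusion_counts(tp = sum(truth == "isLy" & predicted == "isLy"),
                   tn = sum(truth == "notLy" & predicted == "notLy"),
                   fp = sum(truth == "notLy" & predicted == "isLy"),
                   fn = sum(truth == "isLy" & predicted == "notLy"))
}

#' Accuracy, precision, recall and specificity
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `PRE = TP/(TP+FP)`, `REC = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`.  A metric whose denominator is zero is reported as
#' `NA` (undefined), never as an error.
#'
#' @param x a [confusion_counts()].
#' @return named numeric vector `c(acc, pre, rec, spe)`.
#' @export
#' @examples
#' metrics(confusion_counts(7303, 1968, 405, 149))["acc"]  # 0.944...
metrics <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  total <- x$tp + x$tn + x$fp + x$fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(acc = ratio(x$tp + x$tn, total),
    pre = ratio(x$tp, x$tp + x$fp),
    rec = ratio(x$tp, x$tp + x$fn),
    spe = ratio(x$tn, x$tn + x$fp))
}

#' Round half away from zero
#'
#' Published metric tables use conventional half-up rounding; base R rounds
#' half to even, so table comparisons go through this helper.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3, the printed precision).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Published depth-camera benchmark counts
#'
#' Confusion counts and the printed evaluation metrics from the original
#' UR Fall Detection Dataset study of this system (9825 test frames):
#' the classic engine under five premise aggregations, the
#' knowledge-augmented engine under the five `K1`-`K5` operator presets on
#' the full (81-rule) and LEM2-reduced (44-rule) sets, and the comparison of
#' the precedence-based knowledge measure against the two literature
#' measures `K_SLS` and `K_AK`.  Metrics are stored as printed (character),
#' preserving each cell's decimal precision; recomputing them from the
#' counts with [metrics()] reproduces almost every cell at its printed
#' precision (a few cells carry a one-unit slip in the last printed digit).
#'
#' @return data.frame with columns `table` (`classic`/`knowledge`/
#'   `measures`), `config`, `ruleset` (`all`/`reduced`), `tp`, `tn`, `fp`,
#'   `fn`, and printed `acc`, `pre`, `rec`, `spe`.
#' @export
reference_results <- function() {
  long <- rbind(
    data.frame(table = "classic", ruleset = "all",
               config = c("Tm", "Tp", "Amean", "OWA", "F"),
               tp = c(7303, 7303, 7420, 7375, 7420),
               tn = c(1968, 1968, 2069, 2056, 1969),
               fp = c(405, 405, 304, 317, 404),
               fn = c(149, 149, 32, 77, 32),
               acc = c("0.944", "0.944", "0.966", "0.960", "0.956"),
               pre = c("0.947", "0.947", "0.961", "0.959", "0.948"),
               rec = c("0.980", "0.980", "0.996", "0.990", "0.996"),
               spe = c("0.829", "0.829", "0.872", "0.866", "0.830"),
               stringsAsFactors = FALSE),
    data.frame(table = "knowledge",
               ruleset = rep(c("all", "reduced"), 5),
               config = rep(c("K1", "K2", "K3", "K4", "K5"), each = 2),
               tp = c(7443, 7446, 7442, 7446, 7430, 7445, 7440, 7446,
                      7440, 7445),
               tn = c(2066, 1938, 2076, 1956, 2083, 1939, 2063, 1961,
                      2064, 1985),
               fp = c(307, 435, 297, 417, 290, 434, 310, 412, 309, 388),
               fn = c(9, 6, 10, 6, 22, 7, 12, 6, 12, 7),
               acc = c("0.968", "0.956", "0.969", "0.957", "0.968",
                       "0.956", "0.967", "0.957", "0.967", "0.96"),
               pre = c("0.960", "0.945", "0.962", "0.947", "0.962",
                       "0.945", "0.96", "0.948", "0.96", "0.95"),
               rec = c("0.999", "0.999", "0.999", "0.999", "0.997",
                       "0.999", "0.999", "0.999", "0.999", "0.999"),
               spe = c("0.871", "0.817", "0.875", "0.824", "0.878",
                       "0.818", "0.869", "0.826", "0.87", "0.84"),
               stringsAsFactors = FALSE),
    data.frame(table = "measures", ruleset = "all",
               config = c("K", "KSLS", "KAK"),
               tp = c(7442, 7434, 7444),
               tn = c(2076, 2026, 2064),
               fp = c(297, 347, 309),
               fn = c(10, 18, 8),
               acc = c("0.969", "0.963", "0.968"),
               pre = c("0.962", "0.956", "0.960"),
               rec = c("0.999", "0.998", "0.999"),
               spe = c("0.875", "0.854", "0.870"),
               stringsAsFactors = FALSE))
  rownames(long) <- NULL
  long
}

#' Cross-check recomputed metrics against the printed benchmark cells
#'
#' For every configuration in [reference_results()] the four metrics are
#' recomputed from the confusion counts and rounded half-up to each cell's
#' printed precision.
#'
#' @return data.frame with one row per cell: `table`, `config`, `ruleset`,
#'   `metric`, `printed`, `recomputed`, `digits`, `match` (exact at printed
#'   precision) and `abs_diff` (|printed - rounded recomputed|).
#' @export
check_reference_metrics <- function() {
  ref <- reference_results()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    m <- metrics(confusion_counts(ref$tp[i], ref$tn[i], ref$fp[i],
                                  ref$fn[i]))
    do.call(rbind, lapply(c("acc", "pre", "rec", "spe"), function(met) {
      printed_chr <- ref[[met]][i]
      digits <- nchar(sub("^[0-9]*\\.", "", printed_chr))
      printed <- as.numeric(printed_chr)
      rec <- round_half_up(m[[met]], digits)
      data.frame(table = ref$table[i], config = ref$config[i],
                 ruleset = ref$ruleset[i], metric = met,
                 printed = printed, recomputed = m[[met]],
                 digits = digits, match = isTRUE(all.equal(rec, printed)),
                 abs_diff = abs(rec - printed),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
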