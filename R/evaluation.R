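# Evaluation against simulated ground truth: coordinate-based labelling,
# confusion counts, precision/sensitivity, the aligner-MAPQ baseline and
# threshold sweeps.

#' Parse ground truth from encoded read names
#'
#' The simulator encodes each read's origin in its name as
#' `read<i>!<target>!<start>!<strand>`; this extracts the truth table.
#'
#' @param read_names character vector of encoded names.
#' @return data.frame of class `ground_truth` with columns `read_name`,
#'   `target`, `start` (0-based forward-strand origin), `strand`.
#' @export
truth_from_names <- function(read_names) {
  parts <- strsplit(read_names, "!", fixed = TRUE)
  ok <- lengths(parts) == 4L
  if (!all(ok))
    stop(sprintf("read name '%s' does not encode an origin", read_names[!ok][1L]))
  out <- data.frame(read_name = read_names,
                    target = vapply(parts, `[[`, character(1), 2L),
                    start = as.integer(vapply(parts, `[[`, character(1), 3L)),
                    strand = vapply(parts, `[[`, character(1), 4L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$read_name)) stop("duplicate read names in truth")
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Write / read a truth table as TSV
#'
#' @param truth a `ground_truth` data.frame.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Label alignments as correct or false-positive against ground truth
#'
#' An alignment is a false positive when it places the read on a
#' different target than its origin, or when the absolute difference
#' between the alignment's target start and the true start exceeds the
#' tolerance (strictly greater than; the conventional tolerances are
#' 10 bp for HiFi and 30 bp for ONT alignments, matching each
#' technology's start-coordinate jitter). Reads absent from the truth
#' table are labelled `NA` with a warning.
#'
#' @param records a `paf` data.frame.
#' @param truth a `ground_truth` data.frame.
#' @param tolerance maximum allowed start-coordinate difference (bp).
#' @return Character vector (`"correct"` / `"false_positive"` / `NA`),
#'   one element per alignment record.
#' @export
label_alignments <- function(records, truth, tolerance = 10) {
  i <- match(records$query_name, truth$read_name)
  if (anyNA(i))
    warning(sprintf("%d alignment(s) of reads absent from truth left unlabeled",
                    sum(is.na(i))))
  fp <- records$target_name != truth$target[i] |
    abs(records$target_start - truth$start[i]) > tolerance
  ifelse(is.na(i), NA_character_,
         ifelse(fp, "false_positive", "correct"))
}

#' Confusion counts for a filtering run
#'
#' TP: false-positive alignments that were removed (correct detections);
#' FP: correct alignments wrongly removed; FN: false-positive alignments
#' left in the kept set. Unlabeled records are excluded.
#'
#' @param labels labels from [label_alignments()].
#' @param removed logical vector, `TRUE` where the filter removed the
#'   record; same length as `labels`.
#' @return List of class `eval_counts` with `TP`, `FP`, `FN`.
#' @export
score_confusion <- function(labels, removed) {
  if (length(labels) != length(removed))
    stop("labels and filter decisions cover different record sets")
  ok <- !is.na(labels)
  labels <- labels[ok]
  removed <- removed[ok]
  structure(list(TP = sum(labels == "false_positive" & removed),
                 FP = sum(labels == "correct" & removed),
                 FN = sum(labels == "false_positive" & !removed)),
            class = "eval_counts")
}

#' Precision and sensitivity from confusion counts
#'
#' `precision = TP / (TP + FP)`; `sensitivity = TP / (TP + FN)`.
#' A zero denominator yields `NA` (undefined), not an error.
#'
#' @param counts an `eval_counts` list (fields `TP`, `FP`, `FN`).
#' @return List of class `eval_metrics` with `precision`, `sensitivity`
#'   and the counts.
#' @export
compute_metrics <- function(counts) {
  p <- if ((counts$TP + counts$FP) == 0) NA_real_
       else counts$TP / (counts$TP + counts$FP)
  s <- if ((counts$TP + counts$FN) == 0) NA_real_
       else counts$TP / (counts$TP + counts$FN)
  structure(list(precision = p, sensitivity = s,
                 TP = counts$TP, FP = counts$FP, FN = counts$FN),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("TP = %d, FP = %d, FN = %d\nprecision = %s, sensitivity = %s\n",
              x$TP, x$FP, x$FN,
              ifelse(is.na(x$precision), "undefined", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$sensitivity), "undefined", sprintf("%.4f", x$sensitivity))))
  invisible(x)
}

#' Aligner-MAPQ baseline filter
#'
#' Removes alignments whose aligner-assigned MAPQ (PAF column 12) is
#' strictly below the threshold — the conventional quality filter that
#' kMAPQ filtering is compared against.
#'
#' @param records a `paf` data.frame.
#' @param mapq_threshold MAPQ cutoff.
#' @return Logical `removed` vector.
#' @export
mapq_baseline <- function(records, mapq_threshold) {
  records$mapq < mapq_threshold
}

#' Sweep kMAPQ thresholds and tabulate accuracy
#'
#' Applies [filter_by_threshold()] at each threshold and tabulates
#' removal counts, confusion counts, precision and sensitivity.
#'
#' @param scored scored `paf` data.frame.
#' @param labels labels from [label_alignments()] for the same (sorted)
#'   records.
#' @param thresholds numeric vector of thresholds.
#' @param convention see [filter_by_threshold()].
#' @return data.frame with one row per threshold.
#' @export
sweep_thresholds <- function(scored, labels, thresholds = seq(0, 60, by = 2),
                             convention = "printed") {
  rows <- lapply(thresholds, function(t) {
    removed <- filter_by_threshold(scored, t, convention)$removed_mask
    m <- compute_metrics(score_confusion(labels, removed))
    data.frame(threshold = t, removed = sum(removed), TP = m$TP, FP = m$FP,
               FN = m$FN, precision = m$precision, sensitivity = m$sensitivity)
  })
  do.call(rbind, rows)
}
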