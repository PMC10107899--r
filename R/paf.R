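# PAF alignment input/output and target-sorted processing order.

.PAF_COLS <- c("query_name", "query_length", "query_start", "query_end",
               "strand", "target_name", "target_length", "target_start",
               "target_end", "residue_matches", "block_length", "mapq")
.PAF_INT_COLS <- c("query_length", "query_start", "query_end",
                   "target_length", "target_start", "target_end",
                   "residue_matches", "block_length", "mapq")

#' Read alignments from a PAF file
#'
#' Parses the 12 mandatory tab-separated PAF columns (0-based half-open
#' coordinates on query and target) and keeps any further columns as
#' uninterpreted `XX:T:value` tag strings, preserved verbatim on output.
#' Gzipped input is read transparently.
#'
#' @param path PAF file path.
#' @return A data.frame of class `paf` with one row per alignment: the 12
#'   standard columns plus a `tags` list-column of character vectors.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[[1L]]
    stop(errorCondition(
      sprintf("PAF parse error at line %d: %d columns (need >= 12)", bad, nf[bad]),
      class = c("kmapq_paf_parse", "error", "condition")))
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12L)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- .PAF_COLS
  for (col in .PAF_INT_COLS) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[[1L]]
      stop(errorCondition(
        sprintf("PAF parse error at line %d: non-integer '%s'", bad, col),
        class = c("kmapq_paf_parse", "error", "condition")))
    }
    df[[col]] <- v
  }
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- which(!df$strand %in% c("+", "-"))[[1L]]
    stop(errorCondition(
      sprintf("PAF parse error at line %d: strand must be '+' or '-'", bad),
      class = c("kmapq_paf_parse", "error", "condition")))
  }
  df$tags <- lapply(fields, function(f) if (length(f) > 12L) f[-(1:12)] else character(0))
  class(df) <- c("paf", "data.frame")
  df
}

.paf_lines <- function(df, extra_tags = NULL) {
  base <- do.call(paste, c(unname(df[.PAF_COLS]), list(sep = "\t")))
  tagstr <- vapply(seq_len(nrow(df)), function(i) {
    tg <- df$tags[[i]]
    if (!is.null(extra_tags)) tg <- c(tg, extra_tags[[i]])
    if (length(tg)) paste0("\t", paste(tg, collapse = "\t")) else ""
  }, character(1L))
  paste0(base, tagstr)
}

#' Write alignments to a PAF file
#'
#' Inverse of [read_paf()]: original columns and tags round-trip
#' byte-identically.
#'
#' @param records a `paf` data.frame.
#' @param path output path.
#' @export
write_paf <- function(records, path) {
  writeLines(.paf_lines(records), path)
  invisible(path)
}

#' Sort alignments by reference for single-load processing
#'
#' Stable sort by `(target_name, target_start)`; alignments on the same
#' reference become contiguous, so the reference occurrence list need only
#' be loaded once per reference (see [sublist_for_reference()]). Records
#' with equal keys keep their input order.
#'
#' @param records a `paf` data.frame.
#' @return The sorted `paf` data.frame.
#' @export
sort_by_target <- function(records) {
  ord <- order(records$target_name, records$target_start, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write scored alignments, partitioned into kept and removed files
#'
#' Each scorable record gains the tags `km:f:<kMAPQ>`, `kl:i:<l_LIS>`,
#' `kr:i:<l_r>` and `kq:i:<l_q>`; unscorable records (an aligned interval
#' with no rare k-mers, or a sequence missing from a database) instead
#' carry the sentinel tag `ks:i:0` and are always written to the kept
#' file. With a threshold the records are partitioned by
#' [filter_by_threshold()]; without one everything goes to the kept file
#' with scores attached.
#'
#' @param scored a scored `paf` data.frame from [score_paf()].
#' @param kept_path,removed_path output paths.
#' @param threshold optional kMAPQ threshold; `NULL` keeps everything.
#' @param convention filtering convention, see [filter_by_threshold()].
#' @return Invisibly, the logical `removed` vector used for the partition.
#' @export
write_scored_paf <- function(scored, kept_path, removed_path,
                             threshold = NULL, convention = "printed") {
  removed <- if (is.null(threshold)) rep(FALSE, nrow(scored))
             else filter_by_threshold(scored, threshold, convention)$removed_mask
  extra <- lapply(seq_len(nrow(scored)), function(i) {
    if (isTRUE(scored$scorable[i]))
      c(sprintf("km:f:%.4f", scored$kmapq[i]),
        sprintf("kl:i:%d", scored$l_lis[i]),
        sprintf("kr:i:%d", scored$l_r[i]),
        sprintf("kq:i:%d", scored$l_q[i]))
    else "ks:i:0"
  })
  lines <- .paf_lines(scored, extra)
  writeLines(lines[!removed], kept_path)
  writeLines(lines[removed], removed_path)
  invisible(removed)
}
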