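# kMAPQ scoring: match shared rare k-mers between the aligned reference
# and query intervals, measure their collinearity by the longest strictly
# increasing subsequence of reference positions taken in query order, and
# convert the LIS fraction to a phred-like score.

#' Match rare k-mers common to a reference and a query sublist
#'
#' Forms one `(ref_position, qry_position)` pair per canonical code that
#' occurs exactly once in each sublist. Codes occurring 2..m times inside
#' one interval are ambiguous to pair and are excluded from matching
#' (they still count toward the sublist lengths `l_r` and `l_q`). Pairs
#' are returned ordered by query position.
#'
#' @param ref_sub,qry_sub occurrence data.frames (columns `pos`, `code`,
#'   `orient`), sorted by `pos`, from [extract_sublist()] /
#'   [sublist_for_query()].
#' @return data.frame with columns `ref_pos`, `qry_pos`, `code`, ordered
#'   by `qry_pos`.
#' @export
match_common <- function(ref_sub, qry_sub) {
  rcode <- ref_sub$code
  qcode <- qry_sub$code
  runiq <- !(duplicated(rcode) | duplicated(rcode, fromLast = TRUE))
  quniq <- !(duplicated(qcode) | duplicated(qcode, fromLast = TRUE))
  common <- intersect(rcode[runiq], qcode[quniq])
  if (length(common) == 0L)
    return(data.frame(ref_pos = integer(0), qry_pos = integer(0),
                      code = character(0), stringsAsFactors = FALSE))
  ri <- match(common, rcode)
  qi <- match(common, qcode)
  ord <- order(qry_sub$pos[qi])
  data.frame(ref_pos = ref_sub$pos[ri][ord],
             qry_pos = qry_sub$pos[qi][ord],
             code = common[ord], stringsAsFactors = FALSE)
}

#' Reference-position sequence of common k-mers in query order
#'
#' Emits the reference positions of the matched pairs in the order the
#' k-mers appear along the query; for a reverse-strand alignment the
#' query order is reversed first, so that a collinear alignment always
#' yields an increasing sequence.
#'
#' @param pairs matched pairs from [match_common()] (ordered by
#'   `qry_pos`).
#' @param strand alignment strand, `"+"` or `"-"`.
#' @return Integer vector of reference positions.
#' @export
build_position_sequence <- function(pairs, strand = "+") {
  s <- pairs$ref_pos
  if (identical(strand, "-")) s <- rev(s)
  as.integer(s)
}

#' Length of the longest strictly increasing subsequence
#'
#' Patience algorithm (greedy + binary search), O(n log n). Positions
#' within one interval are distinct after the unique-match rule, so the
#' strict and non-strict variants coincide here.
#'
#' @param x integer vector of distinct non-negative values.
#' @return Integer LIS length; 0 for an empty sequence.
#' @export
lis_length <- function(x) {
  if (length(x) == 0L) return(0L)
  cpp_lis(as.integer(x))
}

#' kMAPQ from LIS length and sublist lengths
#'
#' `kMAPQ = -10 * log10(l_lis / min(l_r, l_q))`: 0 when every rare k-mer
#' of the shorter sublist is matched collinearly, growing as the
#' collinear fraction drops. Degenerate cases: `min(l_r, l_q) == 0` makes
#' the alignment unscorable (no rare k-mers to compare; such alignments
#' are kept by [filter_by_threshold()]); `l_lis == 0` with non-empty
#' sublists is reported as the cap value 60.
#'
#' @param l_lis LIS length over the matched common k-mers.
#' @param l_r,l_q lengths of the reference and query sublists
#'   (occurrence counts, not distinct k-mers).
#' @return List with `kmapq`, `lis_fraction` (`l_lis / min(l_r, l_q)`)
#'   and `scorable`.
#' @export
kmapq_score <- function(l_lis, l_r, l_q) {
  mn <- min(l_r, l_q)
  if (l_lis > mn)
    stop("internal consistency failure: l_lis exceeds min(l_r, l_q)")
  if (mn == 0L)
    return(list(kmapq = NA_real_, lis_fraction = NA_real_, scorable = FALSE))
  if (l_lis == 0L)
    return(list(kmapq = 60, lis_fraction = 0, scorable = TRUE))
  frac <- l_lis / mn
  list(kmapq = -10 * log10(frac), lis_fraction = frac, scorable = TRUE)
}

#' Score one alignment against the position databases
#'
#' Extracts the rare k-mer sublists of the aligned reference interval
#' `[target_start, target_end)` (cached in-memory list) and query
#' interval `[query_start, query_end)` (in-file binary search), matches
#' common k-mers, and computes the kMAPQ score. An alignment whose
#' sequence is missing from either database is returned unscorable with
#' the reason recorded.
#'
#' @param record one alignment: a single-row `paf` data.frame or a list
#'   with the PAF fields.
#' @param ref_db,qry_db `position_db` handles built with identical
#'   parameters.
#' @param cache reference-list cache from [new_ref_cache()].
#' @return List with `l_r`, `l_q`, `l_lis`, `lis_fraction`, `kmapq`,
#'   `scorable` and `reason` (`NA` unless unscorable).
#' @export
score_alignment <- function(record, ref_db, qry_db, cache = new_ref_cache()) {
  ref_sub <- tryCatch(
    sublist_for_reference(ref_db, record$target_name,
                          record$target_start, record$target_end, cache),
    kmapq_missing_sequence = function(e) e)
  qry_sub <- tryCatch(
    sublist_for_query(qry_db, record$query_name,
                      record$query_start, record$query_end),
    kmapq_missing_sequence = function(e) e)
  if (inherits(ref_sub, "condition") || inherits(qry_sub, "condition")) {
    reason <- if (inherits(ref_sub, "condition")) conditionMessage(ref_sub)
              else conditionMessage(qry_sub)
    return(list(l_r = NA_integer_, l_q = NA_integer_, l_lis = NA_integer_,
                lis_fraction = NA_real_, kmapq = NA_real_,
                scorable = FALSE, reason = reason))
  }
  l_r <- nrow(ref_sub)
  l_q <- nrow(qry_sub)
  pairs <- match_common(ref_sub, qry_sub)
  l_lis <- lis_length(build_position_sequence(pairs, record$strand))
  sc <- kmapq_score(l_lis, l_r, l_q)
  list(l_r = l_r, l_q = l_q, l_lis = l_lis,
       lis_fraction = sc$lis_fraction, kmapq = sc$kmapq,
       scorable = sc$scorable,
       reason = if (sc$scorable) NA_character_ else "no rare k-mers in interval")
}

#' Score every alignment of a PAF set
#'
#' Sorts the records by reference (see [sort_by_target()]) so each
#' reference occurrence list is loaded once, then scores each alignment.
#' The default `"fast"` method keeps the cached reference list and the
#' interval matching inside compiled code and reads query sublists as
#' raw byte blocks; the `"reference"` method composes the exported
#' step-by-step operations ([sublist_for_reference()],
#' [sublist_for_query()], [match_common()], [lis_length()]) via
#' [score_alignment()]. Both produce identical scores.
#'
#' @param records a `paf` data.frame.
#' @param method `"fast"` or `"reference"`.
#' @inheritParams score_alignment
#' @return The records sorted by target with appended columns `l_r`,
#'   `l_q`, `l_lis`, `lis_fraction`, `kmapq`, `scorable`, `reason`.
#' @export
score_paf <- function(records, ref_db, qry_db,
                      method = c("fast", "reference")) {
  method <- match.arg(method)
  if (!identical(ref_db$k, qry_db$k) || !identical(ref_db$m, qry_db$m))
    stop("reference and query databases were built with different parameters")
  records <- sort_by_target(records)
  n <- nrow(records)
  out <- vector("list", n)
  if (method == "reference") {
    cache <- new_ref_cache()
    for (i in seq_len(n))
      out[[i]] <- score_alignment(records[i, ], ref_db, qry_db, cache)
  } else {
    qcon <- file(qry_db$data_path, "rb")
    on.exit(close(qcon))
    ref_id <- NA_character_
    ref_ptr <- NULL
    tn <- records$target_name; ts <- records$target_start
    te <- records$target_end; qn <- records$query_name
    qs <- records$query_start; qe <- records$query_end
    strand <- records$strand
    for (i in seq_len(n)) {
      if (!identical(tn[i], ref_id)) {
        ref_ptr <- tryCatch(cpp_parse_ref_list(.fetch_line_records(ref_db, tn[i])),
                            kmapq_missing_sequence = function(e) e)
        ref_id <- tn[i]
      }
      block <- tryCatch(.query_block(qry_db, qcon, qn[i], qs[i], qe[i]),
                        kmapq_missing_sequence = function(e) e)
      if (inherits(ref_ptr, "condition") || inherits(block, "condition")) {
        reason <- if (inherits(ref_ptr, "condition")) conditionMessage(ref_ptr)
                  else conditionMessage(block)
        out[[i]] <- list(l_r = NA_integer_, l_q = NA_integer_,
                         l_lis = NA_integer_, lis_fraction = NA_real_,
                         kmapq = NA_real_, scorable = FALSE, reason = reason)
        next
      }
      ln <- cpp_score_interval(ref_ptr, ts[i], te[i], ref_db$k, block, strand[i])
      sc <- kmapq_score(ln$l_lis, ln$l_r, ln$l_q)
      out[[i]] <- list(l_r = ln$l_r, l_q = ln$l_q, l_lis = ln$l_lis,
                       lis_fraction = sc$lis_fraction, kmapq = sc$kmapq,
                       scorable = sc$scorable,
                       reason = if (sc$scorable) NA_character_
                                else "no rare k-mers in interval")
    }
  }
  records$l_r <- vapply(out, `[[`, integer(1), "l_r")
  records$l_q <- vapply(out, `[[`, integer(1), "l_q")
  records$l_lis <- vapply(out, `[[`, integer(1), "l_lis")
  records$lis_fraction <- vapply(out, `[[`, numeric(1), "lis_fraction")
  records$kmapq <- vapply(out, `[[`, numeric(1), "kmapq")
  records$scorable <- vapply(out, `[[`, logical(1), "scorable")
  records$reason <- vapply(out, `[[`, character(1), "reason")
  records
}

#' Partition scored alignments at a kMAPQ threshold
#'
#' Two conventions are provided, both monotone transforms of the LIS
#' fraction (the canonical internal quantity):
#' \describe{
#'   \item{`printed` (default)}{removes scorable records with
#'     `kmapq >= threshold` (inclusive): a high kMAPQ means a low
#'     collinear fraction, i.e. a likely false positive.}
#'   \item{`mapq_like`}{computes `-10 * log10(1 - lis_fraction)` (capped
#'     at 60) so that *good* alignments score high as with aligner MAPQ,
#'     and removes records strictly below the threshold.}
#' }
#' Unscorable records are always kept (an interval without rare k-mers,
#' common in high-error reads, is no evidence of misplacement).
#'
#' @param scored scored `paf` data.frame from [score_paf()].
#' @param threshold non-negative score threshold.
#' @param convention `"printed"` or `"mapq_like"`.
#' @return List with `kept` and `removed` (data.frame partitions) and
#'   `removed_mask` (logical vector aligned with `scored`).
#' @export
filter_by_threshold <- function(scored, threshold,
                                convention = c("printed", "mapq_like")) {
  convention <- match.arg(convention)
  if (threshold < 0) stop("threshold must be >= 0")
  scorable <- scored$scorable %in% TRUE
  removed <- if (convention == "printed") {
    scorable & scored$kmapq >= threshold
  } else {
    s2 <- ifelse(scored$lis_fraction >= 1, 60,
                 pmin(60, -10 * log10(1 - scored$lis_fraction)))
    scorable & s2 < threshold
  }
  removed[is.na(removed)] <- FALSE
  list(kept = scored[!removed, , drop = FALSE],
       removed = scored[removed, , drop = FALSE],
       removed_mask = removed)
}
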