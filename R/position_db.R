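# On-disk rare k-mer position database: one line per sequence plus a
# byte-offset index, with in-memory retrieval for reference sequences and
# in-file binary search for query sequences.
#
# Data file layout (after a single '#'-header line):
#   sequence_id TAB n TAB pos:code:orient[,pos:code:orient]* NL
# with positions 0-based and sorted. Query databases use fixed-width
# records (12-digit positions, 20-digit codes; 36 bytes per record
# including the separator) so a binary search can seek directly in the
# file; reference databases use plain decimal records.

.DB_RECORD_STRIDE <- 36L

.db_paths <- function(prefix, side) {
  list(data = paste0(prefix, ".", side, ".pos"),
       index = paste0(prefix, ".", side, ".idx"))
}

.db_header <- function(side, k, m, fixed) {
  sprintf("#kmapq-db\t1\t%s\tk=%d\tm=%d\tfixed=%d\n", side, k, m, as.integer(fixed))
}

# A plain unnamed length-1 character is a file path; named vectors and
# XStringSets are in-memory sequences.
.read_seqs <- function(x, what) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    if (!file.exists(x))
      stop(errorCondition(sprintf("cannot read sequence file '%s'", x),
                          class = c("kmapq_build_error", "error", "condition")))
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", x, ignore.case = TRUE))
      "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(x, format = fmt)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))  # first token of description
    return(out)
  }
  out <- .as_char_seqs(x)
  if (is.null(names(out)) && length(out))
    names(out) <- paste0(what, seq_along(out))
  out
}

.check_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(errorCondition(
      sprintf("duplicate sequence ID in %s input: '%s'", what, dup[[1L]]),
      class = c("kmapq_build_error", "error", "condition")))
}

.write_index <- function(path, side, k, m, hash, ids, offsets) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#kmapq-idx\t1\t%s\tk=%d\tm=%d\thash=%s", side, k, m, hash),
               paste(ids, sprintf("%.0f", offsets), sep = "\t")),
             con, sep = "\n")
}

.new_db <- function(prefix, side, k, m, fixed, ids, offsets, n_occ, hash) {
  paths <- .db_paths(prefix, side)
  index <- offsets
  names(index) <- ids
  nn <- n_occ
  names(nn) <- ids
  structure(list(data_path = paths$data, index_path = paths$index,
                 side = side, k = k, m = m, fixed = fixed,
                 index = index, n_occ = nn, hash = hash),
            class = "position_db")
}

#' Build rare k-mer position databases for reference and query sequences
#'
#' Counts canonical k-mers over the reference set, selects the rare set
#' (count `<= m`), scans both the reference and the query sequences for
#' rare k-mer occurrences, and writes two databases (`<prefix>.ref.pos` /
#' `.idx` and `<prefix>.qry.pos` / `.idx`). The rare set is defined from
#' the reference only; query sequences are scanned against it. Output is
#' deterministic: identical inputs and parameters give byte-identical
#' files.
#'
#' @param reference reference sequences: FASTA path or named character
#'   vector / `DNAStringSet`.
#' @param query query sequences (reads): FASTA/FASTQ path (gzip accepted)
#'   or named character vector / `DNAStringSet`.
#' @param out_prefix output path prefix for the four database files.
#' @param params a [kmer_params()] object.
#' @param threads accepted for interface parity; scanning is sequential
#'   and output is identical for any value.
#' @return List with `ref` and `qry` (`position_db` handles) and `stats`
#'   (total windows counted, distinct and rare k-mer counts, occurrences
#'   written per side).
#' @export
build_database <- function(reference, query, out_prefix,
                           params = kmer_params(), threads = 1L) {
  stopifnot(inherits(params, "kmer_params"))
  ref <- .read_seqs(reference, "ref")
  qry <- .read_seqs(query, "read")
  if (length(ref) == 0L || all(nchar(ref) == 0L))
    stop(errorCondition("reference input is empty",
                        class = c("kmapq_build_error", "error", "condition")))
  .check_ids(names(ref), "reference")
  .check_ids(names(qry), "query")
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  rp <- .db_paths(out_prefix, "ref")
  qp <- .db_paths(out_prefix, "qry")
  res <- cpp_build_dbs(names(ref), unname(ref), names(qry), unname(qry),
                       params$k, params$m, rp$data, qp$data,
                       .db_header("ref", params$k, params$m, FALSE),
                       .db_header("qry", params$k, params$m, TRUE))
  .write_index(rp$index, "ref", params$k, params$m, res$ref$hash,
               names(ref), res$ref$offset)
  .write_index(qp$index, "qry", params$k, params$m, res$qry$hash,
               names(qry), res$qry$offset)
  list(ref = .new_db(out_prefix, "ref", params$k, params$m, FALSE,
                     names(ref), res$ref$offset, res$ref$n_occ, res$ref$hash),
       qry = .new_db(out_prefix, "qry", params$k, params$m, TRUE,
                     names(qry), res$qry$offset, res$qry$n_occ, res$qry$hash),
       stats = list(total_windows = res$total_windows,
                    distinct_kmers = res$distinct_kmers,
                    rare_kmers = res$rare_kmers,
                    ref_occurrences = res$ref$total_occ,
                    qry_occurrences = res$qry$total_occ))
}

#' Reopen a position database written by [build_database()]
#'
#' @param prefix the `out_prefix` used at build time.
#' @param side `"ref"` or `"qry"`.
#' @return A `position_db` handle.
#' @export
open_database <- function(prefix, side = c("ref", "qry")) {
  side <- match.arg(side)
  paths <- .db_paths(prefix, side)
  if (!file.exists(paths$data) || !file.exists(paths$index))
    stop(errorCondition(sprintf("no %s database at prefix '%s'", side, prefix),
                        class = c("kmapq_build_error", "error", "condition")))
  lines <- readLines(paths$index)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (hdr[[1L]] != "#kmapq-idx") stop("not a kmapq index file")
  k <- as.integer(sub("^k=", "", hdr[[4L]]))
  m <- as.integer(sub("^m=", "", hdr[[5L]]))
  hash <- sub("^hash=", "", hdr[[6L]])
  body <- lines[-1L]
  ids <- sub("\t.*$", "", body)
  offsets <- as.numeric(sub("^.*\t", "", body))
  .new_db(prefix, side, k, m, side == "qry", ids, offsets,
          rep(NA_real_, length(ids)), hash)
}

#' @export
print.position_db <- function(x, ...) {
  cat(sprintf("position_db (%s): %d sequences, k = %d, m = %d\n  data: %s\n",
              x$side, length(x$index), x$k, x$m, x$data_path))
  invisible(x)
}

.db_offset <- function(db, sequence_id) {
  i <- match(sequence_id, names(db$index))
  if (is.na(i))
    stop(errorCondition(
      sprintf("sequence '%s' not present in %s database", sequence_id, db$side),
      class = c("kmapq_missing_sequence", "error", "condition")))
  db$index[[i]]
}

#' Fetch the full rare k-mer occurrence list of one sequence
#'
#' Seeks directly to the sequence's line via the byte-offset index (O(1))
#' and parses the whole occurrence list into memory.
#'
#' @param db a `position_db`.
#' @param sequence_id sequence identifier.
#' @return A `seq_kmer_list` (see [scan_positions()]).
#' @export
fetch_sequence_list <- function(db, sequence_id) {
  stopifnot(inherits(db, "position_db"))
  off <- .db_offset(db, sequence_id)
  con <- file(db$data_path, "rb")
  on.exit(close(con))
  seek(con, off)
  line <- readLines(con, n = 1L)
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (parts[[1L]] != sequence_id)
    stop(sprintf("index corrupt: offset for '%s' resolves to line '%s'",
                 sequence_id, parts[[1L]]))
  if (length(parts) < 3L || !nzchar(parts[[3L]])) {
    occ <- data.frame(pos = integer(0), code = character(0),
                      orient = character(0), stringsAsFactors = FALSE)
  } else {
    res <- cpp_parse_records(parts[[3L]])
    occ <- data.frame(pos = res$pos, code = res$code, orient = res$orient,
                      stringsAsFactors = FALSE)
  }
  structure(list(sequence_id = sequence_id, occurrences = occ, k = db$k),
            class = "seq_kmer_list")
}

#' Extract the occurrences fully contained in an alignment interval
#'
#' Returns exactly the occurrences with `start <= pos` and
#' `pos + k <= end`, i.e. whose whole k-mer window lies inside the
#' 0-based half-open interval `[start, end)`; k-mers straddling the
#' interval ends are not credited. Binary search via `findInterval()`.
#'
#' @param x a `seq_kmer_list` or an occurrence data.frame with a sorted
#'   `pos` column.
#' @param start,end interval bounds, `0 <= start <= end`.
#' @param k k-mer length; taken from `x` when it is a `seq_kmer_list`.
#' @return Occurrence data.frame subset (columns `pos`, `code`, `orient`).
#' @export
extract_sublist <- function(x, start, end, k = NULL) {
  if (inherits(x, "seq_kmer_list")) {
    if (is.null(k)) k <- x$k
    x <- x$occurrences
  }
  if (is.null(k)) stop("k must be supplied when x is a plain data.frame")
  if (start < 0 || end < start) stop("need 0 <= start <= end")
  pos <- x$pos
  i1 <- findInterval(start - 0.5, pos) + 1L
  i2 <- findInterval(end - k + 0.5, pos)
  if (i1 > i2) return(x[0L, , drop = FALSE])
  x[i1:i2, , drop = FALSE]
}

#' Single-slot cache for reference occurrence lists
#'
#' Alignments are processed sorted by reference ID, so one cached list
#' serves every alignment on the same reference; `loads` counts database
#' reads for cache-behaviour checks.
#'
#' @return An environment with fields `id`, `list` and `loads`.
#' @export
new_ref_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$id <- NA_character_
  e$list <- NULL
  e$loads <- 0L
  e
}

#' Reference-side sublist with cached whole-sequence list
#'
#' Loads the reference's full occurrence list into the cache at most once
#' per reference per sorted pass, then answers via [extract_sublist()].
#'
#' @inheritParams fetch_sequence_list
#' @inheritParams extract_sublist
#' @param cache a cache from [new_ref_cache()].
#' @return Occurrence data.frame.
#' @export
sublist_for_reference <- function(db, sequence_id, start, end,
                                  cache = new_ref_cache()) {
  if (!identical(cache$id, sequence_id)) {
    cache$list <- fetch_sequence_list(db, sequence_id)
    cache$id <- sequence_id
    cache$loads <- cache$loads + 1L
  }
  extract_sublist(cache$list, start, end)
}

# Reads the 12-digit position of record i (0-based) of a fixed-width line.
.read_record_pos <- function(con, rec_off, i) {
  seek(con, rec_off + i * .DB_RECORD_STRIDE)
  as.integer(readChar(con, 12L, useBytes = TRUE))
}

# In-file binary search on an open connection: returns the raw byte block
# of the contained records, or "" when the interval holds none.
.query_block <- function(db, con, sequence_id, start, end) {
  off <- .db_offset(db, sequence_id)
  seek(con, off)
  idlen <- nchar(sequence_id, type = "bytes")
  chunk <- readChar(con, idlen + 14L, useBytes = TRUE)
  if (substr(chunk, 1L, idlen) != sequence_id)
    stop(sprintf("index corrupt: offset for '%s' resolves elsewhere", sequence_id))
  rest <- substr(chunk, idlen + 2L, nchar(chunk))
  tab <- regexpr("\t", rest, fixed = TRUE)
  n_str <- substr(rest, 1L, tab - 1L)
  n <- as.numeric(n_str)
  if (n == 0) return("")
  rec_off <- off + idlen + 1L + nchar(n_str) + 1L
  hi_pos <- end - db$k  # largest admissible window start

  # first record with pos >= start
  lo <- 0; hi <- n
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (.read_record_pos(con, rec_off, mid) < start) lo <- mid + 1 else hi <- mid
  }
  first <- lo
  # first record with pos > hi_pos
  lo <- first; hi <- n
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (.read_record_pos(con, rec_off, mid) <= hi_pos) lo <- mid + 1 else hi <- mid
  }
  last <- lo - 1
  if (first > last) return("")
  seek(con, rec_off + first * .DB_RECORD_STRIDE)
  readChar(con, (last - first + 1) * .DB_RECORD_STRIDE, useBytes = TRUE)
}

#' Query-side sublist by in-file binary search
#'
#' Finds the contained occurrence range of a query sequence without
#' materialising its whole list: the query database stores fixed-width
#' records, so record boundaries are computable and the two interval
#' bounds are located by O(log n) seeks directly in the file; only the
#' matching byte range is then read and parsed.
#'
#' @inheritParams fetch_sequence_list
#' @inheritParams extract_sublist
#' @return Occurrence data.frame (same contract as [extract_sublist()]).
#' @export
sublist_for_query <- function(db, sequence_id, start, end) {
  stopifnot(inherits(db, "position_db"))
  if (!isTRUE(db$fixed))
    stop("in-file search requires a fixed-width (query) database")
  if (start < 0 || end < start) stop("need 0 <= start <= end")
  con <- file(db$data_path, "rb")
  on.exit(close(con))
  block <- .query_block(db, con, sequence_id, start, end)
  if (!nzchar(block))
    return(data.frame(pos = integer(0), code = character(0),
                      orient = character(0), stringsAsFactors = FALSE))
  res <- cpp_parse_records(block)
  data.frame(pos = res$pos, code = res$code, orient = res$orient,
             stringsAsFactors = FALSE)
}

# Raw third field (record section) of a sequence's line, for the C++
# fast-scoring path.
.fetch_line_records <- function(db, sequence_id) {
  off <- .db_offset(db, sequence_id)
  con <- file(db$data_path, "rb")
  on.exit(close(con))
  seek(con, off)
  line <- readLines(con, n = 1L)
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (parts[[1L]] != sequence_id)
    stop(sprintf("index corrupt: offset for '%s' resolves to line '%s'",
                 sequence_id, parts[[1L]]))
  if (length(parts) < 3L) "" else parts[[3L]]
}
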