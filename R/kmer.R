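# k-mer engine: 2-bit encoding, rolling windows, canonical form, counting,
# rare-set selection and per-sequence occurrence scanning.

#' k-mer parameters
#'
#' Bundles the k-mer length `k` and the rarity ceiling `m` (maximum
#' genome-wide count for a k-mer to be considered rare). `k` must satisfy
#' `2 * k <= 64` so a k-mer packs into one 64-bit word; the pipeline cap is
#' 32, while the scalar code helpers ([encode_kmer()] and friends), which
#' exchange codes as R doubles, additionally require `k <= 26` so the code
#' stays below 2^53 and is exact.
#'
#' @param k k-mer length in bases (integer, 1..32). Default 21.
#' @param m rarity ceiling: a k-mer is rare when its canonical genome-wide
#'   count is `<= m`. Default 3.
#' @return An object of class `kmer_params`.
#' @export
kmer_params <- function(k = 21L, m = 3L) {
  k <- as.integer(k)
  m <- as.integer(m)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 32L)
    stop(errorCondition("k must be a single integer in 1..32 (2k <= 64)",
                        class = c("kmapq_bad_params", "error", "condition")))
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop(errorCondition("m must be a single integer >= 1",
                        class = c("kmapq_bad_params", "error", "condition")))
  structure(list(k = k, m = m), class = "kmer_params")
}

#' @export
print.kmer_params <- function(x, ...) {
  cat(sprintf("kmer_params: k = %d, m = %d\n", x$k, x$m))
  invisible(x)
}

.check_scalar_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1L || k > 26L)
    stop(errorCondition(
      "k must be in 1..26 for numeric code helpers (codes are exchanged as doubles)",
      class = c("kmapq_bad_length", "error", "condition")))
  as.integer(k)
}

.check_bases <- function(seq) {
  if (grepl("[^ACGTacgt]", seq))
    stop(errorCondition("sequence contains non-ACGT characters",
                        class = c("kmapq_bad_base", "error", "condition")))
}

#' Encode a k-mer as a 2-bit packed integer code
#'
#' Packs a DNA string big-endian into an integer, 2 bits per base with
#' A=00, C=01, G=10, T=11 (first base in the highest-order occupied bit
#' pair), e.g. `"ACGT"` -> binary `00 01 10 11` = 27.
#'
#' @param seq DNA string of length `k`, ACGT only (case-insensitive).
#' @param k k-mer length; defaults to `nchar(seq)`. Must be `<= 26` here
#'   (numeric codes are doubles, exact below 2^53); the scanning pipeline
#'   itself supports `k <= 32`.
#' @return The code as a double.
#' @seealso [decode_kmer()], [roll_forward()], [revcomp_code()]
#' @export
encode_kmer <- function(seq, k = nchar(seq)) {
  k <- .check_scalar_k(k)
  if (nchar(seq) != k)
    stop(errorCondition("sequence length does not equal k",
                        class = c("kmapq_bad_length", "error", "condition")))
  .check_bases(seq)
  cpp_encode(seq, k)
}

#' Decode a packed k-mer code back to a DNA string
#'
#' Inverse of [encode_kmer()]: `encode_kmer(decode_kmer(x, k)) == x`.
#'
#' @param code numeric code (non-negative integer-valued, `< 4^k`).
#' @param k k-mer length in bases.
#' @return DNA string of length `k`.
#' @export
decode_kmer <- function(code, k) {
  k <- .check_scalar_k(k)
  if (length(code) != 1L || is.na(code) || code < 0 || code != trunc(code) ||
      code >= 4^k)
    stop(errorCondition("invalid k-mer code (bits set above 2k-1, or not a non-negative integer)",
                        class = c("kmapq_bad_code", "error", "condition")))
  cpp_decode(code, k)
}

#' Roll a k-mer window forward by one base
#'
#' Updates the code of the window starting at `i` to the window starting at
#' `i + 1`: left-shift by 2 bits, append the 2-bit code of `next_base`, and
#' mask down to the low `2k` bits. Bit-identical to re-encoding the new
#' window directly.
#'
#' A non-ACGT `next_base` raises a condition of class `kmapq_window_reset`:
#' the window cannot be extended and scanning must restart past the
#' offending base.
#'
#' @param prev code of the current window.
#' @param next_base single character, the base entering the window.
#' @param k k-mer length.
#' @return Code of the shifted window (double).
#' @export
roll_forward <- function(prev, next_base, k) {
  k <- .check_scalar_k(k)
  if (nchar(next_base) != 1L)
    stop(errorCondition("next_base must be a single character",
                        class = c("kmapq_bad_length", "error", "condition")))
  if (grepl("[^ACGTacgt]", next_base))
    stop(errorCondition("non-ACGT base: restart the window past it",
                        class = c("kmapq_window_reset", "error", "condition")))
  cpp_roll(prev, next_base, k)
}

#' Reverse-complement a packed k-mer code
#'
#' Works directly on the 2-bit packing: with A=00/C=01/G=10/T=11 the
#' complement of a base is the bitwise NOT of its pair, so the reverse
#' complement is a pairwise NOT plus pair-order reversal. An involution:
#' `revcomp_code(revcomp_code(x, k), k) == x`.
#'
#' @inheritParams decode_kmer
#' @return Code of the reverse-complement k-mer (double).
#' @export
revcomp_code <- function(code, k) {
  k <- .check_scalar_k(k)
  cpp_revcomp(code, k)
}

#' Canonical form of a k-mer code
#'
#' The canonical code is the numerically smaller of a code and its reverse
#' complement; counting canonical codes makes rarity strand-symmetric.
#' Palindromic k-mers (`code == revcomp`) are reported as `"+"`.
#'
#' @inheritParams decode_kmer
#' @return List with `code` (canonical code) and `orient` (`"+"` if the
#'   input was already canonical, `"-"` otherwise).
#' @export
canonical_code <- function(code, k) {
  k <- .check_scalar_k(k)
  rc <- cpp_revcomp(code, k)
  if (code <= rc) list(code = code, orient = "+") else list(code = rc, orient = "-")
}

#' Count canonical k-mers across a set of sequences
#'
#' Slides a k-length window over every sequence; each ACGT-only window
#' contributes one count to its canonical code. Windows containing any
#' non-ACGT character contribute nothing and the rolling state restarts
#' after the offending base. The sum of all counts therefore equals the
#' number of valid windows scanned.
#'
#' @param seqs character vector of DNA sequences (a `DNAStringSet` is
#'   accepted), possibly containing non-ACGT characters.
#' @param k k-mer length (1..32).
#' @return An object of class `kmer_count_table`: list with `code`
#'   (canonical codes as decimal strings, sorted numerically), `count`
#'   (integer counts, all `>= 1`), `k`, and `total_windows`.
#' @export
count_kmers <- function(seqs, k) {
  k <- as.integer(k)
  if (k < 1L || k > 32L)
    stop(errorCondition("k must be in 1..32",
                        class = c("kmapq_bad_params", "error", "condition")))
  seqs <- .as_char_seqs(seqs)
  res <- cpp_count_kmers(unname(seqs), k)
  structure(list(code = res$code, count = res$count, k = k,
                 total_windows = res$total_windows),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: %d distinct canonical %d-mers over %.0f windows\n",
              length(x$code), x$k, x$total_windows))
  invisible(x)
}

#' Select rare k-mers from a count table
#'
#' Keeps exactly the canonical codes whose genome-wide count is `<= m`.
#' The count table should be built over the full reference set, which
#' stands in for the whole genome when the references are non-redundant
#' contigs or scaffolds.
#'
#' @param table a `kmer_count_table` from [count_kmers()].
#' @param m rarity ceiling (integer `>= 1`).
#' @return An object of class `rare_kmer_set`: list with `code` (decimal
#'   strings), `k` and `m`.
#' @export
select_rare <- function(table, m) {
  stopifnot(inherits(table, "kmer_count_table"))
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop(errorCondition("m must be a single integer >= 1",
                        class = c("kmapq_bad_params", "error", "condition")))
  keep <- table$count <= m
  structure(list(code = table$code[keep], k = table$k, m = m),
            class = "rare_kmer_set")
}

#' @export
print.rare_kmer_set <- function(x, ...) {
  cat(sprintf("rare_kmer_set: %d canonical %d-mers with count <= %d\n",
              length(x$code), x$k, x$m))
  invisible(x)
}

#' Scan a sequence for rare k-mer occurrences
#'
#' Slides the k-window 5' to 3' with a rolling 2-bit code (the reverse
#' complement rolls in the opposite direction simultaneously) and records
#' one occurrence per window whose canonical code is in the rare set.
#' Positions are 0-based window starts, strictly increasing; orientation is
#' `"+"` when the forward-strand window equals the canonical form.
#'
#' @param seq a single DNA string (or length-1 `DNAStringSet`).
#' @param rare a `rare_kmer_set` from [select_rare()].
#' @param id sequence identifier stored in the result; defaults to
#'   `names(seq)` or `"seq"`.
#' @return An object of class `seq_kmer_list`: list with `sequence_id` and
#'   `occurrences`, a data.frame with columns `pos` (integer, 0-based),
#'   `code` (decimal string) and `orient` (`"+"`/`"-"`).
#' @export
scan_positions <- function(seq, rare, id = NULL) {
  stopifnot(inherits(rare, "rare_kmer_set"))
  seq <- .as_char_seqs(seq)
  if (length(seq) != 1L) stop("scan_positions() takes a single sequence")
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq) else "seq"
  res <- cpp_scan(unname(seq), rare$code, rare$k)
  occ <- data.frame(pos = res$pos, code = res$code, orient = res$orient,
                    stringsAsFactors = FALSE)
  structure(list(sequence_id = id, occurrences = occ, k = rare$k),
            class = "seq_kmer_list")
}

#' @export
print.seq_kmer_list <- function(x, ...) {
  cat(sprintf("seq_kmer_list '%s': %d rare %d-mer occurrences\n",
              x$sequence_id, nrow(x$occurrences), x$k))
  invisible(x)
}

# Coerce DNAStringSet / DNAString / character to a named character vector.
.as_char_seqs <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString"))
    return(as.character(x))
  if (!is.character(x)) stop("sequences must be character or DNAStringSet")
  x
}
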