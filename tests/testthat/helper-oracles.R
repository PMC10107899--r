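# Independent brute-force oracles: naive string-level k-mer handling, an
# O(n^2) dynamic-programming LIS, and linear-scan interval filtering. These
# never call the package's optimised paths.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

BASE_VAL <- c(A = 0, C = 1, G = 2, T = 3)

naive_encode <- function(seq) {
  v <- BASE_VAL[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]]
  sum(v * 4^(rev(seq_along(v)) - 1))
}

naive_revcomp_str <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]]), collapse = "")
}

naive_canonical_str <- function(w) {
  rc <- naive_revcomp_str(w)
  if (naive_encode(w) <= naive_encode(rc)) list(kmer = w, orient = "+")
  else list(kmer = rc, orient = "-")
}

# All ACGT-only windows of a sequence with their 0-based start positions.
naive_windows <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(0), kmer = character(0)))
  pos <- 0:(n - k)
  kmer <- substring(seq, pos + 1L, pos + k)
  keep <- !grepl("[^ACGT]", kmer)
  data.frame(pos = pos[keep], kmer = kmer[keep], stringsAsFactors = FALSE)
}

# Canonical counts as a named vector keyed by decimal code string.
naive_count <- function(seqs, k) {
  counts <- integer(0)
  for (s in seqs) {
    w <- naive_windows(s, k)
    for (km in w$kmer) {
      cc <- as.character(naive_encode(naive_canonical_str(km)$kmer))
      counts[cc] <- if (is.na(counts[cc])) 1L else counts[cc] + 1L
    }
  }
  counts
}

# Non-rolling scan against a set of canonical code strings.
naive_scan <- function(seq, rare_codes, k) {
  w <- naive_windows(seq, k)
  pos <- integer(0); code <- character(0); orient <- character(0)
  for (i in seq_len(nrow(w))) {
    cn <- naive_canonical_str(w$kmer[i])
    cc <- as.character(naive_encode(cn$kmer))
    if (cc %in% rare_codes) {
      pos <- c(pos, w$pos[i]); code <- c(code, cc); orient <- c(orient, cn$orient)
    }
  }
  data.frame(pos = pos, code = code, orient = orient, stringsAsFactors = FALSE)
}

# O(n^2) DP for the longest strictly increasing subsequence.
lis_dp <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (x[j] < x[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
  max(best)
}

naive_extract <- function(occ, start, end, k) {
  occ[occ$pos >= start & occ$pos + k <= end, , drop = FALSE]
}

# Small deterministic repeat fixture shared by several test files.
make_fixture <- function(seed = 101, background_length = 50000L,
                         unit_length = 2000L, copies = 4L,
                         depth = 3, profile = "hifi",
                         read_length_mean = 5000, read_length_sd = 800) {
  bg <- make_background(background_length, seed = seed)
  gen <- build_repeat_genome(
    repeat_spec(unit_length, copies, mode = "interspersed", seed = seed + 1L), bg)
  sspec <- read_sim_spec(profile, depth = depth,
                         read_length_mean = read_length_mean,
                         read_length_sd = read_length_sd, seed = seed + 2L)
  sim <- simulate_reads(gen$genome, sspec)
  paf <- simulate_alignments(sim$reads, sim$truth, gen$copies, gen$genome,
                             error_rate = sspec$error_rate)
  wd <- tempfile("kmapq_fix")
  dir.create(wd)
  gpath <- file.path(wd, "genome.fa")
  rpath <- file.path(wd, "reads.fq")
  write_fasta(gen$genome, gpath)
  write_fastq(sim$reads, rpath)
  dbs <- build_database(gpath, rpath, file.path(wd, "db"))
  list(gen = gen, sim = sim, paf = paf, dbs = dbs, wd = wd,
       gpath = gpath, rpath = rpath)
}
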