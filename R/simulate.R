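# Synthetic data: repeat-bearing genomes (tandem arrays and interspersed
# copies), HiFi-like / ONT-like long reads with origins encoded in read
# names, and alignment sets containing constructed false placements.
# Everything is deterministic under set.seed(); randomness goes through
# R's RNG, including the C++ read error model.

#' Generate an i.i.d. random background sequence
#'
#' Stand-in for a unique (non-repetitive) chromosome region: bases drawn
#' independently at the requested GC content.
#'
#' @param length sequence length in bases (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @param id sequence name.
#' @return Named character vector of length 1.
#' @export
make_background <- function(length, gc = 0.5, seed = NULL, id = "chrS") {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
               collapse = "")
  names(seq) <- id
  seq
}

#' Derive a diverged repeat copy from a source unit
#'
#' Substitutions are applied first, then deletions, both by exact-count
#' sampling: exactly `floor(sub_rate * L)` positions are substituted
#' (each to one of the three other bases, uniformly) and exactly
#' `floor(del_rate * L)` positions of the substituted sequence are
#' removed, so the realised divergence is deterministic rather than
#' binomially distributed. An optional insertion rate (applied last) is
#' provided as an extension and defaults to 0.
#'
#' @param unit source DNA string.
#' @param sub_rate,del_rate,ins_rate per-base rates in `[0, 1]`.
#' @param seed optional integer seed.
#' @return The mutated copy (character). Length is
#'   `L - floor(del_rate * L)` when `ins_rate = 0`.
#' @export
mutate_copy <- function(unit, sub_rate = 0.03, del_rate = 0.01,
                        ins_rate = 0, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, del_rate >= 0, del_rate <= 1,
            ins_rate >= 0, ins_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(unit, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  n_sub <- floor(sub_rate * L)
  if (n_sub > 0) {
    idx <- sample.int(L, n_sub)
    shift <- sample.int(3L, n_sub, replace = TRUE)
    chars[idx] <- bases[((match(chars[idx], bases) - 1L + shift) %% 4L) + 1L]
  }
  n_del <- floor(del_rate * L)
  if (n_del > 0) chars <- chars[-sample.int(L, n_del)]
  if (ins_rate > 0) {
    n_ins <- floor(ins_rate * length(chars))
    if (n_ins > 0) {
      at <- sort(sample.int(length(chars) + 1L, n_ins, replace = TRUE))
      ins <- sample(bases, n_ins, replace = TRUE)
      out <- vector("list", 2L * n_ins + 1L)
      prev <- 1L
      for (j in seq_len(n_ins)) {       # insert ins[j] before position at[j]
        out[[2L * j - 1L]] <- if (at[j] > prev) chars[prev:(at[j] - 1L)] else character(0)
        out[[2L * j]] <- ins[j]
        prev <- at[j]
      }
      out[[2L * n_ins + 1L]] <-
        if (prev <= length(chars)) chars[prev:length(chars)] else character(0)
      chars <- unlist(out)
    }
  }
  paste(chars, collapse = "")
}

#' Repeat construction parameters
#'
#' @param source_length length of the repeat unit in bases (default
#'   10 kb, a desk-scale stand-in for a 100 kb segment).
#' @param copies number of diverged copies to place (default 10).
#' @param sub_rate,del_rate per-base divergence of each copy from the
#'   unit (defaults 3% substitutions then 1% deletions).
#' @param mode `"interspersed"` (copies inserted at random positions) or
#'   `"tandem"` (copies concatenated head-to-tail into one array).
#' @param seed optional integer seed governing the unit sequence, the
#'   per-copy mutations and the insertion positions.
#' @return An object of class `repeat_spec`.
#' @export
repeat_spec <- function(source_length = 10000L, copies = 10L,
                        sub_rate = 0.03, del_rate = 0.01,
                        mode = c("interspersed", "tandem"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(copies >= 1, source_length >= 1)
  structure(list(source_length = as.integer(source_length),
                 copies = as.integer(copies), sub_rate = sub_rate,
                 del_rate = del_rate, mode = mode, seed = seed),
            class = "repeat_spec")
}

#' Build a repeat-bearing genome with recorded copy coordinates
#'
#' Draws a random repeat unit, derives `copies` independently mutated
#' copies ([mutate_copy()]), and places them either at sorted random
#' non-overlapping insertion points within the background (interspersed)
#' or as one head-to-tail array appended to the background (tandem,
#' a structural analogue of a centromeric higher-order-repeat array).
#' Final copy coordinates (after accounting for upstream insertions) are
#' recorded for ground-truth assessment.
#'
#' @param spec a [repeat_spec()].
#' @param background named background sequence from [make_background()].
#' @param unit optional explicit unit sequence; drawn randomly (same GC
#'   as uniform) when `NULL`.
#' @return List with `genome` (named character, same name as the
#'   background), `copies` (data.frame: `copy`, `start`, `end`,
#'   `length`; 0-based half-open) and `unit`.
#' @export
build_repeat_genome <- function(spec, background, unit = NULL) {
  stopifnot(inherits(spec, "repeat_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(unit))
    unit <- paste(sample(c("A", "C", "G", "T"), spec$source_length,
                         replace = TRUE), collapse = "")
  copies <- vapply(seq_len(spec$copies), function(i)
    mutate_copy(unit, spec$sub_rate, spec$del_rate), character(1))
  lens <- nchar(copies)
  bg <- unname(background)
  L <- nchar(bg)
  id <- names(background)
  if (spec$mode == "interspersed") {
    if (L <= spec$copies)
      stop("background too short for the requested insertions")
    at <- sort(sample.int(L + 1L, spec$copies)) - 1L  # insertion points, 0-based
    pieces <- character(2L * spec$copies + 1L)
    prev <- 0L
    for (i in seq_len(spec$copies)) {
      pieces[2L * i - 1L] <- substr(bg, prev + 1L, at[i])
      pieces[2L * i] <- copies[i]
      prev <- at[i]
    }
    pieces[2L * spec$copies + 1L] <- substr(bg, prev + 1L, L)
    genome <- paste(pieces, collapse = "")
    starts <- at + c(0L, cumsum(lens))[seq_len(spec$copies)]
  } else {
    genome <- paste(c(bg, copies), collapse = "")
    starts <- L + c(0L, cumsum(lens))[seq_len(spec$copies)]
  }
  names(genome) <- id
  list(genome = genome,
       copies = data.frame(copy = seq_len(spec$copies), start = starts,
                           end = starts + lens, length = lens),
       unit = unit)
}

#' Read simulation parameters
#'
#' Profile defaults: `hifi` reads average 15 kb (sd 3 kb) with 0.3%
#' errors; `ont` reads average 25 kb (sd 10 kb) with 7% errors. Lengths
#' are Gaussian, truncated to `[200, genome length]`; errors are
#' substitutions, insertions and deletions in ratio 1:1:1.
#'
#' @param profile `"hifi"` or `"ont"`.
#' @param depth target mean coverage (default 30).
#' @param read_length_mean,read_length_sd,error_rate override the profile
#'   defaults.
#' @param seed optional integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(profile = c("hifi", "ont"), depth = 30,
                          read_length_mean = NULL, read_length_sd = NULL,
                          error_rate = NULL, seed = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "hifi") list(mean = 15000, sd = 3000, err = 0.003)
         else list(mean = 25000, sd = 10000, err = 0.07)
  err <- if (is.null(error_rate)) def$err else error_rate
  stopifnot(depth > 0, err >= 0, err <= 0.3)
  structure(list(profile = profile, depth = depth,
                 read_length_mean = if (is.null(read_length_mean)) def$mean else read_length_mean,
                 read_length_sd = if (is.null(read_length_sd)) def$sd else read_length_sd,
                 error_rate = err, seed = seed),
            class = "read_sim_spec")
}

#' Simulate long reads with known origins
#'
#' Draws reads at uniformly random start positions and strands until the
#' target mean depth (in genomic bases) is reached. Minus-strand reads
#' are reverse-complemented before errors are applied. The origin is
#' encoded in the read name as `read<i>!<target>!<start>!<strand>`
#' (`start` is the 0-based forward-strand origin).
#'
#' @param genome named genome sequence (length 1).
#' @param spec a [read_sim_spec()].
#' @return List with `reads` (named character vector) and `truth`
#'   (`ground_truth` data.frame with an extra `span` column, the genomic
#'   span of each read).
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "read_sim_spec"), length(genome) == 1L)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  G <- nchar(genome)
  min_len <- 200L
  if (G <= min_len)
    stop("genome shorter than the minimum read length")
  id <- names(genome)
  target_bases <- spec$depth * G
  reads <- character(0)
  names_ <- character(0)
  starts <- integer(0)
  strands <- character(0)
  spans <- integer(0)
  total <- 0
  i <- 0L
  while (total < target_bases) {
    i <- i + 1L
    len <- 0L
    while (len < min_len || len > G)
      len <- as.integer(round(rnorm(1, spec$read_length_mean, spec$read_length_sd)))
    start0 <- sample.int(G - len + 1L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    seq <- substr(genome, start0 + 1L, start0 + len)
    if (strand == "-") seq <- cpp_revcomp_string(seq)
    reads[i] <- cpp_apply_read_errors(seq, spec$error_rate)
    names_[i] <- sprintf("read%d!%s!%d!%s", i, id, start0, strand)
    starts[i] <- start0
    strands[i] <- strand
    spans[i] <- len
    total <- total + len
  }
  names(reads) <- names_
  truth <- data.frame(read_name = names_, target = id, start = starts,
                      strand = strands, span = spans, stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  list(reads = reads, truth = truth)
}

#' Simulate an alignment set with constructed false placements
#'
#' `placement` mode derives alignments from the ground truth: every read
#' gets one alignment at its true locus; a read whose genomic interval
#' overlaps a repeat copy additionally gets one alignment per homologous
#' copy at the corresponding within-copy offset — false positives by
#' construction. Match/block columns are approximated from the genomic
#' span and error rate; aligner MAPQ is set to 60 for uniquely placed
#' reads and 1 for multi-placed ones, mimicking an aligner's ambiguity
#' signal. `external` mode instead shells out to a long-read aligner
#' (minimap2-compatible interface) on the written genome and reads.
#'
#' @param reads named read vector from [simulate_reads()].
#' @param truth matching `ground_truth` table (with `span`).
#' @param copies copy coordinate table from [build_repeat_genome()]
#'   (`NULL` means no repeats: one true alignment per read).
#' @param genome named genome sequence (used for lengths, and written
#'   out in `external` mode).
#' @param mode `"placement"` or `"external"`.
#' @param error_rate per-base read error rate used to approximate the
#'   residue-match column.
#' @param aligner,aligner_preset external aligner executable and preset
#'   (`external` mode only).
#' @param work_dir scratch directory for `external` mode.
#' @return A `paf` data.frame.
#' @export
simulate_alignments <- function(reads, truth, copies, genome,
                                mode = c("placement", "external"),
                                error_rate = 0,
                                aligner = "minimap2",
                                aligner_preset = "map-pb",
                                work_dir = tempfile("kmapq_aln")) {
  mode <- match.arg(mode)
  G <- unname(nchar(genome))
  id <- names(genome)
  if (mode == "external") {
    if (Sys.which(aligner) == "")
      stop(errorCondition(sprintf("aligner '%s' not found on PATH", aligner),
                          class = c("kmapq_aligner_missing", "error", "condition")))
    dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
    gpath <- file.path(work_dir, "genome.fa")
    rpath <- file.path(work_dir, "reads.fq")
    opath <- file.path(work_dir, "aln.paf")
    write_fasta(genome, gpath)
    write_fastq(reads, rpath)
    status <- system2(aligner, c("-x", aligner_preset, gpath, rpath),
                      stdout = opath, stderr = FALSE)
    if (!identical(status, 0L)) stop("external aligner failed")
    return(read_paf(opath))
  }
  qn <- character(0); ql <- integer(0); ts <- integer(0); te <- integer(0)
  st <- character(0); mq <- integer(0); span <- integer(0)
  for (i in seq_len(nrow(truth))) {
    s0 <- truth$start[i]
    sp <- truth$span[i]
    e0 <- s0 + sp
    placements <- s0
    if (!is.null(copies) && nrow(copies) > 0L) {
      ovl <- pmin(copies$end, e0) - pmax(copies$start, s0)
      hit <- which(ovl > 0L)
      if (length(hit)) {
        anchor <- hit[which.max(ovl[hit])]
        off <- s0 - copies$start[anchor]
        others <- setdiff(seq_len(nrow(copies)), anchor)
        alt <- copies$start[others] + off
        alt <- alt[alt >= 0 & alt + sp <= G]  # placements falling off the genome are dropped
        placements <- c(s0, alt)
      }
    }
    npl <- length(placements)
    qn <- c(qn, rep(truth$read_name[i], npl))
    ql <- c(ql, rep(nchar(reads[[i]]), npl))
    ts <- c(ts, as.integer(placements))
    te <- c(te, as.integer(placements + sp))
    st <- c(st, rep(truth$strand[i], npl))
    mq <- c(mq, rep(if (npl > 1L) 1L else 60L, npl))
    span <- c(span, rep(sp, npl))
  }
  ql <- unname(ql)
  df <- data.frame(query_name = qn, query_length = ql,
                   query_start = 0L, query_end = ql, strand = st,
                   target_name = id, target_length = G,
                   target_start = ts, target_end = te,
                   residue_matches = as.integer(round(span * (1 - error_rate))),
                   block_length = span, mapq = mq,
                   stringsAsFactors = FALSE)
  df$tags <- rep(list(character(0)), nrow(df))
  class(df) <- c("paf", "data.frame")
  df
}

#' Write sequences as FASTA / FASTQ
#'
#' FASTQ qualities are constant (`I`); the generator does not model
#' per-base quality.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  lines <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs), "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}
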