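# High-level pipeline: build / filter / simulate / eval entry points and
# the end-to-end repeat benchmark used to measure filtering accuracy on
# synthetic data. The command-line wrapper in exec/kmapq calls these.

#' Benchmark presets
#'
#' Four experiment shapes combining repeat architecture and read
#' profile, with desk-scale defaults: interspersed presets insert 10
#' diverged copies of a 10 kb unit into a 2 Mb background; tandem
#' presets append an array of 20 copies of a 10 kb unit to a 1 Mb
#' background (a centromere-style analogue). Copies carry 3%
#' substitutions and 1% deletions. Reads are simulated at 30x depth.
#' Operating points follow the read profile: kMAPQ threshold 12 and
#' ground-truth tolerance 10 bp for HiFi, threshold 10 and 30 bp for
#' ONT.
#'
#' @param name one of `"interspersed-hifi"`, `"interspersed-ont"`,
#'   `"tandem-hifi"`, `"tandem-ont"`.
#' @return Named list of benchmark parameters.
#' @export
kmapq_preset <- function(name = c("interspersed-hifi", "interspersed-ont",
                                  "tandem-hifi", "tandem-ont")) {
  name <- match.arg(name)
  mode <- if (startsWith(name, "tandem")) "tandem" else "interspersed"
  profile <- if (endsWith(name, "ont")) "ont" else "hifi"
  list(name = name, mode = mode, profile = profile,
       background_length = if (mode == "tandem") 1000000L else 2000000L,
       unit_length = 10000L,
       copies = if (mode == "tandem") 20L else 10L,
       sub_rate = 0.03, del_rate = 0.01, depth = 30,
       k = 21L, m = 3L,
       threshold = if (profile == "hifi") 12 else 10,
       tolerance = if (profile == "hifi") 10 else 30,
       convention = "printed")
}

# Stage seeds derived from one master seed; distinct offsets keep the
# genome identical across read profiles (background 1, interspersed
# copies 2, tandem copies 4; HiFi reads 3, ONT reads 5).
.stage_seeds <- function(seed, mode, profile) {
  base <- as.integer(seed) * 10L
  list(background = base + 1L,
       repeats = base + if (mode == "tandem") 4L else 2L,
       reads = base + if (profile == "ont") 5L else 3L)
}

#' Run a full synthetic repeat benchmark
#'
#' Generates a repeat-bearing genome and reads, constructs the alignment
#' set with per-copy false placements, builds the rare k-mer position
#' databases from the written FASTA/FASTQ, scores every alignment and
#' labels it against the ground truth. The result feeds
#' [benchmark_metrics()] and [best_zero_fp_operating_point()].
#'
#' @param preset preset name, see [kmapq_preset()].
#' @param seed master seed; all stage seeds derive from it.
#' @param work_dir scratch directory for the sequence and database files
#'   (created; caller removes it).
#' @param ... overrides for any preset parameter (e.g.
#'   `background_length`, `depth`) — useful for reduced-scale runs.
#' @return List with `scored` (scored `paf`), `labels`, `truth`,
#'   `copies`, `params`, `stats` (database build stats) and
#'   `n_alignments`.
#' @export
kmapq_benchmark <- function(preset = "interspersed-hifi", seed = 1,
                            work_dir = tempfile("kmapq_bench"), ...) {
  p <- utils::modifyList(kmapq_preset(preset), list(...))
  seeds <- .stage_seeds(seed, p$mode, p$profile)
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)

  bg <- make_background(p$background_length, gc = 0.5, seed = seeds$background)
  rspec <- repeat_spec(source_length = p$unit_length, copies = p$copies,
                       sub_rate = p$sub_rate, del_rate = p$del_rate,
                       mode = p$mode, seed = seeds$repeats)
  gen <- build_repeat_genome(rspec, bg)

  sspec <- read_sim_spec(profile = p$profile, depth = p$depth,
                         seed = seeds$reads)
  sim <- simulate_reads(gen$genome, sspec)
  paf <- simulate_alignments(sim$reads, sim$truth, gen$copies, gen$genome,
                             error_rate = sspec$error_rate)

  gpath <- file.path(work_dir, "genome.fa")
  rpath <- file.path(work_dir, "reads.fq")
  write_fasta(gen$genome, gpath)
  write_fastq(sim$reads, rpath)
  dbs <- build_database(gpath, rpath, file.path(work_dir, "db"),
                        kmer_params(p$k, p$m))

  scored <- score_paf(paf, dbs$ref, dbs$qry)
  labels <- label_alignments(scored, sim$truth, tolerance = p$tolerance)
  list(scored = scored, labels = labels, truth = sim$truth,
       copies = gen$copies, params = p, stats = dbs$stats,
       n_alignments = nrow(scored))
}

#' Accuracy of a benchmark at one threshold
#'
#' @param bench result of [kmapq_benchmark()].
#' @param threshold kMAPQ threshold; defaults to the preset's operating
#'   threshold.
#' @param convention see [filter_by_threshold()].
#' @return An `eval_metrics` object.
#' @export
benchmark_metrics <- function(bench, threshold = bench$params$threshold,
                              convention = bench$params$convention) {
  removed <- filter_by_threshold(bench$scored, threshold, convention)$removed_mask
  compute_metrics(score_confusion(bench$labels, removed))
}

#' Best operating point that removes no correct alignment
#'
#' Sweeps thresholds and returns the highest-sensitivity point among
#' those with zero correct alignments removed (FP = 0, i.e. precision 1
#' where defined).
#'
#' @param bench result of [kmapq_benchmark()].
#' @param thresholds thresholds to sweep.
#' @param convention see [filter_by_threshold()].
#' @return One-row data.frame (threshold, counts, precision,
#'   sensitivity).
#' @export
best_zero_fp_operating_point <- function(bench, thresholds = 0:60,
                                         convention = bench$params$convention) {
  sweep <- sweep_thresholds(bench$scored, bench$labels, thresholds, convention)
  ok <- sweep[sweep$FP == 0, , drop = FALSE]
  if (nrow(ok) == 0L) return(sweep[0L, , drop = FALSE])
  ok[which.max(ok$sensitivity), , drop = FALSE]
}

#' Build databases from files, with a stage summary
#'
#' Thin wrapper over [build_database()] that reports counts (sequences
#' scanned, distinct and rare k-mers, occurrences written) the way the
#' command-line `build` subcommand does.
#'
#' @inheritParams build_database
#' @param verbose print the summary.
#' @return As [build_database()].
#' @export
run_build <- function(reference, query, out_prefix, k = 21L, m = 3L,
                      threads = 1L, verbose = TRUE) {
  res <- build_database(reference, query, out_prefix, kmer_params(k, m),
                        threads = threads)
  if (verbose)
    message(sprintf(
      "build: %.0f windows, %.0f distinct k-mers, %.0f rare (m = %d); %.0f ref + %.0f qry occurrences -> %s.{ref,qry}.{pos,idx}",
      res$stats$total_windows, res$stats$distinct_kmers, res$stats$rare_kmers,
      m, res$stats$ref_occurrences, res$stats$qry_occurrences, out_prefix))
  res
}

#' Score and filter a PAF file against built databases
#'
#' Scores every alignment, writes `<out_prefix>.kept.paf` and
#' `<out_prefix>.removed.paf`, and returns the scored records with the
#' partition summary.
#'
#' @param db_prefix database prefix from [run_build()].
#' @param paf_path input PAF.
#' @param out_prefix output prefix.
#' @param threshold kMAPQ threshold (`NULL`: score only, remove
#'   nothing).
#' @param convention see [filter_by_threshold()].
#' @param verbose print the summary.
#' @return List with `scored`, `removed_mask` and the output paths.
#' @export
run_filter <- function(db_prefix, paf_path, out_prefix, threshold = NULL,
                       convention = "printed", verbose = TRUE) {
  ref_db <- open_database(db_prefix, "ref")
  qry_db <- open_database(db_prefix, "qry")
  records <- read_paf(paf_path)
  scored <- score_paf(records, ref_db, qry_db)
  kept_path <- paste0(out_prefix, ".kept.paf")
  removed_path <- paste0(out_prefix, ".removed.paf")
  removed <- write_scored_paf(scored, kept_path, removed_path,
                              threshold, convention)
  if (verbose)
    message(sprintf("filter: %d alignments scored (%d unscorable), %d removed, %d kept",
                    nrow(scored), sum(!scored$scorable), sum(removed),
                    sum(!removed)))
  list(scored = scored, removed_mask = removed,
       kept_path = kept_path, removed_path = removed_path)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes `genome.fa`, `reads.fq`, `truth.tsv` and `alignments.paf` for
#' a preset into `out_dir`.
#'
#' @inheritParams kmapq_benchmark
#' @param out_dir output directory.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(preset = "interspersed-hifi", seed = 1, out_dir,
                         ...) {
  p <- utils::modifyList(kmapq_preset(preset), list(...))
  seeds <- .stage_seeds(seed, p$mode, p$profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bg <- make_background(p$background_length, gc = 0.5, seed = seeds$background)
  gen <- build_repeat_genome(
    repeat_spec(p$unit_length, p$copies, p$sub_rate, p$del_rate, p$mode,
                seed = seeds$repeats), bg)
  sspec <- read_sim_spec(p$profile, p$depth, seed = seeds$reads)
  sim <- simulate_reads(gen$genome, sspec)
  paf <- simulate_alignments(sim$reads, sim$truth, gen$copies, gen$genome,
                             error_rate = sspec$error_rate)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                reads = file.path(out_dir, "reads.fq"),
                truth = file.path(out_dir, "truth.tsv"),
                alignments = file.path(out_dir, "alignments.paf"))
  write_fasta(gen$genome, paths$genome)
  write_fastq(sim$reads, paths$reads)
  write_truth(sim$truth, paths$truth)
  write_paf(paf, paths$alignments)
  invisible(paths)
}

#' Evaluate kept/removed PAF files against a truth table
#'
#' @param kept_path,removed_path partitioned PAF files from
#'   [run_filter()].
#' @param truth a `ground_truth` data.frame, or a TSV path, or `NULL` to
#'   decode the truth from the read names.
#' @param tolerance start-coordinate tolerance (10 HiFi / 30 ONT).
#' @param verbose print the metrics.
#' @return An `eval_metrics` object.
#' @export
run_eval <- function(kept_path, removed_path, truth = NULL, tolerance = 10,
                     verbose = TRUE) {
  kept <- read_paf(kept_path)
  removed <- read_paf(removed_path)
  records <- rbind(kept, removed)
  decisions <- rep(c(FALSE, TRUE), c(nrow(kept), nrow(removed)))
  if (is.null(truth)) truth <- truth_from_names(unique(records$query_name))
  else if (is.character(truth)) truth <- read_truth(truth)
  labels <- label_alignments(records, truth, tolerance)
  m <- compute_metrics(score_confusion(labels, decisions))
  if (verbose) print(m)
  invisible(m)
}

#' One-command scaled demonstration of the whole pipeline
#'
#' Simulate, build, score, filter and evaluate one preset, printing a
#' precision/sensitivity table over a threshold sweep. Scale overrides
#' in `...` make it fast enough for interactive use.
#'
#' @inheritParams kmapq_benchmark
#' @param thresholds thresholds for the sweep.
#' @return Invisibly, a list with the sweep table, the operating-point
#'   metrics and the benchmark object.
#' @export
run_pipeline_demo <- function(preset = "interspersed-hifi", seed = 1,
                              thresholds = seq(0, 20, by = 2),
                              work_dir = tempfile("kmapq_demo"), ...) {
  bench <- kmapq_benchmark(preset, seed, work_dir, ...)
  on.exit(unlink(work_dir, recursive = TRUE), add = TRUE)
  sweep <- sweep_thresholds(bench$scored, bench$labels, thresholds,
                            bench$params$convention)
  op <- benchmark_metrics(bench)
  cat(sprintf("preset %s (seed %d): %d alignments, %d labelled false-positive\n",
              preset, seed, bench$n_alignments,
              sum(bench$labels == "false_positive", na.rm = TRUE)))
  print(sweep, row.names = FALSE)
  cat(sprintf("operating threshold %g: precision = %s, sensitivity = %s\n",
              bench$params$threshold,
              ifelse(is.na(op$precision), "undefined", sprintf("%.3f", op$precision)),
              ifelse(is.na(op$sensitivity), "undefined", sprintf("%.3f", op$sensitivity))))
  invisible(list(sweep = sweep, operating_point = op, bench = bench))
}
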