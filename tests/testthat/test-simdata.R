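# Synthetic-data generator: backgrounds, diverged repeat copies, repeat
# genomes with recorded coordinates, reads with encoded origins, and
# placement-mode alignment sets.

test_that("background generation is deterministic with controllable GC", {
  a <- make_background(5000, seed = 61)
  b <- make_background(5000, seed = 61)
  expect_identical(a, b)
  expect_false(identical(unname(a), unname(make_background(5000, seed = 62))))

  at_only <- make_background(2000, gc = 0, seed = 63)
  expect_false(grepl("[GC]", at_only))

  big <- make_background(1000000, gc = 0.4, seed = 64)
  gc <- (lengths(regmatches(big, gregexpr("[GC]", big)))) / 1000000
  expect_lt(abs(gc - 0.4), 0.01)
})

test_that("mutate_copy applies exact-count substitutions then deletions", {
  set.seed(65)
  unit <- random_dna(5000)
  expect_identical(mutate_copy(unit, 0, 0), unit)
  expect_identical(mutate_copy(unit, 0, 1), "")

  sub_only <- mutate_copy(unit, 0.03, 0, seed = 66)
  expect_identical(nchar(sub_only), 5000L)
  diffs <- sum(strsplit(unit, "")[[1]] != strsplit(sub_only, "")[[1]])
  expect_identical(diffs, 150L)  # exactly floor(0.03 * 5000), never same base

  both <- mutate_copy(unit, 0.03, 0.01, seed = 67)
  expect_identical(nchar(both), 5000L - 50L)  # ceil((1 - 0.01) * 5000)

  with_ins <- mutate_copy(unit, 0, 0, ins_rate = 0.02, seed = 68)
  expect_identical(nchar(with_ins), 5100L)
})

test_that("repeat genomes record coordinates that re-extract the copies", {
  bg <- make_background(60000, seed = 71)

  # zero-rate copies are verbatim substrings at their recorded coordinates
  gen0 <- build_repeat_genome(repeat_spec(1500, 4, sub_rate = 0, del_rate = 0,
                                          seed = 72), bg)
  for (i in 1:4)
    expect_identical(unname(substr(gen0$genome, gen0$copies$start[i] + 1,
                                   gen0$copies$end[i])), gen0$unit)
  expect_identical(unname(nchar(gen0$genome)), 60000L + 4L * 1500L)

  # diverged copies re-extract with the configured divergence
  gen <- build_repeat_genome(repeat_spec(2000, 5, seed = 73), bg)
  expect_identical(unname(nchar(gen$genome)), 60000L + sum(gen$copies$length))
  expect_true(all(gen$copies$length == 2000L - 20L))
  expect_true(all(diff(gen$copies$start) >= gen$copies$length[-5]))
  for (i in 1:5) {
    cp <- substr(gen$genome, gen$copies$start[i] + 1, gen$copies$end[i])
    d <- utils::adist(cp, gen$unit)[1, 1]
    expect_lte(d, 2000 * 0.04 + 1)   # subs + dels
    expect_gte(d, 20L)               # at least the deletions
  }

  # tandem mode appends one contiguous head-to-tail array
  gent <- build_repeat_genome(repeat_spec(1000, 6, mode = "tandem", seed = 74), bg)
  expect_identical(gent$copies$start[1], 60000L)
  expect_identical(gent$copies$start[-1], head(gent$copies$end, -1))

  expect_error(build_repeat_genome(
    repeat_spec(1000, 5, seed = 75), make_background(3, seed = 1)), "too short")
})

test_that("simulated reads hit their encoded origins and target depth", {
  g <- make_background(200000, seed = 81)
  spec0 <- read_sim_spec("hifi", depth = 10, error_rate = 0,
                         read_length_mean = 8000, read_length_sd = 1000,
                         seed = 82)
  sim <- simulate_reads(g, spec0)
  expect_identical(names(sim$reads), sim$truth$read_name)

  # error-free reads are exact (possibly reverse-complemented) substrings
  for (i in seq_len(min(30, nrow(sim$truth)))) {
    sub <- unname(substr(g, sim$truth$start[i] + 1, sim$truth$start[i] + sim$truth$span[i]))
    want <- if (sim$truth$strand[i] == "-") kmapq:::cpp_revcomp_string(sub) else sub
    expect_identical(unname(sim$reads[i]), want)
  }

  # realized depth within 10% of the target
  expect_lt(abs(sum(sim$truth$span) / 200000 - 10) / 10, 0.1)

  # determinism
  sim2 <- simulate_reads(g, spec0)
  expect_identical(sim$reads, sim2$reads)

  # error model changes roughly the requested fraction of bases
  spec_err <- read_sim_spec("hifi", depth = 2, error_rate = 0.05,
                            read_length_mean = 8000, read_length_sd = 1000,
                            seed = 83)
  sime <- simulate_reads(g, spec_err)
  r1 <- sime$reads[[1]]
  sub <- substr(g, sime$truth$start[1] + 1, sime$truth$start[1] + sime$truth$span[1])
  if (sime$truth$strand[1] == "-") sub <- kmapq:::cpp_revcomp_string(sub)
  d <- utils::adist(r1, sub)[1, 1] / nchar(sub)
  expect_gt(d, 0.02)
  expect_lt(d, 0.08)

  expect_error(simulate_reads(c(x = "ACGT"), spec0), "shorter")
})

test_that("placement mode emits one true alignment plus one per homologous copy", {
  bg <- make_background(80000, seed = 91)
  gen <- build_repeat_genome(repeat_spec(3000, 5, seed = 92), bg)
  spec <- read_sim_spec("hifi", depth = 4, read_length_mean = 6000,
                        read_length_sd = 500, seed = 93)
  sim <- simulate_reads(gen$genome, spec)
  paf <- simulate_alignments(sim$reads, sim$truth, gen$copies, gen$genome,
                             error_rate = spec$error_rate)

  n_aln <- table(paf$query_name)[sim$truth$read_name]
  ov <- vapply(seq_len(nrow(sim$truth)), function(i)
    any(gen$copies$start < sim$truth$start[i] + sim$truth$span[i] &
          gen$copies$end > sim$truth$start[i]), logical(1))
  expect_true(all(n_aln[!ov] == 1))
  # one placement per copy, except those that would run off the genome end
  expect_true(all(n_aln[ov] >= 2 & n_aln[ov] <= 5))
  expect_true(any(n_aln[ov] == 5))

  # every constructed false placement violates the tolerance rule and every
  # true placement satisfies it
  labels <- label_alignments(paf, sim$truth, tolerance = 10)
  is_true_locus <- paf$target_start ==
    sim$truth$start[match(paf$query_name, sim$truth$read_name)]
  expect_identical(labels == "correct", is_true_locus)

  # multi-placed reads get low MAPQ, unique ones full confidence
  expect_true(all(paf$mapq[paf$query_name %in% names(n_aln)[n_aln > 1]] <= 3))
  expect_true(all(paf$mapq[paf$query_name %in% names(n_aln)[n_aln == 1]] == 60L))

  expect_error(simulate_alignments(sim$reads, sim$truth, gen$copies,
                                   gen$genome, mode = "external",
                                   aligner = "no_such_aligner_exe"),
               class = "kmapq_aligner_missing")
})

test_that("rare k-mers are depleted inside repeat copies relative to background", {
  fix <- make_fixture(seed = 95, background_length = 80000L,
                      unit_length = 4000L, copies = 6L, depth = 1,
                      read_length_mean = 3000, read_length_sd = 300)
  occ <- fetch_sequence_list(fix$dbs$ref, names(fix$gen$genome))$occurrences
  cp <- fix$gen$copies
  in_copy <- rep(FALSE, length(occ$pos))
  for (i in seq_len(nrow(cp)))
    in_copy <- in_copy | (occ$pos >= cp$start[i] & occ$pos < cp$end[i])
  copy_bases <- sum(cp$length)
  bg_bases <- unname(nchar(fix$gen$genome)) - copy_bases
  density_copy <- sum(in_copy) / copy_bases
  density_bg <- sum(!in_copy) / bg_bases
  expect_lt(density_copy / density_bg, 1)
  unlink(fix$wd, recursive = TRUE)
})
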