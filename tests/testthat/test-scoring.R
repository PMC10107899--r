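# kMAPQ scoring: common k-mer matching, position-sequence construction,
# LIS against the DP oracle, the score formula, end-to-end discrimination
# and threshold filtering.

occ_df <- function(pos, code, orient = rep("+", length(pos))) {
  data.frame(pos = as.integer(pos), code = as.character(code),
             orient = orient, stringsAsFactors = FALSE)
}

test_that("match_common pairs only codes unique in both sublists", {
  a <- occ_df(c(0, 10, 20), c("5", "7", "9"))
  b <- occ_df(c(3, 13, 23), c("11", "13", "17"))
  expect_identical(nrow(match_common(a, b)), 0L)

  b2 <- occ_df(c(3, 13, 23), c("9", "5", "7"))
  m <- match_common(a, b2)
  expect_identical(m$code, c("9", "5", "7"))       # ordered by query position
  expect_identical(m$ref_pos, c(20L, 0L, 10L))
  expect_identical(m$qry_pos, c(3L, 13L, 23L))

  # a code occurring twice in the reference sublist is excluded from pairing
  a3 <- occ_df(c(0, 5, 10, 15, 20), c("5", "7", "5", "9", "11"))
  b3 <- occ_df(c(2, 6, 9), c("5", "9", "11"))
  m3 <- match_common(a3, b3)
  expect_false("5" %in% m3$code)
  expect_identical(sort(m3$code), c("11", "9"))
  # ... and exhaustive pairing over all unique-unique codes agrees
  both <- intersect(a3$code[!duplicated(a3$code) & !duplicated(a3$code, fromLast = TRUE)],
                    b3$code)
  expect_identical(sort(m3$code), sort(both))
})

test_that("position sequence follows query order; '-' strand reverses it", {
  pairs <- data.frame(ref_pos = c(100L, 200L, 300L), qry_pos = c(5L, 15L, 25L),
                      code = c("a", "b", "c"))
  expect_identical(build_position_sequence(pairs, "+"), c(100L, 200L, 300L))
  expect_identical(build_position_sequence(pairs, "-"), c(300L, 200L, 100L))

  # collinear '-' pairs (ref descending in query order) become increasing
  rev_pairs <- data.frame(ref_pos = c(300L, 200L, 100L), qry_pos = c(5L, 15L, 25L))
  s <- build_position_sequence(rev_pairs, "-")
  expect_true(all(diff(s) > 0))

  set.seed(41)
  perm <- sample(1:50)
  pp <- data.frame(ref_pos = perm * 10L, qry_pos = seq(5L, by = 7L, length.out = 50))
  expect_identical(build_position_sequence(pp, "+"), perm * 10L)
})

test_that("LIS length equals the O(n^2) DP oracle", {
  expect_identical(lis_length(integer(0)), 0L)
  expect_identical(lis_length(1:5), 5L)
  expect_identical(lis_length(c(3L, 1L, 4L, 7L, 5L, 9L, 2L, 6L)), 4L)
  set.seed(43)
  for (i in 1:300) {
    n <- sample(1:200, 1)
    x <- sample.int(10 * n, n)
    expect_identical(lis_length(x), lis_dp(x))
  }
})

test_that("kmapq_score reproduces the formula and handles degenerate inputs", {
  expect_equal(kmapq_score(10, 10, 15), list(kmapq = 0, lis_fraction = 1, scorable = TRUE))
  expect_equal(kmapq_score(1, 10, 10)$kmapq, 10)
  expect_equal(kmapq_score(5, 10, 20)$kmapq, -10 * log10(0.5), tolerance = 1e-12)
  expect_equal(kmapq_score(5, 10, 20)$kmapq, 3.0103, tolerance = 1e-4)

  z <- kmapq_score(0, 0, 5)
  expect_false(z$scorable)
  expect_identical(kmapq_score(0, 10, 10)$kmapq, 60)
  expect_error(kmapq_score(6, 5, 10), "consistency")

  # monotone non-increasing in l_lis at fixed sublist lengths
  ks <- vapply(1:20, function(l) kmapq_score(l, 20, 30)$kmapq, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("self-alignments score a full LIS fraction; strand symmetry holds", {
  # an error-free read copied verbatim from a repeat-free reference at its
  # true locus: every rare k-mer of the read matches uniquely and collinearly
  g <- make_background(30000L, seed = 401)
  id <- names(g)
  piece <- unname(substr(g, 10001, 14000))
  wd <- tempfile(); dir.create(wd)
  write_fasta(g, file.path(wd, "g.fa"))
  write_fastq(c(`copy!chrS!10000!+` = piece), file.path(wd, "r.fq"))
  dbs <- build_database(file.path(wd, "g.fa"), file.path(wd, "r.fq"),
                        file.path(wd, "db"))
  rec <- list(query_name = "copy!chrS!10000!+", query_start = 0L,
              query_end = 4000L, target_name = id, target_start = 10000L,
              target_end = 14000L, strand = "+")
  sc <- score_alignment(rec, dbs$ref, dbs$qry)
  expect_identical(sc$lis_fraction, 1)
  expect_identical(sc$kmapq, 0)

  # the reverse-complemented read, aligned as '-', matches the same LIS
  write_fastq(c(`rc!chrS!10000!-` = kmapq:::cpp_revcomp_string(piece)),
              file.path(wd, "r2.fq"))
  dbs2 <- build_database(file.path(wd, "g.fa"), file.path(wd, "r2.fq"),
                         file.path(wd, "db2"))
  rec2 <- list(query_name = "rc!chrS!10000!-", query_start = 0L,
               query_end = 4000L, target_name = id, target_start = 10000L,
               target_end = 14000L, strand = "-")
  sc2 <- score_alignment(rec2, dbs2$ref, dbs2$qry)
  expect_identical(sc2$l_lis, sc$l_lis)
  expect_identical(sc2$lis_fraction, 1)

  # a record on a sequence absent from the query database is unscorable
  rec3 <- rec; rec3$query_name <- "ghost"
  sc3 <- score_alignment(rec3, dbs$ref, dbs$qry)
  expect_false(sc3$scorable)
  unlink(wd, recursive = TRUE)
})

test_that("fast and step-by-step scoring paths agree exactly", {
  fix <- make_fixture(seed = 403, background_length = 40000L,
                      unit_length = 2000L, copies = 3L, depth = 3,
                      read_length_mean = 5000, read_length_sd = 800)
  sf <- score_paf(fix$paf, fix$dbs$ref, fix$dbs$qry, method = "fast")
  sr <- score_paf(fix$paf, fix$dbs$ref, fix$dbs$qry, method = "reference")
  expect_identical(sf$l_r, sr$l_r)
  expect_identical(sf$l_q, sr$l_q)
  expect_identical(sf$l_lis, sr$l_lis)
  expect_equal(sf$kmapq, sr$kmapq)
  expect_identical(sf$scorable, sr$scorable)
  unlink(fix$wd, recursive = TRUE)
})

test_that("true-locus alignments outscore wrong-copy alignments", {
  fix <- make_fixture(seed = 405, background_length = 120000L,
                      unit_length = 4000L, copies = 6L, depth = 5,
                      read_length_mean = 9000, read_length_sd = 1500)
  scored <- score_paf(fix$paf, fix$dbs$ref, fix$dbs$qry)
  labels <- label_alignments(scored, fix$sim$truth, tolerance = 10)
  tru <- scored$lis_fraction[labels == "correct" & scored$scorable]
  fps <- scored$lis_fraction[labels == "false_positive" & scored$scorable]
  expect_gt(length(fps), 100)
  expect_gt(mean(tru) - mean(fps), 0.2)
  unlink(fix$wd, recursive = TRUE)
})

test_that("threshold filtering follows both conventions and keeps unscorables", {
  sc <- data.frame(kmapq = c(0, 5, 12, 30, NA), lis_fraction = c(1, .32, .063, .001, NA),
                   scorable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  f <- filter_by_threshold(sc, 12, "printed")
  expect_identical(f$removed_mask, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(nrow(f$kept) + nrow(f$removed), nrow(sc))

  # boundary: kmapq exactly at the threshold is removed (inclusive)
  expect_true(filter_by_threshold(sc, 12, "printed")$removed_mask[3])
  # threshold 0 removes every scorable record with fraction < 1
  expect_identical(filter_by_threshold(sc, 0, "printed")$removed_mask,
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))

  # mapq_like: -10log10(1 - fraction) below threshold is removed
  g <- filter_by_threshold(sc, 10, "mapq_like")
  s2 <- ifelse(sc$lis_fraction >= 1, 60, -10 * log10(1 - sc$lis_fraction))
  expect_identical(g$removed_mask, ifelse(is.na(s2), FALSE, sc$scorable & s2 < 10))

  expect_error(filter_by_threshold(sc, 12, "bogus"))
  expect_error(filter_by_threshold(sc, -1))

  # brute-force partition check on a random fixture
  set.seed(47)
  rsc <- data.frame(kmapq = runif(10, 0, 60), scorable = TRUE)
  rsc$lis_fraction <- 10^(-rsc$kmapq / 10)
  mask <- filter_by_threshold(rsc, 12, "printed")$removed_mask
  for (i in 1:10) expect_identical(mask[i], rsc$kmapq[i] >= 12)
})
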