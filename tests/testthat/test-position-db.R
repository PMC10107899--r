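# On-disk position database: build determinism, index correctness,
# roundtrip against in-memory scanning, interval extraction vs linear
# filtering, and the in-file query search vs the in-memory path.

fix <- make_fixture()

test_that("build is deterministic and the index resolves every sequence", {
  wd <- tempfile(); dir.create(wd)
  p1 <- file.path(wd, "a"); p2 <- file.path(wd, "b")
  d1 <- build_database(fix$gpath, fix$rpath, p1)
  d2 <- build_database(fix$gpath, fix$rpath, p2)
  for (side in c("ref", "qry")) {
    f1 <- paste0(p1, ".", side, ".pos"); f2 <- paste0(p2, ".", side, ".pos")
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  expect_identical(d1$ref$hash, d2$ref$hash)

  # every index offset points at the line for exactly that ID, and offsets
  # equal cumulative byte counts of the preceding lines
  con <- file(d1$qry$data_path, "rb")
  on.exit(close(con))
  sizes <- numeric(0)
  for (id in names(d1$qry$index)) {
    seek(con, d1$qry$index[[id]])
    line <- readLines(con, n = 1L)
    expect_identical(sub("\t.*$", "", line), id)
    sizes <- c(sizes, nchar(line, type = "bytes") + 1)
  }
  hdr_bytes <- d1$qry$index[[1L]]
  expect_equal(unname(d1$qry$index),
               hdr_bytes + cumsum(c(0, sizes[-length(sizes)])))
  unlink(wd, recursive = TRUE)
})

test_that("fetch after build equals in-memory scanning; absent IDs signal", {
  rare <- select_rare(count_kmers(fix$gen$genome, 21L), 3L)
  want <- scan_positions(fix$gen$genome, rare)$occurrences
  got <- fetch_sequence_list(fix$dbs$ref, names(fix$gen$genome))$occurrences
  expect_equal(got, want, ignore_attr = TRUE)

  # a query read, scanned against the reference-derived rare set
  rid <- names(fix$sim$reads)[5]
  wantq <- scan_positions(fix$sim$reads[rid], rare, id = rid)$occurrences
  gotq <- fetch_sequence_list(fix$dbs$qry, rid)$occurrences
  expect_equal(gotq, wantq, ignore_attr = TRUE)

  expect_error(fetch_sequence_list(fix$dbs$ref, "nope"),
               class = "kmapq_missing_sequence")
})

test_that("every recorded occurrence re-verifies by substring extraction", {
  occ <- fetch_sequence_list(fix$dbs$ref, names(fix$gen$genome))$occurrences
  idx <- seq(1, nrow(occ), length.out = min(200, nrow(occ)))
  for (i in round(idx)) {
    w <- substr(fix$gen$genome, occ$pos[i] + 1, occ$pos[i] + 21)
    cn <- canonical_code(encode_kmer(w), 21)
    expect_identical(as.character(cn$code), occ$code[i])
    expect_identical(cn$orient, occ$orient[i])
  }
})

test_that("a reference with no rare k-mers yields one empty line per sequence", {
  wd <- tempfile(); dir.create(wd)
  db <- build_database(c(only = strrep("A", 100)), c(r1 = strrep("A", 40)),
                       file.path(wd, "z"), kmer_params(3, 1))
  occ <- fetch_sequence_list(db$ref, "only")$occurrences
  expect_identical(nrow(occ), 0L)
  expect_identical(db$stats$rare_kmers, 0)
  unlink(wd, recursive = TRUE)
})

test_that("duplicate sequence IDs abort the build with the offending ID", {
  expect_error(
    build_database(c(a = "ACGTACGTACGT", a = "ACGTTT"), c(r = "ACGT"),
                   tempfile(), kmer_params(3, 3)),
    regexp = "'a'", class = "kmapq_build_error")
  expect_error(build_database(character(0), c(r = "ACGT"), tempfile()),
               class = "kmapq_build_error")
})

test_that("extract_sublist agrees with a linear-scan filter", {
  lst <- fetch_sequence_list(fix$dbs$qry, names(fix$sim$reads)[1])
  expect_equal(extract_sublist(lst, 0, nchar(fix$sim$reads[[1]])),
               lst$occurrences, ignore_attr = TRUE)
  expect_identical(nrow(extract_sublist(lst, 0, 20)), 0L)  # no window fits

  set.seed(31)
  occ <- lst$occurrences
  L <- nchar(fix$sim$reads[[1]])
  for (i in 1:1000) {
    a <- sample(0:L, 1); b <- a + sample(0:(L - a), 1)
    expect_equal(extract_sublist(lst, a, b),
                 naive_extract(occ, a, b, 21L), ignore_attr = TRUE)
  }
})

test_that("in-file query search equals the in-memory path, including boundaries", {
  ids <- names(fix$sim$reads)[1:20]
  set.seed(37)
  for (id in ids) {
    lst <- fetch_sequence_list(fix$dbs$qry, id)
    L <- nchar(fix$sim$reads[[match(id, names(fix$sim$reads))]])
    ivs <- rbind(c(0, L), c(0, 20), c(0, 0),
                 matrix(c(a <- sample(0:L, 5), pmin(L, a + sample(0:L, 5))), ncol = 2))
    if (nrow(lst$occurrences)) {
      p1 <- lst$occurrences$pos[1]; pn <- tail(lst$occurrences$pos, 1)
      ivs <- rbind(ivs, c(p1, p1 + 21), c(p1 + 1, p1 + 21), c(pn, pn + 20),
                   c(pn, pn + 21))
    }
    for (r in seq_len(nrow(ivs))) {
      a <- ivs[r, 1]; b <- max(ivs[r, ])
      expect_equal(sublist_for_query(fix$dbs$qry, id, a, b),
                   extract_sublist(lst, a, b), ignore_attr = TRUE)
    }
  }
  expect_error(sublist_for_query(fix$dbs$qry, "nope", 0, 10),
               class = "kmapq_missing_sequence")
})

test_that("reference cache loads each reference once under sorted processing", {
  cache <- new_ref_cache()
  id <- names(fix$gen$genome)
  s1 <- sublist_for_reference(fix$dbs$ref, id, 0, 5000, cache)
  s2 <- sublist_for_reference(fix$dbs$ref, id, 5000, 9000, cache)
  expect_identical(cache$loads, 1L)
  expect_equal(s2, extract_sublist(fetch_sequence_list(fix$dbs$ref, id), 5000, 9000),
               ignore_attr = TRUE)
  expect_gt(nrow(s1), 0)

  # two references, queries grouped by reference: loads = distinct references
  set.seed(201)
  refs <- c(c1 = random_dna(3000), c2 = random_dna(3000))
  wd <- tempfile(); dir.create(wd)
  dbs <- build_database(refs, c(r1 = random_dna(500)), file.path(wd, "db"))
  cache2 <- new_ref_cache()
  for (q in list(c("c1", 0, 1000), c("c1", 1000, 2000),
                 c("c2", 0, 1000), c("c2", 500, 1500)))
    sublist_for_reference(dbs$ref, q[[1]], as.numeric(q[[2]]),
                          as.numeric(q[[3]]), cache2)
  expect_identical(cache2$loads, 2L)
  unlink(wd, recursive = TRUE)
})

test_that("open_database reconstructs a usable handle with matching hash", {
  db <- open_database(file.path(fix$wd, "db"), "qry")
  expect_identical(db$k, 21L)
  expect_identical(db$m, 3L)
  expect_identical(db$hash, fix$dbs$qry$hash)
  id <- names(fix$sim$reads)[3]
  expect_equal(sublist_for_query(db, id, 0, 2000),
               sublist_for_query(fix$dbs$qry, id, 0, 2000))
})
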