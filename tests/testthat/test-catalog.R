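test_that("catalog construction counts and conserves classified records", {
  ab <- build_alphabet("SBS96")
  r <- make_records("s1", "chr1", c(100L, 5000L, 9000L),
                    ref = "C", alt = "T",
                    context5 = "T", context3 = "G")
  cat1 <- catalog_from_records(r, ab)
  expect_equal(unname(cat1$counts["T[C>T]G", "s1"]), 3L)
  expect_equal(sum(cat1$counts), 3L)

  # mixed types over two samples: column sums = classified records
  set.seed(3)
  n <- 10L
  bases <- c("A", "C", "G", "T")
  ref <- sample(c("C", "T"), n, replace = TRUE)
  alt <- mapply(function(r) sample(setdiff(bases, r), 1), ref)
  rr <- data.frame(sample = rep(c("s1", "s2"), each = 5),
                   chrom = "chr1", pos = seq(1000L, by = 5000L, length.out = n),
                   ref = ref, alt = alt,
                   context5 = sample(bases, n, TRUE),
                   context3 = sample(bases, n, TRUE),
                   stringsAsFactors = FALSE)
  cat2 <- catalog_from_records(rr, ab)
  expect_equal(unname(colSums(cat2$counts)), c(5L, 5L))

  empty <- catalog_from_records(r[0, ], ab)
  expect_equal(ncol(empty$counts), 0L)
})

test_that("extended-class precedence is kataegis, dinucleotide, indel, then substitution", {
  ab <- build_alphabet("SBS96_EXT4")
  # a kataegis run of 6 that also contains adjacent pairs: kataegis wins
  kat <- make_records("s1", "chr1", c(100L, 101L, 200L, 300L, 400L, 500L),
                      ref = "C", alt = "T", context5 = "T", context3 = "G")
  # an isolated adjacent pair elsewhere -> one dinucleotide event
  dinu <- make_records("s1", "chr2", c(1000L, 1001L),
                       ref = "C", alt = "G", context5 = "A", context3 = "A")
  # one repeat indel, one microhomology deletion, one lone substitution
  ind <- data.frame(sample = "s1", chrom = "chr3",
                    pos = c(50L, 150L), ref = c("A", "CTAG"), alt = "-",
                    context5 = NA, context3 = NA,
                    flank5 = c("T", "GGGG"), flank3 = c("AAAT", "CTGA"),
                    stringsAsFactors = FALSE)
  lone <- make_records("s1", "chr4", 7000L, ref = "G", alt = "A",
                       context5 = "C", context3 = "A")
  rec <- merge_all(kat, dinu, ind, lone)
  cat <- catalog_from_records(rec, ab, kataegis_max_imd = 1000L,
                              kataegis_min_run = 6L)
  expect_equal(unname(cat$counts["kataegis", "s1"]), 6L)
  expect_equal(unname(cat$counts["dinucleotide", "s1"]), 1L)
  expect_equal(unname(cat$counts["indel_repeat", "s1"]), 1L)
  expect_equal(unname(cat$counts["indel_microhomology", "s1"]), 1L)
  expect_equal(unname(cat$counts["T[C>T]G", "s1"]), 1L)  # G>A collapsed
  expect_equal(sum(cat$counts), 10L)

  # deterministic: same input, same catalog
  expect_identical(cat$counts,
                   catalog_from_records(rec, ab, kataegis_max_imd = 1000L,
                                        kataegis_min_run = 6L)$counts)
})

test_that("strict mode errors on unclassifiable records, lenient skips", {
  ab <- build_alphabet("SBS96")
  rec <- data.frame(sample = "s1", chrom = "chr1", pos = c(10L, 20L),
                    ref = c("C", "A"), alt = c("T", "-"),
                    context5 = "T", context3 = "G",
                    stringsAsFactors = FALSE)
  lenient <- catalog_from_records(rec, ab)
  expect_equal(sum(lenient$counts), 1L)
  expect_equal(attr(lenient, "skipped"), 1L)
  expect_error(catalog_from_records(rec, ab, strict = TRUE),
               "unclassifiable")
})

test_that("catalog TSV round-trips and enforces invariants", {
  ab <- build_alphabet("SBS96")
  set.seed(9)
  counts <- matrix(rpois(96 * 3, 5), 96, 3)
  cat0 <- new_catalog(counts, ab, c("a", "b", "c"))
  f <- tempfile(fileext = ".tsv")
  write_catalog(cat0, f)
  back <- read_catalog(f)
  expect_identical(unname(back$counts), unname(cat0$counts))
  expect_equal(back$samples, cat0$samples)
  expect_equal(back$alphabet$scheme, "SBS96")

  # shuffled rows are canonicalised back to alphabet order
  lines <- readLines(f)
  shuf <- c(lines[1], sample(lines[-1]))
  f2 <- tempfile(fileext = ".tsv")
  writeLines(shuf, f2)
  expect_identical(read_catalog(f2)$counts, cat0$counts)

  # negative counts rejected
  bad <- lines
  bad[2] <- sub("\t\\d+", "\t-1", bad[2])
  f3 <- tempfile(fileext = ".tsv")
  writeLines(bad, f3)
  expect_error(read_catalog(f3), "negative")

  # ragged rows rejected
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c(lines[1], paste0(lines[2], "\t9"), lines[-(1:2)]), f4)
  expect_error(read_catalog(f4), "ragged")

  # unknown label rejected
  bad2 <- lines
  bad2[2] <- sub("^[^\t]+", "Z[C>T]Q", bad2[2])
  f5 <- tempfile(fileext = ".tsv")
  writeLines(bad2, f5)
  expect_error(read_catalog(f5))
})
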