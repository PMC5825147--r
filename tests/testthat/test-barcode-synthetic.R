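test_that("synth_initial_distribution allocates cells exactly", {
  u <- synth_initial_distribution(14000, 3e5)
  expect_equal(sum(u), 3e5)
  expect_true(all(u %in% c(21, 22))) # 300000/14000 = 21.43
  expect_error(synth_initial_distribution(10, 5), "cannot spread")

  set.seed(601)
  for (trial in 1:3) {
    sk <- synth_initial_distribution(500, 10000, shape = 1.5)
    expect_equal(sum(sk), 10000)
    expect_true(all(sk >= 1))
  }
})

test_that("skew parameter monotonically increases the Gini", {
  set.seed(602)
  gini_at <- function(shape) {
    mean(replicate(4, {
      gini_coefficient(clone_table(synth_initial_distribution(400, 8000,
                                                              shape = shape)))
    }))
  }
  g <- c(gini_at(0.3), gini_at(1), gini_at(2.5))
  expect_true(all(diff(g) > 0))
})

test_that("synthetic libraries satisfy the reference-library invariants", {
  set.seed(603)
  lib <- synth_reference_library(50, width = 12)
  expect_equal(nrow(lib), 50)
  expect_equal(anyDuplicated(lib$barcode), 0)
  expect_equal(sum(lib$frequency), 1)
  expect_true(all(nchar(lib$barcode) == 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_library(lib, path)
  back <- read_reference_library(path)
  expect_equal(back$barcode, lib$barcode)
  expect_equal(back$frequency, lib$frequency, tolerance = 1e-12)
})

test_that("extract_barcodes round-trips synth_fastq counts losslessly", {
  set.seed(604)
  lib <- synth_reference_library(30, width = 16)
  counts <- stats::setNames(stats::rpois(10, 20) + 1, lib$barcode[1:10])
  path <- withr::local_tempfile(fileext = ".fastq")
  synth_fastq(counts, lib, path, error_rate = 0, quality = 70)
  got <- extract_barcodes(path, quality_threshold = 56)
  expect_equal(got[sort(names(counts))], counts[sort(names(counts))])

  # reads below the quality threshold contribute nothing
  synth_fastq(counts, lib, path, error_rate = 0, quality = 30)
  expect_length(extract_barcodes(path, quality_threshold = 56), 0)

  # empty FASTQ -> empty counts
  writeLines(character(0), path)
  expect_length(extract_barcodes(path), 0)
})

test_that("malformed FASTQ records raise indexed errors", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(extract_barcodes(path), "multiple of 4")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), path)
  expect_error(extract_barcodes(path), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), path)
  expect_error(extract_barcodes(path), "record 1")
  expect_error(extract_barcodes(path, quality_offset = 50), "encoding")
})

test_that("substitution errors push reads off-library at the binomial rate", {
  set.seed(605)
  lib <- synth_reference_library(40, width = 20)
  counts <- stats::setNames(rep(50, 40), lib$barcode)
  err <- 0.01
  miss <- replicate(4, {
    path <- tempfile(fileext = ".fastq")
    on.exit(unlink(path), add = TRUE)
    synth_fastq(counts, lib, path, error_rate = err, quality = 70)
    got <- extract_barcodes(path, quality_threshold = 56)
    off <- !(names(got) %in% lib$barcode)
    sum(got[off]) / sum(got)
  })
  p <- 1 - (1 - err)^20
  n_reads <- sum(counts)
  se <- sqrt(p * (1 - p) / n_reads)
  expect_lt(abs(mean(miss) - p), 3 * se)
})

test_that("reference-library filters follow the admission rules", {
  t1 <- c(AAA = 100, CCC = 400, GGG = 1)
  t2 <- c(AAA = 200, CCC = 300, TTT = 50)
  t3 <- c(AAA = 150, CCC = 350)
  lib <- build_reference_library(list(t1, t2, t3), min_freq = 1e-3,
                                 min_replicates = 2)
  # GGG and TTT appear in one replicate only -> excluded regardless
  expect_setequal(lib$barcode, c("AAA", "CCC"))
  expect_equal(sum(lib$frequency), 1)

  # pooled frequency below min_freq -> excluded even if in all replicates
  t4 <- c(AAA = 1e6, CCC = 1)
  t5 <- c(AAA = 1e6, CCC = 1)
  lib2 <- build_reference_library(list(t4, t5), min_freq = 1e-4)
  expect_equal(lib2$barcode, "AAA")

  # idempotence: re-applying the filters to an admitted library is a no-op
  relib <- build_reference_library(list(
    stats::setNames(lib$frequency, lib$barcode),
    stats::setNames(lib$frequency, lib$barcode)), min_freq = 1e-3)
  expect_equal(relib$barcode, lib$barcode)
  expect_equal(relib$frequency, lib$frequency, tolerance = 1e-12)

  expect_error(build_reference_library(list(t1)), "at least 2")
  expect_error(build_reference_library(list(t1, numeric(0))), "empty")
})

test_that("filter_counts_by_library conserves totals", {
  set.seed(606)
  lib <- synth_reference_library(20, width = 8)
  counts <- c(stats::setNames(1:10, lib$barcode[1:10]),
              JUNKJUNK = 40, MOREJUNK = 5)
  kept <- filter_counts_by_library(counts, lib)
  expect_equal(sum(kept) + attr(kept, "dropped_total"), sum(counts))
  expect_true(all(names(kept) %in% lib$barcode))

  none <- filter_counts_by_library(c(XXXXXXXX = 9), lib)
  expect_length(none, 0)
  expect_equal(attr(none, "dropped_total"), 9)

  filled <- filter_counts_by_library(counts, lib, fill_missing = TRUE)
  expect_equal(length(filled), 20)
  expect_equal(sum(filled == 0), 10)
})

test_that("spurious-read contamination only ever adds counts", {
  set.seed(607)
  lib <- synth_reference_library(100, width = 10)
  counts <- stats::setNames(c(rep(0, 60), rep(30, 40)), lib$barcode)
  counts <- counts[counts > 0]
  expect_identical(contaminate_with_spurious_reads(counts, lib, 0), counts)
  cont <- contaminate_with_spurious_reads(counts, lib, 0.05)
  expect_true(all(cont[names(counts)] >= counts))

  # measured clone loss is non-increasing in the contamination rate
  loss_at <- function(rate) {
    set.seed(608) # shared base counts, independent contamination draws
    cc <- contaminate_with_spurious_reads(counts, lib, rate)
    full <- filter_counts_by_library(cc, lib, fill_missing = TRUE)
    clone_loss(clone_table(full))
  }
  losses <- vapply(c(0, 0.02, 0.2), loss_at, numeric(1))
  expect_true(all(diff(losses) <= 0))
})

test_that("contamination distorts clone loss far more than the Gini", {
  set.seed(609)
  # a passaged population with many extinct clones
  tab <- passage_sample(clone_table(c(rep(0, 300), rep(15, 100))), 600)
  lib <- synth_reference_library(400, width = 10)
  counts <- stats::setNames(tab$size, lib$barcode)
  counts <- counts[counts > 0]
  base <- filter_counts_by_library(counts, lib, fill_missing = TRUE)
  cont <- contaminate_with_spurious_reads(counts, lib, 0.02)
  cont <- filter_counts_by_library(cont, lib, fill_missing = TRUE)
  rel_change <- function(f) {
    abs(f(clone_table(cont)) - f(clone_table(base))) /
      max(f(clone_table(base)), 1e-9)
  }
  expect_gt(rel_change(clone_loss), rel_change(gini_coefficient))
})
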