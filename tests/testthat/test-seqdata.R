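toy_genome <- function(seed = 1) {
  stats::setNames(generate_background(2, c(10000L), seed = seed)[1:2],
                  c("chr1", "chr2"))
}

test_that("peak extension re-centres on summit or midpoint at fixed length", {
  sizes <- c(chr1 = 20000L)
  peaks <- tibble::tibble(chrom = "chr1", start = 9900L, end = 10100L,
                          summit = 10000L)
  ext <- extend_peaks(peaks, flank = 250, chrom_sizes = sizes)
  expect_identical(ext$start, 9750L)
  expect_identical(ext$end, 10250L)
  expect_identical(ext$end - ext$start, 500L)

  # near-boundary summit is dropped with a warning
  near <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L, summit = 100L)
  expect_warning(out <- extend_peaks(near, flank = 250, chrom_sizes = sizes),
                 "Dropped")
  expect_identical(nrow(out), 0L)

  # no summit: midpoint rule
  mid <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1400L)
  extm <- extend_peaks(mid, flank = 250, chrom_sizes = sizes)
  expect_identical(extm$start, 950L)
  expect_identical(extm$end, 1450L)

  bad <- tibble::tibble(chrom = "chrX", start = 1L, end = 10L)
  expect_error(extend_peaks(bad, chrom_sizes = sizes), "chrX")
})

test_that("negative sampling avoids exclusions and reports infeasibility", {
  genome <- toy_genome()
  excl <- tibble::tibble(chrom = "chr1",
                         start = as.integer(seq(0, 9000, by = 200)),
                         end = as.integer(seq(0, 9000, by = 200) + 100L))
  neg <- sample_negatives(genome, n = 100, length = 50, exclusions = excl,
                          seed = 4)
  expect_identical(nrow(neg), 100L)
  expect_true(all(neg$end - neg$start == 50L))
  # brute-force overlap check against every exclusion interval
  overlaps <- function(a_start, a_end, b_start, b_end) {
    a_start < b_end & b_start < a_end
  }
  for (i in seq_len(nrow(neg))) {
    same <- excl[excl$chrom == neg$chrom[i], ]
    expect_false(any(overlaps(neg$start[i], neg$end[i], same$start, same$end)))
  }

  whole <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0L, end = 10000L)
  expect_error(
    sample_negatives(genome, n = 5, length = 50, exclusions = whole,
                     seed = 1, max_tries = 2000),
    "Placed only")

  expect_identical(sample_negatives(genome, 20, 80, seed = 9),
                   sample_negatives(genome, 20, 80, seed = 9))
})

test_that("interval sequences come back 0-based half-open", {
  genome <- c(chrA = "ACGTACGTAC")
  iv <- tibble::tibble(chrom = "chrA", start = 2L, end = 6L)
  expect_identical(interval_sequences(genome, iv), c(chrA = "GTAC"))
})

test_that("train/test split is a seeded partition with rounded sizes", {
  s <- tibble::tibble(id = sprintf("s%d", 1:100), x = runif(100))
  sp <- split_dataset(s, 0.8, seed = 11)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_identical(sort(c(sp$train$id, sp$test$id)), sort(s$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0)

  sp2 <- split_dataset(s, 0.8, seed = 11)
  expect_identical(sp, sp2)

  tiny <- split_dataset(s[1:5, ], 0.8, seed = 1)
  expect_identical(nrow(tiny$train), 4L)
  expect_identical(nrow(tiny$test), 1L)

  expect_error(split_dataset(s, 1.2), "between")
  expect_error(split_dataset(s[1, ]), "2 samples")
})

test_that("one-hot encoding is the standard A/C/G/T indicator and inverts", {
  m <- one_hot("ACGT")
  expect_identical(unname(m), diag(4))
  expect_identical(unname(one_hot("N")), matrix(0, 1, 4))
  expect_identical(one_hot("acgt"), one_hot("ACGT"))
  expect_error(one_hot("ACXT"), "position 3")

  seqs <- generate_background(20, 37, seed = 5)
  for (s in seqs[1:5]) expect_identical(decode_one_hot(one_hot(s)), s)
})

test_that("peak files round-trip through BED and narrowPeak conventions", {
  peaks <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100L, 5L),
                          end = c(200L, 55L))
  path <- tempfile(fileext = ".bed")
  write_peaks(peaks, path)
  back <- read_peaks(path)
  expect_identical(back[, c("chrom", "start", "end")], peaks)

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tpk1\t0\t.\t5.5\t4.4\t3.3\t30",
               "chr1\t300\t400\tpk2\t0\t.\t5.5\t4.4\t3.3\t-1"), np)
  got <- read_peaks(np)
  expect_identical(got$summit, c(130L, NA_integer_))
})
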