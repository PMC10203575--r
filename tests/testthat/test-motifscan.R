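random_pwm <- function(width, seed) {
  set.seed(seed)
  m <- matrix(rgamma(width * 4, shape = runif(1, 0.3, 3)), nrow = width)
  pwm(m / rowSums(m), name = sprintf("rand_w%d_s%d", width, seed))
}

test_that("log-odds scores are log2 probability ratios against background", {
  flat <- pwm(matrix(0.25, nrow = 2, ncol = 4), pseudocount = 0)
  expect_equal(unname(log_odds(flat)), matrix(0, 2, 4))

  half_g <- pwm(matrix(c(1/6, 1/6, 0.5, 1/6), nrow = 1), pseudocount = 0)
  expect_equal(unname(log_odds(half_g)[1, "G"]), 1) # log2(0.5 / 0.25) = 1 bit

  # consensus outscores every single-mismatch k-mer
  p <- benchmark_pwm("GCACGT")
  cons <- top_affinity_kmer(p)
  s_cons <- max(position_scores(cons, p, strand = "+"))
  for (i in 1:6) {
    for (b in c("A", "C", "G", "T")) {
      mut <- cons
      substr(mut, i, i) <- b
      if (mut == cons) next
      expect_lt(position_scores(mut, p, strand = "+")[1], s_cons)
    }
  }
})

test_that("top-affinity k-mer is the per-column argmax with A<C<G<T ties", {
  cols <- c("G", "C", "A", "C", "G", "T", "G", "C")
  probs <- matrix(0.01, nrow = 8, ncol = 4)
  probs[cbind(1:8, match(cols, c("A", "C", "G", "T")))] <- 0.97
  expect_identical(top_affinity_kmer(pwm(probs)), "GCACGTGC")

  uniform <- pwm(matrix(0.25, 1, 4))
  expect_identical(top_affinity_kmer(uniform), "A")

  onehot <- pwm(diag(4), pseudocount = 0.1)
  expect_identical(top_affinity_kmer(onehot), "ACGT")
})

test_that("DP score distribution equals exhaustive enumeration on its lattice", {
  for (seed in 1:20) {
    w <- sample(3:5, 1)
    p <- random_pwm(w, seed)
    dp <- score_distribution(p, method = "dp", score_bins = 1000)
    en <- score_distribution(p, method = "enumerate", score_bins = 1000)
    expect_identical(nrow(dp), nrow(en))
    expect_equal(dp$score, en$score, tolerance = 1e-12)
    expect_lt(max(abs(dp$prob - en$prob)), 1e-12)
    # tails agree too
    expect_lt(max(abs(rev(cumsum(rev(dp$prob))) - rev(cumsum(rev(en$prob))))),
              1e-12)
    expect_equal(sum(dp$prob), 1, tolerance = 1e-12)
  }
})

test_that("p-value thresholds behave at the degenerate extremes", {
  # uniform PWM: every w-mer scores 0, tail probability 1 everywhere
  uni <- pwm(matrix(0.25, 4, 4), pseudocount = 0)
  expect_warning(t0 <- threshold_from_pvalue(uni, 1e-5), "minimal achievable")
  expect_equal(t0$p_achieved, 1)

  # total acceptance: threshold is the minimum achievable score
  p <- random_pwm(4, 3)
  dist <- score_distribution(p, method = "enumerate")
  t1 <- threshold_from_pvalue(p, 1)
  expect_equal(t1$threshold, dist$score[1])

  # achieved tail never exceeds the requested cutoff when attainable
  t2 <- threshold_from_pvalue(p, 0.01)
  expect_lte(t2$p_achieved, 0.01)

  expect_error(threshold_from_pvalue(p, 0))
})

test_that("scanning finds planted consensus sites on both strands", {
  p <- benchmark_pwm()
  set.seed(5)
  bg <- generate_background(1, 500, seed = 21)
  seq_fwd <- embed_motif(bg, "GCACGTGC", 100)
  # an 8-mer's best single-word tail is 4^-8 = 1.5e-5, so use 1e-4 here
  hits <- scan_sequences(c(s1 = seq_fwd), p, p_cutoff = 1e-4)
  plus <- hits[hits$strand == "+", ]
  expect_true(100 %in% plus$start)

  # reverse complement: mirrored offset 500 - 100 - 8 = 392, minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  hits_rc <- scan_sequences(c(s1 = rc), p, p_cutoff = 1e-4)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_true(392 %in% minus$start)
  # mirrored hits carry identical scores
  expect_equal(sort(hits$score), sort(hits_rc$score))

  expect_identical(nrow(scan_sequences(c(x = strrep("N", 50)), p,
                                       p_cutoff = 1e-4)), 0L)
})

test_that("MEME-style aggregation schemes reduce as defined", {
  expect_equal(aggregate_scores(list(c(1, -2, 3)), "M1-SUM"), 2)
  expect_equal(aggregate_scores(list(c(1, -2, 3)), "M1-MAX"), 3)
  two <- list(c(1, 2), c(0, 5))
  expect_equal(aggregate_scores(two, "MAX-SUM"), 7)
  expect_equal(aggregate_scores(two, "MAX-MAX"), 5)
  expect_equal(aggregate_scores(two, "SUM-SUM"), 8)
  expect_equal(aggregate_scores(two, "SUM-MAX"), 5)
  expect_error(aggregate_scores(two, "MIN-MAX"))

  # singleton collapse: every scheme is either sum or max of the one track
  s <- rnorm(10)
  for (scheme in c("M1-SUM", "SUM-SUM", "SUM-MAX")) {
    expect_equal(aggregate_scores(list(s), scheme), sum(s))
  }
  for (scheme in c("M1-MAX", "MAX-SUM", "MAX-MAX")) {
    expect_equal(aggregate_scores(list(s), scheme), max(s))
  }
})

test_that("co-occurrence cross-tabulates presence into four exclusive cases", {
  ids <- sprintf("s%d", 1:10)
  ha <- tibble::tibble(sample_id = c("s1", "s1", "s2", "s3"))
  hb <- tibble::tibble(sample_id = c("s3", "s4"))
  tab <- cooccurrence(ha, hb, ids)
  expect_identical(c(tab$neither, tab$only_a, tab$only_b, tab$both),
                   c(6L, 2L, 1L, 1L))
  expect_identical(tab$neither + tab$only_a + tab$only_b + tab$both,
                   tab$n_samples)
  expect_equal(tab$frac_a, 0.3)

  empty <- tibble::tibble(sample_id = character())
  tab0 <- cooccurrence(empty, empty, ids)
  expect_identical(tab0$neither, 10L)
  expect_equal(tab0$frac_both, 0)

  expect_error(cooccurrence(tibble::tibble(sample_id = "zz"), empty, ids),
               "unknown sample")
})

test_that("JASPAR and MEME minimal motif files parse to equivalent PWMs", {
  jp <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 toy",
               "A [ 10  0  2 ]",
               "C [  0 10  2 ]",
               "G [  0  0  4 ]",
               "T [  0  0  2 ]"), jp)
  mj <- read_jaspar(jp)
  expect_named(mj, "MA0001.1")
  expect_identical(mj[[1]]$width, 3L)
  expect_identical(top_affinity_kmer(mj[[1]]), "ACG")

  me <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               "MOTIF toy", "letter-probability matrix: alength= 4 w= 3 nsites= 10",
               " 1.0 0.0 0.0 0.0",
               " 0.0 1.0 0.0 0.0",
               " 0.2 0.2 0.4 0.2"), me)
  mm <- read_meme(me)
  expect_named(mm, "toy")
  expect_identical(top_affinity_kmer(mm[[1]]), "ACG")
  # probabilities agree after each file's pseudocount regularization
  expect_equal(mj[[1]]$probs, mm[[1]]$probs, tolerance = 0.05)
})
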