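test_that("dinucleotide shuffle preserves the full pair-count table", {
  expect_identical(dinuc_shuffle("AAAA", seed = 1), "AAAA")
  expect_error(dinuc_shuffle("ACNGT"), "N")
  expect_error(dinuc_shuffle("A"), "length")
  expect_identical(dinuc_shuffle("ACGTACGTACGT", seed = 9),
                   dinuc_shuffle("ACGTACGTACGT", seed = 9))

  # counting oracle on random sequences, including first/last base identity
  seqs <- random_dna(20, 200, seed = 2)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    sh <- dinuc_shuffle(s, seed = i)
    expect_identical(densebind:::dinuc_counts(sh), densebind:::dinuc_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 200, 200), substr(s, 200, 200))
  }
})

test_that("a constant model attributes nothing anywhere", {
  cm <- constant_model(0.7, input_length = 80)
  s <- random_dna(1, 80, seed = 4)
  tr <- contribution_scores(cm, s, n_references = 3, seed = 1)
  expect_equal(tr$scores, rep(0, 80))
  expect_equal(tr$prediction, 0.7)

  d <- tiling_deletion(cm, s)
  expect_equal(d$deltas$delta, rep(0, 80 - 10 + 1))

  m <- saturation_mutagenesis(cm, s)
  expect_equal(unname(m$deltas), matrix(0, 80, 4))
})

test_that("integrated gradients are exact for an additive PWM scorer", {
  p <- benchmark_pwm("ACGTAC")
  model <- pwm_sum_model(p, input_length = 60, scale = 0.002)
  seqs <- random_dna(5, 60, seed = 6)
  for (i in seq_along(seqs)) {
    tr <- contribution_scores(model, seqs[i], n_references = 4, n_steps = 10,
                              seed = i)
    # linear model: completeness holds to float precision at any step count
    expect_equal(sum(tr$per_base_scores), tr$prediction - tr$reference_mean,
                 tolerance = 1e-10)
  }
})

test_that("tiling deletion obeys its count, sign, and whole-window identities", {
  spec <- densenet_spec(stem_filters = 8, block_layers = c(1, 1, 1, 1),
                        growth_rate = 4, bottleneck_factor = 2, seed = 61)
  m <- build_densenet(spec, 100)
  s <- random_dna(1, 100, seed = 62)
  d <- tiling_deletion(m, s, window = 10, step = 1)
  expect_identical(nrow(d$deltas), 91L)
  expect_identical(d$deltas$start, 0:90)

  # window = L: single delta equal to p(WT) - p(all N)
  dall <- tiling_deletion(m, s, window = 100)
  expect_identical(nrow(dall$deltas), 1L)
  p_wt <- predict(m, s)
  p_null <- predict(m, strrep("N", 100))
  expect_equal(dall$deltas$delta, p_wt - p_null, tolerance = 1e-12)

  expect_error(tiling_deletion(m, s, window = 101), "exceeds")
})

test_that("mutagenesis maps have a zero reference cell per position", {
  spec <- densenet_spec(stem_filters = 8, block_layers = c(1, 1, 1, 1),
                        growth_rate = 4, bottleneck_factor = 2, seed = 63)
  m <- build_densenet(spec, 64)
  s <- random_dna(1, 64, seed = 64)
  mm <- saturation_mutagenesis(m, s)
  expect_identical(dim(mm$deltas), c(64L, 4L))
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  expect_equal(mm$deltas[cbind(1:64, codes)], rep(0, 64))
  # non-reference cells respond for a non-degenerate model
  expect_gt(max(abs(mm$deltas)), 0)
})

test_that("seqlet extraction recovers isolated score bumps", {
  s <- strrep("A", 500)
  mk_track <- function(scores) {
    structure(list(sequence = s, scores = scores,
                   per_base_scores = NULL, n_references = 0,
                   prediction = 0, reference_mean = 0),
              class = "attribution_track")
  }
  expect_identical(nrow(extract_seqlets(mk_track(rep(0, 500)))), 0L)

  # rectangular bump width 12 at offset 100: one seqlet containing the bump,
  # bounded by bump +/- (smoothing half-width + flank)
  sc <- rep(0, 500); sc[101:112] <- 1
  sq <- extract_seqlets(mk_track(sc))
  expect_identical(nrow(sq), 1L)
  expect_lte(sq$start, 100)
  expect_gte(sq$end, 112)
  expect_gte(sq$start, 100 - 7 - 5)
  expect_lte(sq$end, 112 + 7 + 5)
  expect_identical(nchar(sq$subsequence), sq$end - sq$start)

  # two well-separated bumps: two seqlets ordered by mean score
  sc2 <- rep(0, 500); sc2[101:112] <- 0.5; sc2[301:312] <- 1
  sq2 <- extract_seqlets(mk_track(sc2))
  expect_identical(nrow(sq2), 2L)
  expect_gt(sq2$mean_score[1], sq2$mean_score[2])
  expect_true(sq2$start[1] >= 285 && sq2$end[1] <= 330)
})

test_that("interpretation bundles serialize with the documented shapes", {
  cm <- constant_model(0.4, input_length = 64)
  s <- random_dna(1, 64, seed = 71)
  bundle <- interpret_sequence(cm, s, seed = 1)
  path <- tempfile(fileext = ".json")
  write_interpretation(bundle, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(got$contribution_scores, 64)
  expect_length(got$deletion_deltas, 64 - 10 + 1)
  expect_identical(dim(got$mutagenesis_deltas), c(64L, 4L))
})
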