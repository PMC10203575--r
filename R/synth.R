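# Synthetic planted-motif benchmarks: i.i.d. background sequences with a
# literal k-mer or PWM sample written over a known offset, plus the ground
# truth needed to score motif-recovery downstream.

# run code under a seeded RNG, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate i.i.d. background DNA sequences
#'
#' Per-base sampling with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#' No dinucleotide structure is modelled: these backgrounds stand in for
#' negative genomic sequence only as far as planted-motif recovery needs.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc Target G+C fraction in `[0, 1]`.
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return Character vector of `n` sequences over A/C/G/T.
#' @export
#' @examples
#' generate_background(3, 20, gc = 0.4, seed = 1)
generate_background <- function(n, length, gc = 0.5, seed = NULL) {
  n <- check_count(n, "n")
  length <- check_count(length, "length")
  gc <- check_fraction(gc, "gc")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    draws <- sample.int(4L, n * length, replace = TRUE, prob = p)
    apply(matrix(BASES[draws], nrow = length, ncol = n), 2, paste, collapse = "")
  })
}

motif_width <- function(motif) {
  if (is.character(motif)) nchar(motif) else nrow(motif$probs)
}

# draw one concrete instance from a literal k-mer (identity) or a PWM
draw_motif_instance <- function(motif) {
  if (is.character(motif)) return(toupper(motif))
  probs <- motif$probs
  paste(vapply(seq_len(nrow(probs)), function(i) {
    BASES[sample.int(4L, 1L, prob = probs[i, ])]
  }, character(1)), collapse = "")
}

#' Plant a motif into background sequences
#'
#' Overwrites (never inserts, so length is preserved) the bases at a chosen
#' offset in a random subset of the backgrounds with an instance drawn from
#' `motif`, and records every plant in a truth table.
#'
#' @param backgrounds Character vector of equal-length sequences.
#' @param motif Literal k-mer (character) or a [pwm()] to sample instances from.
#' @param fraction Fraction of sequences that receive a plant (rounded to the
#'   nearest count).
#' @param position `"uniform"` for a uniform random legal offset per sequence,
#'   or a single fixed 0-based offset.
#' @param seed Optional integer seed.
#' @return List with `sequences` (character, same length/order as input) and
#'   `truth`, a tibble with `sample_id`, `planted`, `plant_start` (0-based,
#'   `NA` when not planted) and `motif_instance`.
#' @export
plant_motif <- function(backgrounds, motif, fraction = 1, position = "uniform",
                        seed = NULL) {
  n <- length(backgrounds)
  stopifnot(n >= 1)
  len <- unique(nchar(backgrounds))
  if (length(len) != 1L) abort("All backgrounds must share one length.")
  w <- motif_width(motif)
  if (w > len) abort(sprintf("Motif width %d exceeds sequence length %d.", w, len))
  fraction <- check_fraction(fraction, "fraction")
  ids <- names(backgrounds) %||% sprintf("seq_%d", seq_len(n))

  with_seed(seed, {
    n_plant <- round(fraction * n)
    chosen <- sort(sample.int(n, n_plant))
    starts <- rep(NA_integer_, n)
    instances <- rep(NA_character_, n)
    out <- unname(backgrounds)
    for (i in chosen) {
      s <- if (identical(position, "uniform")) {
        sample.int(len - w + 1L, 1L) - 1L
      } else check_count(position, "position", min = 0L)
      inst <- draw_motif_instance(motif)
      substr(out[i], s + 1L, s + w) <- inst
      starts[i] <- s
      instances[i] <- inst
    }
    truth <- tibble::tibble(
      sample_id = ids[chosen],
      planted = TRUE,
      plant_start = starts[chosen],
      motif_instance = instances[chosen]
    )
    list(sequences = stats::setNames(out, ids), truth = truth)
  })
}

#' Build a labelled planted-motif benchmark
#'
#' Positives are backgrounds with a planted motif (label 1); negatives are
#' fresh backgrounds (label 0). Ground truth for every plant is returned so
#' interpretation methods can be scored against known site locations.
#'
#' @param n_pos,n_neg Numbers of positive and negative samples.
#' @param motif Literal k-mer or [pwm()] to plant.
#' @param seq_length Sample length in bp (default 500, the peak-extension
#'   convention of the data module).
#' @param gc_content Background G+C fraction.
#' @param plant_fraction Fraction of positives that receive a plant.
#' @param plant_position `"uniform"` or a fixed 0-based offset.
#' @param seed Optional integer seed; same config + same seed is byte-identical.
#' @return List with `samples`, a tibble (`id`, `sequence`, `label`, `source`),
#'   and `truth`, the plant truth table of [plant_motif()].
#' @export
#' @examples
#' bench <- make_benchmark(20, 20, motif = "GCACGTGC", seq_length = 60, seed = 1)
#' dplyr::count(bench$samples, label)
make_benchmark <- function(n_pos, n_neg, motif, seq_length = 500,
                           gc_content = 0.5, plant_fraction = 1,
                           plant_position = "uniform", seed = NULL) {
  n_pos <- check_count(n_pos, "n_pos")
  n_neg <- check_count(n_neg, "n_neg")
  with_seed(seed, {
    pos_bg <- generate_background(n_pos, seq_length, gc_content)
    names(pos_bg) <- sprintf("pos_%d", seq_len(n_pos))
    planted <- plant_motif(pos_bg, motif, fraction = plant_fraction,
                           position = plant_position)
    neg <- generate_background(n_neg, seq_length, gc_content)
    samples <- tibble::tibble(
      id = c(names(pos_bg), sprintf("neg_%d", seq_len(n_neg))),
      sequence = c(unname(planted$sequences), neg),
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      source = "synthetic"
    )
    list(samples = samples, truth = planted$truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
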