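# Dataset construction from genomes and peak intervals. Coordinates are
# 0-based half-open throughout (the BED dialect); 1-based arithmetic happens
# only inside substr() calls.

#' Read peak intervals from BED or narrowPeak
#'
#' BED3/BED6 and ENCODE narrowPeak are supported. For narrowPeak the summit
#' is `start + column 10` when that offset is `>= 0`; otherwise absent.
#'
#' @param path Path to a BED or narrowPeak file.
#' @param format `"auto"` (by extension/column count), `"bed"` or `"narrowPeak"`.
#' @return Tibble with `chrom`, `start`, `end` and, when available, `name`,
#'   `strand`, `summit` (absolute bp).
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (ncol(raw) >= 10 || grepl("narrowPeak$", path)) "narrowPeak" else "bed"
  }
  out <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 6) out$strand <- as.character(raw[[6]])
  if (format == "narrowPeak" && ncol(raw) >= 10) {
    off <- as.integer(raw[[10]])
    out$summit <- ifelse(off >= 0, out$start + off, NA_integer_)
  }
  if (any(out$start < 0 | out$start >= out$end)) {
    abort("Invalid interval: need 0 <= start < end on every row.")
  }
  out
}

#' Write intervals as BED
#'
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  n <- nrow(peaks)
  col_or <- function(nm, default) {
    if (nm %in% names(peaks)) peaks[[nm]] else default
  }
  bed <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = col_or("name", sprintf("region_%d", seq_len(n))),
    score = col_or("score", rep(0, n)),
    strand = col_or("strand", rep(".", n))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genome_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(genome, nchar, integer(1))
  }
}

genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
}

#' Extend peaks to fixed-length windows around the summit
#'
#' Each peak is re-centred at its summit when present, otherwise at its
#' midpoint, and extended by `flank` bp each side: the output interval is
#' `[c - flank, c + flank)`, length `2 * flank` (500 bp at the default).
#' Windows running past chromosome bounds are dropped with a warning.
#'
#' @param peaks Tibble of intervals as from [read_peaks()].
#' @param flank Extension each side of the centre, in bp.
#' @param chrom_sizes Named vector of chromosome lengths, or a genome
#'   (named character vector / `DNAStringSet`) to take them from.
#' @return Tibble of fixed-length intervals (`chrom`, `start`, `end`,
#'   `summit` = the centre used, plus carried-over `name`/`strand`).
#' @export
extend_peaks <- function(peaks, flank = 250, chrom_sizes) {
  flank <- check_count(flank, "flank")
  if (!is.numeric(chrom_sizes)) chrom_sizes <- genome_lengths(chrom_sizes)
  unknown <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(unknown)) {
    abort(sprintf("Unknown chromosome(s): %s.", paste(unknown, collapse = ", ")))
  }
  centre <- if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L, peaks$summit)
  } else (peaks$start + peaks$end) %/% 2L
  out <- peaks
  out$summit <- as.integer(centre)
  out$start <- as.integer(centre - flank)
  out$end <- as.integer(centre + flank)
  keep <- out$start >= 0 & out$end <= chrom_sizes[out$chrom]
  if (any(!keep)) {
    warn(sprintf("Dropped %d peak(s) whose %d bp window ran past chromosome bounds.",
                 sum(!keep), 2L * flank))
  }
  out[keep, , drop = FALSE]
}

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

#' Sample negative intervals away from exclusions
#'
#' Draws fixed-length intervals uniformly over the genome (chromosomes
#' weighted by length), rejecting any that overlap an exclusion interval by
#' one or more bp or contain more than `max_n_frac` ambiguous bases.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param n Number of intervals to place.
#' @param length Interval length in bp.
#' @param exclusions Optional tibble of intervals to avoid (e.g. the positive
#'   windows plus any masked regions).
#' @param seed Optional integer seed.
#' @param max_tries Candidate-draw budget before giving up (default `50 * n`).
#' @param max_n_frac Maximum tolerated fraction of N bases per interval.
#' @return Tibble of `n` intervals (`chrom`, `start`, `end`).
#' @export
sample_negatives <- function(genome, n, length, exclusions = NULL, seed = NULL,
                             max_tries = 50 * n, max_n_frac = 0.1) {
  n <- check_count(n, "n")
  length <- check_count(length, "length")
  sizes <- genome_lengths(genome)
  seqs <- genome_chars(genome)
  eligible <- sizes[sizes >= length]
  if (!base::length(eligible)) abort("No chromosome is as long as `length`.")
  excl_gr <- if (!is.null(exclusions) && nrow(exclusions)) {
    intervals_to_granges(exclusions)
  } else NULL

  with_seed(seed, {
    placed <- list()
    n_placed <- 0L
    tries <- 0L
    batch <- max(1000L, n)
    while (n_placed < n && tries < max_tries) {
      m <- min(batch, max_tries - tries)
      tries <- tries + m
      chrom <- sample(names(eligible), m, replace = TRUE,
                      prob = as.numeric(eligible))
      start <- floor(runif(m) * (eligible[chrom] - length))
      cand <- tibble::tibble(chrom = chrom, start = as.integer(start),
                             end = as.integer(start + length))
      if (!is.null(excl_gr)) {
        hits <- GenomicRanges::countOverlaps(intervals_to_granges(cand), excl_gr)
        cand <- cand[hits == 0L, , drop = FALSE]
      }
      if (nrow(cand)) {
        frag <- substr(seqs[cand$chrom], cand$start + 1L, cand$end)
        n_frac <- vapply(strsplit(toupper(frag), "", fixed = TRUE),
                         function(ch) mean(ch == "N"), numeric(1))
        cand <- cand[n_frac <= max_n_frac, , drop = FALSE]
      }
      if (nrow(cand)) {
        take <- min(nrow(cand), n - n_placed)
        placed[[base::length(placed) + 1L]] <- cand[seq_len(take), , drop = FALSE]
        n_placed <- n_placed + take
      }
    }
    if (n_placed < n) {
      abort(sprintf(
        "Placed only %d of %d negative intervals within %d tries; relax exclusions or raise max_tries.",
        n_placed, n, as.integer(max_tries)))
    }
    dplyr::bind_rows(placed)
  })
}

#' Extract interval sequences from a genome
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param intervals Tibble of 0-based half-open intervals.
#' @return Character vector of sequences, one per interval.
#' @export
interval_sequences <- function(genome, intervals) {
  seqs <- genome_chars(genome)
  unknown <- setdiff(unique(intervals$chrom), names(seqs))
  if (base::length(unknown)) {
    abort(sprintf("Unknown chromosome(s): %s.", paste(unknown, collapse = ", ")))
  }
  toupper(substr(seqs[intervals$chrom], intervals$start + 1L, intervals$end))
}

#' Split samples into training and test sets
#'
#' Uniform random partition without replacement; `round(train_frac * n)` rows
#' go to training and the rest to test.
#'
#' @param samples Tibble (or data frame) of samples.
#' @param train_frac Training fraction, strictly between 0 and 1.
#' @param seed Optional integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(samples, train_frac = 0.8, seed = NULL) {
  n <- nrow(samples)
  if (n < 2) abort("Need at least 2 samples to split.")
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must lie strictly between 0 and 1.")
  }
  with_seed(seed, {
    idx <- sample.int(n, round(train_frac * n))
    list(train = tibble::as_tibble(samples[sort(idx), , drop = FALSE]),
         test = tibble::as_tibble(samples[sort(setdiff(seq_len(n), idx)), , drop = FALSE]))
  })
}

#' One-hot encode a DNA sequence
#'
#' Channel order A, C, G, T; `N` encodes as an all-zero row, so every other
#' row sums to one. Case-insensitive; any other character is an error naming
#' the offending position.
#'
#' @param sequence A single DNA string over A/C/G/T/N.
#' @return `length x 4` numeric matrix with columns `A`, `C`, `G`, `T`.
#' @export
#' @examples
#' one_hot("ACGTN")
one_hot <- function(sequence) {
  codes <- seq_to_codes(sequence)
  m <- matrix(0, nrow = length(codes), ncol = 4L,
              dimnames = list(NULL, BASES))
  ok <- codes > 0L
  m[cbind(which(ok), codes[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot()] on N-free sequences; all-zero rows decode to `N`.
#'
#' @param mat `length x 4` one-hot matrix, channel order A, C, G, T.
#' @return DNA string.
#' @export
decode_one_hot <- function(mat) {
  codes <- apply(mat, 1, function(r) if (sum(r) == 0) 0L else which.max(r))
  codes_to_seq(as.integer(codes))
}

# batch encoder used by the model: rows are sample-major (sample 1 rows
# 1..L, sample 2 rows L+1..2L, ...), columns the 4 channels
one_hot_batch <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort("All sequences in a batch must share one length.")
  codes <- unlist(lapply(sequences, seq_to_codes), use.names = FALSE)
  m <- matrix(0, nrow = length(codes), ncol = 4L)
  ok <- codes > 0L
  m[cbind(which(ok), codes[ok])] <- 1
  attr(m, "batch") <- length(sequences)
  attr(m, "len") <- L
  m
}
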