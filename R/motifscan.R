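# Position weight matrices, log-odds scanning calibrated by the exact
# null score distribution, MEME-style aggregation baselines, and the
# four-case motif co-occurrence statistic.

#' Construct a position weight matrix
#'
#' Accepts a count matrix or a probability matrix, `width x 4` (columns
#' A, C, G, T) or `4 x width` (rows named A/C/G/T). A pseudocount split by
#' the background is added so every entry is strictly positive: counts
#' become `(counts + pc * bg) / (N + pc)` per position; probability input
#' is treated as coming from `nsites` observations.
#'
#' @param x Numeric count or probability matrix.
#' @param name Motif name.
#' @param background Background base probabilities (A, C, G, T).
#' @param pseudocount Total pseudocount per position, split by background.
#' @param nsites Assumed observation count when `x` holds probabilities.
#' @return A `pwm` object: list with `name`, `probs` (`width x 4`),
#'   `background`, `width`.
#' @export
#' @examples
#' counts <- matrix(c(8, 1, 1, 0), nrow = 1,
#'                  dimnames = list(NULL, c("A", "C", "G", "T")))
#' pwm(counts, name = "toy")
pwm <- function(x, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.8, nsites = 100) {
  x <- as.matrix(x)
  if (nrow(x) == 4 && (!is.null(rownames(x)) &&
                       all(toupper(rownames(x)) %in% BASES) || ncol(x) != 4)) {
    if (!is.null(rownames(x))) x <- x[match(BASES, toupper(rownames(x))), ]
    x <- t(x)
  }
  if (ncol(x) != 4) abort("PWM must have 4 base columns (A, C, G, T).")
  if (any(x < 0) || any(is.na(x))) abort("PWM entries must be non-negative.")
  background <- background / sum(background)
  tot <- rowSums(x)
  if (any(tot == 0)) abort("PWM has an all-zero position.")
  counts <- if (all(abs(tot - 1) < 1e-6)) x * nsites else x
  probs <- sweep(counts, 2, background * pseudocount, "+")
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(NULL, BASES)
  structure(list(name = name, probs = probs, background = background,
                 width = nrow(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n", x$name, x$width,
              top_affinity_kmer(x)))
  invisible(x)
}

#' Log-odds score matrix of a PWM
#'
#' `lo[i, b] = log2(probs[i, b] / background[b])`; a position matching the
#' background exactly scores 0 bits.
#'
#' @param x A [pwm()].
#' @return `width x 4` matrix of log-odds scores in bits.
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  sweep(log2(x$probs), 2, log2(x$background), "-")
}

#' Highest-affinity k-mer of a PWM
#'
#' Per-position argmax base; ties break in A < C < G < T order.
#'
#' @param x A [pwm()].
#' @return The top-affinity k-mer as a string.
#' @export
top_affinity_kmer <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (x$width < 1) abort("Empty PWM.")
  paste(BASES[apply(x$probs, 1, which.max)], collapse = "")
}

reverse_complement_pwm_scores <- function(lo) {
  # complement = reverse column order (T,G,C,A), reverse positions
  lo[rev(seq_len(nrow(lo))), 4:1, drop = FALSE]
}

# per-column integer score lattice shared by the DP and the enumeration
# oracle: column i is shifted by its minimum and scaled by one global delta
discretize_scores <- function(lo, score_bins) {
  mins <- apply(lo, 1, min)
  range_total <- sum(apply(lo, 1, max) - mins)
  delta <- if (range_total > 0) range_total / score_bins else 1
  ints <- round(sweep(lo, 1, mins, "-") / delta)
  list(ints = ints, delta = delta, offset = sum(mins))
}

#' Exact null distribution of the PWM log-odds score
#'
#' Distribution of the score of a random background-distributed w-mer, on a
#' per-column integer score lattice. `method = "dp"` convolves the column
#' distributions; `method = "enumerate"` sums over all `4^w` w-mers on the
#' same lattice, serving as the brute-force oracle.
#'
#' @param x A [pwm()].
#' @param background Base probabilities of the null model.
#' @param score_bins Number of lattice steps spanning the total score range.
#' @param method `"dp"` or `"enumerate"`.
#' @return Tibble with `score` (real-scale lattice value) and `prob`,
#'   ascending in score, probabilities summing to 1.
#' @export
score_distribution <- function(x, background = x$background,
                               score_bins = 1000,
                               method = c("dp", "enumerate")) {
  method <- match.arg(method)
  lo <- log_odds(x)
  d <- discretize_scores(lo, score_bins)
  w <- nrow(lo)
  background <- background / sum(background)
  if (method == "dp") {
    v <- 1
    for (i in seq_len(w)) {
      si <- d$ints[i, ]
      new <- numeric(length(v) + max(si))
      for (b in 1:4) {
        idx <- seq_along(v) + si[b]
        new[idx] <- new[idx] + v * background[b]
      }
      v <- new
    }
    keep <- v > 0
    tibble::tibble(score = (which(keep) - 1L) * d$delta + d$offset,
                   prob = v[keep])
  } else {
    tot_int <- 0L
    tot_p <- 1
    for (i in seq_len(w)) {
      tot_int <- as.vector(outer(tot_int, d$ints[i, ], "+"))
      tot_p <- as.vector(outer(tot_p, background, "*"))
    }
    agg <- rowsum(tot_p, tot_int)
    tibble::tibble(score = as.numeric(rownames(agg)) * d$delta + d$offset,
                   prob = as.numeric(agg))
  }
}

#' Score threshold for a target scan p-value
#'
#' Smallest score `t` on the null lattice with `P(score >= t) <= p_cutoff`
#' under the background model, computed from the exact discretized score
#' distribution (enumeration for width <= 8, dynamic-programming
#' convolution beyond). If even the maximal score is too probable the
#' maximum is returned with a warning.
#'
#' @param x A [pwm()].
#' @param p_cutoff Target tail probability (default `1e-05`).
#' @param background Null base probabilities.
#' @param score_bins Lattice resolution for the DP route.
#' @param method `"auto"`, `"dp"` or `"enumerate"`.
#' @return List with `threshold` (log-odds bits) and `p_achieved`, the exact
#'   tail probability at that threshold.
#' @export
threshold_from_pvalue <- function(x, p_cutoff = 1e-05,
                                  background = x$background,
                                  score_bins = 1000,
                                  method = c("auto", "dp", "enumerate")) {
  method <- match.arg(method)
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff > 1) {
    abort("`p_cutoff` must lie in (0, 1].")
  }
  if (method == "auto") method <- if (x$width <= 8) "enumerate" else "dp"
  dist <- score_distribution(x, background, score_bins, method)
  tail_p <- rev(cumsum(rev(dist$prob)))
  ok <- tail_p <= p_cutoff
  if (!any(ok)) {
    warn(sprintf(
      "p_cutoff %g below the minimal achievable tail %g; using the maximal score.",
      p_cutoff, tail_p[length(tail_p)]))
    return(list(threshold = dist$score[nrow(dist)],
                p_achieved = tail_p[length(tail_p)]))
  }
  i <- which(ok)[1]
  list(threshold = dist$score[i], p_achieved = tail_p[i])
}

# per-offset log-odds of one strand; windows containing N score NA
strand_scores <- function(codes, lo) {
  w <- nrow(lo)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1L
  s <- numeric(n_off)
  bad <- logical(n_off)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n_off - 1L)]
    bad <- bad | ci == 0L
    ci[ci == 0L] <- 1L
    s <- s + lo[i, ci]
  }
  s[bad] <- NA_real_
  s
}

#' Per-position log-odds scores of a sequence under a PWM
#'
#' The raw (unthresholded) score track used by the MEME-style aggregation
#' baselines; N-containing windows are `NA`.
#'
#' @param sequence DNA string.
#' @param x A [pwm()].
#' @param strand `"+"`, `"-"`, or `"both"` (per-offset maximum of the two).
#' @return Numeric vector over 0-based window offsets.
#' @export
position_scores <- function(sequence, x, strand = c("+", "-", "both")) {
  strand <- match.arg(strand)
  codes <- seq_to_codes(sequence)
  lo <- log_odds(x)
  fwd <- strand_scores(codes, lo)
  if (strand == "+") return(fwd)
  rev_ <- strand_scores(codes, reverse_complement_pwm_scores(lo))
  if (strand == "-") rev_ else pmax(fwd, rev_)
}

#' Scan sequences for PWM matches above a p-value-calibrated threshold
#'
#' Every window (both strands by default) whose log-odds score reaches the
#' threshold implied by `p_cutoff` is reported; windows containing N are
#' skipped. A minus-strand hit at `start` means the reverse complement of
#' the window at `start` matches the motif.
#'
#' @param samples Tibble with `id` and `sequence` columns, or a (optionally
#'   named) character vector of sequences.
#' @param x A [pwm()].
#' @param p_cutoff Scan p-value cutoff (default `1e-05`).
#' @param both_strands Scan the reverse complement too?
#' @param score_bins Lattice resolution for threshold calibration.
#' @param threshold Optional explicit score threshold overriding `p_cutoff`.
#' @return Tibble of hits: `sample_id`, `start` (0-based), `strand`,
#'   `score` (bits), `pwm`; sorted by sample then start.
#' @export
scan_sequences <- function(samples, x, p_cutoff = 1e-05, both_strands = TRUE,
                           score_bins = 1000, threshold = NULL) {
  stopifnot(inherits(x, "pwm"))
  if (is.character(samples)) {
    samples <- tibble::tibble(
      id = names(samples) %||% sprintf("seq_%d", seq_along(samples)),
      sequence = unname(samples))
  }
  thr <- threshold %||% threshold_from_pvalue(x, p_cutoff,
                                              score_bins = score_bins)$threshold
  lo <- log_odds(x)
  lo_rc <- reverse_complement_pwm_scores(lo)
  hits <- purrr::map2(samples$id, samples$sequence, function(id, seq) {
    codes <- seq_to_codes(seq)
    collect <- function(lo_m, strand) {
      s <- strand_scores(codes, lo_m)
      keep <- which(!is.na(s) & s >= thr)
      if (!length(keep)) return(NULL)
      tibble::tibble(sample_id = id, start = keep - 1L, strand = strand,
                     score = s[keep], pwm = x$name)
    }
    out <- collect(lo, "+")
    if (both_strands) out <- dplyr::bind_rows(out, collect(lo_rc, "-"))
    out
  })
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) {
    return(tibble::tibble(sample_id = character(), start = integer(),
                          strand = character(), score = numeric(),
                          pwm = character()))
  }
  dplyr::arrange(out, match(.data$sample_id, samples$id), .data$start)
}

#' Write motif hits as BED6
#'
#' Scores are scaled affinely to `[0, 1000]` as BED requires.
#'
#' @param hits Hit tibble from [scan_sequences()].
#' @param path Output path.
#' @param width Motif width (taken from hit geometry for naming the interval).
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, width) {
  if (nrow(hits)) {
    rng <- range(hits$score)
    scaled <- if (diff(rng) > 0) {
      round(1000 * (hits$score - rng[1]) / diff(rng))
    } else rep(1000L, nrow(hits))
    bed <- data.frame(hits$sample_id, hits$start, hits$start + width,
                      hits$pwm, scaled, hits$strand)
  } else {
    bed <- data.frame()
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' MEME-style aggregation of per-position PWM scores
#'
#' The six schemes reduce per-position score tracks of up to five PWMs
#' (the first is "M1") to one scalar per sequence: `M1-SUM` and `M1-MAX`
#' use only the first track; `SUM-SUM` sums every track's sum; `MAX-SUM`
#' sums every track's maximum; `SUM-MAX` takes the maximum of the per-track
#' sums; `MAX-MAX` the maximum of the per-track maxima.
#'
#' @param score_lists List of numeric per-position score vectors, one per
#'   PWM, first being M1. `NA` positions (N windows) are dropped.
#' @param scheme One of `"M1-SUM"`, `"M1-MAX"`, `"SUM-SUM"`, `"MAX-SUM"`,
#'   `"SUM-MAX"`, `"MAX-MAX"`.
#' @return A single aggregated score.
#' @export
aggregate_scores <- function(score_lists,
                             scheme = c("M1-SUM", "M1-MAX", "SUM-SUM",
                                        "MAX-SUM", "SUM-MAX", "MAX-MAX")) {
  scheme <- match.arg(scheme)
  if (!is.list(score_lists)) score_lists <- list(score_lists)
  if (!length(score_lists)) abort("Need at least one score track (M1).")
  sums <- vapply(score_lists, function(s) sum(s, na.rm = TRUE), numeric(1))
  maxs <- vapply(score_lists, function(s) max(s, na.rm = TRUE), numeric(1))
  switch(scheme,
         "M1-SUM" = sums[1],
         "M1-MAX" = maxs[1],
         "SUM-SUM" = sum(sums),
         "MAX-SUM" = sum(maxs),
         "SUM-MAX" = max(sums),
         "MAX-MAX" = max(maxs))
}

#' Four-case co-occurrence of two motifs across samples
#'
#' A sample "contains" a motif when it has at least one hit. Samples are
#' cross-tabulated into the mutually exclusive cases neither / only A /
#' only B / both, with fractions over all samples.
#'
#' @param hits_a,hits_b Hit tibbles (as from [scan_sequences()]) with a
#'   `sample_id` column.
#' @param sample_ids Vector of all sample ids in the scanned set (hits must
#'   reference only these).
#' @return One-row tibble: `n_samples`, counts `neither`, `only_a`,
#'   `only_b`, `both`, and `frac_*` for each case plus `frac_a`/`frac_b`,
#'   the marginal fractions containing each motif.
#' @export
#' @examples
#' hits <- function(ids) tibble::tibble(sample_id = ids)
#' cooccurrence(hits(c("s1", "s2")), hits("s2"), c("s1", "s2", "s3"))
cooccurrence <- function(hits_a, hits_b, sample_ids) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (!n) abort("`sample_ids` is empty.")
  get_ids <- function(h, nm) {
    ids <- as.character(unique(h$sample_id))
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown)) {
      abort(sprintf("%s references unknown sample id(s): %s.", nm,
                    paste(head(unknown, 3), collapse = ", ")))
    }
    ids
  }
  a <- sample_ids %in% get_ids(hits_a, "hits_a")
  b <- sample_ids %in% get_ids(hits_b, "hits_b")
  both <- sum(a & b); only_a <- sum(a & !b); only_b <- sum(!a & b)
  neither <- n - both - only_a - only_b
  tibble::tibble(
    n_samples = n, neither = neither, only_a = only_a, only_b = only_b,
    both = both,
    frac_neither = neither / n, frac_only_a = only_a / n,
    frac_only_b = only_b / n, frac_both = both / n,
    frac_a = (only_a + both) / n, frac_b = (only_b + both) / n
  )
}

#' Read motifs in JASPAR format
#'
#' Parses `.jaspar`/`.pfm` records: a `>` header line followed by four base
#' rows (`A [ 4 19 0 ... ]` or bare numbers in A, C, G, T order).
#'
#' @param path Path to the motif file.
#' @param ... Passed to [pwm()] (background, pseudocount).
#' @return List of [pwm()] objects, named by motif.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) starts <- 1L else lines[starts] <- sub("^>\\s*", "", lines[starts])
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]][1]
    body <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    rows <- lapply(body, function(ln) {
      ln <- gsub("[][]", " ", ln)
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      base <- if (toupper(parts[1]) %in% BASES) toupper(parts[1]) else NA_character_
      vals <- suppressWarnings(as.numeric(parts))
      list(base = base, vals = vals[!is.na(vals)])
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    bases <- vapply(rows, function(r) r$base, character(1))
    if (all(!is.na(bases))) mat <- mat[match(BASES, bases), , drop = FALSE]
    out[[name]] <- pwm(t(mat), name = name, ...)
  }
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' the file's `Background letter frequencies` line, when present, becomes
#' each motif's background.
#'
#' @param path Path to a MEME minimal file.
#' @param ... Passed to [pwm()].
#' @return List of [pwm()] objects, named by motif.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) && bg_i[1] < length(lines)) {
    parts <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    lets <- toupper(parts[is.na(vals)])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 4 && identical(lets, BASES)) bg <- vals
  }
  motif_i <- grep("^MOTIF\\b", lines)
  out <- list()
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- grep("^letter-probability matrix", lines[mi:length(lines)])[1] + mi - 1L
    hdr <- lines[li]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else 100
    mat <- do.call(rbind, lapply(lines[(li + 1L):(li + w)], function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }))
    out[[name]] <- pwm(mat, name = name, background = bg, nsites = nsites, ...)
  }
  out
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
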