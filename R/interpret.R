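# Base-resolution interpretation of a trained sequence classifier:
# contribution scores against dinucleotide-shuffled references, in-silico
# tiling deletion, in-silico saturation mutagenesis, and extraction of
# high-attribution segments (seqlets).

#' Dinucleotide-preserving shuffle
#'
#' Uniform sample over the Eulerian rearrangements of the sequence's
#' dinucleotide multigraph (Altschul-Erickson): the output has exactly the
#' input's 16-entry dinucleotide count table, hence also its mononucleotide
#' counts and its first and last base.
#'
#' @param sequence DNA string over A/C/G/T (length >= 2, no N).
#' @param seed Optional integer seed.
#' @return A shuffled sequence of the same length.
#' @export
#' @examples
#' dinuc_shuffle("ACGTACGTAC", seed = 1)
dinuc_shuffle <- function(sequence, seed = NULL) {
  codes <- seq_to_codes(sequence)
  if (length(codes) < 2) abort("Need a sequence of length >= 2.")
  if (any(codes == 0L)) abort("Cannot dinucleotide-shuffle a sequence containing N.")
  with_seed(seed, {
    L <- length(codes)
    last_v <- codes[L]
    # out-edge target lists per vertex
    edges <- split(codes[-1L], codes[-L])
    verts <- as.integer(names(edges))
    # choose one "last edge" per non-terminal vertex until they form an
    # arborescence into the terminal vertex (rejection sampling)
    repeat {
      last_edge <- stats::setNames(rep(NA_integer_, 4L), 1:4)
      for (v in verts) {
        if (v != last_v) {
          tv <- edges[[as.character(v)]]
          last_edge[v] <- tv[sample.int(length(tv), 1L)]
        }
      }
      ok <- TRUE
      for (v in verts) {
        if (v == last_v) next
        seen <- integer(0)
        cur <- v
        while (cur != last_v) {
          if (cur %in% seen || is.na(last_edge[cur])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[cur]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # shuffle the remaining edges; the designated last edge goes last
    pools <- lapply(1:4, function(v) integer(0))
    for (v in verts) {
      tv <- edges[[as.character(v)]]
      if (v != last_v) {
        drop_i <- match(last_edge[v], tv)
        rest <- tv[-drop_i]
        pools[[v]] <- c(rest[sample.int(length(rest))], last_edge[v])
      } else {
        pools[[v]] <- tv[sample.int(length(tv))]
      }
    }
    nxt <- rep(1L, 4L)
    out <- integer(L)
    out[1L] <- codes[1L]
    cur <- codes[1L]
    for (i in 2:L) {
      step <- pools[[cur]][nxt[cur]]
      nxt[cur] <- nxt[cur] + 1L
      out[i] <- step
      cur <- step
    }
    codes_to_seq(out)
  })
}

dinuc_counts <- function(sequence) {
  codes <- seq_to_codes(sequence)
  table(factor(paste0(BASES[codes[-length(codes)]], BASES[codes[-1]]),
               levels = as.vector(outer(BASES, BASES, paste0))))
}

#' Per-base contribution scores against shuffled references
#'
#' Attributes the difference between the model's prediction on the sequence
#' and its mean prediction on `n_references` dinucleotide-shuffled
#' references to individual bases, by integrated gradients along the
#' straight path from each reference to the sequence (midpoint rule,
#' `n_steps` steps), averaged over references. The scores approximately
#' satisfy completeness: their sum tracks `p(seq) - mean p(refs)`.
#'
#' @param model A model providing [predict_intensity()] and
#'   [input_gradients()].
#' @param sequence DNA string of the model's input length (no N).
#' @param n_references Number of shuffled references.
#' @param n_steps Integration steps per reference.
#' @param seed Optional integer seed (drives the reference shuffles).
#' @return An `attribution_track`: list with `sequence`, `scores` (per-base,
#'   length L), `per_base_scores` (L x 4), `n_references`, `prediction`,
#'   `reference_mean`.
#' @export
contribution_scores <- function(model, sequence, n_references = 10,
                                n_steps = 25, seed = NULL) {
  L <- nchar(sequence)
  check_model_length(model, L)
  n_references <- check_count(n_references, "n_references")
  n_steps <- check_count(n_steps, "n_steps")
  refs <- with_seed(seed, {
    vapply(seq_len(n_references), function(i) dinuc_shuffle(sequence),
           character(1))
  })
  X1 <- one_hot(sequence)
  X0s <- lapply(refs, one_hot)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  # one big batch: n_references * n_steps interpolated inputs
  blocks <- lapply(X0s, function(X0) {
    D <- X1 - X0
    do.call(rbind, lapply(alphas, function(a) X0 + a * D))
  })
  G <- input_gradients(model, do.call(rbind, blocks),
                       n_references * n_steps)
  per_base <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  for (r in seq_len(n_references)) {
    rows <- ((r - 1L) * n_steps * L + 1L):(r * n_steps * L)
    Gr <- G[rows, , drop = FALSE]
    avg_grad <- Reduce(`+`, lapply(seq_len(n_steps), function(s) {
      Gr[((s - 1L) * L + 1L):(s * L), , drop = FALSE]
    })) / n_steps
    per_base <- per_base + (X1 - X0s[[r]]) * avg_grad / n_references
  }
  p_seq <- predict_intensity(model, sequence)
  p_refs <- predict_intensity(model, refs)
  structure(list(
    sequence = sequence,
    scores = rowSums(per_base),
    per_base_scores = per_base,
    n_references = n_references,
    prediction = p_seq,
    reference_mean = mean(p_refs)
  ), class = "attribution_track")
}

check_model_length <- function(model, L) {
  if (!is.null(model$input_length) && model$input_length != L) {
    abort(sprintf("Sequence length %d does not match the model input length %d.",
                  L, model$input_length))
  }
}

#' @export
print.attribution_track <- function(x, ...) {
  cat(sprintf(
    "<attribution_track> %d bp, %d references, p(seq) = %.4f, mean p(ref) = %.4f\n",
    nchar(x$sequence), x$n_references, x$prediction, x$reference_mean))
  invisible(x)
}

#' Tidy an attribution track
#'
#' @param x An `attribution_track`.
#' @param ... Unused.
#' @return Tibble with `position` (0-based), `base`, `score`.
#' @export
tidy.attribution_track <- function(x, ...) {
  tibble::tibble(position = seq_along(x$scores) - 1L,
                 base = strsplit(x$sequence, "")[[1]],
                 score = x$scores)
}

#' In-silico tiling deletion
#'
#' Slides a `window`-bp deletion along the sequence in `step`-bp steps. In
#' `"mask"` mode the window is replaced by N (all-zero input rows); in
#' `"scramble"` mode its content is dinucleotide-shuffled and the prediction
#' averaged over `n_shuffles` shuffles. The reported effect is
#' `delta = p(WT) - p(edited)`, so windows whose removal abolishes binding
#' score high and positive.
#'
#' @param model A model providing [predict_intensity()].
#' @param sequence DNA string of the model's input length.
#' @param window Deletion window in bp.
#' @param step Step between window starts in bp.
#' @param mode `"mask"` (N replacement) or `"scramble"`.
#' @param n_shuffles Shuffles per window in `"scramble"` mode.
#' @param seed Seed for `"scramble"` mode.
#' @return A `deletion_profile`: list with `deltas` tibble (`start`,
#'   `delta`), `window`, `step`, `prediction`.
#' @export
tiling_deletion <- function(model, sequence, window = 10, step = 1,
                            mode = c("mask", "scramble"), n_shuffles = 10,
                            seed = NULL) {
  mode <- match.arg(mode)
  L <- nchar(sequence)
  window <- check_count(window, "window")
  step <- check_count(step, "step")
  if (window > L) abort("`window` exceeds the sequence length.")
  check_model_length(model, L)
  starts <- seq(0L, L - window, by = step)
  p_wt <- predict_intensity(model, sequence)
  if (mode == "mask") {
    variants <- vapply(starts, function(s) {
      v <- sequence
      substr(v, s + 1L, s + window) <- strrep("N", window)
      v
    }, character(1))
    p_var <- predict_intensity(model, variants)
  } else {
    p_var <- with_seed(seed, vapply(starts, function(s) {
      win <- substr(sequence, s + 1L, s + window)
      shuf <- vapply(seq_len(n_shuffles), function(i) {
        v <- sequence
        substr(v, s + 1L, s + window) <- dinuc_shuffle(win)
        v
      }, character(1))
      mean(predict_intensity(model, shuf))
    }, numeric(1)))
  }
  structure(list(
    deltas = tibble::tibble(start = starts, delta = p_wt - p_var),
    window = window, step = step, mode = mode, prediction = p_wt,
    sequence = sequence
  ), class = "deletion_profile")
}

#' @export
print.deletion_profile <- function(x, ...) {
  top <- x$deltas[which.max(x$deltas$delta), ]
  cat(sprintf(
    "<deletion_profile> %d windows of %d bp (step %d, %s); max delta %.4f at %d\n",
    nrow(x$deltas), x$window, x$step, x$mode, top$delta, top$start))
  invisible(x)
}

#' @export
tidy.deletion_profile <- function(x, ...) x$deltas

#' In-silico saturation mutagenesis
#'
#' Evaluates the model on every single-base substitution of the sequence and
#' records `delta[i, b] = p(mutant with base b at i) - p(WT)`; cells of the
#' observed (reference) base are 0 by construction.
#'
#' @param model A model providing [predict_intensity()].
#' @param sequence DNA string of the model's input length.
#' @return A `mutagenesis_map`: list with `deltas` (L x 4, columns
#'   A/C/G/T), `sequence`, `prediction`.
#' @export
saturation_mutagenesis <- function(model, sequence) {
  L <- nchar(sequence)
  check_model_length(model, L)
  codes <- seq_to_codes(sequence)
  p_wt <- predict_intensity(model, sequence)
  muts <- character(0)
  cells <- matrix(integer(0), ncol = 2L)
  for (b in 1:4) {
    pos <- which(codes != b)
    if (!length(pos)) next
    vs <- vapply(pos, function(i) {
      v <- sequence
      substr(v, i, i) <- BASES[b]
      v
    }, character(1))
    muts <- c(muts, vs)
    cells <- rbind(cells, cbind(pos, b))
  }
  p_mut <- predict_intensity(model, muts)
  deltas <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  deltas[cells] <- p_mut - p_wt
  structure(list(deltas = deltas, sequence = sequence, prediction = p_wt),
            class = "mutagenesis_map")
}

#' @export
print.mutagenesis_map <- function(x, ...) {
  cat(sprintf("<mutagenesis_map> %d x 4, p(WT) = %.4f, max |delta| = %.4f\n",
              nrow(x$deltas), x$prediction, max(abs(x$deltas))))
  invisible(x)
}

#' @export
tidy.mutagenesis_map <- function(x, ...) {
  tibble::as_tibble(x$deltas) %>%
    dplyr::mutate(position = dplyr::row_number() - 1L) %>%
    tidyr::pivot_longer(dplyr::all_of(BASES), names_to = "base",
                        values_to = "delta")
}

#' Seqlet-extraction parameters
#'
#' @param sliding_window_size Width of the centred moving average applied to
#'   absolute scores before thresholding.
#' @param flank_size Extension added to each side of an above-threshold run.
#' @param score_quantile Quantile of the smoothed scores used as threshold.
#' @return A `seqlet_params` list.
#' @export
seqlet_params <- function(sliding_window_size = 15, flank_size = 5,
                          score_quantile = 0.85) {
  structure(list(
    sliding_window_size = check_count(sliding_window_size, "sliding_window_size"),
    flank_size = check_count(flank_size, "flank_size", min = 0L),
    score_quantile = check_fraction(score_quantile, "score_quantile",
                                    lo = 1e-9, hi = 1 - 1e-9)
  ), class = "seqlet_params")
}

# centred moving average with truncated (partial) windows at the edges
moving_average <- function(x, width) {
  half <- (width - 1) %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract high-attribution segments (seqlets)
#'
#' Smooths the absolute contribution scores with a centred moving average,
#' thresholds at a quantile of the smoothed values, takes maximal runs above
#' threshold, extends each by `flank_size`, clips to the sequence, and
#' merges overlapping runs.
#'
#' @param track An `attribution_track` from [contribution_scores()].
#' @param params A [seqlet_params()].
#' @return Tibble of seqlets (`start`, `end` 0-based half-open,
#'   `mean_score`, `subsequence`), sorted by `mean_score` descending; empty
#'   when nothing exceeds the threshold.
#' @export
extract_seqlets <- function(track, params = seqlet_params()) {
  stopifnot(inherits(track, "attribution_track"))
  a <- abs(track$scores)
  L <- length(a)
  if (!L) abort("Empty attribution track.")
  sm <- moving_average(a, params$sliding_window_size)
  thr <- stats::quantile(sm, params$score_quantile, names = FALSE)
  above <- sm > thr
  empty <- tibble::tibble(start = integer(), end = integer(),
                          mean_score = numeric(), subsequence = character())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values]) # 1-based inclusive
  runs[, 1] <- pmax(runs[, 1] - params$flank_size, 1L)
  runs[, 2] <- pmin(runs[, 2] + params$flank_size, L)
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      lastr <- merged[[length(merged)]]
      if (runs[i, 1] <= lastr[2] + 1L) {
        merged[[length(merged)]] <- c(lastr[1], max(lastr[2], runs[i, 2]))
      } else merged[[length(merged) + 1L]] <- runs[i, ]
    }
  }
  out <- dplyr::bind_rows(lapply(merged, function(m) {
    tibble::tibble(
      start = m[1] - 1L, end = m[2],
      mean_score = mean(a[m[1]:m[2]]),
      subsequence = substr(track$sequence, m[1], m[2]))
  }))
  dplyr::arrange(out, dplyr::desc(.data$mean_score))
}

#' Run all three interpretation methods on one sequence
#'
#' Convenience wrapper producing the combined per-sequence bundle the
#' pipeline writes: contribution scores, tiling-deletion profile, and
#' saturation-mutagenesis map, plus the extracted seqlets.
#'
#' @param model A trained model.
#' @param sequence DNA string of the model's input length.
#' @param window Tiling-deletion window (bp).
#' @param n_references References for the contribution scores.
#' @param seed Optional integer seed.
#' @param params [seqlet_params()] for seqlet extraction.
#' @return List with `attribution`, `deletion`, `mutagenesis`, `seqlets`.
#' @export
interpret_sequence <- function(model, sequence, window = 10,
                               n_references = 10, seed = NULL,
                               params = seqlet_params()) {
  att <- contribution_scores(model, sequence, n_references = n_references,
                             seed = seed)
  list(
    attribution = att,
    deletion = tiling_deletion(model, sequence, window = window),
    mutagenesis = saturation_mutagenesis(model, sequence),
    seqlets = extract_seqlets(att, params)
  )
}

#' Write an interpretation bundle as JSON
#'
#' @param bundle Result of [interpret_sequence()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_interpretation <- function(bundle, path) {
  payload <- list(
    sequence = bundle$attribution$sequence,
    prediction = bundle$attribution$prediction,
    contribution_scores = unname(bundle$attribution$scores),
    deletion_deltas = bundle$deletion$deltas$delta,
    deletion_window = bundle$deletion$window,
    mutagenesis_deltas = unname(bundle$mutagenesis$deltas),
    seqlets = bundle$seqlets
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
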