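# Global importance analysis: the population-level effect of a motif on
# model predictions, measured by embedding it into many background
# sequences at fixed offsets and averaging the prediction change.

#' Embed a motif into a background sequence
#'
#' Overwrites the bases at `[position, position + width)` with `motif`;
#' the length never changes.
#'
#' @param background DNA string.
#' @param motif Literal motif string.
#' @param position 0-based offset.
#' @return The edited sequence.
#' @export
#' @examples
#' embed_motif("TTTTTTTT", "ACGT", 0)
embed_motif <- function(background, motif, position) {
  w <- nchar(motif)
  position <- check_count(position, "position", min = 0L)
  if (position + w > nchar(background)) {
    abort(sprintf("Motif of width %d at offset %d overruns the %d bp background.",
                  w, position, nchar(background)))
  }
  substr(background, position + 1L, position + w) <- toupper(motif)
  background
}

# shared core: local importance per background given cached original
# predictions; offsets are 0-based
gi_core <- function(model, motif, backgrounds, offsets, p_orig) {
  emb <- vapply(offsets, function(off) {
    predict_intensity(model, vapply(backgrounds, embed_motif, character(1),
                                    motif = motif, position = off))
  }, numeric(length(backgrounds)))
  emb <- matrix(emb, nrow = length(backgrounds))
  list(local = rowMeans(emb) - p_orig,
       per_position = colMeans(emb) - mean(p_orig))
}

#' Global importance of a motif
#'
#' Embeds `motif` into every background at each position, predicts, and
#' averages: for background `x`,
#' `local(x) = mean_p model(embed(x, motif, p)) - model(x)`; the global
#' importance is the mean of the local importances over all backgrounds.
#' Positive values mean the motif promotes the predicted binding.
#'
#' @param model A model providing [predict_intensity()].
#' @param motif Literal motif string (e.g. a PWM's [top_affinity_kmer()]).
#' @param backgrounds Character vector of background sequences (typically
#'   held-out negatives), all of the model's input length.
#' @param positions Embedding start positions (default the 70/170/270/370/470
#'   bp convention).
#' @param one_based Are `positions` 1-based starts (default) rather than
#'   0-based offsets?
#' @return A `gia_result`: list with `motif`, `global_importance`,
#'   `local_importance` (per background), `per_position_mean`, `positions`,
#'   `n_backgrounds`.
#' @export
global_importance <- function(model, motif, backgrounds,
                              positions = c(70, 170, 270, 370, 470),
                              one_based = TRUE) {
  if (!length(backgrounds)) abort("Need at least one background sequence.")
  lens <- unique(nchar(backgrounds))
  if (length(lens) != 1L) abort("Backgrounds must share one length.")
  check_model_length(model, lens)
  offsets <- if (one_based) as.integer(positions) - 1L else as.integer(positions)
  if (any(offsets < 0) || any(offsets + nchar(motif) > lens)) {
    abort("An embedding position runs past the background bounds.")
  }
  p_orig <- predict_intensity(model, backgrounds)
  core <- gi_core(model, motif, backgrounds, offsets, p_orig)
  structure(list(
    motif = toupper(motif),
    global_importance = mean(core$local),
    local_importance = core$local,
    per_position_mean = stats::setNames(core$per_position,
                                        as.character(positions)),
    positions = positions,
    n_backgrounds = length(backgrounds)
  ), class = "gia_result")
}

#' @export
print.gia_result <- function(x, ...) {
  cat(sprintf("<gia_result> %s: global importance %.4f over %d backgrounds (positions %s)\n",
              x$motif, x$global_importance, x$n_backgrounds,
              paste(x$positions, collapse = ", ")))
  invisible(x)
}

#' Tidy a GIA result
#'
#' @param x A `gia_result`.
#' @param ... Unused.
#' @return Tibble with one row per background: `background`,
#'   `local_importance`.
#' @export
tidy.gia_result <- function(x, ...) {
  tibble::tibble(background = seq_along(x$local_importance),
                 local_importance = x$local_importance)
}

#' One-row summary of a GIA result
#'
#' @param x A `gia_result`.
#' @param ... Unused.
#' @return Tibble with `motif`, `global_importance`, `n_backgrounds`.
#' @export
glance.gia_result <- function(x, ...) {
  tibble::tibble(motif = x$motif,
                 global_importance = x$global_importance,
                 n_backgrounds = x$n_backgrounds)
}

#' Single-nucleotide GIA difference map
#'
#' For every single-base mutant `m` of `motif`,
#' `cell[i, b] = GI(m with base b at i) - GI(motif)`; reference-base cells
#' are 0 by construction. For a motif a model has learned as a deterministic
#' consensus, every mutation lowers the global importance.
#'
#' @inheritParams global_importance
#' @return `width x 4` matrix (columns A/C/G/T) of global-importance
#'   differences, with attribute `"global_importance"` holding GI(motif).
#' @export
gia_single_nt_map <- function(model, motif, backgrounds,
                              positions = c(70, 170, 270, 370, 470),
                              one_based = TRUE) {
  motif <- toupper(motif)
  w <- nchar(motif)
  lens <- unique(nchar(backgrounds))
  if (length(lens) != 1L) abort("Backgrounds must share one length.")
  offsets <- if (one_based) as.integer(positions) - 1L else as.integer(positions)
  if (any(offsets < 0) || any(offsets + w > lens)) {
    abort("An embedding position runs past the background bounds.")
  }
  p_orig <- predict_intensity(model, backgrounds)
  gi_ref <- mean(gi_core(model, motif, backgrounds, offsets, p_orig)$local)
  codes <- seq_to_codes(motif)
  out <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  for (i in seq_len(w)) {
    for (b in 1:4) {
      if (b == codes[i]) next
      mut <- motif
      substr(mut, i, i) <- BASES[b]
      gi_mut <- mean(gi_core(model, mut, backgrounds, offsets, p_orig)$local)
      out[i, b] <- gi_mut - gi_ref
    }
  }
  attr(out, "global_importance") <- gi_ref
  attr(out, "motif") <- motif
  out
}

#' Write a GIA result as TSV
#'
#' @param x A `gia_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gia <- function(x, path) {
  df <- data.frame(motif = x$motif, global_importance = x$global_importance,
                   n_backgrounds = x$n_backgrounds,
                   positions = paste(x$positions, collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
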