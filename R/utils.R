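#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif predict
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

# deterministic per-stage seed fan-out from one global seed; kept < 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1000 * h) %% .Machine$integer.max)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.", name, min,
                  paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  as.numeric(x)
}

# DNA string <-> integer codes 1..4 (A,C,G,T), 0 for N
seq_to_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, BASES)
  bad <- is.na(codes) & chars != "N"
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Invalid character '%s' at position %d (allowed: A, C, G, T, N).",
                  chars[i], i))
  }
  codes[is.na(codes)] <- 0L
  codes
}

codes_to_seq <- function(codes) {
  paste(c("N", BASES)[codes + 1L], collapse = "")
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Write sequence samples to FASTA and a label table
#'
#' @param samples Tibble with columns `id`, `sequence` and optionally `label`.
#' @param fasta Path for the FASTA file.
#' @param labels Optional path for a tab-separated `id`, `label` table.
#' @return `fasta`, invisibly.
#' @export
write_samples <- function(samples, fasta, labels = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(samples)))
  dna <- Biostrings::DNAStringSet(samples$sequence)
  names(dna) <- samples$id
  Biostrings::writeXStringSet(dna, fasta)
  if (!is.null(labels)) {
    stopifnot("label" %in% names(samples))
    utils::write.table(samples[, c("id", "label")], labels,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read sequence samples from FASTA (optionally with a label table)
#'
#' @param fasta Path to a FASTA file.
#' @param labels Optional path to a tab-separated `id`, `label` table.
#' @return Tibble with columns `id`, `sequence` (and `label` if supplied).
#' @export
read_samples <- function(fasta, labels = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  out <- tibble::tibble(id = names(dna), sequence = unname(as.character(dna)))
  if (!is.null(labels)) {
    lab <- utils::read.table(labels, header = TRUE, sep = "\t",
                             colClasses = c("character", "integer"))
    out <- dplyr::left_join(out, tibble::as_tibble(lab), by = "id")
  }
  out
}
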