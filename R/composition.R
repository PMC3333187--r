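# Tetranucleotide composition: 256-dimensional relative-frequency vectors over
# all 4-mers (lexicographic ACGT order) and the Manhattan distance between
# them, the compositional similarity metric the whole classifier runs on.

KMER_NAMES <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)

as_dna_set <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) return(seqs)
  if (methods::is(seqs, "XString")) return(Biostrings::DNAStringSet(seqs))
  Biostrings::DNAStringSet(setNames(toupper(as.character(seqs)), names(seqs)))
}

# counts + valid-window totals for a whole set at once; the workhorse behind
# tetra_vector() and the index builder. Windows containing any non-ACGT
# symbol are skipped, so the denominator is the number of counted windows.
tetra_counts <- function(seqs, strand = c("forward", "symmetric")) {
  strand <- match.arg(strand)
  x <- as_dna_set(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(x, width = 4, step = 1)
  if (!is.matrix(cnt)) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, names(cnt)))
  if (strand == "symmetric") {
    rc <- Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(x),
                                               width = 4, step = 1)
    if (!is.matrix(rc)) rc <- matrix(rc, nrow = 1, dimnames = list(NULL, names(rc)))
    cnt <- cnt + rc
  }
  list(counts = cnt, n_counted = as.integer(rowSums(cnt)))
}

# counts -> relative frequencies; all-zero rows stay all-zero
freq_from_counts <- function(counts, n_counted) {
  f <- counts / pmax(n_counted, 1L)
  f[n_counted == 0L, ] <- 0
  dimnames(f) <- list(NULL, KMER_NAMES)
  f
}

tetra_matrix <- function(seqs, strand = "forward") {
  tc <- tetra_counts(seqs, strand)
  list(freq = freq_from_counts(tc$counts, tc$n_counted),
       n_counted = tc$n_counted)
}

#' Tetranucleotide frequency vector of a sequence
#'
#' Counts every length-4 window made solely of A/C/G/T (case-insensitive;
#' windows containing N or any other IUPAC symbol are skipped) and divides by
#' the number of counted windows. Sequences with no valid window yield an
#' all-zero vector with `n_counted = 0`; the classifier marks such reads
#' `too_short`.
#'
#' @param seq a DNA string (character, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @param strand `"forward"` counts the sequence exactly as given;
#'   `"symmetric"` adds the reverse-complement windows. All default distance
#'   thresholds are calibrated for `"forward"`.
#' @return an object of class `"kmer_vector"`: list with `values` (named
#'   numeric of length 256 summing to 1 when non-degenerate) and `n_counted`.
#' @examples
#' v <- tetra_vector("AAAAA")
#' v$values[["AAAA"]]  # 1
#' @export
tetra_vector <- function(seq, strand = c("forward", "symmetric")) {
  strand <- match.arg(strand)
  tm <- tetra_matrix(seq, strand)
  if (nrow(tm$freq) != 1L) stop("tetra_vector() expects a single sequence")
  structure(list(values = setNames(tm$freq[1L, ], KMER_NAMES),
                 n_counted = tm$n_counted[1L],
                 strand = strand),
            class = "kmer_vector")
}

#' @export
print.kmer_vector <- function(x, ...) {
  cat("Tetranucleotide vector:", x$n_counted, "windows counted (",
      x$strand, "strand )\n")
  if (x$n_counted > 0) {
    top <- sort(x$values, decreasing = TRUE)[1:5]
    cat("  top 4-mers:",
        paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  }
  invisible(x)
}

kv_values <- function(x) {
  if (inherits(x, "kmer_vector")) {
    if (x$n_counted == 0L) stop("degenerate vector: no counted 4-mer windows")
    return(x$values)
  }
  if (is.numeric(x) && length(x) == 256L) return(x)
  stop("expected a kmer_vector or a numeric vector of length 256")
}

#' Manhattan distance between two composition vectors
#'
#' Sum of absolute coordinate differences; bounded by 2 on normalized
#' frequency vectors.
#'
#' @param a,b [tetra_vector()] objects (or bare numeric vectors of length
#'   256). Degenerate vectors (`n_counted = 0`) are an error.
#' @return a non-negative number.
#' @export
manhattan <- function(a, b) {
  sum(abs(kv_values(a) - kv_values(b)))
}
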